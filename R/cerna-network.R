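## Five-rule ceRNA screen, network assembly and hypergeometric gene-set
## enrichment.

#' The bundled hair-follicle miRNA whitelist
#'
#' The 17 miRNA family names associated with hair-follicle development
#' and cycling that the ceRNA screen's rule (ii) retains. Shipped as an
#' editable text file in `inst/extdata/hf_mirna_whitelist.txt`.
#'
#' @param path Optional path to an alternative whitelist (one name per
#'   line, `#` comments allowed).
#' @return Character vector of miRNA names.
#' @export
hfMirnaWhitelist <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hf_mirna_whitelist.txt",
                        package = "ceRNAcycle", mustWork = TRUE)
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

.CANONICAL_SEEDS <- c("8mer", "7mer-m8", "7mer-A1")

#' Screen for lncRNAs acting as ceRNAs
#'
#' Implements the five screening rules: (i) the lncRNA is
#' differentially expressed with fold change > `fc_threshold` and
#' adjusted p < `alpha` (strict boundaries, as printed for this rule);
#' (ii) the miRNA is on the hair-follicle whitelist; (iii) the
#' lncRNA-mRNA pair has positive expression correlation
#' `r >= r_min` and the mRNA is differentially expressed; (iv) the
#' miRNA has at least one passing binding site on the lncRNA; (v) the
#' miRNA has a passing site on the mRNA that also carries a canonical
#' seed class (8mer/7mer-m8/7mer-A1) — the intersection of the
#' alignment-based and seed-based predictors (`require_seed = FALSE`
#' relaxes rule (v) to the alignment predictor alone).
#'
#' @param lnc_de DE table for lncRNAs ([runDE()] output: `feature_id`,
#'   `log2fc`, `padj`).
#' @param gene_de DE table for coding genes.
#' @param trans_edges Positive-mode edges from [transTargets()].
#' @param lnc_sites,mrna_sites Site tables from [scanSiteTable()] for
#'   lncRNA and mRNA targets (already thresholded by the scanner).
#' @param whitelist Character vector of retained miRNA names
#'   (default [hfMirnaWhitelist()]); empty is an error.
#' @param fc_threshold,alpha Rule (i)/(iii) thresholds (default 2,
#'   0.05).
#' @param r_min Rule (iii) correlation threshold (default 0.95,
#'   inclusive).
#' @param require_seed Rule (v) seed-class requirement (default `TRUE`).
#' @param de_boundary Boundary mode for the DE calls (default
#'   `"strict"`, as the rules print).
#' @return Data.frame of triplets: `lncrna_id`, `mirna`, `mrna_id`,
#'   `r_lnc_mrna`, `n_lnc_sites`, `n_mrna_sites`, `mrna_seed_support`.
#' @export
screenCeRNA <- function(lnc_de, gene_de, trans_edges, lnc_sites,
                        mrna_sites, whitelist = hfMirnaWhitelist(),
                        fc_threshold = 2, alpha = 0.05, r_min = 0.95,
                        require_seed = TRUE,
                        de_boundary = c("strict", "inclusive")) {
  de_boundary <- match.arg(de_boundary)
  if (!length(whitelist)) stop("miRNA whitelist is empty")
  if (is.null(lnc_sites) || is.null(mrna_sites))
    stop("both site tables are required")
  empty <- data.frame(lncrna_id = character(), mirna = character(),
                      mrna_id = character(), r_lnc_mrna = numeric(),
                      n_lnc_sites = integer(), n_mrna_sites = integer(),
                      mrna_seed_support = logical(),
                      stringsAsFactors = FALSE)
  ## rule (i): DE lncRNAs, strict boundaries
  lc <- callDE(lnc_de, fc_threshold = fc_threshold, alpha = alpha,
               boundary = de_boundary)
  de_lnc <- lc$feature_id[lc$call != "ns"]
  ## DEGs for rule (iii)
  gc <- callDE(gene_de, fc_threshold = fc_threshold, alpha = alpha,
               boundary = de_boundary)
  degs <- gc$feature_id[gc$call != "ns"]
  ## rule (iii): positively correlated DE pairs
  pairs <- trans_edges[trans_edges$r >= r_min &
                         trans_edges$lncrna_id %in% de_lnc &
                         trans_edges$gene_id %in% degs, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    L <- pairs$lncrna_id[i]; M <- pairs$gene_id[i]
    for (m in whitelist) {
      ls <- lnc_sites[lnc_sites$mirna == m & lnc_sites$target_id == L, ,
                      drop = FALSE]
      if (!nrow(ls)) next                       # rule (iv)
      ms <- mrna_sites[mrna_sites$mirna == m & mrna_sites$target_id == M, ,
                       drop = FALSE]
      if (!nrow(ms)) next                       # rule (v), alignment part
      seed_ok <- any(ms$seed %in% .CANONICAL_SEEDS)
      if (require_seed && !seed_ok) next        # rule (v), seed part
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = L, mirna = m, mrna_id = M,
        r_lnc_mrna = pairs$r[i],
        n_lnc_sites = nrow(ls), n_mrna_sites = nrow(ms),
        mrna_seed_support = seed_ok, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the ceRNA network graph
#'
#' Nodes are typed `lncRNA`, `miRNA` or `mRNA`; each triplet contributes
#' a negative miRNA-lncRNA edge, a negative miRNA-mRNA edge and a
#' positive lncRNA-mRNA edge weighted by the pair correlation. The
#' graph is deduplicated.
#'
#' @param triplets Data.frame from [screenCeRNA()].
#' @return An [igraph::igraph] graph with vertex attribute `type` and
#'   edge attributes `sign` and `evidence`; the edge list is also
#'   attached as attribute `edges` (a data.frame accepted by
#'   [writeNetworkEdges()]).
#' @export
buildCernaNetwork <- function(triplets) {
  n <- nrow(triplets)
  ed <- rbind(
    data.frame(source = triplets$mirna, source_type = rep("miRNA", n),
               target = triplets$lncrna_id,
               target_type = rep("lncRNA", n),
               sign = rep("-", n), evidence = rep("miranda_site", n),
               stringsAsFactors = FALSE),
    data.frame(source = triplets$mirna, source_type = rep("miRNA", n),
               target = triplets$mrna_id, target_type = rep("mRNA", n),
               sign = rep("-", n),
               evidence = rep("miranda_targetscan_site", n),
               stringsAsFactors = FALSE),
    data.frame(source = triplets$lncrna_id,
               source_type = rep("lncRNA", n),
               target = triplets$mrna_id, target_type = rep("mRNA", n),
               sign = rep("+", n),
               evidence = if (n) paste0("r=", signif(triplets$r_lnc_mrna, 4))
               else character(0),
               stringsAsFactors = FALSE))
  ed <- ed[!duplicated(ed[, c("source", "target")]), , drop = FALSE]
  nodes <- unique(rbind(
    data.frame(name = ed$source, type = ed$source_type,
               stringsAsFactors = FALSE),
    data.frame(name = ed$target, type = ed$target_type,
               stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(
    ed[, c("source", "target", "sign", "evidence")], directed = FALSE,
    vertices = nodes)
  attr(g, "edges") <- ed
  g
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test `P(X >= k)` of a selected gene list
#' against each set (intersected with the universe), with
#' Benjamini-Hochberg correction across sets.
#'
#' @param selected_genes Character vector, must be a subset of
#'   `universe`.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all testable genes (non-empty).
#' @return Data.frame sorted by p: `set_name`, `k_overlap`, `K_set`,
#'   `n_selected`, `N_universe`, `p`, `padj`.
#' @export
enrichPathways <- function(selected_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selected_genes <- unique(selected_genes)
  if (!all(selected_genes %in% universe))
    stop("selected genes must be a subset of the universe")
  N <- length(universe); n <- length(selected_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, selected_genes))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k_overlap = k, K_set = K, n_selected = n,
               N_universe = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
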