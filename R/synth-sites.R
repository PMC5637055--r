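## Planting of miRNA binding sites into transcript sequences, and
## scrubbing of chance seed anchors from decoy sequences.

## mutate the central base of a 6-mer window until no whitelist miRNA
## anchors remain in the sequence outside protected intervals
.scrubAnchors <- function(seq, mirnas, protect = NULL) {
  inProtected <- function(s, e) {
    if (is.null(protect) || !nrow(protect)) return(FALSE)
    any(s <= protect$end & e >= protect$start)
  }
  pats <- vapply(mirnas, function(m)
    .toDNA(.revcompRNA(substr(.toRNA(m), 2L, 7L))), "", USE.NAMES = FALSE)
  for (it in 1:50) {
    hits <- integer(0)
    for (p in pats) {
      a <- .anchorHits(p, seq)
      hits <- c(hits, a[!vapply(a, function(s) inProtected(s, s + 5L),
                                logical(1))])
    }
    if (!length(hits)) return(seq)
    ## break every offending 6-mer at its centre in one pass
    for (pos in unique(hits) + 2L) {
      old <- substr(seq, pos, pos)
      repl <- setdiff(c("A", "C", "G", "T"), old)[sample.int(3L, 1L)]
      seq <- .replaceAt(seq, pos, repl)
    }
  }
  stop("failed to scrub seed anchors from a decoy sequence")
}

#' Plant miRNA binding sites for ceRNA triplets
#'
#' For every planned (lncRNA, miRNA, mRNA) triplet, the exact DNA
#' reverse complement of the full mature miRNA — which contains the
#' reverse complement of positions 1-8, i.e. a canonical 8mer site when
#' the mature starts with U — is written into both the lncRNA and the
#' mRNA sequence at a recorded offset (mRNA sites go into the 3' part
#' of the transcript). All other sequences are then scrubbed free of
#' chance seed anchors for the given miRNA set, so that decoy
#' combinations carry no passing site.
#'
#' @param mirna_set Named character vector of mature miRNA sequences
#'   (RNA alphabet).
#' @param sequences Named character vector of DNA target sequences.
#' @param triplet_plan Data.frame with columns `lncrna_id`, `mirna`,
#'   `mrna_id`; each id must exist in `sequences`/`mirna_set`.
#' @param seed Integer seed for offset choice and scrubbing.
#' @return List with `sequences` (modified vector) and `sites`
#'   (data.frame `mirna`, `target_id`, `role`, `offset`, `seed_start`).
#' @export
plantTargetSites <- function(mirna_set, sequences, triplet_plan,
                             seed = 1L) {
  stopifnot(all(c("lncrna_id", "mirna", "mrna_id") %in%
                  colnames(triplet_plan)))
  if (!all(triplet_plan$mirna %in% names(mirna_set)))
    stop("triplet plan names unknown miRNA(s)")
  ids <- unique(c(triplet_plan$lncrna_id, triplet_plan$mrna_id))
  if (!all(ids %in% names(sequences)))
    stop("triplet plan names unknown sequence(s)")
  .withSeed(seed, {
    sites <- list()
    protect <- list()
    addProtect <- function(id, s, e) {
      protect[[id]] <<- rbind(protect[[id]],
                              data.frame(start = s, end = e))
    }
    plant <- function(target_id, mirna, role) {
      site <- .revcompDNA(.toDNA(mirna_set[[mirna]]))
      L <- nchar(site)
      tlen <- nchar(sequences[[target_id]])
      if (tlen < L + 40L)
        stop("sequence too short to host a site: ", target_id)
      lo <- if (role == "mrna") max(20L, floor(0.6 * tlen)) else 20L
      hi <- tlen - L - 10L
      if (lo > hi) lo <- 20L
      off <- sample(lo:hi, 1L)
      sequences[[target_id]] <<- .replaceAt(sequences[[target_id]], off, site)
      addProtect(target_id, off, off + L - 1L)
      ## seed 6-mer (positions 2-7) sits 7..2 bases from the site 3' end
      sites[[length(sites) + 1L]] <<- data.frame(
        mirna = mirna, target_id = target_id, role = role,
        offset = off, seed_start = off + L - 7L,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(triplet_plan))) {
      plant(triplet_plan$lncrna_id[i], triplet_plan$mirna[i], "lncrna")
      plant(triplet_plan$mrna_id[i], triplet_plan$mirna[i], "mrna")
    }
    site_df <- if (length(sites)) do.call(rbind, sites) else
      data.frame(mirna = character(), target_id = character(),
                 role = character(), offset = integer(),
                 seed_start = integer(), stringsAsFactors = FALSE)
    ## scrub chance anchors everywhere outside the planted intervals
    for (id in names(sequences)) {
      pr <- protect[[id]]
      sequences[[id]] <- .scrubAnchors(sequences[[id]], mirna_set, pr)
    }
    list(sequences = sequences, sites = site_df)
  })
}
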