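## Quantification normalization and negative-binomial differential
## expression between anagen and telogen.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length_bp * total_fragments)`.
#'
#' @param counts An [ExpressionMatrix-class] with unit `count`.
#' @param feature_lengths Named numeric vector of transcript lengths in
#'   bp, covering every feature.
#' @param totals Named numeric vector of total mapped fragments per
#'   sample; defaults to the column sums of `counts`.
#' @return An [ExpressionMatrix-class] with unit `FPKM`.
#' @examples
#' m <- matrix(100, 1, 1, dimnames = list("t1", "s1"))
#' em <- ExpressionMatrix(m, "count", c(s1 = "anagen"))
#' exprValues(computeFPKM(em, c(t1 = 1000), c(s1 = 1e6)))  # 100
#' @export
computeFPKM <- function(counts, feature_lengths, totals = NULL) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprUnit(counts) != "count") stop("counts must have unit 'count'")
  v <- exprValues(counts)
  if (is.null(totals)) totals <- colSums(v)
  if (!all(rownames(v) %in% names(feature_lengths)))
    stop("missing feature length(s): ",
         paste(head(setdiff(rownames(v), names(feature_lengths))), collapse = ", "))
  len <- feature_lengths[rownames(v)]
  if (any(len <= 0)) stop("feature lengths must be > 0")
  if (!all(colnames(v) %in% names(totals))) stop("missing sample total(s)")
  tot <- totals[colnames(v)]
  if (any(tot <= 0)) stop("per-sample totals must be > 0")
  fpkm <- sweep(v * 1e9 / len, 2L, tot, "/")
  ExpressionMatrix(fpkm, unit = "FPKM", groups = sampleGroups(counts))
}

#' Counts per million (the printed small-RNA normalization)
#'
#' `value = count / library_total * 1e6`.
#'
#' @param counts An [ExpressionMatrix-class] with unit `count`.
#' @param totals Named numeric totals of clean reads per library;
#'   defaults to column sums.
#' @return An [ExpressionMatrix-class] with unit `CPM`.
#' @export
cpmNormalize <- function(counts, totals = NULL) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprUnit(counts) != "count") stop("counts must have unit 'count'")
  v <- exprValues(counts)
  if (is.null(totals)) totals <- colSums(v)
  if (!all(colnames(v) %in% names(totals))) stop("missing library total(s)")
  tot <- totals[colnames(v)]
  if (any(tot <= 0)) stop("library totals must be > 0")
  ExpressionMatrix(sweep(v, 2L, tot, "/") * 1e6, unit = "CPM",
                   groups = sampleGroups(counts))
}

#' Median-of-ratios size factors
#'
#' DESeq-style: per sample, the median ratio of counts to the per-feature
#' geometric mean; features whose geometric mean is zero (any zero count)
#' are excluded from the reference.
#'
#' @param counts Numeric count matrix (features x samples).
#' @return Named numeric vector of positive size factors.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  counts <- as.matrix(counts)
  gm <- exp(rowMeans(log(counts)))
  use <- is.finite(gm) & gm > 0
  if (!any(use))
    return(setNames(rep(1, ncol(counts)), colnames(counts)))
  sf <- apply(counts, 2L, function(cc) median(cc[use] / gm[use]))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor; check the count matrix")
  sf
}

#' Estimate per-feature NB dispersion (method of moments)
#'
#' On size-factor-normalized counts, the within-group sample variances
#' are pooled and `phi = max(0, (s2 - m) / m^2)` with `m` the overall
#' normalized mean, matching the parameterization
#' `variance = mu + phi * mu^2`. Features with all-zero counts get
#' `phi = 0` and are flagged.
#'
#' @param counts An [ExpressionMatrix-class] with unit `count`, at least
#'   two samples per stage.
#' @return An [NBModel-class].
#' @seealso [nbWaldTest()]
#' @export
estimateDispersion <- function(counts) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprUnit(counts) != "count") stop("counts must have unit 'count'")
  v <- exprValues(counts)
  grp <- sampleGroups(counts)
  ns <- table(factor(grp, levels = .GROUPS))
  if (any(ns < 2L)) stop("need >= 2 samples per group to estimate dispersion")
  sf <- sizeFactorsMedianRatio(v)
  nv <- sweep(v, 2L, sf, "/")
  ia <- which(grp == "anagen"); it <- which(grp == "telogen")
  va <- apply(nv[, ia, drop = FALSE], 1L, var)
  vt <- apply(nv[, it, drop = FALSE], 1L, var)
  s2 <- ((length(ia) - 1L) * va + (length(it) - 1L) * vt) /
    (length(ia) + length(it) - 2L)
  m <- rowMeans(nv)
  phi <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  flagged <- rownames(v)[rowSums(v) == 0]
  new("NBModel", dispersion = setNames(phi, rownames(v)),
      sizeFactors = sf, flagged = flagged)
}

#' Negative-binomial Wald test (anagen versus telogen)
#'
#' The log2 fold change is `log2((mA + c) / (mT + c))` on size-factor
#' normalized group means with pseudocount `c`; its standard error comes
#' from the delta method under `var(count) = mu + phi * mu^2`, and the
#' two-sided p-value from the normal reference. By default each
#' feature's dispersion is floored at the across-feature median
#' (`moderate = TRUE`), a conservative moderation in the spirit of early
#' DESeq's max(per-gene, fitted) rule that keeps the test calibrated at
#' 3 + 3 replicates; set `moderate = FALSE` for the raw per-feature
#' estimates. Features with zero counts in both groups are reported with
#' `log2fc = 0`, `p = 1` and flagged.
#'
#' @param counts An [ExpressionMatrix-class] with unit `count`.
#' @param model An [NBModel-class] from [estimateDispersion()].
#' @param pseudocount Pseudocount `c` on normalized group means
#'   (default 1).
#' @param moderate Floor dispersions at their median (default `TRUE`).
#' @return Data.frame with `feature_id`, `mean_anagen`, `mean_telogen`
#'   (normalized group means), `log2fc`, `p`, `flagged`.
#' @export
nbWaldTest <- function(counts, model, pseudocount = 1, moderate = TRUE) {
  stopifnot(is(counts, "ExpressionMatrix"), is(model, "NBModel"))
  v <- exprValues(counts)
  grp <- sampleGroups(counts)
  ia <- which(grp == "anagen"); it <- which(grp == "telogen")
  if (!length(ia) || !length(it)) stop("both groups must be present")
  if (min(length(ia), length(it)) < 3L)
    warning("fewer than 3 replicates in a group: ",
            "dispersion estimation is unstable (pooled sRNA libraries)")
  if (!all(rownames(v) %in% names(dispersions(model))))
    stop("model does not cover all features")
  phi <- dispersions(model)[rownames(v)]
  if (moderate) phi <- pmax(phi, median(phi))
  nv <- sweep(v, 2L, sizeFactors(model)[colnames(v)], "/")
  mA <- rowMeans(nv[, ia, drop = FALSE])
  mT <- rowMeans(nv[, it, drop = FALSE])
  lfc <- log2((mA + pseudocount) / (mT + pseudocount))
  varA <- (mA + phi * mA^2) / length(ia)
  varT <- (mT + phi * mT^2) / length(it)
  se <- sqrt(varA / (mA + pseudocount)^2 + varT / (mT + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(z))
  dead <- mA == 0 & mT == 0
  lfc[dead] <- 0; p[dead] <- 1
  data.frame(feature_id = rownames(v), mean_anagen = mA, mean_telogen = mT,
             log2fc = lfc, p = p, flagged = dead,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min over j >= i of m * p_(j) / j`, clipped at 1 and mapped
#' back to the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- pmin(1, rev(cummin(rev(m * pvalues[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Call differential expression
#'
#' With the default inclusive boundary, `up` means
#' `log2fc >= log2(fc_threshold)` and `padj <= alpha`, `down` the
#' mirrored condition, everything else `ns`. With `boundary = "strict"`
#' the comparisons become `>` / `<` (the convention the ceRNA screen's
#' rule (i) prints).
#'
#' @param results Data.frame with columns `log2fc` and `padj` (and
#'   optionally `p`).
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param boundary `"inclusive"` (default) or `"strict"`.
#' @return `results` with a `call` column in `{up, down, ns}`.
#' @export
callDE <- function(results, fc_threshold = 2, alpha = 0.05,
                   boundary = c("inclusive", "strict")) {
  boundary <- match.arg(boundary)
  if (!all(c("log2fc", "padj") %in% colnames(results)))
    stop("results must have log2fc and padj columns")
  l2 <- log2(fc_threshold)
  if (boundary == "inclusive") {
    up <- results$log2fc >= l2 & results$padj <= alpha
    dn <- results$log2fc <= -l2 & results$padj <= alpha
  } else {
    up <- results$log2fc > l2 & results$padj < alpha
    dn <- results$log2fc < -l2 & results$padj < alpha
  }
  results$call <- ifelse(up, "up", ifelse(dn, "down", "ns"))
  results
}

#' One-call differential expression pipeline
#'
#' Size factors, method-of-moments dispersion, NB Wald test, BH
#' adjustment and threshold calls in one step.
#'
#' @inheritParams nbWaldTest
#' @inheritParams callDE
#' @return Data.frame with `feature_id`, `mean_anagen`, `mean_telogen`,
#'   `log2fc`, `p`, `padj`, `call`.
#' @examples
#' \dontrun{
#' de <- runDE(bundle@mrnaCounts)
#' table(de$call)
#' }
#' @export
runDE <- function(counts, fc_threshold = 2, alpha = 0.05,
                  boundary = c("inclusive", "strict"),
                  pseudocount = 1, moderate = TRUE) {
  boundary <- match.arg(boundary)
  model <- estimateDispersion(counts)
  res <- nbWaldTest(counts, model, pseudocount = pseudocount,
                    moderate = moderate)
  res$padj <- bhAdjust(res$p)
  callDE(res, fc_threshold = fc_threshold, alpha = alpha,
         boundary = boundary)
}
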