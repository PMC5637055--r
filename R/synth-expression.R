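## Negative-binomial expression simulation with planted differential
## expression and planted co-expression via shared per-sample latent
## factors.

#' Simulate a count matrix with planted truth
#'
#' Counts are drawn from a negative binomial with
#' `variance = mu + phi * mu^2` (`phi = 0` degenerates to Poisson).
#' Features with a non-zero `log2fc` have their anagen mean multiplied
#' by `2^log2fc`. Features sharing a `factor_group` label are coupled
#' through a per-sample log-normal latent factor of standard deviation
#' `factor_sd` (on the log scale), which plants an expression
#' correlation between them.
#'
#' @param features Data.frame with columns `id`, `mean` (> 0),
#'   `dispersion` (>= 0; an error otherwise), and optionally `log2fc`
#'   (default 0), `factor_group` (default `NA`: uncoupled) and
#'   `factor_sd` (default 0).
#' @param n_anagen,n_telogen Samples per stage (default 3 + 3).
#' @param seed Integer seed; the result is deterministic given inputs.
#' @return List with `counts` (an [ExpressionMatrix-class], unit
#'   `count`, samples `anagen_1..n`, `telogen_1..n`) and `truth`
#'   (list with `de`: features with planted `log2fc != 0`;
#'   `correlated`: the factor-group pairs).
#' @examples
#' f <- data.frame(id = c("a", "b"), mean = 100, dispersion = 0.05,
#'                 log2fc = c(0, 2))
#' sim <- simulateExpression(f, seed = 1)
#' exprValues(sim$counts)
#' @export
simulateExpression <- function(features, n_anagen = 3L, n_telogen = 3L,
                               seed = 1L) {
  stopifnot(is.data.frame(features),
            all(c("id", "mean", "dispersion") %in% colnames(features)))
  if (any(features$dispersion < 0)) stop("dispersion must be >= 0")
  if (any(features$mean <= 0)) stop("means must be > 0")
  if (anyDuplicated(features$id)) stop("duplicate feature ids")
  if (is.null(features$log2fc)) features$log2fc <- 0
  if (is.null(features$factor_group))
    features$factor_group <- NA_character_
  if (is.null(features$factor_sd)) features$factor_sd <- 0
  n <- nrow(features)
  samples <- c(sprintf("anagen_%d", seq_len(n_anagen)),
               sprintf("telogen_%d", seq_len(n_telogen)))
  groups <- setNames(rep(c("anagen", "telogen"), c(n_anagen, n_telogen)),
                     samples)
  .withSeed(seed, {
    ## per-sample latent factors, one draw per factor group
    fg <- unique(stats::na.omit(features$factor_group))
    fac <- matrix(1, length(fg), length(samples),
                  dimnames = list(fg, samples))
    for (g in fg) {
      sdg <- features$factor_sd[match(g, features$factor_group)]
      fac[g, ] <- exp(rnorm(length(samples), 0, sdg))
    }
    mu <- matrix(features$mean, n, length(samples),
                 dimnames = list(features$id, samples))
    up <- groups == "anagen"
    mu[, up] <- mu[, up] * 2^features$log2fc
    coupled <- !is.na(features$factor_group)
    if (any(coupled))
      mu[coupled, ] <- mu[coupled, ] * fac[features$factor_group[coupled], ,
                                           drop = FALSE]
    counts <- matrix(0, n, length(samples),
                     dimnames = list(features$id, samples))
    for (j in seq_along(samples)) {
      poisson <- features$dispersion == 0
      if (any(poisson))
        counts[poisson, j] <- rpois(sum(poisson), mu[poisson, j])
      if (any(!poisson))
        counts[!poisson, j] <- rnbinom(sum(!poisson),
                                       mu = mu[!poisson, j],
                                       size = 1 / features$dispersion[!poisson])
    }
    de <- features[features$log2fc != 0, c("id", "log2fc"), drop = FALSE]
    corr <- features[coupled, c("id", "factor_group", "factor_sd"),
                     drop = FALSE]
    list(counts = ExpressionMatrix(counts, "count", groups),
         truth = list(de = de, correlated = corr))
  })
}
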