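# Contribution-to-variance sensitivity in the Crystal-Ball sense: the squared
# Spearman rank correlation between each sampled input and the output,
# normalised so contributions over the varying inputs sum to 100%.

#' Contribution-to-variance sensitivity analysis
#'
#' For each varying input, computes the Spearman rank correlation with the
#' per-iteration output; the contribution is the squared rank correlation as
#' a share of the sum over varying inputs (so contributions sum to exactly
#' 100%), with the correlation's sign reported as the direction of
#' association. Inputs held at a point distribution have zero variance and
#' are reported with contribution 0.
#'
#' @param draws A data frame of per-symbol input draws (columns = symbols,
#'   rows = iterations), e.g. `mc_result$draws`.
#' @param output Per-iteration output (risk) values, aligned with `draws`.
#' @return A tibble with columns `symbol`, `contribution` (percent), `sign`
#'   (`+1`/`-1`/`NA` for fixed inputs), `rank_correlation`, `method`.
#' @export
contribution_to_variance <- function(draws, output) {
  draws <- as.data.frame(draws)
  if (nrow(draws) != length(output)) {
    stop("draws and output must be aligned by iteration", call. = FALSE)
  }
  if (stats::var(output) == 0) {
    stop("output has zero variance; nothing to attribute", call. = FALSE)
  }
  varying <- vapply(draws, function(v) stats::var(v) > 0, logical(1))
  if (!any(varying)) stop("no varying inputs", call. = FALSE)
  rho <- rep(NA_real_, ncol(draws))
  names(rho) <- names(draws)
  rho[varying] <- vapply(draws[varying], function(v) {
    stats::cor(v, output, method = "spearman")
  }, numeric(1))
  contrib <- rep(0, ncol(draws))
  contrib[varying] <- 100 * rho[varying]^2 / sum(rho[varying]^2)
  tibble::tibble(
    symbol = names(draws),
    contribution = contrib,
    sign = unname(ifelse(varying, sign(rho), NA_real_)),
    rank_correlation = unname(rho),
    method = "squared-rank-correlation"
  )
}

#' First-order variance contributions by binning (cross-check)
#'
#' A plain variance-based estimate of first-order sensitivity: bins each
#' input into quantile bins, computes the variance of the within-bin output
#' means relative to the total output variance, and normalises across varying
#' inputs to 100%. Useful as an independent check on
#' [contribution_to_variance()]; not its replacement.
#'
#' @param draws Per-symbol input draws.
#' @param output Per-iteration output values.
#' @param bins Number of quantile bins (default 20).
#' @return A tibble with `symbol` and `contribution` (percent).
#' @export
binned_variance_contribution <- function(draws, output, bins = 20) {
  draws <- as.data.frame(draws)
  stopifnot(nrow(draws) == length(output))
  total_var <- stats::var(output)
  if (total_var == 0) stop("output has zero variance", call. = FALSE)
  s1 <- vapply(draws, function(v) {
    if (stats::var(v) == 0) return(0)
    b <- cut(v, breaks = unique(stats::quantile(v, seq(0, 1, length.out = bins + 1))),
             include.lowest = TRUE)
    means <- tapply(output, b, mean)
    stats::var(means[!is.na(means)]) / total_var
  }, numeric(1))
  tot <- sum(s1)
  tibble::tibble(symbol = names(draws),
                 contribution = if (tot > 0) 100 * s1 / tot else s1)
}
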