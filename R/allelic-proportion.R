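#' Allelic proportion from two-channel assay areas
#'
#' Converts raw two-channel area measurements to an allelic proportion on
#' \[0, 1\] by a polar-coordinate transform. Each channel area is first
#' adjusted by its uncertainty and clamped at zero,
#' \eqn{x = \max(a_1 - u_1, 0)}, \eqn{y = \max(a_2 - u_2, 0)}, and the
#' proportion is \eqn{p = \mathrm{atan2}(y, x) / (\pi/2)}, so that 0
#' corresponds to a pure A signal and 1 to a pure B signal. Assays whose
#' adjusted intensity \eqn{x + y} falls below `min_intensity` are treated as
#' failed reactions and set to missing.
#'
#' The failure rule is strict (`< min_intensity`) for individual samples and
#' inclusive (`<= min_intensity`) for pooled samples, matching the slightly
#' different conventions used for the two assay types. Assays where both
#' channels clamp to zero are always missing.
#'
#' @param a1,u1 Area and uncertainty for the A-allele channel (platform
#'   units, non-negative).
#' @param a2,u2 Area and uncertainty for the B-allele channel.
#' @param min_intensity Minimum adjusted intensity for a usable assay
#'   (default 3.0).
#' @param pool Logical; use the inclusive failure rule for pooled assays.
#' @return A data frame with columns `p` (allelic proportion, `NA` when the
#'   reaction failed) and `adjusted_intensity`.
#' @examples
#' allelic_proportion(10, 1, 4, 1)   # p = atan(3/9) / (pi/2)
#' allelic_proportion(5, 0, 5, 0)    # p = 0.5
#' @export
allelic_proportion <- function(a1, u1, a2, u2, min_intensity = 3, pool = FALSE) {
  vals <- cbind(a1 = a1, u1 = u1, a2 = a2, u2 = u2)
  if (any(!is.finite(vals)))
    stop("areas and uncertainties must be finite")
  if (any(vals < 0))
    stop("areas and uncertainties must be non-negative")
  x <- pmax(a1 - u1, 0)
  y <- pmax(a2 - u2, 0)
  r <- x + y
  p <- atan2(y, x) / (pi / 2)
  failed <- if (pool) r <= min_intensity else r < min_intensity
  p[failed | (x == 0 & y == 0)] <- NA_real_
  data.frame(p = p, adjusted_intensity = r)
}

#' Welch statistic for cluster separation
#'
#' Unequal-variance t-statistic between two genotype clusters,
#' \eqn{|m_2 - m_1| / \sqrt{s_1^2/n_1 + s_2^2/n_2}}. Used as a measure of
#' how well an interval of the allelic-proportion axis resolves adjacent
#' genotype classes.
#'
#' @param mean1,sd1,n1 Mean, standard deviation and size of the first cluster.
#' @param mean2,sd2,n2 As above for the second cluster.
#' @return The Welch statistic (non-negative scalar, vectorised).
#' @export
welch_statistic <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(n1, n2) < 2))
    stop("welch_statistic() needs at least 2 observations per cluster")
  if (any(c(sd1, sd2) <= 0))
    stop("welch_statistic() needs positive standard deviations")
  abs(mean2 - mean1) / sqrt(sd1^2 / n1 + sd2^2 / n2)
}
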