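#' Allele frequency from a pooled allelic proportion
#'
#' Maps the allelic proportion of a pooled DNA assay to a B-allele
#' frequency estimate using the SNP's calibrated cluster means as anchor
#' points: 0 at and below `mu_AA`, 0.5 at `mu_AB`, 1 at and above `mu_BB`,
#' with linear interpolation inside the two intervals.
#'
#' @param p Pooled allelic proportion(s); `NA` propagates.
#' @param mu_AA,mu_AB,mu_BB Cluster means for the SNP (vectors recycle
#'   against `p`).
#' @return Frequency estimate(s) in \[0, 1\] (`NA` when `p` or any mean is
#'   missing, e.g. for an unusable SNP).
#' @export
pooled_allele_frequency <- function(p, mu_AA, mu_AB, mu_BB) {
  lower <- 0.5 * (p - mu_AA) / (mu_AB - mu_AA)
  upper <- 0.5 + 0.5 * (p - mu_AB) / (mu_BB - mu_AB)
  f <- ifelse(p <= mu_AB, pmax(lower, 0), pmin(upper, 1))
  f[is.na(p) | is.na(mu_AA) | is.na(mu_AB) | is.na(mu_BB)] <- NA_real_
  f
}

#' Inverse of the pooled-frequency map
#'
#' Maps a true B-allele frequency back to the allelic-proportion axis using
#' the same cluster-mean anchors; used by the simulator to synthesise
#' pooled assays.
#'
#' @param f Frequency in \[0, 1\].
#' @inheritParams pooled_allele_frequency
#' @return Allelic proportion(s).
#' @export
frequency_to_proportion <- function(f, mu_AA, mu_AB, mu_BB) {
  ifelse(f <= 0.5,
         mu_AA + (f / 0.5) * (mu_AB - mu_AA),
         mu_AB + ((f - 0.5) / 0.5) * (mu_BB - mu_AB))
}

#' Welch-statistic weight for a pooled frequency estimate
#'
#' Returns the Welch statistic of the inter-cluster interval containing the
#' pooled proportion: `tau_A` when `p <= mu_AB`, `tau_B` otherwise. The
#' downstream least-squares weight is the square of this value; missing
#' estimates receive weight 1.
#'
#' @param p Pooled allelic proportion(s).
#' @param mu_AB Heterozygote cluster mean(s).
#' @param tau_A,tau_B Welch statistics of the two intervals.
#' @return `tau` value(s), `NA` where `p` is missing.
#' @export
pool_weight <- function(p, mu_AB, tau_A, tau_B) {
  ifelse(p <= mu_AB, tau_A, tau_B)
}

#' Individual-based pool allele frequency
#'
#' The pool frequency implied by the individual samples known to be in the
#' pool: the mean over members (with a non-missing proportion at the SNP)
#' of the piecewise-mapped individual allelic proportions.
#'
#' @param p SNP-by-sample matrix of individual allelic proportions.
#' @param members Character vector of member sample ids.
#' @param panel Calibration data frame (rows aligned with `p`).
#' @return Named numeric vector of per-SNP frequencies (`NA` when no member
#'   has data).
#' @export
individual_pool_frequency <- function(p, members, panel) {
  stopifnot(all(members %in% colnames(p)))
  panel <- panel[rownames(p), ]
  pm <- p[, members, drop = FALSE]
  fm <- pooled_allele_frequency(pm, panel$mu_AA, panel$mu_AB, panel$mu_BB)
  f <- rowMeans(matrix(fm, nrow(pm), ncol(pm)), na.rm = TRUE)
  f[is.nan(f)] <- NA_real_
  names(f) <- rownames(p)
  f
}

#' Expected family allele frequencies
#'
#' Builds the design matrix **X** of the contribution-deconvolution
#' problem: entry (j, l) is the expected offspring B-allele frequency of
#' family l at SNP j, `(T_sire[B] + T_dam[B]) / 2`, from the parents'
#' genotype matrices. A structurally missing parent (`NA` id) contributes
#' the population frequency `f_B`; a named parent with no genotype at a SNP
#' leaves the cell `NA` (filled with 0.5 by [estimate_contributions()]).
#'
#' @param families Data frame with columns `family_id`, `sire_id`, `dam_id`
#'   (`NA` ids allowed).
#' @param store Quantitative `genotype_store` holding the parents.
#' @param freq Allele-frequency data frame (`snp_id`, `f_A`, `f_B`).
#' @return SNP-by-family matrix with families as columns.
#' @export
family_frequency_matrix <- function(families, store, freq) {
  stopifnot(inherits(store, "genotype_store"))
  freq <- freq[match(store$snp_id, freq$snp_id), ]
  fB <- fill_freq(freq$f_B, store_active_snps(store))
  tB <- store$gBB + (store$gAB + store$gBA) / 2
  col_for <- function(id) {
    if (is.na(id)) return(fB)
    if (!id %in% store$sample_id)
      stop("parent absent from genotype store: ", id)
    tB[, id]
  }
  X <- vapply(seq_len(nrow(families)), function(l) {
    (col_for(families$sire_id[l]) + col_for(families$dam_id[l])) / 2
  }, numeric(length(store$snp_id)))
  X <- matrix(X, nrow = length(store$snp_id))
  dimnames(X) <- list(store$snp_id, families$family_id)
  X
}

#' Family contributions to a pool by weighted non-negative least squares
#'
#' Solves `min || sqrt(w) (X beta - y) ||^2` subject to `beta >= 0`, then
#' rescales the solution to sum to 1. `X` holds expected family allele
#' frequencies (SNPs by families), `y` the pooled frequency estimates, and
#' `w` the per-SNP weights (squared Welch statistics). Missing cells in `X`
#' and `y` are pre-filled with 0.5 and missing weights with 1. The
#' non-negativity constraint stands in for the strictly-positive constraint
#' of the estimation problem: zero is the meaningful boundary for a family
#' absent from the pool.
#'
#' @param X SNP-by-family matrix of expected family allele frequencies.
#' @param y Vector of pooled frequency estimates (length `nrow(X)`).
#' @param w Vector of weights (default all 1).
#' @return A `contribution_estimate`: list with `beta` (rescaled, sums
#'   to 1), `beta_raw` (solver output), `sum_raw`, `family_id`, and
#'   `unidentifiable` (families whose `X` column was all zero).
#' @export
estimate_contributions <- function(X, y, w = NULL) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (is.null(w)) w <- rep(1, nrow(X))
  stopifnot(length(w) == nrow(X))
  unident <- colnames(X)[apply(X, 2, function(col) all(!is.na(col) & col == 0))]
  if (length(unident))
    warning("all-zero design column(s); contribution unidentifiable for: ",
            paste(unident, collapse = ", "), call. = FALSE)
  X[is.na(X)] <- 0.5
  y[is.na(y)] <- 0.5
  w[is.na(w)] <- 1
  stopifnot(all(w > 0))
  sw <- sqrt(w)
  fit <- pracma::lsqnonneg(sw * X, sw * y)
  beta_raw <- fit$x
  s <- sum(beta_raw)
  beta <- if (s > 0) beta_raw / s else rep(1 / ncol(X), ncol(X))
  names(beta) <- names(beta_raw) <- colnames(X)
  structure(list(beta = beta, beta_raw = beta_raw, sum_raw = s,
                 family_id = colnames(X), unidentifiable = unident),
            class = "contribution_estimate")
}

#' @export
print.contribution_estimate <- function(x, ...) {
  cat(sprintf("<contribution_estimate: %d families, sum(beta*) = %.3f>\n",
              length(x$beta), x$sum_raw))
  print(round(x$beta, 4))
  invisible(x)
}
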