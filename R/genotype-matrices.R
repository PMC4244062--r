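allele_names <- c("A", "B")

new_genotype_matrix <- function(gAA, gAB, gBA, gBB) {
  matrix(c(gAA, gBA, gAB, gBB), 2, 2,
         dimnames = list(paternal = allele_names, maternal = allele_names))
}

#' Quantitative genotype probability matrix
#'
#' Builds the 2x2 ordered genotype probability matrix for one assay from its
#' allelic proportion and the SNP's calibrated cluster parameters. The
#' unnormalised entry for AA is the height of the N(mu_AA, sigma_AA) density
#' at `p`, the two ordered heterozygote entries are each half the height of
#' the N(mu_AB, sigma_AB) density, and BB is the height of the
#' N(mu_BB, sigma_BB) density; entries are then normalised to sum to 1.
#' Densities are evaluated on the log scale with max-subtraction before
#' exponentiation so extreme proportions cannot underflow to an all-zero
#' matrix; should every log-density be non-finite the genotype is missing.
#'
#' @param p Allelic proportion in \[0, 1\].
#' @param mu Length-3 numeric, cluster means `c(AA, AB, BB)`.
#' @param sigma Length-3 numeric, cluster standard deviations.
#' @return A 2x2 genotype probability matrix (rows: paternal allele,
#'   columns: maternal allele), or `NULL` when the genotype cannot be
#'   estimated.
#' @export
quantitative_genotype_matrix <- function(p, mu, sigma) {
  if (is.na(p) || anyNA(mu) || anyNA(sigma)) return(NULL)
  lAA <- stats::dnorm(p, mu[1], sigma[1], log = TRUE)
  lhet <- stats::dnorm(p, mu[2], sigma[2], log = TRUE) + log(0.5)
  lBB <- stats::dnorm(p, mu[3], sigma[3], log = TRUE)
  logs <- c(lAA, lhet, lhet, lBB)
  m <- max(logs)
  if (!is.finite(m)) return(NULL)
  w <- exp(logs - m)
  w <- w / sum(w)
  new_genotype_matrix(w[1], w[2], w[3], w[4])
}

#' Discrete genotype matrix from a quantitative genotype
#'
#' Collapses a quantitative genotype matrix to a discrete call when the most
#' likely unordered genotype is sufficiently certain: a homozygote is called
#' when its probability exceeds `call_threshold`, a heterozygote when either
#' ordered heterozygote cell exceeds `call_threshold / 2`. Heterozygote mass
#' is stored as 0.5/0.5 over the two ordered cells.
#'
#' @param g Quantitative genotype matrix.
#' @param call_threshold Certainty needed to declare a genotype
#'   (default 0.98).
#' @return A discrete 2x2 genotype matrix, or `NULL` when no genotype
#'   reaches the threshold.
#' @export
discrete_genotype_matrix <- function(g, call_threshold = 0.98) {
  if (is.null(g)) return(NULL)
  if (g[1, 1] > call_threshold) return(new_genotype_matrix(1, 0, 0, 0))
  if (g[2, 2] > call_threshold) return(new_genotype_matrix(0, 0, 0, 1))
  if (max(g[1, 2], g[2, 1]) > call_threshold / 2)
    return(new_genotype_matrix(0, 0.5, 0.5, 0))
  NULL
}

#' Error-perturbed genotype matrix
#'
#' Mixes a discrete genotype with the population genotype distribution at an
#' assumed error rate: `M = (1 - eps) * D + eps * F F'`, where `F` is the
#' allele-frequency vector for the SNP.
#'
#' @param d Discrete genotype matrix.
#' @param eps Error rate in \[0, 1\].
#' @param freq Length-2 allele-frequency vector `c(f_A, f_B)`.
#' @return Perturbed 2x2 genotype matrix, or `NULL` when `d` is missing.
#' @export
perturbed_genotype_matrix <- function(d, eps, freq) {
  if (is.null(d)) return(NULL)
  stopifnot(eps >= 0, eps <= 1)
  (1 - eps) * d + eps * missing_parent_matrix(freq)
}

#' Genotype matrix for a missing parent
#'
#' Outer product of the allele-frequency vector, `F F'`: the ordered genotype
#' distribution expected under Hardy-Weinberg proportions. Used in trio
#' likelihoods when a parent is untyped, and as the null (unrelated)
#' genotype distribution.
#'
#' @param freq Length-2 allele-frequency vector `c(f_A, f_B)` summing to 1.
#' @return A 2x2 genotype probability matrix.
#' @export
missing_parent_matrix <- function(freq) {
  stopifnot(length(freq) == 2, abs(sum(freq) - 1) < 1e-6, all(freq >= 0))
  m <- outer(freq, freq)
  dimnames(m) <- list(paternal = allele_names, maternal = allele_names)
  m
}

## ---- genotype stores: one matrix slice per ordered-genotype cell ----------

#' Quantitative genotypes for a whole panel
#'
#' Vectorised construction of quantitative genotype matrices for every
#' (SNP, sample) cell of a proportion matrix. The result is a *genotype
#' store*: four SNP-by-sample matrices `gAA`, `gAB`, `gBA`, `gBB` holding the
#' ordered genotype probabilities, with `NA` where the genotype is missing
#' (failed assay or unusable SNP).
#'
#' @param p SNP-by-sample proportion matrix (rows must match `panel`).
#' @param panel Calibration data frame from [calibrate_panel()].
#' @return A `genotype_store` object.
#' @export
quantitative_genotypes <- function(p, panel) {
  stopifnot(all(rownames(p) %in% panel$snp_id))
  panel <- panel[rownames(p), ]
  n_snp <- nrow(p); n_sam <- ncol(p)
  slice <- function() matrix(NA_real_, n_snp, n_sam, dimnames = dimnames(p))
  gAA <- slice(); gAB <- slice(); gBA <- slice(); gBB <- slice()
  for (j in seq_len(n_snp)) {
    if (!isTRUE(panel$usable[j])) next
    pj <- p[j, ]
    ok <- !is.na(pj)
    if (!any(ok)) next
    lAA <- stats::dnorm(pj[ok], panel$mu_AA[j], panel$sigma_AA[j], log = TRUE)
    lhet <- stats::dnorm(pj[ok], panel$mu_AB[j], panel$sigma_AB[j], log = TRUE) + log(0.5)
    lBB <- stats::dnorm(pj[ok], panel$mu_BB[j], panel$sigma_BB[j], log = TRUE)
    m <- pmax(lAA, lhet, lBB)
    wAA <- exp(lAA - m); whet <- exp(lhet - m); wBB <- exp(lBB - m)
    tot <- wAA + 2 * whet + wBB
    gAA[j, ok] <- wAA / tot
    gAB[j, ok] <- whet / tot
    gBA[j, ok] <- whet / tot
    gBB[j, ok] <- wBB / tot
  }
  new_genotype_store(gAA, gAB, gBA, gBB, kind = "quantitative")
}

new_genotype_store <- function(gAA, gAB, gBA, gBB, kind) {
  structure(list(gAA = gAA, gAB = gAB, gBA = gBA, gBB = gBB,
                 snp_id = rownames(gAA), sample_id = colnames(gAA),
                 kind = kind),
            class = "genotype_store")
}

#' @export
print.genotype_store <- function(x, ...) {
  cat(sprintf("<genotype_store: %s, %d SNPs x %d samples, %.1f%% missing>\n",
              x$kind, nrow(x$gAA), ncol(x$gAA),
              100 * mean(is.na(x$gAA))))
  invisible(x)
}

#' Extract one genotype matrix from a store
#'
#' @param store A `genotype_store`.
#' @param snp,sample SNP and sample identifiers (or indices).
#' @return A 2x2 genotype matrix or `NULL` when missing.
#' @export
store_matrix <- function(store, snp, sample) {
  v <- c(store$gAA[snp, sample], store$gAB[snp, sample],
         store$gBA[snp, sample], store$gBB[snp, sample])
  if (anyNA(v)) return(NULL)
  new_genotype_matrix(v[1], v[2], v[3], v[4])
}

#' Discrete genotypes for a whole panel
#'
#' Applies the [discrete_genotype_matrix()] calling rule to every cell of a
#' quantitative genotype store.
#'
#' @param store Quantitative `genotype_store`.
#' @param call_threshold Certainty threshold (default 0.98).
#' @return A discrete `genotype_store` (cells `NA` when uncalled).
#' @export
discrete_genotypes <- function(store, call_threshold = 0.98) {
  stopifnot(inherits(store, "genotype_store"))
  hetmax <- pmax(store$gAB, store$gBA)
  isAA <- store$gAA > call_threshold
  isBB <- store$gBB > call_threshold
  ishet <- hetmax > call_threshold / 2 & !isAA & !isBB
  called <- !is.na(store$gAA) & (isAA | isBB | ishet)
  blank <- matrix(NA_real_, nrow(store$gAA), ncol(store$gAA),
                  dimnames = dimnames(store$gAA))
  gAA <- gAB <- gBA <- gBB <- blank
  gAA[which(called)] <- 0; gAB[which(called)] <- 0
  gBA[which(called)] <- 0; gBB[which(called)] <- 0
  gAA[which(called & isAA)] <- 1
  gBB[which(called & isBB)] <- 1
  gAB[which(called & ishet)] <- 0.5
  gBA[which(called & ishet)] <- 0.5
  new_genotype_store(gAA, gAB, gBA, gBB, kind = "discrete")
}

#' Error-perturbed genotypes for a whole panel
#'
#' Applies [perturbed_genotype_matrix()] cellwise with per-SNP error rates
#' and allele frequencies.
#'
#' @param dstore Discrete `genotype_store`.
#' @param eps Numeric vector of per-SNP error rates aligned with the store's
#'   SNPs (recycled if length 1).
#' @param freq Data frame with columns `snp_id`, `f_A`, `f_B` (see
#'   [estimate_allele_frequencies()]).
#' @return A perturbed `genotype_store`.
#' @export
perturbed_genotypes <- function(dstore, eps, freq) {
  stopifnot(inherits(dstore, "genotype_store"), dstore$kind == "discrete")
  n_snp <- length(dstore$snp_id)
  eps <- rep_len(eps, n_snp)
  freq <- freq[match(dstore$snp_id, freq$snp_id), ]
  active <- store_active_snps(dstore)
  fA <- fill_freq(freq$f_A, active)
  fB <- fill_freq(freq$f_B, active)
  mix <- function(d, hw) (1 - eps) * d + eps * hw  # columns recycle over SNPs
  new_genotype_store(mix(dstore$gAA, fA * fA), mix(dstore$gAB, fA * fB),
                     mix(dstore$gBA, fB * fA), mix(dstore$gBB, fB * fB),
                     kind = "perturbed")
}

## active: per-SNP flag, warn only where a missing frequency would be used
fill_freq <- function(f, active = TRUE) {
  if (anyNA(f)) {
    n_used <- sum(is.na(f) & active)
    if (n_used > 0)
      warning("allele frequency missing for ", n_used,
              " SNP(s) with genotype data; using 0.5", call. = FALSE)
    f[is.na(f)] <- 0.5
  }
  f
}

store_active_snps <- function(store) rowSums(!is.na(store$gAA)) > 0

#' Per-SNP genotyping error rates
#'
#' The estimated error rate of a SNP is the mean, over samples with a
#' quantitative genotype, of one minus the probability of the most likely
#' unordered genotype (the heterozygote being the sum of the two ordered
#' heterozygote cells). The assumed error rate floors the estimate at
#' `floor`, allowing for an underlying error rate regardless of assay
#' precision.
#'
#' @param store Quantitative `genotype_store`.
#' @param floor Minimum assumed error rate (default 0.01).
#' @return Data frame with columns `snp_id`, `eps_hat`, `eps_tilde`.
#' @export
estimate_error_rates <- function(store, floor = 0.01) {
  stopifnot(inherits(store, "genotype_store"))
  gmax <- pmax(store$gAA, store$gAB + store$gBA, store$gBB)
  eps_hat <- rowMeans(1 - gmax, na.rm = TRUE)
  eps_hat[is.nan(eps_hat)] <- NA_real_
  data.frame(snp_id = store$snp_id, eps_hat = eps_hat,
             eps_tilde = pmax(eps_hat, floor),
             row.names = store$snp_id, stringsAsFactors = FALSE)
}

#' Allele frequencies from quantitative genotypes
#'
#' Estimates the per-SNP B-allele frequency as the mean matrix-implied
#' B-allele dosage over a reference sample set (typically the candidate
#' parents), where the dosage implied by a genotype matrix is the sum of its
#' B-row and B-column masses.
#'
#' @param store Quantitative `genotype_store`.
#' @param samples Character vector of reference sample ids
#'   (default: all samples in the store).
#' @return Data frame with columns `snp_id`, `f_A`, `f_B` (`NA` when no
#'   reference sample has a genotype).
#' @export
estimate_allele_frequencies <- function(store, samples = NULL) {
  stopifnot(inherits(store, "genotype_store"))
  if (is.null(samples)) samples <- store$sample_id
  dosage_half <- (store$gAB[, samples, drop = FALSE] +
                  store$gBA[, samples, drop = FALSE]) / 2 +
                 store$gBB[, samples, drop = FALSE]
  f_B <- rowMeans(dosage_half, na.rm = TRUE)
  f_B[is.nan(f_B)] <- NA_real_
  data.frame(snp_id = store$snp_id, f_A = 1 - f_B, f_B = f_B,
             row.names = store$snp_id, stringsAsFactors = FALSE)
}
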