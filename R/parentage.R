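#' Allele transmission vector
#'
#' Probabilities that an individual transmits allele A or B at a marker,
#' computed as half the sum of the row and column sums of its genotype
#' probability matrix, `T = (G 1 + G' 1) / 2`. For the symmetric matrices
#' produced here the row and column averages coincide; the general form is
#' kept so asymmetric (phase-known) matrices remain valid input.
#'
#' @param g A 2x2 genotype probability matrix.
#' @return Named length-2 vector of transmission probabilities `c(A, B)`.
#' @export
transmission_vector <- function(g) {
  stopifnot(is.matrix(g), all(dim(g) == 2))
  t_vec <- (rowSums(g) + colSums(g)) / 2
  names(t_vec) <- allele_names
  t_vec
}

#' Trio likelihood at one marker
#'
#' Likelihood of a sire-dam-offspring trio at a single marker: the expected
#' offspring genotype distribution under Mendelian transmission is the outer
#' product of the parental transmission vectors, and the likelihood is its
#' entrywise (Hadamard) product with the offspring genotype matrix, summed,
#' `L = sum((T_s T_d') o G_o)`.
#'
#' @param t_sire,t_dam Length-2 transmission vectors.
#' @param g_off Offspring 2x2 genotype probability matrix.
#' @return Likelihood in \[0, 1\].
#' @export
trio_marker_likelihood <- function(t_sire, t_dam, g_off) {
  sum(outer(t_sire, t_dam) * g_off)
}

#' Null (unrelated offspring) likelihood at one marker
#'
#' Likelihood of the offspring genotype when both parents are replaced by
#' the allele-frequency matrix `F F'` — the null hypothesis that the
#' offspring is unrelated to the tested pair.
#'
#' @param g_off Offspring genotype matrix.
#' @param freq Length-2 allele-frequency vector `c(f_A, f_B)`.
#' @return Likelihood in \[0, 1\].
#' @export
null_marker_likelihood <- function(g_off, freq) {
  trio_marker_likelihood(freq, freq, g_off)
}

#' LOD score for one trio or pair
#'
#' Sums log likelihood ratios `ln(L_trio / L_null)` over SNPs at which the
#' offspring and every named parent have a genotype. Parents given as `NA`
#' are treated as missing and replaced by the allele-frequency matrix
#' `F F'` (their transmission vector is then `F` itself). The score is
#' missing unless at least `min_snps` SNPs are informative. A marker with
#' zero trio likelihood contributes `-Inf`, so the trio ranks below any
#' finite competitor.
#'
#' @param store A `genotype_store` holding the genotypes to score
#'   (quantitative or perturbed).
#' @param offspring Offspring sample id.
#' @param sire,dam Parent sample ids, or `NA` for a missing parent.
#' @param freq Allele-frequency data frame (`snp_id`, `f_A`, `f_B`).
#' @param min_snps Minimum informative SNPs for a retained score
#'   (default 10).
#' @param log_base Base of the logarithm (default natural log).
#' @return A list with `offspring_id`, `sire_id`, `dam_id`, `lod`, `n_snps`,
#'   or `NULL` when fewer than `min_snps` SNPs are informative.
#' @export
trio_lod <- function(store, offspring, sire = NA, dam = NA, freq,
                     min_snps = 10, log_base = exp(1)) {
  stopifnot(inherits(store, "genotype_store"))
  freq <- freq[match(store$snp_id, freq$snp_id), ]
  active <- store_active_snps(store)
  fA <- fill_freq(freq$f_A, active); fB <- fill_freq(freq$f_B, active)
  off <- store_columns(store, offspring)
  ok <- !is.na(off$gAA)
  trans <- function(parent) {
    if (is.na(parent)) {
      list(tA = fA, tB = fB, ok = rep(TRUE, length(fA)))
    } else {
      g <- store_columns(store, parent)
      tA <- g$gAA + (g$gAB + g$gBA) / 2
      list(tA = tA, tB = 1 - tA, ok = !is.na(g$gAA))
    }
  }
  s <- trans(sire); d <- trans(dam)
  ok <- ok & s$ok & d$ok
  n <- sum(ok)
  if (n < min_snps) return(NULL)
  l_trio <- s$tA[ok] * d$tA[ok] * off$gAA[ok] +
            s$tA[ok] * d$tB[ok] * off$gAB[ok] +
            s$tB[ok] * d$tA[ok] * off$gBA[ok] +
            s$tB[ok] * d$tB[ok] * off$gBB[ok]
  l_null <- fA[ok]^2 * off$gAA[ok] + fA[ok] * fB[ok] * (off$gAB[ok] + off$gBA[ok]) +
            fB[ok]^2 * off$gBB[ok]
  lod <- sum(log(l_trio) - log(l_null)) / log(log_base)
  list(offspring_id = offspring, sire_id = sire, dam_id = dam,
       lod = lod, n_snps = n)
}

store_columns <- function(store, sample) {
  list(gAA = store$gAA[, sample], gAB = store$gAB[, sample],
       gBA = store$gBA[, sample], gBB = store$gBB[, sample])
}

#' Resolve a trio score against its single-parent fallbacks
#'
#' When a sire-dam-offspring trio scores below the corresponding
#' sire-offspring pair (dam treated as missing), the pair score is used and
#' the dam is declared missing; likewise for the dam-offspring pair. Ties
#' retain the trio.
#'
#' @param trio,sire_pair,dam_pair Scores from [trio_lod()] (may be `NULL`).
#' @return The winning score (a [trio_lod()] result), or `NULL` when all
#'   inputs are missing.
#' @export
resolve_trio <- function(trio, sire_pair = NULL, dam_pair = NULL) {
  lod_of <- function(x) if (is.null(x)) -Inf else x$lod
  l3 <- lod_of(trio); ls <- lod_of(sire_pair); ld <- lod_of(dam_pair)
  if (l3 == -Inf && ls == -Inf && ld == -Inf) {
    if (is.null(trio) && is.null(sire_pair) && is.null(dam_pair)) return(NULL)
  }
  if (!is.null(trio) && l3 >= ls && l3 >= ld) return(trio)
  if (ls >= ld && !is.null(sire_pair)) return(sire_pair)
  if (!is.null(dam_pair)) return(dam_pair)
  trio
}

#' Classify a parentage assignment
#'
#' Assigns one of five categories from the trio LOD and the two
#' single-parent LODs: `sire+dam` when the trio score is positive and beats
#' both pair scores; `sire+missing` when the sire pair is positive, beats
#' the trio, and the dam pair is below the trio or negative (symmetrically
#' `dam+missing`); `either+missing` when both pair scores are positive and
#' beat the trio; `both_missing` when every score is negative. Missing
#' scores are treated as `-Inf`.
#'
#' @param trio_lod,sire_lod,dam_lod LOD scores (`NA` allowed).
#' @return Category string.
#' @export
classify_assignment <- function(trio_lod, sire_lod, dam_lod) {
  f <- function(x) if (is.null(x) || is.na(x)) -Inf else x
  l3 <- f(trio_lod); ls <- f(sire_lod); ld <- f(dam_lod)
  if (l3 > 0 && l3 > ls && l3 > ld) return("sire+dam")
  if (ls > 0 && ld > 0 && ls > l3 && ld > l3) return("either+missing")
  if (ls > 0 && ls > l3 && (ld < l3 || ld < 0)) return("sire+missing")
  if (ld > 0 && ld > l3 && (ls < l3 || ls < 0)) return("dam+missing")
  "both_missing"
}

#' Count Mendelian mismatches for a trio
#'
#' For the exclusion method: the number of markers at which the discrete
#' trio probability `sum((T_s T_d') o D_o)` is exactly zero, i.e. the
#' offspring genotype is Mendelian-impossible given both parents. Markers
#' where any member lacks a discrete genotype are skipped.
#'
#' @param dstore Discrete `genotype_store`.
#' @param offspring,sire,dam Sample ids.
#' @return A list with `mismatches` and `n_snps` (markers compared).
#' @export
count_mismatches <- function(dstore, offspring, sire, dam) {
  stopifnot(inherits(dstore, "genotype_store"), dstore$kind == "discrete")
  off <- store_columns(dstore, offspring)
  s <- store_columns(dstore, sire)
  d <- store_columns(dstore, dam)
  ok <- !is.na(off$gAA) & !is.na(s$gAA) & !is.na(d$gAA)
  tA_s <- s$gAA[ok] + (s$gAB[ok] + s$gBA[ok]) / 2
  tA_d <- d$gAA[ok] + (d$gAB[ok] + d$gBA[ok]) / 2
  l <- tA_s * tA_d * off$gAA[ok] + tA_s * (1 - tA_d) * off$gAB[ok] +
       (1 - tA_s) * tA_d * off$gBA[ok] + (1 - tA_s) * (1 - tA_d) * off$gBB[ok]
  list(mismatches = sum(l == 0), n_snps = sum(ok))
}
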