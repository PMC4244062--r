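#' Simulation configuration
#'
#' Assembles the parameters of the synthetic data generator. The defaults
#' emulate a low-density (~60 SNP) biallelic panel assayed on a two-channel
#' platform for a closed aquaculture breeding population: heterogeneous
#' per-SNP cluster geometry on the allelic-proportion axis (off-centre
#' heterozygote means, homozygote means pulled away from 0 and 1, unequal
#' cluster spreads), platform call failures, occasional whole-assay
#' dropout, full-sib mating structure, and DNA pools of one to two dozen
#' individuals drawn from the offspring generation.
#'
#' @param n_snps Number of SNPs on the panel.
#' @param maf_range Range of B-allele frequencies drawn per SNP.
#' @param mu_AA_range,mu_AB_range,mu_BB_range Ranges for per-SNP cluster
#'   means (kept disjoint so `mu_AA < mu_AB < mu_BB` holds by
#'   construction).
#' @param cluster_sd_range Range of per-SNP, per-class cluster standard
#'   deviations.
#' @param intensity_range Range of adjusted assay intensities (platform
#'   units); the failed-reaction threshold is 3 in the same units.
#' @param uncertainty_range Range of per-channel area uncertainties.
#' @param missing_rate Probability an assay record is dropped entirely.
#' @param call_failure_rate Probability the platform fails to call an
#'   otherwise valid assay.
#' @param n_sires,n_dams Candidate parents listed for testing.
#' @param n_families Number of mated families.
#' @param offspring_per_family Offspring genotyped per family.
#' @param mating Mating model: `"fullsib"` (disjoint pairs),
#'   `"halfsib2"` (parents may have up to two mates) or `"random"`.
#' @param n_pools Number of DNA pools.
#' @param pool_size_range Range of pool sizes (members per pool).
#' @param pool_families For `pool_composition = "balanced"`: families
#'   represented per pool.
#' @param pool_composition `"random"` (members drawn at random from all
#'   offspring) or `"balanced"` (members drawn from `pool_families`
#'   families).
#' @param noise_sd_pool SD of Gaussian noise added to pooled allelic
#'   proportions.
#' @param seed Mandatory integer seed; all generator randomness flows from
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 58,
                       maf_range = c(0.2, 0.5),
                       mu_AA_range = c(0.02, 0.15),
                       mu_AB_range = c(0.35, 0.65),
                       mu_BB_range = c(0.85, 0.98),
                       cluster_sd_range = c(0.01, 0.03),
                       intensity_range = c(5, 15),
                       uncertainty_range = c(0.1, 0.5),
                       missing_rate = 0.02,
                       call_failure_rate = 0.15,
                       n_sires = 166, n_dams = 124,
                       n_families = 40, offspring_per_family = 5,
                       mating = c("fullsib", "halfsib2", "random"),
                       n_pools = 8, pool_size_range = c(18, 26),
                       pool_families = 12,
                       pool_composition = c("random", "balanced"),
                       noise_sd_pool = 0.03,
                       seed) {
  if (missing(seed)) stop("sim_config() requires a seed")
  mating <- match.arg(mating)
  pool_composition <- match.arg(pool_composition)
  rates <- c(missing_rate, call_failure_rate)
  stopifnot(all(rates >= 0 & rates <= 1), noise_sd_pool >= 0,
            mu_AA_range[2] < mu_AB_range[1], mu_AB_range[2] < mu_BB_range[1])
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a SNP panel truth
#'
#' Draws per-SNP allele frequencies and genotype-cluster geometry
#' (means and standard deviations of the allelic proportion per class).
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per SNP: `snp_id`, `f_B`, `mu_AA`,
#'   `mu_AB`, `mu_BB`, `sigma_AA`, `sigma_AB`, `sigma_BB`.
#' @export
simulate_panel <- function(config) {
  n <- config$n_snps
  r <- function(range, k = n) stats::runif(k, range[1], range[2])
  panel <- data.frame(
    snp_id = sprintf("snp%03d", seq_len(n)),
    f_B = r(config$maf_range),
    mu_AA = r(config$mu_AA_range),
    mu_AB = r(config$mu_AB_range),
    mu_BB = r(config$mu_BB_range),
    sigma_AA = r(config$cluster_sd_range),
    sigma_AB = r(config$cluster_sd_range),
    sigma_BB = r(config$cluster_sd_range),
    stringsAsFactors = FALSE)
  rownames(panel) <- panel$snp_id
  panel
}

#' Simulate a pedigree and true genotypes
#'
#' Candidate parents receive Hardy-Weinberg genotypes at the panel allele
#' frequencies; families are mated under the configured mating model and
#' each offspring inherits one allele per parent uniformly at random.
#'
#' @param config A [sim_config()].
#' @param panel Panel truth from [simulate_panel()].
#' @return List with `pedigree` (data frame `offspring_id`, `sire_id`,
#'   `dam_id`, `family_id`), `genotype` (SNP-by-sample B-allele dosage
#'   matrix for all parents and offspring), `sires`, `dams`, `offspring`.
#' @export
simulate_pedigree <- function(config, panel) {
  sires <- sprintf("S%03d", seq_len(config$n_sires))
  dams <- sprintf("D%03d", seq_len(config$n_dams))
  n_snp <- nrow(panel)
  hw <- function(ids) {
    g <- matrix(stats::rbinom(n_snp * length(ids), 2, panel$f_B),
                n_snp, length(ids), dimnames = list(panel$snp_id, ids))
    g
  }
  geno <- cbind(hw(sires), hw(dams))
  pairs <- draw_matings(sires, dams, config$n_families, config$mating)
  n_off <- config$n_families * config$offspring_per_family
  offspring <- sprintf("O%03d", seq_len(n_off))
  fam_of <- rep(seq_len(config$n_families), each = config$offspring_per_family)
  transmit <- function(dosage) stats::rbinom(length(dosage), 1, dosage / 2)
  off_geno <- vapply(seq_len(n_off), function(i) {
    s <- pairs$sire_id[fam_of[i]]; d <- pairs$dam_id[fam_of[i]]
    transmit(geno[, s]) + transmit(geno[, d])
  }, numeric(n_snp))
  dimnames(off_geno) <- list(panel$snp_id, offspring)
  pedigree <- data.frame(offspring_id = offspring,
                         sire_id = pairs$sire_id[fam_of],
                         dam_id = pairs$dam_id[fam_of],
                         family_id = sprintf("F%03d", fam_of),
                         stringsAsFactors = FALSE)
  list(pedigree = pedigree, genotype = cbind(geno, off_geno),
       sires = sires, dams = dams, offspring = offspring)
}

draw_matings <- function(sires, dams, n_families, mating) {
  if (mating == "fullsib") {
    if (n_families > min(length(sires), length(dams)))
      stop("not enough parents for ", n_families, " full-sib families")
    data.frame(sire_id = sample(sires, n_families),
               dam_id = sample(dams, n_families),
               stringsAsFactors = FALSE)
  } else if (mating == "halfsib2") {
    if (2 * min(length(sires), length(dams)) < n_families)
      stop("not enough parents for ", n_families, " half-sib families")
    repeat {
      s <- sample(rep(sires, 2))[seq_len(n_families)]
      d <- sample(rep(dams, 2))[seq_len(n_families)]
      if (!anyDuplicated(paste(s, d)))
        return(data.frame(sire_id = s, dam_id = d, stringsAsFactors = FALSE))
    }
  } else {
    repeat {
      s <- sample(sires, n_families, replace = TRUE)
      d <- sample(dams, n_families, replace = TRUE)
      if (!anyDuplicated(paste(s, d)))
        return(data.frame(sire_id = s, dam_id = d, stringsAsFactors = FALSE))
    }
  }
}

rtrunc01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Simulate raw assay records
#'
#' Generates the raw two-channel assay table for every (sample, SNP): the
#' allelic proportion is drawn from the genotype class's truncated-normal
#' cluster, an intensity is drawn, and the channel areas are synthesised by
#' inverting the polar-coordinate transform so that the adjusted areas
#' reproduce the drawn proportion exactly. Platform calls report the true
#' class except at the call-failure rate; whole assays are dropped at the
#' missingness rate.
#'
#' @param truth Output of [simulate_pedigree()].
#' @param panel Panel truth from [simulate_panel()].
#' @param config A [sim_config()].
#' @param samples Which samples to assay (default: all in `truth`).
#' @return Assay data frame (`sample_id`, `snp_id`, `a1`, `u1`, `a2`, `u2`,
#'   `call`) with an attribute `"true_p"` holding the noiseless proportion
#'   matrix.
#' @export
simulate_assays <- function(truth, panel, config, samples = NULL) {
  geno <- truth$genotype
  if (!is.null(samples)) geno <- geno[, samples, drop = FALSE]
  n_snp <- nrow(geno); n_sam <- ncol(geno)
  dosage <- as.vector(geno)
  mu <- cbind(panel$mu_AA, panel$mu_AB, panel$mu_BB)
  sg <- cbind(panel$sigma_AA, panel$sigma_AB, panel$sigma_BB)
  row_idx <- rep(seq_len(n_snp), n_sam)
  cls <- dosage + 1L
  p <- rtrunc01(length(dosage), mu[cbind(row_idx, cls)], sg[cbind(row_idx, cls)])
  r <- stats::runif(length(p), config$intensity_range[1],
                    config$intensity_range[2])
  u1 <- stats::runif(length(p), config$uncertainty_range[1],
                     config$uncertainty_range[2])
  u2 <- stats::runif(length(p), config$uncertainty_range[1],
                     config$uncertainty_range[2])
  x <- r * cos(p * pi / 2)
  y <- r * sin(p * pi / 2)
  call <- c("AA", "AB", "BB")[cls]
  call[stats::runif(length(p)) < config$call_failure_rate] <- NA_character_
  assays <- data.frame(
    sample_id = rep(colnames(geno), each = n_snp),
    snp_id = rep(rownames(geno), n_sam),
    a1 = x + u1, u1 = u1, a2 = y + u2, u2 = u2,
    call = call, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(assays)) >= config$missing_rate
  assays <- assays[keep, ]
  rownames(assays) <- NULL
  p_mat <- matrix(p, n_snp, n_sam, dimnames = dimnames(geno))
  attr(assays, "true_p") <- p_mat
  assays
}

#' Simulate pooled DNA assays
#'
#' Allocates offspring to pools, computes each pool's true B-allele
#' frequency per SNP from member genotypes, maps it onto the
#' allelic-proportion axis through the inverse piecewise map (panel truth
#' means), adds truncated Gaussian noise, and synthesises channel areas as
#' for individual assays.
#'
#' @inheritParams simulate_assays
#' @return List with `assays` (pool assay table keyed by `pool_id` in the
#'   `sample_id` column), `members` (data frame `pool_id`, `sample_id`),
#'   `contributions` (data frame `pool_id`, `family_id`, `contribution`),
#'   and `true_freq` (SNP-by-pool matrix of true pool frequencies).
#' @export
simulate_pool_assays <- function(truth, panel, config) {
  sizes <- round(stats::runif(config$n_pools, config$pool_size_range[1],
                              config$pool_size_range[2]))
  ped <- truth$pedigree
  members <- lapply(seq_len(config$n_pools), function(k) {
    if (config$pool_composition == "balanced") {
      fams <- sample(unique(ped$family_id),
                     min(config$pool_families, length(unique(ped$family_id))))
      cand <- ped$offspring_id[ped$family_id %in% fams]
    } else {
      cand <- ped$offspring_id
    }
    sample(cand, min(sizes[k], length(cand)))
  })
  pool_ids <- sprintf("P%02d", seq_len(config$n_pools))
  geno <- truth$genotype
  true_freq <- vapply(members, function(m)
    rowMeans(geno[, m, drop = FALSE]) / 2, numeric(nrow(geno)))
  dimnames(true_freq) <- list(rownames(geno), pool_ids)
  p <- frequency_to_proportion(true_freq, panel$mu_AA, panel$mu_AB,
                               panel$mu_BB)
  if (config$noise_sd_pool > 0)
    p <- pmin(pmax(p + stats::rnorm(length(p), 0, config$noise_sd_pool), 0), 1)
  n <- length(p)
  r <- stats::runif(n, config$intensity_range[1], config$intensity_range[2])
  u1 <- stats::runif(n, config$uncertainty_range[1], config$uncertainty_range[2])
  u2 <- stats::runif(n, config$uncertainty_range[1], config$uncertainty_range[2])
  assays <- data.frame(
    sample_id = rep(pool_ids, each = nrow(geno)),
    snp_id = rep(rownames(geno), config$n_pools),
    a1 = as.vector(r * cos(p * pi / 2)) + u1, u1 = u1,
    a2 = as.vector(r * sin(p * pi / 2)) + u2, u2 = u2,
    call = NA_character_, stringsAsFactors = FALSE)
  member_df <- data.frame(
    pool_id = rep(pool_ids, vapply(members, length, integer(1))),
    sample_id = unlist(members), stringsAsFactors = FALSE)
  contrib <- do.call(rbind, lapply(seq_along(pool_ids), function(k) {
    fam <- ped$family_id[match(members[[k]], ped$offspring_id)]
    tab <- table(fam) / length(fam)
    data.frame(pool_id = pool_ids[k], family_id = names(tab),
               contribution = as.numeric(tab), stringsAsFactors = FALSE)
  }))
  list(assays = assays, members = member_df, contributions = contrib,
       true_freq = true_freq)
}

#' Simulate a complete dataset
#'
#' Runs the whole generator under the configured seed: panel, pedigree and
#' genotypes, individual assays, and pooled assays, with full truth
#' retained for validation.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `panel`, `truth` (pedigree + genotypes),
#'   `assays`, and `pools`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  panel <- simulate_panel(config)
  truth <- simulate_pedigree(config, panel)
  assays <- simulate_assays(truth, panel, config)
  pools <- simulate_pool_assays(truth, panel, config)
  list(config = config, panel = panel, truth = truth, assays = assays,
       pools = pools)
}
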