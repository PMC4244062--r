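#' Pipeline configuration
#'
#' Collects the tunable thresholds of the analysis pipeline. The defaults
#' are the panel's standard operating values: failed reactions below an
#' adjusted intensity of 3.0, at least 10 jointly typed SNPs per retained
#' score, a 0.98 certainty threshold before declaring a discrete genotype,
#' a 1% floor on the assumed genotyping error rate, assignment thresholds
#' LOD > 3 and delta > 3, zero tolerated mismatches for exclusion, and
#' 5000 random restarts of the pedigree search.
#'
#' @param min_intensity Failed-reaction threshold (platform units).
#' @param min_snps Minimum jointly informative SNPs per score.
#' @param call_threshold Certainty needed to declare a discrete genotype.
#' @param error_floor Floor of the assumed error rate.
#' @param lod_threshold,delta_threshold Assignment confidence thresholds.
#' @param max_mismatches Mismatch tolerance for exclusion (0 or 3).
#' @param restarts Pedigree-search restarts.
#' @param min_class_n Minimum called samples per genotype class at
#'   calibration.
#' @param sigma_floor Floor on calibrated cluster standard deviations.
#' @param methods Genotype models to score: subset of `"quantitative"`,
#'   `"perturbed_hat"`, `"perturbed_tilde"`, `"exclusion"`.
#' @param seed Master seed for the stochastic search.
#' @return A `run_config` list.
#' @export
run_config <- function(min_intensity = 3, min_snps = 10,
                       call_threshold = 0.98, error_floor = 0.01,
                       lod_threshold = 3, delta_threshold = 3,
                       max_mismatches = 0, restarts = 5000,
                       min_class_n = 3, sigma_floor = 1e-3,
                       methods = "quantitative", seed = 1) {
  stopifnot(all(methods %in% c("quantitative", "perturbed_hat",
                               "perturbed_tilde", "exclusion")))
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage on an assay table: allelic proportions and panel
#' calibration, quantitative/discrete/perturbed genotype stores, allele
#' frequencies and error rates, trio scoring and ranking for each requested
#' method, constrained pedigree search (full-sib, half-sib, unrestricted)
#' on the quantitative scores, and — when pooled assays are supplied —
#' pooled allele frequencies and family-contribution estimation against the
#' full-sib pedigree. Per-stage counts are reported via `message()`.
#'
#' @param assays Individual assay data frame (`sample_id`, `snp_id`, `a1`,
#'   `u1`, `a2`, `u2`, `call`).
#' @param offspring,sires,dams Character vectors of sample ids.
#' @param reference_samples Samples used for allele-frequency estimation
#'   (default: all candidate parents).
#' @param pool_assays Optional pooled assay table keyed by pool id in
#'   `sample_id`.
#' @param pool_members Optional data frame `pool_id`, `sample_id`.
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return A list of all stage results (panel, freq, error rates, stores,
#'   per-method rankings, pedigrees and summaries, pool frequencies,
#'   contributions, run report).
#' @export
run_pipeline <- function(assays, offspring, sires, dams,
                         reference_samples = NULL,
                         pool_assays = NULL, pool_members = NULL,
                         config = run_config(), out_dir = NULL) {
  if (is.null(reference_samples)) reference_samples <- c(sires, dams)
  set.seed(config$seed)

  mats <- proportion_matrix(assays, min_intensity = config$min_intensity)
  panel <- calibrate_panel(mats$p, mats$call,
                           min_class_n = config$min_class_n,
                           sigma_floor = config$sigma_floor)
  message("calibrate: ", sum(panel$usable), "/", nrow(panel), " SNPs usable")

  gstore <- quantitative_genotypes(mats$p, panel)
  freq <- estimate_allele_frequencies(
    gstore, intersect(reference_samples, gstore$sample_id))
  errs <- estimate_error_rates(gstore, floor = config$error_floor)
  dstore <- discrete_genotypes(gstore, call_threshold = config$call_threshold)
  message("genotypes: ", sum(!is.na(gstore$gAA)), " quantitative, ",
          sum(!is.na(dstore$gAA)), " discrete")

  rankings <- list()
  scores_by_method <- list()
  for (m in config$methods) {
    store_m <- switch(m,
      quantitative = gstore,
      perturbed_hat = perturbed_genotypes(dstore, errs$eps_hat, freq),
      perturbed_tilde = perturbed_genotypes(dstore, errs$eps_tilde, freq),
      exclusion = dstore)
    sc <- score_parentage(store_m, offspring, sires, dams, freq,
                          min_snps = config$min_snps,
                          method = if (m == "exclusion") "exclusion"
                                   else "likelihood")
    rk <- rank_parent_pairs(sc, lod_threshold = config$lod_threshold,
                            delta_threshold = config$delta_threshold,
                            max_mismatches = config$max_mismatches)
    rk$method <- m
    scores_by_method[[m]] <- sc
    rankings[[m]] <- rk
    message("assign [", m, "]: ", sum(rk$assigned), "/", nrow(rk),
            " offspring pass thresholds")
  }

  pedigrees <- NULL
  search_scores <- scores_by_method[[setdiff(config$methods, "exclusion")[1]]]
  if (!is.null(search_scores)) {
    opts <- pedigree_options(search_scores)
    seeds <- sample.int(.Machine$integer.max / 2, 3)
    pedigrees <- list(
      fullsib = stochastic_search(opts, max_mates = 1,
                                  n_restarts = config$restarts,
                                  seed = seeds[1]),
      halfsib = stochastic_search(opts, max_mates = 2,
                                  n_restarts = config$restarts,
                                  seed = seeds[2]),
      unrestricted = stochastic_search(opts, max_mates = Inf,
                                       n_restarts = config$restarts,
                                       seed = seeds[3]))
    for (nm in names(pedigrees))
      message("constrain [", nm, "]: total LOD ",
              round(pedigrees[[nm]]$total_lod, 1))
  }

  pool_freq <- contributions <- NULL
  if (!is.null(pool_assays) && !is.null(pool_members)) {
    pool_res <- pool_stage(pool_assays, pool_members, mats, panel, gstore,
                           freq, pedigrees$fullsib, config)
    pool_freq <- pool_res$freq
    contributions <- pool_res$contributions
    message("poolfreq: ", length(unique(pool_freq$pool_id)),
            " pools processed")
  }

  res <- list(panel = panel, freq = freq, error_rates = errs,
              genotypes = gstore, discrete = dstore,
              scores = scores_by_method, rankings = rankings,
              pedigrees = pedigrees, pool_freq = pool_freq,
              contributions = contributions, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

pool_stage <- function(pool_assays, pool_members, mats, panel, gstore, freq,
                       pedigree, config) {
  pm <- proportion_matrix(pool_assays, min_intensity = config$min_intensity,
                          pool = TRUE)
  pools <- colnames(pm$p)
  usable <- panel$usable
  freq_rows <- lapply(pools, function(k) {
    p_pool <- pm$p[, k]
    f_hat <- pooled_allele_frequency(p_pool, panel$mu_AA, panel$mu_AB,
                                     panel$mu_BB)
    f_hat[!usable] <- NA_real_
    tau <- pool_weight(p_pool, panel$mu_AB, panel$tau_A, panel$tau_B)
    members <- pool_members$sample_id[pool_members$pool_id == k]
    members <- intersect(members, colnames(mats$p))
    f_star <- individual_pool_frequency(mats$p, members, panel)
    f_star[!usable] <- NA_real_
    data.frame(pool_id = k, snp_id = panel$snp_id, p_pool = p_pool,
               f_hat = f_hat, tau = tau, f_star = f_star,
               stringsAsFactors = FALSE)
  })
  pool_freq <- do.call(rbind, freq_rows)
  rownames(pool_freq) <- NULL

  contributions <- NULL
  if (!is.null(pedigree)) {
    ped <- pedigree$assignments
    contrib_rows <- lapply(pools, function(k) {
      members <- pool_members$sample_id[pool_members$pool_id == k]
      fam <- ped[ped$offspring_id %in% members, c("sire_id", "dam_id")]
      fam <- unique(fam)
      if (!nrow(fam)) return(NULL)
      fam$family_id <- paste0(partner_keys(fam$sire_id), "x",
                              partner_keys(fam$dam_id))
      X <- family_frequency_matrix(fam, gstore, freq)
      pf <- pool_freq[pool_freq$pool_id == k, ]
      keep <- usable & !is.na(pf$f_hat)
      est <- estimate_contributions(X[keep, , drop = FALSE],
                                    pf$f_hat[keep],
                                    ifelse(is.na(pf$tau[keep]), 1,
                                           pf$tau[keep]^2))
      data.frame(pool_id = k, family_id = fam$family_id,
                 sire_id = fam$sire_id, dam_id = fam$dam_id,
                 beta = est$beta, stringsAsFactors = FALSE)
    })
    contributions <- do.call(rbind, contrib_rows)
    rownames(contributions) <- NULL
  }
  list(freq = pool_freq, contributions = contributions)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(res$panel, file.path(out_dir, "panel.csv"), "snp_id")
  write_table_csv(res$freq, file.path(out_dir, "allele_freq.csv"), "snp_id")
  write_table_csv(res$error_rates, file.path(out_dir, "error_rates.csv"),
                  "snp_id")
  for (m in names(res$rankings))
    write_table_csv(res$rankings[[m]],
                    file.path(out_dir, paste0("assignments_", m, ".csv")),
                    "offspring_id")
  if (!is.null(res$pedigrees)) {
    for (nm in names(res$pedigrees)) {
      write_table_csv(res$pedigrees[[nm]]$assignments,
                      file.path(out_dir, paste0("pedigree_", nm, ".csv")),
                      "offspring_id")
    }
    summaries <- do.call(rbind, lapply(res$pedigrees, pedigree_summary))
    summaries <- cbind(pedigree = names(res$pedigrees), summaries)
    write_table_csv(summaries, file.path(out_dir, "pedigree_summary.csv"),
                    "pedigree")
  }
  if (!is.null(res$pool_freq))
    write_table_csv(res$pool_freq, file.path(out_dir, "pool_freq.csv"),
                    c("pool_id", "snp_id"))
  if (!is.null(res$contributions))
    write_table_csv(res$contributions,
                    file.path(out_dir, "contributions.csv"),
                    c("pool_id", "family_id"))
  report <- list(
    snps_usable = sum(res$panel$usable),
    snps_total = nrow(res$panel),
    methods = names(res$rankings),
    assigned = lapply(res$rankings, function(r) sum(r$assigned)),
    settings = unclass(res$config)[c("min_intensity", "min_snps",
                                     "call_threshold", "error_floor",
                                     "lod_threshold", "delta_threshold",
                                     "max_mismatches", "restarts", "seed")])
  write_run_report(report, file.path(out_dir, "run_report.json"))
  invisible(out_dir)
}
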