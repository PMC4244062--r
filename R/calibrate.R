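#' Arrange an assay table as aligned matrices
#'
#' Computes allelic proportions for a long assay table and reshapes the
#' result into SNP-by-sample matrices aligned on sorted identifiers.
#'
#' @param assays Data frame with columns `sample_id`, `snp_id`, `a1`, `u1`,
#'   `a2`, `u2` and optionally `call` (values `AA`, `AB`, `BB` or `NA`).
#' @param min_intensity Failed-reaction threshold passed to
#'   [allelic_proportion()].
#' @param pool Logical; use the pooled-sample failure rule.
#' @return A list with matrices `p`, `intensity` and `call`
#'   (SNPs in rows, samples in columns).
#' @export
proportion_matrix <- function(assays, min_intensity = 3, pool = FALSE) {
  req <- c("sample_id", "snp_id", "a1", "u1", "a2", "u2")
  miss <- setdiff(req, names(assays))
  if (length(miss))
    stop("assay table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(assays[c("sample_id", "snp_id")]))
    stop("duplicate (sample_id, snp_id) rows in assay table")
  ap <- allelic_proportion(assays$a1, assays$u1, assays$a2, assays$u2,
                           min_intensity = min_intensity, pool = pool)
  snps <- sort(unique(as.character(assays$snp_id)))
  samples <- sort(unique(as.character(assays$sample_id)))
  shape <- function(values, init) {
    m <- matrix(init, length(snps), length(samples),
                dimnames = list(snps, samples))
    m[cbind(as.character(assays$snp_id), as.character(assays$sample_id))] <- values
    m
  }
  calls <- if ("call" %in% names(assays)) as.character(assays$call)
           else rep(NA_character_, nrow(assays))
  calls[!calls %in% c("AA", "AB", "BB")] <- NA_character_
  list(p = shape(ap$p, NA_real_),
       intensity = shape(ap$adjusted_intensity, NA_real_),
       call = shape(calls, NA_character_))
}

#' Calibrate cluster parameters for one SNP
#'
#' Estimates per-genotype-class means and standard deviations of the allelic
#' proportion from samples with a platform genotype call, together with the
#' Welch statistics for the two inter-cluster intervals. Proportions are used
#' as-is (no rescaling of the class means to 0/0.5/1).
#'
#' A SNP is flagged unusable when any class has fewer than `min_class_n`
#' called samples or when the class means are not strictly increasing
#' (`mu_AA < mu_AB < mu_BB`). Class standard deviations are floored at
#' `sigma_floor` to avoid degenerate spikes.
#'
#' @param p Numeric vector of allelic proportions for one SNP.
#' @param call Character vector of platform calls (`AA`, `AB`, `BB`, or `NA`)
#'   aligned with `p`.
#' @param snp_id Identifier recorded in the output row.
#' @param min_class_n Minimum called samples per class (default 3).
#' @param sigma_floor Lower bound on class standard deviations (default 1e-3).
#' @return One-row data frame with columns `snp_id`, `mu_AA`, `mu_AB`,
#'   `mu_BB`, `sigma_AA`, `sigma_AB`, `sigma_BB`, `n_AA`, `n_AB`, `n_BB`,
#'   `tau_A`, `tau_B`, `usable`.
#' @export
calibrate_snp <- function(p, call, snp_id = NA_character_,
                          min_class_n = 3, sigma_floor = 1e-3) {
  stopifnot(length(p) == length(call))
  keep <- !is.na(p) & call %in% c("AA", "AB", "BB")
  p <- p[keep]; call <- call[keep]
  cls <- c("AA", "AB", "BB")
  n <- vapply(cls, function(g) sum(call == g), integer(1))
  mu <- vapply(cls, function(g) if (n[[g]] > 0) mean(p[call == g]) else NA_real_,
               numeric(1))
  sg <- vapply(cls, function(g) if (n[[g]] > 1) stats::sd(p[call == g]) else NA_real_,
               numeric(1))
  sg <- pmax(sg, sigma_floor)
  usable <- all(n >= min_class_n) &&
    !anyNA(mu) && mu[["AA"]] < mu[["AB"]] && mu[["AB"]] < mu[["BB"]]
  tau_A <- tau_B <- NA_real_
  if (usable) {
    tau_A <- welch_statistic(mu[["AA"]], sg[["AA"]], n[["AA"]],
                             mu[["AB"]], sg[["AB"]], n[["AB"]])
    tau_B <- welch_statistic(mu[["AB"]], sg[["AB"]], n[["AB"]],
                             mu[["BB"]], sg[["BB"]], n[["BB"]])
  }
  data.frame(snp_id = snp_id,
             mu_AA = mu[["AA"]], mu_AB = mu[["AB"]], mu_BB = mu[["BB"]],
             sigma_AA = sg[["AA"]], sigma_AB = sg[["AB"]], sigma_BB = sg[["BB"]],
             n_AA = n[["AA"]], n_AB = n[["AB"]], n_BB = n[["BB"]],
             tau_A = tau_A, tau_B = tau_B, usable = usable,
             stringsAsFactors = FALSE)
}

#' Calibrate a SNP panel
#'
#' Applies [calibrate_snp()] to every SNP of aligned proportion and call
#' matrices (see [proportion_matrix()]).
#'
#' @param p SNP-by-sample matrix of allelic proportions.
#' @param call SNP-by-sample matrix of platform calls.
#' @inheritParams calibrate_snp
#' @return Data frame with one row per SNP (see [calibrate_snp()]).
#' @export
calibrate_panel <- function(p, call, min_class_n = 3, sigma_floor = 1e-3) {
  stopifnot(is.matrix(p), identical(dim(p), dim(call)))
  rows <- lapply(rownames(p), function(j)
    calibrate_snp(p[j, ], call[j, ], snp_id = j,
                  min_class_n = min_class_n, sigma_floor = sigma_floor))
  panel <- do.call(rbind, rows)
  rownames(panel) <- panel$snp_id
  panel
}
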