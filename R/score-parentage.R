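#' Score all candidate trios for a set of offspring
#'
#' Computes, for every offspring, the LOD of every candidate (sire, dam)
#' trio together with the two single-parent fallback scores (the other
#' parent replaced by the allele-frequency matrix). Likelihoods follow the
#' matrix formulation: per SNP the trio likelihood is
#' `sum((T_s T_d') o G_o)` and the null likelihood replaces both parents by
#' `F F'`; the LOD is the sum of natural-log likelihood ratios over SNPs at
#' which the offspring and every named parent have a genotype. Scores with
#' fewer than `min_snps` informative SNPs are set to `NA`. For
#' `method = "exclusion"` the same machinery counts Mendelian-impossible
#' markers instead of accumulating log ratios.
#'
#' @param store A `genotype_store` for all samples; pass the quantitative
#'   store for the quantitative method, a perturbed store for the perturbed
#'   methods, or a discrete store for exclusion.
#' @param offspring,sires,dams Character vectors of sample ids
#'   (must be columns of `store`).
#' @param freq Allele-frequency data frame (`snp_id`, `f_A`, `f_B`).
#' @param min_snps Minimum jointly informative SNPs (default 10).
#' @param method `"likelihood"` (default, whatever store is supplied) or
#'   `"exclusion"`.
#' @return A `parentage_scores` object: per offspring the trio LOD (or
#'   mismatch-count) matrix over sires x dams, informative-SNP counts, and
#'   the sire-pair and dam-pair score vectors.
#' @export
score_parentage <- function(store, offspring, sires, dams, freq,
                            min_snps = 10,
                            method = c("likelihood", "exclusion")) {
  method <- match.arg(method)
  stopifnot(inherits(store, "genotype_store"))
  all_ids <- store$sample_id
  for (ids in list(offspring, sires, dams))
    if (!all(ids %in% all_ids))
      stop("sample ids absent from genotype store: ",
           paste(setdiff(ids, all_ids), collapse = ", "))
  freq <- freq[match(store$snp_id, freq$snp_id), ]
  active <- store_active_snps(store)
  fA <- fill_freq(freq$f_A, active); fB <- fill_freq(freq$f_B, active)

  tA <- store$gAA + (store$gAB + store$gBA) / 2   # snps x samples
  tB <- 1 - tA
  avail <- !is.na(store$gAA)
  availS <- avail[, sires, drop = FALSE] + 0
  availD <- avail[, dams, drop = FALSE] + 0
  tA_S <- tA[, sires, drop = FALSE]; tB_S <- tB[, sires, drop = FALSE]
  tA_D <- tA[, dams, drop = FALSE]; tB_D <- tB[, dams, drop = FALSE]

  per_off <- vector("list", length(offspring))
  names(per_off) <- offspring
  for (o in offspring) {
    go <- store_columns(store, o)
    offj <- which(!is.na(go$gAA))
    ns <- length(sires); nd <- length(dams)
    n3 <- t(availS[offj, , drop = FALSE]) %*% availD[offj, , drop = FALSE]
    n_s <- colSums(availS[offj, , drop = FALSE])
    n_d <- colSums(availD[offj, , drop = FALSE])
    if (method == "likelihood") {
      l_null <- fA^2 * go$gAA + fA * fB * (go$gAB + go$gBA) + fB^2 * go$gBB
      ## single-parent components: cA/cB multiply the parent's tA/tB
      cA <- fA * go$gAA + fB * go$gAB
      cB <- fA * go$gBA + fB * go$gBB
      ratio_s <- log(tA_S * cA + tB_S * cB) - log(l_null)  # recycled by column
      ratio_d <- log(tA_D * cA + tB_D * cB) - log(l_null)
      ratio_s[availS == 0] <- 0
      ratio_d[availD == 0] <- 0
      lod_s <- colSums(ratio_s[offj, , drop = FALSE])
      lod_d <- colSums(ratio_d[offj, , drop = FALSE])
      lod3 <- matrix(0, ns, nd, dimnames = list(sires, dams))
      for (j in offj) {
        gm <- matrix(c(go$gAA[j], go$gBA[j], go$gAB[j], go$gBB[j]), 2, 2)
        sj <- cbind(tA_S[j, ], tB_S[j, ])
        dj <- rbind(tA_D[j, ], tB_D[j, ])
        r <- log(sj %*% gm %*% dj) - log(l_null[j])
        if (any(availS[j, ] == 0)) r[availS[j, ] == 0, ] <- 0
        if (any(availD[j, ] == 0)) r[, availD[j, ] == 0] <- 0
        lod3 <- lod3 + r
      }
      lod3[n3 < min_snps] <- NA_real_
      lod_s[n_s < min_snps] <- NA_real_
      lod_d[n_d < min_snps] <- NA_real_
      per_off[[o]] <- list(trio = lod3, n3 = n3,
                           sire_pair = lod_s, n_s = n_s,
                           dam_pair = lod_d, n_d = n_d)
    } else {
      mm <- matrix(0, ns, nd, dimnames = list(sires, dams))
      for (j in offj) {
        gm <- matrix(c(go$gAA[j], go$gBA[j], go$gAB[j], go$gBB[j]), 2, 2)
        sj <- cbind(tA_S[j, ], tB_S[j, ])
        dj <- rbind(tA_D[j, ], tB_D[j, ])
        bad <- (sj %*% gm %*% dj) == 0
        bad[availS[j, ] == 0, ] <- FALSE
        bad[, availD[j, ] == 0] <- FALSE
        mm <- mm + bad
      }
      mm[n3 < min_snps] <- NA_real_
      per_off[[o]] <- list(trio = mm, n3 = n3)
    }
  }
  structure(list(scores = per_off, offspring = offspring, sires = sires,
                 dams = dams, min_snps = min_snps, method = method,
                 kind = store$kind),
            class = "parentage_scores")
}

#' @export
print.parentage_scores <- function(x, ...) {
  cat(sprintf("<parentage_scores: %s/%s, %d offspring x (%d sires x %d dams)>\n",
              x$method, x$kind, length(x$offspring), length(x$sires),
              length(x$dams)))
  invisible(x)
}

resolve_matrix <- function(sc) {
  ## effective score per (sire, dam) after single-parent fallback
  trio <- sc$trio
  trio[is.na(trio)] <- -Inf
  sp <- sc$sire_pair; sp[is.na(sp)] <- -Inf
  dp <- sc$dam_pair; dp[is.na(dp)] <- -Inf
  spM <- matrix(sp, nrow(trio), ncol(trio))
  dpM <- matrix(dp, nrow(trio), ncol(trio), byrow = TRUE)
  lod <- pmax(trio, spM, dpM)
  type <- matrix("trio", nrow(trio), ncol(trio))
  type[spM > trio & spM >= dpM] <- "sire_pair"
  type[dpM > trio & dpM > spM] <- "dam_pair"
  type[lod == -Inf] <- "none"
  list(lod = lod, type = type)
}

#' Rank candidate parent pairs per offspring
#'
#' For each offspring, resolves every candidate (sire, dam) combination
#' against its single-parent fallbacks, ranks the resolved scores, and
#' reports the best assignment, the margin `delta` to the best combination
#' with a different effective parent pair, and whether the assignment passes
#' the confidence thresholds (`lod > lod_threshold` and
#' `delta > delta_threshold` for likelihood methods; mismatch count at most
#' `max_mismatches` with a unique minimum for exclusion). Exact ties are
#' broken by lexicographic (sire, dam) order so results are deterministic.
#'
#' @param scores A `parentage_scores` object.
#' @param lod_threshold,delta_threshold Assignment thresholds for likelihood
#'   methods (defaults 3 and 3).
#' @param max_mismatches Mismatch tolerance for exclusion (default 0;
#'   3 is the usual lenient setting).
#' @return Data frame with one row per offspring: `offspring_id`, `sire_id`,
#'   `dam_id` (`NA` for a missing parent), `lod` (or negative mismatch count
#'   for exclusion), `n_snps`, `mismatches`, `category`, `delta`, `assigned`.
#' @export
rank_parent_pairs <- function(scores, lod_threshold = 3, delta_threshold = 3,
                              max_mismatches = 0) {
  stopifnot(inherits(scores, "parentage_scores"))
  rows <- lapply(scores$offspring, function(o) {
    sc <- scores$scores[[o]]
    if (scores$method == "exclusion")
      rank_one_exclusion(o, sc, scores, max_mismatches)
    else
      rank_one_likelihood(o, sc, scores, lod_threshold, delta_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

rank_one_likelihood <- function(o, sc, scores, lod_threshold, delta_threshold) {
  res <- resolve_matrix(sc)
  base <- data.frame(offspring_id = o, sire_id = NA_character_,
                     dam_id = NA_character_, lod = NA_real_,
                     n_snps = NA_integer_, mismatches = NA_integer_,
                     category = "both_missing", delta = NA_real_,
                     assigned = FALSE, stringsAsFactors = FALSE)
  if (all(res$lod == -Inf)) return(base)
  ns <- length(scores$sires)
  ord <- order(-res$lod, rep(seq_along(scores$sires), length(scores$dams)),
               rep(seq_along(scores$dams), each = ns))
  top <- ord[1]
  si <- (top - 1) %% ns + 1
  di <- (top - 1) %/% ns + 1
  eff <- function(idx) {
    s_i <- (idx - 1) %% ns + 1; d_i <- (idx - 1) %/% ns + 1
    switch(res$type[idx],
           trio = c(scores$sires[s_i], scores$dams[d_i]),
           sire_pair = c(scores$sires[s_i], NA_character_),
           dam_pair = c(NA_character_, scores$dams[d_i]),
           c(NA_character_, NA_character_))
  }
  best <- eff(top)
  delta <- NA_real_
  for (idx in ord[-1]) {
    if (res$lod[idx] == -Inf) break
    if (!identical(eff(idx), best)) {
      delta <- res$lod[top] - res$lod[idx]
      break
    }
  }
  cat_ <- classify_assignment(sc$trio[si, di], sc$sire_pair[si], sc$dam_pair[di])
  n_snps <- switch(res$type[top],
                   trio = sc$n3[si, di],
                   sire_pair = sc$n_s[si],
                   dam_pair = sc$n_d[di])
  base$sire_id <- best[1]; base$dam_id <- best[2]
  base$lod <- res$lod[top]; base$n_snps <- as.integer(n_snps)
  base$category <- cat_; base$delta <- delta
  base$assigned <- isTRUE(res$lod[top] > lod_threshold &&
                          !is.na(delta) && delta > delta_threshold)
  base
}

rank_one_exclusion <- function(o, sc, scores, max_mismatches) {
  mm <- sc$trio
  base <- data.frame(offspring_id = o, sire_id = NA_character_,
                     dam_id = NA_character_, lod = NA_real_,
                     n_snps = NA_integer_, mismatches = NA_integer_,
                     category = "both_missing", delta = NA_real_,
                     assigned = FALSE, stringsAsFactors = FALSE)
  if (all(is.na(mm))) return(base)
  ns <- length(scores$sires)
  mmv <- mm; mmv[is.na(mmv)] <- Inf
  ord <- order(mmv, rep(seq_along(scores$sires), length(scores$dams)),
               rep(seq_along(scores$dams), each = ns))
  top <- ord[1]
  si <- (top - 1) %% ns + 1; di <- (top - 1) %/% ns + 1
  second <- if (length(ord) > 1) mmv[ord[2]] else Inf
  base$sire_id <- scores$sires[si]; base$dam_id <- scores$dams[di]
  base$mismatches <- as.integer(mm[top])
  base$lod <- -mm[top]
  base$n_snps <- as.integer(sc$n3[si, di])
  base$delta <- if (is.finite(second)) second - mm[top] else NA_real_
  base$assigned <- isTRUE(mm[top] <= max_mismatches &&
                          is.finite(second) && second > mm[top])
  base$category <- if (base$assigned) "sire+dam" else "both_missing"
  base
}

#' Candidate options for the pedigree search
#'
#' Flattens a `parentage_scores` object into per-offspring option tables for
#' [stochastic_search()]: every resolved candidate with a positive score,
#' deduplicated by effective (sire, dam) assignment keeping the highest
#' score, sorted by decreasing score with lexicographic tie-break.
#'
#' @param scores A `parentage_scores` object (likelihood method).
#' @return Named list (by offspring) of data frames with columns `sire_id`,
#'   `dam_id`, `lod`.
#' @export
pedigree_options <- function(scores) {
  stopifnot(inherits(scores, "parentage_scores"),
            scores$method == "likelihood")
  lapply(stats::setNames(scores$offspring, scores$offspring), function(o) {
    sc <- scores$scores[[o]]
    res <- resolve_matrix(sc)
    keep <- which(res$lod > 0)
    if (!length(keep))
      return(data.frame(sire_id = character(), dam_id = character(),
                        lod = numeric(), stringsAsFactors = FALSE))
    ns <- length(scores$sires)
    si <- (keep - 1) %% ns + 1; di <- (keep - 1) %/% ns + 1
    type <- res$type[keep]
    df <- data.frame(
      sire_id = ifelse(type == "dam_pair", NA_character_, scores$sires[si]),
      dam_id = ifelse(type == "sire_pair", NA_character_, scores$dams[di]),
      lod = res$lod[keep], stringsAsFactors = FALSE)
    df <- df[order(-df$lod, df$sire_id, df$dam_id), ]
    df <- df[!duplicated(paste(df$sire_id, df$dam_id)), ]
    rownames(df) <- NULL
    df
  })
}
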