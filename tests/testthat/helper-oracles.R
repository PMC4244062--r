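# Independent oracles and small fixture builders used across the suite.

# Brute-force trio likelihood: enumerate the transmitted allele of each
# parent explicitly (probability of transmitting allele x is the sum over
# the parent's ordered genotypes of genotype probability times the share of
# x in that genotype), then sum P(transmit) * G_o over the four offspring
# ordered genotypes. Kept loop-based and free of package code.
brute_trio_likelihood <- function(g_s, g_d, g_o) {
  transmit_prob <- function(g, x) {
    p <- 0
    for (a in 1:2) for (b in 1:2)
      p <- p + g[a, b] * ((a == x) + (b == x)) / 2
    p
  }
  L <- 0
  for (x in 1:2) for (y in 1:2)
    L <- L + transmit_prob(g_s, x) * transmit_prob(g_d, y) * g_o[x, y]
  L
}

# Random non-negative 2x2 matrix summing to 1; symmetric on request.
random_genotype_matrix <- function(symmetric = FALSE) {
  w <- stats::runif(4)
  if (symmetric) {
    het <- (w[2] + w[3]) / 2
    w[2] <- w[3] <- het
  }
  matrix(w / sum(w), 2, 2)
}

# Certain (discrete) genotype matrices by class label.
gm <- function(class) {
  switch(class,
         AA = matrix(c(1, 0, 0, 0), 2, 2),
         AB = matrix(c(0, 0.5, 0.5, 0), 2, 2),
         BB = matrix(c(0, 0, 0, 1), 2, 2),
         stop("unknown class"))
}

# Build a genotype_store from a named list of per-sample genotype matrix
# lists (entries may be NULL for missing); all samples must list the same
# number of SNPs.
make_store <- function(samples, kind = "quantitative", snp_ids = NULL) {
  n_snp <- length(samples[[1]])
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%02d", seq_len(n_snp))
  ids <- names(samples)
  slice <- function(i, j) {
    m <- matrix(NA_real_, n_snp, length(ids),
                dimnames = list(snp_ids, ids))
    for (s in seq_along(ids)) for (k in seq_len(n_snp)) {
      g <- samples[[s]][[k]]
      if (!is.null(g)) m[k, s] <- g[i, j]
    }
    m
  }
  structure(list(gAA = slice(1, 1), gAB = slice(1, 2),
                 gBA = slice(2, 1), gBB = slice(2, 2),
                 snp_id = snp_ids, sample_id = ids, kind = kind),
            class = "genotype_store")
}

# Store where every sample is certain of the stated class at every SNP.
certain_store <- function(classes, n_snp = 1, kind = "quantitative") {
  make_store(lapply(classes, function(cl) {
    rep(list(if (is.na(cl)) NULL else gm(cl)), n_snp)
  }), kind = kind)
}

uniform_freq <- function(snp_ids) {
  data.frame(snp_id = snp_ids, f_A = 0.5, f_B = 0.5,
             stringsAsFactors = FALSE)
}

# Exhaustive pedigree oracle: enumerate every assignment of each offspring
# to one of its options (or both-missing), keep those satisfying the
# mating constraint, return the maximum total LOD. Independent of the
# package's greedy/search code.
exhaustive_best_pedigree <- function(options, max_mates) {
  offs <- names(options)
  n <- length(offs)
  choice_sets <- lapply(options, function(df) {
    c(list(NULL), split(df, seq_len(nrow(df))))
  })
  feasible <- function(rows) {
    fams <- unique(do.call(rbind, lapply(rows, function(r)
      if (is.null(r)) NULL else data.frame(s = ifelse(is.na(r$sire_id), ".", r$sire_id),
                                           d = ifelse(is.na(r$dam_id), ".", r$dam_id)))))
    if (is.null(fams) || !nrow(fams)) return(TRUE)
    s_ok <- all(table(fams$s[fams$s != "."]) <= max_mates)
    d_ok <- all(table(fams$d[fams$d != "."]) <= max_mates)
    s_ok && d_ok
  }
  best <- 0
  idx <- rep(1L, n)
  sizes <- vapply(choice_sets, length, integer(1))
  repeat {
    rows <- lapply(seq_len(n), function(i) choice_sets[[i]][[idx[i]]])
    if (feasible(rows)) {
      tot <- sum(vapply(rows, function(r) if (is.null(r)) 0 else r$lod,
                        numeric(1)))
      best <- max(best, tot)
    }
    k <- n
    while (k >= 1) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L
      k <- k - 1
    }
    if (k < 1) break
  }
  best
}

# Random small pedigree-search instance with overlapping parents so that
# mating constraints bind.
random_search_instance <- function(n_off = 4, n_opts = 3) {
  sires <- sprintf("s%d", 1:3)
  dams <- sprintf("d%d", 1:3)
  opts <- lapply(seq_len(n_off), function(i) {
    k <- sample(n_opts, 1)
    df <- data.frame(sire_id = sample(sires, k, replace = TRUE),
                     dam_id = sample(dams, k, replace = TRUE),
                     lod = round(stats::runif(k, 0.5, 10), 2),
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(paste(df$sire_id, df$dam_id)), , drop = FALSE]
    df[order(-df$lod), , drop = FALSE]
  })
  names(opts) <- sprintf("o%d", seq_len(n_off))
  opts
}

# Small, clean, well-separated simulated dataset reused by several tests.
clean_sim <- function(seed, n_families = 8, offspring_per_family = 3,
                      n_sires = 15, n_dams = 12, n_pools = 2,
                      pool_size_range = c(10, 12), ...) {
  simulate_dataset(sim_config(seed = seed, n_sires = n_sires, n_dams = n_dams,
                              n_families = n_families,
                              offspring_per_family = offspring_per_family,
                              missing_rate = 0, call_failure_rate = 0,
                              n_pools = n_pools,
                              pool_size_range = pool_size_range, ...))
}

# Fabricated parentage_scores object with known score tables, for testing
# ranking logic in isolation.
fake_scores <- function(trio, sire_pair = NULL, dam_pair = NULL, n = 50,
                        min_snps = 10, method = "likelihood") {
  sires <- rownames(trio); dams <- colnames(trio)
  if (is.null(sire_pair)) sire_pair <- rep(NA_real_, length(sires))
  if (is.null(dam_pair)) dam_pair <- rep(NA_real_, length(dams))
  sc <- list(trio = trio,
             n3 = matrix(n, nrow(trio), ncol(trio),
                         dimnames = dimnames(trio)),
             sire_pair = stats::setNames(sire_pair, sires),
             n_s = stats::setNames(rep(n, length(sires)), sires),
             dam_pair = stats::setNames(dam_pair, dams),
             n_d = stats::setNames(rep(n, length(dams)), dams))
  structure(list(scores = list(off1 = sc), offspring = "off1",
                 sires = sires, dams = dams, min_snps = min_snps,
                 method = method, kind = "quantitative"),
            class = "parentage_scores")
}
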