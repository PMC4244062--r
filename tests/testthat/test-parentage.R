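test_that("transmission vectors halve the row and column mass", {
  expect_equal(transmission_vector(gm("AA")), c(A = 1, B = 0))
  expect_equal(transmission_vector(gm("AB")), c(A = 0.5, B = 0.5))
  # asymmetric matrix exercises the general (row + column)/2 form
  g <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2, byrow = TRUE)
  expect_equal(transmission_vector(g), c(A = 0.75, B = 0.25))
})

test_that("trio marker likelihood follows Mendelian transmission", {
  expect_equal(trio_marker_likelihood(c(1, 0), c(1, 0), gm("AA")), 1)
  expect_equal(trio_marker_likelihood(c(1, 0), c(1, 0), gm("BB")), 0)
  # the 0.5/0.5 ordered-het representation halves raw likelihoods (the
  # Mendelian het probability is 0.5); ratios are unaffected
  expect_equal(trio_marker_likelihood(c(0.5, 0.5), c(0.5, 0.5), gm("AB")), 0.25)
})

test_that("trio likelihood equals brute-force transmitted-allele enumeration", {
  set.seed(10)
  for (i in 1:50) {
    g_s <- random_genotype_matrix()
    g_d <- random_genotype_matrix()
    g_o <- random_genotype_matrix()
    L <- trio_marker_likelihood(transmission_vector(g_s),
                                transmission_vector(g_d), g_o)
    expect_equal(L, brute_trio_likelihood(g_s, g_d, g_o), tolerance = 1e-14)
  }
})

test_that("null likelihood treats both parents as drawn from the population", {
  expect_equal(null_marker_likelihood(gm("AA"), c(0.5, 0.5)), 0.25)
  expect_equal(null_marker_likelihood(gm("AB"), c(0.5, 0.5)), 0.25)
  expect_equal(null_marker_likelihood(gm("AA"), c(0.3, 0.7)), 0.09)
})

test_that("trio LOD sums log ratios over informative SNPs", {
  st <- certain_store(list(o = "AA", s = "AA", d = "AA"))
  freq <- uniform_freq(st$snp_id)
  sc <- trio_lod(st, "o", "s", "d", freq, min_snps = 1)
  expect_equal(sc$lod, log(4))
  expect_equal(sc$n_snps, 1L)
  # both parents missing: numerator equals denominator
  sc0 <- trio_lod(st, "o", NA, NA, freq, min_snps = 1)
  expect_equal(sc0$lod, 0)
  # fewer informative SNPs than required: no score
  st9 <- certain_store(list(o = "AA", s = "AA", d = "AA"), n_snp = 9)
  expect_null(trio_lod(st9, "o", "s", "d", uniform_freq(st9$snp_id),
                       min_snps = 10))
})

test_that("LOD is unchanged by uninformative markers, increased by informative ones", {
  # AB x AB -> AB has likelihood ratio exactly 1 at f = 0.5
  st1 <- certain_store(list(o = "AB", s = "AB", d = "AB"), n_snp = 3)
  f1 <- uniform_freq(st1$snp_id)
  expect_equal(trio_lod(st1, "o", "s", "d", f1, min_snps = 1)$lod, 0)
  # appending an informative marker strictly increases the LOD
  st2 <- make_store(list(o = c(rep(list(gm("AB")), 3), list(gm("AA"))),
                         s = c(rep(list(gm("AB")), 3), list(gm("AA"))),
                         d = c(rep(list(gm("AB")), 3), list(gm("AA")))))
  f2 <- uniform_freq(st2$snp_id)
  expect_equal(trio_lod(st2, "o", "s", "d", f2, min_snps = 1)$lod, log(4))
})

test_that("a Mendelian-impossible marker drives the LOD to -Inf", {
  st <- make_store(list(o = list(gm("BB"), gm("AB")),
                        s = list(gm("AA"), gm("AB")),
                        d = list(gm("AA"), gm("AB"))))
  sc <- trio_lod(st, "o", "s", "d", uniform_freq(st$snp_id), min_snps = 1)
  expect_equal(sc$lod, -Inf)
})

test_that("trio scores fall back to the better single-parent pair", {
  trio <- list(lod = 8, n_snps = 30)
  sp <- list(lod = 3, n_snps = 30)
  dp <- list(lod = 2, n_snps = 30)
  expect_equal(resolve_trio(trio, sp, dp)$lod, 8)
  expect_equal(resolve_trio(list(lod = 2), list(lod = 5), list(lod = 1))$lod, 5)
  expect_equal(resolve_trio(NULL, NULL, list(lod = 4))$lod, 4)
  expect_null(resolve_trio(NULL, NULL, NULL))
})

test_that("assignment categories follow the LOD ordering rules", {
  expect_equal(classify_assignment(5, 3, 2), "sire+dam")
  expect_equal(classify_assignment(3, 4, -1), "sire+missing")
  expect_equal(classify_assignment(3, -1, 4), "dam+missing")
  expect_equal(classify_assignment(2, 4, 3), "either+missing")
  expect_equal(classify_assignment(-2, -1, -3), "both_missing")
  expect_equal(classify_assignment(NA, 4, NA), "sire+missing")
})

test_that("exclusion counts Mendelian-impossible markers", {
  st <- certain_store(list(o = "BB", s = "AA", d = "AA"), kind = "discrete")
  expect_equal(count_mismatches(st, "o", "s", "d")$mismatches, 1L)
  st2 <- certain_store(list(o = "AB", s = "AA", d = "BB"), kind = "discrete")
  expect_equal(count_mismatches(st2, "o", "s", "d")$mismatches, 0L)
  st3 <- certain_store(list(o = "AB", s = "AA", d = "AA"), kind = "discrete")
  expect_equal(count_mismatches(st3, "o", "s", "d")$mismatches, 1L)
  # a marker missing in any member is skipped
  st4 <- make_store(list(o = list(gm("BB"), NULL), s = list(gm("AA"), gm("AA")),
                         d = list(gm("AA"), gm("AA"))), kind = "discrete")
  mm <- count_mismatches(st4, "o", "s", "d")
  expect_equal(mm$mismatches, 1L)
  expect_equal(mm$n_snps, 1L)
})

test_that("ranking applies LOD and delta thresholds", {
  trio <- matrix(c(7.2, 3.0), 1, 2, dimnames = list("s1", c("d1", "d2")))
  rk <- rank_parent_pairs(fake_scores(trio))
  expect_true(rk$assigned)
  expect_equal(rk$delta, 4.2)
  expect_equal(c(rk$sire_id, rk$dam_id), c("s1", "d1"))
  # insufficient margin between the top two pairs
  trio2 <- matrix(c(7.2, 6.0), 1, 2, dimnames = list("s1", c("d1", "d2")))
  rk2 <- rank_parent_pairs(fake_scores(trio2))
  expect_false(rk2$assigned)
  expect_equal(rk2$delta, 1.2)
})

test_that("ranking resolves trios against single-parent fallbacks", {
  trio <- matrix(c(2, 1), 1, 2, dimnames = list("s1", c("d1", "d2")))
  rk <- rank_parent_pairs(fake_scores(trio, sire_pair = 5),
                          lod_threshold = 3, delta_threshold = 1)
  expect_equal(rk$lod, 5)
  expect_true(is.na(rk$dam_id))
  expect_equal(rk$category, "sire+missing")
})

test_that("exclusion ranking tolerates the allowed mismatch count", {
  mm <- matrix(c(0, 4), 1, 2, dimnames = list("s1", c("d1", "d2")))
  rk <- rank_parent_pairs(fake_scores(mm, method = "exclusion"),
                          max_mismatches = 3)
  expect_true(rk$assigned)
  expect_equal(rk$mismatches, 0L)
  rk0 <- rank_parent_pairs(fake_scores(mm + 1, method = "exclusion"),
                           max_mismatches = 0)
  expect_false(rk0$assigned)
})

test_that("quantitative and perturbed scoring agree on clean, tight data", {
  sim <- clean_sim(41, cluster_sd_range = c(0.003, 0.006))
  mats <- proportion_matrix(sim$assays)
  panel <- calibrate_panel(mats$p, mats$call)
  gs <- quantitative_genotypes(mats$p, panel)
  freq <- estimate_allele_frequencies(gs, c(sim$truth$sires, sim$truth$dams))
  ds <- discrete_genotypes(gs)
  ms <- perturbed_genotypes(ds, 0, freq)
  rk_q <- rank_parent_pairs(score_parentage(gs, sim$truth$offspring,
                                            sim$truth$sires, sim$truth$dams,
                                            freq))
  rk_m <- rank_parent_pairs(score_parentage(ms, sim$truth$offspring,
                                            sim$truth$sires, sim$truth$dams,
                                            freq))
  expect_equal(rk_q$sire_id, rk_m$sire_id)
  expect_equal(rk_q$dam_id, rk_m$dam_id)
})

test_that("batch scoring matches the single-trio path", {
  sim <- clean_sim(51)
  mats <- proportion_matrix(sim$assays)
  panel <- calibrate_panel(mats$p, mats$call)
  gs <- quantitative_genotypes(mats$p, panel)
  freq <- estimate_allele_frequencies(gs, c(sim$truth$sires, sim$truth$dams))
  sc <- score_parentage(gs, sim$truth$offspring[1:4], sim$truth$sires,
                        sim$truth$dams, freq)
  for (o in sim$truth$offspring[1:4]) {
    s <- sample(sim$truth$sires, 1); d <- sample(sim$truth$dams, 1)
    single <- trio_lod(gs, o, s, d, freq)
    expect_equal(sc$scores[[o]]$trio[s, d], single$lod, tolerance = 1e-10)
    pair <- trio_lod(gs, o, s, NA, freq)
    expect_equal(unname(sc$scores[[o]]$sire_pair[s]), pair$lod,
                 tolerance = 1e-10)
  }
})
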