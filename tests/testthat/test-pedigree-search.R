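opt_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(sire_id = r[[1]], dam_id = r[[2]], lod = as.numeric(r[[3]]),
               stringsAsFactors = FALSE)))
  df[order(-df$lod), , drop = FALSE]
}

test_that("greedy assignment picks the best feasible option", {
  opts <- list(o1 = opt_df(list("s1", "d1", 5), list("s2", "d2", 3)))
  set.seed(1)
  sol <- greedy_random_pedigree(opts, max_mates = 1)
  expect_equal(sol$assignments$sire_id, "s1")
  expect_equal(sol$total_lod, 5)
})

test_that("full-sib constraint redirects later offspring to the open option", {
  opts <- list(o1 = opt_df(list("s1", "d1", 5)),
               o2 = opt_df(list("s1", "d2", 6), list("s1", "d1", 4)))
  # the optimum keeps both offspring in family (s1, d1): total 9, versus 6
  best <- stochastic_search(opts, max_mates = 1, n_restarts = 20, seed = 2)
  expect_equal(best$total_lod, 9)
  expect_equal(best$assignments$dam_id, c("d1", "d1"))
  expect_equal(best$total_lod,
               exhaustive_best_pedigree(opts, max_mates = 1))
})

test_that("unrestricted search decouples offspring", {
  opts <- list(o1 = opt_df(list("s1", "d1", 5)),
               o2 = opt_df(list("s1", "d2", 6)),
               o3 = opt_df(list("s1", "d3", 2), list("s2", "d3", 1)))
  sol <- stochastic_search(opts, max_mates = Inf, n_restarts = 5, seed = 3)
  expect_equal(sol$total_lod, 13)
})

test_that("offspring with no feasible positive option fall back to both-missing", {
  opts <- list(o1 = opt_df(list("s1", "d1", 5)),
               o2 = opt_df(list("s1", "d2", 1)),
               o3 = list(data.frame(sire_id = character(),
                                    dam_id = character(), lod = numeric()))[[1]])
  sol <- stochastic_search(opts, max_mates = 1, n_restarts = 20, seed = 4)
  expect_equal(sol$total_lod, 5)
  expect_true(is.na(sol$assignments$sire_id[sol$assignments$offspring_id == "o3"]))
})

test_that("stochastic search attains the exhaustive optimum on small instances", {
  set.seed(99)
  for (i in 1:15) {
    opts <- random_search_instance(n_off = sample(3:5, 1),
                                   n_opts = sample(2:4, 1))
    for (mm in c(1, 2)) {
      got <- stochastic_search(opts, max_mates = mm, n_restarts = 200,
                               seed = i)$total_lod
      want <- exhaustive_best_pedigree(opts, max_mates = mm)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("relaxing the mating constraint never lowers the best total LOD", {
  set.seed(7)
  for (i in 1:8) {
    opts <- random_search_instance(n_off = 5, n_opts = 4)
    lods <- vapply(c(1, 2, Inf), function(mm)
      stochastic_search(opts, max_mates = mm, n_restarts = 100,
                        seed = 11)$total_lod, numeric(1))
    expect_true(all(diff(lods) >= -1e-12))
  }
})

test_that("solutions respect the mating constraint", {
  set.seed(13)
  for (i in 1:5) {
    opts <- random_search_instance(n_off = 6, n_opts = 4)
    sol <- stochastic_search(opts, max_mates = 2, n_restarts = 50, seed = i)
    fam <- unique(sol$assignments[!is.na(sol$assignments$sire_id) |
                                  !is.na(sol$assignments$dam_id),
                                  c("sire_id", "dam_id")])
    expect_true(all(table(fam$sire_id[!is.na(fam$sire_id)]) <= 2))
    expect_true(all(table(fam$dam_id[!is.na(fam$dam_id)]) <= 2))
  }
})

test_that("search is deterministic given its seed and replicates across seeds", {
  sim <- clean_sim(61)
  mats <- proportion_matrix(sim$assays)
  panel <- calibrate_panel(mats$p, mats$call)
  gs <- quantitative_genotypes(mats$p, panel)
  freq <- estimate_allele_frequencies(gs, c(sim$truth$sires, sim$truth$dams))
  opts <- pedigree_options(score_parentage(gs, sim$truth$offspring,
                                           sim$truth$sires, sim$truth$dams,
                                           freq))
  a <- stochastic_search(opts, max_mates = 1, n_restarts = 50, seed = 5)
  b <- stochastic_search(opts, max_mates = 1, n_restarts = 50, seed = 5)
  expect_identical(a$assignments, b$assignments)
  # well-separated data: different seeds reach the same solution
  c_ <- stochastic_search(opts, max_mates = 1, n_restarts = 50, seed = 6)
  expect_equal(a$assignments[c("sire_id", "dam_id")],
               c_$assignments[c("sire_id", "dam_id")])
  # and it is the true pedigree
  expect_equal(a$assignments$sire_id, sim$truth$pedigree$sire_id)
  expect_equal(a$assignments$dam_id, sim$truth$pedigree$dam_id)
})

test_that("pedigree summaries count families and parents", {
  empty <- greedy_random_pedigree(list(), max_mates = 1)
  s0 <- pedigree_summary(empty)
  expect_equal(s0$n_families, 0)
  expect_equal(s0$total_lod, 0)
  opts <- list(o1 = opt_df(list("s1", "d1", 5)),
               o2 = opt_df(list("s1", "d1", 4)),
               o3 = opt_df(list("s2", NA_character_, 3)))
  sol <- stochastic_search(opts, max_mates = 1, n_restarts = 10, seed = 1)
  s <- pedigree_summary(sol)
  expect_equal(s$n_families, 2)
  expect_equal(s$largest_family, 2)
  expect_equal(s$n_missing_dam, 1)
  expect_equal(s$total_lod, 12)
})
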