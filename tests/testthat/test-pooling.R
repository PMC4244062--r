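mus <- list(mu_AA = 0.1, mu_AB = 0.45, mu_BB = 0.9)

test_that("piecewise frequency map anchors at the cluster means", {
  f <- function(p) pooled_allele_frequency(p, mus$mu_AA, mus$mu_AB, mus$mu_BB)
  expect_equal(f(0.45), 0.5)
  expect_equal(f(0.05), 0)
  expect_equal(f(0.95), 1)
  expect_equal(f(0.1), 0)
  expect_equal(f(0.9), 1)
  expect_equal(f((0.45 + 0.9) / 2), 0.75)
  expect_equal(f((0.1 + 0.45) / 2), 0.25)
  expect_true(is.na(f(NA)))
  expect_true(is.na(pooled_allele_frequency(0.5, NA, 0.45, 0.9)))
})

test_that("frequency map is non-decreasing and inverts the simulator map", {
  p <- seq(0, 1, by = 0.01)
  f <- pooled_allele_frequency(p, mus$mu_AA, mus$mu_AB, mus$mu_BB)
  expect_true(all(diff(f) >= 0))
  # round trip through the inverse map is the identity
  ftrue <- seq(0, 1, by = 0.05)
  p_back <- frequency_to_proportion(ftrue, mus$mu_AA, mus$mu_AB, mus$mu_BB)
  expect_equal(pooled_allele_frequency(p_back, mus$mu_AA, mus$mu_AB,
                                       mus$mu_BB),
               ftrue, tolerance = 1e-12)
})

test_that("pool weights use the Welch statistic of the containing interval", {
  expect_equal(pool_weight(0.45, 0.45, 10, 20), 10)  # boundary goes to tau_A
  expect_equal(pool_weight(0.4501, 0.45, 10, 20), 20)
  expect_true(is.na(pool_weight(NA, 0.45, 10, 20)))
})

test_that("individual-based pool frequencies average member estimates", {
  panel <- data.frame(snp_id = "s1", mu_AA = 0.1, mu_AB = 0.45, mu_BB = 0.9,
                      row.names = "s1")
  p <- matrix(c(0.1, 0.1), 1, 2, dimnames = list("s1", c("i1", "i2")))
  expect_equal(unname(individual_pool_frequency(p, c("i1", "i2"), panel)), 0)
  p2 <- matrix(c(0.1, 0.9), 1, 2, dimnames = list("s1", c("i1", "i2")))
  expect_equal(unname(individual_pool_frequency(p2, c("i1", "i2"), panel)), 0.5)
  p3 <- matrix(c(0.1, 0.45), 1, 2, dimnames = list("s1", c("i1", "i2")))
  expect_equal(unname(individual_pool_frequency(p3, c("i1", "i2"), panel)), 0.25)
  # members without data are skipped; none at all gives NA
  p4 <- matrix(c(NA, 0.45), 1, 2, dimnames = list("s1", c("i1", "i2")))
  expect_equal(unname(individual_pool_frequency(p4, c("i1", "i2"), panel)), 0.5)
  p5 <- matrix(c(NA, NA), 1, 2, dimnames = list("s1", c("i1", "i2")))
  expect_true(is.na(individual_pool_frequency(p5, c("i1", "i2"), panel)))
})

test_that("family frequency matrix encodes Mendelian expectations", {
  st <- certain_store(list(s1 = "AA", d1 = "BB", s2 = "AB"))
  freq <- data.frame(snp_id = st$snp_id, f_A = 0.4, f_B = 0.6)
  fams <- data.frame(family_id = c("f1", "f2", "f3"),
                     sire_id = c("s1", "s2", NA),
                     dam_id = c("d1", "s1", NA), stringsAsFactors = FALSE)
  X <- family_frequency_matrix(fams, st, freq)
  expect_equal(unname(X[1, ]), c(0.5, 0.25, 0.6))
})

test_that("contribution solver recovers exact mixtures", {
  est <- estimate_contributions(diag(2), c(0.3, 0.7))
  expect_equal(unname(est$beta), c(0.3, 0.7))
  # noiseless 58 x 12 recovery
  set.seed(5)
  X <- matrix(sample(c(0, 0.25, 0.5, 0.75, 1), 58 * 12, replace = TRUE),
              58, 12)
  beta_true <- runif(12); beta_true <- beta_true / sum(beta_true)
  est2 <- estimate_contributions(X, as.vector(X %*% beta_true))
  expect_lt(max(abs(est2$beta - beta_true)), 1e-6)
})

test_that("contributions are non-negative, normalised and weight-scale invariant", {
  set.seed(6)
  X <- matrix(runif(30 * 5), 30, 5)
  y <- runif(30)
  w <- runif(30, 0.5, 4)
  est <- estimate_contributions(X, y, w)
  expect_true(all(est$beta >= 0))
  expect_equal(sum(est$beta), 1, tolerance = 1e-9)
  est2 <- estimate_contributions(X, y, 2 * w)
  expect_equal(est$beta, est2$beta, tolerance = 1e-9)
})

test_that("missing cells are filled with their neutral values", {
  X <- matrix(c(1, NA, 0, 1), 2, 2)
  y <- c(0.6, NA)
  est <- estimate_contributions(X, y, c(NA, 2))
  X2 <- matrix(c(1, 0.5, 0, 1), 2, 2)
  est2 <- estimate_contributions(X2, c(0.6, 0.5), c(1, 2))
  expect_equal(est$beta, est2$beta)
})

test_that("weighted NNLS agrees with an independent constrained solver", {
  skip_if_not_installed("mgcv")
  set.seed(8)
  X <- matrix(runif(40 * 6), 40, 6)
  beta_true <- c(0.3, 0.25, 0.2, 0.15, 0.1, 0)
  y <- as.vector(X %*% beta_true) + rnorm(40, 0, 0.01)
  w <- runif(40, 0.5, 2)
  est <- estimate_contributions(X, y, w)
  M <- list(y = sqrt(w) * y, X = sqrt(w) * X, w = rep(1, 40),
            Ain = diag(6), bin = rep(0, 6), C = matrix(0, 0, 0),
            S = list(), off = NULL, sp = NULL,
            p = rep(0.2, 6))
  beta_pcls <- as.numeric(mgcv::pcls(M))
  expect_equal(unname(est$beta), beta_pcls / sum(beta_pcls),
               tolerance = 1e-4)
})

test_that("an all-zero design column is flagged as unidentifiable", {
  X <- cbind(c(0.5, 0.25), 0)
  colnames(X) <- c("f1", "f2")
  expect_warning(est <- estimate_contributions(X, c(0.5, 0.25)),
                 "unidentifiable")
  expect_equal(sum(est$beta), 1, tolerance = 1e-9)
})
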