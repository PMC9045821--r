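matrix_from_counts <- function(n_mod, n_tot, position = 20, sample = "s") {
  probs <- cbind(c(rep(0.95, n_mod), rep(0.05, n_tot - n_mod)))
  mod_profile_matrix(probs,
                     data.frame(read_id = sprintf("%s_%04d", sample, seq_len(n_tot)),
                                sample = sample, stringsAsFactors = FALSE),
                     data.frame(contig = "c", position = position,
                                stringsAsFactors = FALSE))
}

multi_site_matrix <- function(freqs, n, sample = "s") {
  probs <- sapply(freqs, function(f)
    sample(c(rep(0.95, round(f * n)), rep(0.05, n - round(f * n)))))
  mod_profile_matrix(probs,
                     data.frame(read_id = sprintf("%s_%04d", sample, seq_len(n)),
                                sample = sample, stringsAsFactors = FALSE),
                     data.frame(contig = "c",
                                position = seq(20, by = 10, along.with = freqs),
                                stringsAsFactors = FALSE))
}

test_that("a strong frequency change passes every filter", {
  wt <- lapply(c(950, 960, 940), matrix_from_counts, n_tot = 1000)
  ex <- matrix_from_counts(600, 1000)
  res <- frequency_change_test(ex, wt)
  expect_equal(res$delta_min, 0.34)
  expect_lt(res$p_max, 1e-6)
  expect_true(res$pass_q && res$pass_global && res$pass_wt_range && res$changed)
  # direct chi-square oracle for the most conservative pair (0.94 vs 0.60)
  oracle <- chisq.test(rbind(c(940, 60), c(600, 400)), correct = FALSE)$p.value
  expect_equal(res$p_max, unname(oracle), tolerance = 1e-12)
})

test_that("identical counts give chi-square p = 1 and no flag", {
  wt <- lapply(1:3, function(i) matrix_from_counts(500, 1000))
  ex <- matrix_from_counts(500, 1000)
  res <- frequency_change_test(ex, wt)
  expect_equal(res$p_max, 1)
  expect_equal(res$delta_min, 0)
  expect_false(res$changed)
})

test_that("null experiments are flagged at no more than alpha plus MC error", {
  set.seed(61)
  n_sites <- 120; n <- 400
  freqs <- runif(n_sites, 0.3, 0.9)
  gen <- function(s) multi_site_matrix(freqs, n, s)
  res <- frequency_change_test(gen("e1"), list(gen("w1"), gen("w2"), gen("w3")))
  # q-significance alone (before the effect-size filters)
  expect_lte(mean(res$pass_q), 0.05 + 3 * sqrt(0.05 * 0.95 / n_sites))
  expect_lte(mean(res$changed), mean(res$pass_q))
})

test_that("frequency test is symmetric in replicate order", {
  wt <- lapply(c(900, 850, 880), matrix_from_counts, n_tot = 1000)
  ex <- matrix_from_counts(700, 1000)
  r1 <- frequency_change_test(ex, wt)
  r2 <- frequency_change_test(ex, rev(wt))
  expect_equal(r1$p_max, r2$p_max)
  expect_equal(r1$delta_min, r2$delta_min)
  expect_equal(r1$wt_range, r2$wt_range)
})

test_that("pairwise Spearman: monotone transforms, nulls, planted copulas", {
  # monotone transform gives rho = 1
  set.seed(71)
  a <- runif(200)
  m <- mod_profile_matrix(cbind(a, a^3),
                          sprintf("r%03d", 1:200),
                          data.frame(contig = "c", position = c(20, 30)))
  ps <- pairwise_spearman(m)
  expect_equal(ps$rho, 1)
  expect_equal(ps$p, 0)

  # independent columns: type-I error near 5%
  set.seed(72)
  n <- 500; k <- 12
  probs <- matrix(runif(n * k), n, k)  # 66 pairs
  m2 <- mod_profile_matrix(probs, sprintf("r%04d", 1:n),
                           data.frame(contig = "c", position = seq(20, by = 5, length.out = k)))
  ps2 <- pairwise_spearman(m2)
  expect_lt(abs(mean(ps2$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(ps2)) + 0.02)

  # planted bivariate Gaussian copula with Spearman rho = 0.6
  set.seed(73)
  n <- 1000
  r_latent <- 2 * sin(0.6 * pi / 6)
  z1 <- rnorm(n); z2 <- r_latent * z1 + sqrt(1 - r_latent^2) * rnorm(n)
  m3 <- mod_profile_matrix(cbind(pnorm(z1), pnorm(z2)), sprintf("r%04d", 1:n),
                           data.frame(contig = "c", position = c(20, 30)))
  ps3 <- pairwise_spearman(m3)
  expect_lt(abs(ps3$rho - 0.6), 0.05)

  # constant column: undefined with warning
  m4 <- mod_profile_matrix(cbind(rep(0.5, 50), runif(50)), sprintf("r%03d", 1:50),
                           data.frame(contig = "c", position = c(20, 30)))
  expect_warning(ps4 <- pairwise_spearman(m4), "constant")
  expect_true(is.na(ps4$rho))
})

test_that("Fisher z comparison: equality, the closed-form case, and the dual star rule", {
  expect_equal(fisher_z_test(0.4, 100, 0.4, 200), 1)
  # rho 0.5 vs 0.0 at n = 103 each: Z = atanh(0.5)/sqrt(2/100) ~ 3.884
  p <- fisher_z_test(0.5, 103, 0.0, 103)
  expect_equal(p, 2 * pnorm(-atanh(0.5) / sqrt(2 / 100)), tolerance = 1e-12)
  expect_equal(p, 1.0e-4, tolerance = 0.05)
  expect_error(fisher_z_test(1, 50, 0.2, 50), "infinite")
  expect_error(fisher_z_test(0.5, 3, 0.2, 50), "n > 3")

  pairs_tbl <- function(rho, n = 103) data.frame(
    site_i = c("c:20", "c:20", "c:30"), site_j = c("c:30", "c:40", "c:40"),
    rho = rho, n = n, p = NA, q = NA, stringsAsFactors = FALSE)
  # pair 1: different between samples AND nonzero in focal -> star
  # pair 2: different between samples but focal rho ~ 0 -> no star
  # pair 3: no difference -> no star
  a <- pairs_tbl(c(0.6, 0.02, 0.30))
  b <- pairs_tbl(c(0.0, 0.60, 0.30))
  res <- compare_correlations(a, b)
  expect_equal(res$star, c(TRUE, FALSE, FALSE))
  expect_equal(res$delta_rho[3], 0)
  expect_equal(res$q[3], 1)

  # compare with itself: p = 1 everywhere
  self <- compare_correlations(a, a)
  expect_true(all(self$q == 1))
  expect_true(all(self$delta_rho == 0))
})

test_that("replicate aggregation takes the smallest difference and largest q", {
  tbl <- function(rho) data.frame(site_i = "c:20", site_j = "c:30", rho = rho,
                                  n = 200, p = NA, q = NA, stringsAsFactors = FALSE)
  res <- compare_correlations(list(tbl(0.5), tbl(0.55)), list(tbl(0.1), tbl(0.2)))
  expect_equal(res$delta_rho, 0.3)  # 0.5 - 0.2, the smallest |difference|
  worst_p <- fisher_z_test(0.5, 200, 0.2, 200)
  expect_equal(res$q, worst_p, tolerance = 1e-12)
})

test_that("Empirical Brown's method: identity, independence and duplication limits", {
  # m = 1 reduces to the input p
  one <- empirical_browns(0.031, data = cbind(rnorm(100)))
  expect_equal(one$p, 0.031, tolerance = 1e-12)
  expect_equal(one$f, 2)
  expect_equal(one$c, 1)

  # with the covariance forced to zero it reduces exactly to Fisher
  ps <- c(0.01, 0.2, 0.5)
  red <- empirical_browns(ps, data = NULL)
  expect_equal(red$p, fishers_method(ps), tolerance = 1e-15)

  # independence: f within 2m +/- 10%, combined p within 1.5x of Fisher
  set.seed(81)
  m <- 5; n <- 2000
  ratios <- replicate(40, {
    data <- matrix(rnorm(n * m), n, m)
    pv <- runif(m, 0.01, 0.5)
    eb <- empirical_browns(pv, data)
    c(eb$f, eb$p / eb$fisher_p)
  })
  expect_lt(mean(abs(ratios[1, ] - 2 * m)), 0.1 * 2 * m)
  expect_true(all(ratios[2, ] > 1 / 1.5 & ratios[2, ] < 1.5))

  # two identical columns ~ single test with halved df (perfect dependence)
  set.seed(82)
  x <- rnorm(2000)
  pv <- c(0.03, 0.03)
  dup <- empirical_browns(pv, cbind(x, x))
  stat <- -2 * sum(log(pv))
  halved <- pchisq(stat / 2, df = 2, lower.tail = FALSE)
  expect_equal(dup$p, halved, tolerance = 0.05)

  expect_warning(empirical_browns(c(0, 0.5), data = NULL), "clipped")
})

test_that("BH correction is monotone after the step-up pass", {
  set.seed(91)
  for (i in 1:5) {
    p <- runif(50)^2
    q <- p.adjust(p, "BH")
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
  }
})
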