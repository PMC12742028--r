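test_that("grand-mean threshold classifier handles the canonical cases", {
  expect_equal(univariate_threshold_accuracy(rep(0, 50), rep(1, 50),
                                             "low_is_positive"), 1.0)
  set.seed(2)
  v <- rnorm(2000)
  acc <- univariate_threshold_accuracy(v[1:1000], v[1001:2000],
                                       "high_is_positive")
  expect_lt(abs(acc - 0.5), 0.05)
  # degenerate zero-variance data scores 0.5 by the tie convention
  expect_equal(univariate_threshold_accuracy(rep(3, 5), rep(3, 7),
                                             "low_is_positive"), 0.5)
})

test_that("threshold accuracy converges to Phi(d/2) for Gaussian classes", {
  set.seed(7)
  n <- 1e5
  acc <- univariate_threshold_accuracy(rnorm(n, 0.4), rnorm(n, 0),
                                       "high_is_positive")
  expect_lt(abs(acc - pnorm(0.2)), 0.01)
})

test_that("boundary sweep improves only where asymmetry allows", {
  set.seed(3)
  a <- rnorm(5000, 1); b <- rnorm(5000, -1)
  grid <- seq(-2, 2, by = 0.01)
  sw <- boundary_sweep(a, b, "high_is_positive", grid)
  expect_lt(sw$delta, 0.01)            # symmetric: grand mean near-optimal
  expect_gte(sw$best_accuracy, sw$grand_mean_accuracy)  # grid superset
  # skewed class sizes can beat the grand mean
  a2 <- rnorm(9000, 0.5); b2 <- rnorm(1000, -0.5)
  sw2 <- boundary_sweep(a2, b2, "high_is_positive", grid)
  expect_gt(sw2$delta, 0)
  expect_error(boundary_sweep(a, b, "high_is_positive", numeric(0)),
               "empty")
})

test_that("Cohen's d follows its definition", {
  set.seed(4)
  x <- rnorm(50)
  expect_equal(cohens_d(x, x), 0)
  y <- rnorm(200); z <- y + sd(y)
  expect_equal(cohens_d(z, y), 1, tolerance = 1e-10)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero pooled")
})

test_that("exact binomial test matches closed forms and is symmetric", {
  expect_equal(binomial_vs_chance(5, 10), 1.0)
  expect_equal(binomial_vs_chance(10, 10), 2 * 0.5^10)
  for (k in 0:20)
    expect_equal(binomial_vs_chance(k, 20), binomial_vs_chance(20 - k, 20))
})

test_that("binomial test is type-I calibrated at both epoch counts", {
  set.seed(12)
  for (n in c(75, 300)) {
    k <- rbinom(5000, n, 0.5)
    rej <- mean(vapply(k, binomial_vs_chance, 0, n = n) < 0.05)
    expect_lte(rej, 0.05 + 2 * sqrt(0.05 * 0.95 / 5000))
  }
})

test_that("Fisher combination matches hand computation and edge cases", {
  fc <- fisher_combine(c(0.1, 0.1))
  expect_equal(fc$chi2, -2 * (log(0.1) + log(0.1)), tolerance = 1e-10)
  expect_equal(fc$chi2, 9.2103, tolerance = 1e-4)
  expect_equal(fc$df, 4)
  expect_equal(fc$p, pchisq(9.2103404, 4, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(fc$p, 0.05605, tolerance = 1e-3)
  expect_equal(fisher_combine(0.37)$p, 0.37, tolerance = 1e-12)
  all1 <- fisher_combine(c(1, 1, 1))
  expect_equal(all1$chi2, 0)
  expect_equal(all1$p, 1)
  expect_warning(fisher_combine(c(0, 0.5)), "clipped")
  expect_error(fisher_combine(numeric(0)), "no p-values")
})

test_that("Fisher combination of uniform p-values is uniform", {
  set.seed(9)
  comb <- replicate(5000, fisher_combine(runif(5))$p)
  expect_gt(stats::ks.test(comb, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches hand computation and respects families", {
  expect_equal(bh_fdr(0.03, "univariate"), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), rep("univariate", 4)),
               rep(0.04, 4))
  p <- c(0.001, 0.04, 0.001, 0.04, 0.9)
  fam <- c("univariate", "univariate", "multivariate", "multivariate",
           "multivariate")
  adj <- bh_fdr(p, fam)
  # family B unchanged when family A grows
  adj2 <- bh_fdr(c(p, 0.5), c(fam, "univariate"))
  expect_equal(adj[fam == "multivariate"], adj2[c(3, 4, 5)])
  expect_error(bh_fdr(0.5, "exploratory"), "unknown family")
})

test_that("BH controls the empirical FDR in an all-null 44-test family", {
  set.seed(15)
  fdp <- replicate(2000, {
    p <- vapply(rbinom(44, 75, 0.5), binomial_vs_chance, 0, n = 75)
    disc <- sum(stats::p.adjust(p, "BH") < 0.05)
    disc / max(disc, 1)
  })
  expect_lte(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(2000))
})

test_that("participant summaries combine binomial evidence correctly", {
  # all participants exactly at chance: every p = 1, combined p = 1
  rep0 <- participant_summary(data.frame(k = rep(30, 10), n = rep(60, 10)))
  expect_true(all(rep0$p_per_participant == 1))
  expect_equal(rep0$p_combined, 1)
  # 41 participants -> 41 p-values and a CI that covers the mean
  set.seed(18)
  d41 <- data.frame(k = rbinom(41, 75, 0.55), n = 75)
  rep41 <- participant_summary(d41)
  expect_length(rep41$p_per_participant, 41)
  expect_true(rep41$ci95[1] < rep41$mean_accuracy &&
                rep41$mean_accuracy < rep41$ci95[2])
  # evidence spread weakly over everyone: Fisher accumulates it while a
  # Bonferroni-corrected minimum stays non-significant
  d <- data.frame(k = rep(45, 10), n = 75)
  repf <- participant_summary(d)
  expect_lt(repf$p_combined, 0.05)
  expect_lt(repf$p_combined, min(repf$p_per_participant) * 10)
})

test_that("covariate correlations: monotone, null-calibrated, outlier-robust", {
  x <- 1:10
  r <- covariate_correlation(x, x^3)
  expect_equal(r$spearman_rho, 1)
  # evidence of absence under independence
  set.seed(25)
  bfs <- replicate(50, covariate_correlation(rnorm(41), rnorm(41))$bf10)
  expect_lt(median(bfs), 1)
  # an extreme outlier is excluded
  m <- c(rnorm(20), 50)
  cv <- rnorm(21)
  rr <- covariate_correlation(m, cv)
  expect_lte(rr$n_after_outlier_removal, 20)
  expect_error(covariate_correlation(rep(1, 10), rnorm(10)),
               "constant")
})
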