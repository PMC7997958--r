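# core one-tailed combiners ------------------------------------------------

test_that("single-study identity holds for every combiner", {
  p <- c(0.37, 0.05, 0.2, 0.4, 0.2, 0.9, 1e-12)
  fns <- list(
    function(p) fisher_combine(p),
    function(p) stouffer_combine(p),
    function(p) weighted_z_combine(p, n = 100),
    function(p) lancaster_combine(p, df = 7),
    function(p) wfisher_combine(p, n = 123),
    function(p) ordmeta_combine(p),
    function(p) rop_combine(p, r = 1))
  for (fn in fns)
    for (pp in p)
      expect_equal(fn(pp)$p, pp, tolerance = 1e-12)
})

test_that("Fisher matches its chi-squared closed form and endpoints", {
  # chi-squared(4) survival at t is exp(-t/2) (1 + t/2)
  t4 <- -4 * log(0.1)
  expect_equal(fisher_combine(c(0.1, 0.1))$p, exp(-t4 / 2) * (1 + t4 / 2),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.1, 0.1))$p, 0.0560517, tolerance = 1e-6)
  expect_warning(at_one <- fisher_combine(c(1, 1)), "clamped")
  expect_equal(at_one$p, 1)
  expect_equal(fisher_combine(c(0.1, 0.1))$df_total, 4)
  expect_error(fisher_combine(numeric(0)), "non-empty")
})

test_that("Stouffer and weighted Z match direct normal evaluation", {
  expect_equal(stouffer_combine(c(0.5, 0.5))$p, 0.5)
  z <- 2 * qnorm(0.975) / sqrt(2)
  expect_equal(stouffer_combine(c(0.025, 0.025))$p, pnorm(z, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(stouffer_combine(c(0.025, 0.025))$statistic, 2.7718, tolerance = 1e-4)
  # sqrt(sample size) weights, normalised by the root of their square sum
  p <- c(0.01, 0.5); s <- c(400, 100)
  zor <- sum(sqrt(s) * qnorm(1 - p)) / sqrt(sum(s))
  expect_equal(weighted_z_combine(p, n = s)$p, pnorm(zor, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(weighted_z_combine(c(0.1, 0.2)), "sample size")
})

test_that("Lancaster matches direct chi-squared evaluation and rejects bad df", {
  p <- c(0.1, 0.1); d <- c(30, 60)
  stat <- sum(qchisq(p, df = d, lower.tail = FALSE))
  expect_equal(lancaster_combine(p, df = d)$p,
               pchisq(stat, df = 90, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(lancaster_combine(0.2, df = 7)$p, 0.2, tolerance = 1e-12)
  expect_error(lancaster_combine(p, df = c(0, 5)), "positive")
  # non-integer df are honoured through the gamma form, not rounded
  expect_equal(lancaster_combine(0.2, df = 2.5)$p, 0.2, tolerance = 1e-12)
})

test_that("wFisher matches direct gamma evaluation with proportional shapes", {
  p <- c(0.01, 0.5); s <- c(100, 50)
  k <- 2 * s / sum(s)                    # c(4/3, 2/3)
  expect_equal(wfisher_combine(p, n = s)$shape, k)
  stat <- sum(qgamma(p, shape = k, scale = 2, lower.tail = FALSE))
  expect_equal(wfisher_combine(p, n = s)$p,
               pgamma(stat, shape = 2, scale = 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(wfisher_combine(c(0.1, 0.1), n = c(50, 50))$p, 0.0560517,
               tolerance = 1e-6)
  expect_error(wfisher_combine(p), "sample size")
  expect_warning(wfisher_combine(c(0.1, 0.2), n = c(1, 1e9)), "clamped")
})

test_that("missing studies are dropped and weights renormalised", {
  r <- wfisher_combine(c(0.01, NA, 0.5), n = c(100, 77, 50))
  expect_equal(r$p, wfisher_combine(c(0.01, 0.5), n = c(100, 50))$p)
  expect_equal(r$n_studies, 2L)
  expect_error(study_evidence(c(NA_real_, NA_real_)), "non-missing")
  expect_error(study_evidence(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("extreme inputs survive in log space instead of underflowing", {
  expect_warning(r <- fisher_combine(c(0, 0.5)), "clamped")
  expect_gt(r$p, 0)
  r2 <- fisher_combine(c(1e-150, 1e-150))
  expect_gt(r2$p, 0)
  expect_lt(r2$p, 1e-290)
  # beyond double range the log-space value is still finite and exact
  r3 <- fisher_combine(c(1e-300, 1e-300))
  expect_true(is.finite(r3$log_p))
  expect_lt(r3$log_p, -1300)
  expect_true(is.finite(stouffer_combine(c(1e-310, 0.2))$statistic))
})

# invariance properties -----------------------------------------------------

test_that("reordering studies with their weights leaves the result unchanged", {
  set.seed(11)
  for (i in 1:20) {
    m <- sample(2:8, 1)
    p <- runif(m); s <- sample(30:500, m); sg <- sample(c(-1, 1), m, TRUE)
    perm <- sample(m)
    expect_equal(wfisher_combine(p, n = s)$p,
                 wfisher_combine(p[perm], n = s[perm])$p, tolerance = 1e-12)
    expect_equal(ordmeta_combine(p)$p, ordmeta_combine(p[perm])$p,
                 tolerance = 1e-12)
    expect_equal(combine_directional(p, sg, "stouffer")$p,
                 combine_directional(p[perm], sg[perm], "stouffer")$p,
                 tolerance = 1e-12)
  }
})

test_that("equal weights collapse the weighted methods onto their parents", {
  set.seed(12)
  for (i in 1:50) {
    m <- sample(2:10, 1)
    p <- runif(m)
    s <- rep(sample(30:2000, 1), m)
    expect_equal(wfisher_combine(p, n = s)$p, fisher_combine(p)$p,
                 tolerance = 1e-12)
    expect_equal(lancaster_combine(p, df = rep(2, m))$p, fisher_combine(p)$p,
                 tolerance = 1e-12)
    expect_equal(weighted_z_combine(p, n = s)$p, stouffer_combine(p)$p,
                 tolerance = 1e-12)
  }
})

test_that("decreasing any single p-value never increases the combined p", {
  set.seed(13)
  for (i in 1:25) {
    m <- sample(2:7, 1)
    p <- runif(m); s <- sample(30:500, m)
    j <- sample(m, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    for (fn in list(function(x) fisher_combine(x)$p,
                    function(x) stouffer_combine(x)$p,
                    function(x) weighted_z_combine(x, n = s)$p,
                    function(x) lancaster_combine(x, n = s)$p,
                    function(x) wfisher_combine(x, n = s)$p))
      expect_lte(fn(p2), fn(p) + 1e-14)
  }
})

test_that("null combined p-values are calibrated at the 5% level", {
  set.seed(14)
  reps <- 4000; m <- 5
  P <- matrix(runif(reps * m), reps, m)
  tol <- 3 * sqrt(0.05 * 0.95 / reps)
  for (method in c("fisher", "stouffer", "wz", "lancaster", "wfisher",
                   "ordmeta")) {
    rate <- mean(metacomb:::combine_matrix(P, method, sizes = 50) < 0.05)
    expect_lt(abs(rate - 0.05), tol, label = sprintf("%s rate", method))
  }
})

# directional wrapper -------------------------------------------------------

test_that("directional wrapper halves, synchronises, and doubles correctly", {
  # single study: recovers the two-tailed p exactly
  expect_equal(combine_directional(0.1, sign = 1, method = "fisher")$p, 0.1,
               tolerance = 1e-12)
  # discordant signs, closed chi-squared form
  stat <- -2 * (log(0.005) + log(0.995))
  expect_equal(combine_directional(c(0.01, 0.01), sign = c(1, -1),
                                   method = "fisher")$p,
               2 * exp(-stat / 2) * (1 + stat / 2), tolerance = 1e-10)
  # doubling is capped at 1
  expect_lte(combine_directional(c(0.9, 0.95), sign = c(1, -1),
                                 method = "fisher")$p, 1)
  expect_error(combine_directional(c(0.1, 0.2), method = "fisher"),
               "direction")
  expect_error(combine_pvalues(0.5, method = "nope"), "registered")
})

test_that("flipping all signs flips the direction but not the p-value", {
  set.seed(15)
  for (i in 1:20) {
    m <- sample(2:8, 1)
    p <- runif(m); sg <- sample(c(-1, 1), m, TRUE); s <- sample(30:500, m)
    for (method in c("fisher", "stouffer", "wfisher", "ordmeta")) {
      a <- combine_directional(p, sg, method, n = s)
      b <- combine_directional(p, -sg, method, n = s)
      expect_equal(a$p, b$p, tolerance = 1e-9)
      expect_equal(a$direction, -b$direction)
    }
  }
})

test_that("synchronized one-tailed inputs reproduce the published locus value", {
  r <- combine_directional(c(0.71, 0.39, 2.80e-6, 6.50e-6),
                           method = "ordmeta", synchronized = TRUE)
  expect_equal(signif(r$p, 3), 2.03e-9)
  expect_equal(r$optimal_order, 2L)
})
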