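# t-test generator ----------------------------------------------------------

test_that("zero-effect draws are uniform and seeded draws are reproducible", {
  cfg <- ttest_sim_config(n_assoc = 200, mean_range = c(0, 0),
                          p0_interval = c(0, 1), seed = 51)
  set.seed(cfg$seed)
  sim <- simulate_ttest_pvalues(cfg, m0 = 200)
  expect_gt(ks.test(sim$p[sim$truth], "punif")$p.value, 0.01)
  expect_gt(ks.test(sim$p[!sim$truth], "punif")$p.value, 0.01)
  set.seed(99); a <- simulate_ttest_pvalues(cfg, m0 = 10)
  set.seed(99); b <- simulate_ttest_pvalues(cfg, m0 = 10)
  expect_identical(a, b)
})

test_that("large effects at large sample sizes give small p1-values", {
  cfg <- ttest_sim_config(n_assoc = 300, sample_size_range = c(2000, 2000),
                          mean_range = c(0.1, 0.1), seed = 52)
  set.seed(cfg$seed)
  sim <- simulate_ttest_pvalues(cfg, m0 = 0)
  # noncentrality 0.1 * sqrt(2000) ~ 4.47: nearly all p1 far below 0.05
  expect_lt(median(sim$p), 1e-3)
  expect_gt(mean(sim$p < 0.05), 0.95)
})

test_that("config validation rejects degenerate ranges", {
  expect_error(ttest_sim_config(sample_size_range = c(2000, 30)), "increasing")
  expect_error(ttest_sim_config(p0_interval = c(0.5, 0.4)), "interval")
  expect_error(rnaseq_sim_config(n_assoc_studies = 30, n_studies = 20),
               "exceed")
  expect_error(rnaseq_sim_config(de_fraction = 0), "0, 1")
  expect_error(rnaseq_sim_config(min_fold_change = 0.9), "fold")
})

# vectorised kernels --------------------------------------------------------

test_that("matrix kernels agree with the per-vector combiners", {
  set.seed(53)
  P <- matrix(runif(40), 8, 5)
  sizes <- c(40, 100, 250, 30, 700)
  for (method in c("fisher", "stouffer", "wz", "lancaster", "wfisher",
                   "ordmeta", "rop")) {
    got <- metacomb:::combine_matrix(P, method, sizes = sizes, r = 2)
    want <- apply(P, 1, function(p)
      combine_pvalues(p, method = method, n = sizes, r = 2)$p)
    expect_equal(got, want, tolerance = 1e-10, label = method)
  }
})

# experiment drivers --------------------------------------------------------

test_that("type-I rates sit at the nominal level and saturate at alpha = 1", {
  res <- run_type1_experiment(m_values = c(2, 10), reps = 3000,
                              methods = c("fisher", "wfisher", "ordmeta"),
                              seed = 54)
  tol <- 3 * sqrt(0.05 * 0.95 / 3000)
  expect_true(all(abs(res$rate - 0.05) < tol))
  one <- run_type1_experiment(m_values = 2, reps = 200, methods = "fisher",
                              alpha = 1, seed = 54)
  expect_equal(one$rate, 1)
})

test_that("power grows with associated evidence and is null-calibrated at zero", {
  base <- ttest_sim_config(n_assoc = 0, n_unassoc_max = 6, reps = 800,
                           seed = 55)
  res0 <- run_power_experiment(base, methods = c("fisher", "ordmeta"),
                               m0_values = 6)
  # no associated p-values: power equals the cutoff up to MC error
  expect_true(all(abs(res0$power - 0.01) < 3 * sqrt(0.01 * 0.99 / 800) + 1e-9))
  cfg2 <- ttest_sim_config(n_assoc = 2, n_unassoc_max = 0, reps = 300,
                           seed = 56)
  cfg8 <- ttest_sim_config(n_assoc = 8, n_unassoc_max = 0, reps = 300,
                           seed = 56)
  for (method in c("fisher", "wfisher", "stouffer")) {
    p2 <- run_power_experiment(cfg2, methods = method, m0_values = 0)$power
    p8 <- run_power_experiment(cfg8, methods = method, m0_values = 0)$power
    expect_gte(p8, p2)
  }
})

# RNA-seq generator ---------------------------------------------------------

test_that("the count simulator honours its design contract", {
  cfg <- rnaseq_sim_config(n_genes = 300, n_studies = 5, n_assoc_studies = 2,
                           de_fraction = 0.10, samples_per_group = 6,
                           seed = 57)
  set.seed(cfg$seed)
  sim <- simulate_rnaseq_meta(cfg)
  expect_length(sim$counts, 5)
  expect_equal(dim(sim$counts[[1]]), c(300, 12))
  expect_true(all(vapply(sim$counts, function(m)
    all(m >= 0) && all(m == round(m)), logical(1))))
  expect_equal(sum(sim$truth), 30)          # exactly round(0.10 * 300)
  expect_length(sim$assoc_studies, 2)
  expect_true(all(abs(sim$direction[sim$truth]) == 1))
  expect_true(all(sim$fold_change[sim$truth] >= cfg$min_fold_change))
  expect_true(all(sim$fold_change[!sim$truth] == 1))
})

test_that("simulated counts show negative-binomial mean-variance scaling", {
  # one gene, many samples: var ~ mu + phi mu^2
  set.seed(58)
  mu <- 200; phi <- 0.3
  x <- rnbinom(20000, mu = mu, size = 1 / phi)
  expect_equal(mean(x), mu, tolerance = 0.05)
  expect_equal(var(x), mu + phi * mu^2, tolerance = 0.1)
  # and the generator's null studies reproduce their per-gene means
  cfg <- rnaseq_sim_config(n_genes = 40, n_studies = 1, n_assoc_studies = 0,
                           samples_per_group = 500, seed = 58)
  set.seed(cfg$seed)
  sim <- simulate_rnaseq_meta(cfg)
  cts <- sim$counts[[1]]
  emp_mu <- rowMeans(cts)
  emp_v <- apply(cts, 1, var)
  # variance exceeds the mean (overdispersion) for essentially all genes
  expect_gt(mean(emp_v > emp_mu), 0.9)
})

test_that("the per-study DE test is calibrated and directionally accurate", {
  set.seed(59)
  g <- 400; spg <- 20
  mu <- exp(rnorm(g, 4, 1))
  disp <- 0.15 + 2 / mu
  null_cts <- matrix(rnbinom(g * 2 * spg, mu = mu, size = 1 / disp), g)
  de <- per_study_de_test(null_cts, rep(c("a", "b"), each = spg))
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
  # a strong fold change on 10% of genes (so CPM normalisation is barely
  # perturbed) is detected with the right sign
  up <- mu * ifelse(seq_len(g) <= 40, 4, 1)
  cts <- cbind(matrix(rnbinom(g * spg, mu = mu, size = 1 / disp), g),
               matrix(rnbinom(g * spg, mu = up, size = 1 / disp), g))
  de2 <- per_study_de_test(cts, rep(c("a", "b"), each = spg))
  expect_gt(mean(de2$p[1:40] < 0.01), 0.95)
  expect_gt(mean(de2$sign[1:40] == 1), 0.95)
  expect_error(per_study_de_test(cts, rep("a", 2 * spg)), "two levels")
  expect_error(per_study_de_test(cts[, 1:3], c("a", "a", "b")), "at least two")
})

test_that("the meta-analysis benchmark is deterministic given its seed", {
  cfg <- rnaseq_sim_config(n_genes = 60, n_studies = 4, n_assoc_studies = 2,
                           samples_per_group = 4, reps = 1, seed = 60)
  a <- run_rnaseq_meta_experiment(cfg, methods = c("fisher", "fem"))
  b <- run_rnaseq_meta_experiment(cfg, methods = c("fisher", "fem"))
  expect_identical(a, b)
  expect_true(all(a$auc >= 0 & a$auc <= 1))
  expect_true(all(c("auc", "tpr", "true_fdr", "n_significant") %in% names(a)))
})
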