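test_that("zero-noise data started at truth recover the generating rates", {
  exp0 <- make_experiment(seed = 61, cv = 0, n_replicates = 2)
  dwt <- generate_timecourse(exp0$wt)$quant
  dmut <- generate_timecourse(exp0$mut)$quant
  truth <- c(k_t_wt = wt_params()$k_t, k_t_mut = yafk_params()$k_t,
             k_h = wt_params()$k_h)
  f <- fit_kinetics(dwt, dmut, start = as.list(truth), n_starts = 0)
  expect_true(f$converged)
  expect_lt(max(abs(f$estimates[names(truth)] / truth - 1)), 1e-6)
  expect_lt(f$loss, 1e-10)
})

test_that("hydrolysis-free data fit a near-zero hydrolysis rate", {
  exp0 <- make_experiment(seed = 71, cv = 0.05, n_replicates = 4)
  dmut <- generate_timecourse(exp0$mut)$quant
  f <- fit_kinetics(dmut, n_starts = 4, seed = 2)
  # truth k_h = 0; at 5 % CV the estimate must stay below the noise scale
  expect_lt(f$estimates[["k_h"]], 0.002)
})

test_that("multistart fitting without an oracle start still finds the optimum", {
  exp0 <- make_experiment(seed = 81, cv = 0.10, n_replicates = 5)
  dwt <- generate_timecourse(exp0$wt)$quant
  dmut <- generate_timecourse(exp0$mut)$quant
  f <- fit_kinetics(dwt, dmut, n_starts = 8, seed = 3)
  expect_true(f$converged)
  expect_lt(abs(f$estimates[["k_h"]] / wt_params()$k_h - 1), 0.25)
  # deterministic given data and seed
  f2 <- fit_kinetics(dwt, dmut, n_starts = 8, seed = 3)
  expect_identical(f$estimates, f2$estimates)
})

test_that("bootstrap intervals are reproducible and collapse on noiseless data", {
  exp0 <- make_experiment(seed = 91, cv = 0.10, n_replicates = 4)
  dwt <- generate_timecourse(exp0$wt)$quant
  dmut <- generate_timecourse(exp0$mut)$quant
  f <- fit_kinetics(dwt, dmut, n_starts = 2, seed = 4)
  b1 <- bootstrap_ci(f, dwt, dmut, n_boot = 100, seed = 5)
  b2 <- bootstrap_ci(f, dwt, dmut, n_boot = 100, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci[, "lower"] <= f$estimates[f$free] + 1e-12))
  expect_true(all(b1$ci[, "upper"] >= f$estimates[f$free] - 1e-12))

  exp1 <- make_experiment(seed = 92, cv = 0, n_replicates = 3)
  dwt0 <- generate_timecourse(exp1$wt)$quant
  dmut0 <- generate_timecourse(exp1$mut)$quant
  f0 <- fit_kinetics(dwt0, dmut0, n_starts = 2, seed = 4)
  b0 <- bootstrap_ci(f0, dwt0, dmut0, n_boot = 100, seed = 5)
  expect_lt(max(b0$ci[, "upper"] - b0$ci[, "lower"]), 1e-6)
})

test_that("the headline estimator is scale-invariant and null at identical series", {
  exp0 <- make_experiment(seed = 101, cv = 0.10, n_replicates = 4)
  pw <- generate_peaklists(exp0$wt)
  pm <- generate_peaklists(exp0$mut)
  qw <- quantify_peaklist(pw$ms1)
  qm <- quantify_peaklist(pm$ms1)
  h <- headline_estimate(qw, qm)
  # rescaling every intensity leaves relative abundances untouched
  pw2 <- pw$ms1; pw2$intensity <- pw2$intensity * 1e3
  h2 <- headline_estimate(quantify_peaklist(pw2), qm)
  expect_equal(h$estimate, h2$estimate, tolerance = 1e-12)
  expect_equal(headline_estimate(qw, qw)$estimate, 0)
  expect_gt(h$estimate, 0)
})
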