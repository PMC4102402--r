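test_that("omnibus EM recovers well-separated mixture parameters", {
  set.seed(11)
  x <- c(rnorm(1000, 0.5, 0.5), rnorm(1000, 8, 1))
  fit <- fit_omnibus_mixture(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_noise - 0.5), 0.1)
  expect_lt(abs(fit$mu_signal - 8), 0.1)
  expect_lt(abs(fit$pi_signal - 0.5), 0.03)
  # independent EM implementation as cross-check
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(mc$parameters$mean) -
                      c(fit$mu_noise, fit$mu_signal))), 0.05)
  expect_lt(abs(mc$loglik - fit$loglik), 1)
})

test_that("unimodal data is recognisably unimodal after fitting", {
  set.seed(12)
  x <- rnorm(200, 5, 1)
  fit <- fit_omnibus_mixture(x)
  # EM on one Gaussian must not manufacture real separation: the mixture
  # log-likelihood can exceed the single-Gaussian one only marginally
  ll1 <- sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE))
  expect_lt(fit$loglik - ll1, 6)
  # and the clusters it does report overlap heavily (< 2 sd apart), which
  # the table-level unimodal fallback is designed to catch
  expect_lt(fit$mu_signal - fit$mu_noise, 2 * sd(x))
  expect_error(fit_omnibus_mixture(rep(3, 50)), "degenerate")
})

test_that("perfectly separated clusters give the empirical mixing fraction", {
  set.seed(13)
  x <- c(rnorm(300, 0, 0.01), rnorm(700, 10, 0.01))
  fit <- fit_omnibus_mixture(x)
  expect_equal(fit$pi_signal, 0.7, tolerance = 1e-3)
  expect_lt(fit$mu_noise, fit$mu_signal)
})

test_that("prior construction matches the stated hyperparameters", {
  fit <- toy_fit(mu_noise = 1, mu_signal = 8, var_noise = 0.3,
                 var_signal = 1.2, pi_signal = 0.6)
  prior <- build_prior(fit, kappa = 3, nt = 5, mix_weight = 5)
  expect_equal(prior$mean_locations, c(1, 8))
  expect_equal(prior$mean_strength, 15)
  expect_equal(c(prior$mix_a, prior$mix_b), c(5, 5))
  # inverse-gamma mode matched to the omnibus variances
  expect_equal(prior$var_scale / (prior$var_shape + 1), c(0.3, 1.2))
  expect_error(build_prior(fit, kappa = -1), "positive")
})

test_that("per-gene MAP fit recovers parameters drawn from the prior centres", {
  set.seed(14)
  omni <- toy_fit(mu_noise = 1, mu_signal = 8, var_noise = 0.25,
                  var_signal = 1, pi_signal = 0.5)
  prior <- build_prior(omni)
  x <- c(rnorm(120, 1, 0.5), rnorm(180, 8, 1))  # separation 6+ sd
  fit <- fit_gene_map(x, prior)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_noise - 1), 0.2)
  expect_lt(abs(fit$mu_signal - 8), 0.2)
  expect_lt(abs(fit$pi_signal - 0.6), 0.05)
})

test_that("an informative prior retains the noise cluster for all-high genes", {
  omni <- toy_fit(mu_noise = 1, mu_signal = 8)
  prior <- build_prior(omni)
  x <- c(7.8, 8.1, 8.4, 7.9, 8.2)
  fit <- fit_gene_map(x, prior)
  expect_lt(abs(fit$mu_noise - 1), 1)       # noise cluster near prior centre
  expect_gt(fit$pi_signal, 0.5)
  # returned parameters are a mode of the posterior objective: no grid point
  # in a neighbourhood beats them
  obj_at <- function(mu_n, mu_s, pi2)
    scHurdle:::.map_objective(x, c(mu_n, mu_s),
                              c(fit$var_noise, fit$var_signal), pi2, prior)
  best <- obj_at(fit$mu_noise, fit$mu_signal, fit$pi_signal)
  grid <- expand.grid(mu_n = fit$mu_noise + seq(-1, 1, 0.25),
                      mu_s = fit$mu_signal + seq(-1, 1, 0.25),
                      pi2 = pmin(pmax(fit$pi_signal + seq(-0.3, 0.3, 0.1),
                                      0.01), 0.99))
  vals <- mapply(obj_at, grid$mu_n, grid$mu_s, grid$pi2)
  expect_gte(best, max(vals) - 1e-6)
})

test_that("three identical observations are handled by the prior", {
  omni <- toy_fit()
  prior <- build_prior(omni)
  fit <- fit_gene_map(c(4, 4, 4), prior)
  expect_true(is.finite(fit$loglik))
  expect_true(fit$var_noise > 0 && fit$var_signal > 0)
})

test_that("MAP mixing proportion satisfies the Beta-MAP update at convergence", {
  set.seed(15)
  omni <- toy_fit()
  prior <- build_prior(omni)
  x <- c(0.8, 1.2, 7.5, 8.5)
  fit <- fit_gene_map(x, prior, tol = 1e-12)
  r <- posterior_signal_prob(x, fit)
  expect_equal(fit$pi_signal, (sum(r) + 4) / (length(x) + 8),
               tolerance = 1e-6)
})

test_that("kappa -> infinity pins the MAP means to the prior centres", {
  set.seed(16)
  omni <- toy_fit(mu_noise = 1, mu_signal = 8)
  prior <- build_prior(omni, kappa = 1e7, nt = 5)
  x <- c(rnorm(50, 2, 0.5), rnorm(50, 9, 1))
  fit <- fit_gene_map(x, prior)
  expect_lt(abs(fit$mu_noise - 1), 1e-2)
  expect_lt(abs(fit$mu_signal - 8), 1e-2)
})

test_that("posterior signal probability matches the direct density ratio", {
  fit <- toy_fit(mu_noise = 1, mu_signal = 6, var_noise = 0.4,
                 var_signal = 2, pi_signal = 0.35)
  xs <- seq(-3, 12, length.out = 100)
  direct <- fit$pi_signal * dnorm(xs, 6, sqrt(2)) /
    (fit$pi_signal * dnorm(xs, 6, sqrt(2)) +
       (1 - fit$pi_signal) * dnorm(xs, 1, sqrt(0.4)))
  expect_equal(posterior_signal_prob(xs, fit), direct, tolerance = 1e-12)
  # symmetric fit: midpoint of the means is exactly 1/2
  sym <- toy_fit(mu_noise = 2, mu_signal = 6, var_noise = 1, var_signal = 1,
                 pi_signal = 0.5)
  expect_equal(posterior_signal_prob(4, sym), 0.5)
  # deep noise tail saturates (equal variances, so the tail is monotone)
  expect_lt(posterior_signal_prob(2 - 10, sym), 1e-6)
})

test_that("thresholding truncates noise-classified values only", {
  fit <- toy_fit()
  expect_equal(threshold_gene(c(0.2, 9.1), fit), c(0, 9.1))
  # exactly at posterior 1/2 the value is kept (truncate only when > .5)
  sym <- toy_fit(mu_noise = 2, mu_signal = 6, var_noise = 1, var_signal = 1,
                 pi_signal = 0.5)
  expect_equal(threshold_gene(4, sym), 4)
  expect_equal(threshold_gene(3.999, sym), 0)
  # the implied scalar threshold sits at the posterior-1/2 crossing
  expect_equal(posterior_signal_prob(threshold_point(sym), sym), 0.5,
               tolerance = 1e-8)
})

test_that("classification accuracy exceeds 99% at 6-sd separation", {
  set.seed(17)
  n <- 2000
  labels <- rbinom(n, 1, 0.6)
  x <- ifelse(labels == 1, rnorm(n, 7, 1), rnorm(n, 1, 1))
  omni <- fit_omnibus_mixture(x)
  prior <- build_prior(omni)
  fit <- fit_gene_map(x, prior)
  et <- threshold_gene(x, fit)
  expect_gte(mean((et > 0) == (labels == 1)), 0.99)
})

test_that("cluster relabeling holds for arbitrary data", {
  set.seed(18)
  for (i in 1:10) {
    x <- rnorm(100, runif(1, 0, 10), runif(1, 0.5, 3)) +
      rbinom(100, 1, 0.5) * runif(1, 0, 8)
    fit <- fit_omnibus_mixture(x)
    expect_lte(fit$mu_noise, fit$mu_signal)
    expect_true(fit$var_noise > 0 && fit$var_signal > 0)
    expect_true(fit$pi_signal > 0 && fit$pi_signal < 1)
  }
})

test_that("table-level thresholding keeps values or zeroes them, never edits", {
  spec <- simulation_spec(n_genes = 15, n_cells_per_group = 15)
  sim <- simulate_dataset(spec, seed = 19)
  thr <- threshold_cell_table(sim$table, value_col = "lcount")
  expect_true(all(thr$et == 0 | thr$et == thr$lcount))
  expect_true(all(thr$et >= 0))
  # ngeneson is consistent with the thresholded data
  on_frac <- tapply(thr$et > 0, thr$cell_id, mean)
  expect_equal(as.numeric(on_frac[thr$cell_id]), thr$ngeneson)
  # zero inputs are always background
  expect_true(all(thr$et[thr$lcount == 0] == 0))
})
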