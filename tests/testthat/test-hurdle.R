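# oracle fits via stats::glm / stats::lm with matched sum-to-zero coding
oracle_loglik <- function(df, cycle = TRUE, ngeneson = TRUE) {
  terms <- c(if (length(unique(df$cell_line)) > 1) "cell_line",
             if (cycle) "cycle", if (ngeneson) "ngeneson")
  f <- as.formula(paste("y ~", paste(c("1", terms), collapse = "+")))
  df$cell_line <- factor(df$cell_line)
  df$cycle <- factor(df$cycle, levels = intersect(c("G0/G1", "S", "G2/M"),
                                                  unique(df$cycle)))
  contr <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(contr))
  df$y <- as.numeric(df$et > 0)
  ll_d <- as.numeric(logLik(glm(f, binomial, df)))
  pos <- df[df$et > 0, ]
  pos$y <- pos$et
  fit_c <- lm(f, pos)
  ll_c <- as.numeric(logLik(fit_c))  # lm logLik uses the ML variance
  c(discrete = ll_d, continuous = ll_c)
}

test_that("both hurdle parts agree with reference GLM fits", {
  spec <- plant_cycle_effect(simulation_spec(n_genes = 6, n_cells_per_group = 30),
                             genes = 1, size_disc = 1, size_cont = 1)
  sim <- simulate_dataset(spec, seed = 41)
  fit <- fit_hurdle(sim$table, "G001")
  df <- as.data.frame(sim$table)[sim$table$gene_id == "G001", ]
  ll <- oracle_loglik(df)
  expect_equal(fit$loglik_discrete, ll[["discrete"]], tolerance = 1e-6)
  expect_equal(fit$loglik_continuous, ll[["continuous"]], tolerance = 1e-8)
  expect_equal(fit$deviance, -2 * (fit$loglik_discrete + fit$loglik_continuous),
               tolerance = 1e-10)
})

test_that("null genes show no spurious effects; planted effects are recovered", {
  spec <- plant_cycle_effect(simulation_spec(n_genes = 6, n_cells_per_group = 100),
                             genes = 1, size_disc = 0, size_cont = 1,
                             pattern = c(0, 0, 1))
  sim <- simulate_dataset(spec, seed = 42)
  # planted continuous pattern: centered (−1/3, −1/3, +2/3) on G2/M
  fit <- fit_hurdle(sim$table, "G001")
  b <- fit$coef_continuous
  est <- c(b[["cycle1"]], b[["cycle2"]], -b[["cycle1"]] - b[["cycle2"]])
  expect_lt(max(abs(est - c(-1 / 3, -1 / 3, 2 / 3))), 0.3)
  # an unaffected gene has effects near zero
  fit0 <- fit_hurdle(sim$table, "G004")
  b0 <- fit0$coef_continuous
  est0 <- c(b0[["cycle1"]], b0[["cycle2"]], -b0[["cycle1"]] - b0[["cycle2"]])
  expect_lt(max(abs(est0)), 0.3)
})

test_that("the combined statistic is the exact sum of its parts", {
  spec <- plant_cycle_effect(simulation_spec(n_genes = 5, n_cells_per_group = 40),
                             genes = 1:2)
  sim <- simulate_dataset(spec, seed = 43)
  for (g in c("G001", "G003")) {
    tr <- hurdle_cycle_test(sim$table, g)
    expect_identical(tr$lambda, tr$lambda_d + tr$lambda_c)
    expect_gte(tr$lambda_d, 0)
    expect_gte(tr$lambda_c, 0)
    expect_equal(tr$df, 4)
    # components match independently computed logistic-only and
    # Gaussian-only likelihood-ratio statistics
    df <- as.data.frame(sim$table)[sim$table$gene_id == g, ]
    full <- oracle_loglik(df); red <- oracle_loglik(df, cycle = FALSE)
    expect_equal(tr$lambda_d, 2 * (full[["discrete"]] - red[["discrete"]]),
                 tolerance = 1e-6)
    expect_equal(tr$lambda_c, 2 * (full[["continuous"]] - red[["continuous"]]),
                 tolerance = 1e-6)
  }
})

test_that("identical models give a zero statistic and p-value one", {
  sim <- simulate_dataset(simulation_spec(n_genes = 3, n_cells_per_group = 15),
                          seed = 44)
  fit <- fit_hurdle(sim$table, "G001")
  tr <- lrt_cycle(fit, fit)
  expect_equal(tr$lambda, 0)
  expect_equal(tr$p_combined, 1)
  # non-nested designs are refused
  no_cycle <- fit_hurdle(sim$table, "G001", cycle = FALSE, ngeneson = FALSE)
  with_ng <- fit_hurdle(sim$table, "G001", cycle = FALSE, ngeneson = TRUE)
  expect_error(lrt_cycle(no_cycle, with_ng), "nested")
})

test_that("test statistics are invariant to factor level relabeling", {
  sim <- simulate_dataset(
    plant_cycle_effect(simulation_spec(n_genes = 3, n_cells_per_group = 25),
                       genes = 1), seed = 45)
  tr1 <- hurdle_cycle_test(sim$table, "G001")
  relab <- as.data.frame(sim$table)
  # rename phases so their lexical (and .PHASES) order changes
  relab$cycle <- c("G0/G1" = "zz_late", "S" = "aa_mid", "G2/M" = "mm")[relab$cycle]
  relab$cell_line <- c(H9 = "lineC", MB231 = "lineA", PC3 = "lineB")[relab$cell_line]
  tr2 <- suppressWarnings(hurdle_cycle_test(as_cell_table(relab), "G001"))
  expect_equal(tr1$lambda, tr2$lambda, tolerance = 1e-8)
  expect_equal(tr1$p_combined, tr2$p_combined, tolerance = 1e-8)
})

test_that("union test follows the Bonferroni-allocated rejection rule", {
  expect_true(union_test(0.001, 0.9, alpha = 0.05))
  expect_false(union_test(0.5, 0.5, alpha = 0.05))
  expect_true(union_test(0.9, 0.02, alpha = 0.05))
  expect_false(union_test(0.03, 0.9, alpha = 0.05))  # 0.03 > 0.025
})

test_that("Bonferroni adjustment is the clamped product", {
  expect_equal(bonferroni_adjust(1e-4, m = 253), 0.0253)
  expect_equal(bonferroni_adjust(0.5, m = 253), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.7), m = 1), c(0.2, 0.7))
})

test_that("deviance ratio equals OLS R-squared for fully continuous data", {
  set.seed(46)
  n <- 120
  cycle <- rep(c("G0/G1", "S", "G2/M"), each = n / 3)
  et <- 5 + (cycle == "S") * 0.8 + (cycle == "G2/M") * 1.5 + rnorm(n)
  tab <- long_table(matrix(et, n, 1), cycle = cycle, et = matrix(et, n, 1))
  dr <- deviance_ratio(tab, "g01", ngeneson = FALSE)
  r2 <- summary(lm(et ~ factor(cycle)))$r.squared
  expect_equal(dr$ratio, r2, tolerance = 1e-8)
  # noise-free phase-determined expression drives the ratio to one
  et2 <- 5 + (cycle == "S") * 1 + (cycle == "G2/M") * 2
  tab2 <- long_table(matrix(et2, n, 1), cycle = cycle, et = matrix(et2, n, 1))
  dr2 <- deviance_ratio(tab2, "g01", ngeneson = FALSE)
  expect_equal(dr2$ratio, 1, tolerance = 1e-6)
})

test_that("cycle-free genes have small deviance ratios", {
  sim <- simulate_dataset(simulation_spec(n_genes = 4, n_cells_per_group = 100),
                          seed = 47)
  ratios <- sapply(sprintf("G%03d", 1:4),
                   function(g) deviance_ratio(sim$table, g)$ratio)
  expect_lt(median(ratios), 0.02)
})

test_that("omitting the detection-rate covariate attenuates the cycle ratio", {
  # a reasonably sized panel so the detection rate is a stable proxy for
  # the latent efficiency (with few genes it is dominated by the target)
  spec <- plant_cycle_effect(
    simulation_spec(n_genes = 60, n_cells_per_group = 60, efficiency_sd = 1.5),
    genes = 1:4, size_disc = 1.5, size_cont = 1)
  sim <- simulate_dataset(spec, seed = 48)
  with_ng <- sapply(sprintf("G%03d", 1:4),
                    function(g) deviance_ratio(sim$table, g)$ratio)
  without <- sapply(sprintf("G%03d", 1:4),
                    function(g) deviance_ratio(sim$table, g,
                                               ngeneson = FALSE)$ratio)
  expect_lt(median(without), median(with_ng))
})

test_that("peak phase is the argmax of mean expression with ordered ties", {
  cycle <- rep(c("G0/G1", "S", "G2/M"), each = 4)
  et <- matrix(c(rep(2, 4), rep(2, 4), rep(5, 4)), 12, 1)
  tab <- long_table(matrix(1, 12, 1), cycle = cycle, et = et)
  pk <- estimate_peaktime(tab)
  expect_equal(pk$peaktime, "G2/M")
  expect_false(pk$tie)
  et_tie <- matrix(3, 12, 1)
  pk2 <- estimate_peaktime(long_table(matrix(1, 12, 1), cycle = cycle,
                                      et = et_tie))
  expect_equal(pk2$peaktime, "G0/G1")
  expect_true(pk2$tie)
})

test_that("a planted frequency shift moves the estimated peak phase", {
  hits <- 0L
  for (r in 1:50) {
    spec <- plant_cycle_effect(
      simulation_spec(n_genes = 1, n_cells_per_group = 30, line_sd_disc = 0,
                      line_sd_cont = 0),
      genes = 1, size_disc = 2, size_cont = 1, pattern = c(0, 0, 1))
    sim <- simulate_dataset(spec, seed = 4800 + r)
    if (estimate_peaktime(sim$table)$peaktime == "G2/M") hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("fully expressed genes degrade gracefully to the continuous part", {
  sim <- simulate_dataset(simulation_spec(n_genes = 3, n_cells_per_group = 20,
                                          freq_range = c(0.999, 0.999)),
                          seed = 49)
  # force full expression for gene 1
  tab <- as.data.frame(sim$table)
  g1 <- tab$gene_id == "G001"
  tab$et[g1] <- pmax(tab$et[g1], tab$lcount[g1], 1)
  tab <- as_cell_table(tab)
  fit <- fit_hurdle(tab, "G001")
  expect_true(fit$discrete_degenerate)
  expect_equal(fit$loglik_discrete, 0)
  tr <- hurdle_cycle_test(tab, "G001")
  expect_equal(tr$lambda_d, 0)
  expect_equal(tr$df, 2)  # continuous degrees of freedom only
})

test_that("the per-gene test table is coherent", {
  spec <- plant_cycle_effect(simulation_spec(n_genes = 8, n_cells_per_group = 30),
                             genes = 1:3, size_disc = 2, size_cont = 1.5)
  sim <- simulate_dataset(spec, seed = 50)
  res <- test_cycle_genes(sim$table)
  expect_equal(nrow(res), 8)
  expect_equal(res$lambda, res$lambda_d + res$lambda_c)
  expect_equal(res$p_adj, pmin(1, res$p * 8))
  expect_true(all(res$significant[1:3]))  # strong planted effects detected
  expect_equal(res$neglog10_p, -log10(res$p))
  expect_true(all(res$peaktime %in% c("G0/G1", "S", "G2/M")))
})
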