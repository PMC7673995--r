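test_that("panel draws are exact for zero SE and unbiased for one cell", {
  pan <- make_panel(cbind(c(0.4, 0.7), c(0.2, 0.9)), se = 0)
  set.seed(1)
  expect_identical(draw_coupled_panel(pan)$mean, pan$mean)

  one <- make_panel(matrix(0.6), se = 0.1)
  set.seed(2)
  draws <- replicate(10000, draw_coupled_panel(one)$mean[1, 1])
  # Monte-Carlo check against the normal-mean oracle: within 3 se / sqrt(n)
  expect_lt(abs(mean(draws) - 0.6), 3 * 0.1 / sqrt(10000))
  expect_equal(sd(draws), 0.1, tolerance = 0.05)
})

test_that("treatments sharing a component are coupled through the shared column", {
  pan <- make_panel(cbind(c(0.4, 0.7), c(0.2, 0.9), c(0.5, 0.5)), se = 0.1)
  set.seed(3)
  sim <- draw_coupled_panel(pan)
  # any two treatments referencing column a@1 see the identical draw
  t1 <- panel_treatment(pan, c("a@1", "b@1"))
  t2 <- panel_treatment(pan, c("a@1", "c@1"))
  expect_identical(sim$mean[, panel_columns_for(sim, t1)[1]],
                   sim$mean[, panel_columns_for(sim, t2)[1]])
})

test_that("line resampling returns a size-preserving uniform multiset", {
  expect_identical(resample_lines("only"), "only")
  expect_error(resample_lines(character()), class = "idascreen_input_error")
  lines <- sprintf("L%02d", 1:10)
  set.seed(4)
  out <- replicate(2000, length(unique(resample_lines(lines))) / 10)
  expect_equal(length(resample_lines(lines)), 10)
  # expected distinct fraction 1 - (1 - 1/n)^n
  expect_equal(mean(out), 1 - (1 - 1 / 10)^10, tolerance = 0.01)
})

test_that("bootstrap_statistic is deterministic, handles constants, and matches the resampling SE oracle", {
  set.seed(5)
  pan <- random_panel(20, 1, se = 0)
  stat <- function(p, idx) mean(p$mean[idx, 1])
  cfg <- bootstrap_config(n_sims = 10000, seed = 11)
  bt1 <- bootstrap_statistic(stat, pan, cfg)
  bt2 <- bootstrap_statistic(stat, pan, cfg)
  expect_identical(bt1$sims, bt2$sims)

  const <- bootstrap_statistic(function(p, idx) 42, pan,
                               bootstrap_config(n_sims = 50, seed = 1))
  expect_identical(const$se, 0)
  expect_equal(unname(const$ci), c(42, 42))

  # with zero measurement error the bootstrap SE of the mean approaches
  # the analytic with-replacement resampling SE sd_pop / sqrt(n)
  v <- pan$mean[, 1]
  analytic <- sqrt(mean((v - mean(v))^2)) / sqrt(length(v))
  expect_lt(abs(bt1$se / analytic - 1), 0.15)

  # a statistic failing in most simulations (here: whenever resampling
  # repeats a line) raises the bootstrap-failure error with diagnostics
  fragile <- function(p, idx) {
    if (anyDuplicated(idx)) stop("resample not supported")
    mean(p$mean[idx, 1])
  }
  expect_error(
    bootstrap_statistic(fragile, pan, bootstrap_config(n_sims = 20, seed = 1)),
    regexp = "more than half", class = "idascreen_bootstrap_error")
})

test_that("identical coupled treatments give HR exactly 1 with zero SE in every simulation", {
  set.seed(6)
  pan <- random_panel(8, 2, se = 0.1, vmin = 0.2, vmax = 0.9)
  tr <- panel_treatment(pan)
  bt <- bootstrap_hr_power(pan, tr, tr, design = trial_design(100),
                           config = bootstrap_config(n_sims = 10000, seed = 2))
  expect_true(all(bt$hr$sims == 1))
  expect_identical(bt$hr$se, 0)
  expect_identical(bt$hr$point, 1)
  expect_equal(bt$power$point, 0.025)

  # uncoupled draws break the degeneracy
  bt_un <- bootstrap_hr_power(
    pan, tr, tr, config = bootstrap_config(n_sims = 200, seed = 2,
                                           couple_shared_drugs = FALSE))
  expect_gt(bt_un$hr$se, 0)
})

test_that("bootstrap CIs cover the true mean combination viability at nominal rate", {
  # population truth by large-sample enumeration (independent oracle)
  set.seed(77)
  draw_true <- function(n) cbind(runif(n, 0.2, 1), runif(n, 0.2, 1))
  truth <- oracle_ida_mean(draw_true(2e5))
  n_lines <- 30
  meas_se <- 0.05
  cover <- logical(200)
  for (r in seq_len(200)) {
    tv <- draw_true(n_lines)
    obs <- tv + matrix(rnorm(2 * n_lines, 0, meas_se), n_lines, 2)
    pan <- make_panel(obs, se = meas_se)
    tr <- panel_treatment(pan)
    stat <- function(p, idx) {
      cols <- c("a@1", "b@1")
      mean(apply(p$mean[idx, cols, drop = FALSE], 1, min))
    }
    bt <- bootstrap_statistic(stat, pan,
                              bootstrap_config(n_sims = 300, seed = 1000 + r))
    cover[r] <- truth >= bt$ci[1] && truth <= bt$ci[2]
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("empirical null probability counts non-positive scores", {
  expect_equal(empirical_null_probability(c(0.1, 0.2, -0.05, 0.3)), 0.25)
  expect_equal(empirical_null_probability(c(-1, 0, -0.2)), 1.0)
  p0 <- empirical_null_probability(runif(1000, 0.01, 1))
  expect_equal(as.numeric(p0), 0)
  expect_equal(attr(p0, "upper_bound"), 0.001)
  expect_error(empirical_null_probability(numeric()),
               class = "idascreen_input_error")
})

test_that("BH adjustment matches the textbook step-up oracle and is idempotent", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(19)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-15)
    expect_true(all(adj >= p))
    # sorted by raw p, adjusted values are non-decreasing
    expect_true(all(diff(adj[order(p)]) >= 0))
    # agreement with the oracle holds on any input, including re-adjustment
    expect_equal(bh_fdr(adj), oracle_bh(adj))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "idascreen_input_error")
})

test_that("subsampling dispersion vanishes at full size and grows for small subsets", {
  set.seed(20)
  pan <- random_panel(50, 2, se = 0.02, vmin = 0.1, vmax = 1)
  tr <- panel_treatment(pan)
  tab <- subsample_stability(pan, tr, sizes = c(5, 40, 50), reps = 100, seed = 3)
  expect_equal(tab$sd_mean_prediction[tab$size == 50], 0)
  expect_gt(tab$sd_mean_prediction[tab$size == 5],
            tab$sd_mean_prediction[tab$size == 40])

  tab2 <- subsample_stability(pan, tr, sizes = c(5, 40, 50), reps = 100, seed = 3)
  expect_identical(tab, tab2)
  expect_error(subsample_stability(pan, tr, sizes = 60),
               class = "idascreen_input_error")
})

test_that("comboscore bootstrap annotates score, SE and null probability", {
  set.seed(21)
  pan <- random_panel(12, 2, se = 0.03, vmin = 0.2, vmax = 0.9)
  tr <- panel_treatment(pan)
  res <- bootstrap_comboscore(pan, tr,
                              config = bootstrap_config(n_sims = 400, seed = 5))
  expect_true(is.finite(res$se) && res$se >= 0)
  expect_true(res$null_p >= 0 && res$null_p <= 1)
  expect_equal(res$score, res$delta_via * (1 - res$hr_c_mbest),
               tolerance = 1e-12)
  # reproducible under the same seed
  res2 <- bootstrap_comboscore(pan, tr,
                               config = bootstrap_config(n_sims = 400, seed = 5))
  expect_identical(res$se, res2$se)
  expect_identical(as.numeric(res$null_p), as.numeric(res2$null_p))
})
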