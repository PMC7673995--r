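test_that("viability maps linearly to hazard with the stated anchors", {
  expect_equal(viability_to_hazard(1.0), 1.0)
  expect_equal(viability_to_hazard(0.0), 0.0)
  expect_equal(viability_to_hazard(0.5), 0.5)
  expect_message(h <- viability_to_hazard(-0.2), "floored")
  expect_equal(h, 0)
  expect_error(viability_to_hazard(NaN), class = "idascreen_input_error")
})

test_that("hazard ratios divide mean test by mean control viability", {
  pan <- make_panel(cbind(c(0.2, 0.2), c(0.4, 0.4)))
  t_test <- panel_treatment(pan, "a@1")
  t_ctrl <- panel_treatment(pan, "b@1")
  hr <- hazard_ratio(ida_combo(pan, t_test), ida_combo(pan, t_ctrl))
  expect_equal(hr$hr, 0.5)

  same <- hazard_ratio(ida_combo(pan, t_test), ida_combo(pan, t_test))
  expect_equal(same$hr, 1.0)

  zero <- make_panel(cbind(c(0.2, 0.2), c(0, 0)))
  expect_error(hazard_ratio(ida_combo(zero, panel_treatment(zero, "a@1")),
                            ida_combo(zero, panel_treatment(zero, "b@1"))),
               class = "idascreen_input_error")

  # reciprocal identity
  hr_rev <- hazard_ratio(ida_combo(pan, t_ctrl), ida_combo(pan, t_test))
  expect_equal(hr$hr * hr_rev$hr, 1.0)

  # mismatched cell-line sets are rejected
  p3 <- make_panel(cbind(c(0.2, 0.2, 0.2), c(0.4, 0.4, 0.4)))
  a3 <- ida_combo(p3, panel_treatment(p3, "a@1"),
                  lines = c("L01", "L02", "L03"))
  b2 <- ida_combo(p3, panel_treatment(p3, "b@1"), lines = c("L01", "L02"))
  expect_error(hazard_ratio(a3, b2), class = "idascreen_consistency_error")
})

test_that("log-rank power matches the Freedman closed form on an independent oracle", {
  d <- trial_design(100, allocation_ratio = 1, alpha = 0.05)
  # no-effect limit: alpha/2 exactly
  expect_identical(logrank_power(1, d)$power, pnorm(-qnorm(0.975)))
  expect_equal(logrank_power(1, d)$power, 0.025)
  expect_equal(logrank_power(1, trial_design(500, 2, 0.10))$power, 0.05)

  # worked value: hr = 0.5, m = 100, k = 1
  expect_equal(logrank_power(0.5, d)$power,
               pnorm(sqrt(100) * 0.5 / 1.5 - qnorm(0.975)))
  expect_equal(logrank_power(0.5, d)$power, 0.915, tolerance = 1e-3)

  # 100-point grid against an independent normal-CDF evaluation (erf-based)
  skip_if_not_installed("pracma")
  phi <- function(x) 0.5 * (1 + pracma::erf(x / sqrt(2)))
  set.seed(8)
  grid <- expand.grid(hr = runif(10, 0.2, 2.5), m = c(50, 120, 400, 900, 2000))
  grid <- grid[sample(nrow(grid), 100, replace = TRUE), ]
  grid$k <- runif(100, 0.5, 2)
  for (i in seq_len(100)) {
    des <- trial_design(grid$m[i], grid$k[i], 0.05)
    expected <- phi(sqrt(grid$k[i] * grid$m[i]) * abs(grid$hr[i] - 1) /
                      (grid$k[i] * grid$hr[i] + 1) - qnorm(0.975))
    expect_equal(logrank_power(grid$hr[i], des)$power, expected,
                 tolerance = 1e-10)
  }
})

test_that("power is monotone in hr and events, and saturates for large trials", {
  d <- trial_design(40)
  hrs <- seq(0.25, 0.95, by = 0.05)
  pows <- vapply(hrs, function(h) logrank_power(h, d)$power, numeric(1))
  # strictly decreasing on (0, 1) wherever power has not saturated at 1
  expect_true(all(diff(pows) < 0))

  ms <- c(10, 50, 200, 1000, 5000)
  pows_m <- vapply(ms, function(m) logrank_power(0.8, trial_design(m))$power,
                   numeric(1))
  expect_true(all(diff(pows_m) > 0))
  expect_gt(logrank_power(0.8, trial_design(1e6))$power, 1 - 1e-10)

  expect_error(logrank_power(Inf, d), class = "idascreen_input_error")
})

test_that("trial classification uses the >= threshold convention", {
  expect_true(classify_trial(0.85))
  expect_true(classify_trial(0.80))
  expect_false(classify_trial(0.10))
  d <- trial_design(100)
  expect_true(classify_trial(logrank_power(0.5, d), threshold = 0.80))
  expect_error(classify_trial(0.5, threshold = 1.2),
               class = "idascreen_input_error")
})

test_that("IDAcomboscore rewards improvement over the best reference", {
  # combo mean 0.3, best mono 0.6: dVia 0.3, HR 0.5, score 0.15
  pan <- make_panel(cbind(c(0.6, 0.6), c(0.8, 0.8), c(0.3, 0.3)),
                    cols = c("a@1", "b@1", "combo@1"))
  res <- idacomboscore(pan, treatment("combo", 1),
                       references = list(treatment("a", 1), treatment("b", 1)))
  expect_equal(res$delta_via, 0.3)
  expect_equal(res$hr_c_mbest, 0.5)
  expect_equal(res$score, 0.15)
  expect_equal(res$best_reference, "a@1")

  # score 0 when the combination equals its best reference
  pan0 <- make_panel(cbind(c(0.5, 0.7), c(0.9, 0.9)))
  t_ab <- panel_treatment(pan0)
  # single-component combination equal to the best reference
  res0 <- idacomboscore(pan0, panel_treatment(pan0, "a@1"),
                        references = panel_treatment(pan0, "a@1"))
  expect_identical(res0$score, 0)

  # default references are the single-drug components
  res_ab <- idacomboscore(pan0, t_ab)
  ida_ab <- ida_combo(pan0, t_ab)$mean
  best <- min(mean(pan0$mean[, 1]), mean(pan0$mean[, 2]))
  expect_equal(res_ab$delta_via, best - ida_ab)
})

test_that("IDAcomboscore identities hold on random inputs", {
  set.seed(9)
  for (i in 1:50) {
    pan <- random_panel(6, 3, vmin = 0.05, vmax = 1)
    tr <- panel_treatment(pan)
    res <- idacomboscore(pan, tr)
    # algebraic identity score = dVia * (1 - HR)
    expect_equal(res$score, res$delta_via * (1 - res$hr_c_mbest),
                 tolerance = 1e-12)
    # sign iff the combination beats its best reference
    expect_identical(res$score > 0,
                     res$combo_mean < res$best_reference_mean)
  }
})

test_that("a multi-drug backbone is scored as a single reference therapy", {
  pan <- make_panel(cbind(c(0.5, 0.9), c(0.8, 0.4), c(0.9, 0.9)),
                    cols = c("cis@1", "gem@1", "ele@1"))
  backbone <- treatment(c("cis", "gem"), c(1, 1))
  triple <- treatment(c("cis", "gem", "ele"), c(1, 1, 1))
  res <- idacomboscore(pan, triple, references = list(backbone))
  expect_equal(res$best_reference, backbone$label)
  bb_mean <- ida_combo(pan, backbone)$mean
  expect_equal(res$delta_via, bb_mean - ida_combo(pan, triple)$mean)
})

test_that("the pairwise score table is order-invariant and marks insufficient pairs", {
  set.seed(10)
  pan <- random_panel(6, 3, vmin = 0.1, vmax = 1)
  drugs <- pan$treatments$drug
  cm <- tibble::tibble(drug = drugs, csustained = 1, max_tested = 1,
                       dose_note = NA)
  tab <- comboscore_matrix(pan, drugs, cm, min_lines = 3)
  expect_equal(nrow(tab), 3)  # 3 unordered pairs
  tab_rev <- comboscore_matrix(pan, rev(drugs), cm, min_lines = 3)
  expect_equal(tab[order(tab$drug_a, tab$drug_b), ]$score,
               tab_rev[order(tab_rev$drug_a, tab_rev$drug_b), ]$score)

  # a pair without enough shared lines becomes an explicit missing marker
  pan_miss <- pan
  pan_miss$mean[1:4, 1] <- NA
  tab_miss <- comboscore_matrix(pan_miss, drugs, cm, min_lines = 3)
  a_col <- pan$treatments$drug[1]
  expect_true(all(is.na(tab_miss$score[tab_miss$drug_a == a_col |
                                       tab_miss$drug_b == a_col])))
})

test_that("dose-grid surfaces reduce to monotherapies on the axes and decrease monotonically", {
  gen <- generate_screen(synthetic_screen_config(n_lines = 6, drugs = 2,
                                                 noise_sd = 0.02, seed = 12))
  fits <- fit_ll4_screen(gen$observations)
  grid <- c(0, 0.1, 0.5, 1, 5)
  surf <- dose_grid_scan(fits, "drug1", "drug2", grid, grid)
  expect_equal(nrow(surf), 25)

  # (0, 0) is the mean of per-line min of the upper asymptotes
  d_upper <- sapply(c("drug1", "drug2"), function(dr)
    sapply(sprintf("line%03d", 1:6), function(l) fits[[paste0(l, "|", dr)]]$d))
  expect_equal(surf$mean_viability[surf$conc_a == 0 & surf$conc_b == 0],
               mean(pmin(d_upper[, 1], d_upper[, 2])))

  # degenerate axis equals the monotherapy mean
  mono_a <- mean(sapply(sprintf("line%03d", 1:6), function(l)
    predict_viability(fits[[paste0(l, "|drug1")]], 5)$mean))
  expect_equal(surf$mean_viability[surf$conc_a == 5 & surf$conc_b == 0],
               mono_a)

  # non-increasing along each axis when all fitted curves are decreasing
  if (all(sapply(fits, function(f) f$b > 0 && f$c < f$d))) {
    wide <- matrix(surf$mean_viability, length(grid), length(grid),
                   byrow = TRUE)  # rows = conc_a
    expect_true(all(apply(wide, 1, function(r) all(diff(r) <= 1e-12))))
    expect_true(all(apply(wide, 2, function(r) all(diff(r) <= 1e-12))))
  }

  expect_error(dose_grid_scan(fits, "drug1", "drug2", c(0, 1e6), grid),
               class = "idascreen_range_error")
})
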