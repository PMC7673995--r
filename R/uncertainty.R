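#' Bootstrap configuration
#'
#' @param n_sims Number of simulations (convention: 10,000 for trial
#'   control/experimental comparisons, 1,000 for prospective combination
#'   scoring).
#' @param seed Integer root seed; per-simulation substreams are derived
#'   from it, so results are reproducible and order-independent.
#' @param ci_level Confidence level, default 0.95.
#' @param couple_shared_drugs When comparing two treatments that share
#'   compounds, reuse the same standard-normal deviate for a given
#'   (cell line, drug, concentration) in both arms so shared compounds
#'   move together (default `TRUE`).
#' @param ci_method `"normal"` (point +/- z * se, default) or
#'   `"percentile"`.
#' @return A `bootstrap_config` object.
#' @export
bootstrap_config <- function(n_sims = 1000, seed = 1L, ci_level = 0.95,
                             couple_shared_drugs = TRUE,
                             ci_method = c("normal", "percentile")) {
  ci_method <- match.arg(ci_method)
  if (n_sims < 1) abort_input("n_sims must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) abort_input("ci_level must be in (0, 1)")
  structure(list(n_sims = as.integer(n_sims), seed = as.integer(seed),
                 ci_level = ci_level,
                 couple_shared_drugs = isTRUE(couple_shared_drugs),
                 ci_method = ci_method),
            class = "bootstrap_config")
}

# Counter-derived substream seed, kept below 2^31 - 1 and never 0.
derive_seed <- function(root, i) {
  s <- (abs(as.numeric(root)) + 48271 * as.numeric(i)) %% 2147483646
  as.integer(s) + 1L
}

#' Draw one simulated panel (semi-parametric bootstrap step 1)
#'
#' Each simulated viability is `v* = v_hat + z * se` with `z` a standard
#' normal deviate. Because a panel holds exactly one column per
#' (drug, concentration), a single drawn panel reuses the same deviate
#' wherever that component appears, which is precisely the
#' shared-compound coupling: treatments sharing a compound at a matching
#' concentration move together. For uncoupled comparisons draw one panel
#' per treatment arm.
#'
#' @param panel A `monotherapy_panel` with finite means and SEs in every
#'   non-missing cell.
#' @return A `monotherapy_panel` with perturbed means (SEs carried over).
#' @export
draw_coupled_panel <- function(panel) {
  z <- matrix(rnorm(length(panel$mean)), nrow(panel$mean), ncol(panel$mean))
  sim <- panel
  sim$mean <- panel$mean + z * panel$se
  sim
}

#' Resample cell lines with replacement (bootstrap step 3)
#'
#' @param cell_lines Non-empty character vector of cell-line ids.
#' @return A multiset of the same size, drawn uniformly with replacement.
#' @export
resample_lines <- function(cell_lines) {
  n <- length(cell_lines)
  if (n == 0) abort_input("cannot resample an empty cell-line set")
  cell_lines[sample.int(n, n, replace = TRUE)]
}

new_bootstrap_result <- function(point, sims, config) {
  sims_ok <- sims[is.finite(sims)]
  se <- if (length(sims_ok) > 1) sd(sims_ok) else 0
  a <- (1 - config$ci_level) / 2
  ci <- if (config$ci_method == "normal") {
    point + qnorm(c(a, 1 - a)) * se
  } else {
    unname(quantile(sims_ok, c(a, 1 - a), type = 7))
  }
  structure(list(point = point, se = se, ci = ci, sims = sims,
                 n_sims = config$n_sims, seed = config$seed,
                 ci_level = config$ci_level, ci_method = config$ci_method),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> point %.5g, se %.3g, %g%% CI [%.5g, %.5g] (%d sims)\n",
              x$point, x$se, 100 * x$ci_level, x$ci[1], x$ci[2], x$n_sims))
  invisible(x)
}

#' Bootstrap an arbitrary panel statistic
#'
#' Runs the full semi-parametric scheme: per simulation, perturb every
#' viability by its measurement SE (step 1), resample cell lines with
#' replacement (step 3), and evaluate the statistic on the simulated
#' panel restricted to the resampled multiset (steps 2, 4, 5). The SD of
#' the simulated statistics is the reported standard error.
#'
#' @param stat `function(panel, lines)` returning a scalar; `lines` is a
#'   character multiset of cell-line ids (repeats meaningful).
#' @param panel A `monotherapy_panel`.
#' @param config A [bootstrap_config()].
#' @param lines Cell-line set to resample from (default all panel lines).
#' @return A `bootstrap_result` (`point` is the statistic on the
#'   unperturbed panel and full line set; `sims` holds the simulated
#'   values).
#' @export
bootstrap_statistic <- function(stat, panel, config = bootstrap_config(),
                                lines = panel_cell_lines(panel)) {
  point <- stat(panel, lines)
  sims <- numeric(config$n_sims)
  first_error <- NULL
  for (i in seq_len(config$n_sims)) {
    set.seed(derive_seed(config$seed, i))
    sp <- draw_coupled_panel(panel)
    idx <- resample_lines(lines)
    sims[i] <- tryCatch(stat(sp, idx), error = function(e) {
      if (is.null(first_error)) first_error <<- conditionMessage(e)
      NA_real_
    })
  }
  if (mean(is.na(sims)) > 0.5) {
    abort(paste0("statistic failed in more than half of the simulations",
                 if (!is.null(first_error)) paste0(" (first error: ",
                                                   first_error, ")")),
          class = "idascreen_bootstrap_error")
  }
  new_bootstrap_result(point, sims, config)
}

# Per-line IDA/Bliss values for a line multiset on a (possibly simulated)
# panel, without re-running complete-case selection.
mean_efficacy_on <- function(panel, treatment, lines, model = "IDA") {
  cols <- panel_columns_for(panel, treatment)
  sub <- panel$mean[lines, cols, drop = FALSE]
  per_line <- if (model == "Bliss") {
    apply(pmin(pmax(sub, 0), 1), 1, prod)
  } else if (panel$orientation == "viability") {
    apply(sub, 1, min)
  } else {
    apply(sub, 1, max)
  }
  mean(per_line)
}

#' Bootstrap a trial hazard ratio and its log-rank power
#'
#' Per simulation both treatment arms are evaluated on the same drawn
#' panel when coupling is on (shared compounds get identical deviates) or
#' on independently drawn panels when off, then the resampled-line means,
#' the HR and the power are recomputed.
#'
#' @param panel A `monotherapy_panel`.
#' @param test,control Treatments (or spec strings).
#' @param design A [trial_design()]; `NULL` skips the power part.
#' @param config A [bootstrap_config()].
#' @param min_lines Minimum shared complete-case cell lines.
#' @param model `"IDA"` (default) or `"Bliss"`.
#' @return List with `hr` and (when `design` given) `power`, both
#'   `bootstrap_result`s, plus `n_lines`.
#' @export
bootstrap_hr_power <- function(panel, test, control, design = NULL,
                               config = bootstrap_config(n_sims = 10000),
                               min_lines = 1, model = c("IDA", "Bliss")) {
  model <- match.arg(model)
  test <- as_treatment(test); control <- as_treatment(control)
  lines <- complete_case_lines(panel, list(test, control), min_lines)
  hr_of <- function(p_test, p_ctrl, idx) {
    h_t <- max(mean_efficacy_on(p_test, test, idx, model), 0)
    h_c <- max(mean_efficacy_on(p_ctrl, control, idx, model), 0)
    if (h_c == 0) return(NA_real_)
    h_t / h_c
  }
  point <- hr_of(panel, panel, lines)
  sims <- numeric(config$n_sims)
  for (i in seq_len(config$n_sims)) {
    set.seed(derive_seed(config$seed, i))
    sp_test <- draw_coupled_panel(panel)
    sp_ctrl <- if (config$couple_shared_drugs) sp_test else draw_coupled_panel(panel)
    idx <- resample_lines(lines)
    sims[i] <- hr_of(sp_test, sp_ctrl, idx)
  }
  if (mean(is.na(sims)) > 0.5) {
    abort("hazard ratio undefined in more than half of the simulations",
          class = "idascreen_bootstrap_error")
  }
  out <- list(hr = new_bootstrap_result(point, sims, config),
              n_lines = length(lines))
  if (!is.null(design)) {
    p_of <- function(h) if (is.finite(h) && h > 0) logrank_power(h, design)$power
                        else NA_real_
    p_point <- p_of(point)
    p_sims <- vapply(sims, p_of, numeric(1))
    pow <- new_bootstrap_result(p_point, p_sims, config)
    # power is a probability: report a CI clipped to [0, 1]
    pow$ci <- pmin(pmax(pow$ci, 0), 1)
    out$power <- pow
  }
  out
}

#' Bootstrap an IDAcomboscore with its empirical null probability
#'
#' @param panel A `monotherapy_panel`.
#' @param combination Candidate treatment.
#' @param references Reference treatments (default: single components).
#' @param min_lines Minimum shared complete-case cell lines.
#' @param config A [bootstrap_config()] (convention: 1,000 sims for
#'   prospective scoring).
#' @return The `idacomboscore_result` with `se`, `null_p`, `ci` filled,
#'   plus a `bootstrap` element holding the full `bootstrap_result`.
#' @export
bootstrap_comboscore <- function(panel, combination, references = NULL,
                                 min_lines = 1,
                                 config = bootstrap_config(n_sims = 1000)) {
  combination <- as_treatment(combination)
  refs <- if (is.null(references)) component_treatments(combination)
          else if (inherits(references, "idascreen_treatment")) list(references)
          else lapply(references, as_treatment)
  point <- idacomboscore(panel, combination, refs, min_lines)
  lines <- complete_case_lines(panel, c(list(combination), refs), min_lines)
  score_of <- function(p, idx) {
    ref_means <- vapply(refs, function(r) mean_efficacy_on(p, r, idx), numeric(1))
    best <- min(ref_means)
    cm <- mean_efficacy_on(p, combination, idx)
    if (max(best, 0) == 0) return(NA_real_)
    delta <- best - cm
    delta - delta * (max(cm, 0) / max(best, 0))
  }
  boot <- bootstrap_statistic(score_of, panel, config, lines = lines)
  point$se <- boot$se
  point$ci <- boot$ci
  point$null_p <- empirical_null_probability(boot$sims[is.finite(boot$sims)])
  point$bootstrap <- boot
  point
}

#' Empirical probability that a score is not positive
#'
#' The null probability of a simulated score distribution: the fraction
#' of simulated scores `<= 0`. A raw value of exactly 0 is returned as 0
#' with an `upper_bound` attribute of `1 / n` (the resolution limit of
#' the simulation).
#'
#' @param simulated_scores Non-empty numeric vector.
#' @return Fraction in [0, 1].
#' @export
empirical_null_probability <- function(simulated_scores) {
  if (length(simulated_scores) == 0) {
    abort_input("empty score vector")
  }
  p <- mean(simulated_scores <= 0)
  if (p == 0) attr(p, "upper_bound") <- 1 / length(simulated_scores)
  p
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjustment (monotonicity enforced); output order
#' matches input order. FDRs `<= 0.05` are conventionally called
#' significant.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Stability of the mean IDA prediction under cell-line subsampling
#'
#' Quantifies how prediction dispersion grows as fewer cell lines are
#' used: for each requested size, `reps` random subsets are drawn without
#' replacement and the SD of the recomputed IDA mean across subsets is
#' reported. Prediction reliability degrades rapidly below about 50
#' lines.
#'
#' @param panel A `monotherapy_panel`.
#' @param treatment Treatment to predict.
#' @param sizes Subset sizes (each `<=` available complete-case lines).
#' @param reps Subsets per size (default 50).
#' @param seed Integer seed.
#' @return Tibble with columns `size`, `sd_mean_prediction`, `n_reps`.
#' @export
subsample_stability <- function(panel, treatment, sizes, reps = 50, seed = 1L) {
  treatment <- as_treatment(treatment)
  lines <- complete_case_lines(panel, treatment)
  if (any(sizes > length(lines)) || any(sizes < 1)) {
    abort_input(sprintf("sizes must be within [1, %d]", length(lines)))
  }
  rows <- lapply(seq_along(sizes), function(si) {
    vals <- numeric(reps)
    for (r in seq_len(reps)) {
      set.seed(derive_seed(seed, si * 100000 + r))
      sub <- sample(lines, sizes[si], replace = FALSE)
      vals[r] <- mean_efficacy_on(panel, treatment, sub)
    }
    tibble::tibble(size = sizes[si], sd_mean_prediction = sd(vals),
                   n_reps = reps)
  })
  dplyr::bind_rows(rows)
}
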