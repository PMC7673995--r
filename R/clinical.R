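#' Trial design parameters for a log-rank power calculation
#'
#' @param events Total number of observed endpoint events (PFS/TTP or OS),
#'   `>= 1`.
#' @param allocation_ratio Ratio of experimental to control participants
#'   (`> 0`, default 1).
#' @param alpha Two-sided significance level in (0, 1), default 0.05.
#' @return A `trial_design` object.
#' @export
trial_design <- function(events, allocation_ratio = 1, alpha = 0.05) {
  if (!is.numeric(events) || events < 1) abort_input("events must be >= 1")
  if (!is.numeric(allocation_ratio) || allocation_ratio <= 0) {
    abort_input("allocation_ratio must be > 0")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_input("alpha must be in (0, 1)")
  }
  structure(list(events = events, allocation_ratio = allocation_ratio,
                 alpha = alpha), class = "trial_design")
}

#' Map a predicted mean viability to a hazard
#'
#' Mean remaining viability after treatment is taken as a proxy for the
#' patient hazard under that therapy: 100% viability anchors to hazard 1
#' (no cell kill), 0% viability to hazard 0 (complete kill), linearly in
#' between. Negative predicted viabilities are floored at 0 (hazards are
#' non-negative) with a message.
#'
#' @param mean_viability Viability fraction(s).
#' @return Hazard value(s), `>= 0`.
#' @export
viability_to_hazard <- function(mean_viability) {
  if (any(!is.finite(mean_viability))) {
    abort_input("mean viability must be finite")
  }
  neg <- mean_viability < 0
  if (any(neg)) {
    inform(paste0(sum(neg), " negative mean viability value(s) floored to hazard 0"))
  }
  pmax(mean_viability, 0)
}

#' Hazard ratio between a test and a control prediction
#'
#' The predicted HR of a comparison is the mean test-treatment viability
#' divided by the mean control-treatment viability (on the hazard scale
#' after flooring). Both predictions must have been computed on the same
#' cell-line set.
#'
#' @param test,control `combo_prediction` objects sharing one cell-line
#'   set.
#' @return A `hazard_ratio_estimate`: `hr`, plus `se`/`ci95` slots filled
#'   by the bootstrap (see [bootstrap_hr_power()]).
#' @export
hazard_ratio <- function(test, control) {
  if (!setequal(test$cell_lines, control$cell_lines) ||
      test$n_lines != control$n_lines) {
    abort("test and control predictions must share the same cell-line set",
          class = "idascreen_consistency_error")
  }
  h_test <- viability_to_hazard(test$mean)
  h_ctrl <- viability_to_hazard(control$mean)
  if (h_ctrl == 0) {
    abort("control mean hazard is 0; hazard ratio undefined",
          class = "idascreen_input_error")
  }
  structure(
    list(hr = h_test / h_ctrl, se = NA_real_, ci95 = c(NA_real_, NA_real_),
         test = test$treatment$label, control = control$treatment$label,
         n_lines = test$n_lines),
    class = "hazard_ratio_estimate"
  )
}

#' @export
print.hazard_ratio_estimate <- function(x, ...) {
  cat(sprintf("<hazard_ratio> %s vs %s: HR = %.4f\n", x$test, x$control, x$hr))
  invisible(x)
}

#' Approximate log-rank power for a hazard ratio
#'
#' Freedman-type approximation for the power of a two-arm log-rank test
#' given the total number of events `m`, the allocation ratio `k`
#' (experimental : control) and a two-sided significance level:
#' `power = pnorm( sqrt(k * m) * |hr - 1| / (k * hr + 1) - qnorm(1 - alpha/2) )`.
#' At `hr = 1` this reduces to `alpha / 2`.
#'
#' @param hr Hazard ratio(s), `> 0`.
#' @param design A [trial_design()].
#' @return A `power_estimate`: `power` in [0, 1], `se` (filled by the
#'   bootstrap), `hr`.
#' @export
logrank_power <- function(hr, design) {
  stopifnot(inherits(design, "trial_design"))
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    abort_input("hazard ratio must be finite and > 0")
  }
  k <- design$allocation_ratio
  m <- design$events
  power <- pnorm(sqrt(k * m) * abs(hr - 1) / (k * hr + 1) -
                   qnorm(1 - design$alpha / 2))
  structure(list(power = power, se = NA_real_, hr = hr, design = design),
            class = "power_estimate")
}

#' Classify a trial comparison against a power threshold
#'
#' @param power_estimate A `power_estimate` (or bare power value).
#' @param threshold Power cutoff in (0, 1); the conventional 80% by
#'   default. A power exactly at the threshold counts as predicted
#'   success (`>=` convention).
#' @return Logical: predicted to detect a statistically significant
#'   improvement.
#' @export
classify_trial <- function(power_estimate, threshold = 0.80) {
  if (threshold <= 0 || threshold >= 1) abort_input("threshold must be in (0, 1)")
  p <- if (inherits(power_estimate, "power_estimate")) power_estimate$power
       else power_estimate
  p >= threshold
}

#' IDAcomboscore: prospective ranking of a combination
#'
#' Scores how much a combination improves on its best reference therapy:
#' `IDAcomboscore = delta_via - delta_via * HR_C/Mbest`, where `delta_via`
#' is the best reference mean viability minus the combination mean
#' viability (both under IDA, on one shared complete-case cell-line set)
#' and `HR_C/Mbest` is the ratio of the combination mean to the best
#' reference mean. Larger scores indicate combinations expected to be more
#' efficacious than their best constituent (or backbone) therapy.
#'
#' @param panel A viability-orientation `monotherapy_panel`.
#' @param combination The candidate treatment.
#' @param references Reference treatments; default the single-drug
#'   components of the combination. A multi-drug backbone passed here is
#'   treated as one reference "monotherapy".
#' @param min_lines Minimum shared complete-case cell lines.
#' @return An `idacomboscore_result` with `score`, `delta_via`,
#'   `hr_c_mbest`, `best_reference`, `n_lines`, and bootstrap annotation
#'   slots `se`, `null_p`, `fdr` (filled by [bootstrap_comboscore()]).
#' @export
idacomboscore <- function(panel, combination, references = NULL, min_lines = 1) {
  combination <- as_treatment(combination)
  if (is.null(references)) {
    references <- component_treatments(combination)
  } else if (inherits(references, "idascreen_treatment")) {
    references <- list(references)
  } else {
    references <- lapply(references, as_treatment)
  }
  lines <- complete_case_lines(panel, c(list(combination), references), min_lines)
  combo <- ida_combo(panel, combination, lines = lines)
  ref_preds <- lapply(references, function(r) ida_combo(panel, r, lines = lines))
  ref_means <- vapply(ref_preds, function(p) p$mean, numeric(1))
  best_i <- which.min(ref_means)
  best <- ref_preds[[best_i]]
  if (viability_to_hazard(best$mean) == 0) {
    abort("best reference mean hazard is 0; HR undefined",
          class = "idascreen_input_error")
  }
  delta_via <- best$mean - combo$mean
  hr <- viability_to_hazard(combo$mean) / viability_to_hazard(best$mean)
  structure(
    list(score = delta_via - delta_via * hr,
         delta_via = delta_via, hr_c_mbest = hr,
         best_reference = best$treatment$label,
         combination = combination$label, n_lines = length(lines),
         combo_mean = combo$mean, best_reference_mean = best$mean,
         se = NA_real_, null_p = NA_real_, fdr = NA_real_),
    class = "idacomboscore_result"
  )
}

#' @export
print.idacomboscore_result <- function(x, ...) {
  cat(sprintf("<idacomboscore> %s vs %s: score %.4g (dVia %.4g, HR %.4g, n = %d)\n",
              x$combination, x$best_reference, x$score, x$delta_via,
              x$hr_c_mbest, x$n_lines))
  invisible(x)
}

#' Score every unordered pair of drugs at prospective concentrations
#'
#' Each drug is evaluated at its stored clinical concentration (Csustained
#' capped at the maximum tested concentration, see [prospective_doses()]);
#' pairs with fewer than `min_lines` shared cell lines are emitted with
#' `NA` score (explicit missing markers). The score of a pair does not
#' depend on the order in which the drugs are listed.
#'
#' @param panel A `monotherapy_panel` containing a column for every drug
#'   at its prospective concentration.
#' @param drugs Drugs to score (must appear in `conc_map`).
#' @param conc_map Output of [read_concentration_table()].
#' @param min_lines Minimum shared complete-case cell lines (default 50,
#'   the pan-cancer convention).
#' @param display_cutoff Optional score filter: keep only drugs with at
#'   least one pair score `>=` the cutoff (the headline heat-map used
#'   0.004). `NULL` (default) keeps everything.
#' @return Tibble with one row per unordered pair: `drug_a`, `drug_b`,
#'   `score`, `delta_via`, `hr_c_mbest`, `best_reference`, `n_lines`.
#' @export
comboscore_matrix <- function(panel, drugs, conc_map, min_lines = 50,
                              display_cutoff = NULL) {
  missing <- setdiff(drugs, conc_map$drug)
  if (length(missing) > 0) {
    abort(paste0("drug(s) absent from concentration table: ",
                 paste(missing, collapse = ", ")),
          class = "idascreen_lookup_error")
  }
  doses <- prospective_doses(conc_map[match(drugs, conc_map$drug), ])
  pairs <- utils::combn(sort(drugs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tr <- treatment(c(a, b),
                    doses$concentration[match(c(a, b), doses$drug)])
    res <- tryCatch(
      idacomboscore(panel, tr, min_lines = min_lines),
      idascreen_insufficient_data = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(drug_a = a, drug_b = b, score = NA_real_,
                     delta_via = NA_real_, hr_c_mbest = NA_real_,
                     best_reference = NA_character_, n_lines = NA_integer_)
    } else {
      tibble::tibble(drug_a = a, drug_b = b, score = res$score,
                     delta_via = res$delta_via, hr_c_mbest = res$hr_c_mbest,
                     best_reference = res$best_reference,
                     n_lines = as.integer(res$n_lines))
    }
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(display_cutoff)) {
    keep_drugs <- unique(c(
      out$drug_a[!is.na(out$score) & out$score >= display_cutoff],
      out$drug_b[!is.na(out$score) & out$score >= display_cutoff]
    ))
    out <- out[out$drug_a %in% keep_drugs & out$drug_b %in% keep_drugs, ,
               drop = FALSE]
  }
  out
}

#' Mean IDA viability surface over a two-drug concentration grid
#'
#' Evaluates the mean IDA-predicted viability over the complete-case cell
#' lines at every grid point (x_a, x_b), with concentration 0 allowed
#' (the untreated upper asymptote). Also reports the best-monotherapy
#' plane: the lower of the two monotherapy means at their maximal grid
#' doses, the benchmark a combination must beat.
#'
#' @param fits List of `ll4_fit` objects covering both drugs.
#' @param drug_a,drug_b Drug identifiers.
#' @param grid_a,grid_b Concentration grids (µM, typically 0 to
#'   Csustained).
#' @param extrapolation_limit Passed to [predict_viability()].
#' @return Tibble (`conc_a`, `conc_b`, `mean_viability`, `n_lines`) with
#'   attribute `best_monotherapy`.
#' @export
dose_grid_scan <- function(fits, drug_a, drug_b, grid_a, grid_b,
                           extrapolation_limit = 2) {
  cl <- vapply(fits, function(f) f$cell_line, character(1))
  dg <- vapply(fits, function(f) f$drug, character(1))
  lines <- intersect(cl[dg == drug_a], cl[dg == drug_b])
  if (length(lines) == 0) {
    abort("no cell line has fits for both drugs",
          class = "idascreen_insufficient_data", n_lines = 0L)
  }
  pred_mat <- function(drug, grid) {
    m <- matrix(NA_real_, length(lines), length(grid))
    for (i in seq_along(lines)) {
      f <- fits[[which(cl == lines[i] & dg == drug)[1]]]
      m[i, ] <- vapply(grid, function(x) {
        predict_viability(f, x, extrapolation_limit = extrapolation_limit)$mean
      }, numeric(1))
    }
    m
  }
  va <- pred_mat(drug_a, grid_a)
  vb <- pred_mat(drug_b, grid_b)
  out <- tidyr::expand_grid(conc_a = grid_a, conc_b = grid_b)
  out$mean_viability <- mapply(function(a, b) {
    i <- match(a, grid_a); j <- match(b, grid_b)
    mean(pmin(va[, i], vb[, j]))
  }, out$conc_a, out$conc_b)
  out$n_lines <- length(lines)
  attr(out, "best_monotherapy") <- min(mean(va[, which.max(grid_a)]),
                                       mean(vb[, which.max(grid_b)]))
  out
}
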