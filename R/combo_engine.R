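#' Cell lines with complete data for a treatment
#'
#' Combination predictions are strict complete-case: only cell lines with
#' a non-missing estimate for every component of the treatment(s) enter
#' the population mean.
#'
#' @param panel A `monotherapy_panel`.
#' @param treatment An `idascreen_treatment` (or spec string), or a list of
#'   them; the intersection across all components of all treatments is
#'   returned.
#' @param min_lines Minimum surviving cell lines; an insufficient-data
#'   error carrying the count is raised below this. Conventional values:
#'   50 for pan-cancer analyses, 3 for subtype analyses.
#' @return Character vector of cell-line ids.
#' @export
complete_case_lines <- function(panel, treatment, min_lines = 1) {
  treatments <- if (inherits(treatment, "idascreen_treatment") ||
                    is.character(treatment)) list(treatment) else treatment
  cols <- unique(unlist(lapply(treatments, function(t) panel_columns_for(panel, t))))
  sub <- panel$mean[, cols, drop = FALSE]
  ok <- rowSums(!is.finite(sub)) == 0
  lines <- rownames(sub)[ok]
  if (length(lines) < min_lines) {
    abort(sprintf("only %d complete-case cell line(s) available (need >= %d)",
                  length(lines), min_lines),
          class = "idascreen_insufficient_data", n_lines = length(lines))
  }
  lines
}

new_combo_prediction <- function(treatment, model, per_line, cell_lines) {
  structure(
    list(treatment = treatment, model = model,
         per_line = setNames(per_line, cell_lines),
         mean = mean(per_line), n_lines = length(per_line),
         cell_lines = cell_lines),
    class = "combo_prediction"
  )
}

#' @export
print.combo_prediction <- function(x, ...) {
  cat(sprintf("<combo_prediction> %s [%s]: mean %.4f over %d cell lines\n",
              x$treatment$label, x$model, x$mean, x$n_lines))
  invisible(x)
}

#' Predict combination efficacy under independent drug action
#'
#' Under IDA the effect of a combination on a cell line equals the effect
#' of its single best constituent drug: per line the minimum viability
#' across components (viability orientation) or the maximum effect
#' (effect orientation). The population efficacy is the arithmetic mean
#' of the per-line predictions. Raw viabilities outside [0, 1] are used
#' as-is.
#'
#' @inheritParams complete_case_lines
#' @param lines Optional pre-computed cell-line set (must be complete-case
#'   for the treatment); defaults to [complete_case_lines()].
#' @return A `combo_prediction` with fields `per_line`, `mean`, `n_lines`.
#' @export
ida_combo <- function(panel, treatment, min_lines = 1, lines = NULL) {
  treatment <- as_treatment(treatment)
  cols <- panel_columns_for(panel, treatment)
  if (is.null(lines)) {
    lines <- complete_case_lines(panel, treatment, min_lines)
  }
  sub <- panel$mean[lines, cols, drop = FALSE]
  per_line <- if (panel$orientation == "viability") {
    apply(sub, 1, min)
  } else {
    apply(sub, 1, max)
  }
  new_combo_prediction(treatment, "IDA", unname(per_line), lines)
}

#' Predict combination efficacy under Bliss Independence
#'
#' Treats each component viability as an independent per-cell survival
#' probability: the combination survival is their product. Defined only
#' for probabilities, so component viabilities are clamped to [0, 1]
#' before multiplying (values below 0 rounded up to 0, above 1 rounded
#' down to 1). Requires a viability-orientation panel.
#'
#' @inheritParams ida_combo
#' @return A `combo_prediction`.
#' @export
bliss_combo <- function(panel, treatment, min_lines = 1, lines = NULL) {
  if (panel$orientation != "viability") {
    abort("Bliss Independence is defined on survival probabilities; needs a viability-orientation panel",
          class = "idascreen_orientation_error")
  }
  treatment <- as_treatment(treatment)
  cols <- panel_columns_for(panel, treatment)
  if (is.null(lines)) {
    lines <- complete_case_lines(panel, treatment, min_lines)
  }
  sub <- pmin(pmax(panel$mean[lines, cols, drop = FALSE], 0), 1)
  per_line <- apply(sub, 1, prod)
  new_combo_prediction(treatment, "Bliss", unname(per_line), lines)
}

#' Compare IDA and Bliss predictions on an identical cell-line set
#'
#' @inheritParams ida_combo
#' @return List with `ida`, `bliss` (both `combo_prediction`s on the same
#'   cell lines) and `mean_difference` (IDA mean minus Bliss mean).
#' @export
compare_models <- function(panel, treatment, min_lines = 1) {
  treatment <- as_treatment(treatment)
  lines <- complete_case_lines(panel, treatment, min_lines)
  ida <- ida_combo(panel, treatment, lines = lines)
  bliss <- bliss_combo(panel, treatment, lines = lines)
  list(ida = ida, bliss = bliss, mean_difference = ida$mean - bliss$mean)
}

#' Export combination predictions as a tidy table
#'
#' @param predictions A `combo_prediction` or list of them.
#' @param per_line Include one row per cell line instead of one summary
#'   row per prediction.
#' @return A tibble.
#' @export
predictions_to_table <- function(predictions, per_line = FALSE) {
  if (inherits(predictions, "combo_prediction")) predictions <- list(predictions)
  rows <- lapply(predictions, function(p) {
    if (per_line) {
      tibble::tibble(treatment = p$treatment$label, model = p$model,
                     cell_line = p$cell_lines,
                     predicted_viability = unname(p$per_line))
    } else {
      tibble::tibble(treatment = p$treatment$label, model = p$model,
                     n_lines = p$n_lines, mean = p$mean)
    }
  })
  dplyr::bind_rows(rows)
}
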