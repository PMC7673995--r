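#' Construct a monotherapy panel from mean and SE matrices
#'
#' The panel is the substrate of every combination prediction: a cell-line
#' by treatment-column matrix of viability point estimates with matching
#' standard errors. Columns are keyed `"drug@concentration"`; missing
#' estimates are `NA` in both matrices. A single orientation applies to the
#' whole panel: `"viability"` (lower = more effective, the default) or
#' `"effect"` (higher = more effective, e.g. viability reduction).
#'
#' @param mean,se Numeric matrices with identical dimensions; rownames are
#'   cell-line ids, colnames are `"drug@conc"` keys.
#' @param orientation `"viability"` or `"effect"`.
#' @return An object of class `monotherapy_panel`.
#' @export
monotherapy_panel <- function(mean, se, orientation = c("viability", "effect")) {
  orientation <- match.arg(orientation)
  mean <- as.matrix(mean); se <- as.matrix(se)
  if (!identical(dim(mean), dim(se))) {
    abort_input("mean and se matrices must have identical dimensions")
  }
  if (is.null(rownames(mean)) || is.null(colnames(mean))) {
    abort_input("panel matrices need cell-line rownames and 'drug@conc' colnames")
  }
  dimnames(se) <- dimnames(mean)
  if (any(se < 0, na.rm = TRUE)) {
    abort_input("standard errors must be >= 0")
  }
  cols <- colnames(mean)
  split_at <- regexpr("@[^@]*$", cols)
  structure(
    list(
      mean = mean,
      se = se,
      treatments = tibble::tibble(
        column = cols,
        drug = substr(cols, 1, split_at - 1),
        concentration = as.numeric(substr(cols, split_at + 1, nchar(cols)))
      ),
      orientation = orientation
    ),
    class = "monotherapy_panel"
  )
}

#' @export
print.monotherapy_panel <- function(x, ...) {
  cat(sprintf("<monotherapy_panel> %d cell lines x %d treatment columns (%s)\n",
              nrow(x$mean), ncol(x$mean), x$orientation))
  cat("  columns:", paste(head(colnames(x$mean), 6), collapse = ", "),
      if (ncol(x$mean) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.monotherapy_panel <- function(x) dim(x$mean)

#' Cell lines of a panel
#' @param panel A `monotherapy_panel`.
#' @export
panel_cell_lines <- function(panel) rownames(panel$mean)

panel_columns_for <- function(panel, treatment) {
  treatment <- as_treatment(treatment)
  cols <- treatment$components$column
  missing <- setdiff(cols, colnames(panel$mean))
  if (length(missing) > 0) {
    abort(paste0("treatment component(s) not in panel: ",
                 paste(missing, collapse = ", ")),
          class = "idascreen_lookup_error")
  }
  cols
}

#' Build a panel from fitted dose-response curves
#'
#' Evaluates each fitted curve at the requested (drug, concentration)
#' doses; (cell line, drug) pairs without a fit become explicit `NA`
#' markers. Concentrations must respect the extrapolation limit of every
#' fit they are evaluated against.
#'
#' @param fits List of `ll4_fit` objects (e.g. from [fit_ll4_screen()]).
#' @param doses Tibble/data frame with columns `drug` and `concentration`
#'   (µM), one panel column per row.
#' @param extrapolation_limit,se_floor Passed to [predict_viability()].
#' @return A `monotherapy_panel` with orientation `"viability"`.
#' @export
build_panel <- function(fits, doses, extrapolation_limit = 2, se_floor = 1e-6) {
  if (is.null(doses) || nrow(as.data.frame(doses)) == 0) {
    abort_input("doses list is empty")
  }
  doses <- tibble::as_tibble(doses)[, c("drug", "concentration")]
  doses <- dplyr::distinct(doses)
  lines <- sort(unique(vapply(fits, function(f) f$cell_line, character(1))))
  keys <- column_key(doses$drug, doses$concentration)
  mu <- matrix(NA_real_, length(lines), nrow(doses),
               dimnames = list(lines, keys))
  sg <- mu
  fit_keys <- paste(vapply(fits, function(f) f$cell_line, character(1)),
                    vapply(fits, function(f) f$drug, character(1)), sep = "|")
  for (j in seq_len(nrow(doses))) {
    for (i in seq_along(lines)) {
      k <- match(paste(lines[i], doses$drug[j], sep = "|"), fit_keys)
      if (is.na(k)) next
      p <- predict_viability(fits[[k]], doses$concentration[j],
                             extrapolation_limit = extrapolation_limit,
                             se_floor = se_floor)
      mu[i, j] <- p$mean
      sg[i, j] <- p$se
    }
  }
  monotherapy_panel(mu, sg, orientation = "viability")
}

#' Build a panel from measured viabilities (no curve fitting)
#'
#' For sparse dose designs (e.g. three-dose screens) where curve fitting
#' is impractical, the viability at a requested dose is the measured value
#' at exactly that dose. Replicates are averaged; the SE is the standard
#' error of the replicate mean, or `default_se` when only one replicate
#' exists.
#'
#' @param table An observation table.
#' @param doses Optional tibble with `drug` and `concentration` columns;
#'   defaults to every (drug, concentration) present in the table.
#' @param default_se Standard error assigned to single-replicate cells
#'   (viability units, default 0.05).
#' @param se_floor Lower bound on reported SEs (default 1e-6).
#' @return A `monotherapy_panel` with orientation `"viability"`.
#' @export
panel_from_observations <- function(table, doses = NULL, default_se = 0.05,
                                    se_floor = 1e-6) {
  agg <- table |>
    dplyr::group_by(.data$cell_line, .data$drug, .data$concentration) |>
    dplyr::summarise(
      mean = mean(.data$viability),
      se = if (dplyr::n() > 1) stats::sd(.data$viability) / sqrt(dplyr::n())
           else default_se,
      .groups = "drop"
    )
  if (is.null(doses)) {
    doses <- dplyr::distinct(agg, .data$drug, .data$concentration)
  } else {
    doses <- dplyr::distinct(tibble::as_tibble(doses)[, c("drug", "concentration")])
  }
  agg$column <- column_key(agg$drug, agg$concentration)
  keys <- column_key(doses$drug, doses$concentration)
  lines <- sort(unique(agg$cell_line))
  mu <- matrix(NA_real_, length(lines), length(keys),
               dimnames = list(lines, keys))
  sg <- mu
  idx_row <- match(agg$cell_line, lines)
  idx_col <- match(agg$column, keys)
  keep <- !is.na(idx_col)
  mu[cbind(idx_row[keep], idx_col[keep])] <- agg$mean[keep]
  sg[cbind(idx_row[keep], idx_col[keep])] <- pmax(agg$se[keep], se_floor)
  monotherapy_panel(mu, sg, orientation = "viability")
}

#' Write a panel as a wide CSV pair
#'
#' @param panel A `monotherapy_panel`.
#' @param mean_path,se_path Output paths for the point-estimate and SE
#'   matrices (cell lines as the first column).
#' @export
write_panel <- function(panel, mean_path, se_path) {
  to_tbl <- function(m) {
    tibble::as_tibble(m, rownames = "cell_line")
  }
  readr::write_csv(to_tbl(panel$mean), mean_path)
  readr::write_csv(to_tbl(panel$se), se_path)
  invisible(panel)
}
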