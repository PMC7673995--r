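#' Read a long-format monotherapy screen export
#'
#' Reads a CSV of per-well relative viabilities (one row per cell line,
#' drug, concentration and optionally replicate/site) into the canonical
#' observation table used by the rest of the package. Viability is stored
#' as a fraction of the untreated control (1.0 = untreated level); raw
#' screens routinely overshoot this range and values are deliberately not
#' clamped at ingestion — only the Bliss model clamps, downstream.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema_map Named list mapping canonical roles to column names in
#'   the file. Mandatory roles: `cell_line`, `drug`, `concentration`,
#'   `viability`. Optional: `replicate`, `site`. Defaults to the canonical
#'   dialect `cell_line`, `drug`, `concentration_uM`, `viability`,
#'   `replicate`, `site`.
#' @param viability_percent Set `TRUE` when the file stores viability on a
#'   0–100 percent scale; values are divided by 100. The scale is never
#'   guessed from the data.
#' @return A tibble with columns `cell_line`, `drug`, `concentration`,
#'   `viability`, `replicate`, `site` (the last two `NA` when absent).
#'   Rows with unparseable or non-finite numerics, negative concentrations,
#'   or empty identifiers are dropped with a reported count.
#' @export
read_monotherapy_screen <- function(path,
                                    schema_map = default_schema_map(),
                                    viability_percent = FALSE) {
  if (!file.exists(path)) {
    abort_input(paste0("screen file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  for (role in c("cell_line", "drug", "concentration", "viability")) {
    col <- schema_map[[role]]
    if (is.null(col)) {
      abort(paste0("schema_map is missing the mandatory role '", role, "'"),
            class = "idascreen_schema_error")
    }
    if (!col %in% names(raw)) {
      abort(paste0("screen file has no column '", col, "' (role '", role, "')"),
            class = "idascreen_schema_error")
    }
  }
  out <- tibble::tibble(
    cell_line = as.character(raw[[schema_map$cell_line]]),
    drug = as.character(raw[[schema_map$drug]]),
    concentration = suppressWarnings(as.numeric(raw[[schema_map$concentration]])),
    viability = suppressWarnings(as.numeric(raw[[schema_map$viability]])),
    replicate = if (!is.null(schema_map$replicate) &&
                    schema_map$replicate %in% names(raw)) {
      as.character(raw[[schema_map$replicate]])
    } else NA_character_,
    site = if (!is.null(schema_map$site) && schema_map$site %in% names(raw)) {
      as.character(raw[[schema_map$site]])
    } else NA_character_
  )
  if (viability_percent) {
    out$viability <- out$viability / 100
  }
  keep <- is.finite(out$concentration) & out$concentration >= 0 &
    is.finite(out$viability) &
    !is.na(out$cell_line) & nzchar(out$cell_line) &
    !is.na(out$drug) & nzchar(out$drug)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(paste0("dropped ", n_drop, " row(s) with unparseable or invalid values"))
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort_input("screen table is empty after validation")
  }
  out
}

#' @rdname read_monotherapy_screen
#' @export
default_schema_map <- function() {
  list(cell_line = "cell_line", drug = "drug",
       concentration = "concentration_uM", viability = "viability",
       replicate = "replicate", site = "site")
}

#' Write an observation table in the canonical CSV dialect
#'
#' @param table An observation table as returned by
#'   [read_monotherapy_screen()].
#' @param path Output path. Numeric columns are written with shortest
#'   round-trippable representations, so write-then-read reproduces the
#'   values bit-identically.
#' @export
write_observation_table <- function(table, path) {
  out <- tibble::tibble(
    cell_line = table$cell_line,
    drug = table$drug,
    concentration_uM = table$concentration,
    viability = table$viability,
    replicate = table$replicate,
    site = table$site
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an identifier-harmonization mapping
#'
#' Screens from different providers use slightly different names for the
#' same drugs and cell lines; a user-supplied mapping reconciles them.
#'
#' @param path CSV with columns `source`, `canonical`, `kind` (kind is
#'   `"drug"` or `"cell_line"`).
#' @return A tibble with those three columns.
#' @export
read_identifier_mapping <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  need <- c("source", "canonical", "kind")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0) {
    abort(paste0("mapping file lacks column(s): ", paste(missing, collapse = ", ")),
          class = "idascreen_schema_error")
  }
  bad_kind <- setdiff(unique(m$kind), c("drug", "cell_line"))
  if (length(bad_kind) > 0) {
    abort(paste0("mapping kind must be 'drug' or 'cell_line', got: ",
                 paste(bad_kind, collapse = ", ")),
          class = "idascreen_config_error")
  }
  m[, need]
}

#' Replace drug and cell-line names by canonical identifiers
#'
#' @param table An observation table.
#' @param mapping Tibble with columns `source`, `canonical`, `kind`
#'   (see [read_identifier_mapping()]). Must be functional: one canonical
#'   name per (source, kind).
#' @return The table with names substituted. Unmapped names pass through
#'   unchanged (so single-dataset runs need no mapping) and are reported.
#'   Row count is always preserved.
#' @export
harmonize_identifiers <- function(table, mapping) {
  if (nrow(mapping) == 0) return(table)
  conflicts <- mapping |>
    dplyr::distinct(.data$source, .data$canonical, .data$kind) |>
    dplyr::count(.data$source, .data$kind) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0("mapping is not functional; conflicting entries for: ",
                 paste(conflicts$source, collapse = ", ")),
          class = "idascreen_config_error")
  }
  mapping <- dplyr::distinct(mapping, .data$source, .data$canonical, .data$kind)
  apply_map <- function(values, kind) {
    sub <- mapping[mapping$kind == kind, ]
    idx <- match(values, sub$source)
    ifelse(is.na(idx), values, sub$canonical[idx])
  }
  unmapped_drugs <- setdiff(unique(table$drug),
                            mapping$source[mapping$kind == "drug"])
  unmapped_lines <- setdiff(unique(table$cell_line),
                            mapping$source[mapping$kind == "cell_line"])
  n_un <- length(unmapped_drugs) + length(unmapped_lines)
  if (n_un > 0) {
    inform(paste0(n_un, " identifier(s) had no mapping and were kept as-is"))
  }
  table$drug <- apply_map(table$drug, "drug")
  table$cell_line <- apply_map(table$cell_line, "cell_line")
  table
}

#' Restrict to the dominant screening site and average replicates
#'
#' Multi-site screens can mix protocols; for each (drug, cell line) unit
#' only rows from the site that performed the most experiments are kept
#' (ties broken by lexicographically smallest site id, reported), then any
#' remaining replicates at the same (cell line, drug, concentration) are
#' averaged into a single row. The operation is idempotent.
#'
#' @param table An observation table.
#' @return The reduced table with one row per (cell line, drug,
#'   concentration); `replicate` becomes `NA`.
#' @export
apply_replicate_policy <- function(table) {
  has_site <- any(!is.na(table$site))
  if (has_site) {
    counts <- table |>
      dplyr::filter(!is.na(.data$site)) |>
      dplyr::count(.data$cell_line, .data$drug, .data$site)
    chosen <- counts |>
      dplyr::group_by(.data$cell_line, .data$drug) |>
      dplyr::arrange(dplyr::desc(.data$n), .data$site, .by_group = TRUE) |>
      dplyr::summarise(site = .data$site[1], tie = sum(.data$n == .data$n[1]) > 1,
                       .groups = "drop")
    n_ties <- sum(chosen$tie)
    if (n_ties > 0) {
      inform(paste0(n_ties, " site tie(s) broken by lexicographic site id"))
    }
    table <- table |>
      dplyr::left_join(chosen |> dplyr::select(-"tie") |>
                         dplyr::rename(.chosen_site = "site"),
                       by = c("cell_line", "drug")) |>
      dplyr::filter(is.na(.data$.chosen_site) |
                      is.na(.data$site) |
                      .data$site == .data$.chosen_site) |>
      dplyr::select(-".chosen_site")
  }
  table |>
    dplyr::group_by(.data$cell_line, .data$drug, .data$concentration) |>
    dplyr::summarise(viability = mean(.data$viability),
                     replicate = NA_character_,
                     site = if (all(is.na(.data$site))) NA_character_
                            else min(.data$site, na.rm = TRUE),
                     .groups = "drop")
}

#' Read a clinical-concentration table
#'
#' Maps each drug to its sustained clinical plasma concentration
#' (Csustained, the maximum plasma concentration at least 6 h after
#' administration) and the maximum concentration tested in vitro. When a
#' drug appears in several rows (several clinical doses), the highest
#' clinical concentration is stored for prospective use.
#'
#' @param path CSV with columns `drug`, `csustained_uM`, `max_tested_uM`
#'   and an optional free-text `dose_note`.
#' @return A tibble with one row per drug: `drug`, `csustained`,
#'   `max_tested`, `dose_note`.
#' @export
read_concentration_table <- function(path) {
  cc <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("drug", "csustained_uM", "max_tested_uM")
  missing <- setdiff(need, names(cc))
  if (length(missing) > 0) {
    abort(paste0("concentration table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "idascreen_schema_error")
  }
  cs <- as.numeric(cc$csustained_uM)
  mt <- as.numeric(cc$max_tested_uM)
  if (any(!is.finite(cs)) || any(!is.finite(mt)) || any(cs <= 0) || any(mt <= 0)) {
    abort_input("concentrations must be finite and > 0")
  }
  tibble::tibble(
    drug = as.character(cc$drug),
    csustained = cs,
    max_tested = mt,
    dose_note = if ("dose_note" %in% names(cc)) as.character(cc$dose_note)
                else NA_character_
  ) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      csustained = max(.data$csustained),
      max_tested = max(.data$max_tested),
      dose_note = .data$dose_note[which.max(.data$csustained)],
      .groups = "drop"
    )
}

#' Prospective prediction concentrations from a concentration map
#'
#' Each drug is evaluated at its Csustained, capped at the maximum
#' concentration tested in vitro (predictions beyond the tested range are
#' reserved for explicitly requested extrapolation).
#'
#' @param conc_map Output of [read_concentration_table()].
#' @return Tibble with columns `drug`, `concentration`, `capped` (flag).
#' @export
prospective_doses <- function(conc_map) {
  tibble::tibble(
    drug = conc_map$drug,
    concentration = pmin(conc_map$csustained, conc_map$max_tested),
    capped = conc_map$csustained > conc_map$max_tested
  )
}
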