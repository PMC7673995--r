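#' Read a trial-design table
#'
#' @param path CSV with columns `trial_id`, `endpoint` (PFS/TTP/OS),
#'   `events`, `allocation_ratio` (defaults to 1 when blank), `alpha`
#'   (defaults to 0.05 when blank), `control`, `test` (treatment specs in
#'   the `"drugA@concA+drugB@concB"` µM syntax). Multi-arm trials are
#'   expressed as one row per control-vs-experimental comparison.
#' @return A tibble with validated columns.
#' @export
read_trial_table <- function(path) {
  tt <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("trial_id", "endpoint", "events", "control", "test")
  missing <- setdiff(need, names(tt))
  if (length(missing) > 0) {
    abort(paste0("trial table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "idascreen_schema_error")
  }
  if (!"allocation_ratio" %in% names(tt)) tt$allocation_ratio <- 1
  if (!"alpha" %in% names(tt)) tt$alpha <- 0.05
  tt$allocation_ratio[is.na(tt$allocation_ratio)] <- 1
  tt$alpha[is.na(tt$alpha)] <- 0.05
  tt
}

#' Build a viability panel from a screen, choosing fit vs measured per drug
#'
#' Drugs tested at four or more distinct positive concentrations get LL4
#' fits evaluated at the requested doses; drugs with sparser designs use
#' the measured value at an exactly matching dose (with replicate-spread
#' or default SE). The two sub-panels are merged over the union of cell
#' lines.
#'
#' @param table An observation table.
#' @param doses Tibble with `drug` and `concentration` columns.
#' @param default_se SE for single-replicate measured cells.
#' @param extrapolation_limit Passed to [predict_viability()].
#' @return A `monotherapy_panel`.
#' @export
build_panel_auto <- function(table, doses, default_se = 0.05,
                             extrapolation_limit = 2) {
  doses <- dplyr::distinct(tibble::as_tibble(doses)[, c("drug", "concentration")])
  n_doses <- table |>
    dplyr::filter(.data$concentration > 0) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$concentration), .groups = "drop")
  fit_drugs <- n_doses$drug[n_doses$n >= 4]
  panels <- list()
  d_fit <- doses[doses$drug %in% fit_drugs, , drop = FALSE]
  if (nrow(d_fit) > 0) {
    fits <- fit_ll4_screen(table[table$drug %in% d_fit$drug, , drop = FALSE])
    panels$fit <- build_panel(fits, d_fit,
                              extrapolation_limit = extrapolation_limit)
  }
  d_meas <- doses[!doses$drug %in% fit_drugs, , drop = FALSE]
  if (nrow(d_meas) > 0) {
    panels$meas <- panel_from_observations(
      table[table$drug %in% d_meas$drug, , drop = FALSE],
      doses = d_meas, default_se = default_se)
  }
  if (length(panels) == 1) return(panels[[1]])
  lines <- sort(unique(c(rownames(panels$fit$mean), rownames(panels$meas$mean))))
  keys <- c(colnames(panels$fit$mean), colnames(panels$meas$mean))
  mu <- matrix(NA_real_, length(lines), length(keys),
               dimnames = list(lines, keys))
  sg <- mu
  for (p in panels) {
    mu[rownames(p$mean), colnames(p$mean)] <- p$mean
    sg[rownames(p$se), colnames(p$se)] <- p$se
  }
  monotherapy_panel(mu, sg, orientation = "viability")
}

read_screen_inputs <- function(config) {
  schema <- config$schema_map %||% default_schema_map()
  tab <- read_monotherapy_screen(config$screen, schema_map = schema,
                                 viability_percent = isTRUE(config$viability_percent))
  if (!is.null(config$mapping)) {
    tab <- harmonize_identifiers(tab, read_identifier_mapping(config$mapping))
  }
  apply_replicate_policy(tab)
}

write_manifest <- function(config, path, extra = list()) {
  manifest <- c(
    list(package = "idascreen",
         version = as.character(utils::packageVersion("idascreen")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = config[!vapply(config, is.function, logical(1))]),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the clinical trial validation pipeline
#'
#' Reads a monotherapy screen and a trial table, builds a viability panel
#' at every concentration the trials reference, and for each
#' control-vs-experimental comparison computes the predicted hazard ratio,
#' its bootstrap SE, the log-rank power at the trial's event count, and
#' the predicted-success classification at the power threshold.
#'
#' @param config Named list: `screen` (CSV path), `trials` (CSV path),
#'   optional `mapping`, `schema_map`, `viability_percent`, `model`
#'   (`"IDA"`/`"Bliss"`; `"both"` runs each), `min_lines` (default 50),
#'   `n_sims` (default 10000), `seed` (default 1), `power_threshold`
#'   (default 0.8), `default_se` (default 0.05), `out_dir` (default a
#'   tempdir subdir).
#' @return Tibble of per-comparison results (also written to
#'   `trial_powers.csv` in `out_dir` with a `manifest.json`), invisibly.
#' @export
run_trial_validation <- function(config) {
  config$min_lines <- config$min_lines %||% 50
  config$n_sims <- config$n_sims %||% 10000
  config$seed <- config$seed %||% 1L
  config$power_threshold <- config$power_threshold %||% 0.8
  config$model <- config$model %||% "IDA"
  config$out_dir <- config$out_dir %||% file.path(tempdir(), "idascreen-trials")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- read_screen_inputs(config)
  trials <- read_trial_table(config$trials)
  specs <- unique(c(trials$control, trials$test))
  treatments <- lapply(specs, parse_treatment)
  doses <- dplyr::distinct(dplyr::bind_rows(
    lapply(treatments, function(t) t$components[, c("drug", "concentration")])))
  unknown <- setdiff(doses$drug, unique(tab$drug))
  if (length(unknown) > 0) {
    abort(paste0("trial drug(s) not present in screen: ",
                 paste(unknown, collapse = ", ")),
          class = "idascreen_lookup_error")
  }
  panel <- build_panel_auto(tab, doses, default_se = config$default_se %||% 0.05)

  models <- if (identical(config$model, "both")) c("IDA", "Bliss") else config$model
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    design <- trial_design(trials$events[i], trials$allocation_ratio[i],
                           trials$alpha[i])
    for (model in models) {
      bt <- bootstrap_hr_power(
        panel, trials$test[i], trials$control[i], design,
        config = bootstrap_config(n_sims = config$n_sims,
                                  seed = derive_seed(config$seed, i)),
        min_lines = config$min_lines, model = model)
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_id = trials$trial_id[i], endpoint = trials$endpoint[i],
        model = model, control = trials$control[i], test = trials$test[i],
        n_lines = bt$n_lines, hr = bt$hr$point, hr_se = bt$hr$se,
        hr_ci_low = bt$hr$ci[1], hr_ci_high = bt$hr$ci[2],
        power = bt$power$point, power_se = bt$power$se,
        predicted_success = classify_trial(bt$power$point,
                                           config$power_threshold)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, file.path(config$out_dir, "trial_powers.csv"))
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 extra = list(n_comparisons = nrow(out)))
  invisible(out)
}

#' Run the prospective combination-scoring pipeline
#'
#' Reads a monotherapy screen and a clinical-concentration table, builds a
#' panel at each drug's prospective concentration (Csustained capped at
#' the tested range), scores every unordered drug pair with the
#' IDAcomboscore, bootstraps SEs and empirical null probabilities, and
#' appends Benjamini-Hochberg FDRs.
#'
#' @param config Named list: `screen`, `concentrations` (CSV paths),
#'   optional `mapping`, `schema_map`, `viability_percent`, `min_lines`
#'   (default 50), `n_sims` (default 1000), `seed`, `display_cutoff`,
#'   `default_se`, `out_dir`.
#' @return Tibble of pair scores with `se`, `null_p`, `fdr` columns (also
#'   written to `comboscores.csv` with a `manifest.json`), invisibly.
#' @export
run_comboscore <- function(config) {
  config$min_lines <- config$min_lines %||% 50
  config$n_sims <- config$n_sims %||% 1000
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% file.path(tempdir(), "idascreen-comboscore")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- read_screen_inputs(config)
  conc_map <- read_concentration_table(config$concentrations)
  drugs <- intersect(conc_map$drug, unique(tab$drug))
  if (length(drugs) < 2) {
    abort_input("need at least two drugs present in both screen and concentration table")
  }
  doses <- prospective_doses(conc_map[match(drugs, conc_map$drug), ])
  panel <- build_panel_auto(tab, doses, default_se = config$default_se %||% 0.05)

  scores <- comboscore_matrix(panel, drugs, conc_map,
                              min_lines = config$min_lines,
                              display_cutoff = config$display_cutoff)
  if (all(is.na(scores$score))) {
    warn("no drug pair reached the minimum cell-line count; all scores missing")
  }
  scores$se <- NA_real_
  scores$null_p <- NA_real_
  for (i in seq_len(nrow(scores))) {
    if (is.na(scores$score[i])) next
    tr <- treatment(c(scores$drug_a[i], scores$drug_b[i]),
                    doses$concentration[match(c(scores$drug_a[i], scores$drug_b[i]),
                                              doses$drug)])
    bt <- bootstrap_comboscore(
      panel, tr, min_lines = config$min_lines,
      config = bootstrap_config(n_sims = config$n_sims,
                                seed = derive_seed(config$seed, i)))
    scores$se[i] <- bt$se
    scores$null_p[i] <- as.numeric(bt$null_p)
  }
  scores$fdr <- NA_real_
  ok <- !is.na(scores$null_p)
  if (any(ok)) scores$fdr[ok] <- bh_fdr(scores$null_p[ok])
  readr::write_csv(scores, file.path(config$out_dir, "comboscores.csv"))
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 extra = list(n_pairs = nrow(scores)))
  invisible(scores)
}
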