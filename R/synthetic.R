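#' Configuration for a synthetic monotherapy screen
#'
#' Emulates a CTRPv2/GDSC-style screen: each (cell line, drug) pair gets
#' its own true LL4 curve, evaluated over a log-spaced dose design with
#' replicate-level Gaussian noise. True parameters are drawn per pair:
#' upper asymptote `d` anchored at the untreated level 1.0, lower
#' asymptote `c ~ Uniform(0, 0.6)`, `ln e ~ Normal(mu_loge, sd_loge)`
#' (potencies spread over orders of magnitude), slope
#' `b ~ Uniform(0.5, 3)`.
#'
#' @param n_lines Number of cell lines.
#' @param drugs Character vector of drug names, or a count.
#' @param n_doses Log-spaced doses per drug (default 8).
#' @param n_replicates Replicates per dose (default 3).
#' @param dose_min,dose_max Dose range in µM (defaults 0.01 and 100,
#'   bracketing the potency distribution).
#' @param noise_sd Gaussian noise SD in viability units (default 0.05,
#'   typical replicate scatter in large screens).
#' @param heteroskedastic If `TRUE`, noise SD is proportional to the true
#'   viability (`noise_sd * v_true`), exercising the robust-covariance
#'   path.
#' @param mu_loge,sd_loge Location/scale of the log-potency distribution
#'   (defaults 0 and 1).
#' @param seed Integer seed.
#' @return A `synthetic_screen_config` list.
#' @export
synthetic_screen_config <- function(n_lines = 50, drugs = 2, n_doses = 8,
                                    n_replicates = 3, dose_min = 0.01,
                                    dose_max = 100, noise_sd = 0.05,
                                    heteroskedastic = FALSE, mu_loge = 0,
                                    sd_loge = 1, seed = 1L) {
  if (is.numeric(drugs)) drugs <- paste0("drug", seq_len(drugs))
  if (n_lines < 1) abort_input("n_lines must be >= 1")
  if (n_doses < 2) abort_input("n_doses must be >= 2")
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  structure(list(n_lines = n_lines, drugs = drugs, n_doses = n_doses,
                 n_replicates = n_replicates, dose_min = dose_min,
                 dose_max = dose_max, noise_sd = noise_sd,
                 heteroskedastic = heteroskedastic, mu_loge = mu_loge,
                 sd_loge = sd_loge, seed = as.integer(seed)),
            class = "synthetic_screen_config")
}

#' Generate a synthetic monotherapy screen with known ground truth
#'
#' @param config A [synthetic_screen_config()].
#' @return List with `observations` (canonical observation table:
#'   `cell_line`, `drug`, `concentration`, `viability`, `replicate`,
#'   `site`) and `truth` (tibble `cell_line`, `drug`, `b`, `c`, `d`, `e`)
#'   for recovery tests. Fully reproducible from the seed.
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  set.seed(config$seed)
  lines <- sprintf("line%03d", seq_len(config$n_lines))
  doses <- exp(seq(log(config$dose_min), log(config$dose_max),
                   length.out = config$n_doses))
  truth <- tidyr::expand_grid(cell_line = lines, drug = config$drugs)
  n_pairs <- nrow(truth)
  truth$b <- runif(n_pairs, 0.5, 3)
  truth$c <- runif(n_pairs, 0, 0.6)
  truth$d <- 1.0
  truth$e <- exp(rnorm(n_pairs, config$mu_loge, config$sd_loge))
  obs <- tidyr::expand_grid(
    truth[, c("cell_line", "drug")],
    concentration = doses,
    replicate = as.character(seq_len(config$n_replicates))
  )
  ti <- match(paste(obs$cell_line, obs$drug),
              paste(truth$cell_line, truth$drug))
  v_true <- ll4(obs$concentration, truth$b[ti], truth$c[ti],
                truth$d[ti], truth$e[ti])
  sdv <- if (config$heteroskedastic) {
    pmax(config$noise_sd * v_true, 1e-4)
  } else {
    config$noise_sd
  }
  obs$viability <- v_true + rnorm(nrow(obs), 0, sdv)
  obs$site <- NA_character_
  list(observations = tibble::as_tibble(obs), truth = truth)
}

#' Configuration for synthetic combination measurements
#'
#' @param truth_model Null model generating the "measured" combinations:
#'   `"IDA"` (per-line minimum) or `"Bliss"` (product of clamped
#'   survivals).
#' @param interaction_offset Viability units added to the null-model
#'   per-line value: negative injects synergy, positive antagonism
#'   (default 0, no interaction).
#' @param noise_sd Measurement noise SD (default 0.05).
#' @param seed Integer seed.
#' @return A `synthetic_combo_config` list.
#' @export
synthetic_combo_config <- function(truth_model = c("IDA", "Bliss"),
                                   interaction_offset = 0, noise_sd = 0.05,
                                   seed = 1L) {
  truth_model <- match.arg(truth_model)
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  structure(list(truth_model = truth_model,
                 interaction_offset = interaction_offset,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_combo_config")
}

#' Generate measured combination viabilities from monotherapy truth
#'
#' Plays the role of an experimentally measured combination screen: per
#' cell line the combination viability is the null-model value computed
#' from the true monotherapy viabilities, plus the interaction offset,
#' plus Gaussian noise.
#'
#' @param truth Tibble of true per-line monotherapy viabilities with
#'   columns `cell_line`, `drug`, `concentration`, `viability`, covering
#'   every component of every treatment.
#' @param treatments A treatment, spec string, or list of treatments;
#'   defaults to the single combination of all (drug, concentration)
#'   pairs present in `truth`.
#' @param config A [synthetic_combo_config()].
#' @return Tibble with columns `cell_line`, `treatment`, `viability`.
#' @export
generate_combo_measurements <- function(truth, treatments = NULL,
                                        config = synthetic_combo_config()) {
  stopifnot(inherits(config, "synthetic_combo_config"))
  if (is.null(treatments)) {
    comps <- dplyr::distinct(truth, .data$drug, .data$concentration)
    treatments <- list(treatment(comps$drug, comps$concentration))
  } else if (inherits(treatments, "idascreen_treatment") ||
             is.character(treatments)) {
    treatments <- list(as_treatment(treatments))
  } else {
    treatments <- lapply(treatments, as_treatment)
  }
  truth$column <- column_key(truth$drug, truth$concentration)
  lines <- sort(unique(truth$cell_line))
  set.seed(config$seed)
  rows <- lapply(treatments, function(tr) {
    cols <- tr$components$column
    vm <- sapply(cols, function(cc) {
      idx <- match(paste(lines, cc), paste(truth$cell_line, truth$column))
      truth$viability[idx]
    })
    vm <- matrix(vm, nrow = length(lines))
    if (any(is.na(vm))) {
      abort_input(paste0("truth table incomplete for treatment ", tr$label))
    }
    null_val <- if (config$truth_model == "IDA") {
      apply(vm, 1, min)
    } else {
      apply(pmin(pmax(vm, 0), 1), 1, prod)
    }
    measured <- null_val + config$interaction_offset +
      rnorm(length(null_val), 0, config$noise_sd)
    tibble::tibble(cell_line = lines, treatment = tr$label,
                   viability = measured)
  })
  dplyr::bind_rows(rows)
}
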