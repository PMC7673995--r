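#' Four-parameter log-logistic dose-response function
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (ln x - ln e)))`, the LL4 curve with
#' slope `b`, lower asymptote `c`, upper asymptote `d` and inflection
#' concentration `e` (µM). With the sign convention `b > 0`, viability
#' decreases with dose; `f(0) = d` and `f(Inf) = c`.
#'
#' @param x Concentration(s), µM, `>= 0`.
#' @param b,c,d,e LL4 parameters (`e > 0`).
#' @return Predicted viability fraction(s).
#' @export
ll4 <- function(x, b, c, d, e) {
  lx <- ifelse(x > 0, log(x), -Inf)
  eta <- b * (lx - log(e))
  # plogis(-eta) = 1 / (1 + exp(eta)), numerically stable for large |eta|
  c + (d - c) * stats::plogis(-eta)
}

# Gradient of ll4 with respect to (b, c, d, e), n x 4. Degenerate doses
# (x = 0) hit the asymptote limits where the b and e sensitivities vanish.
ll4_gradient <- function(x, b, c, d, e) {
  lx <- ifelse(x > 0, log(x), -Inf)
  eta <- b * (lx - log(e))
  p <- stats::plogis(eta)        # u / (1 + u)
  q <- stats::plogis(-eta)       # 1 / (1 + u)
  w <- p * q
  t_ <- lx - log(e)
  g_b <- -(d - c) * w * t_
  g_b[w == 0] <- 0               # limit w * t -> 0 at the asymptotes
  g_e <- (d - c) * w * b / e
  cbind(b = g_b, c = p, d = q, e = g_e)
}

#' Fit a four-parameter log-logistic curve to one cell line x drug series
#'
#' Bounded Levenberg-Marquardt least squares on (b, c, d, ln e). On
#' non-convergence the fit is retried from three jittered starts; if no
#' start converges, the object falls back to monotone linear interpolation
#' of per-dose mean viabilities and is flagged `converged = FALSE`.
#' Constant viability series yield a degenerate flat fit.
#'
#' @param observations Data frame with columns `concentration` (µM) and
#'   `viability` (fraction); replicate rows welcome.
#' @param cell_line,drug Optional identifiers stored on the fit.
#' @param lower,upper Parameter bounds on (b, c, d, ln e). Defaults:
#'   `|b| <= 20`, `c, d` in `[-0.5, 1.5]` (raw screens overshoot the [0, 1]
#'   band), `e` within `[min dose / 100, max dose * 100]`.
#' @param cov_type Sandwich covariance flavour, `"HC0"` (default) or
#'   `"HC1"`; see [robust_param_covariance()].
#' @return An object of class `ll4_fit`: parameters `b`, `c`, `d`, `e`,
#'   `vcov` (4x4, order b, c, d, e), `n_points`, `max_tested`, `converged`,
#'   `degenerate`, `method` (`"ll4"` or `"interpolation"`), `residual_sd`.
#' @export
fit_ll4 <- function(observations, cell_line = NA_character_,
                    drug = NA_character_, lower = NULL, upper = NULL,
                    cov_type = c("HC0", "HC1")) {
  cov_type <- match.arg(cov_type)
  x <- as.numeric(observations$concentration)
  y <- as.numeric(observations$viability)
  ok <- is.finite(x) & is.finite(y) & x >= 0
  x <- x[ok]; y <- y[ok]
  pos <- unique(x[x > 0])
  if (length(pos) < 2) {
    abort("need at least 2 distinct positive concentrations to fit",
          class = "idascreen_fit_error")
  }
  max_tested <- max(x)

  fit <- list(cell_line = cell_line, drug = drug, n_points = length(x),
              max_tested = max_tested, cov_type = cov_type)
  class(fit) <- "ll4_fit"

  if (sd(y) == 0) {
    # flat series: every dose at the same viability
    fit$b <- 1; fit$c <- y[1]; fit$d <- y[1]
    fit$e <- exp(mean(log(pos)))
    fit$vcov <- matrix(0, 4, 4, dimnames = list(c("b", "c", "d", "e"),
                                                c("b", "c", "d", "e")))
    fit$converged <- TRUE
    fit$degenerate <- TRUE
    fit$method <- "ll4"
    fit$residual_sd <- 0
    fit$dose_means <- dose_means(x, y)
    return(fit)
  }

  if (is.null(lower)) lower <- c(-20, -0.5, -0.5, log(min(pos) / 100))
  if (is.null(upper)) upper <- c(20, 1.5, 1.5, log(max(pos) * 100))

  d0 <- min(max(y), upper[3]); c0 <- max(min(y), lower[2])
  half <- (c0 + d0) / 2
  dm <- dose_means(x, y)
  e0 <- dm$concentration[which.min(abs(dm$viability - half))]
  if (e0 <= 0) e0 <- exp(mean(log(pos)))
  start <- c(1, c0, d0, log(e0))
  start <- pmin(pmax(start, lower), upper)

  resid_fn <- function(th) y - ll4(x, th[1], th[2], th[3], exp(th[4]))
  run_once <- function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
  }

  best <- NULL
  jitters <- list(c(0, 0, 0, 0), c(1, -1, 1, -1), c(-1, 1, -1, 1), c(2, 0, 0, 1))
  for (j in jitters) {
    st <- pmin(pmax(start + c(0.5, 0.05, 0.05, 0.7) * j, lower), upper)
    res <- run_once(st)
    if (is.null(res)) next
    conv <- res$info %in% 1:3
    dev <- res$deviance
    if (is.null(best) ||
        (conv && !best$conv) ||
        (conv == best$conv && dev < best$dev)) {
      best <- list(res = res, conv = conv, dev = dev)
    }
    if (conv && j[1] == 0) break  # default start converged; keep it
  }

  if (!is.null(best) && best$conv) {
    th <- best$res$par
    fit$b <- th[1]; fit$c <- th[2]; fit$d <- th[3]; fit$e <- exp(th[4])
    fit$converged <- TRUE
    fit$degenerate <- FALSE
    fit$method <- "ll4"
    r <- resid_fn(th)
    fit$residual_sd <- if (length(r) > 4) sqrt(sum(r^2) / (length(r) - 4)) else sd(r)
    fit$dose_means <- dm
    fit$vcov <- robust_param_covariance(fit, data.frame(concentration = x,
                                                        viability = y))
  } else {
    # interpolation fallback, flagged
    fit$b <- NA_real_; fit$c <- NA_real_; fit$d <- NA_real_; fit$e <- NA_real_
    fit$converged <- FALSE
    fit$degenerate <- FALSE
    fit$method <- "interpolation"
    fit$dose_means <- dm
    pred <- approx(dm$concentration, dm$viability, xout = x, rule = 2)$y
    fit$residual_sd <- sqrt(mean((y - pred)^2))
    fit$vcov <- matrix(NA_real_, 4, 4, dimnames = list(c("b", "c", "d", "e"),
                                                       c("b", "c", "d", "e")))
  }
  fit
}

dose_means <- function(x, y) {
  agg <- tapply(y, x, mean)
  tibble::tibble(concentration = as.numeric(names(agg)),
                 viability = as.numeric(agg)) |>
    dplyr::arrange(.data$concentration)
}

#' @export
print.ll4_fit <- function(x, ...) {
  cat("<ll4_fit>", x$cell_line, "/", x$drug, "\n")
  if (x$method == "ll4") {
    cat(sprintf("  b=%.4g c=%.4g d=%.4g e=%.4g uM (n=%d, max tested %.4g uM)\n",
                x$b, x$c, x$d, x$e, x$n_points, x$max_tested))
  } else {
    cat("  non-convergent; interpolation fallback\n")
  }
  invisible(x)
}

#' Heteroskedasticity-consistent covariance of LL4 parameters
#'
#' Sandwich estimator for nonlinear least squares built from the analytic
#' Jacobian J and raw residuals r:
#' `V = (J'J)^-1 J' diag(r^2) J (J'J)^-1` (HC0; HC1 rescales by
#' `n / (n - 4)`). The result is symmetrized and eigenvalue-floored at 0 so
#' it is positive semi-definite by construction. A singular `J'J` is
#' handled with the Moore-Penrose pseudo-inverse and flagged via the
#' `"pseudo_inverse"` attribute.
#'
#' @param fit A converged `ll4_fit`.
#' @param observations Data frame with `concentration` and `viability`
#'   used in the fit.
#' @param type `"HC0"` (default) or `"HC1"`.
#' @return 4x4 matrix, parameter order (b, c, d, e).
#' @export
robust_param_covariance <- function(fit, observations,
                                    type = fit$cov_type %||% "HC0") {
  if (!isTRUE(fit$converged) || fit$method != "ll4") {
    abort("robust covariance needs a converged LL4 fit",
          class = "idascreen_fit_error")
  }
  x <- as.numeric(observations$concentration)
  y <- as.numeric(observations$viability)
  r <- y - ll4(x, fit$b, fit$c, fit$d, fit$e)
  nm <- c("b", "c", "d", "e")
  if (all(r == 0)) {
    return(matrix(0, 4, 4, dimnames = list(nm, nm)))
  }
  J <- ll4_gradient(x, fit$b, fit$c, fit$d, fit$e)
  JtJ <- crossprod(J)
  pseudo <- FALSE
  A <- tryCatch(solve(JtJ), error = function(e) {
    pseudo <<- TRUE
    MASS::ginv(JtJ)
  })
  meat <- crossprod(J * r)       # J' diag(r^2) J
  V <- A %*% meat %*% A
  if (type == "HC1") {
    n <- length(r)
    V <- V * n / max(n - 4, 1)
  }
  V <- (V + t(V)) / 2
  eg <- eigen(V, symmetric = TRUE)
  eg$values[eg$values < 0] <- 0
  V <- eg$vectors %*% diag(eg$values, 4) %*% t(eg$vectors)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(nm, nm)
  if (pseudo) attr(V, "pseudo_inverse") <- TRUE
  V
}

#' Predict viability (with delta-method standard error) at a concentration
#'
#' @param fit An `ll4_fit`.
#' @param concentration Concentration in µM, `>= 0`.
#' @param extrapolation_limit Hard cap as a multiple of the maximum tested
#'   concentration; requests beyond `extrapolation_limit * max_tested`
#'   raise a range error (default 2, mirroring the rule that clinical
#'   concentrations must not exceed 2x the tested range). Predictions
#'   above 1x max tested are allowed but flagged `extrapolated`.
#' @param se_floor Lower bound on the reported standard error (default
#'   1e-6) so downstream bootstrap draws stay well-defined for
#'   zero-residual fits.
#' @return List with `mean`, `se` (`sqrt(g' V g)` with `g` the LL4 gradient,
#'   capped at the curve's dynamic range `|d - c|` plus the residual SD,
#'   since the delta-method linearization can blow up for ill-determined
#'   steep fits while the prediction itself is bounded by the asymptotes),
#'   `source` (`"fitted"` or `"interpolated"`), `extrapolated`.
#' @export
predict_viability <- function(fit, concentration, extrapolation_limit = 2,
                              se_floor = 1e-6) {
  stopifnot(inherits(fit, "ll4_fit"))
  if (!is.finite(concentration) || concentration < 0) {
    abort_input("concentration must be finite and >= 0")
  }
  if (concentration > extrapolation_limit * fit$max_tested) {
    abort(sprintf(
      "concentration %.4g uM for drug '%s' exceeds %gx the maximum tested (%.4g uM)",
      concentration, fit$drug, extrapolation_limit, fit$max_tested),
      class = "idascreen_range_error")
  }
  extrapolated <- concentration > fit$max_tested
  if (fit$method == "ll4") {
    m <- ll4(concentration, fit$b, fit$c, fit$d, fit$e)
    g <- drop(ll4_gradient(concentration, fit$b, fit$c, fit$d, fit$e))
    se <- sqrt(max(0, drop(t(g) %*% fit$vcov %*% g)))
    # the prediction is bounded within the asymptotes, so its sampling SD
    # cannot meaningfully exceed the curve's dynamic range; this caps the
    # delta-method linearization blow-up of ill-determined steep fits
    se <- min(se, abs(fit$d - fit$c) + fit$residual_sd)
    src <- "fitted"
  } else {
    m <- approx(fit$dose_means$concentration, fit$dose_means$viability,
                xout = concentration, rule = 2)$y
    se <- fit$residual_sd
    src <- "interpolated"
  }
  list(mean = m, se = max(se, se_floor), source = src,
       extrapolated = extrapolated)
}

#' Fit LL4 curves for every (cell line, drug) series in a screen
#'
#' Series with fewer than `min_doses` distinct positive concentrations are
#' skipped (three-dose designs are handled by measured-value panels, see
#' [panel_from_observations()]).
#'
#' @param table An observation table.
#' @param min_doses Minimum distinct positive doses to attempt a curve fit
#'   (default 4).
#' @param ... Passed to [fit_ll4()].
#' @return A list of `ll4_fit` objects named `"cell_line|drug"`.
#' @export
fit_ll4_screen <- function(table, min_doses = 4, ...) {
  groups <- split(table, paste(table$cell_line, table$drug, sep = "|"))
  fits <- list()
  for (key in names(groups)) {
    g <- groups[[key]]
    if (length(unique(g$concentration[g$concentration > 0])) < min_doses) next
    fits[[key]] <- fit_ll4(g, cell_line = g$cell_line[1], drug = g$drug[1], ...)
  }
  fits
}

#' Serialize fitted curves to a flat table
#'
#' @param fits List of `ll4_fit` objects.
#' @return Tibble with one row per fit: identifiers, parameters,
#'   `max_tested_uM`, `converged`, and the flattened covariance columns
#'   `cov_<p>_<q>`.
#' @export
fits_to_table <- function(fits) {
  nm <- c("b", "c", "d", "e")
  rows <- lapply(fits, function(f) {
    cov_vals <- as.numeric(f$vcov)
    names(cov_vals) <- paste0("cov_", rep(nm, times = 4), "_", rep(nm, each = 4))
    tibble::tibble(cell_line = f$cell_line, drug = f$drug,
                   b = f$b, c = f$c, d = f$d, e = f$e,
                   max_tested_uM = f$max_tested, converged = f$converged,
                   !!!as.list(cov_vals))
  })
  dplyr::bind_rows(rows)
}
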