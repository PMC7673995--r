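# Shared fixtures: tiny panels, brute-force oracles, CSV writers.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_panel <- function(mean, se = 0.02, lines = NULL, cols = NULL,
                       orientation = "viability") {
  mean <- as.matrix(mean)
  if (is.null(lines)) lines <- sprintf("L%02d", seq_len(nrow(mean)))
  if (is.null(cols)) cols <- paste0(letters[seq_len(ncol(mean))], "@1")
  dimnames(mean) <- list(lines, cols)
  if (length(se) == 1) se <- matrix(se, nrow(mean), ncol(mean))
  dimnames(se) <- dimnames(mean)
  monotherapy_panel(mean, se, orientation = orientation)
}

random_panel <- function(n_lines, n_drugs, se = 0.02, vmin = -0.1, vmax = 1.2) {
  m <- matrix(runif(n_lines * n_drugs, vmin, vmax), n_lines, n_drugs)
  make_panel(m, se = se)
}

panel_treatment <- function(panel, cols = colnames(panel$mean)) {
  comps <- panel$treatments[match(cols, panel$treatments$column), ]
  treatment(comps$drug, comps$concentration)
}

# Independent brute-force enumeration oracles for the null models.
oracle_ida_mean <- function(viab_matrix) {
  mean(apply(viab_matrix, 1, min))
}
oracle_bliss_mean <- function(viab_matrix) {
  mean(apply(pmin(pmax(viab_matrix, 0), 1), 1, prod))
}

# Textbook step-up BH adjustment, kept independent of the implementation.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

write_screen_csv <- function(table, path = tempfile(fileext = ".csv")) {
  write_observation_table(table, path)
  path
}

write_conc_csv <- function(drugs, csustained, max_tested,
                           path = tempfile(fileext = ".csv")) {
  readr::write_csv(
    tibble::tibble(drug = drugs, csustained_uM = csustained,
                   max_tested_uM = max_tested),
    path)
  path
}
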