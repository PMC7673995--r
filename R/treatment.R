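#' Define a treatment (one or more drugs at fixed concentrations)
#'
#' A treatment is a set of (drug, concentration) components applied together.
#' A single component describes a monotherapy; multi-drug backbones (e.g.
#' cisplatin + gemcitabine) are themselves treatments and can serve as the
#' reference "monotherapy" in prospective scoring.
#'
#' @param drugs Character vector of drug identifiers.
#' @param concentrations Numeric vector of concentrations in µM, recycled
#'   against `drugs` if length 1. Concentration 0 is allowed (untreated
#'   anchor, maps to the upper asymptote of a fitted curve).
#' @param label Optional display label; defaults to
#'   `"drugA@concA+drugB@concB"`.
#' @return An object of class `idascreen_treatment` with fields `components`
#'   (tibble with columns `drug`, `concentration`, `column`) and `label`.
#' @examples
#' treatment(c("cisplatin", "gemcitabine"), c(3.3, 10))
#' @export
treatment <- function(drugs, concentrations, label = NULL) {
  if (length(drugs) == 0) {
    abort_input("a treatment needs at least one component")
  }
  if (length(concentrations) == 1L) {
    concentrations <- rep(concentrations, length(drugs))
  }
  if (length(concentrations) != length(drugs)) {
    abort_input("`drugs` and `concentrations` must have matching lengths")
  }
  if (!is.numeric(concentrations) || any(!is.finite(concentrations)) ||
      any(concentrations < 0)) {
    abort_input("concentrations must be finite and >= 0")
  }
  components <- tibble::tibble(
    drug = as.character(drugs),
    concentration = as.numeric(concentrations),
    column = column_key(drugs, concentrations)
  )
  if (anyDuplicated(components$column)) {
    abort_input("duplicate (drug, concentration) components in treatment")
  }
  structure(
    list(
      components = components,
      label = label %||% paste(components$column, collapse = "+")
    ),
    class = "idascreen_treatment"
  )
}

#' Parse a treatment specification string
#'
#' Accepts the `"drugA@concA+drugB@concB"` syntax used in trial-design
#' tables, with concentrations in µM.
#'
#' @param spec A single specification string.
#' @return An `idascreen_treatment`.
#' @examples
#' parse_treatment("paclitaxel@0.2+navitoclax@2.9")
#' @export
parse_treatment <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(trimws(spec), "+", fixed = TRUE)[[1]]
  pieces <- strsplit(parts, "@", fixed = TRUE)
  bad <- vapply(pieces, length, integer(1)) != 2L
  if (length(parts) == 0 || any(bad)) {
    abort_input(
      paste0("cannot parse treatment spec '", spec,
             "'; expected 'drug@conc' components joined by '+'")
    )
  }
  drugs <- trimws(vapply(pieces, `[[`, character(1), 1L))
  concs <- suppressWarnings(as.numeric(vapply(pieces, `[[`, character(1), 2L)))
  if (any(is.na(concs))) {
    abort_input(paste0("non-numeric concentration in treatment spec '", spec, "'"))
  }
  treatment(drugs, concs, label = spec)
}

#' @export
print.idascreen_treatment <- function(x, ...) {
  cat("<treatment>", x$label, "\n")
  invisible(x)
}

as_treatment <- function(x) {
  if (inherits(x, "idascreen_treatment")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_treatment(x))
  abort_input("expected an idascreen_treatment or a 'drug@conc' spec string")
}

# Single-component treatments for each component of `x` (the default
# reference set for IDAcomboscore calculations).
component_treatments <- function(x) {
  lapply(seq_len(nrow(x$components)), function(i) {
    treatment(x$components$drug[i], x$components$concentration[i])
  })
}
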