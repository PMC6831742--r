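## Element property tables for the supported organic set.

#' Supported chemical elements
#'
#' The package handles organic molecules built from ten elements:
#' C, H, N, O, P, S, F, Cl, Br and I.  Every parser rejects anything else.
#'
#' @return Character vector of the ten supported element symbols, in the
#'   canonical order used throughout the feature schema.
#' @export
supported_elements <- function() {
  c("C", "H", "N", "O", "P", "S", "F", "Cl", "Br", "I")
}

## Single-bond covalent radii (Angstrom), standard values.
COVALENT_RADIUS <- c(
  C = 0.76, H = 0.31, N = 0.71, O = 0.66, P = 1.07,
  S = 1.05, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39
)

## Hard valence caps used by Molecule validation (sum of bond orders).
MAX_VALENCE <- c(
  C = 4, H = 1, N = 4, O = 2, P = 5,
  S = 6, F = 1, Cl = 1, Br = 1, I = 1
)

## Typical neutral-organic valences used when filling implicit hydrogens.
FILL_VALENCE <- c(
  C = 4, H = 1, N = 3, O = 2, P = 3,
  S = 2, F = 1, Cl = 1, Br = 1, I = 1
)

## Pauling electronegativities (dimensionless), used by the charge oracle.
PAULING_CHI <- c(
  C = 2.55, H = 2.20, N = 3.04, O = 3.44, P = 2.19,
  S = 2.58, F = 3.98, Cl = 3.16, Br = 2.96, I = 2.66
)

normalize_element <- function(sym) {
  sym <- trimws(sym)
  out <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
  out[nchar(sym) == 0] <- ""
  out
}

check_elements <- function(elements, where = "input") {
  bad <- setdiff(unique(elements), supported_elements())
  if (length(bad) > 0) {
    stop(sprintf("unsupported element(s) in %s: %s (supported: %s)",
                 where, paste(bad, collapse = ", "),
                 paste(supported_elements(), collapse = ", ")),
         call. = FALSE)
  }
  invisible(elements)
}
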