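#' Van der Waals radii table
#'
#' Fixed element-to-radius lookup (Angstrom) used for all steric scoring.
#' Values follow the Bondi/UFF-style conventions common in docking codes;
#' unknown heavy elements fall back to 1.7 A with a warning.
#'
#' @format Named numeric vector, element symbol to radius in Angstrom.
#' @export
vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98,
  H = 1.20, B = 1.92, Se = 1.90, Fe = 1.80, Zn = 1.39,
  Mg = 1.73, Ca = 2.00, Mn = 1.80, Na = 2.27, K = 2.75
)

#' Look up vdW radii for element symbols
#'
#' @param elements character vector of element symbols (e.g. "C", "Cl").
#' @return numeric vector of radii in Angstrom.
#' @keywords internal
lookup_radii <- function(elements) {
  el <- normalize_element(elements)
  r <- unname(vdw_radii[el])
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using 1.7 A", call. = FALSE)
    r[is.na(r)] <- 1.7
  }
  r
}

# "CL"/" C" etc. -> canonical symbol case
normalize_element <- function(elements) {
  el <- trimws(elements)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

is_hydrogen <- function(elements) normalize_element(elements) == "H"
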