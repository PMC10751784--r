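# Element tables used for bond perception and typing.

# Covalent radii in Angstrom (Cordero et al. single-bond radii; low-spin
# values for first-row transition metals).
.COV_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20, Br = 1.20, I = 1.39,
  Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39, Fe = 1.32,
  Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54, Tc = 1.47, Ru = 1.46,
  Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44,
  Hf = 1.75, Ta = 1.70, W = 1.62, Re = 1.51, Os = 1.44, Ir = 1.41,
  Pt = 1.36, Au = 1.36, Hg = 1.32,
  DD = 0.00
)

.METALS <- c(
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg"
)

#' Is an element symbol a (transition) metal?
#'
#' @param element character vector of element symbols.
#' @return logical vector.
#' @export
is_metal <- function(element) element %in% .METALS

#' Covalent radius of an element
#'
#' @param element character vector of element symbols (case-sensitive,
#'   e.g. "Ru"); the dummy pseudo-element "DD" has radius 0.
#' @return numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .COV_RADII[element]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# Normalize an element symbol: "RU"/"ru" -> "Ru", "C" -> "C".
.norm_element <- function(x) {
  x <- trimws(x)
  out <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  out[toupper(x) == "DD"] <- "DD"   # dummy pseudo-element
  out
}

.known_element <- function(x) x %in% names(.COV_RADII)
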