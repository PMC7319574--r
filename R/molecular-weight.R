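# IUPAC conventional standard atomic weights (abridged), g/mol
.atomicWeights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Sc = 44.956, Ti = 47.867, V = 50.942, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904,
  Kr = 83.798, Rb = 85.468, Sr = 87.62, Y = 88.906, Zr = 91.224,
  Mo = 95.95, Ru = 101.07, Rh = 102.91, Pd = 106.42, Ag = 107.87,
  Cd = 112.41, Sn = 118.71, Sb = 121.76, Te = 127.60, I = 126.90,
  Xe = 131.29, Cs = 132.91, Ba = 137.33, W = 183.84, Pt = 195.08,
  Au = 196.97, Hg = 200.59, Pb = 207.2, Bi = 208.98, U = 238.03
)

#' Molecular weight from a Hill-notation chemical formula
#'
#' Sums standard atomic weights over the parsed element counts. Formulas that
#' are empty, missing, or not a plain element/count sequence (polymeric "R" or
#' "X" groups, "*" repeats, parentheses, unknown element symbols) yield `NA`:
#' the function never raises. Fractional counts, as found in biomass
#' pseudo-metabolites, are accepted.
#'
#' @param formula character vector of chemical formulas (e.g. `"C6H12O6"`).
#' @return numeric vector of weights in g/mol; `NA` where not computable.
#' @examples
#' molecularWeight(c("H2O", "C6H12O6", "", "RC6H5"))
#' @export
molecularWeight <- function(formula) {
  vapply(as.character(formula), .mwOne, numeric(1), USE.NAMES = FALSE)
}

.mwOne <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NA_real_)
  rest <- f
  total <- 0
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", rest))[[1]]
    if (length(m) == 0 || !nzchar(m[1])) return(NA_real_)
    elem <- m[2]
    w <- .atomicWeights[elem]
    if (is.na(w)) return(NA_real_)
    count <- if (nzchar(m[3])) suppressWarnings(as.numeric(m[3])) else 1
    if (is.na(count)) return(NA_real_)
    total <- total + w * count
    rest <- substr(rest, nchar(m[1]) + 1, nchar(rest))
  }
  if (total <= 0) NA_real_ else unname(total)
}
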