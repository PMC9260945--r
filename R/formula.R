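# Molecular formulas and standard atomic weights.

# IUPAC 2021 standard atomic weights (conventional values, g/mol), to at
# least three decimals. Covers the elements of typical drug-like organic
# molecules; extend here if a library needs more.
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845,
  Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.904
)

#' Parse a Hill-style molecular formula
#'
#' Splits a molecular formula such as `"C21H20N2O2"` into an element ->
#' count map. Element symbols are validated against the standard atomic
#' weight table; counts may have several digits and default to 1.
#'
#' @param text A single formula string, e.g. `"C21H20N2O2"`.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C21H20N2O2")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty molecular formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed molecular formula: ", text)
  }
  sym <- sub("[0-9]*$", "", tokens)
  num <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(num == "", 1L, suppressWarnings(as.integer(num)))
  unknown <- setdiff(sym, names(.atomic_weights))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(cnt < 1L)) stop("element counts must be >= 1")
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  # report in Hill order: C, H, then alphabetical
  hill <- c(intersect(c("C", "H"), names(out)),
            sort(setdiff(names(out), c("C", "H"))))
  out[hill]
}

#' Molecular weight from an element-count map
#'
#' Sum of count times standard atomic weight over all elements. Reporting
#' convention is two decimals, half away from zero (`digits = 2`); the
#' default returns full precision so that weights stay exactly additive.
#'
#' @param formula Named numeric vector of element counts, as produced by
#'   [parse_formula()], or a formula string.
#' @param digits Optional decimal places for report rounding (half-up).
#' @return Molecular weight in g/mol.
#' @export
#' @examples
#' molecular_weight("H2O", digits = 2)  # 18.02
molecular_weight <- function(formula, digits = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  unknown <- setdiff(names(formula), names(.atomic_weights))
  if (length(unknown)) {
    stop("no standard atomic weight for: ", paste(unknown, collapse = ", "))
  }
  mw <- sum(formula * .atomic_weights[names(formula)])
  if (!is.null(digits)) mw <- round_half_up(mw, digits)
  mw
}
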