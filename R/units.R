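#' Parse a value with an optional physical unit suffix
#'
#' Configuration files accept numbers with explicit unit suffixes
#' (e.g. `"23e-8 S"`, `"-62.309 mV"`, `"6.4 ms"`, `"-400 pA"`). Everything is
#' converted to strict SI (V, A, S, F, s, Hz, M).
#'
#' @param x a numeric, or a string `"<number> <unit>"`.
#' @return numeric value in SI units.
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  if (!is.character(x)) stop("cannot parse quantity: ", deparse(x))
  scale <- c(
    V = 1, mV = 1e-3, uV = 1e-6,
    A = 1, mA = 1e-3, uA = 1e-6, nA = 1e-9, pA = 1e-12,
    S = 1, mS = 1e-3, uS = 1e-6, nS = 1e-9,
    F = 1, uF = 1e-6, nF = 1e-9, pF = 1e-12,
    s = 1, ms = 1e-3, us = 1e-6,
    Hz = 1, kHz = 1e3,
    M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9,
    "%" = 1
  )
  out <- vapply(x, function(xi) {
    m <- regmatches(xi, regexec(
      "^\\s*([-+]?[0-9.]+(?:[eE][-+]?[0-9]+)?)\\s*([a-zA-Z%]*)\\s*$", xi))[[1]]
    if (length(m) == 0) stop("cannot parse quantity: '", xi, "'")
    val <- as.numeric(m[2])
    unit <- m[3]
    if (nzchar(unit)) {
      if (!unit %in% names(scale)) stop("unknown unit '", unit, "' in '", xi, "'")
      val <- val * scale[[unit]]
    }
    val
  }, numeric(1))
  unname(out)
}
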