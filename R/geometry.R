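#' Diameter of a single-walled carbon nanotube from its chirality indices
#'
#' A SWCNT is a graphene sheet rolled along the chiral vector defined by the
#' integer pair (p, q). Its diameter follows the standard relation
#' \deqn{d = 0.0783 \sqrt{p^2 + q^2 + p q}\ \mathrm{nm},}
#' the prefactor being \eqn{a_{cc}\sqrt{3}/\pi} for a C-C bond length of
#' 1.421 Angstrom. For armchair tubes (p = q) this reduces to
#' \eqn{d = 0.0783\, p \sqrt{3}}.
#'
#' @param p,q non-negative integer chirality indices, not both zero.
#'   Vectorized.
#' @return diameter in nm, full precision (round at display time).
#' @examples
#' chiralityDiameter(24, 24)   # 3.25 nm, armchair
#' chiralityDiameter(30, 33)   # 4.27 nm, chiral
#' @export
chiralityDiameter <- function(p, q) {
  .checkChirality(p, q)
  0.0783 * sqrt(p^2 + q^2 + p * q)
}

#' Geometry class of a SWCNT
#'
#' Armchair tubes have p = q, zigzag tubes have one index zero, and every
#' other combination is chiral.
#'
#' @inheritParams chiralityDiameter
#' @return character vector in `c("armchair", "zigzag", "chiral")`
#' @examples
#' classifyChirality(24, 24)  # armchair
#' classifyChirality(20, 0)   # zigzag
#' classifyChirality(23, 25)  # chiral
#' @export
classifyChirality <- function(p, q) {
  .checkChirality(p, q)
  ifelse(p == q, "armchair", ifelse(p == 0 | q == 0, "zigzag", "chiral"))
}

.checkChirality <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(!is.finite(p)) || any(!is.finite(q)) ||
      any(p != round(p)) || any(q != round(q)) || any(p < 0) || any(q < 0))
    stop("chirality indices must be non-negative integers")
  if (any(p == 0 & q == 0))
    stop("invalid chirality: indices (0,0) do not define a nanotube")
  invisible(TRUE)
}

#' Thermal energy kBT in pN nm
#'
#' Converts a temperature to the thermal energy scale used throughout the
#' elasticity estimators: kB = 1.380649e-23 J/K, and 1 J = 1e21 pN nm, so
#' kBT(300 K) = 4.1419 pN nm.
#'
#' @param temperature temperature in kelvin, > 0
#' @return kBT in pN nm
#' @export
thermalEnergy <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive (kelvin)")
  1.380649e-23 * temperature * 1e21
}
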