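# mass of one water molecule in grams
.M_WATER_G <- 2.9915e-23

#' Hydration-shell water count per base pair
#'
#' Counts water oxygens inside a cylindrical shell around the duplex: the
#' duplex axis is the principal axis of the base-pair origins (anchored at
#' their centroid), the duplex radius R_dna is the 95th percentile of the
#' DNA atoms' radial distances from that axis (robust to frayed ends), and a
#' water counts if its radial distance is at most R_dna + `thickness` and
#' its axial coordinate falls within the axial span of the base-pair
#' origins. The count is reported per base pair. Waters in the grooves
#' (r < R_dna) are included.
#'
#' @param dnaAtoms numeric `N x 3` matrix of DNA heavy-atom coordinates
#'   (Angstrom)
#' @param bpOrigins numeric `nBp x 3` matrix of base-pair origins (Angstrom),
#'   >= 2 rows
#' @param waterO numeric `M x 3` matrix of water oxygen coordinates
#'   (Angstrom); may have zero rows
#' @param thickness shell thickness, Angstrom (default 3)
#' @param perBp divisor for per-base-pair reporting (default 14, the central
#'   base pairs of a 16-bp duplex after end trimming)
#' @param radiusQuantile quantile of atom radial distances defining R_dna
#'   (default 0.95)
#' @return waters per base pair (numeric)
#' @export
shellWaterCount <- function(dnaAtoms, bpOrigins, waterO, thickness = 3,
                            perBp = 14, radiusQuantile = 0.95) {
  bpOrigins <- as.matrix(bpOrigins)
  if (nrow(bpOrigins) < 2L)
    stop("axis error: need >= 2 base-pair origins")
  ctr <- colMeans(bpOrigins)
  sv <- svd(sweep(bpOrigins, 2, ctr))
  u <- sv$v[, 1]
  axial <- function(P) as.vector(sweep(as.matrix(P), 2, ctr) %*% u)
  radial <- function(P) {
    d <- sweep(as.matrix(P), 2, ctr)
    sqrt(pmax(rowSums(d^2) - (d %*% u)^2, 0))
  }
  rDNA <- stats::quantile(radial(dnaAtoms), radiusQuantile, names = FALSE)
  span <- range(axial(bpOrigins))
  if (!nrow(as.matrix(waterO))) return(0)
  wr <- radial(waterO); wz <- axial(waterO)
  sum(wr <= rDNA + thickness & wz >= span[1] & wz <= span[2]) / perBp
}

#' Axial water density along a cylindrical pore
#'
#' Bins water oxygens along the tube axis (taken as z) and converts counts
#' to mass density: count x m_water / (pi r_eff^2 dz), in g/cm^3, with
#' m_water = 2.9915e-23 g and r_eff the tube radius minus a carbon
#' van-der-Waals exclusion (default 1.7 Angstrom = 0.17 nm), so that the
#' density refers to the water-accessible volume. Since bulk water is
#' 1 g/cm^3, the values double as relative densities.
#'
#' @param waterO numeric `M x 3` matrix of water oxygen positions (nm),
#'   axis along z
#' @param radius tube radius, nm (> carbonExclusion)
#' @param nBins number of uniform axial bins (>= 2)
#' @param zlim axial range to bin over (nm); defaults to the data range
#' @param carbonExclusion wall exclusion subtracted from the radius, nm
#'   (default 0.17)
#' @return a [DensityProfile-class]
#' @export
axialDensity <- function(waterO, radius, nBins, zlim = NULL,
                         carbonExclusion = 0.17) {
  if (radius <= 0) stop("radius must be positive")
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  rEff <- radius - carbonExclusion
  if (rEff <= 0) stop("radius must exceed the carbon exclusion")
  z <- as.matrix(waterO)[, 3]
  if (is.null(zlim)) zlim <- range(z)
  breaks <- seq(zlim[1], zlim[2], length.out = nBins + 1L)
  counts <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE,
                                  all.inside = FALSE), nbins = nBins + 1L)
  counts <- counts[seq_len(nBins)]
  dz <- diff(breaks)[1]
  area <- pi * rEff^2
  rho <- counts * .M_WATER_G / (area * dz * 1e-21)   # nm^3 -> cm^3
  new("DensityProfile", z = (breaks[-1] + breaks[-(nBins + 1L)]) / 2,
      rho = rho, binWidth = dz, area = area)
}

#' Potential of mean force by Boltzmann inversion of an axial density
#'
#' \deqn{PMF(z) = -k_BT \ln \varrho(z)} in units of kBT, with the density
#' in g/cm^3 (equivalently relative to bulk water at 1 g/cm^3), so a bin at
#' bulk density has PMF 0. Zero-density bins are masked, not set to +Inf.
#'
#' @param profile a [DensityProfile-class]
#' @return a [PMFProfile-class]
#' @export
pmfFromDensity <- function(profile) {
  stopifnot(is(profile, "DensityProfile"))
  masked <- profile@rho <= 0
  if (all(masked)) stop("empty PMF: all density bins are zero")
  pmf <- rep(NA_real_, length(profile@rho))
  pmf[!masked] <- -log(profile@rho[!masked])
  pmf[masked] <- 0   # placeholder; masked bins are never used downstream
  new("PMFProfile", z = profile@z, pmf = pmf, masked = masked)
}

#' Free-energy barrier from a PMF profile
#'
#' The barrier water molecules face at a pore mouth: the maximum PMF inside
#' the stated window minus a reference level, taken as the median PMF of
#' unmasked bins outside the tube (|z| > `tubeHalfLength`). The result is
#' invariant under a uniform rescaling of the density (which only shifts the
#' PMF).
#'
#' @param pmf a [PMFProfile-class]
#' @param window numeric length-2 axial interval (nm) to search for the
#'   barrier maximum
#' @param tubeHalfLength half-length of the tube (nm); bins beyond it define
#'   the bulk reference level
#' @return barrier height in kBT
#' @export
barrierHeight <- function(pmf, window, tubeHalfLength) {
  stopifnot(is(pmf, "PMFProfile"), length(window) == 2L)
  window <- sort(window)
  inWin <- !pmf@masked & pmf@z >= window[1] & pmf@z <= window[2]
  if (sum(inWin) < 2L)
    stop("insufficient data: window overlaps fewer than 2 unmasked bins")
  outside <- !pmf@masked & abs(pmf@z) > tubeHalfLength
  if (!any(outside))
    stop("insufficient data: no unmasked bins outside the tube for the reference level")
  max(pmf@pmf[inWin]) - stats::median(pmf@pmf[outside])
}
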