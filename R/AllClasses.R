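#' @import methods
NULL

#' DuplexTrajectory: per-frame base-pair frames of a DNA duplex
#'
#' Container for an ensemble of duplex conformations described at the
#' base-pair level: per-frame, per-base-pair origins (nm) and unit tangents,
#' plus the per-frame step twists (degrees) between consecutive base pairs.
#' Atomic coordinate sets, when available, ride along in `atoms`.
#'
#' @slot sequence single-character string, one strand of the duplex (5'->3');
#'   one letter per base pair. "N" is allowed where the sequence is synthetic.
#' @slot origins numeric array `nFrames x nBasePairs x 3`, base-pair centre
#'   positions in nm.
#' @slot tangents numeric array `nFrames x nBasePairs x 3`, local unit vectors
#'   along the contour.
#' @slot stepTwists numeric matrix `nFrames x (nBasePairs - 1)`, twist of each
#'   base-pair step in degrees.
#' @slot atoms list of per-frame atomic coordinate data frames (possibly
#'   empty), coordinates in Angstrom.
#' @slot time numeric vector of frame timestamps in ns, or length zero.
#'
#' @exportClass DuplexTrajectory
setClass("DuplexTrajectory",
  representation(
    sequence   = "character",
    origins    = "array",
    tangents   = "array",
    stepTwists = "matrix",
    atoms      = "list",
    time       = "numeric"
  )
)

setValidity("DuplexTrajectory", function(object) {
  msg <- character()
  d <- dim(object@origins)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "origins must be an nFrames x nBasePairs x 3 array")
  if (!identical(dim(object@tangents), d))
    msg <- c(msg, "tangents must have the same dimensions as origins")
  if (length(d) == 3L) {
    if (nchar(object@sequence) != d[2])
      msg <- c(msg, "sequence length must equal the base-pair count")
    if (!identical(dim(object@stepTwists), c(d[1], d[2] - 1L)))
      msg <- c(msg, "stepTwists must be nFrames x (nBasePairs - 1)")
    nrm <- sqrt(apply(object@tangents^2, c(1, 2), sum))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "tangents must be unit vectors (|t| = 1 within 1e-6)")
    if (length(object@time) && length(object@time) != d[1])
      msg <- c(msg, "time must be empty or have one entry per frame")
  }
  if (!all(is.finite(object@origins)))
    msg <- c(msg, "origins must be finite")
  if (length(msg)) msg else TRUE
})

#' WCDuplex: idealized Watson-Crick duplex coordinates
#'
#' A reduced atomic model of a B-form duplex carrying, for every base pair,
#' the canonical Watson-Crick donor/hydrogen/acceptor triplets (three for G-C,
#' two for A-T) and one backbone phosphorus marker per residue. Coordinates
#' are in Angstrom.
#'
#' @slot sequence one strand of the duplex, 5'->3'.
#' @slot atoms data frame with columns `name`, `resid`, `chain`, `x`, `y`, `z`.
#' @slot donors,hydrogens integer index vectors of equal length; `hydrogens[k]`
#'   is the hydrogen covalently bound to `donors[k]`.
#' @slot acceptors integer indices of acceptor atoms.
#' @slot bp integer vector mapping every atom to its base-pair index.
#'
#' @exportClass WCDuplex
setClass("WCDuplex",
  representation(
    sequence  = "character",
    atoms     = "data.frame",
    donors    = "integer",
    hydrogens = "integer",
    acceptors = "integer",
    bp        = "integer"
  )
)

setValidity("WCDuplex", function(object) {
  msg <- character()
  n <- nrow(object@atoms)
  if (length(object@donors) != length(object@hydrogens))
    msg <- c(msg, "donors and hydrogens must be parallel vectors")
  idx <- c(object@donors, object@hydrogens, object@acceptors)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    msg <- c(msg, "donor/hydrogen/acceptor indices out of range")
  if (length(object@bp) != n)
    msg <- c(msg, "bp must map every atom to a base pair")
  if (length(msg)) msg else TRUE
})

#' DensityProfile: binned axial water density
#'
#' Axial density of water along a cylindrical pore, in g/cm^3 (equivalently
#' relative density, taking bulk water as 1 g/cm^3).
#'
#' @slot z numeric bin centres along the tube axis, nm.
#' @slot rho numeric densities, g/cm^3, one per bin.
#' @slot binWidth bin width in nm.
#' @slot area effective cross-section area in nm^2 used for the conversion.
#'
#' @exportClass DensityProfile
setClass("DensityProfile",
  representation(z = "numeric", rho = "numeric",
                 binWidth = "numeric", area = "numeric")
)

setValidity("DensityProfile", function(object) {
  msg <- character()
  if (length(object@z) != length(object@rho))
    msg <- c(msg, "z and rho must have equal length")
  if (any(object@rho < 0)) msg <- c(msg, "densities must be non-negative")
  if (length(object@z) > 1) {
    dz <- diff(object@z)
    if (any(abs(dz - dz[1]) > 1e-9 * abs(dz[1])))
      msg <- c(msg, "bins must be uniform")
  }
  if (length(msg)) msg else TRUE
})

#' PMFProfile: potential of mean force along the tube axis
#'
#' Boltzmann inversion of a [DensityProfile-class]; values in units of kBT.
#' Bins whose density was zero are masked rather than set to +Inf.
#'
#' @slot z numeric bin centres, nm.
#' @slot pmf numeric PMF values in kBT; finite on unmasked bins.
#' @slot masked logical, TRUE where the density was zero.
#'
#' @exportClass PMFProfile
setClass("PMFProfile",
  representation(z = "numeric", pmf = "numeric", masked = "logical")
)

setValidity("PMFProfile", function(object) {
  msg <- character()
  if (length(object@z) != length(object@pmf) ||
      length(object@z) != length(object@masked))
    msg <- c(msg, "z, pmf and masked must have equal length")
  if (any(!is.finite(object@pmf[!object@masked])))
    msg <- c(msg, "pmf must be finite on unmasked bins")
  if (length(msg)) msg else TRUE
})

#' ElasticFit: worm-like-chain elastic constants with diagnostics
#'
#' Result of the elasticity estimators: persistence length (nm), stretch
#' modulus (pN) and torsional stiffness (pN nm^2), each with a moment-based
#' companion, the derived torsional persistence length (nm), bootstrap
#' standard errors when requested, and fit diagnostics.
#'
#' @slot estimates named numeric: `lp`, `lpMoment`, `gamma`, `gammaMoment`,
#'   `C`, `torsionalPersistence`, `L0`, `kBT`.
#' @slot se named numeric of bootstrap standard errors (possibly empty).
#' @slot diagnostics list of per-fit diagnostics (slope, intercept, R^2,
#'   bins used).
#'
#' @exportClass ElasticFit
setClass("ElasticFit",
  representation(estimates = "numeric", se = "numeric", diagnostics = "list")
)

setValidity("ElasticFit", function(object) {
  est <- object@estimates
  need <- c("lp", "gamma", "C", "torsionalPersistence", "L0", "kBT")
  if (!all(need %in% names(est)))
    return(paste("estimates must contain", paste(need, collapse = ", ")))
  if (is.finite(est["C"]) &&
      abs(est["torsionalPersistence"] - est["C"] / est["kBT"]) >
        1e-9 * max(1, abs(est["torsionalPersistence"])))
    return("torsionalPersistence must equal C/kBT")
  TRUE
})
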