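#' Per-frame bending angles of a duplex trajectory
#'
#' The global bending angle of an n-bp duplex is the angle between the
#' tangents at its first and last base pairs,
#' \eqn{\theta = \cos^{-1}(\vec t_1 \cdot \vec t_n)}, with the dot product
#' clamped to [-1, 1] against round-off.
#'
#' @param traj a [DuplexTrajectory-class] (trim beforehand with
#'   [trimEnds()] if desired)
#' @return numeric vector of angles in radians, one per frame
#' @export
bendAngles <- function(traj) {
  stopifnot(is(traj, "DuplexTrajectory"))
  nbp <- nBasePairs(traj)
  if (nbp < 2L) stop("need >= 2 base pairs")
  t1 <- matrix(traj@tangents[, 1L, ], nFrames(traj), 3L)
  tn <- matrix(traj@tangents[, nbp, ], nFrames(traj), 3L)
  n1 <- rowSums(t1^2); n2 <- rowSums(tn^2)
  if (any(n1 < 1e-12) || any(n2 < 1e-12))
    stop("geometry error: degenerate (zero) tangent vector")
  acos(pmin(pmax(rowSums(t1 * tn) / sqrt(n1 * n2), -1), 1))
}

#' Per-frame contour lengths and their time average
#'
#' The contour length of a frame is the sum of distances between
#' consecutive base-pair origins; `L0` is its time average over frames.
#'
#' @param traj a [DuplexTrajectory-class]
#' @return list with `L` (numeric vector, nm) and `L0` (its mean, nm)
#' @export
contourLengths <- function(traj) {
  stopifnot(is(traj, "DuplexTrajectory"))
  d <- traj@origins
  nbp <- dim(d)[2]
  if (nbp < 2L) stop("need >= 2 base pairs")
  seg <- sqrt(apply((d[, -1L, , drop = FALSE] -
                       d[, -nbp, , drop = FALSE])^2, c(1, 2), sum))
  L <- rowSums(matrix(seg, dim(d)[1]))
  list(L = L, L0 = mean(L))
}

#' Per-frame cumulative twist
#'
#' The global twist coordinate phi of a frame is the plain sum of its step
#' twists, accumulated without wrapping (for a 16-bp duplex phi is around
#' 515 degrees, so variance on wrapped angles would be meaningless).
#'
#' @param traj a [DuplexTrajectory-class]
#' @return numeric vector, degrees, one per frame
#' @export
cumulativeTwist <- function(traj) {
  stopifnot(is(traj, "DuplexTrajectory"))
  rowSums(traj@stepTwists)
}

.histFit <- function(y, x, w) {
  fit <- stats::lm(y ~ x, weights = w)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r.squared = s$r.squared)
}

#' Persistence length from the bending-angle distribution
#'
#' Histograms the bending angles, then fits ln P(theta) against
#' (1 - cos theta) by weighted least squares (weights = bin counts, bins
#' with fewer than `minCount` entries dropped); the persistence length is
#' \eqn{l_p = -slope \times L_0}.
#'
#' Bend angles extracted from 3D trajectories are magnitudes of an
#' isotropic two-component deflection, so their distribution carries a
#' sin(theta) geometric factor; with `jacobian = TRUE` (default) the
#' histogram density is divided by sin(theta) before the fit, which makes
#' the estimator consistent -- without it the slope recovers exactly half
#' the true persistence length in the small-angle regime. Set
#' `jacobian = FALSE` only for series that are genuinely signed
#' one-dimensional Gaussian deflections.
#'
#' A moment-based companion estimator is reported alongside:
#' \eqn{2 L_0/\langle\theta^2\rangle} for magnitudes (jacobian = TRUE),
#' \eqn{L_0/Var(\theta)} for signed series (jacobian = FALSE).
#'
#' @param theta bending angles, radians; >= 1000 samples recommended
#'   (a warning is issued below that)
#' @param L0 time-averaged contour length, nm
#' @param nBins histogram bins (default 40)
#' @param minCount minimum bin count for a bin to enter the fit (default 5)
#' @param jacobian divide the density by sin(theta) (default TRUE)
#' @return list with `lp`, `lpMoment` (nm) and `diagnostics` (slope,
#'   intercept, r.squared, nBinsUsed)
#' @export
fitPersistenceLength <- function(theta, L0, nBins = 40L, minCount = 5L,
                                 jacobian = TRUE) {
  theta <- theta[is.finite(theta)]
  if (length(theta) < 1000L)
    warning("fewer than 1000 bending-angle samples; estimate will be noisy")
  if (diff(range(theta)) == 0)
    stop("fit error: degenerate (constant) bending-angle series")
  h <- summarizeDistribution(theta, nBins)
  keep <- h$counts >= minCount & h$density > 0
  if (jacobian) keep <- keep & sin(h$mids) > 0
  if (sum(keep) < 3L)
    stop("fit error: fewer than 3 usable histogram bins")
  y <- log(h$density[keep])
  if (jacobian) y <- y - log(sin(h$mids[keep]))
  fit <- .histFit(y, 1 - cos(h$mids[keep]), h$counts[keep])
  lp <- -fit$slope * L0
  lpMoment <- if (jacobian) 2 * L0 / mean(theta^2) else L0 / stats::var(theta)
  list(lp = lp, lpMoment = lpMoment,
       diagnostics = c(fit, nBinsUsed = sum(keep)))
}

#' Stretch modulus from the contour-length distribution
#'
#' Histograms the contour lengths and fits ln P(L) against (L/L0 - 1)^2 by
#' weighted least squares; the stretch modulus is
#' \eqn{\gamma = -2\, slope\, k_BT / L_0}. The moment companion is
#' \eqn{\gamma = k_BT L_0 / Var(L)}. A zero-variance series signals
#' infinite stiffness (both estimates `Inf`) rather than failing.
#'
#' @param L contour lengths, nm
#' @param kBT thermal energy, pN nm (see [thermalEnergy()])
#' @param nBins,minCount as in [fitPersistenceLength()]
#' @return list with `gamma`, `gammaMoment` (pN), `L0` (nm) and
#'   `diagnostics`
#' @export
fitStretchModulus <- function(L, kBT, nBins = 40L, minCount = 5L) {
  L <- L[is.finite(L)]
  if (length(L) < 1000L)
    warning("fewer than 1000 contour-length samples; estimate will be noisy")
  L0 <- mean(L)
  if (stats::var(L) == 0)
    return(list(gamma = Inf, gammaMoment = Inf, L0 = L0,
                diagnostics = list(slope = -Inf, note = "zero variance")))
  h <- summarizeDistribution(L, nBins)
  keep <- h$counts >= minCount & h$density > 0
  if (sum(keep) < 3L)
    stop("fit error: fewer than 3 usable histogram bins")
  fit <- .histFit(log(h$density[keep]), (h$mids[keep] / L0 - 1)^2,
                  h$counts[keep])
  list(gamma = -2 * fit$slope * kBT / L0,
       gammaMoment = kBT * L0 / stats::var(L),
       L0 = L0, diagnostics = c(fit, nBinsUsed = sum(keep)))
}

#' Torsional stiffness from the twist variance
#'
#' \deqn{C = k_BT\, L_0 / \sigma^2_\phi} with the cumulative twist phi in
#' radians; the torsional persistence length is \eqn{L_0/\sigma^2_\phi =
#' C/k_BT}. Zero variance signals infinite stiffness.
#'
#' @param phi cumulative twist per frame, degrees; >= 2 samples
#' @param L0 time-averaged contour length, nm
#' @param kBT thermal energy, pN nm
#' @return list with `C` (pN nm^2), `torsionalPersistence` (nm) and
#'   `varPhi` (rad^2)
#' @export
torsionalStiffness <- function(phi, L0, kBT) {
  phi <- phi[is.finite(phi)]
  if (length(phi) < 2L) stop("need >= 2 twist samples")
  v <- stats::var(phi * pi / 180)
  if (v == 0)
    return(list(C = Inf, torsionalPersistence = Inf, varPhi = 0))
  list(C = kBT * L0 / v, torsionalPersistence = L0 / v, varPhi = v)
}

#' Bootstrap standard error of an estimator
#'
#' Standard deviation of `statistic` over series resampled with
#' replacement; seeded and reproducible. Fails (rather than reporting a
#' misleading number) if the estimator errors on more than 20% of
#' resamples.
#'
#' @param x numeric series
#' @param statistic function of a numeric vector returning one number
#' @param nBoot number of resamples, >= 100
#' @param seed integer seed
#' @return standard error (numeric)
#' @export
bootstrapSE <- function(x, statistic, nBoot = 200L, seed = NULL) {
  nBoot <- as.integer(nBoot)
  if (nBoot < 100L) stop("nBoot must be >= 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  vals <- vapply(seq_len(nBoot), function(b) {
    xb <- x[sample.int(length(x), replace = TRUE)]
    tryCatch(as.numeric(statistic(xb)), error = function(e) NA_real_)
  }, numeric(1))
  fail <- mean(!is.finite(vals))
  if (fail > 0.2)
    stop("unstable estimate: estimator failed on ",
         round(100 * fail), "% of resamples")
  stats::sd(vals[is.finite(vals)])
}

#' Full worm-like-chain elasticity estimate for a duplex trajectory
#'
#' End-to-end pipeline: trims the duplex ends, extracts the bending-angle,
#' contour-length and cumulative-twist series, and inverts each for the
#' elastic constants -- persistence length (histogram-slope fit with a
#' moment companion), stretch modulus (likewise) and torsional stiffness
#' (twist variance). Optional bootstrap standard errors. A discrepancy
#' above 20% between a slope estimate and its moment companion triggers a
#' diagnostics warning (non-Gaussian sampling).
#'
#' @param traj a [DuplexTrajectory-class]
#' @param temperature kelvin (default 300)
#' @param trim base pairs removed from each end before analysis (default 1)
#' @param nBins histogram bins for the slope fits (default 40)
#' @param nBoot bootstrap resamples (0 disables; otherwise >= 100)
#' @param seed seed for the bootstrap
#' @param jacobian see [fitPersistenceLength()]
#' @return an [ElasticFit-class]
#' @examples
#' traj <- sampleChainFrames(5000, seed = 7)
#' estimateElasticity(traj)
#' @export
estimateElasticity <- function(traj, temperature = 300, trim = 1L,
                               nBins = 40L, nBoot = 0L, seed = NULL,
                               jacobian = TRUE) {
  stopifnot(is(traj, "DuplexTrajectory"))
  kBT <- thermalEnergy(temperature)
  tt <- trimEnds(traj, trim)
  theta <- bendAngles(tt)
  cl <- contourLengths(tt)
  phi <- cumulativeTwist(tt)

  pfit <- fitPersistenceLength(theta, cl$L0, nBins = nBins,
                               jacobian = jacobian)
  gfit <- fitStretchModulus(cl$L, kBT, nBins = nBins)
  tfit <- torsionalStiffness(phi, cl$L0, kBT)

  relDiff <- function(a, b) abs(a - b) / max(abs(a), abs(b))
  if (is.finite(pfit$lp) && relDiff(pfit$lp, pfit$lpMoment) > 0.2)
    warning("slope and moment persistence-length estimates differ by >20%;",
            " sampling may be non-Gaussian")
  if (is.finite(gfit$gamma) && relDiff(gfit$gamma, gfit$gammaMoment) > 0.2)
    warning("slope and moment stretch-modulus estimates differ by >20%;",
            " sampling may be non-Gaussian")

  se <- numeric()
  if (nBoot > 0L) {
    se <- c(
      lp = bootstrapSE(theta, function(s)
        fitPersistenceLength(s, cl$L0, nBins = nBins,
                             jacobian = jacobian)$lp,
        nBoot = nBoot, seed = seed),
      gamma = bootstrapSE(cl$L, function(s)
        fitStretchModulus(s, kBT, nBins = nBins)$gamma,
        nBoot = nBoot, seed = seed),
      C = bootstrapSE(phi, function(s)
        torsionalStiffness(s, cl$L0, kBT)$C,
        nBoot = nBoot, seed = seed))
  }
  new("ElasticFit",
      estimates = c(lp = pfit$lp, lpMoment = pfit$lpMoment,
                    gamma = gfit$gamma, gammaMoment = gfit$gammaMoment,
                    C = tfit$C,
                    torsionalPersistence = tfit$torsionalPersistence,
                    L0 = cl$L0, kBT = kBT),
      se = se,
      diagnostics = list(persistence = pfit$diagnostics,
                         stretch = gfit$diagnostics,
                         twistVariance = tfit$varPhi,
                         nFrames = nFrames(tt)))
}
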