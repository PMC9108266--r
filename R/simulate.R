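#' Sample discrete worm-like-chain duplex trajectories
#'
#' Generates an ensemble of duplex conformations from the discrete worm-like
#' chain in the weakly bending regime (contour length much shorter than the
#' persistence length, as for a 16-bp duplex). Per frame and per base-pair
#' step i, independently:
#' \itemize{
#'   \item step length \eqn{l_i \sim N(rise_0,\ rise_0 k_BT/\gamma)} (nm),
#'   \item two transverse bending tilts \eqn{\sim N(0,\ rise_0/l_p)} each,
#'     applied as successive rotations of the local tangent with parallel
#'     transport of the transverse frame,
#'   \item step twist \eqn{\sim N(twist_0,\ k_BT\, rise_0/C)} (variance in
#'     rad^2, stored in degrees).
#' }
#' Origins are cumulative sums along the tangents. Over the ensemble this
#' realizes the Gaussian statistics the estimators invert:
#' \eqn{\langle\theta^2\rangle = 2 L_0/l_p} (two transverse modes),
#' \eqn{Var(L) = L_0 k_BT/\gamma}, and \eqn{Var(\phi) = k_BT L_0 / C}.
#'
#' Passing `Inf` for an elastic constant freezes the corresponding degree of
#' freedom, giving straight chains of exact length and twist.
#'
#' @param nFrames number of frames to generate (>= 1)
#' @param nBasePairs base pairs per frame (>= 4); default 16, the duplex
#'   length used throughout this package's reference analyses
#' @param rise0 mean helical rise per step, nm (default 0.34)
#' @param twist0 mean helical twist per step, degrees (default 34.3, a
#'   conventional B-DNA helical repeat of ~10.5 bp/turn)
#' @param persistenceLength bending persistence length l_p, nm
#' @param stretchModulus stretch modulus gamma, pN
#' @param torsionalStiffness torsional stiffness C, pN nm^2
#' @param temperature kelvin (default 300)
#' @param sequence optional strand sequence (nchar == nBasePairs); "N" filler
#'   is used when absent
#' @param seed integer seed for reproducibility; identical seed and
#'   parameters give bit-identical trajectories
#' @return a [DuplexTrajectory-class]
#' @examples
#' traj <- sampleChainFrames(100, seed = 1)
#' traj
#' @export
sampleChainFrames <- function(nFrames, nBasePairs = 16L, rise0 = 0.34,
                              twist0 = 34.3,
                              persistenceLength = 51.21,
                              stretchModulus = 1181.09,
                              torsionalStiffness = 473.84,
                              temperature = 300, sequence = NULL,
                              seed = NULL) {
  if (nFrames < 1) stop("nFrames must be >= 1")
  nBasePairs <- as.integer(nBasePairs)
  if (nBasePairs < 4L) stop("nBasePairs must be >= 4")
  if (rise0 <= 0 || persistenceLength <= 0 || stretchModulus <= 0 ||
      torsionalStiffness <= 0)
    stop("rise0 and all elastic constants must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  kBT <- thermalEnergy(temperature)

  nS <- nBasePairs - 1L
  sdL  <- if (is.finite(stretchModulus)) sqrt(rise0 * kBT / stretchModulus) else 0
  sdB  <- if (is.finite(persistenceLength)) sqrt(rise0 / persistenceLength) else 0
  sdTw <- if (is.finite(torsionalStiffness))
    sqrt(kBT * rise0 / torsionalStiffness) * 180 / pi else 0

  len <- matrix(stats::rnorm(nFrames * nS, rise0, sdL), nFrames, nS)
  tw  <- matrix(stats::rnorm(nFrames * nS, twist0, sdTw), nFrames, nS)
  # bending increments act between consecutive steps: none before step 1
  ba  <- matrix(stats::rnorm(nFrames * nS, 0, sdB), nFrames, nS)
  bb  <- matrix(stats::rnorm(nFrames * nS, 0, sdB), nFrames, nS)

  O <- array(0, c(nFrames, nBasePairs, 3L))
  Tn <- array(0, c(nFrames, nBasePairs, 3L))
  t  <- matrix(rep(c(0, 0, 1), each = nFrames), nFrames, 3L)
  e1 <- matrix(rep(c(1, 0, 0), each = nFrames), nFrames, 3L)
  e2 <- matrix(rep(c(0, 1, 0), each = nFrames), nFrames, 3L)

  for (i in seq_len(nS)) {
    if (i > 1L && sdB > 0) {
      a <- ba[, i]; b <- bb[, i]
      ang <- sqrt(a^2 + b^2)
      snc <- ifelse(ang > 1e-12, sin(ang) / ang, 1)
      tNew <- cos(ang) * t + snc * (b * e1 - a * e2)
      tNew <- tNew / sqrt(rowSums(tNew^2))
      # parallel-transport the transverse frame onto the new tangent
      e1 <- e1 - rowSums(e1 * tNew) * tNew
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(tNew[, 2] * e1[, 3] - tNew[, 3] * e1[, 2],
                  tNew[, 3] * e1[, 1] - tNew[, 1] * e1[, 3],
                  tNew[, 1] * e1[, 2] - tNew[, 2] * e1[, 1])
      t <- tNew
    }
    Tn[, i, ] <- t
    O[, i + 1L, ] <- O[, i, ] + len[, i] * t
  }
  Tn[, nBasePairs, ] <- t   # last base pair inherits the last step direction

  if (is.null(sequence)) sequence <- strrep("N", nBasePairs)
  if (nchar(sequence) != nBasePairs)
    stop("sequence length must equal nBasePairs")
  new("DuplexTrajectory", sequence = sequence, origins = O, tangents = Tn,
      stepTwists = tw, atoms = list(), time = numeric())
}

# canonical Watson-Crick hydrogen-bond multiplicity per base
.WC_NBONDS <- c(A = 2L, T = 2L, G = 3L, C = 3L)

.checkDNASequence <- function(sequence, minLen = 2L) {
  if (length(sequence) != 1L || !is.character(sequence) ||
      is.na(sequence) || nchar(sequence) < minLen)
    stop("sequence must be a single DNA string of length >= ", minLen)
  b <- strsplit(toupper(sequence), "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("sequence contains characters outside {A,C,G,T}")
  b
}

#' Build an idealized Watson-Crick B-form duplex
#'
#' Constructs a reduced atomic model of a B-form duplex: base pairs stacked
#' with a rise of 3.4 Angstrom and a twist of 36 degrees per step. Each base
#' pair carries its canonical Watson-Crick donor-hydrogen-acceptor triplets
#' (three for G-C, two for A-T) at ideal geometry -- heavy-atom D...A
#' distance 2.9 Angstrom with D-H...A collinear -- plus one backbone
#' phosphorus marker per residue for RMSD and contact analyses. The model
#' deliberately carries only the hydrogen-bonding atoms and the P markers;
#' it is a geometry target for the detectors, not a full nucleotide model.
#'
#' @param sequence one strand of the duplex, 5'->3', over \{A,C,G,T\},
#'   length >= 2
#' @return a [WCDuplex-class]
#' @examples
#' d <- buildIdealDuplex("GTCGCGAATTCGCGAC")
#' nrow(detectHBonds(d))          # 3 per G-C + 2 per A-T
#' @export
buildIdealDuplex <- function(sequence) {
  bases <- .checkDNASequence(sequence, minLen = 2L)
  nbp <- length(bases)
  rise <- 3.4; twist <- 36 * pi / 180
  dDA <- 2.9; dDH <- 1.0
  yD <- dDA / 2; yH <- yD - dDH; yA <- -dDA / 2
  pRad <- 8.9   # backbone P marker radius, Angstrom

  rows <- vector("list", nbp)
  for (i in seq_len(nbp)) {
    al <- (i - 1L) * twist
    z <- (i - 1L) * rise
    ca <- cos(al); sa <- sin(al)
    rot <- function(x, y) c(x * ca - y * sa, x * sa + y * ca)
    nb <- .WC_NBONDS[[bases[i]]]
    xs <- if (nb == 3L) c(-4.5, 0, 4.5) else c(-4.5, 4.5)
    # alternate bond polarity as in real WC pairs (donor strand varies)
    flip <- if (nb == 3L) c(1, -1, 1) else c(1, -1)
    loc <- list()
    for (k in seq_len(nb)) {
      f <- flip[k]
      loc[[length(loc) + 1L]] <- data.frame(
        name = paste0(c("D", "H", "A"), k),
        role = c("D", "H", "A"),
        lx = rep(xs[k], 3), ly = f * c(yD, yH, yA))
    }
    loc <- do.call(rbind, loc)
    xy <- t(vapply(seq_len(nrow(loc)),
                   function(j) rot(loc$lx[j], loc$ly[j]), numeric(2)))
    bpAtoms <- data.frame(name = loc$name, role = loc$role,
                          resid = i, chain = "A",
                          x = xy[, 1], y = xy[, 2], z = z)
    p1 <- rot(pRad * cos(2 * pi / 3), pRad * sin(2 * pi / 3))
    p2 <- rot(pRad * cos(-2 * pi / 3), pRad * sin(-2 * pi / 3))
    bpAtoms <- rbind(bpAtoms,
      data.frame(name = "P", role = "P", resid = i, chain = "A",
                 x = p1[1], y = p1[2], z = z),
      data.frame(name = "P", role = "P", resid = 2L * nbp + 1L - i,
                 chain = "B", x = p2[1], y = p2[2], z = z))
    bpAtoms$bp <- i
    rows[[i]] <- bpAtoms
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  new("WCDuplex",
      sequence  = paste(bases, collapse = ""),
      atoms     = atoms[, c("name", "resid", "chain", "x", "y", "z")],
      donors    = which(atoms$role == "D"),
      hydrogens = which(atoms$role == "H"),
      acceptors = which(atoms$role == "A"),
      bp        = as.integer(atoms$bp))
}

#' Reverse complement of a DNA string
#' @param sequence DNA string over \{A,C,G,T\}
#' @return the reverse complement
#' @export
reverseComplement <- function(sequence) {
  b <- .checkDNASequence(sequence, minLen = 1L)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  paste(rev(comp[b]), collapse = "")
}

#' Sample water oxygens in a cylinder with an imposed axial density profile
#'
#' Places water oxygen positions uniformly over the cylinder cross-section
#' and along the axis by thinning: a candidate at axial coordinate z is
#' accepted with probability proportional to the relative density at z
#' (linear interpolation of the supplied profile, flat extrapolation beyond
#' its range). Expected per-bin counts are therefore proportional to
#' profile x bin volume, which is what the axial-density / PMF analysis
#' inverts.
#'
#' @param n number of accepted positions to return (>= 0)
#' @param radius cylinder radius, nm (> 0)
#' @param halfLength half-length of the sampled axial range, nm (> 0);
#'   z is drawn uniformly on (-halfLength, halfLength) before thinning
#' @param profile data frame with columns `z` (nm) and `density` (relative,
#'   >= 0); the default is a flat profile of 1
#' @param seed integer seed
#' @return numeric matrix `n x 3` of positions (nm), columns x, y, z
#' @export
sampleCylinderWater <- function(n, radius, halfLength,
                                profile = NULL, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (radius <= 0 || halfLength <= 0)
    stop("radius and halfLength must be positive")
  if (is.null(profile))
    profile <- data.frame(z = c(-halfLength, halfLength), density = c(1, 1))
  if (!all(c("z", "density") %in% names(profile)))
    stop("profile needs columns 'z' and 'density'")
  if (any(profile$density < 0)) stop("relative density must be >= 0")
  dmax <- max(profile$density)
  if (n > 0 && dmax <= 0)
    stop("cannot generate water from an all-zero density profile")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 0) return(matrix(numeric(), 0L, 3L,
                            dimnames = list(NULL, c("x", "y", "z"))))
  out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  got <- 0L
  while (got < n) {
    m <- max(1000L, ceiling((n - got) * 1.5))
    z <- stats::runif(m, -halfLength, halfLength)
    rel <- stats::approx(profile$z, profile$density, xout = z, rule = 2)$y
    keep <- stats::runif(m) < rel / dmax
    z <- z[keep]
    if (!length(z)) next
    take <- min(length(z), n - got)
    z <- z[seq_len(take)]
    r <- radius * sqrt(stats::runif(take))
    ph <- stats::runif(take, 0, 2 * pi)
    out[got + seq_len(take), ] <- cbind(r * cos(ph), r * sin(ph), z)
    got <- got + take
  }
  out
}
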