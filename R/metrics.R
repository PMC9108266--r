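#' Geometric hydrogen-bond criteria
#'
#' The IUPAC-style geometric definition used throughout: a donor-acceptor
#' heavy-atom distance cutoff of 3.5 Angstrom combined with a
#' donor-hydrogen...acceptor angle cutoff of 120 degrees (angles at or above
#' the cutoff pass; a collinear D-H...A arrangement is 180 degrees).
#'
#' @param daCutoff donor-acceptor heavy-atom distance cutoff, Angstrom
#' @param angleMin minimum D-H...A angle, degrees, in (0, 180]
#' @return an object of class `hbondCriteria`
#' @export
hbondCriteria <- function(daCutoff = 3.5, angleMin = 120) {
  if (daCutoff <= 0) stop("daCutoff must be positive")
  if (angleMin <= 0 || angleMin > 180) stop("angleMin must be in (0, 180]")
  structure(list(daCutoff = daCutoff, angleMin = angleMin),
            class = "hbondCriteria")
}

#' Detect hydrogen bonds by geometric criteria
#'
#' Reports every (donor, hydrogen, acceptor) triple with
#' dist(D, A) <= `daCutoff` and angle(D-H...A) >= `angleMin`. Donors and
#' hydrogens are parallel vectors (each hydrogen mapped to its covalent
#' donor); the acceptor list is scanned exhaustively against every D-H pair.
#'
#' @param x either a numeric `N x 3` coordinate matrix (Angstrom) or a
#'   [WCDuplex-class] (whose built-in donor/acceptor topology is used)
#' @param donors,hydrogens,acceptors integer atom indices (matrix method);
#'   `donors` and `hydrogens` must have equal length
#' @param criteria an [hbondCriteria()] object
#' @param trim for the `WCDuplex` method: base pairs dropped from each end
#'   before detection (default 0)
#' @param ... passed through
#' @return data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance` (Angstrom), `angle` (degrees); zero rows when nothing is found
#' @export
setGeneric("detectHBonds", function(x, ...) standardGeneric("detectHBonds"))

#' @rdname detectHBonds
setMethod("detectHBonds", "matrix",
  function(x, donors, hydrogens, acceptors, criteria = hbondCriteria()) {
    if (length(donors) != length(hydrogens))
      stop("topology error: every hydrogen must be mapped to its donor")
    if (!length(donors) || !length(acceptors))
      return(data.frame(donor = integer(), hydrogen = integer(),
                        acceptor = integer(), distance = numeric(),
                        angle = numeric()))
    D <- x[donors, , drop = FALSE]
    H <- x[hydrogens, , drop = FALSE]
    A <- x[acceptors, , drop = FALSE]
    hits <- vector("list", length(donors))
    for (k in seq_along(donors)) {
      dv <- sweep(A, 2, D[k, ])
      dist <- sqrt(rowSums(dv^2))
      ok <- dist <= criteria$daCutoff & acceptors != donors[k] &
        acceptors != hydrogens[k]
      if (!any(ok)) next
      hd <- D[k, ] - H[k, ]
      ha <- sweep(A[ok, , drop = FALSE], 2, H[k, ])
      cosang <- (ha %*% hd) /
        (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      pass <- ang >= criteria$angleMin
      if (!any(pass)) next
      hits[[k]] <- data.frame(donor = donors[k], hydrogen = hydrogens[k],
                              acceptor = acceptors[ok][pass],
                              distance = dist[ok][pass], angle = ang[pass])
    }
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (!length(hits))
      return(data.frame(donor = integer(), hydrogen = integer(),
                        acceptor = integer(), distance = numeric(),
                        angle = numeric()))
    out <- do.call(rbind, hits)
    rownames(out) <- NULL
    out
  })

#' @rdname detectHBonds
setMethod("detectHBonds", "WCDuplex",
  function(x, criteria = hbondCriteria(), trim = 0L) {
    if (trim > 0L) x <- trimEnds(x, trim)
    co <- as.matrix(x@atoms[, c("x", "y", "z")])
    detectHBonds(co, donors = x@donors, hydrogens = x@hydrogens,
                 acceptors = x@acceptors, criteria = criteria)
  })

#' Canonical Watson-Crick hydrogen-bond count
#'
#' Book-keeping count over the central base pairs of a duplex: each G-C pair
#' contributes three hydrogen bonds and each A-T pair two. For the 16-bp
#' duplex d[GTCGCGAATTCGCGAC] with one base pair trimmed from each end this
#' gives 36 bonds over 14 bp (~2.6 per bp).
#'
#' @param sequence one strand of the duplex over \{A,C,G,T\}
#' @param trim base pairs excluded from each end (default 1)
#' @return integer bond count
#' @examples
#' canonicalHbondCount("GTCGCGAATTCGCGAC")        # 36
#' @export
canonicalHbondCount <- function(sequence, trim = 1L) {
  b <- .checkDNASequence(sequence, minLen = 1L)
  trim <- as.integer(trim)
  if (trim < 0L || 2L * trim >= length(b))
    stop("trim must satisfy 0 <= trim < length(sequence)/2")
  core <- b[(trim + 1L):(length(b) - trim)]
  sum(.WC_NBONDS[core])
}

#' Root mean square deviation between two coordinate sets
#'
#' \deqn{RMSD = \sqrt{\frac{1}{N}\sum_i \|x_i - x_i^{ref}\|^2}.}
#' By default no superposition is applied, matching the bare formula; with
#' `superpose = TRUE` an optimal rigid-body least-squares fit
#' ([bio3d::fit.xyz()], Kabsch) is performed first.
#'
#' @param frame,reference numeric `N x 3` matrices (Angstrom), same N >= 1
#' @param superpose apply a rigid-body fit before measuring (default FALSE)
#' @return RMSD in Angstrom
#' @export
calcRMSD <- function(frame, reference, superpose = FALSE) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  if (!identical(dim(frame), dim(reference)) || nrow(frame) < 1L)
    stop("alignment error: selections must match and contain >= 1 atom")
  if (superpose) {
    idx <- seq_len(3L * nrow(frame))
    moved <- bio3d::fit.xyz(fixed = as.vector(t(reference)),
                            mobile = as.vector(t(frame)),
                            fixed.inds = idx, mobile.inds = idx)
    frame <- matrix(moved, ncol = 3L, byrow = TRUE)
  }
  sqrt(mean(rowSums((frame - reference)^2)))
}

#' Per-atom root mean square fluctuation
#'
#' \deqn{RMSF_i = \sqrt{\frac{1}{T}\sum_t \|x_i(t) - \bar{x}_i\|^2}}
#' about the time-averaged position of each atom.
#'
#' @param coords list of `N x 3` coordinate matrices (one per frame,
#'   Angstrom) or a numeric array `nFrames x N x 3`; >= 2 frames
#' @return numeric vector of length N, Angstrom
#' @export
calcRMSF <- function(coords) {
  if (is.list(coords)) {
    arr <- array(0, c(length(coords), nrow(coords[[1]]), 3L))
    for (f in seq_along(coords)) arr[f, , ] <- as.matrix(coords[[f]])
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[1] < 2L)
    stop("insufficient data: RMSF needs at least 2 frames")
  mu <- apply(coords, c(2, 3), mean)
  dev <- sweep(coords, c(2, 3), mu)
  sqrt(apply(dev^2, 2, mean) * 3)  # mean over frames of |dx|^2 = 3 * mean per-coord
}

#' Contact count between two atom groups
#'
#' A contact is a pair (a in A, b in B) with distance <= cutoff.
#'
#' @param A,B numeric `N x 3` coordinate matrices (Angstrom), non-empty
#' @param cutoff distance cutoff, Angstrom (default 3.0)
#' @return integer contact count
#' @export
countContacts <- function(A, B, cutoff = 3.0) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!nrow(A) || !nrow(B)) stop("empty atom group")
  if (cutoff <= 0) stop("cutoff must be positive")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sum(d2 <= cutoff^2 + 1e-12)
}

#' Non-native contacts relative to a reference frame
#'
#' The number of non-native contacts of a frame is the contact count of the
#' frame minus the contact count of the reference structure (typically the
#' energy-minimized starting structure), using the same atom groups and
#' cutoff; the result may be negative.
#'
#' @param frame,reference full coordinate matrices (Angstrom), same atom order
#' @param groupA,groupB integer index vectors selecting the two groups
#' @param cutoff distance cutoff, Angstrom (default 3.0)
#' @return integer (possibly negative)
#' @export
nonnativeContacts <- function(frame, reference, groupA, groupB, cutoff = 3.0) {
  if (!length(groupA) || !length(groupB)) stop("empty atom group")
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  countContacts(frame[groupA, , drop = FALSE],
                frame[groupB, , drop = FALSE], cutoff) -
    countContacts(reference[groupA, , drop = FALSE],
                  reference[groupB, , drop = FALSE], cutoff)
}

#' Summarize a scalar series as a density histogram with moments
#'
#' Density-normalized histogram (unit integral) plus mean and standard
#' deviation, the common reduction for helical-parameter and elasticity
#' series. A constant series yields a degenerate single-bin histogram with
#' SD 0 and a warning.
#'
#' @param x numeric series, >= 2 samples
#' @param nBins number of uniform bins over the data range (default 40)
#' @return list with `mids`, `breaks`, `counts`, `density`, `mean`, `sd`
#' @export
summarizeDistribution <- function(x, nBins = 40L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 samples")
  if (nBins < 1L) stop("nBins must be >= 1")
  if (diff(range(x)) == 0) {
    warning("degenerate histogram: constant series")
    return(list(mids = x[1], breaks = c(x[1] - 0.5, x[1] + 0.5),
                counts = length(x), density = 1,
                mean = x[1], sd = 0))
  }
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = nBins + 1L),
                      plot = FALSE)
  list(mids = h$mids, breaks = h$breaks, counts = h$counts,
       density = h$density, mean = mean(x), sd = stats::sd(x))
}
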