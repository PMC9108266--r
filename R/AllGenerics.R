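#' Number of frames in a trajectory
#' @param x a [DuplexTrajectory-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of base pairs
#' @param x a [DuplexTrajectory-class] or [WCDuplex-class]
#' @return integer base-pair count
#' @export
setGeneric("nBasePairs", function(x) standardGeneric("nBasePairs"))

#' Duplex sequence (one strand, 5'->3')
#' @param x a [DuplexTrajectory-class] or [WCDuplex-class]
#' @return character string
#' @export
setGeneric("duplexSequence", function(x) standardGeneric("duplexSequence"))

#' Trim base pairs from both duplex ends
#'
#' Removes `n` base pairs from each end before analysis, the usual guard
#' against end-fraying artefacts in duplex trajectories.
#'
#' @param x a [DuplexTrajectory-class] or [WCDuplex-class]
#' @param n base pairs to drop from each end (default 1)
#' @return an object of the same class with `2 n` fewer base pairs
#' @export
setGeneric("trimEnds", function(x, n = 1L) standardGeneric("trimEnds"))

#' Base-pair origins
#' @param x a [DuplexTrajectory-class]
#' @return numeric array `nFrames x nBasePairs x 3`, nm
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))

#' Base-pair tangents
#' @param x a [DuplexTrajectory-class]
#' @return numeric array `nFrames x nBasePairs x 3` of unit vectors
#' @export
setGeneric("tangents", function(x) standardGeneric("tangents"))

#' Per-step twists
#' @param x a [DuplexTrajectory-class]
#' @return numeric matrix `nFrames x (nBasePairs - 1)`, degrees
#' @export
setGeneric("stepTwists", function(x) standardGeneric("stepTwists"))

#' @rdname nFrames
setMethod("nFrames", "DuplexTrajectory", function(x) dim(x@origins)[1])

#' @rdname nBasePairs
setMethod("nBasePairs", "DuplexTrajectory", function(x) dim(x@origins)[2])

#' @rdname nBasePairs
setMethod("nBasePairs", "WCDuplex", function(x) nchar(x@sequence))

#' @rdname duplexSequence
setMethod("duplexSequence", "DuplexTrajectory", function(x) x@sequence)

#' @rdname duplexSequence
setMethod("duplexSequence", "WCDuplex", function(x) x@sequence)

#' @rdname origins
setMethod("origins", "DuplexTrajectory", function(x) x@origins)

#' @rdname tangents
setMethod("tangents", "DuplexTrajectory", function(x) x@tangents)

#' @rdname stepTwists
setMethod("stepTwists", "DuplexTrajectory", function(x) x@stepTwists)

#' @rdname trimEnds
setMethod("trimEnds", "DuplexTrajectory", function(x, n = 1L) {
  n <- as.integer(n)
  nbp <- nBasePairs(x)
  if (n < 0L) stop("n must be non-negative")
  if (n == 0L) return(x)
  if (2L * n >= nbp - 1L)
    stop("cannot trim ", n, " base pairs from each end of a ", nbp, "-bp duplex")
  keep <- (n + 1L):(nbp - n)
  steps <- (n + 1L):(nbp - 1L - n)   # steps joining the kept base pairs
  new("DuplexTrajectory",
      sequence   = substr(x@sequence, n + 1L, nbp - n),
      origins    = x@origins[, keep, , drop = FALSE],
      tangents   = x@tangents[, keep, , drop = FALSE],
      stepTwists = x@stepTwists[, steps, drop = FALSE],
      atoms      = x@atoms,
      time       = x@time)
})

#' @rdname trimEnds
setMethod("trimEnds", "WCDuplex", function(x, n = 1L) {
  n <- as.integer(n)
  nbp <- nchar(x@sequence)
  if (n < 0L) stop("n must be non-negative")
  if (n == 0L) return(x)
  if (2L * n >= nbp) stop("trim too large for a ", nbp, "-bp duplex")
  keepBp <- (n + 1L):(nbp - n)
  keep <- which(x@bp %in% keepBp)
  remap <- match(seq_len(nrow(x@atoms)), keep)
  sub <- function(idx) {
    m <- remap[idx]
    m[!is.na(m)]
  }
  # donors and hydrogens are parallel; keep pairs whose donor survives
  dOK <- !is.na(remap[x@donors])
  new("WCDuplex",
      sequence  = substr(x@sequence, n + 1L, nbp - n),
      atoms     = x@atoms[keep, , drop = FALSE],
      donors    = remap[x@donors][dOK],
      hydrogens = remap[x@hydrogens][dOK],
      acceptors = sub(x@acceptors),
      bp        = (x@bp[keep] - n))
})

setMethod("show", "DuplexTrajectory", function(object) {
  cat("DuplexTrajectory:", nFrames(object), "frames x",
      nBasePairs(object), "bp\n")
  cat("  sequence:", object@sequence, "\n")
  if (length(object@time))
    cat("  time: ", min(object@time), "-", max(object@time), "ns\n")
  if (length(object@atoms))
    cat("  atomic coordinates:", length(object@atoms), "frame(s)\n")
})

setMethod("show", "WCDuplex", function(object) {
  cat("WCDuplex:", nchar(object@sequence), "bp idealized B-form duplex\n")
  cat("  sequence:", object@sequence, "\n")
  cat("  atoms:", nrow(object@atoms),
      " (", length(object@donors), "D-H,", length(object@acceptors), "A )\n")
})

setMethod("show", "DensityProfile", function(object) {
  cat("DensityProfile:", length(object@z), "bins, dz =",
      signif(object@binWidth, 4), "nm\n")
  cat("  rho range:", signif(min(object@rho), 4), "-",
      signif(max(object@rho), 4), "g/cm^3\n")
})

setMethod("show", "PMFProfile", function(object) {
  ok <- !object@masked
  cat("PMFProfile:", length(object@z), "bins (", sum(!ok), "masked )\n")
  if (any(ok))
    cat("  pmf range:", signif(min(object@pmf[ok]), 4), "-",
        signif(max(object@pmf[ok]), 4), "kBT\n")
})

setMethod("show", "ElasticFit", function(object) {
  e <- object@estimates
  fmt <- function(key, unit) {
    se <- object@se[key]
    cat(sprintf("  %-22s %10.4g %s%s\n", key, e[key], unit,
                if (!is.na(se)) sprintf("  (SE %.3g)", se) else ""))
  }
  cat("ElasticFit (L0 =", signif(e["L0"], 5), "nm, kBT =",
      signif(e["kBT"], 5), "pN nm)\n")
  fmt("lp", "nm")
  if ("lpMoment" %in% names(e)) fmt("lpMoment", "nm")
  fmt("gamma", "pN")
  if ("gammaMoment" %in% names(e)) fmt("gammaMoment", "pN")
  fmt("C", "pN nm^2")
  fmt("torsionalPersistence", "nm")
})

#' @export
#' @method as.data.frame DensityProfile
as.data.frame.DensityProfile <- function(x, ...)
  data.frame(z = x@z, rho = x@rho)

#' @export
#' @method as.data.frame PMFProfile
as.data.frame.PMFProfile <- function(x, ...)
  data.frame(z = x@z, pmf = x@pmf, masked = x@masked)
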