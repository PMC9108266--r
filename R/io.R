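#' Read a (possibly multi-model) PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] returning one coordinate set per
#' MODEL record (a single set for single-model files). Atom naming is
#' preserved verbatim; coordinates stay in Angstrom, the native unit of the
#' format and of every atomic-scale cutoff in this package.
#'
#' @param path path to a PDB file
#' @return list of data frames, each with columns `name`, `resid`, `chain`,
#'   `x`, `y`, `z` (Angstrom)
#' @export
readPDBModels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nAtoms <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * nAtoms)
    stop("inconsistent atom counts across models in '", path, "'")
  ch <- pdb$atom$chain
  ch[is.na(ch)] <- ""
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    data.frame(name = pdb$atom$elety, resid = pdb$atom$resno, chain = ch,
               x = co[, 1], y = co[, 2], z = co[, 3])
  })
}

#' Write coordinate sets as a multi-model PDB file
#'
#' Deterministic fixed-width writer emitting one MODEL/ENDMDL block per
#' coordinate set (bio3d's writer covers single models only). Coordinates
#' are written at the format's native 1e-3 Angstrom precision.
#'
#' @param models a single data frame or a list of data frames with columns
#'   `name`, `resid`, `chain`, `x`, `y`, `z` (Angstrom); optional `res`
#'   column supplies residue names (default "MOL")
#' @param path output path
#' @return `path`, invisibly
#' @export
writePDBModels <- function(models, path) {
  if (is.data.frame(models)) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    a <- models[[m]]
    res <- if ("res" %in% names(a)) a$res else rep("MOL", nrow(a))
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    nm <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       seq_len(nrow(a)) %% 100000L, nm, substr(res, 1, 3),
                       substr(ifelse(a$chain == "", "A", a$chain), 1, 1),
                       a$resid %% 10000L, a$x, a$y, a$z, 1, 0), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a base-pair-step parameter table
#'
#' Parses the plain-text dialect this package writes and that mirrors
#' 3DNA-style `.par` output: any number of comment lines starting with `#`,
#' a whitespace-separated header naming the columns, then one row per
#' base-pair step, `stepsPerFrame` consecutive rows forming one frame. The
#' columns `rise` (Angstrom), `twist` (degrees) and `roll` (degrees) are
#' required; rise is converted to nm on input.
#'
#' Per frame the reader also assembles the two global helical coordinates:
#' the contour length `L` (sum of rises, nm) and the cumulative twist
#' `phi` (sum of twists, degrees).
#'
#' @param path path to the table
#' @param stepsPerFrame number of base-pair steps per frame (n_bp - 1)
#' @return list with matrices `rise` (nm), `twist`, `roll` (degrees), each
#'   `nFrames x stepsPerFrame`, and a data frame `frames` with columns
#'   `frame`, `L` (nm), `phi` (degrees)
#' @export
readBpStepTable <- function(path, stepsPerFrame) {
  if (!file.exists(path)) stop("no such file: ", path)
  stepsPerFrame <- as.integer(stepsPerFrame)
  if (stepsPerFrame < 1L) stop("stepsPerFrame must be >= 1")
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (length(ln) < 2L)
    stop("framing error: table has no data rows")
  header <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  need <- c("rise", "twist", "roll")
  if (!all(need %in% header))
    stop("schema error: missing required column(s) ",
         paste(setdiff(need, header), collapse = ", "))
  dat <- utils::read.table(text = ln[-1], col.names = header)
  if (nrow(dat) %% stepsPerFrame != 0L)
    stop("framing error: ", nrow(dat),
         " rows are not divisible by ", stepsPerFrame, " steps per frame")
  nf <- nrow(dat) %/% stepsPerFrame
  shape <- function(v) matrix(v, nrow = nf, ncol = stepsPerFrame, byrow = TRUE)
  rise <- shape(dat$rise) / 10   # Angstrom -> nm
  twist <- shape(dat$twist)
  roll <- shape(dat$roll)
  list(rise = rise, twist = twist, roll = roll,
       frames = data.frame(frame = seq_len(nf),
                           L = rowSums(rise), phi = rowSums(twist)))
}

#' Write a base-pair-step parameter table
#'
#' Writes the dialect read by [readBpStepTable()]. For a
#' [DuplexTrajectory-class] the rise of each step is the distance between
#' consecutive base-pair origins and the twist comes from the stored step
#' twists; roll is zero unless supplied (the generator does not model it).
#'
#' @param x a [DuplexTrajectory-class], or a list with matrices `rise` (nm),
#'   `twist` and optionally `roll` (degrees)
#' @param path output path
#' @return `path`, invisibly
#' @export
writeBpStepTable <- function(x, path) {
  if (is(x, "DuplexTrajectory")) {
    d <- origins(x)
    nbp <- dim(d)[2]
    rise <- sqrt(apply((d[, -1L, , drop = FALSE] -
                          d[, -nbp, , drop = FALSE])^2, c(1, 2), sum))
    x <- list(rise = rise, twist = stepTwists(x))
  }
  rise <- as.matrix(x$rise) * 10   # nm -> Angstrom
  twist <- as.matrix(x$twist)
  roll <- if (!is.null(x$roll)) as.matrix(x$roll) else 0 * twist
  stopifnot(identical(dim(rise), dim(twist)),
            identical(dim(rise), dim(roll)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# base-pair step parameters",
               sprintf("# %d frames x %d steps; rise in Angstrom, angles in degrees",
                       nrow(rise), ncol(rise)),
               "rise twist roll"), con)
  for (f in seq_len(nrow(rise)))
    writeLines(sprintf("%.8f %.8f %.8f", rise[f, ], twist[f, ], roll[f, ]), con)
  invisible(path)
}

#' Assemble base-pair frames from atomic coordinate sets
#'
#' Computes per-frame base-pair origins as the (optionally mass-weighted)
#' centre of mass of each base pair's atoms, converts Angstrom to nm, and
#' derives tangents by central differences: for interior base pairs
#' \eqn{t_i = \mathrm{normalize}(o_{i+1} - o_{i-1})}, with forward/backward
#' differences at the ends. Step twists are not derivable from plain
#' coordinates and are set to zero.
#'
#' @param models list of coordinate data frames (columns `x`, `y`, `z`,
#'   Angstrom), one per frame, identical atom order
#' @param bpIndex integer vector mapping every atom to a base-pair index
#'   (1-based, contiguous); atoms with NA are ignored
#' @param masses optional per-atom masses for weighting (default unit masses)
#' @param sequence optional strand sequence
#' @return a [DuplexTrajectory-class]
#' @export
framesFromAtoms <- function(models, bpIndex, masses = NULL, sequence = NULL) {
  if (is.data.frame(models)) models <- list(models)
  nAtoms <- nrow(models[[1]])
  if (length(bpIndex) != nAtoms)
    stop("bpIndex must map every atom")
  keep <- !is.na(bpIndex)
  grp <- as.integer(bpIndex[keep])
  nbp <- max(grp)
  if (!all(seq_len(nbp) %in% grp))
    stop("grouping error: base pair(s) with zero atoms: ",
         paste(setdiff(seq_len(nbp), grp), collapse = ", "))
  w <- if (is.null(masses)) rep(1, sum(keep)) else {
    if (length(masses) != nAtoms) stop("masses must be per-atom")
    masses[keep]
  }
  wSum <- tapply(w, grp, sum)
  nf <- length(models)
  O <- array(0, c(nf, nbp, 3L))
  for (f in seq_len(nf)) {
    co <- as.matrix(models[[f]][keep, c("x", "y", "z")])
    for (k in 1:3)
      O[f, , k] <- tapply(w * co[, k], grp, sum) / wSum / 10  # A -> nm
  }
  Tn <- array(0, c(nf, nbp, 3L))
  for (i in seq_len(nbp)) {
    lo <- max(1L, i - 1L); hi <- min(nbp, i + 1L)
    d <- O[, hi, , drop = FALSE] - O[, lo, , drop = FALSE]
    d <- matrix(d, nf, 3L)
    nrm <- sqrt(rowSums(d^2))
    if (any(nrm < 1e-12))
      stop("geometry error: coincident base-pair origins at bp ", i)
    Tn[, i, ] <- d / nrm
  }
  if (is.null(sequence)) sequence <- strrep("N", nbp)
  new("DuplexTrajectory", sequence = sequence, origins = O, tangents = Tn,
      stepTwists = matrix(0, nf, nbp - 1L), atoms = models, time = numeric())
}
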