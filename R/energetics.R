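#' Pairwise non-bonded interaction energy between two atom groups
#'
#' Generic Lennard-Jones 12-6 plus Coulomb energy summed over all
#' inter-group pairs within a real-space cutoff, the decomposition used for
#' DNA-nanotube interaction analyses. Per pair,
#' \deqn{E_{vdw} = \epsilon_{ij}\left[(r_{min,ij}/r)^{12} -
#'   2 (r_{min,ij}/r)^{6}\right], \qquad
#'   E_{elec} = k\, q_i q_j / r,}
#' with Lorentz-Berthelot combination
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}},
#' \eqn{r_{min,ij} = r_{min,i}/2 + r_{min,j}/2}. Both terms are plainly
#' truncated (no shift or switch) at the cutoff. At r = r_min the LJ term
#' is exactly -epsilon; a charge-neutral group contributes zero
#' electrostatic energy.
#'
#' @param groupA,groupB data frames with columns `x`, `y`, `z` (Angstrom),
#'   `charge` (e), `epsilon` (kcal/mol, >= 0), `rminHalf` (Angstrom); the
#'   groups must be disjoint atom sets
#' @param cutoff real-space cutoff, Angstrom (default 10)
#' @param coulombK Coulomb constant, kcal A / (mol e^2) (default 332.0636)
#' @param perBp optional divisor for per-base-pair reporting (e.g. 14)
#' @return list with `vdw` and `elec`, kcal/mol
#' @export
pairEnergy <- function(groupA, groupB, cutoff = 10, coulombK = 332.0636,
                       perBp = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  for (g in list(groupA, groupB)) {
    need <- c("x", "y", "z", "charge", "epsilon", "rminHalf")
    if (!all(need %in% names(g)))
      stop("parameter error: groups need columns ",
           paste(need, collapse = ", "))
    bad <- which(!stats::complete.cases(g[, need]) | g$epsilon < 0)
    if (length(bad))
      stop("parameter error: invalid parameters for atom(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  A <- as.matrix(groupA[, c("x", "y", "z")])
  B <- as.matrix(groupB[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  r <- sqrt(pmax(d2, 0))
  ok <- r <= cutoff & r > 0
  if (!any(ok)) {
    out <- list(vdw = 0, elec = 0)
  } else {
    eps <- sqrt(outer(groupA$epsilon, groupB$epsilon))
    rmin <- outer(groupA$rminHalf, groupB$rminHalf, "+")
    qq <- outer(groupA$charge, groupB$charge)
    sr6 <- (rmin[ok] / r[ok])^6
    out <- list(vdw = sum(eps[ok] * (sr6^2 - 2 * sr6)),
                elec = sum(coulombK * qq[ok] / r[ok]))
  }
  if (!is.null(perBp)) out <- lapply(out, function(e) e / perBp)
  out
}
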