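# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus small fixture builders. Everything here is written
# as plain double loops on purpose.

bruteHbonds <- function(co, donors, hydrogens, acceptors,
                        daCutoff = 3.5, angleMin = 120) {
  hits <- list()
  for (k in seq_along(donors)) {
    for (a in acceptors) {
      if (a == donors[k] || a == hydrogens[k]) next
      dv <- co[a, ] - co[donors[k], ]
      d <- sqrt(sum(dv^2))
      if (d > daCutoff) next
      v1 <- co[donors[k], ] - co[hydrogens[k], ]
      v2 <- co[a, ] - co[hydrogens[k], ]
      ang <- acos(min(max(sum(v1 * v2) /
        sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang >= angleMin)
        hits[[length(hits) + 1L]] <- c(donors[k], hydrogens[k], a)
    }
  }
  if (!length(hits)) return(matrix(integer(), 0L, 3L))
  do.call(rbind, hits)
}

bruteContacts <- function(A, B, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      if (sqrt(sum((A[i, ] - B[j, ])^2)) <= cutoff) n <- n + 1L
  n
}

bruteCOM <- function(coords, grp, w = rep(1, nrow(coords))) {
  out <- matrix(0, max(grp), 3L)
  for (g in seq_len(max(grp))) {
    idx <- which(grp == g)
    for (k in 1:3)
      out[g, k] <- sum(w[idx] * coords[idx, k]) / sum(w[idx])
  }
  out
}

brutePairEnergy <- function(A, B, cutoff = 10, K = 332.0636) {
  vdw <- 0; elec <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      r <- sqrt(sum((unlist(A[i, c("x", "y", "z")]) -
                       unlist(B[j, c("x", "y", "z")]))^2))
      if (r > cutoff || r == 0) next
      eps <- sqrt(A$epsilon[i] * B$epsilon[j])
      rmin <- A$rminHalf[i] + B$rminHalf[j]
      vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
      elec <- elec + K * A$charge[i] * B$charge[j] / r
    }
  }
  list(vdw = vdw, elec = elec)
}

bruteRMSD <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) s <- s + sum((a[i, ] - b[i, ])^2)
  sqrt(s / nrow(a))
}

randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# hand-built trajectory with explicit origins/tangents (nm)
makeTraj <- function(origins, tangents, stepTwists = NULL) {
  nf <- dim(origins)[1]; nbp <- dim(origins)[2]
  if (is.null(stepTwists)) stepTwists <- matrix(0, nf, nbp - 1L)
  new("DuplexTrajectory", sequence = strrep("N", nbp),
      origins = origins, tangents = tangents, stepTwists = stepTwists,
      atoms = list(), time = numeric())
}

straightTraj <- function(nFrames = 3L, nbp = 16L, rise = 0.34) {
  O <- array(0, c(nFrames, nbp, 3L))
  Tn <- array(0, c(nFrames, nbp, 3L))
  for (i in seq_len(nbp)) O[, i, 3] <- (i - 1L) * rise
  Tn[, , 3] <- 1
  makeTraj(O, Tn)
}

# random hydrogen-bond test instance: donors with attached hydrogens plus
# free acceptors scattered in a box
randomHbondInstance <- function(nD = 15L, nA = 25L, box = 12) {
  co <- matrix(runif((2L * nD + nA) * 3, 0, box), ncol = 3L)
  donors <- seq_len(nD)
  hydrogens <- nD + seq_len(nD)
  for (k in seq_len(nD)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    co[hydrogens[k], ] <- co[donors[k], ] + u   # 1 A covalent offset
  }
  acceptors <- 2L * nD + seq_len(nA)
  list(co = co, donors = donors, hydrogens = hydrogens,
       acceptors = acceptors)
}
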