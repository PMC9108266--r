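test_that("RMSD: identities, closed form, and brute-force oracle", {
  set.seed(31)
  ref <- matrix(rnorm(30), 10)
  expect_equal(calcRMSD(ref, ref), 0)
  # one atom of N displaced by d -> d/sqrt(N)
  fr <- ref; fr[4, 1] <- fr[4, 1] + 2.5
  expect_equal(calcRMSD(fr, ref), 2.5 / sqrt(10))
  fr2 <- ref + matrix(rnorm(30), 10)
  expect_equal(calcRMSD(fr2, ref), bruteRMSD(fr2, ref), tolerance = 1e-12)
  expect_error(calcRMSD(ref[1:3, ], ref), "alignment error")
})

test_that("superposed RMSD is invariant under rigid motion and matches bio3d", {
  set.seed(32)
  ref <- matrix(rnorm(36, sd = 4), 12)
  fr <- ref + matrix(rnorm(36, sd = 0.3), 12)
  moved <- fr %*% t(randomRotation()) +
    matrix(rep(c(5, -3, 11), each = 12), 12)
  expect_equal(calcRMSD(moved, ref, superpose = TRUE),
               calcRMSD(fr, ref, superpose = TRUE), tolerance = 1e-9)
  idx <- seq_len(36)
  expect_equal(calcRMSD(moved, ref, superpose = TRUE),
               as.numeric(bio3d::rmsd(as.vector(t(ref)), as.vector(t(moved)),
                                      a.inds = idx, b.inds = idx, fit = TRUE)),
               tolerance = 2e-3)  # bio3d::rmsd rounds to 3 decimals
})

test_that("RMSF: static, two-point and white-noise cases", {
  base <- matrix(rnorm(15), 5)
  expect_equal(calcRMSF(list(base, base, base)), rep(0, 5))
  # one atom alternating +/- d about its mean along one axis -> RMSF = d
  a <- base; b <- base
  a[2, 3] <- base[2, 3] + 1.7; b[2, 3] <- base[2, 3] - 1.7
  expect_equal(calcRMSF(list(a, b, a, b))[2], 1.7)
  # white noise sigma per axis -> sigma * sqrt(3)
  set.seed(33)
  frames <- lapply(1:4000, function(i) matrix(rnorm(15, sd = 0.8), 5))
  expect_equal(calcRMSF(frames), rep(0.8 * sqrt(3), 5), tolerance = 0.05)
  expect_error(calcRMSF(list(base)), "insufficient data")
})

test_that("geometric H-bond detector honours both criteria", {
  crit <- hbondCriteria()
  # canonical geometry: D...A 2.9 A, D-H...A 175 degrees -> detected
  co <- rbind(D = c(0, 0, 0), H = c(0, 1, 0.05), A = c(0, 2.9, 0))
  expect_equal(nrow(detectHBonds(co, 1L, 2L, 3L, crit)), 1L)
  # D...A = 3.6 A -> beyond cutoff
  co2 <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 3.6, 0))
  expect_equal(nrow(detectHBonds(co2, 1L, 2L, 3L, crit)), 0L)
  # angle below 120 -> rejected even at short distance
  co3 <- rbind(c(0, 0, 0), c(0, 1, 0), c(1.8, 1.9, 0))
  ang <- 180 / pi * acos(sum(-co3[2, ] * (co3[3, ] - co3[2, ])) /
    (sqrt(sum(co3[2, ]^2)) * sqrt(sum((co3[3, ] - co3[2, ])^2))))
  expect_lt(ang, 120)
  expect_equal(nrow(detectHBonds(co3, 1L, 2L, 3L, crit)), 0L)
  expect_error(detectHBonds(co, 1L, c(2L, 3L), 3L, crit), "topology error")
  expect_error(hbondCriteria(daCutoff = -1), "positive")
  expect_error(hbondCriteria(angleMin = 200), "angleMin")
})

test_that("H-bond detector matches the exhaustive oracle on random instances", {
  set.seed(34)
  for (rep in 1:4) {
    inst <- randomHbondInstance(nD = 12L + rep, nA = 20L + rep, box = 10)
    got <- detectHBonds(inst$co, inst$donors, inst$hydrogens,
                        inst$acceptors)
    ora <- bruteHbonds(inst$co, inst$donors, inst$hydrogens, inst$acceptors)
    expect_equal(nrow(got), nrow(ora))
    if (nrow(got)) {
      key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
      expect_identical(key(as.matrix(got[, 1:3])), key(ora))
    }
  }
})

test_that("canonical H-bond accounting", {
  expect_identical(canonicalHbondCount("GTCGCGAATTCGCGAC", trim = 1), 36L)
  expect_identical(canonicalHbondCount("AAAAAAAAAA", trim = 0), 20L)
  expect_identical(canonicalHbondCount("GC", trim = 0), 6L)
  expect_error(canonicalHbondCount("", 0), "sequence")
  expect_error(canonicalHbondCount("ACGT", trim = 2), "trim")
  # invariance under reverse complement
  for (s in c("GTCGCGAATTCGCGAC", "AACGTT", "GATTACA"))
    expect_identical(canonicalHbondCount(s, 0),
                     canonicalHbondCount(reverseComplement(s), 0))
})

test_that("contact counting: identity, construction, and oracle", {
  set.seed(35)
  ref <- matrix(runif(60, 0, 30), 20)
  expect_identical(nonnativeContacts(ref, ref, 1:8, 9:20), 0L)
  # reference has zero contacts; frame brings 5 B atoms within 2.9 A of A
  refC <- rbind(c(0, 0, 0), matrix(100, 5, 3))
  frC <- refC
  frC[2:6, ] <- 2.9 * rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                            c(-1, 0, 0), c(0, -1, 0))
  expect_identical(nonnativeContacts(frC, refC, 1L, 2:6, cutoff = 3), 5L)
  # random toy vs double loop, including negative results
  for (rep in 1:3) {
    fr <- ref + matrix(rnorm(60, sd = 2), 20)
    got <- nonnativeContacts(fr, ref, 1:8, 9:20, cutoff = 6)
    ora <- bruteContacts(fr[1:8, ], fr[9:20, ], 6) -
      bruteContacts(ref[1:8, ], ref[9:20, ], 6)
    expect_identical(got, as.integer(ora))
  }
  expect_error(nonnativeContacts(ref, ref, integer(), 1:3), "empty")
})

test_that("distribution summaries are density-normalized with exact moments", {
  set.seed(36)
  x <- rnorm(20000)
  s <- summarizeDistribution(x, 50)
  expect_equal(sum(s$density * diff(s$breaks)), 1, tolerance = 1e-9)
  expect_equal(s$mean, 0, tolerance = 0.05)
  expect_equal(s$sd, 1, tolerance = 0.05)
  expect_warning(sc <- summarizeDistribution(rep(2.5, 10), 5), "degenerate")
  expect_equal(sc$sd, 0)
  expect_error(summarizeDistribution(1), "2 samples")
})
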