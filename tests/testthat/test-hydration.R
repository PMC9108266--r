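test_that("shell water count: empty, constructed, and volume-oracle cases", {
  ori <- cbind(0, 0, seq(0, 44.2, length.out = 14))   # Angstrom
  ang <- seq(0, 2 * pi, length.out = 41)[-41]
  dna <- cbind(9 * cos(ang), 9 * sin(ang), runif(40, 2, 42))
  expect_equal(shellWaterCount(dna, ori, matrix(numeric(), 0, 3)), 0)
  # 28 waters at R_dna + 1 A inside the span, perBp = 14 -> 2.0
  wAng <- seq(0, 2 * pi, length.out = 29)[-29]
  wat <- cbind(10 * cos(wAng), 10 * sin(wAng), seq(1, 43, length.out = 28))
  expect_equal(shellWaterCount(dna, ori, wat, thickness = 3, perBp = 14), 2)
  # waters at R_dna + 4 A are outside a 3 A shell
  watFar <- cbind(13.2 * cos(wAng), 13.2 * sin(wAng),
                  seq(1, 43, length.out = 28))
  expect_equal(shellWaterCount(dna, ori, watFar, thickness = 3), 0)
  expect_error(shellWaterCount(dna, ori[1, , drop = FALSE], wat),
               "axis error")
})

test_that("uniform water recovers shell volume times density", {
  set.seed(41)
  ori <- cbind(0, 0, seq(0, 47.6, length.out = 15))
  ang <- runif(60, 0, 2 * pi)
  dna <- cbind(9 * cos(ang), 9 * sin(ang), runif(60, 0, 47.6))
  # uniform waters in a generous box; R_dna ~ 9 A (95th pct of fixed radius)
  rho <- 0.02   # waters per A^3
  box <- 16; zlo <- -5; zhi <- 52.6
  n <- 60000L
  wat <- cbind(runif(n, -box, box), runif(n, -box, box),
               runif(n, zlo, zhi))
  got <- shellWaterCount(dna, ori, wat, thickness = 3, perBp = 1)
  rShell <- 9 + 3
  expVol <- pi * rShell^2 * 47.6
  expCount <- expVol * n / ((2 * box)^2 * (zhi - zlo))
  expect_lt(abs(got - expCount), 4 * sqrt(expCount))
})

test_that("shell count is invariant under joint rigid transformation", {
  set.seed(42)
  ori <- cbind(0, 0, seq(0, 40, length.out = 12))
  dna <- cbind(rnorm(50, sd = 6), rnorm(50, sd = 6), runif(50, 0, 40))
  wat <- cbind(rnorm(200, sd = 10), rnorm(200, sd = 10), runif(200, -5, 45))
  base <- shellWaterCount(dna, ori, wat)
  R <- randomRotation(); tr <- c(12, -7, 3)
  mv <- function(m) m %*% t(R) + matrix(rep(tr, each = nrow(m)), nrow(m))
  expect_equal(shellWaterCount(mv(dna), mv(ori), mv(wat)), base)
})

test_that("axial density converts counts to g/cm^3 and conserves mass", {
  set.seed(43)
  radius <- 1.355; rEff <- radius - 0.17
  n <- 40000L
  r <- rEff * sqrt(runif(n)); ph <- runif(n, 0, 2 * pi)
  w <- cbind(r * cos(ph), r * sin(ph), runif(n, -6, 6))
  # density implied by n molecules in the accessible cylinder
  expRho <- n * 2.9915e-23 / (pi * rEff^2 * 12 * 1e-21)
  dp <- axialDensity(w, radius, nBins = 24, zlim = c(-6, 6))
  df <- as.data.frame(dp)
  expect_equal(mean(df$rho), expRho, tolerance = 0.02)
  # mass conservation: sum over bins of rho * bin volume = total mass
  expect_equal(sum(df$rho * dp@area * dp@binWidth * 1e-21),
               n * 2.9915e-23, tolerance = 1e-9)
  expect_error(axialDensity(w, 0, 10), "radius")
  expect_error(axialDensity(w, radius, 1), "nBins")
})

test_that("PMF is the exact Boltzmann inverse of the density", {
  z <- seq(-5, 5, length.out = 21)
  mk <- function(rho) new("DensityProfile", z = z, rho = rho,
                          binWidth = 0.5, area = 1)
  # rho = 1 everywhere -> PMF = 0
  expect_equal(pmfFromDensity(mk(rep(1, 21)))@pmf, rep(0, 21))
  # a bin at exp(-0.5) -> PMF 0.5 there
  rho <- rep(1, 21); rho[11] <- exp(-0.5)
  expect_equal(pmfFromDensity(mk(rho))@pmf[11], 0.5)
  # uniform rescaling shifts the PMF by -log(c)
  p1 <- pmfFromDensity(mk(rho)); p2 <- pmfFromDensity(mk(3 * rho))
  expect_equal(p2@pmf - p1@pmf, rep(-log(3), 21), tolerance = 1e-12)
  # identity: rho = exp(-pmf) inverts exactly on unmasked bins
  back <- pmfFromDensity(mk(exp(-p1@pmf)))
  expect_equal(back@pmf, p1@pmf, tolerance = 1e-12)
  # masking
  rho0 <- rho; rho0[3] <- 0
  pm <- pmfFromDensity(mk(rho0))
  expect_true(pm@masked[3] && !pm@masked[4])
  expect_error(pmfFromDensity(mk(rep(0, 21))), "empty PMF")
})

test_that("barrier height: flat profile, imposed dip, scale invariance", {
  z <- seq(-7.5, 7.5, length.out = 31)
  flat <- new("PMFProfile", z = z, pmf = rep(0.3, 31),
              masked = rep(FALSE, 31))
  expect_equal(barrierHeight(flat, c(4, 7), tubeHalfLength = 6), 0)

  # generation/analysis round trip at reduced sample size
  prof <- data.frame(z = c(-7.5, 4.99, 5, 6, 6.01, 7.5),
                     density = c(1, 1, exp(-0.5), exp(-0.5), 1, 1))
  w <- sampleCylinderWater(40000, radius = 1.355, halfLength = 7.5,
                           profile = prof, seed = 44)
  pmf <- pmfFromDensity(axialDensity(w, 1.355, nBins = 60,
                                     zlim = c(-7.5, 7.5)))
  b <- barrierHeight(pmf, c(4.8, 6.2), tubeHalfLength = 6)
  expect_equal(b, 0.5, tolerance = 0.2)
  # uniform density rescaling leaves the barrier unchanged
  dp <- axialDensity(w, 1.355, nBins = 60, zlim = c(-7.5, 7.5))
  dp2 <- new("DensityProfile", z = dp@z, rho = 5 * dp@rho,
             binWidth = dp@binWidth, area = dp@area)
  expect_equal(barrierHeight(pmfFromDensity(dp2), c(4.8, 6.2), 6), b,
               tolerance = 1e-12)
  expect_error(barrierHeight(flat, c(100, 101), 6), "insufficient data")
})
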