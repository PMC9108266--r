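test_that("bend angles: straight chain, right angle, arccos oracle", {
  expect_equal(bendAngles(straightTraj()), rep(0, 3))
  # tangents (0,0,1) and (0,1,0) -> pi/2
  O <- array(0, c(1, 3, 3)); O[1, 2, 3] <- 0.34; O[1, 3, ] <- c(0, 0.34, 0.34)
  Tn <- array(0, c(1, 3, 3))
  Tn[1, 1, ] <- c(0, 0, 1); Tn[1, 2, ] <- c(0, 0, 1); Tn[1, 3, ] <- c(0, 1, 0)
  expect_equal(bendAngles(makeTraj(O, Tn)), pi / 2)
  # random frames vs independent arccos
  set.seed(51)
  traj <- sampleChainFrames(20, seed = 51)
  t1 <- tangents(traj)[, 1, ]; tn <- tangents(traj)[, 16, ]
  ora <- vapply(1:20, function(f)
    acos(min(max(sum(t1[f, ] * tn[f, ]), -1), 1)), numeric(1))
  expect_equal(bendAngles(traj), ora, tolerance = 1e-12)
})

test_that("contour lengths: constant rise, mean identity, pairwise oracle", {
  expect_equal(contourLengths(straightTraj(nbp = 16))$L, rep(5.1, 3))
  traj <- sampleChainFrames(30, seed = 52)
  cl <- contourLengths(traj)
  expect_identical(cl$L0, mean(cl$L))
  ora <- vapply(1:30, function(f) {
    s <- 0
    for (i in 1:15)
      s <- s + sqrt(sum((origins(traj)[f, i + 1, ] -
                           origins(traj)[f, i, ])^2))
    s
  }, numeric(1))
  expect_equal(cl$L, ora, tolerance = 1e-12)
})

test_that("persistence length fit recovers a signed scalar Gaussian (no Jacobian)", {
  set.seed(53)
  L0 <- 5.1; lpTrue <- 51.21
  th <- rnorm(50000, 0, sqrt(L0 / lpTrue))
  fit <- fitPersistenceLength(th, L0, jacobian = FALSE)
  expect_equal(fit$lp, lpTrue, tolerance = 0.1)
  expect_equal(fit$lpMoment, L0 / var(th), tolerance = 1e-9)
  expect_error(fitPersistenceLength(rep(0, 5000), L0), "degenerate")
})

test_that("persistence length fit on angle magnitudes needs the Jacobian", {
  set.seed(54)
  L0 <- 4.42; lpTrue <- 51.21
  sc <- sqrt(L0 / lpTrue)
  th <- sqrt(rnorm(50000, 0, sc)^2 + rnorm(50000, 0, sc)^2)
  withJac <- fitPersistenceLength(th, L0, jacobian = TRUE)
  expect_equal(withJac$lp, lpTrue, tolerance = 0.1)
  expect_equal(withJac$lpMoment, lpTrue, tolerance = 0.05)
  # omitting the geometric factor halves the estimate in this regime
  noJac <- fitPersistenceLength(th, L0, jacobian = FALSE)
  expect_equal(noJac$lp, lpTrue / 2, tolerance = 0.15)
})

test_that("stretch modulus fit: recovery, estimator agreement, rigid limit", {
  set.seed(55)
  kBT <- thermalEnergy(300)
  L0 <- 5.1; gTrue <- 1181.09
  L <- rnorm(50000, L0, sqrt(L0 * kBT / gTrue))
  fit <- fitStretchModulus(L, kBT)
  expect_equal(fit$gamma, gTrue, tolerance = 0.1)
  # slope and moment estimators agree on well-sampled Gaussians
  expect_lt(abs(fit$gamma - fit$gammaMoment) / fit$gammaMoment, 0.05)
  rigid <- fitStretchModulus(rep(L0, 2000), kBT)
  expect_identical(rigid$gamma, Inf)
})

test_that("torsional stiffness and torsional persistence length", {
  kBT <- thermalEnergy(300)
  # C = 473.84 pN nm^2 at 300 K corresponds to ~114 nm torsional persistence
  expect_equal(473.84 / kBT, 114, tolerance = 0.005)
  set.seed(56)
  L0 <- 4.42; cTrue <- 473.84
  phi <- rnorm(50000, 514.5, sqrt(kBT * L0 / cTrue) * 180 / pi)
  ts <- torsionalStiffness(phi, L0, kBT)
  expect_equal(ts$C, cTrue, tolerance = 0.05)
  expect_equal(ts$torsionalPersistence, ts$C / kBT, tolerance = 1e-9)
  # quadrupling the variance quarters the stiffness
  mu <- mean(phi)
  ts4 <- torsionalStiffness(mu + 2 * (phi - mu), L0, kBT)
  expect_equal(ts4$C, ts$C / 4, tolerance = 1e-9)
  expect_identical(torsionalStiffness(rep(500, 10), L0, kBT)$C, Inf)
})

test_that("bootstrap standard errors are seeded and calibrated", {
  set.seed(57)
  x <- rnorm(10000)
  expect_equal(bootstrapSE(x, mean, 200, seed = 3),
               bootstrapSE(x, mean, 200, seed = 3))
  expect_equal(bootstrapSE(x, mean, 200, seed = 3), 0.01, tolerance = 0.25)
  expect_equal(bootstrapSE(x, function(z) 7, 100, seed = 1), 0)
  expect_error(bootstrapSE(x, mean, 50), "nBoot")
  expect_error(bootstrapSE(x, function(z) stop("boom"), 100, seed = 1),
               "unstable")
})

test_that("stiffer generator chains bend less (lp sweep is monotone)", {
  m2 <- vapply(c(20, 51.21, 150), function(lp) {
    traj <- sampleChainFrames(3000, persistenceLength = lp, seed = 58)
    mean(bendAngles(trimEnds(traj, 1))^2)
  }, numeric(1))
  expect_true(all(diff(m2) < 0))
})

test_that("full elasticity pipeline returns a consistent ElasticFit", {
  traj <- sampleChainFrames(8000, seed = 59)
  fit <- estimateElasticity(traj, nBoot = 100, seed = 60)
  e <- fit@estimates
  expect_s4_class(fit, "ElasticFit")
  expect_equal(unname(e["torsionalPersistence"]),
               unname(e["C"] / e["kBT"]), tolerance = 1e-9)
  expect_equal(unname(e["L0"]), 13 * 0.34, tolerance = 0.01)
  expect_true(all(c("lp", "gamma", "C") %in% names(fit@se)))
  expect_true(all(fit@se[c("lp", "gamma", "C")] > 0))
  # units: lp scales linearly with L0 at fixed slope
  th <- bendAngles(trimEnds(traj, 1))
  f1 <- fitPersistenceLength(th, 4.42)
  f2 <- fitPersistenceLength(th, 8.84)
  expect_equal(f2$lp / f1$lp, 2, tolerance = 1e-9)
})
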