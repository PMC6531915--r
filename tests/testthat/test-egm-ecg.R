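test_that("LAT annotation picks the bipolar deflection nearest the unipolar slope", {
  t <- seq(0, 200, by = 0.5)
  uni <- -2 / (1 + exp(-(t - 100)))              # steepest descent at 100 ms
  bip <- 0.3 * exp(-(t - 97)^2 / 4) - 0.8 * exp(-(t - 140)^2 / 6)
  ann <- annotateLat(t, uni, bip)
  expect_true(ann$valid)
  expect_equal(ann$lat, 97, tolerance = 1)
  # a flat trace is invalid
  flat <- annotateLat(t, rep(0, length(t)), rep(0, length(t)))
  expect_false(flat$valid)
  # time equivariance
  ann2 <- annotateLat(t + 37, uni, bip)
  expect_equal(ann2$lat - ann$lat, 37)
})

test_that("point filtering drops low voltage first, then LAT outliers", {
  set.seed(8)
  n <- 20
  pts <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20), z = 0,
                    amplitude = 2)
  pts$lat <- 2 * pts$x + pts$y            # smooth field
  pts$amplitude[3] <- 0.4
  pts$lat[7] <- pts$lat[7] + 60           # single outlier
  out <- filterPoints(pts, radius = 30)
  expect_false(out$valid[3])
  expect_equal(out$reason[3], "low_voltage")
  expect_false(out$valid[7])
  expect_equal(out$reason[7], "lat_outlier")
  expect_equal(sum(!out$valid), 2)
  # identical LATs: nothing dropped by coherence
  pts2 <- pts; pts2$lat <- 5; pts2$amplitude <- 1
  out2 <- filterPoints(pts2, radius = 30)
  expect_true(all(out2$valid))
  # idempotence
  again <- filterPoints(out[out$valid, names(pts)], radius = 30,
                        threshold = attr(out, "threshold"))
  expect_true(all(again$valid))
})

test_that("extracellular solve is gauged, linear and matches a dense solve", {
  g <- ivtlab:::.new_grid(c(4, 4, 4), dx = 0.5)
  g <- assignFibers(g, helixEndo = 30, helixEpi = -30)
  sys <- assembleDiffusion(g)
  n <- length(sys@mass)
  # uniform Vm: no gradients, phi_e identically zero after gauge fixing
  phi0 <- extracellularFromVm(sys, rep(20, n))
  expect_lt(max(abs(phi0)), 1e-9)
  set.seed(5)
  vm <- rnorm(n, -60, 30)
  phi <- extracellularFromVm(sys, vm)
  expect_lt(abs(mean(phi)), 1e-9)
  # linearity
  expect_equal(extracellularFromVm(sys, 3 * vm), 3 * phi,
               tolerance = 1e-9)
  # dense direct oracle with explicit null-space deflation
  Ki <- 2 * as.matrix(sys@K)
  Kie <- 2 * Ki
  P <- diag(n) - matrix(1 / n, n, n)
  dense <- P %*% MASS::ginv(Kie) %*% (-Ki %*% vm)
  expect_equal(phi, as.numeric(dense), tolerance = 1e-6)
})

test_that("torso solve reproduces harmonic solutions", {
  torso <- buildPhantomTorso(size = c(60, 60, 60), h = 10,
                             heartCenter = c(30, 30, 30),
                             heartSize = c(20, 20, 20))
  # uniform Dirichlet value: every node at that value
  sol <- solveTorso(torso, rep(3.5, length(torso@heartNodes)),
                    fullField = TRUE)
  expect_lt(max(abs(sol$field - 3.5)), 1e-9)
  # scale invariance of the Laplace problem
  hv <- torso@nodes[torso@heartNodes, 1] / 10
  s1 <- solveTorso(torso, hv, fullField = TRUE)
  torso2 <- torso
  torso2@sigma <- torso@sigma * 2
  s2 <- solveTorso(torso2, hv, fullField = TRUE)
  expect_equal(s1$field, s2$field, tolerance = 1e-9)
  # gauge: shifting the Dirichlet data shifts every potential equally
  s3 <- solveTorso(torso, hv + 11, fullField = TRUE)
  expect_equal(s3$field, s1$field + 11, tolerance = 1e-8)
})

test_that("spherical shell matches the closed-form series solution within 2%", {
  a <- 30; R <- 60
  mesh <- sphericalShellMesh(a = a, R = R, nr = 10, ntheta = 24, nphi = 32)
  ct <- mesh@nodes[mesh@heartNodes, 3] / a
  sol <- solveTorso(mesh, ct, fullField = TRUE)  # V0 cos(theta), V0 = 1
  # exact: phi = (A r + B / r^2) cos(theta), d(phi)/dr = 0 at R,
  # phi = cos(theta) at a
  B <- 1 / (2 * a / R^3 + 1 / a^2)
  A <- 2 * B / R^3
  r <- sqrt(rowSums(mesh@nodes^2))
  cth <- mesh@nodes[, 3] / r
  exact <- (A * r + B / r^2) * cth
  err <- max(abs(sol$field[1, ] - exact)) / max(abs(exact))
  expect_lt(err, 0.02)
})

test_that("a dipole flip reverses every lead on the symmetric phantom", {
  torso <- buildPhantomTorso(size = c(60, 60, 60), h = 7.5,
                             heartCenter = c(30, 30, 30),
                             heartSize = c(15, 15, 15))
  hz <- torso@nodes[torso@heartNodes, 3] - 30
  up <- solveTorso(torso, hz)
  down <- solveTorso(torso, -hz)
  expect_equal(down$electrodes, -up$electrodes, tolerance = 1e-9)
})

test_that("ECG comparison equals a hand covariance and respects sign", {
  t10 <- 1:10
  x <- c(1, 3, 2, 5, 4, 6, 5, 7, 6, 8)
  y <- c(2, 4, 3, 6, 5, 7, 6, 8, 7, 9)
  byHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  sim <- list(time = t10, leads = cbind(V1 = x))
  ref <- list(time = t10, leads = cbind(V1 = y))
  expect_equal(unname(compareEcg(sim, ref, resample = FALSE)["V1"]), byHand)
  expect_equal(unname(compareEcg(sim, sim)["V1"]), 1)
  neg <- list(time = t10, leads = cbind(V1 = -x))
  expect_equal(unname(compareEcg(sim, neg)["V1"]), -1)
  const <- list(time = t10, leads = cbind(V1 = rep(1, 10)))
  expect_true(is.na(compareEcg(sim, const)["V1"]))
})

test_that("the forward-ECG chain produces six finite precordial leads", {
  cfg <- solverConfig(chiCm = 2.17, cgTol = 1e-5)
  g <- buildFixture("slab", size = c(6, 6, 1.2), dx = 0.4)
  sys <- assembleDiffusion(g)
  stim <- stimulusDef(nodesNear(sys, c(0, 0, 0), 1.2), 0, 2, -80)
  run <- runSimulation(sys, 60, list(stim), config = cfg,
                       snapshotNodes = seq_along(sys@mass), snapshotDt = 2)
  torso <- buildPhantomTorso(size = c(60, 60, 60), h = 10,
                             heartCenter = c(30, 30, 30),
                             heartSize = c(12, 12, 6))
  ecg <- forwardEcg(sys, run, torso, heartOrigin = c(27, 27, 29.4))
  expect_equal(colnames(ecg$leads), paste0("V", 1:6))
  expect_true(all(is.finite(ecg$leads)))
  # depolarization must generate signal on the body surface
  expect_gt(max(abs(ecg$leads)), 1e-6)
  expect_equal(unname(compareEcg(ecg, ecg)), rep(1, 6))
})
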