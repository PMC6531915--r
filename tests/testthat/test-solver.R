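test_that("diffusion operator is symmetric with constants in its null space", {
  g <- buildFixture("slab", size = c(4, 4, 2), dx = 0.4)
  g <- assignFibers(g, helixEndo = 40, helixEpi = -50)
  sys <- assembleDiffusion(g)
  K <- sys@K
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12)
  expect_lt(max(abs(K %*% rep(1, nrow(K)))), 1e-10)
  expect_lt(max(abs(Matrix::t(rep(1, nrow(K))) %*% K)), 1e-10)
})

test_that("assembly matches a brute-force element-by-element oracle on 3x3x3", {
  g <- ivtlab:::.new_grid(c(3, 3, 3), dx = 0.5)
  set.seed(42)
  th <- runif(27, 0, 2 * pi); ph <- runif(27, -1, 1)
  g@fiber <- cbind(sqrt(1 - ph^2) * cos(th), sqrt(1 - ph^2) * sin(th), ph)
  g@sigma <- cbind(runif(27, 0.1, 0.3), runif(27, 0.01, 0.1))
  sys <- assembleDiffusion(g)
  # oracle: dense assembly via explicit nodal-quadrature loops
  en <- ivtlab:::.elem_nodes(c(3L, 3L, 3L))
  hg <- ivtlab:::.hex_gradients(0.5, "fd")
  n <- 64
  Kd <- matrix(0, n, n)
  for (e in 1:27) {
    f <- g@fiber[e, ]
    D <- g@sigma[e, 2] * diag(3) + (g@sigma[e, 1] - g@sigma[e, 2]) *
      tcrossprod(f)
    for (B in hg$B) {
      Ke <- hg$w * t(B) %*% D %*% B
      Kd[en[e, ], en[e, ]] <- Kd[en[e, ], en[e, ]] + Ke
    }
  }
  expect_lt(max(abs(as.matrix(sys@K) - Kd)), 1e-12)
})

test_that("an element walled off by scar has no coupling to its surroundings", {
  g <- ivtlab:::.new_grid(c(5, 5, 1), dx = 0.4)
  lab <- array(1L, c(5, 5, 1))
  lab[2:4, 2:4, 1] <- 2L  # scar ring
  lab[3, 3, 1] <- 1L      # isolated conducting core
  g@label <- as.integer(as.vector(lab))
  g <- applyConductivities(g)
  sys <- assembleDiffusion(g)
  core <- which(sys@coords[, 1] >= 0.8 - 1e-9 & sys@coords[, 1] <= 1.2 + 1e-9 &
                sys@coords[, 2] >= 0.8 - 1e-9 & sys@coords[, 2] <= 1.2 + 1e-9)
  K <- as.matrix(sys@K)
  outside <- setdiff(seq_len(nrow(K)), core)
  expect_true(all(K[core, outside] == 0))
})

test_that("non-unit fibers on conducting elements are rejected", {
  g <- smallStrand()
  g@fiber[3, ] <- c(2, 0, 0)
  expect_error(assembleDiffusion(g), "unit")
})

test_that("with negligible coupling a stimulated node reproduces the single cell", {
  g <- smallStrand(length_mm = 2)
  g <- applyConductivities(g, healthy = c(1e-9, 1e-10))
  sys <- assembleDiffusion(g)
  run <- runSimulation(sys, 350, list(stimulusDef(1L, 0, 1, -52)),
                       config = tissueConfig(), probes = 1L, probeDt = 0.5)
  cell <- paceSingleCell(derivePhenotype("epi"), bcl = 350, nBeats = 1,
                         stimAmp = -52, stimDur = 1)
  expect_lt(max(abs(run@probeV[, 1] - cell$Vm_mV)), 1)
})

test_that("an unstimulated healthy tissue stays quiescent", {
  g <- buildFixture("slab", size = c(6, 6, 1.2), dx = 0.4)
  sys <- assembleDiffusion(g)
  run <- runSimulation(sys, 1000, config = tissueConfig(),
                       probes = seq_len(length(sys@mass)), probeDt = 500)
  rmp <- restingState("myocyte")[["Vm"]]
  expect_lt(max(abs(run@probeV[nrow(run@probeV), ] - rmp)), 1)
})

test_that("identical runs are bit-identical and dt halving moves LAT < 2%", {
  g <- smallStrand(length_mm = 10)
  sys <- assembleDiffusion(g)
  stim <- stimulusDef(which(sys@coords[, 1] < 0.5), 0, 2, -80)
  probe <- which(sys@coords[, 1] == 8 & sys@coords[, 2] == 0 &
                 sys@coords[, 3] == 0)
  r1 <- runSimulation(sys, 40, list(stim), config = tissueConfig(),
                      windows = c(0, 40))
  r2 <- runSimulation(sys, 40, list(stim), config = tissueConfig(),
                      windows = c(0, 40))
  expect_identical(r1@lat, r2@lat)
  r3 <- runSimulation(sys, 40, list(stim),
                      config = tissueConfig(dt = 0.01), windows = c(0, 40))
  expect_lt(abs(r3@lat[probe, 1] - r1@lat[probe, 1]) / r1@lat[probe, 1],
            0.02)
})

test_that("quadrupling sigma_l doubles longitudinal CV within 10%", {
  # continuum-limit property: measured on a finer grid so that lattice
  # slowing does not distort the weaker-conductivity case
  cv1 <- ivtlab:::.strand_cv(c(0.06, 0.01), chiCm = CHI_CM, cvMin = 0.15,
                             length_mm = 24, dx = 0.2)
  cv2 <- ivtlab:::.strand_cv(c(0.24, 0.01), chiCm = CHI_CM, cvMin = 0.3,
                             length_mm = 24, dx = 0.2)
  expect_equal(cv2 / cv1, 2, tolerance = 0.1)
})

test_that("planar-wave CV is independent of the measurement span", {
  g <- smallStrand(length_mm = 24)
  sys <- assembleDiffusion(g)
  stim <- stimulusDef(which(sys@coords[, 1] < 0.5), 0, 2, -80)
  run <- runSimulation(sys, 60, list(stim), config = tissueConfig(),
                       windows = c(0, 60))
  node <- function(x) which(sys@coords[, 1] == x & sys@coords[, 2] == 0 &
                            sys@coords[, 3] == 0)
  cvShort <- measureCV(run, sys, node(10), node(14))
  cvLong <- measureCV(run, sys, node(8), node(16))
  expect_equal(cvShort, cvLong, tolerance = 0.01)
  # a non-captured site reports block
  rEarly <- runSimulation(sys, 5, list(stim), config = tissueConfig(),
                          windows = c(0, 5))
  expect_error(measureCV(rEarly, sys, node(10), node(14)), "block")
})

test_that("online LAT/APD maps match an independent scan of stored Vm", {
  g <- smallStrand(length_mm = 8)
  sys <- assembleDiffusion(g)
  stim <- stimulusDef(which(sys@coords[, 1] < 0.5), 0, 2, -80)
  run <- runSimulation(sys, 400, list(stim), config = tissueConfig(),
                       windows = c(0, 400),
                       snapshotNodes = seq_along(sys@mass),
                       snapshotDt = 0.02)
  maps <- computeLatApdMaps(run, c(0, 400))
  expect_equal(maps$lat, unname(latMap(run)), tolerance = 1e-8)
  # the on-line tracker keeps single-precision thresholds; the slow tail
  # of repolarization turns those ~0.03 mV into sub-millisecond shifts
  expect_lt(max(abs(maps$apd - apdMap(run))), 1)
  # LAT increases monotonically along the strand
  ix <- order(sys@coords[, 1])
  lat <- latMap(run)[ix]
  expect_true(all(diff(lat[!duplicated(sys@coords[ix, 1])]) > 0))
})

test_that("fibrosis stabilization reaches a quiescent reusable state", {
  g <- buildFixture("isthmus_sheet", size = c(16, 16), dx = 0.8,
                    scarSize = c(8, 6), mouthLower = 1.6, mouthUpper = 3.2,
                    rimWidth = 2.4, tailLength = 0)
  g <- assignFibrosis(g, 30)
  sys <- assembleDiffusion(g, bzRemodeled = TRUE)
  expect_gt(sum(sys@nodeType == 6L), 0)
  st <- stabilizeFibrosis(sys, tissueConfig(), duration = 1000)
  expect_true(st$quiescent)
  # the stabilized state is a fixed point: another second changes little
  again <- runSimulation(sys, 1000, config = tissueConfig(),
                         init = st$state,
                         probes = seq_along(sys@mass), probeDt = 500)
  drift <- max(abs(again@probeV[nrow(again@probeV), ] - again@probeV[1, ]))
  expect_lt(drift, 0.5)
  # myocyte nodes adjacent to fibrosis sit at an elevated resting potential
  myo <- which(sys@nodeType < 6L)
  vm <- st$state[myo, 1]
  fib <- which(sys@nodeType == 6L)
  d2fib <- vapply(myo, function(i)
    min(colSums((t(sys@coords[fib, , drop = FALSE]) - sys@coords[i, ])^2)),
    numeric(1))
  near <- vm[d2fib <= 0.8^2]
  far <- vm[d2fib >= 36]
  expect_gt(mean(near), mean(far) + 0.5)
})
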