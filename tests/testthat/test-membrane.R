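test_that("phenotype derivation applies the border-zone scalings from base values", {
  healthy <- derivePhenotype("epi", remodeled = FALSE)
  expect_equal(unname(healthy@scalings), rep(1, 4))
  rem <- derivePhenotype("epi", remodeled = TRUE)
  expect_equal(unname(rem@scalings), c(0.38, 0.31, 0.30, 0.20))
  # idempotent: always scales from the published base set
  expect_identical(derivePhenotype("epi", TRUE)@scalings, rem@scalings)
  expect_error(derivePhenotype("midwall"), "arg")
})

test_that("resting myocyte is near a fixed point and stimulus depolarizes", {
  s <- restingState("myocyte")
  ds <- myocyteRhs(s, derivePhenotype("epi"))
  # published initial condition sits close to (not exactly at) rest
  expect_lt(abs(ds[["Vm"]]), 0.1)
  dsStim <- myocyteRhs(s, derivePhenotype("epi"), istim = -52)
  expect_gt(dsStim[["Vm"]], 10)
  expect_error(myocyteRhs(replace(s, 1, NaN), derivePhenotype("epi")),
               "finite")
})

test_that("unstimulated integration drifts less than 1 mV over 5 s", {
  tr <- paceSingleCell(derivePhenotype("epi"), bcl = 5000, nBeats = 1,
                       stimAmp = 0, allBeats = TRUE)
  expect_lt(max(tr$Vm_mV) - min(tr$Vm_mV), 1)
})

test_that("gates stay in [0,1] through a paced action potential", {
  res <- ivtlab:::.cpp_pace_cell(numeric(0), 2L, rep(1, 4), 500, 2, 0,
                                 0.02, -52, 1, 10L, 0.2, 50L)
  gates <- res$state[, 2:13]
  expect_true(all(gates >= -1e-9 & gates <= 1 + 1e-9))
})

test_that("biomarkers handle analytic and degenerate traces", {
  t <- seq(0, 500, by = 0.5)
  v <- ifelse(t >= 10 & t < 310, 15, -85)
  bm <- computeBiomarkers(data.frame(time_ms = t, Vm_mV = v))
  expect_equal(bm$APD90, 300, tolerance = 0.01)
  expect_equal(bm$APA, 100)
  expect_equal(bm$RMP, -85)

  flat <- computeBiomarkers(data.frame(time_ms = t, Vm_mV = rep(-85, length(t))))
  expect_true(is.na(flat$APD90))
  expect_equal(flat$RMP, -85)
})

test_that("zero-amplitude stimulus yields no action potential", {
  tr <- paceSingleCell(derivePhenotype("epi"), bcl = 400, nBeats = 1,
                       stimAmp = 0)
  expect_false(attr(tr, "capture"))
  expect_lt(max(tr$Vm_mV), -80)
})

test_that("pacing reaches steady state: last two beats differ by < 1 ms APD90", {
  ph <- derivePhenotype("epi")
  st <- attr(paceSingleCell(ph, bcl = 800, nBeats = 19), "final")
  b19 <- paceSingleCell(ph, bcl = 800, nBeats = 1, init = st)
  b20 <- paceSingleCell(ph, bcl = 800, nBeats = 1,
                        init = attr(b19, "final"))
  a1 <- computeBiomarkers(b19)$APD90
  a2 <- computeBiomarkers(b20)$APD90
  expect_lt(abs(a1 - a2), 1)
})

test_that("remodeling prolongs APD90 and reduces upstroke and amplitude", {
  cmp <- runCellComparison(layer = "epi", bcl = 800, nBeats = 8)
  healthy <- cmp[!cmp$remodeled, ]
  rem <- cmp[cmp$remodeled, ]
  expect_gt(rem$APD90, healthy$APD90)
  expect_lt(rem$dVdt_max, healthy$dVdt_max)
  expect_lt(rem$APA, healthy$APA)
})

test_that("production integrator matches the RK4 small-step oracle within 1 mV", {
  for (layer in c("endo", "M", "epi")) for (rem in c(FALSE, TRUE)) {
    ph <- derivePhenotype(layer, rem)
    st <- attr(paceSingleCell(ph, bcl = 800, nBeats = 3), "final")
    a <- paceSingleCell(ph, bcl = 800, nBeats = 1, init = st)
    b <- paceSingleCellRK4(ph, bcl = 800, nBeats = 1, init = st,
                           dt = 0.001)
    expect_lt(max(abs(a$Vm_mV - b$Vm_mV)), 1)
    bm <- computeBiomarkers(a)
    bmO <- computeBiomarkers(b)
    expect_lt(abs(bm$APD90 - bmO$APD90), 1)
    expect_lt(abs(bm$Vpeak - bmO$Vpeak), 0.5)
  }
})

test_that("resting fibroblast is a fixed point with RMP near -50 mV", {
  rest <- ivtlab:::.cpp_relax_fibroblast(numeric(0), 5000, 0.05)
  ds <- fibroblastRhs(rest)
  expect_lt(abs(ds[["Vf"]]), 1e-3)
  expect_gt(rest[1], -60)
  expect_lt(rest[1], -40)
})

test_that("fibroblast coupling raises myocyte RMP and shortens APD90, monotonically", {
  cmp <- runCouplingComparison(ggap = c(0, 1.5, 4), nBeats = 4)
  expect_true(all(diff(cmp$APD90) < 0))
  expect_true(all(diff(cmp$RMP) > 0))
})

test_that("vanishing coupling conductance recovers the uncoupled myocyte", {
  ph <- derivePhenotype("epi")
  un <- paceSingleCell(ph, bcl = 600, nBeats = 2)
  co <- paceCoupledPair(ph, ggap = 1e-9, bcl = 600, nBeats = 2)
  expect_lt(max(abs(un$Vm_mV - co$Vm_mV)), 0.01)
})
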