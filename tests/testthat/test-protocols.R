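test_that("sinus schedules fire at LAT offsets from the earliest site", {
  sch <- buildSinusSchedule(data.frame(site = c("a", "b", "c"),
                                       lat = c(12, 5, 30)),
                            bcl = 800, nBeats = 6)
  expect_equal(sch$offsets$offset, c(7, 0, 25))
  tt <- sinusTimes(sch)
  expect_equal(min(tt$time), 0)
  expect_equal(max(tt$time[tt$site == "b"]), 5 * 800 - 5 + 5)
  expect_equal(min(tt$time[tt$beat == 5]), 4000)
  one <- buildSinusSchedule(data.frame(site = 1, lat = 99), nBeats = 1)
  expect_equal(sinusTimes(one)$time, 0)
  expect_error(buildSinusSchedule(data.frame(site = c(1, 1),
                                             lat = c(0, 10))),
               "conflicting")
})

test_that("PES expansion follows the drive-train arithmetic", {
  p <- pesProtocol()
  expect_equal(expandPes(p, 400), c(0, 600, 1200, 1800, 2400, 3000, 3400))
  expect_equal(tail(expandPes(p, 360, stage = "S3"), 2), c(3360, 3720))
  cis <- ciSequence(p)
  expect_equal(head(cis, 3), c(400, 390, 380))
  expect_true(all(diff(cis) == -10))
  expect_error(pesProtocol(ciStep = 0))
})

test_that("reentry detection distinguishes sustained trains from echoes", {
  # constructed activation train with period 300 ms after the stimulus
  det <- detectReentry(c(100, 500, 800, 1100, 1400), lastStimTime = 100,
                       minCycles = 3)
  expect_true(det$sustained)
  expect_equal(det$vtBcl, 300)
  # activity that extinguishes right after the last stimulus
  det2 <- detectReentry(c(100, 180), lastStimTime = 100)
  expect_false(det2$sustained)
  expect_equal(bclToBpm(526), 114)
  expect_equal(bclToBpm(506), 119)
})

test_that("the model-version enumeration has the study's 8 rows", {
  v <- modelVersions()
  expect_equal(nrow(v), 8)
  expect_equal(v$fibrosis, rep(c(0, 10, 20, 30), 2))
  expect_equal(v$er, rep(c(FALSE, TRUE), each = 4))
  expect_false(anyDuplicated(v$version) > 0)
})

test_that("inducibility results validate their invariants", {
  expect_error(new("InducibilityResult", outcome = "VT", stage = "none",
                   ci = 360, vtBcl = 526, vtRate = 114,
                   blockType = "unidirectional",
                   events = data.frame()),
               "stage")
  expect_error(new("InducibilityResult", outcome = "VT", stage = "S2",
                   ci = 360, vtBcl = 526, vtRate = 120,
                   blockType = "unidirectional", events = data.frame()),
               "vtRate")
  ok <- new("InducibilityResult", outcome = "VT", stage = "S2", ci = 360,
            vtBcl = 526, vtRate = 114, blockType = "unidirectional",
            events = data.frame())
  expect_equal(ok@vtRate, 114)
})

test_that("a healthy slab is non-inducible at every coupling interval", {
  g <- buildFixture("slab", size = c(9.6, 9.6, 0.8), dx = 0.8)
  sys <- assembleDiffusion(g)
  pac <- nodesNear(sys, c(1, 1, 0.4), 1)
  prot <- pesProtocol(s1Count = 2L, s1Bcl = 500, ciStart = 340,
                      ciStep = 40, ciMin = 260, s3 = FALSE)
  res <- runInducibilityTest(sys, pac, prot,
                             tissueConfig(dt = 0.05, cgTol = 1e-5),
                             observe = 500)
  expect_equal(res@outcome, "no_VT")
  expect_equal(res@stage, "none")
  # the CI loop terminated (finite attempts, all logged)
  expect_true(all(grepl("CI", eventLog(res)$detail[
    eventLog(res)$event == "S2-attempt"])))
})

test_that("the inducibility matrix wires versions, fibrosis and stabilization", {
  g <- buildFixture("isthmus_sheet", size = c(16, 16), dx = 0.8,
                    scarSize = c(8, 6), mouthLower = 1.6, mouthUpper = 3.2,
                    rimWidth = 2.4, tailLength = 0)
  tab <- inducibilityMatrix(
    g, pacingSites = list(south = c(8, 2, 0.4)),
    protocol = pesProtocol(s1Count = 1L, ciStart = 320, ciStep = 10,
                           ciMin = 320, s3 = FALSE),
    config = solverConfig(dt = 0.05, chiCm = 2.17, cgTol = 1e-5),
    versions = modelVersions()[2, ],  # 10% fibrosis, no remodeling
    observe = 300)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$south, "no VT")
  res <- attr(tab, "results")[[1]]
  expect_s4_class(res, "InducibilityResult")
  expect_true(any(grepl("S2-attempt", eventLog(res)$event)))
})
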