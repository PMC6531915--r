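# Desk-scale experiment orchestration: the conduction-velocity
# calibration suite, single-cell remodeling comparison, fibroblast
# coupling check, the fixture inducibility matrix and the phantom-torso
# ECG smoke test, with seeds and JSON reports.

#' Run the conduction-velocity calibration suite
#'
#' Step 0 calibrates chi * Cm once against the healthy along-fiber
#' target; every subsequent row is a prediction with the product frozen:
#' healthy transverse; border-zone longitudinal and transverse with
#' (0.05, 0.01) S/m under the remodeled and the original membrane; and
#' the two alternative border-zone conductivity sets (0.12, 0.03) and
#' (0.22, 0.0485) S/m with percent CV reductions relative to healthy.
#' Each measurement is one planar-wave simulation on a pseudo-1D strand
#' at 0.4 mm resolution.
#'
#' @param chiCm optional frozen chi * Cm product; calibrated when NULL.
#' @param dx,dt discretization (mm, ms).
#' @param targetCv calibration target for healthy longitudinal CV (m/s).
#' @return data.frame of measurements (m/s) with attributes
#'   \code{chiCm} and \code{reductions} (percent, for the alternative
#'   BZ conductivity sets).
#' @export
runCvSuite <- function(chiCm = NULL, dx = 0.4, dt = 0.02, targetCv = 0.68) {
  if (is.null(chiCm)) {
    cal <- calibrateChiCm(target = targetCv, dx = dx, dt = dt)
    chiCm <- cal$chiCm
  }
  sets <- conductivitySets()
  f <- function(sigma, bz, rem, axis, cvMin)
    .strand_cv(sigma, bzLabel = bz, remodeled = rem, fiberAxis = axis,
               chiCm = chiCm, dx = dx, dt = dt, cvMin = cvMin)
  rows <- list(
    healthy_long = list(sets$healthy, FALSE, FALSE, "x", 0.25),
    healthy_trans = list(sets$healthy, FALSE, FALSE, "y", 0.1),
    bz_remodeled_long = list(sets$bz75, TRUE, TRUE, "x", 0.06),
    bz_remodeled_trans = list(sets$bz75, TRUE, TRUE, "y", 0.012),
    bz_original_long = list(sets$bz75, TRUE, FALSE, "x", 0.08),
    bz_original_trans = list(sets$bz75, TRUE, FALSE, "y", 0.02),
    bz50_remodeled_long = list(sets$bz50, TRUE, TRUE, "x", 0.1),
    bz25_remodeled_long = list(sets$bz25, TRUE, TRUE, "x", 0.15))
  cv <- vapply(rows, function(r) {
    tryCatch(f(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]]),
             error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(measurement = names(rows),
                    sigma_l = vapply(rows, function(r) r[[1]][1], numeric(1)),
                    sigma_t = vapply(rows, function(r) r[[1]][2], numeric(1)),
                    membrane = ifelse(vapply(rows, function(r) r[[3]],
                                             logical(1)),
                                      "remodeled", "original"),
                    direction = ifelse(vapply(rows, function(r) r[[4]],
                                              character(1)) == "x",
                                       "longitudinal", "transverse"),
                    cv_m_per_s = unname(cv))
  red <- c(bz50 = 100 * (1 - cv[["bz50_remodeled_long"]] /
                           cv[["healthy_long"]]),
           bz25 = 100 * (1 - cv[["bz25_remodeled_long"]] /
                           cv[["healthy_long"]]))
  attr(out, "chiCm") <- chiCm
  attr(out, "reductions") <- red
  out
}

#' Single-cell remodeling comparison
#'
#' Paces healthy and remodeled cells of one transmural layer to steady
#' state at a fixed cycle length and reports their biomarkers: the
#' border-zone remodeling prolongs APD90 and reduces the upstroke
#' velocity and amplitude.
#'
#' @param layer transmural layer.
#' @param bcl cycle length (ms).
#' @param nBeats pre-pacing beats.
#' @return data.frame with one row per phenotype and biomarker columns.
#' @export
runCellComparison <- function(layer = "epi", bcl = 800, nBeats = 20) {
  out <- lapply(c(FALSE, TRUE), function(rem) {
    tr <- paceSingleCell(derivePhenotype(layer, rem), bcl = bcl,
                         nBeats = nBeats)
    bm <- computeBiomarkers(tr)
    data.frame(layer = layer, remodeled = rem, APD90 = bm$APD90,
               APA = bm$APA, RMP = bm$RMP, dVdt_max = bm$dVdt_max,
               Vpeak = bm$Vpeak)
  })
  do.call(rbind, out)
}

#' Myocyte-fibroblast coupling comparison
#'
#' @param ggap gap conductances to test (nS); 0 is the uncoupled
#'   reference.
#' @param layer,bcl,nBeats pacing setup.
#' @return data.frame of biomarkers per coupling conductance.
#' @export
runCouplingComparison <- function(ggap = c(0, 3), layer = "epi", bcl = 800,
                                  nBeats = 6) {
  out <- lapply(ggap, function(g) {
    tr <- paceCoupledPair(derivePhenotype(layer), ggap = g, bcl = bcl,
                          nBeats = nBeats)
    bm <- computeBiomarkers(tr[, c("time_ms", "Vm_mV")])
    data.frame(ggap_nS = g, APD90 = bm$APD90, RMP = bm$RMP, APA = bm$APA)
  })
  do.call(rbind, out)
}

#' Fixture defaults for the inducibility experiment
#'
#' The shipped isthmus-sheet substrate and its standard pacing and
#' landmark coordinates: the pacing site sits just below the narrow
#' (lower) channel mouth, the reference/mouth landmarks at the two
#' channel ends.
#'
#' @param dx element edge (mm).
#' @param seed pseudo-intensity seed.
#' @return list with \code{grid}, \code{pacingSites},
#'   \code{mouthPoints}.
#' @export
isthmusExperimentSetup <- function(dx = 0.8, seed = 7L) {
  g <- buildFixture("isthmus_sheet", size = c(44, 48), dx = dx, seed = seed)
  size <- g@dims * dx
  cx <- size[1] / 2; cy <- size[2] / 2
  scarH <- 22; tail <- 6
  list(grid = g,
       pacingSites = list(
         mouth_lower = c(cx, cy - scarH / 2 - tail - 3.2, dx / 2),
         lateral = c(4, cy, dx / 2)),
       mouthPoints = list(
         lower = c(cx, cy - scarH / 2 + 1.2, dx / 2),
         upper = c(cx, cy + scarH / 2 - 1.2, dx / 2)))
}

#' Run the fixture inducibility experiment
#'
#' Builds the isthmus-sheet fixture and runs the PES loop for the
#' requested model versions from the standard pacing site(s), producing
#' the study-shaped inducibility table.
#'
#' @param versions rows of [modelVersions()] to run (default all 8).
#' @param sites names of pacing sites to use.
#' @param protocol,config,observe,minCycles see [inducibilityMatrix()].
#' @param dx fixture resolution (mm).
#' @param seed pseudo-intensity seed.
#' @return the [inducibilityMatrix()] table.
#' @export
runInducibilityExperiment <- function(versions = modelVersions(),
                                      sites = "mouth_lower",
                                      protocol = pesProtocol(),
                                      config = solverConfig(),
                                      observe = 1800, minCycles = 3,
                                      dx = 0.8, seed = 7L) {
  setup <- isthmusExperimentSetup(dx = dx, seed = seed)
  inducibilityMatrix(setup$grid, setup$pacingSites[sites],
                     protocol = protocol, config = config,
                     versions = versions, mouthPoints = setup$mouthPoints,
                     observe = observe, minCycles = minCycles)
}

#' ECG smoke test on the phantom torso
#'
#' Runs one paced beat on a small healthy slab, computes the forward ECG
#' through the box phantom torso and reports basic signal statistics.
#' Qualitative by design: the patient-specific anatomy of the source
#' study is out of scope.
#'
#' @param config a [solverConfig()].
#' @return list with \code{ecg} (ECGSet) and \code{correlationSelf}
#'   (per-lead self-correlation after a resampling round trip; equals 1
#'   up to interpolation error).
#' @export
runEcgSmoke <- function(config = solverConfig(chiCm = 2.17)) {
  g <- buildFixture("slab", size = c(8, 8, 2.4), dx = 0.4)
  sys <- assembleDiffusion(g)
  stim <- stimulusDef(nodesNear(sys, c(0, 0, 0), 1.2), 0, 2, -80)
  run <- runSimulation(sys, 120, list(stim), config = config,
                       snapshotNodes = seq_along(sys@mass), snapshotDt = 2)
  torso <- buildPhantomTorso()
  ecg <- forwardEcg(sys, run, torso, heartOrigin = c(51, 26, 72.8))
  self <- compareEcg(ecg, ecg, resample = TRUE)
  list(ecg = ecg, correlationSelf = self)
}

#' Aggregate experiment artifacts into a run report
#'
#' @param artifacts named list of result objects or file paths produced
#'   by the experiment functions.
#' @param seed RNG seed used for the run.
#' @param file optional path; when given the report is written as JSON.
#' @return list with \code{metrics}, \code{provenance} (config hash,
#'   seed, package version) and \code{artifacts}.
#' @export
makeReport <- function(artifacts, seed = NA_integer_, file = NULL) {
  if (!length(artifacts)) stop("no artifacts to report")
  if (is.null(names(artifacts)) || any(names(artifacts) == ""))
    stop("artifacts must be named")
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    if (is.character(a) && length(a) == 1 && !file.exists(a))
      stop("missing artifact file: ", a)
  }
  metrics <- lapply(artifacts, function(a) {
    if (is.data.frame(a)) a
    else if (is.list(a) && !is.object(a)) a
    else if (is.character(a)) list(path = a)
    else as.character(class(a))
  })
  hash <- sum(utf8ToInt(paste(names(artifacts), collapse = "|"))) +
    (if (is.na(seed)) 0 else seed)
  report <- list(metrics = metrics,
                 provenance = list(
                   configHash = sprintf("%08x", as.integer(hash %% 2^31)),
                   seed = seed,
                   package = as.character(utils::packageVersion("ivtlab"))),
                 artifacts = names(artifacts))
  if (!is.null(file))
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  report
}
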