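# Stimulation protocols: LAT-driven sinus schedules, the S1-S2(-S3)
# programmed-electrical-stimulation loop with coupling-interval
# decrement, reentry detection and the model-version x pacing-site
# inducibility matrix.

#' Build a multi-site sinus stimulation schedule from LAT annotations
#'
#' The site with the earliest local activation time fires at t = 0; every
#' other site fires at its LAT offset relative to that site, repeated
#' every cycle.
#'
#' @param points data.frame with columns \code{site} (identifier or node
#'   index) and \code{lat} (ms).
#' @param bcl basic cycle length (ms).
#' @param nBeats number of beats.
#' @return list of class \code{SinusSchedule} with \code{offsets}
#'   data.frame, \code{bcl}, \code{nBeats} and a \code{times()} helper
#'   evaluated via [sinusTimes()].
#' @export
buildSinusSchedule <- function(points, bcl = 800, nBeats = 6) {
  stopifnot(nrow(points) >= 1, all(c("site", "lat") %in% names(points)))
  if (anyDuplicated(points$site)) {
    sp <- split(points$lat, points$site)
    if (any(vapply(sp, function(x) length(unique(x)) > 1, logical(1))))
      stop("duplicate sites with conflicting LATs")
    points <- points[!duplicated(points$site), ]
  }
  off <- points$lat - min(points$lat)
  structure(list(offsets = data.frame(site = points$site, offset = off),
                 bcl = bcl, nBeats = as.integer(nBeats)),
            class = "SinusSchedule")
}

#' Stimulus times of a sinus schedule
#'
#' @param schedule a [buildSinusSchedule()] result.
#' @return data.frame with \code{site}, \code{beat} (0-based) and
#'   \code{time} (ms).
#' @export
sinusTimes <- function(schedule) {
  stopifnot(inherits(schedule, "SinusSchedule"))
  beats <- seq_len(schedule$nBeats) - 1L
  out <- do.call(rbind, lapply(beats, function(k)
    data.frame(site = schedule$offsets$site, beat = k,
               time = schedule$offsets$offset + k * schedule$bcl)))
  out[order(out$time, out$site), ]
}

#' Programmed-electrical-stimulation protocol definition
#'
#' The clinical protocol: a drive train of S1 stimuli, then a premature
#' S2 whose coupling interval is decremented until VT induction or
#' capture failure at the pacing site; if S2 alone never induces, the
#' loop is repeated with an added S3 coupled at the same interval as S2.
#'
#' @param s1Count number of S1 stimuli.
#' @param s1Bcl S1 cycle length (ms).
#' @param ciStart initial S2 coupling interval (ms).
#' @param ciStep coupling-interval decrement (ms, > 0).
#' @param ciMin safety floor for the coupling interval (ms).
#' @param s3 enable the S3 phase after S2-only exhaustion?
#' @export
pesProtocol <- function(s1Count = 6L, s1Bcl = 600, ciStart = 400,
                        ciStep = 10, ciMin = 150, s3 = TRUE) {
  stopifnot(s1Count >= 1, s1Bcl > 0, ciStart > 0, ciStep > 0)
  structure(list(s1Count = as.integer(s1Count), s1Bcl = s1Bcl,
                 ciStart = ciStart, ciStep = ciStep, ciMin = ciMin,
                 s3 = isTRUE(s3)),
            class = "PESProtocol")
}

#' Expand a PES protocol into stimulus times
#'
#' @param protocol a [pesProtocol()].
#' @param ci coupling interval for the premature stimuli (ms).
#' @param stage "S2" (drive + one extra) or "S3" (drive + two extras at
#'   equal coupling).
#' @return numeric stimulus onset times (ms).
#' @examples
#' expandPes(pesProtocol(), 400)  # 0, 600, ..., 3000, 3400
#' @export
expandPes <- function(protocol, ci, stage = c("S2", "S3")) {
  stage <- match.arg(stage)
  stopifnot(ci > 0)
  s1 <- (seq_len(protocol$s1Count) - 1) * protocol$s1Bcl
  lastS1 <- s1[length(s1)]
  times <- c(s1, lastS1 + ci)
  if (stage == "S3") times <- c(times, lastS1 + 2 * ci)
  times
}

#' Coupling-interval sequence of the PES loop
#'
#' @param protocol a [pesProtocol()].
#' @return decreasing CI values from \code{ciStart} by \code{ciStep}
#'   down to \code{ciMin}.
#' @export
ciSequence <- function(protocol) {
  seq(protocol$ciStart, protocol$ciMin, by = -protocol$ciStep)
}

#' Detect sustained reentry from activation-crossing times
#'
#' A run is classified as sustained reentrant activity when a reference
#' node shows at least \code{minCycles} full activations after the last
#' stimulus, with no stimulus support. The VT cycle length is the mean
#' inter-activation interval over the detected cycles.
#'
#' @param crossTimes numeric vector of 0 mV upstroke-crossing times at a
#'   reference node (ms).
#' @param lastStimTime time of the last delivered stimulus (ms).
#' @param minCycles activations required beyond the last paced response.
#' @param margin time after the last stimulus within which an activation
#'   is attributed to pacing rather than reentry (ms).
#' @return list with \code{sustained} (logical), \code{vtBcl} (ms) and
#'   \code{cycles} (count of unsupported activations).
#' @export
detectReentry <- function(crossTimes, lastStimTime, minCycles = 3,
                          margin = 150) {
  post <- crossTimes[crossTimes > lastStimTime + margin]
  sustained <- length(post) >= minCycles
  vtBcl <- if (length(post) >= 2) mean(diff(post)) else NA_real_
  list(sustained = sustained, vtBcl = vtBcl, cycles = length(post))
}

#' Convert a VT cycle length to a rate
#' @param bcl cycle length (ms).
#' @return rate in beats per minute, rounded.
#' @export
bclToBpm <- function(bcl) round(60000 / bcl)

#' Enumerate the border-zone model versions
#'
#' The eight combinations of electrical remodeling (off/on) with 0, 10,
#' 20 and 30% image-based patchy fibrosis, in the study's order.
#'
#' @return data.frame with \code{version}, \code{fibrosis} (percent) and
#'   \code{er} (logical).
#' @export
modelVersions <- function() {
  data.frame(version = paste0("#", 1:8),
             fibrosis = rep(c(0, 10, 20, 30), 2),
             er = rep(c(FALSE, TRUE), each = 4))
}

# run one PES attempt (one stage, one CI) from a pre-paced state
.pes_attempt <- function(system, config, state, tLastS1, stimNodes, protocol,
                         ci, stage, refNodes, mouthNodes, observe) {
  times <- if (stage == "S2") tLastS1 + ci else tLastS1 + c(ci, 2 * ci)
  stims <- c(list(stimulusDef(stimNodes, tLastS1, 2, -80)),
             lapply(times, function(tt) stimulusDef(stimNodes, tt, 2, -80)))
  lastStim <- max(times)
  dur <- (lastStim - tLastS1) + observe
  watch <- c(stimNodes[1], refNodes,
             if (!is.null(mouthNodes)) unlist(mouthNodes))
  run <- runSimulation(system, dur, stims, config = config, t0 = tLastS1,
                       init = state, watch = watch)
  names(run@crossings) <- NULL
  list(run = run, lastStim = lastStim,
       siteCross = run@crossings[[1]],
       refCross = run@crossings[1 + seq_along(refNodes)],
       mouthCross = if (!is.null(mouthNodes))
         run@crossings[1 + length(refNodes) + seq_along(unlist(mouthNodes))]
       else NULL)
}

#' Run a programmed-stimulation inducibility test
#'
#' Implements the clinical loop: after the S1 drive train, an S2 coupling
#' interval starting at \code{ciStart} is decremented until sustained
#' reentry or capture failure at the pacing site; on failure without
#' induction, the loop restarts with an added S3 at equal coupling. The
#' S1 phase is simulated once and its end state reused for every
#' coupling interval.
#'
#' @param system a [MonodomainSystem-class] of the substrate (with the
#'   desired model version already applied).
#' @param pacingNodes conducting-node indices of the pacing site.
#' @param protocol a [pesProtocol()].
#' @param config a [solverConfig()].
#' @param refNodes reference nodes for reentry detection (defaults to a
#'   node far from the pacing site).
#' @param mouthNodes optional named list with \code{lower} and
#'   \code{upper} conducting-node indices at the channel mouths; enables
#'   block-type classification on isthmus fixtures.
#' @param initState initial condition (e.g. from [stabilizeFibrosis()]).
#' @param observe observation time after the last premature stimulus
#'   (ms); must cover \code{minCycles} reentrant cycles.
#' @param minCycles sustained-reentry criterion (unsupported
#'   activations).
#' @return an [InducibilityResult-class].
#' @export
runInducibilityTest <- function(system, pacingNodes, protocol = pesProtocol(),
                                config = solverConfig(), refNodes = NULL,
                                mouthNodes = NULL, initState = NULL,
                                observe = 1800, minCycles = 3) {
  stopifnot(is(system, "MonodomainSystem"))
  if (any(system@nodeType[pacingNodes] >= 6L))
    stop("pacing site is not conducting myocardium")
  if (is.null(refNodes)) {
    d2 <- colSums((t(system@coords) - system@coords[pacingNodes[1], ])^2)
    refNodes <- which.max(d2)
  }
  ev <- data.frame(time = numeric(0), event = character(0),
                   detail = character(0), stringsAsFactors = FALSE)
  logev <- function(time, event, detail) {
    ev <<- rbind(ev, data.frame(time = time, event = event, detail = detail,
                                stringsAsFactors = FALSE))
  }

  # S1 drive up to (but excluding) the last S1, simulated once
  tLastS1 <- (protocol$s1Count - 1) * protocol$s1Bcl
  driveState <- initState
  if (protocol$s1Count > 1) {
    drive <- runSimulation(system, tLastS1,
                           list(stimulusDef(pacingNodes, 0, 2, -80,
                                            period = protocol$s1Bcl,
                                            count = protocol$s1Count - 1L)),
                           config = config, init = initState,
                           watch = pacingNodes[1])
    driveState <- finalState(drive)
    logev(0, "S1", sprintf("%d drive stimuli at BCL %g ms",
                           protocol$s1Count - 1L, protocol$s1Bcl))
  }

  mouths <- if (!is.null(mouthNodes)) list(lower = mouthNodes$lower,
                                           upper = mouthNodes$upper)
  result <- NULL
  for (stage in c("S2", if (protocol$s3) "S3")) {
    for (ci in ciSequence(protocol)) {
      att <- .pes_attempt(system, config, driveState, tLastS1, pacingNodes,
                          protocol, ci, stage, refNodes, mouths, observe)
      lastStim <- att$lastStim
      # capture check at the pacing site for the final premature stimulus
      captured <- any(att$siteCross > lastStim - 1e-9 &
                      att$siteCross <= lastStim + 10)
      logev(lastStim, paste0(stage, "-attempt"),
            sprintf("CI %g ms, %s", ci,
                    if (captured) "captured" else "capture failure"))
      if (!captured) {
        logev(lastStim, "block-at-site",
              sprintf("%s capture failure at CI %g ms", stage, ci))
        break
      }
      det <- detectReentry(unlist(att$refCross), lastStim,
                           minCycles = minCycles)
      if (det$sustained) {
        bt <- "none"
        if (!is.null(mouths)) {
          bt <- .classify_block(att$mouthCross, lastStim, det$vtBcl)
          logev(lastStim, "mouth-block",
                sprintf("%s at the lower (narrow) channel mouth", bt))
        }
        logev(lastStim + det$vtBcl, "reentry",
              sprintf("sustained VT, %d unsupported cycles, BCL %.0f ms",
                      det$cycles, det$vtBcl))
        result <- new("InducibilityResult", outcome = "VT", stage = stage,
                      ci = ci, vtBcl = det$vtBcl,
                      vtRate = bclToBpm(det$vtBcl), blockType = bt,
                      events = ev)
        break
      }
    }
    if (!is.null(result)) break
  }
  if (is.null(result))
    result <- new("InducibilityResult", outcome = "no_VT", stage = "none",
                  ci = NA_real_, vtBcl = NA_real_, vtRate = NA_real_,
                  blockType = "none", events = ev)
  result
}

# classify conduction block at the channel mouths after the last
# premature stimulus: unidirectional if the lower (narrow) mouth fails to
# activate in the immediate post-stimulus window but is re-entered later
# (retrograde, after the upper mouth); bidirectional if neither mouth
# conducts again.
.classify_block <- function(mouthCross, lastStim, vtBcl) {
  lower <- mouthCross[[1]]
  upper <- mouthCross[[2]]
  win <- if (is.finite(vtBcl)) max(200, 0.6 * vtBcl) else 250
  lowerEarly <- any(lower > lastStim & lower <= lastStim + win)
  upperAny <- any(upper > lastStim)
  lowerLate <- any(lower > lastStim + win)
  if (!lowerEarly && upperAny && lowerLate) "unidirectional"
  else if (!lowerEarly && !lowerLate) "bidirectional"
  else "none"
}

#' Inducibility matrix over model versions and pacing sites
#'
#' Applies each border-zone model version (electrical remodeling off/on
#' times fibrosis 0/10/20/30%) to the substrate grid, stabilizes
#' myocyte-fibroblast couplings where fibrosis is present, and runs the
#' PES loop from each pacing site.
#'
#' @param grid a labeled [TissueGrid-class] with mapped intensities on
#'   its BZ elements (used for fibrosis ranking).
#' @param pacingSites named list of coordinates (mm) of pacing sites.
#' @param protocol a [pesProtocol()].
#' @param config a [solverConfig()].
#' @param versions subset of rows of [modelVersions()] to run (default
#'   all 8).
#' @param bz border-zone conductivity pair (S/m).
#' @param mouthPoints optional named list of \code{lower}/\code{upper}
#'   channel-mouth coordinates for block classification.
#' @param observe,minCycles see [runInducibilityTest()].
#' @return data.frame in the study's table shape: one row per version,
#'   one outcome column per pacing site, each cell "no VT" or
#'   "STAGE-CI ms BCL ms-RATE bpm"; the full
#'   [InducibilityResult-class] objects are attached as attribute
#'   \code{results}.
#' @export
inducibilityMatrix <- function(grid, pacingSites, protocol = pesProtocol(),
                               config = solverConfig(),
                               versions = modelVersions(),
                               bz = c(0.05, 0.01), mouthPoints = NULL,
                               observe = 1800, minCycles = 3) {
  out <- versions
  results <- list()
  for (site in names(pacingSites)) out[[site]] <- NA_character_
  for (vi in seq_len(nrow(versions))) {
    v <- versions[vi, ]
    gv <- assignFibrosis(grid, v$fibrosis)
    gv <- applyConductivities(gv, bz = bz)
    sys <- assembleDiffusion(gv, bzRemodeled = v$er)
    init <- NULL
    if (any(gv@label == .LABELS[["fibrosis"]]))
      init <- stabilizeFibrosis(sys, config)$state
    mouths <- NULL
    if (!is.null(mouthPoints))
      mouths <- list(lower = nodesNear(sys, mouthPoints$lower, 0.5)[1],
                     upper = nodesNear(sys, mouthPoints$upper, 0.5)[1])
    for (site in names(pacingSites)) {
      nodes <- nodesNear(sys, pacingSites[[site]], 1)
      res <- runInducibilityTest(sys, nodes, protocol, config,
                                 mouthNodes = mouths, initState = init,
                                 observe = observe, minCycles = minCycles)
      results[[paste(v$version, site, sep = ":")]] <- res
      out[vi, site] <- if (res@outcome == "VT")
        sprintf("%s-%g ms %.0f ms-%d bpm", res@stage, res@ci, res@vtBcl,
                res@vtRate)
      else "no VT"
    }
  }
  attr(out, "results") <- results
  out
}
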