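# Single-cell electrophysiology: ten Tusscher-Panfilov (2006) human
# ventricular myocyte with optional border-zone ionic remodeling, and the
# MacCannell (2007) active fibroblast.

.BZ_SCALINGS <- c(I_Na = 0.38, I_CaL = 0.31, I_Kr = 0.30, I_Ks = 0.20)

.layer_code <- function(layer) {
  if (!layer %in% names(.LAYERS)) stop("unknown layer: ", layer)
  unname(.LAYERS[layer]) - 1L  # 0-based for the compiled core
}

#' Derive a myocyte phenotype
#'
#' Returns the ionic phenotype for a transmural layer, optionally with the
#' border-zone electrical remodeling applied: the maximal conductances of
#' I_Na, I_CaL, I_Kr and I_Ks are scaled to 38%, 31%, 30% and 20% of
#' their healthy values. Scalings are always applied to the published base
#' parameter set, so the operation is idempotent.
#'
#' @param layer "endo", "M" or "epi".
#' @param remodeled apply border-zone ionic remodeling?
#' @return a [MyocytePhenotype-class].
#' @examples
#' derivePhenotype("epi", remodeled = TRUE)
#' @export
derivePhenotype <- function(layer = c("endo", "M", "epi"), remodeled = FALSE) {
  layer <- match.arg(layer)
  sc <- if (remodeled) .BZ_SCALINGS else
    c(I_Na = 1, I_CaL = 1, I_Kr = 1, I_Ks = 1)
  new("MyocytePhenotype", layer = layer, remodeled = remodeled, scalings = sc)
}

#' Resting state vectors of the membrane models
#'
#' The published resting initial condition of the ventricular myocyte
#' model (19 state variables) or of the fibroblast model (3 variables).
#'
#' @param type "myocyte" or "fibroblast".
#' @return named numeric state vector.
#' @export
restingState <- function(type = c("myocyte", "fibroblast")) {
  type <- match.arg(type)
  if (type == "myocyte") {
    s <- .cpp_tp06_initial()
    names(s) <- .MYO_STATE_NAMES
  } else {
    s <- .cpp_fib_initial()
    names(s) <- .FIB_STATE_NAMES
  }
  s
}

.MYO_STATE_NAMES <- c("Vm", "m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
                      "Xr1", "Xr2", "Xs", "Rbar", "Cai", "CaSR", "CaSS",
                      "Nai", "Ki")
.FIB_STATE_NAMES <- c("Vf", "r", "s")

#' Time-derivatives of the myocyte state
#'
#' Evaluates the right-hand side of the ventricular action potential model
#' for a given state, phenotype and stimulus current. The membrane
#' equation is dVm/dt = -(sum(I_ion) + I_stim), currents in pA/pF.
#'
#' @param state numeric state vector of length 19 (see [restingState()]).
#' @param phenotype a [MyocytePhenotype-class].
#' @param istim stimulus current density (pA/pF; negative depolarizes).
#' @return named derivative vector d(state)/dt.
#' @export
myocyteRhs <- function(state, phenotype = derivePhenotype("epi"), istim = 0) {
  if (length(state) != 19) stop("state must have length 19")
  if (any(!is.finite(state))) stop("non-finite state")
  ds <- .cpp_myocyte_rhs(as.numeric(state), .layer_code(phenotype@layer),
                         unname(phenotype@scalings), istim)
  names(ds) <- .MYO_STATE_NAMES
  ds
}

#' Time-derivatives of the fibroblast state
#'
#' @param state numeric state vector of length 3 (Vf and two I_Kv gates).
#' @param icoupling coupling current density received by the fibroblast
#'   (pA/pF; positive hyperpolarizes).
#' @return named derivative vector.
#' @export
fibroblastRhs <- function(state, icoupling = 0) {
  if (length(state) != 3) stop("state must have length 3")
  if (any(!is.finite(state))) stop("non-finite state")
  ds <- .cpp_fibroblast_rhs(as.numeric(state), icoupling)
  names(ds) <- .FIB_STATE_NAMES
  ds
}

#' Pace a single myocyte and return the final-beat trace
#'
#' Paces an isolated myocyte for \code{nBeats} beats at cycle length
#' \code{bcl} with the production integrator (Rush-Larsen gate updates,
#' adaptive forward-Euler substepping for potential and concentrations)
#' and returns the trace of the final beat.
#'
#' @param phenotype a [MyocytePhenotype-class].
#' @param bcl basic cycle length (ms).
#' @param nBeats number of paced beats (>= 1).
#' @param stimAmp,stimDur stimulus amplitude (pA/pF, negative
#'   depolarizes) and duration (ms).
#' @param dt base integration step (ms).
#' @param init optional full-state initial condition (default: published
#'   resting state).
#' @param recordDt trace sampling interval (ms).
#' @param allBeats return the whole pacing run instead of the last beat.
#' @return data.frame with \code{time_ms}, \code{Vm_mV}, \code{Cai_mM}
#'   plus attributes \code{final} (state vector) and \code{capture}
#'   (logical: did the final beat elicit an action potential).
#' @examples
#' tr <- paceSingleCell(derivePhenotype("epi"), bcl = 800, nBeats = 2)
#' computeBiomarkers(tr)
#' @export
paceSingleCell <- function(phenotype, bcl = 800, nBeats = 1, stimAmp = -52,
                           stimDur = 1, dt = 0.02, init = NULL,
                           recordDt = 0.5, allBeats = FALSE) {
  stopifnot(bcl > 0, nBeats >= 1)
  stride <- max(1L, as.integer(round(recordDt / dt)))
  res <- .cpp_pace_cell(if (is.null(init)) numeric(0) else as.numeric(init),
                        .layer_code(phenotype@layer),
                        unname(phenotype@scalings), bcl, as.integer(nBeats),
                        0, dt, stimAmp, stimDur, stride, 0.2, 50L)
  keep <- if (allBeats) rep(TRUE, length(res$time)) else
    res$time >= (nBeats - 1) * bcl
  out <- data.frame(time_ms = res$time[keep] - if (allBeats) 0 else
                      (nBeats - 1) * bcl,
                    Vm_mV = res$state[keep, 1],
                    Cai_mM = res$state[keep, 15])
  fin <- res$final
  names(fin) <- .MYO_STATE_NAMES
  attr(out, "final") <- fin
  attr(out, "capture") <- max(out$Vm_mV) > 0
  if (!attr(out, "capture") && stimAmp != 0)
    attr(out, "noCapture") <- TRUE
  out
}

#' Fixed-step Runge-Kutta reference integration of a paced myocyte
#'
#' Classic fourth-order Runge-Kutta at a small fixed step on the exact
#' right-hand side (no lookup tables). Used as the independent reference
#' for integrator-accuracy checks; considerably slower than
#' [paceSingleCell()].
#'
#' @inheritParams paceSingleCell
#' @export
paceSingleCellRK4 <- function(phenotype, bcl = 800, nBeats = 1, stimAmp = -52,
                              stimDur = 1, dt = 0.001, init = NULL,
                              recordDt = 0.5) {
  stride <- max(1L, as.integer(round(recordDt / dt)))
  res <- .cpp_pace_cell_rk4(if (is.null(init)) numeric(0) else
                              as.numeric(init),
                            .layer_code(phenotype@layer),
                            unname(phenotype@scalings), bcl,
                            as.integer(nBeats), 0, dt, stimAmp, stimDur,
                            stride)
  keep <- res$time >= (nBeats - 1) * bcl
  out <- data.frame(time_ms = res$time[keep] - (nBeats - 1) * bcl,
                    Vm_mV = res$state[keep, 1])
  fin <- res$final
  names(fin) <- .MYO_STATE_NAMES
  attr(out, "final") <- fin
  out
}

#' Pace an electrotonically coupled myocyte-fibroblast pair
#'
#' A single myocyte coupled to a single fibroblast through a fixed gap
#' junctional conductance. The fibroblast acts as a current sink during
#' the plateau and as a source at rest, elevating the myocyte resting
#' potential and shortening its action potential duration.
#'
#' @inheritParams paceSingleCell
#' @param ggap gap-junction conductance (nS); 0 recovers the uncoupled
#'   myocyte.
#' @return data.frame with \code{time_ms}, \code{Vm_mV}, \code{Vf_mV} for
#'   the final beat, with attribute \code{final} (list of both states).
#' @export
paceCoupledPair <- function(phenotype, ggap = 3, bcl = 800, nBeats = 1,
                            stimAmp = -52, stimDur = 1, dt = 0.02,
                            recordDt = 0.5) {
  stride <- max(1L, as.integer(round(recordDt / dt)))
  res <- .cpp_pace_pair(numeric(0), numeric(0),
                        .layer_code(phenotype@layer),
                        unname(phenotype@scalings), ggap, bcl,
                        as.integer(nBeats), 0, dt, stimAmp, stimDur, stride,
                        0.2, 50L)
  keep <- res$time >= (nBeats - 1) * bcl
  out <- data.frame(time_ms = res$time[keep] - (nBeats - 1) * bcl,
                    Vm_mV = res$vm[keep], Vf_mV = res$vf[keep])
  attr(out, "final") <- list(myocyte = res$final_myo,
                             fibroblast = res$final_fib)
  out
}

#' Action-potential biomarkers of a Vm trace
#'
#' Measures resting membrane potential (RMP), peak potential, action
#' potential amplitude (APA), maximum upstroke velocity (dVdt_max) and
#' APD90. APD90 runs from the time of maximum upstroke velocity to 90%
#' repolarization toward the per-beat minimum. A quiescent trace yields
#' the RMP only, with the remaining biomarkers NA.
#'
#' @param trace data.frame with columns \code{time_ms} and \code{Vm_mV}
#'   (one beat), as returned by [paceSingleCell()].
#' @param apThreshold minimum depolarized excursion (mV above the trace
#'   minimum) required to count an action potential.
#' @return named list: APD90 (ms), APA (mV), RMP (mV), dVdt_max (mV/ms),
#'   Vpeak (mV).
#' @export
computeBiomarkers <- function(trace, apThreshold = 40) {
  t <- trace$time_ms
  v <- trace$Vm_mV
  if (length(t) < 3) stop("trace too short")
  vmin <- min(v)
  vpeak <- max(v)
  if (vpeak - vmin < apThreshold) {
    return(list(APD90 = NA_real_, APA = NA_real_, RMP = vmin,
                dVdt_max = NA_real_, Vpeak = NA_real_))
  }
  dv <- diff(v) / diff(t)
  iup <- which.max(dv)
  tact <- t[iup + 1L]
  takeoff <- v[iup]  # potential just before the fastest upstroke sample
  base <- min(v[seq_len(iup)])
  v90 <- vpeak - 0.9 * (vpeak - base)
  after <- which(t > tact & v < v90)
  after <- after[after > which.max(v)]
  apd <- if (length(after)) t[after[1]] - tact else NA_real_
  list(APD90 = apd, APA = vpeak - takeoff, RMP = base,
       dVdt_max = max(dv), Vpeak = vpeak)
}
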