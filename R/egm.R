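# Electrogram processing: local-activation-time annotation on
# unipolar/bipolar pairs and the amplitude + spatio-temporal coherence
# point filters used to clean mapping-catheter data.

#' Annotate the local activation time of an electrogram
#'
#' The activation time is the deflection of the bipolar signal closest to
#' the point of maximum negative slope of the distal unipolar signal.
#' Bipolar deflections are local extrema of the absolute bipolar signal
#' above a noise floor (a fraction of its peak-to-peak amplitude).
#'
#' @param time sample times (ms).
#' @param unipolar distal unipolar signal (mV).
#' @param bipolar bipolar signal (mV); defaults to the difference of the
#'   two unipolar electrodes when given as a matrix in \code{unipolar}.
#' @param noiseFloor deflection threshold as a fraction of the bipolar
#'   peak-to-peak amplitude.
#' @return list with \code{lat} (ms, NA when the trace is flat),
#'   \code{tSlope} (time of maximum negative unipolar slope) and
#'   \code{valid}.
#' @export
annotateLat <- function(time, unipolar, bipolar = NULL, noiseFloor = 0.05) {
  if (is.matrix(unipolar) && ncol(unipolar) == 2) {
    if (is.null(bipolar)) bipolar <- unipolar[, 1] - unipolar[, 2]
    unipolar <- unipolar[, 1]
  }
  stopifnot(length(time) == length(unipolar), length(time) == length(bipolar))
  if (max(unipolar) - min(unipolar) < 1e-12 ||
      max(bipolar) - min(bipolar) < 1e-12)
    return(list(lat = NA_real_, tSlope = NA_real_, valid = FALSE))
  du <- diff(unipolar) / diff(time)
  tSlope <- time[which.min(du) + 1L]
  ab <- abs(bipolar)
  floorLev <- noiseFloor * (max(bipolar) - min(bipolar))
  n <- length(ab)
  isExt <- c(FALSE, ab[2:(n - 1)] >= ab[1:(n - 2)] &
                    ab[2:(n - 1)] >= ab[3:n], FALSE) & ab > floorLev
  cand <- which(isExt)
  if (!length(cand)) cand <- which.max(ab)
  lat <- time[cand[which.min(abs(time[cand] - tSlope))]]
  list(lat = lat, tSlope = tSlope, valid = TRUE)
}

#' Filter mapping points by amplitude and LAT coherence
#'
#' First discards points whose bipolar peak-to-peak amplitude is below
#' the voltage cutoff (non-excitable tissue, reason \code{low_voltage});
#' then discards points whose annotated LAT deviates from the
#' inverse-distance-weighted LAT of their neighbors by more than the
#' coherence threshold (reason \code{lat_outlier}). The amplitude filter
#' strictly precedes the coherence filter, and the combined filter is
#' idempotent.
#'
#' @param points data.frame with columns \code{x}, \code{y}, \code{z}
#'   (mm), \code{lat} (ms) and \code{amplitude} (mV).
#' @param radius neighbor search radius (mm).
#' @param voltageCutoff minimum peak-to-peak bipolar amplitude (mV).
#' @param threshold absolute LAT residual cutoff (ms); default 3 times
#'   the median absolute residual of the amplitude-passing points.
#' @return the data.frame with logical \code{valid} and character
#'   \code{reason} columns added, and the coherence threshold used
#'   attached as attribute \code{threshold} (pass it back in to make
#'   repeated filtering idempotent).
#' @export
filterPoints <- function(points, radius = 10, voltageCutoff = 0.5,
                         threshold = NULL) {
  stopifnot(all(c("x", "y", "z", "lat", "amplitude") %in% names(points)))
  if (!all(is.finite(as.matrix(points[, c("x", "y", "z")]))))
    stop("point positions must be finite")
  n <- nrow(points)
  valid <- rep(TRUE, n)
  reason <- rep("", n)
  lowv <- points$amplitude < voltageCutoff | !is.finite(points$lat)
  valid[lowv] <- FALSE
  reason[lowv] <- "low_voltage"

  keep <- which(valid)
  if (length(keep) >= 3) {
    pos <- as.matrix(points[keep, c("x", "y", "z")])
    lat <- points$lat[keep]
    resid <- rep(NA_real_, length(keep))
    for (i in seq_along(keep)) {
      d <- sqrt(colSums((t(pos) - pos[i, ])^2))
      nb <- which(d > 1e-12 & d <= radius)
      if (!length(nb)) next
      w <- 1 / d[nb]
      resid[i] <- lat[i] - sum(w * lat[nb]) / sum(w)
    }
    if (is.null(threshold)) {
      mad0 <- median(abs(resid), na.rm = TRUE)
      threshold <- max(3 * mad0, 1e-9)
    }
    bad <- which(is.finite(resid) & abs(resid) > threshold)
    valid[keep[bad]] <- FALSE
    reason[keep[bad]] <- "lat_outlier"
  }
  points$valid <- valid
  points$reason <- reason
  attr(points, "threshold") <- threshold
  points
}
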