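#' Element label names
#'
#' Per-element tissue labels of a [TissueGrid] as a factor with levels
#' \code{healthy}, \code{scar}, \code{BZ}, \code{fibrosis}.
#' @param x a TissueGrid.
#' @return factor of length \code{nElements(x)}.
#' @export
labelNames <- function(x) {
  stopifnot(is(x, "TissueGrid"))
  factor(names(.LABELS)[x@label], levels = names(.LABELS))
}

#' @rdname labelNames
#' @export
nElements <- function(x) {
  stopifnot(is(x, "TissueGrid"))
  prod(x@dims)
}

#' Node count of the full grid lattice
#' @param x a TissueGrid.
#' @export
nNodes <- function(x) {
  stopifnot(is(x, "TissueGrid"))
  prod(x@dims + 1L)
}

#' Element centroid coordinates (mm)
#' @param x a TissueGrid.
#' @return nelem x 3 matrix.
#' @export
elementCentroids <- function(x) {
  stopifnot(is(x, "TissueGrid"))
  d <- x@dims
  ii <- arrayInd(seq_len(prod(d)), d)
  sweep((ii - 0.5) * x@dx, 2, x@origin, `+`)
}

#' Grid node coordinates (mm)
#' @param x a TissueGrid.
#' @return nnode x 3 matrix in lattice order (x fastest).
#' @export
nodeCoordinates <- function(x) {
  stopifnot(is(x, "TissueGrid"))
  d <- x@dims + 1L
  ii <- arrayInd(seq_len(prod(d)), d)
  sweep((ii - 1) * x@dx, 2, x@origin, `+`)
}

#' Conductivity accessor/replacement
#' @param x a TissueGrid.
#' @export
conductivities <- function(x) {
  stopifnot(is(x, "TissueGrid"))
  colnames(x@sigma) <- c("sigma_l", "sigma_t")
  x@sigma
}

#' Activation-time map of a simulation window
#' @param x a [SimResult].
#' @param window window index.
#' @return numeric vector, NA for non-captured nodes.
#' @export
latMap <- function(x, window = 1L) {
  stopifnot(is(x, "SimResult"))
  x@lat[, window]
}

#' @rdname latMap
#' @export
apdMap <- function(x, window = 1L) {
  stopifnot(is(x, "SimResult"))
  x@apd[, window]
}

#' Final state of a simulation segment
#'
#' Matrix of per-node state variables usable as \code{init} of a
#' follow-on [runSimulation()] segment.
#' @param x a [SimResult].
#' @export
finalState <- function(x) {
  stopifnot(is(x, "SimResult"))
  x@finalState
}

#' Event log of a simulation or inducibility test
#' @param x a [SimResult] or [InducibilityResult].
#' @export
eventLog <- function(x) {
  if (is(x, "SimResult") || is(x, "InducibilityResult")) return(x@events)
  stop("no event log for this object")
}
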