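#' @useDynLib ivtlab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats approx cor median rnorm sd
#' @importFrom utils head tail write.csv
NULL

.LABELS <- c(healthy = 1L, scar = 2L, BZ = 3L, fibrosis = 4L)
.LAYERS <- c(endo = 1L, M = 2L, epi = 3L)

#' DE-MRI-like scalar intensity volume
#'
#' A 3D scalar field on an isotropic voxel lattice, emulating a
#' delayed-enhancement MRI acquisition. Intensities are in arbitrary
#' units; the voxel spacing and origin are in millimetres.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing isotropic voxel edge length (mm).
#' @slot origin position of the centre of voxel (1,1,1) (mm).
#' @slot seed integer seed recorded by the synthetic generator (NA for
#'   volumes read from file).
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 seed = "integer"),
  prototype(spacing = 1.4, origin = c(0, 0, 0), seed = NA_integer_),
  validity = function(object) {
    if (length(dim(object@data)) != 3) return("data must be a 3D array")
    if (length(object@spacing) != 1 || object@spacing <= 0)
      return("spacing must be a single positive number")
    if (length(object@origin) != 3) return("origin must have length 3")
    if (!all(is.finite(object@data))) return("intensities must be finite")
    TRUE
  })

#' Segmentation regions of interest for SD-method classification
#'
#' Boolean masks aligned with a [VoxelVolume]: the myocardium, the remote
#' (healthy reference) ROI and the infarcted ROI. Remote and infarct ROIs
#' are disjoint subsets of the myocardium.
#'
#' @slot myocardium,remote,infarct logical 3D arrays.
#' @export
setClass("RegionMasks",
  representation(myocardium = "array", remote = "array", infarct = "array"),
  validity = function(object) {
    d <- dim(object@myocardium)
    if (!identical(d, dim(object@remote)) || !identical(d, dim(object@infarct)))
      return("mask dimensions differ")
    if (any(object@remote & object@infarct))
      return("remote and infarct ROIs must be disjoint")
    if (any(object@remote & !object@myocardium) ||
        any(object@infarct & !object@myocardium))
      return("ROIs must lie within the myocardium mask")
    TRUE
  })

#' Labeled anisotropic hexahedral tissue grid
#'
#' A regular hexahedral grid of cardiac tissue with per-element label
#' (healthy / scar / BZ / fibrosis), fiber unit vector, transmural layer,
#' conductivity pair and (optionally) a mapped image intensity used for
#' ranking patchy fibrosis. Elements are unit cubes of edge \code{dx} mm;
#' nodes are the lattice vertices.
#'
#' @slot dims integer element counts (nx, ny, nz).
#' @slot dx element edge length (mm).
#' @slot origin node (0,0,0) position (mm).
#' @slot label integer per-element label code (see [labelNames()]).
#' @slot fiber nelem x 3 matrix of unit fiber vectors.
#' @slot layer integer per-element transmural layer (1 endo, 2 M, 3 epi).
#' @slot sigma nelem x 2 matrix, longitudinal and transverse conductivity
#'   (S/m). Ignored for scar elements, which are excluded from the
#'   conducting domain.
#' @slot intensity per-element mapped image intensity (NA when unmapped).
#' @export
setClass("TissueGrid",
  representation(dims = "integer", dx = "numeric", origin = "numeric",
                 label = "integer", fiber = "matrix", layer = "integer",
                 sigma = "matrix", intensity = "numeric"),
  validity = function(object) {
    ne <- prod(object@dims)
    if (length(object@dims) != 3 || any(object@dims < 1))
      return("dims must be three positive element counts")
    if (object@dx <= 0) return("dx must be positive")
    if (length(object@label) != ne) return("label length != element count")
    if (!all(object@label %in% .LABELS)) return("unknown label code")
    if (nrow(object@fiber) != ne || ncol(object@fiber) != 3)
      return("fiber must be nelem x 3")
    cond <- object@label != .LABELS[["scar"]]
    nrm <- sqrt(rowSums(object@fiber[cond, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      return("fiber vectors of conducting elements must be unit length")
    if (length(object@layer) != ne) return("layer length != element count")
    if (nrow(object@sigma) != ne || ncol(object@sigma) != 2)
      return("sigma must be nelem x 2")
    sl <- object@sigma[cond, 1]; st <- object@sigma[cond, 2]
    if (any(!(sl >= st & st > 0)))
      return("conducting elements need sigma_L >= sigma_T > 0")
    if (length(object@intensity) != ne)
      return("intensity length != element count")
    TRUE
  })

#' Ionic phenotype of a ventricular myocyte
#'
#' Transmural layer plus the multiplicative maximal-conductance scalings
#' applied to the base human ventricular action potential model. The
#' border-zone electrical remodeling phenotype scales I_Na to 38%, I_CaL
#' to 31%, I_Kr to 30% and I_Ks to 20% of their healthy values.
#'
#' @slot layer one of "endo", "M", "epi".
#' @slot remodeled logical; TRUE selects the border-zone remodeling.
#' @slot scalings named numeric scalings for (I_Na, I_CaL, I_Kr, I_Ks).
#' @export
setClass("MyocytePhenotype",
  representation(layer = "character", remodeled = "logical",
                 scalings = "numeric"),
  validity = function(object) {
    if (!object@layer %in% names(.LAYERS)) return("unknown layer")
    if (length(object@scalings) != 4 || any(object@scalings <= 0))
      return("scalings must be 4 positive numbers")
    TRUE
  })

#' Discretized monodomain system on the conducting sub-grid
#'
#' The assembled finite-element operators of a [TissueGrid]: stiffness
#' matrix of the anisotropic conductivity tensor over conducting elements
#' only (scar removed, equivalent to an internal no-flux boundary), lumped
#' mass vector, and per-node membrane assignment.
#'
#' @slot K sparse symmetric stiffness matrix (mS * mm), conducting nodes.
#' @slot Mc consistent (non-lumped) mass matrix (mm^3).
#' @slot mass lumped mass vector (mm^3).
#' @slot nodes global grid-node index of each conducting node.
#' @slot nodeType integer per conducting node: 0..5 myocyte
#'   (layer - 1 + 3 * remodeled), 6 fibroblast.
#' @slot coords conducting node coordinates (mm).
#' @slot elems conducting-element corner connectivity (local node ids).
#' @slot grid the source [TissueGrid].
#' @export
setClass("MonodomainSystem",
  representation(K = "ANY", Mc = "ANY", mass = "numeric", nodes = "integer",
                 nodeType = "integer", coords = "matrix", elems = "matrix",
                 grid = "TissueGrid"))

#' Result of a monodomain tissue simulation
#'
#' Per-node activation (LAT) and repolarization (APD90) maps for each
#' requested measurement window, probe traces, optional Vm snapshots,
#' watched 0 mV upstroke-crossing times, the final state (usable as the
#' initial condition of a follow-on segment) and an event log.
#'
#' @export
setClass("SimResult",
  representation(lat = "matrix", apd = "matrix", dvdtMax = "matrix",
                 windows = "matrix", probeT = "numeric", probeV = "matrix",
                 probeNodes = "integer", snapT = "numeric", snapV = "matrix",
                 snapNodes = "integer", crossings = "list",
                 watchNodes = "integer", finalState = "matrix",
                 t0 = "numeric", duration = "numeric", events = "data.frame",
                 cgMaxIterations = "integer"))

#' Tetrahedral torso volume conductor
#'
#' @slot nodes n x 3 node coordinates (mm).
#' @slot tets m x 4 vertex indices.
#' @slot region integer region label per tetrahedron.
#' @slot sigma conductivity per tetrahedron (S/m).
#' @slot heartNodes indices of nodes on the ventricles-torso interface
#'   where Dirichlet values (heart extracellular potentials) are imposed.
#' @slot electrodes named k x 3 matrix of electrode positions; each is
#'   snapped to the nearest mesh node when potentials are extracted.
#' @export
setClass("TorsoModel",
  representation(nodes = "matrix", tets = "matrix", region = "integer",
                 sigma = "numeric", heartNodes = "integer",
                 electrodes = "matrix"),
  validity = function(object) {
    if (ncol(object@nodes) != 3) return("nodes must be n x 3")
    if (ncol(object@tets) != 4) return("tets must be m x 4")
    if (length(object@sigma) != nrow(object@tets))
      return("sigma length != tet count")
    if (any(object@sigma <= 0)) return("conductivities must be positive")
    TRUE
  })

#' Outcome of a programmed-stimulation inducibility test
#'
#' @slot outcome "no_VT" or "VT".
#' @slot stage inducing stage: "S2", "S3" or "none".
#' @slot ci successful coupling interval (ms; NA if not inducible).
#' @slot vtBcl cycle length of the induced VT (ms).
#' @slot vtRate VT rate, round(60000 / vtBcl) (bpm).
#' @slot blockType "none", "unidirectional" or "bidirectional".
#' @slot events event log (time, event, detail).
#' @export
setClass("InducibilityResult",
  representation(outcome = "character", stage = "character", ci = "numeric",
                 vtBcl = "numeric", vtRate = "numeric", blockType = "character",
                 events = "data.frame"),
  validity = function(object) {
    if (!object@outcome %in% c("no_VT", "VT")) return("bad outcome")
    if (!object@stage %in% c("S2", "S3", "none")) return("bad stage")
    if (object@outcome == "VT" && object@stage == "none")
      return("a VT outcome requires an inducing stage")
    if (object@outcome == "VT" && is.finite(object@vtBcl) &&
        object@vtRate != round(60000 / object@vtBcl))
      return("vtRate must equal round(60000 / vtBcl)")
    TRUE
  })

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, %.2f mm isotropic\n",
              d[1], d[2], d[3], object@spacing))
  cat(sprintf("  intensity range [%.1f, %.1f]%s\n", min(object@data),
              max(object@data),
              if (is.na(object@seed)) "" else sprintf(", seed %d", object@seed)))
})

setMethod("show", "TissueGrid", function(object) {
  d <- object@dims
  cat(sprintf("TissueGrid: %d x %d x %d elements (dx = %.2f mm, %.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], object@dx, d[1] * object@dx, d[2] * object@dx,
              d[3] * object@dx))
  tab <- table(factor(names(.LABELS)[object@label], levels = names(.LABELS)))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "MyocytePhenotype", function(object) {
  cat(sprintf("MyocytePhenotype: %s, %s\n", object@layer,
              if (object@remodeled) "remodeled (border zone)" else "healthy"))
  cat("  scalings:", paste(sprintf("%s=%.2f", names(object@scalings),
                                   object@scalings), collapse = ", "), "\n")
})

setMethod("show", "MonodomainSystem", function(object) {
  cat(sprintf("MonodomainSystem: %d conducting nodes (%d fibroblast), %d nonzeros\n",
              length(object@nodes), sum(object@nodeType == 6L),
              length(object@K@x)))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: t = [%.1f, %.1f] ms, %d nodes, %d measurement window(s)\n",
              object@t0, object@t0 + object@duration, nrow(object@lat),
              ncol(object@lat)))
  if (ncol(object@lat) > 0)
    cat(sprintf("  window 1: %d/%d nodes captured\n",
                sum(!is.na(object@lat[, 1])), nrow(object@lat)))
})

setMethod("show", "InducibilityResult", function(object) {
  if (object@outcome == "VT")
    cat(sprintf("InducibilityResult: VT (%s - %g ms, BCL %g ms - %g bpm, block %s)\n",
                object@stage, object@ci, object@vtBcl, object@vtRate,
                object@blockType))
  else cat("InducibilityResult: no VT\n")
})

setMethod("show", "TorsoModel", function(object) {
  cat(sprintf("TorsoModel: %d nodes, %d tetrahedra, %d heart-interface nodes, %d electrodes\n",
              nrow(object@nodes), nrow(object@tets), length(object@heartNodes),
              nrow(object@electrodes)))
})
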