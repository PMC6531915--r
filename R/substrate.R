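# Synthetic DE-MRI-like volumes, SD-method scar/BZ classification,
# voxel-to-element mapping, patchy fibrosis, fibers, layers and the
# strand / slab / isthmus-sheet fixtures.

# --- small 3D helpers -------------------------------------------------------

# dense band matrix applying a 1D kernel with replicated edges
.conv_mat <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - 1L - r
    idx <- seq_len(n) + off
    idx <- pmin(pmax(idx, 1L), n)  # replicate edges
    M[cbind(seq_len(n), idx)] <- M[cbind(seq_len(n), idx)] + kernel[k]
  }
  M
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing of a 3D array (sigma in voxels, may be 0)
.gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- .gauss_kernel(sigma)
  d <- dim(arr)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- .conv_mat(da[1], k) %*% matrix(a, da[1])
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

# Chebyshev (26-connected) binary dilation by one voxel
.dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[sx, sy, sz, drop = FALSE]
  }
  out
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# --- synthetic infarct volume ----------------------------------------------

#' Specification of a synthetic infarct intensity volume
#'
#' Parameters of the synthetic delayed-enhancement-like volume: a remote
#' plateau with Gaussian variability, a hyper-enhanced scar core, a
#' border-zone rim whose noise-free intensities ramp across the
#' (mean + 2 SD, mean + 3 SD] band, and a lower-intensity channel
#' (isthmus) crossing the scar.
#'
#' @param dims voxel counts (nx, ny, nz).
#' @param spacing isotropic voxel edge (mm).
#' @param remoteMean,remoteSd remote myocardium intensity mean and the SD
#'   unit used for the plateau/band definitions.
#' @param scarSigma scar plateau height in units of \code{remoteSd} above
#'   \code{remoteMean} (must be >= 3).
#' @param scarSize scar box extent (mm, length 3); any zero disables the
#'   scar.
#' @param bzWidth border-zone rim width (mm).
#' @param channelWidth width of the through-scar channel (mm); 0 disables.
#' @param channelAxis axis the channel runs along ("x", "y" or "z").
#' @param corrLength spatial correlation length of the correlated noise
#'   component (mm).
#' @param noiseSd total noise SD in units of \code{remoteSd}.
#' @param corrFrac fraction of the noise variance that is spatially
#'   correlated (clustering of bright BZ voxels into patches).
#' @param seed RNG seed recorded in the generated volume.
#' @return object of class \code{SyntheticInfarctSpec} (a validated list).
#' @export
syntheticInfarctSpec <- function(dims = c(48L, 48L, 24L), spacing = 1.4,
                                 remoteMean = 100, remoteSd = 10,
                                 scarSigma = 5, scarSize = c(25, 25, 14),
                                 bzWidth = 4.2, channelWidth = 4.2,
                                 channelAxis = "y", corrLength = 2.8,
                                 noiseSd = 0.5, corrFrac = 0.5, seed = 1L) {
  stopifnot(length(dims) == 3, all(dims >= 4), spacing > 0, remoteSd > 0,
            noiseSd >= 0, corrFrac >= 0, corrFrac <= 1)
  if (scarSigma < 3) stop("scar plateau must be at least 3 SD above the remote mean")
  if (channelWidth > 0 && any(scarSize > 0)) {
    perp <- setdiff(c("x", "y", "z"), channelAxis)
    idx <- match(perp, c("x", "y", "z"))
    if (channelWidth >= min(scarSize[idx]))
      stop("channel wider than the scar")
  }
  structure(list(dims = as.integer(dims), spacing = spacing,
                 remoteMean = remoteMean, remoteSd = remoteSd,
                 scarSigma = scarSigma, scarSize = scarSize,
                 bzWidth = bzWidth, channelWidth = channelWidth,
                 channelAxis = channelAxis, corrLength = corrLength,
                 noiseSd = noiseSd, corrFrac = corrFrac,
                 seed = as.integer(seed)),
            class = "SyntheticInfarctSpec")
}

#' Generate a synthetic infarct volume with ground truth
#'
#' Builds the noise-free base field (remote plateau, scar plateau,
#' border-zone intensity ramp, lower-intensity channel crossing the
#' scar), adds spatially correlated Gaussian noise, and returns the
#' intensity volume, the segmentation ROIs and the intended ground-truth
#' label volume. Deterministic for a fixed seed.
#'
#' @param spec a [syntheticInfarctSpec()].
#' @return list with elements \code{volume} ([VoxelVolume-class]),
#'   \code{masks} ([RegionMasks-class]) and \code{truth} (integer array;
#'   1 healthy, 2 scar, 3 BZ).
#' @export
generateSyntheticInfarct <- function(spec) {
  stopifnot(inherits(spec, "SyntheticInfarctSpec"))
  d <- spec$dims
  sp <- spec$spacing
  ctr <- (d / 2) * sp
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - 0.5) * sp)
  X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)

  scar <- array(FALSE, d)
  if (all(spec$scarSize > 0)) {
    scar <- abs(X - ctr[1]) <= spec$scarSize[1] / 2 &
            abs(Y - ctr[2]) <= spec$scarSize[2] / 2 &
            abs(Z - ctr[3]) <= spec$scarSize[3] / 2
  }
  channel <- array(FALSE, d)
  if (spec$channelWidth > 0 && any(scar)) {
    hw <- spec$channelWidth / 2
    channel <- switch(spec$channelAxis,
      x = abs(Y - ctr[2]) <= hw & abs(Z - ctr[3]) <= hw,
      y = abs(X - ctr[1]) <= hw & abs(Z - ctr[3]) <= hw,
      z = abs(X - ctr[1]) <= hw & abs(Y - ctr[2]) <= hw,
      stop("channelAxis must be x, y or z"))
    channel <- channel & scar
    scar <- scar & !channel
  }

  # BZ rim by iterative 26-connected dilation; ramp across the 2-3 SD band
  nrim <- max(1L, round(spec$bzWidth / sp))
  rimIter <- array(0L, d)
  cur <- scar
  for (it in seq_len(nrim)) {
    nxt <- .dilate1(cur)
    ring <- nxt & !cur & !channel
    rimIter[ring & rimIter == 0L] <- it
    cur <- nxt
  }
  rim <- rimIter > 0L

  s <- spec$remoteSd
  base <- array(spec$remoteMean, d)
  base[scar] <- spec$remoteMean + spec$scarSigma * s
  if (any(rim)) {
    frac <- (rimIter[rim] - 1) / max(nrim - 1, 1)
    base[rim] <- spec$remoteMean + s * (2.95 - 0.9 * frac)
  }
  base[channel] <- spec$remoteMean + 2.5 * s

  noise <- .with_seed(spec$seed, {
    w <- array(rnorm(prod(d)), d)
    g <- .gauss_smooth3(array(rnorm(prod(d)), d), spec$corrLength / sp)
    g <- g / sd(g)
    sqrt(1 - spec$corrFrac) * w + sqrt(spec$corrFrac) * g
  })
  vol <- base + spec$noiseSd * s * noise

  margin <- 1L
  myo <- array(FALSE, d)
  myo[(margin + 1):(d[1] - margin), (margin + 1):(d[2] - margin),
      (margin + 1):(d[3] - margin)] <- TRUE
  infarctCore <- scar | rim | channel
  infarctROI <- .dilate1(infarctCore) & myo
  remoteROI <- myo & !.dilate1(.dilate1(infarctROI))

  truth <- array(.LABELS[["healthy"]], d)
  truth[scar] <- .LABELS[["scar"]]
  truth[rim | channel] <- .LABELS[["BZ"]]
  truth[!myo] <- .LABELS[["healthy"]]

  list(volume = new("VoxelVolume", data = vol, spacing = sp,
                    origin = c(0, 0, 0) + sp / 2, seed = spec$seed),
       masks = new("RegionMasks", myocardium = myo, remote = remoteROI,
                   infarct = infarctROI),
       truth = truth)
}

# --- SD-method classification ----------------------------------------------

#' Standard-deviation scar / border-zone classification
#'
#' Classifies every voxel of the infarcted ROI from remote-myocardium
#' intensity statistics: scar for intensities at or above mean + 3 SD,
#' border zone between mean + 2 SD (inclusive) and mean + 3 SD, healthy
#' below mean + 2 SD. Voxels outside the infarct ROI are healthy. In
#' per-slice mode (the default) the statistics come from the remote ROI
#' of each axial (z) slice.
#'
#' @param volume a [VoxelVolume-class].
#' @param masks a [RegionMasks-class].
#' @param mode "per-slice" or "global" remote statistics.
#' @return integer label array (1 healthy, 2 scar, 3 BZ).
#' @export
sdClassify <- function(volume, masks, mode = c("per-slice", "global")) {
  mode <- match.arg(mode)
  stopifnot(is(volume, "VoxelVolume"), is(masks, "RegionMasks"))
  v <- volume@data
  d <- dim(v)
  if (!identical(d, dim(masks@remote)))
    stop("volume and masks have different dimensions")
  lab <- array(.LABELS[["healthy"]], d)
  if (mode == "global") {
    if (!any(masks@remote)) stop("remote ROI is empty")
    mu <- mean(v[masks@remote]); s <- sd(v[masks@remote])
    inf <- masks@infarct
    lab[inf & v >= mu + 3 * s] <- .LABELS[["scar"]]
    lab[inf & v >= mu + 2 * s & v < mu + 3 * s] <- .LABELS[["BZ"]]
  } else {
    for (k in seq_len(d[3])) {
      infk <- masks@infarct[, , k]
      if (!any(infk)) next
      remk <- masks@remote[, , k]
      if (!any(remk))
        stop(sprintf("slice %d contains infarct ROI but an empty remote ROI", k))
      mu <- mean(v[, , k][remk]); s <- sd(v[, , k][remk])
      vk <- v[, , k]
      labk <- lab[, , k]
      labk[infk & vk >= mu + 3 * s] <- .LABELS[["scar"]]
      labk[infk & vk >= mu + 2 * s & vk < mu + 3 * s] <- .LABELS[["BZ"]]
      lab[, , k] <- labk
    }
  }
  lab
}

# --- voxel -> element mapping ----------------------------------------------

#' Sample a voxel volume (or label array) at element centroids
#'
#' Each grid element receives the value of the voxel containing its
#' centroid. With 1.4 mm voxels and 0.4 mm elements one voxel maps to up
#' to ceiling(1.4 / 0.4)^3 = 64 hexahedra.
#'
#' @param values a [VoxelVolume-class] or a plain 3D array (then
#'   \code{spacing} and \code{origin} must be given).
#' @param grid a [TissueGrid-class] whose bounding box lies inside the
#'   volume.
#' @param spacing,origin voxel geometry when \code{values} is an array.
#' @return vector of sampled values, one per element.
#' @export
mapToGrid <- function(values, grid, spacing = NULL, origin = NULL) {
  stopifnot(is(grid, "TissueGrid"))
  if (is(values, "VoxelVolume")) {
    arr <- values@data; spacing <- values@spacing
    origin <- values@origin
  } else {
    arr <- values
    if (is.null(spacing) || is.null(origin))
      stop("spacing and origin required for a plain array")
  }
  d <- dim(arr)
  cen <- elementCentroids(grid)
  # origin is the centre of voxel (1,1,1)
  idx <- sweep(cen, 2, origin - spacing / 2, `-`) / spacing
  ijk <- floor(idx) + 1
  if (any(ijk < 1) || any(ijk[, 1] > d[1]) || any(ijk[, 2] > d[2]) ||
      any(ijk[, 3] > d[3]))
    stop("element centroid outside the volume")
  arr[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
}

#' Transfer voxel labels onto a tissue grid
#'
#' @param labels integer label array (codes as produced by
#'   [sdClassify()]) or a [VoxelVolume-class] holding label codes.
#' @inheritParams mapToGrid
#' @return the grid with per-element labels replaced.
#' @export
mapLabelsToGrid <- function(labels, grid, spacing = NULL, origin = NULL) {
  lab <- as.integer(round(mapToGrid(labels, grid, spacing, origin)))
  if (!all(lab %in% .LABELS)) stop("mapped values are not label codes")
  grid@label <- lab
  validObject(grid)
  grid
}

# --- patchy fibrosis --------------------------------------------------------

#' Assign image-based patchy fibrosis within the border zone
#'
#' Relabels exactly \code{round(p / 100 * N_BZ)} border-zone elements as
#' fibrosis, selecting those with the highest mapped image intensity
#' (ties broken by ascending element index, so the choice is
#' deterministic).
#'
#' @param grid a [TissueGrid-class] with BZ elements.
#' @param intensity per-element intensities (default: the grid's mapped
#'   \code{intensity} slot).
#' @param level fibrosis level p in percent (0-100; the study uses 0,
#'   10, 20, 30).
#' @return the grid with fibrotic elements relabeled.
#' @export
assignFibrosis <- function(grid, level, intensity = NULL) {
  stopifnot(is(grid, "TissueGrid"))
  if (length(level) != 1 || !is.finite(level) || level < 0 || level > 100)
    stop("fibrosis level must be a percentage in [0, 100]")
  if (is.null(intensity)) intensity <- grid@intensity
  bz <- which(grid@label == .LABELS[["BZ"]])
  nfib <- round(level / 100 * length(bz))
  if (nfib > 0) {
    if (any(!is.finite(intensity[bz])))
      stop("BZ elements lack mapped intensities")
    ord <- bz[order(-intensity[bz], bz)]
    grid@label[ord[seq_len(nfib)]] <- .LABELS[["fibrosis"]]
  }
  grid
}

# --- fibers and transmural layers ------------------------------------------

.axis_index <- function(axis) match(axis, c("x", "y", "z"))

# normalized transmural depth (0 at endo face, 1 at epi face) per element
.transmural_depth <- function(grid, axis) {
  ai <- .axis_index(axis)
  n <- grid@dims[ai]
  if (n < 1) stop("zero-thickness wall")
  idx <- arrayInd(seq_len(prod(grid@dims)), grid@dims)[, ai]
  (idx - 0.5) / n
}

#' Rule-based fiber orientation
#'
#' Assigns per-element unit fiber vectors with the helix angle varying
#' linearly across normalized transmural depth between the endocardial
#' and epicardial limits (defaults +60 deg to -60 deg), plus an optional
#' constant transmural angle and optional 3D Gaussian smoothing (followed
#' by renormalization).
#'
#' @param grid a [TissueGrid-class].
#' @param helixEndo,helixEpi helix angle limits (degrees).
#' @param transverseAngle transmural (sheet) angle (degrees).
#' @param smoothSigma Gaussian smoothing SD (mm; 0 disables).
#' @param transmuralAxis grid axis spanning the wall thickness.
#' @return the grid with its fiber field replaced.
#' @export
assignFibers <- function(grid, helixEndo = 60, helixEpi = -60,
                         transverseAngle = 0, smoothSigma = 0,
                         transmuralAxis = "z") {
  stopifnot(is(grid, "TissueGrid"))
  dpt <- .transmural_depth(grid, transmuralAxis)
  helix <- (helixEndo + (helixEpi - helixEndo) * dpt) * pi / 180
  at <- transverseAngle * pi / 180
  # local frame: circumferential, longitudinal, transmural unit vectors
  tAxis <- .axis_index(transmuralAxis)
  circ <- c(1, 2, 3)[-tAxis][1]
  long <- c(1, 2, 3)[-tAxis][2]
  f <- matrix(0, length(dpt), 3)
  f[, circ] <- cos(at) * cos(helix)
  f[, long] <- cos(at) * sin(helix)
  f[, tAxis] <- sin(at)
  if (smoothSigma > 0) {
    sig <- smoothSigma / grid@dx
    for (c3 in 1:3) {
      a <- array(f[, c3], grid@dims)
      f[, c3] <- as.vector(.gauss_smooth3(a, sig))
    }
    f <- f / sqrt(rowSums(f^2))
  }
  grid@fiber <- f
  validObject(grid)
  grid
}

#' Transmural layer assignment
#'
#' Labels elements endo / M / epi by normalized transmural depth using
#' the wall-thickness fractions (defaults 17%, 41%, 42%, i.e. cut points
#' at depth 0.17 and 0.58).
#'
#' @param grid a [TissueGrid-class].
#' @param fractions thicknesses of the endo, M and epi layers (must sum
#'   to 1).
#' @param transmuralAxis grid axis spanning the wall thickness.
#' @return the grid with per-element layers replaced.
#' @export
assignTransmuralLayers <- function(grid, fractions = c(0.17, 0.41, 0.42),
                                   transmuralAxis = "z") {
  stopifnot(is(grid, "TissueGrid"))
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-6)
    stop("layer fractions must sum to 1")
  dpt <- .transmural_depth(grid, transmuralAxis)
  cut1 <- fractions[1]
  cut2 <- fractions[1] + fractions[2]
  lay <- rep(.LAYERS[["epi"]], length(dpt))
  lay[dpt < cut2] <- .LAYERS[["M"]]
  lay[dpt < cut1] <- .LAYERS[["endo"]]
  grid@layer <- as.integer(lay)
  grid
}

# --- conductivities ---------------------------------------------------------

#' Reference conductivity sets (S/m)
#'
#' Healthy myocardium (0.24, 0.0456); border-zone sets giving roughly
#' 75%, 50% and 25% conduction-velocity reduction with the remodeled
#' membrane: (0.05, 0.01), (0.12, 0.03), (0.22, 0.0485); isotropic 0.1
#' for fibrotic tissue.
#' @return named list of (sigma_l, sigma_t) pairs.
#' @export
conductivitySets <- function() {
  list(healthy = c(0.24, 0.0456),
       bz75 = c(0.05, 0.01),
       bz50 = c(0.12, 0.03),
       bz25 = c(0.22, 0.0485),
       fibrosis = c(0.1, 0.1))
}

#' Apply per-label conductivities to a grid
#'
#' @param grid a [TissueGrid-class].
#' @param healthy,bz (sigma_l, sigma_t) pairs in S/m.
#' @param fibrosis isotropic fibrotic conductivity (S/m).
#' @return the grid with its sigma table replaced. Scar conductivity is
#'   irrelevant (scar is excluded from the conducting domain).
#' @export
applyConductivities <- function(grid, healthy = c(0.24, 0.0456),
                                bz = c(0.05, 0.01), fibrosis = 0.1) {
  stopifnot(is(grid, "TissueGrid"))
  sig <- matrix(0, nElements(grid), 2)
  lab <- grid@label
  sig[lab == .LABELS[["healthy"]], 1] <- healthy[1]
  sig[lab == .LABELS[["healthy"]], 2] <- healthy[2]
  sig[lab == .LABELS[["BZ"]], 1] <- bz[1]
  sig[lab == .LABELS[["BZ"]], 2] <- bz[2]
  sig[lab == .LABELS[["fibrosis"]], ] <- fibrosis
  sig[lab == .LABELS[["scar"]], ] <- bz  # placeholder; never assembled
  grid@sigma <- sig
  grid
}

# --- fixtures ---------------------------------------------------------------

.new_grid <- function(dims, dx, origin = c(0, 0, 0)) {
  ne <- prod(dims)
  f <- matrix(0, ne, 3); f[, 1] <- 1
  new("TissueGrid", dims = as.integer(dims), dx = dx, origin = origin,
      label = rep(.LABELS[["healthy"]], ne), fiber = f,
      layer = rep(.LAYERS[["epi"]], ne),
      sigma = matrix(rep(c(0.24, 0.0456), each = ne), ne, 2),
      intensity = rep(NA_real_, ne))
}

#' Build a test-geometry tissue grid
#'
#' Three fixtures: \describe{
#'   \item{strand}{a thin pseudo-1D bar (default 30 x 1.6 x 1.6 mm) for
#'     conduction-velocity measurement; fibers along \code{fiberAxis}.}
#'   \item{slab}{the 20 x 20 x 6 mm calibration block at 0.4 mm edge
#'     length; fibers along x.}
#'   \item{isthmus_sheet}{a thin sheet holding two scar blocks separated
#'     by a border-zone channel whose lower mouth is narrow and upper
#'     mouth wide (a funnel-shaped slow conducting channel), a BZ rim
#'     around the scar, and healthy tissue elsewhere. Elements carry a
#'     deterministic pseudo-intensity (bright near scar, spatially
#'     correlated) used for ranking patchy fibrosis.}
#' }
#'
#' @param kind fixture name.
#' @param size physical dimensions (mm): length 3 for strand/slab, length
#'   2 (sheet extent in x, y) for the isthmus sheet.
#' @param dx element edge length (mm); dims must divide by dx.
#' @param fiberAxis fiber direction for strand/slab ("x", "y" or "z").
#' @param scarSize (x, y) extent of each scar block region (mm): total
#'   scar+channel width in x, scar height in y.
#' @param mouthLower,mouthUpper channel widths at the lower (apical,
#'   small y) and upper (basal) mouth (mm). Zero blocks the channel.
#' @param rimWidth BZ rim width around scar (mm).
#' @param seed seed for the pseudo-intensity field.
#' @return a [TissueGrid-class] with labels, fibers, layers (all epi) and
#'   default conductivities assigned.
#' @examples
#' g <- buildFixture("slab")
#' g@dims  # 50 x 50 x 15 elements
#' @export
buildFixture <- function(kind = c("strand", "slab", "isthmus_sheet"),
                         size = NULL, dx = 0.4, fiberAxis = "x",
                         scarSize = c(26, 22), mouthLower = 3.2,
                         mouthUpper = 6.4, rimWidth = 3.2, tailLength = 6,
                         seed = 7L) {
  kind <- match.arg(kind)
  if (kind == "strand") {
    if (is.null(size)) size <- c(30, 1.6, 1.6)
  } else if (kind == "slab") {
    if (is.null(size)) size <- c(20, 20, 6)
  } else {
    if (is.null(size)) size <- c(44, 40)
  }
  ndim <- if (kind == "isthmus_sheet") c(size / dx, 1) else size / dx
  if (any(abs(ndim - round(ndim)) > 1e-9))
    stop("dimensions must be divisible by dx")
  ndim <- as.integer(round(ndim))
  g <- .new_grid(ndim, dx)

  if (kind %in% c("strand", "slab")) {
    ai <- .axis_index(fiberAxis)
    f <- matrix(0, nElements(g), 3); f[, ai] <- 1
    g@fiber <- f
    return(applyConductivities(g))
  }

  # isthmus sheet
  if (mouthLower < 0 || mouthUpper < 0) stop("channel width <= 0 is not allowed; use 0 to block")
  cen <- elementCentroids(g)
  cx <- size[1] / 2; cy <- size[2] / 2
  hh <- scarSize[2] / 2
  inBand <- abs(cen[, 2] - cy) <= hh
  # channel half-width varies linearly from lower to upper mouth
  yfrac <- (cen[, 2] - (cy - hh)) / scarSize[2]
  chw <- (mouthLower + (mouthUpper - mouthLower) * pmin(pmax(yfrac, 0), 1)) / 2
  inChannel <- inBand & abs(cen[, 1] - cx) < chw & chw > 0
  inScar <- inBand & abs(cen[, 1] - cx) <= scarSize[1] / 2 & !inChannel
  # trumpet exit: thin scar walls diverge at 45 degrees below the narrow
  # mouth so the corridor widens gradually into the open sheet (a graded
  # expansion; an abrupt exit blocks by source-sink mismatch)
  if (tailLength > 0 && mouthLower > 0) {
    yb <- cy - hh
    inTailBand <- cen[, 2] < yb & cen[, 2] >= yb - tailLength
    wloc <- mouthLower / 2 + (yb - cen[, 2])
    dxc <- abs(cen[, 1] - cx)
    tailWall <- inTailBand & abs(dxc - (wloc + dx)) <= dx
    tailCorr <- inTailBand & dxc < wloc
    inScar <- inScar | tailWall
    inChannel <- inChannel | (tailCorr & !tailWall)
  }
  lab <- rep(.LABELS[["healthy"]], nElements(g))
  lab[inScar] <- .LABELS[["scar"]]
  lab[inChannel & !inScar] <- .LABELS[["BZ"]]
  # rim: within rimWidth (Chebyshev) of scar
  scarArr <- array(lab == .LABELS[["scar"]], g@dims)
  rim <- scarArr
  for (i in seq_len(max(1L, round(rimWidth / dx)))) rim <- .dilate1(rim)
  rimIdx <- as.vector(rim) & lab == .LABELS[["healthy"]]
  lab[rimIdx] <- .LABELS[["BZ"]]
  g@label <- lab

  # fibers along the channel axis (y)
  f <- matrix(0, nElements(g), 3); f[, 2] <- 1
  g@fiber <- f

  # pseudo-intensity: bright near scar with correlated texture
  dscar <- array(Inf, g@dims)
  cur <- scarArr; dist <- 0
  while (any(cur) && any(!is.finite(dscar))) {
    dscar[cur & !is.finite(dscar)] <- dist
    newcur <- .dilate1(cur)
    if (all(newcur == cur)) break
    cur <- newcur; dist <- dist + 1
    if (dist > max(g@dims)) break
  }
  tex <- .with_seed(seed, .gauss_smooth3(array(rnorm(prod(g@dims)), g@dims),
                                         2 / dx))
  tex <- tex / sd(tex)
  g@intensity <- as.vector(exp(-as.vector(dscar) * dx / 3) + 0.35 * as.vector(tex))
  applyConductivities(g)
}
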