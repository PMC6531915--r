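# Forward ECG: extracellular potentials from the passive bidomain
# relation on the heart grid, a tetrahedral-FEM Laplace solve through a
# heterogeneous torso volume conductor, electrode extraction and
# waveform comparison.

#' Extracellular potentials from transmembrane potentials
#'
#' Solves the passive (diffusion-only) part of the bidomain equations,
#' div((Di + De) grad phi_e) = -div(Di grad Vm), on the conducting heart
#' grid. The intracellular/extracellular split follows the
#' equal-anisotropy-ratio convention: Di = (1 + lambda)/lambda * sigma_m
#' and De = lambda * Di, whose harmonic combination returns the
#' monodomain conductivity sigma_m. The potential is determined up to a
#' constant, fixed by a zero-mean gauge.
#'
#' @param system a [MonodomainSystem-class].
#' @param vm transmembrane potentials on the conducting nodes (vector,
#'   or nodes x time matrix).
#' @param lambda extracellular-to-intracellular conductivity ratio.
#' @return extracellular potentials, same shape as \code{vm}.
#' @export
extracellularFromVm <- function(system, vm, lambda = 1) {
  stopifnot(is(system, "MonodomainSystem"), lambda > 0)
  Ki <- ((1 + lambda) / lambda) * system@K
  Kie <- (1 + lambda) * Ki
  one <- matrix(vm, nrow = length(system@mass))
  rhs <- -(Ki %*% one)
  # pure-Neumann system: pin one node, then shift each solution to zero
  # mean (the right-hand side is compatible because K annihilates
  # constants)
  n <- nrow(Kie)
  Kp <- Kie
  Kp[1, ] <- 0
  Kp[, 1] <- 0
  Kp[1, 1] <- 1
  rhs[1, ] <- 0
  phi <- as.matrix(Matrix::solve(Kp, rhs))
  phi <- sweep(phi, 2, colMeans(phi))
  if (is.matrix(vm)) phi else as.numeric(phi)
}

#' Reference torso tissue conductivities (S/m)
#'
#' Literature values used for the torso volume conductor: lungs 0.0389,
#' liver 0.147, bone 0.02, blood pools 0.7, and 0.239 for space not
#' covered by any labeled organ (the average over tissues, including
#' skeletal muscle). Myocardium keeps the anisotropic tissue model.
#' @return named numeric vector.
#' @export
torsoConductivities <- function() {
  c(lungs = 0.0389, liver = 0.147, bone = 0.02, blood = 0.7,
    unassigned = 0.239)
}

# --- tetrahedral torso meshes ----------------------------------------------

# split the cube with corner ids c8 (standard ordering) into 6 tets
.KUHN_TETS <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                    c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

#' Build a box phantom torso with an embedded heart block
#'
#' A rectangular volume conductor meshed with structured tetrahedra (six
#' per cube), a centred cuboidal heart region whose nodes carry the
#' Dirichlet heart potentials, uniform background conductivity (the
#' averaged-tissue value 0.239 S/m by default) and six electrodes on the
#' anterior surface emulating the precordial leads.
#'
#' @param size box dimensions (mm).
#' @param h target cell edge (mm).
#' @param heartCenter,heartSize heart block position and extent (mm).
#' @param sigma background conductivity (S/m).
#' @param electrodes named electrode positions (k x 3 matrix); default
#'   six points spread on the anterior (minimum-y) face.
#' @return a [TorsoModel-class].
#' @export
buildPhantomTorso <- function(size = c(120, 80, 140), h = 10,
                              heartCenter = c(55, 30, 75),
                              heartSize = c(40, 30, 50), sigma = 0.239,
                              electrodes = NULL) {
  nc <- pmax(2L, as.integer(round(size / h)))
  hx <- size / nc
  d <- nc + 1L
  idx <- arrayInd(seq_len(prod(d)), d)
  nodes <- sweep(idx - 1, 2, hx, `*`)
  cube <- .elem_nodes(nc)
  tets <- do.call(rbind, lapply(seq_len(6), function(k) cube[, .KUHN_TETS[k, ]]))
  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] +
          nodes[tets[, 4], ]) / 4
  inHeart <- abs(cen[, 1] - heartCenter[1]) <= heartSize[1] / 2 &
             abs(cen[, 2] - heartCenter[2]) <= heartSize[2] / 2 &
             abs(cen[, 3] - heartCenter[3]) <= heartSize[3] / 2
  region <- ifelse(inHeart, 2L, 1L)
  heartNodes <- sort(unique(as.vector(tets[inHeart, ])))
  if (is.null(electrodes)) {
    ex <- seq(0.2, 0.8, length.out = 3) * size[1]
    ez <- c(0.4, 0.6) * size[3]
    electrodes <- as.matrix(expand.grid(x = ex, y = 0, z = ez))
    rownames(electrodes) <- paste0("V", 1:6)
  }
  new("TorsoModel", nodes = nodes, tets = tets, region = region,
      sigma = rep(sigma, nrow(tets)), heartNodes = as.integer(heartNodes),
      electrodes = as.matrix(electrodes))
}

#' Structured spherical-shell mesh
#'
#' A tetrahedral mesh of the shell a <= r <= R built on a spherical
#' lattice (poles merged, degenerate cells dropped). Inner-surface nodes
#' are the Dirichlet interface. Used for validating the Laplace solver
#' against closed-form series solutions.
#'
#' @param a,R inner and outer radii (mm).
#' @param nr,ntheta,nphi lattice resolution.
#' @param sigma conductivity (S/m).
#' @return a [TorsoModel-class] (no electrodes).
#' @export
sphericalShellMesh <- function(a = 30, R = 60, nr = 8, ntheta = 20,
                               nphi = 28, sigma = 0.2) {
  rr <- seq(a, R, length.out = nr + 1)
  th <- seq(0, pi, length.out = ntheta + 1)
  ph <- seq(0, 2 * pi, length.out = nphi + 1)[-(nphi + 1)]
  grid3 <- expand.grid(ir = seq_len(nr + 1), it = seq_len(ntheta + 1),
                       ip = seq_len(nphi))
  x <- rr[grid3$ir] * sin(th[grid3$it]) * cos(ph[grid3$ip])
  y <- rr[grid3$ir] * sin(th[grid3$it]) * sin(ph[grid3$ip])
  z <- rr[grid3$ir] * cos(th[grid3$it])
  nodes <- cbind(x, y, z)
  # merge coincident nodes (poles)
  key <- paste(round(nodes[, 1], 6), round(nodes[, 2], 6),
               round(nodes[, 3], 6))
  uk <- !duplicated(key)
  remap <- match(key, key[uk])
  nodes <- nodes[uk, , drop = FALSE]
  lin <- function(ir, it, ip) {
    ipw <- ((ip - 1L) %% nphi) + 1L
    (ir) + (nr + 1L) * ((it - 1L) + (ntheta + 1L) * (ipw - 1L))
  }
  cells <- list()
  for (ip in seq_len(nphi)) for (it in seq_len(ntheta)) for (ir in seq_len(nr)) {
    c8 <- c(lin(ir, it, ip), lin(ir + 1L, it, ip),
            lin(ir, it + 1L, ip), lin(ir + 1L, it + 1L, ip),
            lin(ir, it, ip + 1L), lin(ir + 1L, it, ip + 1L),
            lin(ir, it + 1L, ip + 1L), lin(ir + 1L, it + 1L, ip + 1L))
    cells[[length(cells) + 1L]] <- remap[c8]
  }
  cube <- do.call(rbind, cells)
  tets <- do.call(rbind, lapply(seq_len(6), function(k) cube[, .KUHN_TETS[k, ]]))
  vol <- .tet_volumes(nodes, tets)
  keep <- vol > 1e-9
  tets <- tets[keep, , drop = FALSE]
  rad <- sqrt(rowSums(nodes^2))
  heartNodes <- which(abs(rad - a) < 1e-6)
  new("TorsoModel", nodes = nodes, tets = tets,
      region = rep(1L, nrow(tets)), sigma = rep(sigma, nrow(tets)),
      heartNodes = as.integer(heartNodes),
      electrodes = matrix(numeric(0), 0, 3))
}

.tet_volumes <- function(nodes, tets) {
  v1 <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  v2 <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  v3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cx <- v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]
  cy <- v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]
  cz <- v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
  abs(v1[, 1] * cx + v1[, 2] * cy + v1[, 3] * cz) / 6
}

# P1 stiffness of the tetrahedral mesh with per-element conductivity
.tet_stiffness <- function(torso) {
  p <- torso@nodes
  tt <- torso@tets
  v1 <- p[tt[, 2], , drop = FALSE] - p[tt[, 1], , drop = FALSE]
  v2 <- p[tt[, 3], , drop = FALSE] - p[tt[, 1], , drop = FALSE]
  v3 <- p[tt[, 4], , drop = FALSE] - p[tt[, 1], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(v2, v3); c31 <- cr(v3, v1); c12 <- cr(v1, v2)
  det <- rowSums(v1 * c23)
  g2 <- c23 / det; g3 <- c31 / det; g4 <- c12 / det
  g1 <- -(g2 + g3 + g4)
  vol <- abs(det) / 6
  G <- list(g1, g2, g3, g4)
  m <- nrow(tt)
  rows <- integer(16 * m); cols <- integer(16 * m); vals <- numeric(16 * m)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    ii <- seq_len(m) + pos
    rows[ii] <- tt[, a]
    cols[ii] <- tt[, b]
    vals[ii] <- vol * torso@sigma * rowSums(G[[a]] * G[[b]])
    pos <- pos + m
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nrow(p), nrow(p)))
}

#' Solve the torso Laplace problem
#'
#' Imposes the heart extracellular potentials as Dirichlet values at the
#' ventricles-torso interface nodes, a no-flux (Neumann) condition on
#' the torso surface, and solves the heterogeneous Laplace equation by
#' sparse Cholesky factorization (factorized once and reused across time
#' steps). Potentials are returned at the electrodes (snapped to the
#' nearest mesh node) and optionally on the full mesh.
#'
#' @param torso a [TorsoModel-class].
#' @param heartPhi Dirichlet values at \code{torso@heartNodes}: a vector
#'   or a time x nodes matrix.
#' @param fullField also return node x time potentials?
#' @return list with \code{electrodes} (time x lead matrix) and, when
#'   requested, \code{field}.
#' @export
solveTorso <- function(torso, heartPhi, fullField = FALSE) {
  stopifnot(is(torso, "TorsoModel"))
  K <- .tet_stiffness(torso)
  n <- nrow(torso@nodes)
  dNodes <- torso@heartNodes
  fNodes <- setdiff(seq_len(n), dNodes)
  if (is.vector(heartPhi)) heartPhi <- matrix(heartPhi, nrow = 1)
  if (ncol(heartPhi) != length(dNodes))
    stop("heartPhi must have one value per heart-interface node")
  Kff <- K[fNodes, fNodes]
  Kfd <- K[fNodes, dNodes]
  ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Kff),
                                     "CsparseMatrix"), LDL = FALSE)
  phi <- matrix(0, nrow(heartPhi), n)
  phi[, dNodes] <- heartPhi
  rhs <- -Matrix::tcrossprod(Kfd, heartPhi)
  sol <- as.matrix(Matrix::solve(ch, rhs))
  phi[, fNodes] <- t(sol)
  elec <- NULL
  if (nrow(torso@electrodes) > 0) {
    eIdx <- vapply(seq_len(nrow(torso@electrodes)), function(k)
      which.min(colSums((t(torso@nodes) - torso@electrodes[k, ])^2)),
      integer(1))
    elec <- phi[, eIdx, drop = FALSE]
    colnames(elec) <- rownames(torso@electrodes)
  }
  out <- list(electrodes = elec)
  if (fullField) out$field <- phi
  out
}

#' Forward ECG from a simulation's snapshots
#'
#' Chains the passive-bidomain extracellular solve and the torso Laplace
#' solve: Vm snapshots on the heart grid are converted to extracellular
#' potentials, interpolated onto the torso's heart-interface nodes by
#' nearest neighbor, and propagated to the electrodes.
#'
#' @param system the heart [MonodomainSystem-class].
#' @param result a [SimResult-class] whose snapshots cover all
#'   conducting nodes.
#' @param torso a [TorsoModel-class].
#' @param heartOrigin translation applied to heart coordinates to place
#'   the grid inside the torso (mm).
#' @param lambda see [extracellularFromVm()].
#' @return list of class \code{ECGSet}: \code{time} (ms), \code{leads}
#'   (time x lead mV matrix).
#' @export
forwardEcg <- function(system, result, torso, heartOrigin = c(0, 0, 0),
                       lambda = 1) {
  if (!length(result@snapT)) stop("result holds no snapshots")
  vm <- t(result@snapV)  # nodes x time
  if (nrow(vm) != length(system@mass))
    stop("snapshots must cover every conducting node")
  phiH <- extracellularFromVm(system, vm, lambda = lambda)
  hc <- sweep(system@coords, 2, heartOrigin, `+`)
  tc <- torso@nodes[torso@heartNodes, , drop = FALSE]
  nn <- vapply(seq_len(nrow(tc)), function(k)
    which.min(colSums((t(hc) - tc[k, ])^2)), integer(1))
  heartPhi <- t(phiH[nn, , drop = FALSE])  # time x interface nodes
  sol <- solveTorso(torso, heartPhi)
  structure(list(time = result@snapT, leads = sol$electrodes),
            class = "ECGSet")
}

#' Compare ECG waveforms lead by lead
#'
#' Optionally resamples the simulated cycle linearly onto the reference
#' time base (removing rate differences), then reports the Pearson
#' correlation per common lead. Leads with zero variance yield NA.
#'
#' @param sim,ref lists with \code{time} and \code{leads} (time x lead
#'   matrices with column names), e.g. from [forwardEcg()].
#' @param resample stretch the simulated cycle onto the reference cycle
#'   length before correlating?
#' @return named numeric vector of per-lead correlations.
#' @export
compareEcg <- function(sim, ref, resample = TRUE) {
  common <- intersect(colnames(sim$leads), colnames(ref$leads))
  if (!length(common)) stop("no common leads")
  out <- setNames(numeric(length(common)), common)
  for (ld in common) {
    s <- sim$leads[, ld]
    r <- ref$leads[, ld]
    if (resample) {
      u <- seq(0, 1, length.out = length(r))
      us <- seq(0, 1, length.out = length(s))
      s <- approx(us, s, xout = u)$y
    } else if (length(s) != length(r)) {
      stop("lead lengths differ; enable resampling")
    }
    out[ld] <- if (sd(s) < 1e-12 || sd(r) < 1e-12) NA_real_ else cor(s, r)
  }
  out
}
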