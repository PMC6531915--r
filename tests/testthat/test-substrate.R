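test_that("synthetic infarct generation is deterministic and honest about ground truth", {
  spec <- syntheticInfarctSpec(dims = c(32, 32, 12), scarSize = c(12, 12, 6),
                               seed = 11L)
  a <- generateSyntheticInfarct(spec)
  b <- generateSyntheticInfarct(spec)
  expect_identical(a$volume@data, b$volume@data)
  expect_identical(a$truth, b$truth)
  expect_true(any(a$truth == 2L))
  expect_true(any(a$truth == 3L))
  # a zero-extent scar produces no scar voxels
  none <- generateSyntheticInfarct(
    syntheticInfarctSpec(dims = c(24, 24, 8), scarSize = c(0, 0, 0),
                         channelWidth = 0))
  expect_false(any(none$truth == 2L))
  # channel wider than scar is rejected
  expect_error(syntheticInfarctSpec(scarSize = c(10, 10, 10),
                                    channelWidth = 12), "wider")
})

test_that("SD classification applies the 2/3 SD thresholds", {
  # constructed volume: remote mean 100, SD 10
  d <- c(12, 12, 1)
  set.seed(1)
  v <- array(100, d)
  rem <- array(FALSE, d); rem[2:11, 2:4, 1] <- TRUE
  v[rem] <- rep(c(90, 110), 15)  # mean 100, sd ~10.17
  inf <- array(FALSE, d); inf[2:11, 8:11, 1] <- TRUE
  myo <- rem | inf
  s <- sd(v[rem])
  v[3, 8, 1] <- 100 + 3.1 * s   # scar
  v[4, 8, 1] <- 100 + 2.5 * s   # BZ
  v[5, 8, 1] <- 100 + 1.5 * s   # healthy
  vol <- new("VoxelVolume", data = v, spacing = 1.4, origin = rep(0.7, 3))
  masks <- new("RegionMasks", myocardium = myo, remote = rem, infarct = inf)
  lab <- sdClassify(vol, masks)
  expect_equal(lab[3, 8, 1], 2L)
  expect_equal(lab[4, 8, 1], 3L)
  expect_equal(lab[5, 8, 1], 1L)
  # voxels outside the infarct ROI stay healthy no matter how bright
  v2 <- v; v2[2, 2, 1] <- 1e5
  lab2 <- sdClassify(new("VoxelVolume", data = v2, spacing = 1.4,
                         origin = rep(0.7, 3)), masks)
  expect_equal(lab2[2, 2, 1], 1L)
})

test_that("classification matches the brute-force two-threshold oracle", {
  gen <- generateSyntheticInfarct(syntheticInfarctSpec(dims = c(28, 28, 10),
                                                       scarSize = c(12, 12, 6),
                                                       seed = 3L))
  lab <- sdClassify(gen$volume, gen$masks)
  expect_identical(lab, oracleSdScan(gen$volume, gen$masks))
})

test_that("classification recovers >= 90% of ground-truth scar voxels", {
  gen <- generateSyntheticInfarct(syntheticInfarctSpec(dims = c(32, 32, 12),
                                                       scarSize = c(12, 12, 6),
                                                       noiseSd = 0.5,
                                                       seed = 5L))
  lab <- sdClassify(gen$volume, gen$masks)
  scarTruth <- gen$truth == 2L
  expect_gte(mean(lab[scarTruth] == 2L), 0.9)
})

test_that("classification is invariant to a constant intensity shift", {
  gen <- generateSyntheticInfarct(syntheticInfarctSpec(dims = c(24, 24, 8),
                                                       scarSize = c(10, 10, 5),
                                                       seed = 9L))
  lab <- sdClassify(gen$volume, gen$masks)
  shifted <- gen$volume
  shifted@data <- shifted@data + 500
  expect_identical(lab, sdClassify(shifted, gen$masks))
})

test_that("an empty per-slice remote ROI is reported with the slice number", {
  gen <- generateSyntheticInfarct(syntheticInfarctSpec(dims = c(24, 24, 8),
                                                       scarSize = c(10, 10, 5),
                                                       seed = 2L))
  masks <- gen$masks
  k <- which(apply(masks@infarct, 3, any))[1]
  masks@remote[, , k] <- FALSE
  expect_error(sdClassify(gen$volume, masks), as.character(k))
})

test_that("voxel-to-element mapping assigns by centroid containment", {
  gen <- generateSyntheticInfarct(syntheticInfarctSpec(dims = c(24, 24, 8),
                                                       scarSize = c(10, 10, 5),
                                                       seed = 4L))
  lab <- sdClassify(gen$volume, gen$masks)
  g <- ivtlab:::.new_grid(c(20, 20, 6), dx = 0.4, origin = c(8, 8, 2.8))
  mapped <- mapLabelsToGrid(lab, g, spacing = 1.4, origin = rep(0.7, 3))
  # oracle: explicit centroid-in-voxel lookup
  cen <- elementCentroids(g)
  ijk <- floor(cen / 1.4) + 1
  expect_identical(mapped@label,
                   as.integer(lab[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]))
  # aligned identical-resolution grid copies labels one to one
  g1 <- ivtlab:::.new_grid(dim(lab), dx = 1.4, origin = c(0, 0, 0))
  m1 <- mapLabelsToGrid(lab, g1, spacing = 1.4, origin = rep(0.7, 3))
  expect_identical(m1@label, as.integer(as.vector(lab)))
  # 1.4 mm voxels cover at most ceiling(1.4 / 0.4)^3 = 64 elements
  vox <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  expect_lte(max(table(vox)), 64)
  # centroids outside the volume are an error
  gBig <- ivtlab:::.new_grid(c(40, 4, 4), dx = 1.4, origin = c(0, 0, 0))
  expect_error(mapToGrid(lab, gBig, spacing = 1.4, origin = rep(0.7, 3)),
               "outside")
})

test_that("fibrosis assignment takes exactly the top-intensity BZ fraction", {
  g <- buildFixture("isthmus_sheet", dx = 0.8)
  nbz <- sum(g@label == 3L)
  for (p in c(0, 10, 20, 30, 100)) {
    gf <- assignFibrosis(g, p)
    expect_equal(sum(gf@label == 4L), round(p / 100 * nbz))
    # fibrosis only ever replaces former BZ
    expect_true(all(g@label[gf@label == 4L] == 3L))
  }
  # selection equals a brute-force full sort by (intensity desc, index)
  p <- 30
  gf <- assignFibrosis(g, p)
  bz <- which(g@label == 3L)
  ord <- bz[order(-g@intensity[bz], bz)]
  expect_identical(which(gf@label == 4L),
                   sort(ord[seq_len(round(p / 100 * length(bz)))]))
  expect_error(assignFibrosis(g, -5), "percentage")
  expect_error(assignFibrosis(g, 150), "percentage")
})

test_that("fibrotic patches grow with the noise correlation length", {
  patchSize <- function(corr) {
    gen <- generateSyntheticInfarct(
      syntheticInfarctSpec(dims = c(40, 40, 6), scarSize = c(16, 16, 3),
                           channelWidth = 0, bzWidth = 7,
                           corrLength = corr, corrFrac = 1, seed = 21L))
    g <- ivtlab:::.new_grid(c(38, 38, 4) * 1L, dx = 1.4,
                            origin = c(1.4, 1.4, 1.4))
    g@label <- as.integer(mapToGrid(gen$truth, g, spacing = 1.4,
                                    origin = rep(0.7, 3)))
    inten <- mapToGrid(gen$volume, g)
    gf <- assignFibrosis(g, 30, intensity = inten)
    fib <- array(gf@label == 4L, g@dims)
    # mean 26-connected component size
    comp <- array(0L, dim(fib)); nc <- 0L
    for (i in which(fib)) {
      if (comp[i] > 0) next
      nc <- nc + 1L
      frontier <- i
      comp[i] <- nc
      while (length(frontier)) {
        nb <- integer(0)
        for (f in frontier) {
          ijk <- arrayInd(f, dim(fib))
          for (dx1 in -1:1) for (dy in -1:1) for (dz in -1:1) {
            p <- ijk + c(dx1, dy, dz)
            if (any(p < 1) || any(p > dim(fib))) next
            li <- p[1] + dim(fib)[1] * (p[2] - 1 + dim(fib)[2] * (p[3] - 1))
            if (fib[li] && comp[li] == 0L) { comp[li] <- nc; nb <- c(nb, li) }
          }
        }
        frontier <- nb
      }
    }
    sum(fib) / nc
  }
  expect_gt(patchSize(4.2), patchSize(0.5))
})

test_that("fiber rules give unit vectors with the expected helix profile", {
  g <- ivtlab:::.new_grid(c(6, 6, 10), dx = 0.4)
  gf <- assignFibers(g, helixEndo = 60, helixEpi = -60)
  expect_true(all(abs(sqrt(rowSums(gf@fiber^2)) - 1) < 1e-12))
  dpt <- ivtlab:::.transmural_depth(g, "z")
  mid <- which(abs(dpt - 0.5) < 1e-9)
  # mid-depth helix angle 0: fiber along the circumferential (x) axis
  expect_true(all(abs(gf@fiber[mid, 1] - 1) < 1e-9))
  # smoothing with vanishing kernel leaves the field unchanged
  gs <- assignFibers(g, smoothSigma = 1e-9)
  expect_lt(max(abs(gs@fiber - gf@fiber)), 1e-9)
  expect_error(assignFibers(ivtlab:::.new_grid(c(4, 4, 1), 0.4),
                            transmuralAxis = "z"), NA)
})

test_that("transmural layers follow the 17/41/42 cut points", {
  g <- ivtlab:::.new_grid(c(2, 2, 100), dx = 0.1)
  gl <- assignTransmuralLayers(g)
  dpt <- ivtlab:::.transmural_depth(g, "z")
  expect_true(all(gl@layer[dpt < 0.17] == 1L))
  expect_true(all(gl@layer[dpt >= 0.17 & dpt < 0.58] == 2L))
  expect_true(all(gl@layer[dpt >= 0.58] == 3L))
  # oracle re-count by explicit binning
  expect_equal(as.integer(table(gl@layer)),
               as.integer(table(cut(dpt, c(0, 0.17, 0.58, 1),
                                    right = FALSE))))
  expect_true(all(assignTransmuralLayers(g, c(1, 0, 0))@layer == 1L))
  expect_error(assignTransmuralLayers(g, c(0.5, 0.2, 0.2)), "sum")
})

test_that("fixture geometries are exact", {
  slab <- buildFixture("slab")
  expect_identical(slab@dims, c(50L, 50L, 15L))
  # blocked channel: fully scarred between the blocks
  blocked <- buildFixture("isthmus_sheet", dx = 0.8, mouthLower = 0,
                          mouthUpper = 0, tailLength = 0)
  open <- buildFixture("isthmus_sheet", dx = 0.8, tailLength = 0)
  cx <- blocked@dims[1] * 0.8 / 2
  cen <- elementCentroids(blocked)
  inBand <- abs(cen[, 2] - blocked@dims[2] * 0.8 / 2) <= 11
  midline <- inBand & abs(cen[, 1] - cx) < 0.8
  expect_true(all(blocked@label[midline] == 2L))
  expect_true(any(open@label[midline] == 3L))
  # label census against the analytic region areas (one element-layer slack)
  sheet <- buildFixture("isthmus_sheet", dx = 0.8, tailLength = 0)
  dx <- 0.8
  scarArea <- sum(sheet@label == 2L) * dx^2
  hh <- 22; wTot <- 26
  chanArea <- (3.2 + 6.4) / 2 * hh
  expected <- wTot * hh - chanArea
  # perimeter elements can fall either side of the analytic boundary
  perim <- (2 * (wTot + hh) + 2 * hh) * dx
  expect_lt(abs(scarArea - expected), perim)
})
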