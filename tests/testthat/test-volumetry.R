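test_that("rigid transforms compose, invert and apply correctly", {
  ctr <- c(50, 50)
  a <- rigidTransform(30, c(5, -3), ctr)
  b <- rigidTransform(-12, c(-8, 4), ctr)
  p <- cbind(c(10, 80, 33), c(20, 70, 90))
  ## composition agrees with sequential application
  expect_equal(applyTransform(composeTransform(a, b), p),
               applyTransform(a, applyTransform(b, p)), tolerance = 1e-10)
  ## inverse undoes the transform
  expect_equal(applyTransform(invertTransform(a), applyTransform(a, p)), p,
               tolerance = 1e-10)
  id <- composeTransform(a, invertTransform(a))
  expect_equal(id@rotation, 0)
  expect_equal(id@translation, c(0, 0), tolerance = 1e-10)
  ## scaling a transform scales its translation and center
  s <- scaleTransform(a, 0.25)
  expect_equal(s@translation, a@translation * 0.25)
  expect_equal(s@rotation, a@rotation)
})

test_that("self-registration returns the identity", {
  g <- smallSection()
  r <- registerPair(g$section, g$section)
  expect_lt(abs(r@rotation), 0.25)
  expect_lt(max(abs(r@translation)), 0.5)
  expect_false(attr(r, "low_confidence"))
})

test_that("a known rotation + shift of an image is recovered", {
  g <- smallSection()
  feat <- necrotherm:::opponentChannel(g$section)
  d <- dim(feat)
  ctr <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  applied <- rigidTransform(5, c(12, -7), ctr)
  moving <- necrotherm:::warpMatrix(feat, applied, fill = 0)
  r <- registerPair(feat, moving)
  want <- invertTransform(applied)
  expect_lt(abs(r@rotation - want@rotation), 1)
  expect_lt(max(abs(r@translation - want@translation)), 2)
})

test_that("pure translation of a ring fixture recovers zero rotation", {
  ## plain ring feature image
  d <- 256
  xy <- expand.grid(x = 1:d, y = 1:d)
  rr <- sqrt((xy$x - 128.5)^2 + (xy$y - 128.5)^2)
  ring <- matrix(as.numeric(rr > 70 & rr < 90) * 50, d, d)
  ## remove rotational ambiguity with a gap
  ang <- atan2(xy$y - 128.5, xy$x - 128.5)
  ring[abs(ang) < 0.4 & rr > 60] <- 0
  applied <- rigidTransform(0, c(9, 5), c(128.5, 128.5))
  moving <- necrotherm:::warpMatrix(ring, applied, fill = 0)
  r <- registerPair(ring, moving, smooth_px = 4)
  expect_lt(abs(r@rotation), 0.5)
  expect_lt(max(abs(r@translation - c(-9, -5))), 1.5)
})

test_that("stack registration recovers known per-section perturbations", {
  p <- synthSectionParams(canvas_um = 1200, um_per_px = 0.5,
                          radius_um = 300, ring_width_um = 60)
  stk <- genStack(p, n_sections = 5, jitter_rot_sd = 5,
                  jitter_trans_sd = 12, shared_section = TRUE, seed = 11)
  rs <- registerStack(stk$sections, maps = stk$truth_maps, map_scale = 1)
  ref <- rs@reference
  expect_equal(rs@transforms[[ref]]@rotation, 0)
  expect_equal(rs@transforms[[ref]]@translation, c(0, 0))
  for (i in seq_along(stk$sections)) {
    want <- composeTransform(stk$jitters[[ref]],
                             invertTransform(stk$jitters[[i]]))
    got <- rs@transforms[[i]]
    expect_lt(abs(got@rotation - want@rotation), 1)
    expect_lt(max(abs(got@translation - want@translation)), 2)
  }
})

test_that("map warping is value-preserving and approximately mass-conserving", {
  g <- smallSection()
  map <- g$truth
  ## identity leaves the map unchanged
  id <- rigidTransform(0, c(0, 0), c(1, 1))
  expect_equal(values(warpMap(map, id)), values(map))
  ## smooth fixture: round-trip within interpolation tolerance
  d <- 41
  sm <- outer(1:d, 1:d, function(i, j)
    100 * exp(-((i - 21)^2 + (j - 21)^2) / 60))
  smap <- necrosisMap(sm)
  tr <- rigidTransform(7, c(2.5, -1.5), c(21, 21))
  back <- warpMap(warpMap(smap, tr), invertTransform(tr))
  interior <- values(back)[10:32, 10:32] - sm[10:32, 10:32]
  expect_lt(max(abs(interior)), 2)
  ## mass approximately conserved under a small transform
  w <- warpMap(smap, rigidTransform(2, c(1, 1), c(21, 21)))
  expect_lt(abs(sum(values(w)) - sum(sm)) / sum(sm), 0.02)
})

test_that("depth interpolation is linear with preserved nodes", {
  m1 <- necrosisMap(matrix(c(0, 40, 80, 100), 2, 2), depth_um = 0)
  m2 <- necrosisMap(matrix(c(20, 40, 0, 60), 2, 2), depth_um = 40)
  mk_stack <- function(maps) {
    n <- length(maps)
    new("RegisteredStack", maps = maps,
        transforms = replicate(n, rigidTransform(0, c(0, 0), c(1.5, 1.5))),
        reference = 1L, spacing_um = 40, flags = logical(n))
  }
  vol <- interpolateStack(mk_stack(list(m1, m2)), target_step = 4)
  expect_equal(dim(values(vol))[3], 11)
  expect_equal(values(vol)[, , 1], values(m1))
  expect_equal(values(vol)[, , 11], values(m2))
  ## midpoint is the elementwise mean
  expect_equal(values(vol)[, , 6], (values(m1) + values(m2)) / 2)
  ## identical maps: constant along depth
  vol2 <- interpolateStack(mk_stack(list(m1, m1)), target_step = 4)
  for (k in 1:11) expect_equal(values(vol2)[, , k], values(m1))
  expect_error(interpolateStack(mk_stack(list(m1))), "at least 2")
})

test_that("volume metrics match analytic solids", {
  ## constant-50% cylinder: radius 5 patches, 11 depth levels
  d <- 21
  disk <- outer(1:d, 1:d, function(i, j)
    as.numeric((i - 11)^2 + (j - 11)^2 <= 25) * 50)
  vol <- new("NecrosisVolume",
             values = array(rep(disk, 11), c(d, d, 11)),
             patch_um = 200, step_um = 4, depths_um = seq(0, 40, by = 4))
  m <- volumeMetrics(vol)
  npix <- sum(disk > 0)
  expect_equal(m$volume_mm3, npix * 11 * 0.2^2 * 0.004)
  ## within one voxel shell of the analytic cylinder volume
  expect_equal(npix, pi * 5^2, tolerance = 0.15)
  expect_true(all(m$profile$area_cm2 == npix * (200e-4)^2))
  expect_true(all(m$profile$percent == 50))
  ## all-zero volume
  z <- new("NecrosisVolume", values = array(0, c(5, 5, 3)), patch_um = 200,
           step_um = 4, depths_um = c(0, 4, 8))
  mz <- volumeMetrics(z)
  expect_equal(mz$volume_mm3, 0)
  expect_true(all(mz$profile$area_cm2 == 0))
  expect_true(all(mz$profile$percent == 0))
})

test_that("volume metrics are invariant under a rigid transform of the stack", {
  d <- 41
  disk <- outer(1:d, 1:d, function(i, j)
    as.numeric((i - 21)^2 + (j - 21)^2 <= 64) * 80)
  maps <- list(necrosisMap(disk), necrosisMap(disk), necrosisMap(disk))
  id <- rigidTransform(0, c(0, 0), c(21, 21))
  mv <- rigidTransform(9, c(2, -3), c(21, 21))
  st1 <- new("RegisteredStack", maps = maps,
             transforms = list(id, id, id), reference = 1L,
             spacing_um = 40, flags = logical(3))
  ## same stack rigidly moved as a whole (maps pre-warped)
  st2 <- new("RegisteredStack", maps = lapply(maps, warpMap, t = mv),
             transforms = list(id, id, id), reference = 1L,
             spacing_um = 40, flags = logical(3))
  ## compare at the half-plateau contour: bilinear resampling spreads a
  ## sharp-edged lesion symmetrically about its 50% level, so that contour
  ## is the rigid-invariant one (the configurable eps of volumeMetrics)
  v1 <- volumeMetrics(interpolateStack(st1, 4), eps = 40)$volume_mm3
  v2 <- volumeMetrics(interpolateStack(st2, 4), eps = 40)$volume_mm3
  expect_lt(abs(v1 - v2) / v1, 0.05)
})

test_that("volume export writes TIFF, metrics and profile", {
  vol <- new("NecrosisVolume",
             values = array(stats::runif(5 * 5 * 3, 0, 100), c(5, 5, 3)),
             patch_um = 200, step_um = 4, depths_um = c(0, 4, 8))
  dir <- withr::local_tempdir()
  writeVolume(vol, dir)
  expect_true(file.exists(file.path(dir, "volume.tif")))
  met <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(met$volume_mm3, volumeMetrics(vol)$volume_mm3,
               tolerance = 1e-8)
  prof <- data.table::fread(file.path(dir, "depth_profile.csv"))
  expect_equal(nrow(prof), 3)
})
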