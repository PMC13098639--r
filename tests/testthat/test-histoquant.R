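test_that("mosaic planning reproduces the printed whole-slide tilings", {
  p1 <- planMosaic(30720, 30976)
  expect_equal(c(p1@mosaic_cols, p1@mosaic_rows), c(32L, 32L))
  expect_equal(c(p1@tile_w, p1@tile_h), c(960L, 968L))
  expect_equal(p1@mosaic_cols * p1@mosaic_rows, 1024L)
  p2 <- planMosaic(103680, 101376)
  expect_equal(c(p2@tile_w, p2@tile_h), c(810L, 792L))
  expect_equal(p2@mosaic_cols * p2@mosaic_rows, 16384L)
  p3 <- planMosaic(76800, 81664)
  expect_equal(c(p3@tile_w, p3@tile_h), c(1200L, 638L))
  expect_equal(p3@mosaic_cols * p3@mosaic_rows, 8192L)
  ## every tile obeys the byte bound
  for (p in list(p1, p2, p3))
    expect_lte(as.double(p@tile_w) * p@tile_h * 4, 4 * 1024^2)
})

test_that("split/stitch is a lossless partition", {
  set.seed(1)
  px <- array(sample(0:255, 2048 * 1536 * 3, TRUE), c(1536, 2048, 3))
  plan <- planMosaic(2048, 1536)
  tiles <- splitSection(px, plan)
  expect_equal(length(tiles), plan@mosaic_cols * plan@mosaic_rows)
  expect_identical(stitchSection(tiles, plan), px * 1)
  ## edge tiles smaller, extents reconstruct the raster
  plan2 <- planMosaic(500, 300, byte_bound = 128 * 128 * 4)
  px2 <- array(stats::runif(500 * 300 * 3, 0, 255), c(300, 500, 3))
  tiles2 <- splitSection(px2, plan2)
  widths <- vapply(1:plan2@mosaic_cols,
                   function(cc) dim(tiles2[[sprintf("r1_c%d", cc)]])[2], 1)
  expect_equal(sum(widths), 500)
  expect_equal(stitchSection(tiles2, plan2), px2)
  ## missing tile is reported by grid position
  tiles2[["r1_c2"]] <- NULL
  expect_error(stitchSection(tiles2, plan2), "row 1, col 2")
})

test_that("classical segmenter recovers isolated and touching cells", {
  ## blank tile: nothing to segment
  blank <- array(245, c(120, 120, 3))
  expect_equal(max(segmentCellsClassical(blank, um_per_px = 1)), 0)
  ## 50 non-touching disks on a grid, radius 3 um at 1 um/px
  set.seed(3)
  tile <- array(245, c(400, 400, 3))
  centers <- expand.grid(x = seq(30, 390, by = 51),
                         y = seq(30, 390, by = 51))[1:50, ]
  for (i in 1:50) {
    xs <- (centers$x[i] - 4):(centers$x[i] + 4)
    ys <- (centers$y[i] - 4):(centers$y[i] + 4)
    dd <- sqrt(outer((ys - centers$y[i])^2, (xs - centers$x[i])^2, `+`))
    for (ch in 1:3) {
      col <- c(170, 195, 200)[ch]
      sub <- tile[ys, xs, ch]
      sub[dd <= 3] <- col
      tile[ys, xs, ch] <- sub
    }
  }
  seg <- segmentCells(tile, um_per_px = 1)
  expect_equal(nrow(cellTable(seg)), 50)
  found <- cellTable(seg)
  ord <- order(found$cy * 1000 + found$cx)
  truth_ord <- order(centers$y * 1000 + centers$x)
  expect_true(all(abs(found$cx[ord] - centers$x[truth_ord]) <= 1))
  expect_true(all(abs(found$cy[ord] - centers$y[truth_ord]) <= 1))
  ## two overlapping disks split by the watershed
  tile2 <- array(245, c(60, 60, 3))
  for (ctr in list(c(25, 30), c(37, 30))) {
    xs <- 1:60; ys <- 1:60
    dd <- sqrt(outer((ys - ctr[2])^2, (xs - ctr[1])^2, `+`))
    for (ch in 1:3) {
      sub <- tile2[, , ch]
      sub[dd <= 8] <- c(150, 100, 80)[ch]
      tile2[, , ch] <- sub
    }
  }
  seg2 <- segmentCells(tile2, um_per_px = 1)
  expect_equal(nrow(cellTable(seg2)), 2)
})

test_that("RGB box classification matches the printed rules and is disjoint", {
  expect_equal(classifyRGB(100, 100, 100), "brown")
  expect_equal(classifyRGB(170, 200, 200), "blue")
  expect_equal(classifyRGB(255, 255, 255), "unclassified")
  ## boundary membership is inclusive
  expect_equal(classifyRGB(60, 151, 130), "brown")
  expect_equal(classifyRGB(150, 155, 160), "blue")
  ## exhaustive disjointness over a coarse RGB lattice
  rr <- seq(0, 255, by = 5)
  grid <- expand.grid(r = rr, g = rr, b = rr)
  rules <- cellClassRules()
  brown <- grid$r >= 60 & grid$r <= 210 & grid$g <= 151 & grid$b <= 130
  blue <- grid$r >= 150 & grid$r <= 186 & grid$g >= 155 & grid$b >= 160
  expect_false(any(brown & blue))
  ## overlapping G ranges are rejected at construction
  expect_error(cellClassRules(brown_g_max = 200, blue_g_min = 160),
               "disjoint")
})

test_that("patch fractions implement the blue/brown area model", {
  ## synthetic cell table: patch (1,1) blue-only, (1,2) equal areas,
  ## (2,1) empty, (2,2) brown-heavy
  cells <- data.frame(
    label = 1:5,
    area_px = c(100, 80, 80, 50, 400),
    area_um2 = c(100, 80, 80, 50, 400),
    mean_r = 0, mean_g = 0, mean_b = 0,
    cx = c(50, 250, 260, 350, 360),
    cy = c(50, 50, 60, 250, 260),
    class = c("blue", "blue", "brown", "blue", "brown"))
  seg <- fakeSegmentation(cells, um_per_px = 1, dim_px = c(400, 400))
  ps <- patchFractions(seg, patch_um = 200)
  st <- patchTable(ps)
  g11 <- st[st$row == 1 & st$col == 1, ]
  expect_equal(g11$gamma, 1)
  expect_equal(g11$rho, 0)
  expect_equal(necrosisFromPatch(g11$gamma, g11$rho), 100)
  g12 <- st[st$row == 1 & st$col == 2, ]
  expect_equal(g12$gamma, 0.5)
  g21 <- st[st$row == 2 & st$col == 1, ]
  expect_true(is.na(g21$gamma))
  expect_equal(necrosisFromPatch(g21$gamma, g21$rho), 0)
  g22 <- st[st$row == 2 & st$col == 2, ]
  expect_equal(g22$rho, 400 / 40000)
  ## edge patches carry their true area
  seg2 <- fakeSegmentation(cells, um_per_px = 1, dim_px = c(300, 300))
  st2 <- patchTable(patchFractions(seg2, patch_um = 200))
  expect_equal(st2$patch_area_um2[st2$row == 2 & st2$col == 2], 100 * 100)
  ## missing scale metadata is an error
  seg3 <- fakeSegmentation(cells, um_per_px = 1)
  seg3@um_per_px <- numeric()
  expect_error(patchFractions(seg3), "scale metadata")
})

test_that("patch necrosis score follows the exponential decay model", {
  expect_equal(necrosisFromPatch(1, 0), 100)
  expect_equal(necrosisFromPatch(0, 0.3), 0)
  expect_equal(necrosisFromPatch(0.5, 0.01), 50 * exp(-1))
  ## monotone: increasing in gamma, decreasing in rho
  gam <- seq(0, 1, by = 0.1)
  expect_true(all(diff(necrosisFromPatch(gam, 0.01)) > 0))
  rho <- seq(0, 0.1, by = 0.01)
  expect_true(all(diff(necrosisFromPatch(0.8, rho)) < 0))
})

test_that("multilevel Otsu agrees with exhaustive search", {
  set.seed(5)
  ## quadrimodal sample: thresholds must fall between adjacent modes
  x <- c(stats::rnorm(300, 10, 1.5), stats::rnorm(300, 30, 1.5),
         stats::rnorm(300, 50, 1.5), stats::rnorm(300, 70, 1.5))
  th <- multilevelOtsu(x, 3, bins = 64)
  expect_true(th[1] > 13 && th[1] < 27)
  expect_true(th[2] > 33 && th[2] < 47)
  expect_true(th[3] > 53 && th[3] < 67)
  ## equivalence with the plain-R exhaustive oracle on the same histogram
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = 65),
                      plot = FALSE)
  expect_equal(necrotherm:::multi_otsu_cpp(h$counts, 3L), otsuOracle(h$counts, 3))
  ## single-threshold case matches the classical brute-force scan
  y <- c(stats::rnorm(400, 20, 3), stats::rnorm(400, 60, 3))
  hy <- graphics::hist(y, breaks = seq(min(y), max(y), length.out = 65),
                       plot = FALSE)
  expect_equal(necrotherm:::multi_otsu_cpp(hy$counts, 1L), otsuOracle(hy$counts, 1))
  ## permutation invariance and degenerate input
  expect_equal(multilevelOtsu(sample(x), 3, bins = 64), th)
  expect_error(multilevelOtsu(rep(1, 50), 3), "degenerate")
})

test_that("stage-1 centroid locks onto the component holding the maximum", {
  ## quadrimodal map: background 0, scattered low values, a weaker
  ## peripheral blob, and a central disk holding the maximum
  mk <- function(jit) {
    m <- matrix(0, 21, 21)
    for (i in 1:21) for (j in 1:21) {
      if ((i + 2 * j) %% 9 == 0) m[i, j] <- 22 + (i %% 4)
      if ((i - 3)^2 + (j - 18)^2 <= 2) m[i, j] <- 52 + (j %% 3)
      if ((i - 11)^2 + (j - 11)^2 <= 16) m[i, j] <- 90 + jit * (i %% 3)
    }
    m
  }
  maps <- lapply(1:4, function(s) necrosisMap(mk(s %% 2)))
  cen <- stage1Centroid(maps)
  expect_lt(abs(cen["x"] - 11), 1)
  expect_lt(abs(cen["y"] - 11), 1)
  ## all-zero maps degenerate
  zero <- lapply(1:3, function(i) necrosisMap(matrix(0, 21, 21)))
  expect_error(stage1Centroid(zero), "degenerate|empty")
})

test_that("stage-2 filter keeps the compact lesion and drops artifacts", {
  ## background 0, scattered low noise, intermediate artifacts (one thin
  ## cross close by, one compact blob far away), central high-value disk
  m <- matrix(0, 25, 25)
  for (i in 1:25) for (j in 1:25) {
    if ((3 * i + j) %% 11 == 0) m[i, j] <- 20 + (i %% 4)
    if (i >= 2 & i <= 4 & j >= 20 & j <= 24) m[i, j] <- 62 + (j %% 3)
    if ((i - 13)^2 + (j - 13)^2 <= 20) m[i, j] <- 85 + ((i + j) %% 4)
  }
  m[15:25, 4] <- 64
  m[20, 1:9] <- 64
  map <- necrosisMap(m)
  fr <- stage2Filter(map, centroid = c(x = 13, y = 13))
  expect_false(fr@empty)
  out <- values(fr@map)
  expect_true(all(out <= m + 1e-9))                  # filtered <= input
  expect_true(all(out[out > 0] >= 85))               # only the disk kept
  expect_equal(sum(out > 0), sum(m >= 85))
  ## nonzero support is a single connected component
  expect_equal(max(EBImage::bwlabel(out > 0)), 1)
  ## solidity arithmetic: convex disk ~1, thin cross well below 0.6
  idx <- which(m >= 85, arr.ind = TRUE)
  expect_gte(necrotherm:::componentSolidity(idx[, 1], idx[, 2]), 0.9)
  cross <- rbind(cbind(15:25, rep(4, 11)), cbind(rep(20, 9), 1:9))
  expect_lt(necrotherm:::componentSolidity(cross[, 1], cross[, 2]), 0.6)
  ## no survivor: all components below the solidity floor
  m2 <- matrix(0, 25, 25)
  for (i in 1:25) for (j in 1:25)
    if ((3 * i + j) %% 11 == 0) m2[i, j] <- 20 + (i %% 4)
  m2[2:12, 20] <- 62 + (2:12) %% 3   # intermediate thin cross
  m2[7, 15:25] <- 62 + (15:25) %% 3
  m2[10:22, 8] <- 85 + (10:22) %% 4  # high thin cross
  m2[16, 2:14] <- 85 + (2:14) %% 4
  expect_warning(fr2 <- stage2Filter(necrosisMap(m2), c(x = 13, y = 13)),
                 "no object")
  expect_true(fr2@empty)
  expect_true(all(values(fr2@map) == 0))
})

test_that("necrosis map CSV round-trips", {
  m <- necrosisMap(matrix(stats::runif(30, 0, 100), 5, 6), depth_um = 120,
                   section_id = "s1")
  path <- withr::local_tempfile(fileext = ".csv")
  writeNecrosisMap(m, path)
  m2 <- readNecrosisMap(path)
  expect_equal(values(m2), values(m))
  expect_equal(m2@depth_um, 120)
  expect_equal(m2@section_id, "s1")
})
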