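## Whole-slide mosaic planning, cell classification, patchwise necrosis
## scoring and the two-stage artifact filter.

#' Plan a power-of-two mosaic decomposition
#'
#' Reconstructs the tiling rule of whole-slide export under a per-tile
#' storage bound: starting from a 1 x 1 mosaic, the tile count is doubled
#' along the dimension whose current tile extent is larger (ties double the
#' columns) until `tile_w * tile_h * 4` bytes fits the bound. Mosaic
#' dimensions are therefore powers of two and tile sizes are
#' `ceiling(width / cols)` x `ceiling(height / rows)`.
#'
#' @param width,height section size, px
#' @param byte_bound per-tile bound, bytes (default 4 MiB)
#' @param bytes_per_px bytes per pixel in the accounting (default 4)
#' @return a [MosaicPlan-class]
#' @examples
#' planMosaic(30720, 30976)    # 32 x 32 mosaic, 960 x 968 tiles
#' planMosaic(103680, 101376)  # 128 x 128 mosaic, 810 x 792 tiles
#' @export
planMosaic <- function(width, height, byte_bound = 4 * 1024^2,
                       bytes_per_px = 4) {
  if (width < 1 || height < 1) stop("width and height must be >= 1")
  cols <- 1L; rows <- 1L
  repeat {
    tw <- ceiling(width / cols); th <- ceiling(height / rows)
    if (as.double(tw) * th * bytes_per_px <= byte_bound) break
    if (tw >= th) cols <- cols * 2L else rows <- rows * 2L
  }
  new("MosaicPlan", mosaic_cols = as.integer(cols),
      mosaic_rows = as.integer(rows), tile_w = as.integer(tw),
      tile_h = as.integer(th), byte_bound = byte_bound,
      width = as.integer(width), height = as.integer(height))
}

#' Split a section into mosaic tiles
#'
#' Row-major tile order; edge tiles may be smaller. The partition is
#' lossless: [stitchSection()] reproduces the raster exactly.
#'
#' @param section a [SectionImage-class] (or pixel array)
#' @param plan a [MosaicPlan-class] matching the section size
#' @return list of pixel arrays named `"r<row>_c<col>"`
#' @export
splitSection <- function(section, plan) {
  px <- if (is(section, "SectionImage")) section@pixels else section
  d <- dim(px)
  if (d[1] != plan@height || d[2] != plan@width)
    stop("plan does not match the section size")
  tiles <- list()
  for (r in seq_len(plan@mosaic_rows)) {
    y0 <- (r - 1) * plan@tile_h + 1
    y1 <- min(r * plan@tile_h, d[1])
    if (y0 > d[1]) next
    for (cc in seq_len(plan@mosaic_cols)) {
      x0 <- (cc - 1) * plan@tile_w + 1
      x1 <- min(cc * plan@tile_w, d[2])
      if (x0 > d[2]) next
      tiles[[sprintf("r%d_c%d", r, cc)]] <- px[y0:y1, x0:x1, , drop = FALSE]
    }
  }
  attr(tiles, "plan") <- plan
  tiles
}

#' Stitch mosaic tiles back into a raster
#'
#' @param tiles list from [splitSection()]
#' @param plan the [MosaicPlan-class]
#' @return pixel array of size height x width x 3
#' @export
stitchSection <- function(tiles, plan = attr(tiles, "plan")) {
  if (is.null(plan)) stop("a MosaicPlan is required")
  out <- array(0, dim = c(plan@height, plan@width, 3))
  for (r in seq_len(plan@mosaic_rows)) {
    y0 <- (r - 1) * plan@tile_h + 1
    if (y0 > plan@height) next
    for (cc in seq_len(plan@mosaic_cols)) {
      x0 <- (cc - 1) * plan@tile_w + 1
      if (x0 > plan@width) next
      key <- sprintf("r%d_c%d", r, cc)
      tile <- tiles[[key]]
      if (is.null(tile))
        stop("missing tile at mosaic position row ", r, ", col ", cc)
      out[y0:(y0 + dim(tile)[1] - 1), x0:(x0 + dim(tile)[2] - 1), ] <- tile
    }
  }
  out
}

#' Classical stain-based cell segmenter
#'
#' Default segmenter behind [segmentCells()]: both hematoxylin-blue and
#' DAB-brown cells are darker in the green channel than the near-white
#' slide background, but by very different amounts, so a single Otsu cut
#' would swallow the faint blue class into the background. Foreground is
#' instead everything darker than the background level (the median, since
#' background dominates the tile) by at least `bg_margin`. Holes are
#' filled, touching cells are split by watershed on the distance map, and
#' objects outside a plausible cell-area band (5-10 um cell diameters) are
#' removed.
#'
#' @param tile pixel array (h x w x 3, 0-255)
#' @param um_per_px microns per pixel
#' @param bg_margin minimum darkness contrast over the background level
#'   (fraction of full scale)
#' @param diameter_band_um plausible cell diameter range, um
#' @param band_relax multiplicative relaxation of the area band
#' @param watershed_tolerance see [EBImage::watershed()]
#' @return integer label matrix (0 = background)
#' @export
segmentCellsClassical <- function(tile, um_per_px, bg_margin = 0.05,
                                  diameter_band_um = c(5, 10),
                                  band_relax = 4,
                                  watershed_tolerance = 1) {
  dark <- (255 - tile[, , 2]) / 255
  rng <- range(dark)
  if (diff(rng) < bg_margin) return(matrix(0L, nrow(dark), ncol(dark)))
  mask <- dark > stats::median(dark) + bg_margin
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::watershed(EBImage::distmap(mask),
                               tolerance = watershed_tolerance)
  labels <- matrix(as.integer(labels), nrow(dark), ncol(dark))
  ## area band in px^2
  amin <- pi * (diameter_band_um[1] / 2)^2 / band_relax / um_per_px^2
  amax <- pi * (diameter_band_um[2] / 2)^2 * band_relax / um_per_px^2
  tab <- tabulate(labels)
  keep <- which(tab >= amin & tab <= amax)
  relab <- integer(max(labels, 1L))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]
  labels
}

#' Segment cells in a raster with a pluggable segmenter
#'
#' Applies `segmenter` (any function mapping a pixel array to an integer
#' label matrix; default [segmentCellsClassical()]) and tabulates per-cell
#' area, mean RGB and centroid. An empty segmentation is allowed.
#'
#' @param tile pixel array (h x w x 3, 0-255) or [SectionImage-class]
#' @param um_per_px microns per pixel (taken from the section if omitted)
#' @param segmenter segmentation function
#' @param ... passed on to the segmenter
#' @return a [CellSegmentation-class]
#' @export
segmentCells <- function(tile, um_per_px = NULL,
                         segmenter = segmentCellsClassical, ...) {
  if (is(tile, "SectionImage")) {
    if (is.null(um_per_px)) um_per_px <- tile@um_per_px
    tile <- tile@pixels
  }
  if (is.null(um_per_px)) stop("um_per_px is required")
  labels <- segmenter(tile, um_per_px = um_per_px, ...)
  cells <- cellStats(labels, tile, um_per_px)
  new("CellSegmentation", labels = labels, cells = cells,
      um_per_px = um_per_px)
}

## per-label area, mean RGB and centroid
cellStats <- function(labels, tile, um_per_px) {
  idx <- which(labels > 0)
  if (!length(idx)) {
    return(data.frame(label = integer(), area_px = numeric(),
                      area_um2 = numeric(), mean_r = numeric(),
                      mean_g = numeric(), mean_b = numeric(),
                      cx = numeric(), cy = numeric()))
  }
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  npx <- prod(dim(labels))
  area <- as.numeric(tapply(lab, lab, length))
  ids <- as.integer(names(tapply(lab, lab, length)))
  mr <- as.numeric(tapply(tile[idx], lab, mean))
  mg <- as.numeric(tapply(tile[idx + npx], lab, mean))
  mb <- as.numeric(tapply(tile[idx + 2 * npx], lab, mean))
  cx <- as.numeric(tapply(cols, lab, mean))
  cy <- as.numeric(tapply(rows, lab, mean))
  out <- data.frame(label = ids, area_px = area,
                    area_um2 = area * um_per_px^2,
                    mean_r = mr, mean_g = mg, mean_b = mb, cx = cx, cy = cy)
  out[order(out$label), , drop = FALSE]
}

#' Classify segmented cells into blue / brown / unclassified
#'
#' Applies the RGB box rules to each cell's mean RGB. Cells matching neither
#' box are `"unclassified"` and excluded from all area statistics
#' downstream. The default boxes are disjoint by construction (their G
#' ranges do not overlap).
#'
#' @param seg a [CellSegmentation-class]
#' @param rules a [CellClassRules-class]
#' @return the segmentation with a `class` column added to the cell table
#' @export
classifyCells <- function(seg, rules = cellClassRules()) {
  stopifnot(is(seg, "CellSegmentation"))
  validObject(rules)
  cl <- classifyRGB(seg@cells$mean_r, seg@cells$mean_g, seg@cells$mean_b,
                    rules)
  seg@cells$class <- cl
  seg
}

#' Classify RGB triples by the box rules
#' @param r,g,b mean RGB components, 0-255 (vectorized)
#' @param rules a [CellClassRules-class]
#' @return character vector: "brown", "blue" or "unclassified"
#' @export
classifyRGB <- function(r, g, b, rules = cellClassRules()) {
  brown <- r >= rules@brown_r[1] & r <= rules@brown_r[2] &
    g <= rules@brown_g_max & b <= rules@brown_b_max
  blue <- r >= rules@blue_r[1] & r <= rules@blue_r[2] &
    g >= rules@blue_g_min & b >= rules@blue_b_min
  out <- rep("unclassified", length(r))
  out[blue] <- "blue"
  out[brown] <- "brown"  # boxes are disjoint; order immaterial
  out
}

#' Patchwise blue/brown area fractions
#'
#' Lays a non-overlapping patch grid (default 200 um) anchored at the raster
#' origin over the section, assigns each classified cell to the patch
#' containing its centroid, and computes per patch the blue-area fraction
#' among classified cells `gamma = blue / (blue + brown)` and the brown-area
#' fraction of the patch `rho = brown / patch area`. Edge patches are
#' truncated and use their true area. `gamma` is NA (undefined) in patches
#' with no classified cell.
#'
#' @param seg a classified [CellSegmentation-class] (see [classifyCells()])
#' @param width_px,height_px raster size, px (taken from the label matrix if
#'   omitted)
#' @param patch_um patch edge, microns
#' @param decay_k decay constant of the necrosis score
#' @return a [PatchStats-class]
#' @export
patchFractions <- function(seg, width_px = NULL, height_px = NULL,
                           patch_um = 200, decay_k = 100) {
  stopifnot(is(seg, "CellSegmentation"))
  if (!"class" %in% names(seg@cells))
    stop("run classifyCells() first")
  if (is.null(seg@um_per_px) || !length(seg@um_per_px) ||
      seg@um_per_px <= 0)
    stop("missing um-per-pixel scale metadata")
  if (is.null(width_px)) width_px <- ncol(seg@labels)
  if (is.null(height_px)) height_px <- nrow(seg@labels)
  upp <- seg@um_per_px
  w_um <- width_px * upp; h_um <- height_px * upp
  ncols <- max(1L, ceiling(w_um / patch_um - 1e-9))
  nrows <- max(1L, ceiling(h_um / patch_um - 1e-9))
  cells <- seg@cells[seg@cells$class %in% c("blue", "brown"), , drop = FALSE]
  pc <- pmin(floor((cells$cx - 0.5) * upp / patch_um) + 1L, ncols)
  pr <- pmin(floor((cells$cy - 0.5) * upp / patch_um) + 1L, nrows)
  grid <- expand.grid(row = seq_len(nrows), col = seq_len(ncols))
  key <- paste(pr, pc)
  agg <- function(cls) {
    s <- tapply(cells$area_um2[cells$class == cls],
                key[cells$class == cls], sum)
    v <- setNames(rep(0, nrow(grid)), paste(grid$row, grid$col))
    v[names(s)] <- s
    as.numeric(v)
  }
  blue <- agg("blue"); brown <- agg("brown")
  pw <- pmin(patch_um, w_um - (grid$col - 1) * patch_um)
  ph <- pmin(patch_um, h_um - (grid$row - 1) * patch_um)
  parea <- pw * ph
  tot <- blue + brown
  gamma <- ifelse(tot > 0, blue / tot, NA_real_)
  rho <- pmin(brown / parea, 1)
  stats <- data.frame(row = grid$row, col = grid$col,
                      blue_area_um2 = blue, brown_area_um2 = brown,
                      patch_area_um2 = parea, gamma = gamma, rho = rho)
  new("PatchStats", stats = stats, patch_um = patch_um, decay_k = decay_k)
}

#' Exponential patch necrosis score
#'
#' `necrosis = gamma * exp(-k rho) * 100` percent: full necrosis (100%) for
#' a patch of only blue cells, decaying steeply as the local brown-cell area
#' fraction rho grows. Patches with undefined gamma (no classified cells)
#' score 0%.
#'
#' @param gamma blue fraction among classified cells, in \[0, 1\] or NA
#' @param rho brown-area fraction of the patch, in \[0, 1\]
#' @param decay_k decay constant (default 100: rho enters as a fraction
#'   while k rho spans percent scale)
#' @return percent in \[0, 100\] (vectorized)
#' @examples
#' necrosisFromPatch(1, 0)       # 100
#' necrosisFromPatch(0.5, 0.01)  # 50 exp(-1) = 18.39
#' @export
necrosisFromPatch <- function(gamma, rho, decay_k = 100) {
  out <- ifelse(is.na(gamma), 0, gamma * exp(-decay_k * rho) * 100)
  pmin(pmax(out, 0), 100)
}

#' Necrosis map of a section from patch statistics
#'
#' @param patches a [PatchStats-class]
#' @param depth_um section depth, microns
#' @param section_id identifier
#' @return a [NecrosisMap-class]
#' @export
necrosisMapFromPatches <- function(patches, depth_um = 0,
                                   section_id = "map") {
  st <- patches@stats
  m <- matrix(0, max(st$row), max(st$col))
  m[cbind(st$row, st$col)] <- necrosisFromPatch(st$gamma, st$rho,
                                                patches@decay_k)
  necrosisMap(m, patch_um = patches@patch_um, depth_um = depth_um,
              section_id = section_id)
}

#' Quantify a section end to end
#'
#' Convenience driver: segment, classify, compute patch fractions and the
#' necrosis map for one section.
#'
#' @param section a [SectionImage-class]
#' @param rules a [CellClassRules-class]
#' @param patch_um patch edge, microns
#' @param decay_k decay constant
#' @param segmenter pluggable segmentation function
#' @param ... passed to the segmenter
#' @return a [NecrosisMap-class]
#' @export
quantifySection <- function(section, rules = cellClassRules(),
                            patch_um = 200, decay_k = 100,
                            segmenter = segmentCellsClassical, ...) {
  seg <- segmentCells(section, segmenter = segmenter, ...)
  seg <- classifyCells(seg, rules)
  ps <- patchFractions(seg, patch_um = patch_um, decay_k = decay_k)
  necrosisMapFromPatches(ps, depth_um = section@depth_um,
                         section_id = section@section_id)
}

#' Multilevel Otsu thresholds
#'
#' Thresholds maximizing the between-class variance over `n_thresholds + 1`
#' classes, computed by exhaustive search on a binned histogram.
#' Deterministic (lowest-tuple tie-break) and invariant to input order.
#'
#' @param x numeric values
#' @param n_thresholds 1 to 3
#' @param bins histogram bins
#' @return thresholds on the scale of `x`, length `n_thresholds`
#' @export
multilevelOtsu <- function(x, n_thresholds = 3, bins = 256) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < n_thresholds + 1)
    stop("degenerate histogram: need more than ", n_thresholds,
         " distinct values")
  rng <- range(x)
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                      plot = FALSE)
  th_bins <- multi_otsu_cpp(h$counts, as.integer(n_thresholds))
  h$breaks[th_bins + 1]  # lower edge of the first bin of each upper class
}

## shared binarization rule of the two filtering stages: 3-level Otsu on the
## map values scaled to 0-255, cut at the second threshold
binarizeNecrosis <- function(values) {
  scaled <- values / 100 * 255
  th <- multilevelOtsu(as.vector(scaled), 3)
  values > th[2] / 255 * 100
}

#' Stage-1 artifact filter: reference centroid of the necrotic region
#'
#' Averages the registered necrosis maps, computes three Otsu thresholds on
#' the average (its histogram is near-quadrimodal: background, low,
#' intermediate, high necrosis), binarizes at the second threshold, labels
#' connected components and keeps the component containing the global
#' maximum of the average map. Returns that component's centroid, the
#' reference point for per-section filtering in [stage2Filter()].
#'
#' @param maps list of registered [NecrosisMap-class] on a common grid
#' @return centroid `c(x, y)` in patch coordinates (col, row)
#' @export
stage1Centroid <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 maps")
  mats <- lapply(maps, function(m)
    if (is(m, "NecrosisMap")) m@values else m)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("maps must share a common grid")
  avg <- Reduce(`+`, mats) / length(mats)
  bin <- binarizeNecrosis(avg)
  if (!any(bin)) stop("binarized average map is empty")
  labels <- EBImage::bwlabel(bin)
  imax <- which.max(avg)
  lab_max <- labels[imax]
  if (lab_max == 0) {  # max not inside a component (plateau ties); take nearest
    lab_max <- labels[which(labels > 0)[1]]
  }
  idx <- which(labels == lab_max)
  rows <- (idx - 1) %% d[1] + 1
  cols <- (idx - 1) %/% d[1] + 1
  c(x = mean(cols), y = mean(rows))
}

## exact convex-image solidity: component area over the pixel count of its
## rasterized convex hull
componentSolidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2) return(1)
  pts <- cbind(cols, rows)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  if (nrow(hp) <= 2) return(1)
  m <- nrow(hp)
  ## orient counter-clockwise so "inside" means left of every edge
  nxt <- c(2:m, 1)
  sa <- sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2]) / 2
  if (sa < 0) hp <- hp[m:1, , drop = FALSE]
  ## rasterize hull over pixel centers of the bounding box
  xr <- range(cols); yr <- range(rows)
  gx <- rep(xr[1]:xr[2], times = yr[2] - yr[1] + 1)
  gy <- rep(yr[1]:yr[2], each = xr[2] - xr[1] + 1)
  inside <- rep(TRUE, length(gx))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- hp[j, 1] - hp[i, 1]; ey <- hp[j, 2] - hp[i, 2]
    cr <- ex * (gy - hp[i, 2]) - ey * (gx - hp[i, 1])
    inside <- inside & (cr >= -1e-9)
  }
  hull_area <- sum(inside)
  if (hull_area < n) return(1)  # degenerate rasterization
  n / hull_area
}

#' Stage-2 artifact filter: per-section solidity and proximity filtering
#'
#' Binarizes the map with the same Otsu rule as stage 1, discards components
#' with solidity (area over convex-hull area) below `solidity_min` — such
#' irregular shapes are unlikely to be the roughly circular necrotic region
#' — and keeps, among the survivors, the component whose centroid is nearest
#' the stage-1 reference centroid. The input map is multiplied by the
#' resulting binary mask.
#'
#' @param map a [NecrosisMap-class]
#' @param centroid stage-1 centroid `c(x, y)` from [stage1Centroid()]
#' @param solidity_min minimum solidity (default 0.6)
#' @return a [FilterResult-class]; when no object survives, the filtered map
#'   is all zero and `empty` is TRUE (with a warning)
#' @export
stage2Filter <- function(map, centroid, solidity_min = 0.6) {
  stopifnot(is(map, "NecrosisMap"))
  v <- map@values
  d <- dim(v)
  empty_result <- function() {
    warning("no object survived the solidity filter; returning a zero map")
    new("FilterResult",
        map = necrosisMap(matrix(0, d[1], d[2]), patch_um = map@patch_um,
                          depth_um = map@depth_um,
                          section_id = map@section_id),
        kept_label = NA_integer_, centroid = centroid, empty = TRUE)
  }
  bin <- tryCatch(binarizeNecrosis(v), error = function(e) NULL)
  if (is.null(bin) || !any(bin)) return(empty_result())
  labels <- EBImage::bwlabel(bin)
  nlab <- max(labels)
  keep <- integer(0); cents <- NULL
  for (l in seq_len(nlab)) {
    idx <- which(labels == l)
    rows <- (idx - 1) %% d[1] + 1
    cols <- (idx - 1) %/% d[1] + 1
    if (componentSolidity(rows, cols) >= solidity_min) {
      keep <- c(keep, l)
      cents <- rbind(cents, c(mean(cols), mean(rows)))
    }
  }
  if (!length(keep)) return(empty_result())
  dist2 <- (cents[, 1] - centroid[1])^2 + (cents[, 2] - centroid[2])^2
  lab <- keep[which.min(dist2)]
  mask <- labels == lab
  out <- v * mask
  new("FilterResult",
      map = necrosisMap(out, patch_um = map@patch_um,
                        depth_um = map@depth_um,
                        section_id = map@section_id),
      kept_label = as.integer(lab), centroid = centroid, empty = FALSE)
}
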