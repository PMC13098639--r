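## Synthetic IHC-like fixtures with analytic ground truth, and piecewise
## temperature traces. Every pipeline stage is testable with these alone.

#' Parameters of the synthetic IHC section generator
#'
#' The rendered geometry emulates the four hallmark features of a
#' caspase-stained section around a circular irradiated region: blue cells
#' everywhere, reduced cell density inside the region, a brown-cell ring
#' around its boundary, and sparse brown cells inside whose density falls
#' with irradiation time. A configurable angular gap in the ring gives each
#' section an identifiable orientation (lesion boundaries are irregular in
#' practice) so rigid registration is well-posed.
#'
#' @param canvas_um canvas size, microns (width, height; recycled)
#' @param um_per_px microns per pixel of the rendered raster
#' @param center_um irradiated-region center, microns (defaults to canvas
#'   center)
#' @param radius_um irradiated-region radius, microns
#' @param cell_radius_um cell radius range, microns (5-10 um diameters)
#' @param density_out blue-cell density outside the region, cells/mm^2
#' @param density_in blue-cell density inside the region, cells/mm^2
#'   (must be below `density_out`)
#' @param ring_width_um brown ring width, microns
#' @param ring_density brown-cell density inside the ring, cells/mm^2
#' @param brown_out_density scattered brown density outside ring/region,
#'   cells/mm^2 (chosen so non-lesion areas score in the moderate artifact
#'   range rather than rivalling the lesion interior)
#' @param brown_in_base base inside-brown density, cells/mm^2; the density
#'   used is `brown_in_base / (1 + irradiation_min)` (inversely
#'   proportional to irradiation time)
#' @param irradiation_min irradiation time driving the inside-brown density
#' @param ring_gap_deg angular width of the ring gap, degrees
#' @param ring_gap_center gap center angle, degrees
#' @param color_jitter_sd per-cell RGB jitter standard deviation
#' @param background background gray level, 0-255
#' @param density_mod optional vectorized function `(x_um, y_um) ->
#'   multiplier` modulating the blue-cell density, emulating the smooth
#'   lobular density variation of liver parenchyma. Adjacent serial
#'   sections share this field (see [genStack()]), which is what makes
#'   their rigid registration well-posed
#' @return named list of parameters
#' @export
synthSectionParams <- function(canvas_um = 4000, um_per_px = 0.23,
                               center_um = NULL, radius_um = 1500,
                               cell_radius_um = c(2.5, 5),
                               density_out = 2500, density_in = 800,
                               ring_width_um = 100, ring_density = 4000,
                               brown_out_density = 250,
                               brown_in_base = 300, irradiation_min = 20,
                               ring_gap_deg = 40, ring_gap_center = 30,
                               color_jitter_sd = 6, background = 245,
                               density_mod = NULL) {
  canvas_um <- rep_len(canvas_um, 2)
  if (is.null(center_um)) center_um <- canvas_um / 2
  if (density_in >= density_out)
    stop("inside cell density must be below the outside density")
  if (min(density_out, density_in, ring_density, brown_out_density,
          brown_in_base) < 0)
    stop("densities must be >= 0")
  list(canvas_um = canvas_um, um_per_px = um_per_px, center_um = center_um,
       radius_um = radius_um, cell_radius_um = cell_radius_um,
       density_out = density_out, density_in = density_in,
       ring_width_um = ring_width_um, ring_density = ring_density,
       brown_out_density = brown_out_density,
       brown_in_base = brown_in_base, irradiation_min = irradiation_min,
       ring_gap_deg = ring_gap_deg, ring_gap_center = ring_gap_center,
       color_jitter_sd = color_jitter_sd, background = background,
       density_mod = density_mod)
}

## draw base colors strictly inside the classification boxes
sampleCellColors <- function(n, class, jitter_sd) {
  if (class == "brown") {
    base <- cbind(stats::runif(n, 110, 160), stats::runif(n, 70, 120),
                  stats::runif(n, 40, 100))
  } else {
    base <- cbind(stats::runif(n, 155, 181), stats::runif(n, 170, 215),
                  stats::runif(n, 175, 230))
  }
  pmin(pmax(base + matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3), 0), 255)
}

## Poisson point samples over the canvas, filtered by a region predicate;
## optional inhomogeneous intensity via thinning against `mod`
samplePoints <- function(lambda_mm2, area_um2, canvas_um, keep,
                         mod = NULL) {
  mod_max <- 1
  if (!is.null(mod)) {
    gx <- seq(0, canvas_um[1], length.out = 40)
    gy <- seq(0, canvas_um[2], length.out = 40)
    mod_max <- max(mod(rep(gx, times = 40), rep(gy, each = 40))) * 1.05
  }
  area_um2 <- max(area_um2, 0)  # region clipping can drive this negative
  n <- stats::rpois(1, lambda_mm2 * mod_max * area_um2 / 1e6)
  if (n == 0) return(cbind(x = numeric(), y = numeric()))
  ## oversample uniformly on the canvas, keep the predicate subset of size n
  got <- NULL
  total_area <- prod(canvas_um)
  frac <- max(area_um2 / total_area, 1e-6)
  while (is.null(got) || nrow(got) < n) {
    m <- ceiling((n + 10) / frac * 1.3)
    pts <- cbind(x = stats::runif(m, 0, canvas_um[1]),
                 y = stats::runif(m, 0, canvas_um[2]))
    pts <- pts[keep(pts), , drop = FALSE]
    got <- rbind(got, pts)
  }
  got <- got[seq_len(n), , drop = FALSE]
  if (!is.null(mod)) {
    p <- mod(got[, 1], got[, 2]) / mod_max
    got <- got[stats::runif(n) < p, , drop = FALSE]
  }
  got
}

#' Generate a synthetic IHC section with analytic ground truth
#'
#' Renders anti-aliased cell disks with class-consistent colors on a light
#' background and computes the ground-truth necrosis map by applying the
#' patch model (centroid assignment, exact disk areas) to the generated
#' geometry directly, bypassing rendering and segmentation.
#'
#' @param params list from [synthSectionParams()]
#' @param seed RNG seed (generation is seed-deterministic)
#' @param depth_um section depth recorded in the metadata, microns
#' @param jitter optional [RigidTransform-class] (in pixel units) applied to
#'   the cell geometry before rendering, emulating sectioning/mounting
#'   misalignment; ground truth stays in the canonical (unjittered) frame
#' @param patch_um patch edge of the truth map, microns
#' @return list with `section` ([SectionImage-class]), `truth`
#'   ([NecrosisMap-class], canonical frame), `cells` (data.frame of centers,
#'   radii, classes) and `params`
#' @export
genSection <- function(params = synthSectionParams(), seed = 1,
                       depth_um = 0, jitter = NULL, patch_um = 200) {
  set.seed(seed)
  p <- params
  cu <- p$canvas_um; ctr <- p$center_um; R <- p$radius_um
  rad2 <- function(pts) (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
  in_region <- function(pts) rad2(pts) <= R^2
  gap <- function(pts) {
    ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]) * 180 / pi
    dd <- (ang - p$ring_gap_center + 180) %% 360 - 180
    abs(dd) <= p$ring_gap_deg / 2
  }
  in_ring <- function(pts) {
    r2 <- rad2(pts)
    r2 > R^2 & r2 <= (R + p$ring_width_um)^2 & !gap(pts)
  }
  total <- prod(cu)
  region_area <- pi * R^2
  ring_area <- pi * ((R + p$ring_width_um)^2 - R^2) *
    (1 - p$ring_gap_deg / 360)

  lam_bi <- p$brown_in_base / (1 + p$irradiation_min)
  sets <- list(
    list(cls = "blue", pts = samplePoints(p$density_out,
         total - region_area, cu, function(q) !in_region(q),
         mod = p$density_mod)),
    list(cls = "blue", pts = samplePoints(p$density_in, region_area, cu,
         in_region, mod = p$density_mod)),
    list(cls = "brown", pts = samplePoints(p$ring_density, ring_area, cu,
         in_ring)),
    list(cls = "brown", pts = samplePoints(lam_bi, region_area, cu,
         in_region)),
    list(cls = "brown", pts = samplePoints(p$brown_out_density,
         total - region_area - ring_area, cu,
         function(q) !in_region(q) & !in_ring(q), mod = p$density_mod)))

  cells <- do.call(rbind, lapply(sets, function(s) {
    n <- nrow(s$pts)
    if (!n) return(NULL)
    data.frame(x_um = s$pts[, 1], y_um = s$pts[, 2],
               r_um = stats::runif(n, p$cell_radius_um[1],
                                   p$cell_radius_um[2]),
               class = s$cls)
  }))
  if (is.null(cells)) cells <- data.frame(x_um = numeric(),
                                          y_um = numeric(),
                                          r_um = numeric(),
                                          class = character())
  cover <- sum(pi * cells$r_um^2) / total
  if (cover > 0.8)
    stop(sprintf("unrealistic slide: %.0f%% cell coverage", 100 * cover))
  cols <- matrix(0, nrow(cells), 3)
  for (cl in c("blue", "brown")) {
    i <- which(cells$class == cl)
    if (length(i)) cols[i, ] <- sampleCellColors(length(i), cl,
                                                 p$color_jitter_sd)
  }
  cells$r_col <- cols[, 1]; cells$g_col <- cols[, 2]; cells$b_col <- cols[, 3]

  ## ground truth from canonical geometry (exact disk areas, centroid rule)
  truth <- truthMap(cells, cu, patch_um, depth_um)

  ## optional rigid jitter of the geometry before rendering
  rcells <- cells
  if (!is.null(jitter)) {
    upp <- p$um_per_px
    pts_px <- cbind(cells$x_um / upp, cells$y_um / upp)
    moved <- applyTransform(jitter, pts_px)
    rcells$x_um <- moved[, 1] * upp
    rcells$y_um <- moved[, 2] * upp
  }
  section <- renderSection(rcells, cu, p$um_per_px, p$background,
                           depth_um = depth_um)
  list(section = section, truth = truth, cells = cells, params = p)
}

## analytic patch statistics from cell geometry
truthMap <- function(cells, canvas_um, patch_um, depth_um = 0) {
  ncols <- max(1L, ceiling(canvas_um[1] / patch_um - 1e-9))
  nrows <- max(1L, ceiling(canvas_um[2] / patch_um - 1e-9))
  m <- matrix(0, nrows, ncols)
  if (nrow(cells)) {
    pc <- pmin(floor(cells$x_um / patch_um) + 1L, ncols)
    pr <- pmin(floor(cells$y_um / patch_um) + 1L, nrows)
    area <- pi * cells$r_um^2
    key <- paste(pr, pc)
    for (ij in unique(key)) {
      sel <- key == ij
      blue <- sum(area[sel & cells$class == "blue"])
      brown <- sum(area[sel & cells$class == "brown"])
      rc <- as.integer(strsplit(ij, " ")[[1]])
      pw <- min(patch_um, canvas_um[1] - (rc[2] - 1) * patch_um)
      ph <- min(patch_um, canvas_um[2] - (rc[1] - 1) * patch_um)
      gamma <- if (blue + brown > 0) blue / (blue + brown) else NA
      rho <- min(brown / (pw * ph), 1)
      m[rc[1], rc[2]] <- necrosisFromPatch(gamma, rho)
    }
  }
  necrosisMap(m, patch_um = patch_um, depth_um = depth_um,
              section_id = "truth")
}

## paint anti-aliased cell disks
renderSection <- function(cells, canvas_um, um_per_px, background,
                          depth_um = 0) {
  W <- max(1L, round(canvas_um[1] / um_per_px))
  H <- max(1L, round(canvas_um[2] / um_per_px))
  px <- array(background, dim = c(H, W, 3))
  if (nrow(cells)) {
    cx <- cells$x_um / um_per_px + 0.5
    cy <- cells$y_um / um_per_px + 0.5
    rp <- cells$r_um / um_per_px
    for (i in seq_len(nrow(cells))) {
      x0 <- max(1L, floor(cx[i] - rp[i] - 1))
      x1 <- min(W, ceiling(cx[i] + rp[i] + 1))
      y0 <- max(1L, floor(cy[i] - rp[i] - 1))
      y1 <- min(H, ceiling(cy[i] + rp[i] + 1))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      dmat <- sqrt(outer((ys - cy[i])^2, (xs - cx[i])^2, `+`))
      cov <- pmin(pmax(rp[i] + 0.5 - dmat, 0), 1)
      for (ch in 1:3) {
        col <- c(cells$r_col[i], cells$g_col[i], cells$b_col[i])[ch]
        px[ys, xs, ch] <- cov * col + (1 - cov) * px[ys, xs, ch]
      }
    }
  }
  sectionImage(px, um_per_px = um_per_px, depth_um = depth_um,
               section_id = sprintf("synth_d%g", depth_um))
}

#' Generate a jittered serial-section stack with ground truth
#'
#' Sections are generated at successive depths with the irradiated-region
#' radius growing linearly with depth (tissue curvature makes deeper
#' sections larger), each rendered after a known per-section rigid jitter.
#' The jitter transforms and the canonical-frame truth maps are returned as
#' ground truth for registration and volumetry tests.
#'
#' @param params list from [synthSectionParams()] (radius of the top
#'   section)
#' @param n_sections number of sections (>= 2)
#' @param spacing_um inter-section spacing, microns
#' @param radius_growth radius increase per micron of depth
#' @param jitter_rot_sd per-section rotation jitter SD, degrees
#' @param jitter_trans_sd per-section translation jitter SD, px
#' @param parenchyma_amp amplitude of the shared smooth blue-density
#'   modulation (lobular parenchyma texture common to all sections; 0
#'   disables). Without a shared large-scale structure, serial sections of
#'   randomly placed cells would carry no registration signal beyond the
#'   (rotationally ambiguous) lesion ring
#' @param parenchyma_wavelength_um typical wavelength of that field, microns
#' @param shared_section if TRUE, every level is the same rendered section
#'   warped by its jitter (pure known rigid perturbations: the sharpest test
#'   of registration recovery); if FALSE (default), each level gets fresh
#'   cells so only the lesion, ring and parenchyma field are shared, as
#'   between real serial sections
#' @param seed RNG seed
#' @return list with `sections`, `truth_maps` (canonical frame), `jitters`
#'   (list of [RigidTransform-class] mapping canonical -> rendered frame),
#'   `spacing_um`
#' @export
genStack <- function(params = synthSectionParams(), n_sections = 5,
                     spacing_um = 40, radius_growth = 0.5,
                     jitter_rot_sd = 2, jitter_trans_sd = 4,
                     parenchyma_amp = 0.5,
                     parenchyma_wavelength_um = 600,
                     shared_section = FALSE, seed = 1) {
  if (n_sections < 2) stop("n_sections must be >= 2")
  set.seed(seed)
  if (parenchyma_amp > 0) {
    nwave <- 4
    kvec <- matrix(stats::rnorm(2 * nwave), nwave, 2)
    kvec <- kvec / sqrt(rowSums(kvec^2)) * (2 * pi / parenchyma_wavelength_um)
    phase <- stats::runif(nwave, 0, 2 * pi)
    amp_i <- parenchyma_amp / sqrt(nwave)
    params$density_mod <- function(x, y) {
      v <- 1
      for (w in seq_len(nwave))
        v <- v + amp_i * cos(kvec[w, 1] * x + kvec[w, 2] * y + phase[w])
      pmax(v, 0.1)
    }
  }
  W <- round(params$canvas_um[1] / params$um_per_px)
  H <- round(params$canvas_um[2] / params$um_per_px)
  ctr <- c((W + 1) / 2, (H + 1) / 2)
  jit <- lapply(seq_len(n_sections), function(i)
    rigidTransform(rotation = stats::rnorm(1, 0, jitter_rot_sd),
                   translation = stats::rnorm(2, 0, jitter_trans_sd),
                   center = ctr))
  seeds <- sample.int(1e6, n_sections)
  sections <- vector("list", n_sections)
  truth <- vector("list", n_sections)
  if (shared_section) {
    base <- genSection(params, seed = seeds[1])
    bg <- params$background
    for (i in seq_len(n_sections)) {
      px <- base$section@pixels
      wr <- array(0, dim(px))
      for (ch in 1:3)
        wr[, , ch] <- warpMatrix(px[, , ch], jit[[i]], fill = bg)
      sections[[i]] <- sectionImage(wr, um_per_px = params$um_per_px,
                                    depth_um = (i - 1) * spacing_um,
                                    section_id = sprintf("shared_%d", i))
      truth[[i]] <- base$truth
    }
  } else {
    for (i in seq_len(n_sections)) {
      depth <- (i - 1) * spacing_um
      pi_ <- params
      pi_$radius_um <- params$radius_um + radius_growth * depth
      g <- genSection(pi_, seed = seeds[i], depth_um = depth,
                      jitter = jit[[i]])
      sections[[i]] <- g$section
      truth[[i]] <- g$truth
    }
  }
  list(sections = sections, truth_maps = truth, jitters = jit,
       spacing_um = spacing_um)
}

#' Generate a piecewise-linear temperature trace
#'
#' Breakpoints describe the characteristic heating phases (e.g. fast rise,
#' slow rise, plateau); the trace is sampled linearly between them. Default
#' breakpoints follow the three-phase 73 mJ heating curve: 293.15 K at
#' t = 0, 315.15 K at 0.34 min, 333.15 K at 3.88 min, 333.44 K plateau.
#'
#' @param breakpoints data.frame with columns `time_min` and `kelvin`
#' @param step_s sampling step, s
#' @param t_end_min trace end, min (default: last breakpoint)
#' @return a [TemperatureTrace-class]
#' @export
genTemperatureTrace <- function(breakpoints = data.frame(
                                  time_min = c(0, 0.34, 3.88, 20),
                                  kelvin = c(293.15, 315.15, 333.15,
                                             333.44)),
                                step_s = 1, t_end_min = NULL) {
  if (any(diff(breakpoints$time_min) <= 0))
    stop("breakpoint times must be increasing")
  if (any(breakpoints$kelvin < 273 | breakpoints$kelvin > 400))
    stop("breakpoint temperatures must lie in 273-400 K")
  if (is.null(t_end_min)) t_end_min <- max(breakpoints$time_min)
  tt <- seq(0, t_end_min * 60, by = step_s)
  TT <- stats::approx(breakpoints$time_min * 60, breakpoints$kelvin,
                      xout = tt, rule = 2)$y
  temperatureTrace(tt, TT)
}
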