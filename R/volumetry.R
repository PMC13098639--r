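## Serial-section rigid registration, map warping, depth interpolation and
## volume metrics.

#' Apply a rigid transform to points
#' @param t a [RigidTransform-class]
#' @param pts 2-column matrix (x, y)
#' @return transformed points
#' @export
applyTransform <- function(t, pts) {
  th <- t@rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(pts, 2, t@center) %*% t(R), 2,
        t@center + t@translation, `+`)
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#'
#' Both transforms must share the rotation center.
#'
#' @param a,b [RigidTransform-class] objects
#' @return the composed [RigidTransform-class]
#' @export
composeTransform <- function(a, b) {
  if (any(abs(a@center - b@center) > 1e-6))
    stop("transforms must share the rotation center")
  th <- a@rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigidTransform(rotation = a@rotation + b@rotation,
                 translation = as.numeric(R %*% b@translation) +
                   a@translation,
                 center = a@center)
}

#' Invert a rigid transform
#' @param t a [RigidTransform-class]
#' @return the inverse [RigidTransform-class]
#' @export
invertTransform <- function(t) {
  th <- -t@rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigidTransform(rotation = -t@rotation,
                 translation = as.numeric(-R %*% t@translation),
                 center = t@center)
}

#' Rescale a pixel-frame transform to another coordinate scale
#'
#' Registration runs on section pixels; necrosis maps live on the patch
#' grid. A transform estimated in pixels converts to patch units by scaling
#' translation and center by `um_per_px / patch_um`.
#'
#' @param t a [RigidTransform-class]
#' @param factor coordinate scale factor
#' @return rescaled [RigidTransform-class]
#' @export
scaleTransform <- function(t, factor) {
  rigidTransform(rotation = t@rotation, translation = t@translation * factor,
                 center = t@center * factor)
}

## bilinear inverse-mapped warp of a matrix; fill outside the source
warpMatrix <- function(m, t, fill = 0) {
  d <- dim(m)
  inv <- invertTransform(t)
  gx <- rep(seq_len(d[2]), each = d[1])
  gy <- rep(seq_len(d[1]), times = d[2])
  src <- applyTransform(inv, cbind(gx, gy))
  x <- src[, 1]; y <- src[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  get <- function(yy, xx) {
    ok <- xx >= 1 & xx <= d[2] & yy >= 1 & yy <= d[1]
    v <- rep(fill, length(xx))
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * get(y0, x0) +
    fx * (1 - fy) * get(y0, x0 + 1) +
    (1 - fx) * fy * get(y0 + 1, x0) +
    fx * fy * get(y0 + 1, x0 + 1)
  matrix(v, d[1], d[2])
}

## brown-sensitive opponent channel (a*-like: red-green difference) used as
## the registration feature; highlights the DAB ring around the lesion
opponentChannel <- function(x) {
  px <- if (is(x, "SectionImage")) x@pixels else x
  if (length(dim(px)) == 3) px[, , 1] - px[, , 2] else px
}

## block-mean downsampling by an integer factor (trailing rows/cols cropped)
downsampleMatrix <- function(m, f) {
  if (f <= 1) return(m)
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  ## average f x f blocks
  m <- matrix(colMeans(matrix(m, nrow = f)), nrow = nr)   # rows
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = nc))  # cols
}

## separable box blur via running sums (edge-truncated window)
blurAlongRows <- function(M, k) {
  n <- nrow(M); half <- k %/% 2
  cs <- rbind(0, apply(M, 2, cumsum))
  lo <- pmax(seq_len(n) - half, 1); hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}
boxBlur <- function(M, k) {
  if (k <= 1) return(M)
  t(blurAlongRows(t(blurAlongRows(M, k)), k))
}

## translation by FFT cross correlation between equally sized matrices;
## returns (dx, dy) with parabolic sub-pixel refinement and the normalized
## correlation score
xcorrShift <- function(Fm, Mm, max_shift) {
  d <- dim(Fm)
  P <- stats::nextn(2 * d[1], c(2, 3, 5))
  Q <- stats::nextn(2 * d[2], c(2, 3, 5))
  Fc <- Fm - mean(Fm); Mc <- Mm - mean(Mm)
  Fp <- matrix(0, P, Q); Fp[seq_len(d[1]), seq_len(d[2])] <- Fc
  Mp <- matrix(0, P, Q); Mp[seq_len(d[1]), seq_len(d[2])] <- Mc
  CC <- Re(stats::fft(stats::fft(Fp) * Conj(stats::fft(Mp)),
                      inverse = TRUE)) / (P * Q)
  dy <- ifelse(seq_len(P) - 1 <= P / 2, seq_len(P) - 1, seq_len(P) - 1 - P)
  dx <- ifelse(seq_len(Q) - 1 <= Q / 2, seq_len(Q) - 1, seq_len(Q) - 1 - Q)
  ok <- outer(abs(dy) <= max_shift[1], abs(dx) <= max_shift[2])
  CCm <- CC; CCm[!ok] <- -Inf
  pk <- which.max(CCm)
  iy <- (pk - 1) %% P + 1; ix <- (pk - 1) %/% P + 1
  sub <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (is.finite(den) && abs(den) > 1e-12)
      max(-0.5, min(0.5, 0.5 * (cm - cp) / den)) else 0
  }
  at <- function(ddy, ddx)
    CC[(iy - 1 + ddy) %% P + 1, (ix - 1 + ddx) %% Q + 1]
  list(shift = c(dx[ix] + sub(at(0, -1), at(0, 0), at(0, 1)),
                 dy[iy] + sub(at(-1, 0), at(0, 0), at(1, 0))),
       score = CC[pk] / (sqrt(sum(Fc^2)) * sqrt(sum(Mc^2)) + 1e-12))
}

#' Register a moving image onto a fixed image (rigid)
#'
#' Estimates rotation + translation maximizing the normalized cross
#' correlation of a brown-region-sensitive opponent channel (R - G, the
#' a*-like axis that highlights the DAB ring). Multiscale: the rotation is
#' scanned on a coarse grid over block-downsampled features (about
#' `coarse_px` across) and refined by golden-section search; the final
#' translation comes from the FFT cross-correlation peak at a finer scale
#' (about `refine_px` across) with parabolic sub-pixel refinement.
#'
#' @param fixed,moving [SectionImage-class] objects or matrices (feature
#'   images); must share dimensions
#' @param rot_range rotation search interval, degrees
#' @param rot_step coarse grid step, degrees
#' @param max_shift translation search bound, px
#' @param coarse_px approximate image extent of the rotation-search scale
#' @param refine_px approximate image extent of the translation-refinement
#'   scale
#' @param smooth_px smoothing window (full-resolution px) applied to the
#'   feature before correlating. Serial sections share smooth stain-density
#'   structure (the DAB ring, the interior cell deficit) but not individual
#'   cells, so the correlation must run on a smoothed density field; 0
#'   disables smoothing
#' @return a [RigidTransform-class] mapping moving into the fixed frame,
#'   with attributes `score` (normalized correlation) and `low_confidence`
#' @export
registerPair <- function(fixed, moving, rot_range = c(-10, 10),
                         rot_step = 1, max_shift = 30,
                         coarse_px = 280, refine_px = 1400,
                         smooth_px = 24) {
  Fm <- opponentChannel(fixed); Mm <- opponentChannel(moving)
  if (!identical(dim(Fm), dim(Mm)))
    stop("fixed and moving must share dimensions")
  d <- dim(Fm)
  ctr <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  fr <- max(1L, 2^ceiling(log2(max(d) / refine_px)))
  fc2 <- max(1L, 2^ceiling(log2(max(d) / fr / coarse_px)))  # on top of fr
  kb <- min(round(smooth_px / fr), min(d %/% fr) %/% 8)
  Fb <- boxBlur(downsampleMatrix(Fm, fr), kb)
  Mb <- boxBlur(downsampleMatrix(Mm, fr), kb)
  Fds <- downsampleMatrix(Fb, fc2)
  Mds0 <- downsampleMatrix(Mb, fc2)
  dctr <- c((ncol(Fds) + 1) / 2, (nrow(Fds) + 1) / 2)
  ms_c <- ceiling(max_shift / (fr * fc2)) + 2

  eval_theta <- function(theta) {
    Mr <- if (abs(theta) > 1e-12)
      warpMatrix(Mds0, rigidTransform(theta, c(0, 0), dctr),
                 fill = mean(Mds0))
    else Mds0
    xcorrShift(Fds, Mr, c(ms_c, ms_c))$score
  }
  thetas <- seq(rot_range[1], rot_range[2], by = rot_step)
  scores <- vapply(thetas, eval_theta, numeric(1))
  best <- thetas[which.max(scores)]
  theta <- if (length(thetas) > 1) {
    stats::optimize(eval_theta,
                    lower = max(rot_range[1], best - rot_step),
                    upper = min(rot_range[2], best + rot_step),
                    maximum = TRUE, tol = 0.02)$maximum
  } else best

  fctr <- c((ncol(Fb) + 1) / 2, (nrow(Fb) + 1) / 2)
  Mr <- if (abs(theta) > 1e-12)
    warpMatrix(Mb, rigidTransform(theta, c(0, 0), fctr), fill = mean(Mb))
  else Mb
  ms_f <- ceiling(max_shift / fr) + 2
  fin <- xcorrShift(Fb, Mr, c(ms_f, ms_f))
  out <- rigidTransform(rotation = theta, translation = fin$shift * fr,
                        center = ctr)
  attr(out, "score") <- fin$score
  attr(out, "low_confidence") <- fin$score < 0.2
  out
}

#' Register an ordered stack of sections or maps
#'
#' Pairwise registration of direct neighbours, composed outward from a
#' reference section in the middle of the stack (forward and backward); the
#' reference transform is the identity.
#'
#' @param objects list of [SectionImage-class] or [NecrosisMap-class]
#'   (feature source for registration)
#' @param maps optional list of [NecrosisMap-class] carried along; defaults
#'   to `objects` when those are maps
#' @param reference reference index (default: middle of the stack)
#' @param spacing_um inter-section spacing, microns
#' @param map_scale coordinate scale from the registration frame to the map
#'   frame (e.g. `um_per_px / patch_um`); 1 when registering maps directly
#' @param ... passed to [registerPair()]
#' @return a [RegisteredStack-class]
#' @export
registerStack <- function(objects, maps = NULL, reference = NULL,
                          spacing_um = 40, map_scale = 1, ...) {
  n <- length(objects)
  if (n < 2) stop("need at least 2 sections")
  if (is.null(reference)) reference <- (n + 1) %/% 2
  reference <- as.integer(reference)
  if (is.null(maps)) {
    if (!all(vapply(objects, is, logical(1), "NecrosisMap")))
      stop("supply maps= when registering section images")
    maps <- objects
  }
  transforms <- vector("list", n)
  flags <- logical(n)
  feat <- lapply(objects, opponentChannel)
  ctr <- {
    d <- dim(feat[[reference]])
    c((d[2] + 1) / 2, (d[1] + 1) / 2)
  }
  transforms[[reference]] <- rigidTransform(0, c(0, 0), ctr * map_scale)
  if (reference < n) {
    for (i in (reference + 1):n) {
      p <- registerPair(feat[[i - 1]], feat[[i]], ...)
      flags[i] <- isTRUE(attr(p, "low_confidence"))
      transforms[[i]] <- composeTransform(transforms[[i - 1]],
                                          scaleTransform(p, map_scale))
    }
  }
  if (reference > 1) {
    for (i in (reference - 1):1) {
      p <- registerPair(feat[[i + 1]], feat[[i]], ...)
      flags[i] <- isTRUE(attr(p, "low_confidence"))
      transforms[[i]] <- composeTransform(transforms[[i + 1]],
                                          scaleTransform(p, map_scale))
    }
  }
  new("RegisteredStack", maps = maps, transforms = transforms,
      reference = reference, spacing_um = spacing_um, flags = flags)
}

#' Warp a necrosis map by a rigid transform
#'
#' Bilinear resampling in patch coordinates; values clipped to `\[0, 100\]`,
#' regions mapped from outside the source are 0.
#'
#' @param map a [NecrosisMap-class]
#' @param t a [RigidTransform-class] in the map's patch frame
#' @return warped [NecrosisMap-class]
#' @export
warpMap <- function(map, t) {
  stopifnot(is(map, "NecrosisMap"))
  v <- warpMatrix(map@values, t, fill = 0)
  necrosisMap(pmin(pmax(v, 0), 100), patch_um = map@patch_um,
              depth_um = map@depth_um, section_id = map@section_id)
}

#' Interpolate a registered stack into a necrosis volume
#'
#' Warps every map into the reference frame and linearly interpolates the
#' necrosis values along depth from the inter-section spacing down to
#' `target_step` (values at the original depths are preserved exactly).
#' With `binary = TRUE` the interpolation acts on the binarized (> 0) masks
#' instead of the continuous values.
#'
#' @param stack a [RegisteredStack-class]
#' @param target_step depth step of the volume, microns
#' @param binary interpolate binary masks instead of values
#' @return a [NecrosisVolume-class]
#' @export
interpolateStack <- function(stack, target_step = 4, binary = FALSE) {
  stopifnot(is(stack, "RegisteredStack"))
  n <- length(stack@maps)
  if (n < 2) stop("need at least 2 maps to interpolate")
  warped <- lapply(seq_len(n), function(i) {
    w <- warpMap(stack@maps[[i]], stack@transforms[[i]])@values
    if (binary) (w > 0) * 100 else w
  })
  d <- dim(warped[[1]])
  if (!all(vapply(warped, function(m) identical(dim(m), d), logical(1))))
    stop("maps must share a common grid")
  sp <- stack@spacing_um
  depth0 <- stack@maps[[1]]@depth_um
  depths <- seq(0, (n - 1) * sp, by = target_step)
  vol <- array(0, dim = c(d[1], d[2], length(depths)))
  for (k in seq_along(depths)) {
    z <- depths[k] / sp
    i0 <- min(floor(z) + 1, n - 1)
    f <- z - (i0 - 1)
    vol[, , k] <- (1 - f) * warped[[i0]] + f * warped[[i0 + 1]]
  }
  new("NecrosisVolume", values = vol,
      patch_um = stack@maps[[1]]@patch_um, step_um = target_step,
      depths_um = depth0 + depths)
}

#' Volume, area-vs-depth and percent-vs-depth metrics
#'
#' Necrotic volume counts voxels with necrosis above `eps` times the voxel
#' volume (in-plane patch area times the depth step). The per-depth area is
#' the count of above-`eps` patches times the patch area; the per-depth
#' percentage is the mean over those patches (0 where none).
#'
#' @param vol a [NecrosisVolume-class]
#' @param eps necrosis threshold counting toward the volume (default 0:
#'   any nonzero necrosis)
#' @return list with `volume_mm3` and `profile`, a data.frame
#'   (depth_um, area_cm2, percent)
#' @export
volumeMetrics <- function(vol, eps = 0) {
  stopifnot(is(vol, "NecrosisVolume"))
  vv_mm3 <- (vol@patch_um * 1e-3)^2 * (vol@step_um * 1e-3)
  pa_cm2 <- (vol@patch_um * 1e-4)^2
  nz <- vol@values > eps
  volume_mm3 <- sum(nz) * vv_mm3
  nlev <- dim(vol@values)[3]
  area <- numeric(nlev); pct <- numeric(nlev)
  for (k in seq_len(nlev)) {
    m <- vol@values[, , k]; sel <- m > eps
    area[k] <- sum(sel) * pa_cm2
    pct[k] <- if (any(sel)) mean(m[sel]) else 0
  }
  list(volume_mm3 = volume_mm3,
       profile = data.frame(depth_um = vol@depths_um, area_cm2 = area,
                            percent = pct))
}

#' Write a necrosis volume to disk
#'
#' Multi-page TIFF of the depth levels (values scaled to 0-1), a JSON
#' metrics file and a depth-profile CSV.
#'
#' @param vol a [NecrosisVolume-class]
#' @param dir output directory (created if needed)
#' @param eps threshold passed to [volumeMetrics()]
#' @return `dir`, invisibly
#' @export
writeVolume <- function(vol, dir, eps = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pages <- lapply(seq_len(dim(vol@values)[3]),
                  function(k) vol@values[, , k] / 100)
  tiff::writeTIFF(pages, file.path(dir, "volume.tif"))
  m <- volumeMetrics(vol, eps = eps)
  jsonlite::write_json(list(volume_mm3 = m$volume_mm3,
                            patch_um = vol@patch_um,
                            step_um = vol@step_um),
                       file.path(dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  data.table::fwrite(m$profile, file.path(dir, "depth_profile.csv"))
  invisible(dir)
}
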