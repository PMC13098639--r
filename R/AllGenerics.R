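## Generics and simple accessors. Bioconductor convention: no direct slot
## access from user code.

#' Grid dimensions (voxels per axis)
#' @param x a [VoxelGrid-class] or object carrying one
#' @return integer vector (nx, ny, nz)
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname gridDims
setMethod("gridDims", "VoxelGrid", function(x) as.integer(round(x@extent / x@voxel)))

#' @rdname gridDims
setMethod("gridDims", "EnergyDensityGrid", function(x) gridDims(x@grid))

#' Voxel volume in cubic metres
#' @param x a [VoxelGrid-class]
#' @return scalar, m^3
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname voxelVolume
setMethod("voxelVolume", "VoxelGrid", function(x) (x@voxel * 1e-3)^3)

#' Extract the numeric payload of a container
#'
#' Returns the deposition array of an [EnergyDensityGrid-class], the patch
#' matrix of a [NecrosisMap-class], the voxel array of a
#' [NecrosisVolume-class], or the pixel array of a [SectionImage-class].
#'
#' @param x container object
#' @return numeric array/matrix
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
setMethod("values", "EnergyDensityGrid", function(x) x@values)

#' @rdname values
setMethod("values", "NecrosisMap", function(x) x@values)

#' @rdname values
setMethod("values", "NecrosisVolume", function(x) x@values)

#' @rdname values
setMethod("values", "SectionImage", function(x) x@pixels)

#' Escaped energy fraction of a transport run
#' @param x an [EnergyDensityGrid-class]
#' @return scalar in \[0, 1\]
#' @export
setGeneric("escapedFraction", function(x) standardGeneric("escapedFraction"))

#' @rdname escapedFraction
setMethod("escapedFraction", "EnergyDensityGrid", function(x) x@escaped_fraction)

#' Time axis of a trace
#' @param x a [TemperatureTrace-class] or [DamageTrace-class]
#' @return numeric vector, s
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname traceTimes
setMethod("traceTimes", "TemperatureTrace", function(x) x@times)

#' @rdname traceTimes
setMethod("traceTimes", "DamageTrace", function(x) x@times)

#' Probe temperatures of a trace
#' @param x a [TemperatureTrace-class]
#' @return numeric vector, K
#' @export
setGeneric("traceTemperature", function(x) standardGeneric("traceTemperature"))

#' @rdname traceTemperature
setMethod("traceTemperature", "TemperatureTrace", function(x) x@temperature)

#' Degree-of-injury curve of a damage trace
#' @param x a [DamageTrace-class]
#' @return numeric vector (dimensionless, may exceed 1)
#' @export
setGeneric("damageAlpha", function(x) standardGeneric("damageAlpha"))

#' @rdname damageAlpha
setMethod("damageAlpha", "DamageTrace", function(x) x@alpha)

#' Necrotic fraction curve of a damage trace
#' @param x a [DamageTrace-class]
#' @return numeric vector in \[0, 1\]
#' @export
setGeneric("necroticFraction", function(x) standardGeneric("necroticFraction"))

#' @rdname necroticFraction
setMethod("necroticFraction", "DamageTrace", function(x) x@theta_d)

#' Per-cell table of a segmentation
#' @param x a [CellSegmentation-class]
#' @return data.frame, one row per cell
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname cellTable
setMethod("cellTable", "CellSegmentation", function(x) x@cells)

#' Patch statistics table
#' @param x a [PatchStats-class]
#' @return data.frame, one row per patch
#' @export
setGeneric("patchTable", function(x) standardGeneric("patchTable"))

#' @rdname patchTable
setMethod("patchTable", "PatchStats", function(x) x@stats)

#' Microns per pixel of a raster object
#' @param x a [SectionImage-class] or [CellSegmentation-class]
#' @return scalar, um/px
#' @export
setGeneric("umPerPx", function(x) standardGeneric("umPerPx"))

#' @rdname umPerPx
setMethod("umPerPx", "SectionImage", function(x) x@um_per_px)

#' @rdname umPerPx
setMethod("umPerPx", "CellSegmentation", function(x) x@um_per_px)

## ------------------------------------------------------------------ show ---

setMethod("show", "OpticalProperties", function(object) {
  cat("OpticalProperties: mu_a =", object@mu_a, "1/mm, mu_s =", object@mu_s,
      "1/mm, g =", object@g, "\n")
})

setMethod("show", "EnergyDensityGrid", function(object) {
  d <- gridDims(object)
  cat(sprintf(paste0("EnergyDensityGrid: %d x %d x %d voxels (%.3g mm), ",
                     "%g photons, escaped fraction %.4f\n"),
              d[1], d[2], d[3], object@grid@voxel, object@n_photons,
              object@escaped_fraction))
})

setMethod("show", "TemperatureTrace", function(object) {
  n <- length(object@times)
  cat(sprintf("TemperatureTrace: %d samples over %.1f s, T in [%.2f, %.2f] K\n",
              n, if (n) max(object@times) else 0,
              if (n) min(object@temperature) else NA,
              if (n) max(object@temperature) else NA))
})

setMethod("show", "DamageTrace", function(object) {
  n <- length(object@times)
  cat(sprintf("DamageTrace: %d samples, final alpha = %.4g, necrosis = %.2f%%\n",
              n, if (n) object@alpha[n] else 0,
              if (n) 100 * object@theta_d[n] else 0))
})

setMethod("show", "SectionImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SectionImage '%s': %d x %d px, %.3g um/px, depth %g um\n",
              object@section_id, d[2], d[1], object@um_per_px,
              object@depth_um))
})

setMethod("show", "MosaicPlan", function(object) {
  cat(sprintf("MosaicPlan: %d x %d mosaic (cols x rows), tiles %d x %d px, %d tiles\n",
              object@mosaic_cols, object@mosaic_rows, object@tile_w,
              object@tile_h, object@mosaic_cols * object@mosaic_rows))
})

setMethod("show", "NecrosisMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("NecrosisMap '%s': %d x %d patches (%g um), depth %g um, mean of nonzero %.2f%%\n",
              object@section_id, d[1], d[2], object@patch_um, object@depth_um,
              if (any(object@values > 0)) mean(object@values[object@values > 0]) else 0))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.2f, %.2f), center (%.1f, %.1f)\n",
              object@rotation, object@translation[1], object@translation[2],
              object@center[1], object@center[2]))
})

setMethod("show", "RegisteredStack", function(object) {
  cat(sprintf("RegisteredStack: %d maps, reference %d, spacing %g um\n",
              length(object@maps), object@reference, object@spacing_um))
})

setMethod("show", "NecrosisVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("NecrosisVolume: %d x %d patches x %d depth levels (%g um step)\n",
              d[1], d[2], d[3], object@step_um))
})
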