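## Raster and map file IO. Sections travel as standard PNG/TIFF RGB rasters
## with the scale metadata supplied alongside (whole-slide container formats
## are not parsed).

#' Read a section raster (PNG or TIFF)
#' @param path image file; format chosen by extension
#' @param um_per_px microns per pixel (required metadata)
#' @param depth_um section depth, microns
#' @param section_id identifier (default: file name)
#' @return a [SectionImage-class]
#' @export
readSection <- function(path, um_per_px, depth_um = 0,
                        section_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  sectionImage(img * 255, um_per_px = um_per_px, depth_um = depth_um,
               section_id = section_id)
}

#' Write a section raster (PNG or TIFF)
#' @param section a [SectionImage-class]
#' @param path output file; format chosen by extension
#' @return `path`, invisibly
#' @export
writeSection <- function(section, path) {
  img <- section@pixels / 255
  img[img < 0] <- 0; img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported raster format: .", ext))
  invisible(path)
}

#' Write a necrosis map as a CSV matrix
#'
#' Patch values (percent) as a plain matrix, preceded by `#` comments
#' carrying patch size, depth and id; round-trips through
#' [readNecrosisMap()].
#'
#' @param map a [NecrosisMap-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeNecrosisMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# patch_um %s", format(map@patch_um, digits = 17)),
               sprintf("# depth_um %s", format(map@depth_um, digits = 17)),
               sprintf("# section_id %s", map@section_id)), con)
  utils::write.table(format(map@values, digits = 17, trim = TRUE), con,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a necrosis map CSV written by [writeNecrosisMap()]
#' @param path input file
#' @return a [NecrosisMap-class]
#' @export
readNecrosisMap <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  getf <- function(key, num = TRUE) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop("missing header field: ", key)
    v <- sub(paste0("^# ", key, " "), "", ln[1])
    if (num) as.numeric(v) else v
  }
  vals <- as.matrix(utils::read.table(text = lines[!is_hdr], sep = ","))
  dimnames(vals) <- NULL
  necrosisMap(vals, patch_um = getf("patch_um"),
              depth_um = getf("depth_um"),
              section_id = getf("section_id", num = FALSE))
}

#' Load a simulation configuration from YAML
#'
#' Reads the parameter blocks (`optics`, `grid`, `beam`, `thermal`,
#' `perfusion`, `boundary`, `damage`, `laser`, `cases`) and materializes the
#' corresponding parameter objects, falling back to package defaults for
#' absent fields.
#'
#' @param path YAML file
#' @return named list of parameter objects ready for [predictNecrosis()]
#' @export
loadConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- function(block, key, default) {
    v <- cfg[[block]][[key]]
    if (is.null(v)) default else v
  }
  list(
    optics = opticalProperties(mu_a = g("optics", "mu_a", 0.1),
                               mu_s = g("optics", "mu_s", 6.14),
                               g = g("optics", "g", 0.9)),
    grid = voxelGrid(extent = g("grid", "extent_mm", 20),
                     voxel = g("grid", "voxel_mm", 0.5)),
    beam_diameter_mm = g("beam", "diameter_mm", 5),
    thermal = thermalProperties(rho = g("thermal", "rho", 1079),
                                cp = g("thermal", "cp", 3540),
                                k_cond = g("thermal", "k", 0.52)),
    perfusion = perfusionParams(
      omega_b = g("perfusion", "omega_b", 0.0175),
      c_b = g("perfusion", "c_b", 3617),
      rho_b = g("perfusion", "rho_b", 1050),
      T_b = g("perfusion", "T_b", 310.15)),
    boundary = boundarySpec(h_conv = g("boundary", "h_conv", 10),
                            T_ambient = g("boundary", "T_ambient", 293.15),
                            dirichlet_T = g("boundary", "dirichlet_T",
                                            293.15)),
    damage = arrheniusParams(A = g("damage", "A", 5.51e41),
                             dE = g("damage", "dE", 2.77e5),
                             n = g("damage", "n", 3)),
    rep_rate = g("laser", "rep_rate", 10),
    pulse_duration = g("laser", "pulse_duration", 5e-9),
    T0 = g("laser", "T0", 293.15),
    cases = if (is.null(cfg$cases)) {
      data.frame(energy_mJ = 73, duration_min = 20)
    } else {
      do.call(rbind, lapply(cfg$cases, as.data.frame))
    })
}
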