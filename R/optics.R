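## Dosimetry arithmetic and voxel Monte Carlo photon transport.

#' Peak power of a single laser pulse
#'
#' `pulse energy / pulse duration`. A 73 mJ, 5 ns pulse carries a peak power
#' of 1.46e7 W.
#'
#' @param pulse_energy J
#' @param pulse_duration s
#' @return W
#' @examples
#' peakPower(0.073, 5e-9)  # 1.46e7
#' @export
peakPower <- function(pulse_energy, pulse_duration) {
  if (any(pulse_energy <= 0) || any(pulse_duration <= 0))
    stop("pulse_energy and pulse_duration must be > 0")
  pulse_energy / pulse_duration
}

#' Time-averaged power of a pulse train
#'
#' `pulse energy x repetition rate`; equals peak power times the duty cycle.
#' This is the source power of the average-mode bioheat source.
#'
#' @param pulse_energy J
#' @param rep_rate Hz
#' @return W
#' @examples
#' averagePower(0.073, 10)  # 0.73 W
#' @export
averagePower <- function(pulse_energy, rep_rate) {
  if (any(pulse_energy <= 0) || any(rep_rate <= 0))
    stop("pulse_energy and rep_rate must be > 0")
  pulse_energy * rep_rate
}

#' Beam fluence of a flat-top pulse
#'
#' Energy per unit beam cross-section: `E / (pi d^2 / 4)` with the mm^2 to
#' cm^2 conversion, so 73 mJ over a 5 mm disk gives 371.79 mJ/cm^2.
#'
#' @param pulse_energy_mJ pulse energy, mJ
#' @param beam_diameter_mm beam diameter, mm
#' @return fluence, mJ/cm^2
#' @examples
#' fluence(73, 5)  # 371.79
#' fluence(30, 5)  # 152.79
#' @export
fluence <- function(pulse_energy_mJ, beam_diameter_mm) {
  if (any(pulse_energy_mJ <= 0) || any(beam_diameter_mm <= 0))
    stop("pulse_energy_mJ and beam_diameter_mm must be > 0")
  area_cm2 <- pi * (beam_diameter_mm / 10)^2 / 4
  pulse_energy_mJ / area_cm2
}

#' On/off square wave of a pulsed laser trigger
#'
#' 1 while the laser fires (the first `pulse_duration` seconds of each
#' repetition period), 0 otherwise.
#'
#' @param t time, s (vectorized), >= 0
#' @param rep_rate Hz
#' @param pulse_duration s
#' @return 0/1 vector
#' @examples
#' onoff(2e-9, 10, 5e-9)  # 1
#' onoff(0.05, 10, 5e-9)  # 0
#' @export
onoff <- function(t, rep_rate, pulse_duration) {
  if (any(t < 0)) stop("t must be >= 0")
  as.numeric(t %% (1 / rep_rate) < pulse_duration)
}

#' Run voxel Monte Carlo photon transport
#'
#' Launches `n_photons` photon packets uniformly over the flat-top beam disk,
#' normal to the irradiated (z = 0) face of a homogeneous block. Free paths
#' are sampled from the exponential with mu_t = mu_a + mu_s; at each
#' interaction a fraction mu_a/mu_t of the packet weight is deposited in the
#' enclosing voxel (implicit capture) and the remainder is scattered through
#' a Henyey-Greenstein deflection with anisotropy g. Packets leaving the
#' block terminate; packets below `w_threshold` play Russian roulette with
#' survival probability `p_survive`. The returned deposition is normalized
#' per launched energy and per voxel volume (1/m^3).
#'
#' Deterministic for a fixed `seed` and photon count. Energy is conserved
#' exactly: `sum(values) * voxel volume + escaped fraction = 1` (the escaped
#' fraction includes the net Russian-roulette residual).
#'
#' @param props an [OpticalProperties-class]
#' @param beam a [BeamSpec-class]
#' @param grid a [VoxelGrid-class]
#' @param n_photons photons to launch (>= 1e4 recommended for smooth fields)
#' @param seed RNG seed
#' @param w_threshold roulette weight threshold
#' @param p_survive roulette survival probability
#' @param specular specular reflection coefficient at the entry face
#'   (default 0: matched boundary)
#' @return an [EnergyDensityGrid-class]
#' @examples
#' g <- voxelGrid(extent = 10, voxel = 1)
#' e <- runPhotonTransport(opticalProperties(), beamSpec(grid = g), g,
#'                         n_photons = 5e3, seed = 1)
#' sum(values(e)) * voxelVolume(g) + escapedFraction(e)  # 1
#' @export
runPhotonTransport <- function(props, beam, grid, n_photons = 1e6,
                               seed = 1L, w_threshold = 1e-4,
                               p_survive = 0.1, specular = 0) {
  stopifnot(is(props, "OpticalProperties"), is(beam, "BeamSpec"),
            is(grid, "VoxelGrid"))
  validObject(props); validObject(beam); validObject(grid)
  if (n_photons < 1) stop("n_photons must be >= 1")
  r <- beam@diameter / 2
  if (any(beam@center - r < 0) || any(beam@center + r > grid@extent[1:2]))
    stop("beam disk extends outside the entry face")
  d <- gridDims(grid)
  set.seed(seed)
  res <- mc_transport_cpp(props@mu_a, props@mu_s, props@g,
                          r, beam@center[1], beam@center[2],
                          d[1], d[2], d[3], grid@voxel,
                          as.double(n_photons), w_threshold, p_survive,
                          specular)
  vals <- array(res$absorbed / n_photons / voxelVolume(grid), dim = d)
  new("EnergyDensityGrid", grid = grid, values = vals,
      escaped_fraction = res$escaped_fraction, n_photons = n_photons,
      seed = as.integer(seed))
}

#' Voxel-center coordinates of a grid
#' @param grid a [VoxelGrid-class]
#' @return list of numeric vectors x, y, z (mm)
#' @export
voxelCenters <- function(grid) {
  d <- gridDims(grid)
  lapply(seq_len(3), function(a) (seq_len(d[a]) - 0.5) * grid@voxel)
}

#' Write an energy-density grid to CSV
#'
#' Four columns (x, y, z voxel-center coordinates in mm and the density
#' value in 1/m^3) preceded by a `#`-comment header carrying the grid
#' metadata. [readEnergyDensity()] round-trips exactly.
#'
#' @param e an [EnergyDensityGrid-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeEnergyDensity <- function(e, path) {
  stopifnot(is(e, "EnergyDensityGrid"))
  cc <- voxelCenters(e@grid)
  d <- gridDims(e@grid)
  dt <- data.table::data.table(
    x = rep(cc[[1]], times = d[2] * d[3]),
    y = rep(rep(cc[[2]], each = d[1]), times = d[3]),
    z = rep(cc[[3]], each = d[1] * d[2]),
    value = as.vector(e@values))
  hdr <- c(sprintf("# extent_mm %s", paste(format(e@grid@extent, digits = 17),
                                           collapse = " ")),
           sprintf("# voxel_mm %s", format(e@grid@voxel, digits = 17)),
           sprintf("# n_photons %s", format(e@n_photons, digits = 17)),
           sprintf("# seed %d", e@seed),
           sprintf("# escaped_fraction %s",
                   format(e@escaped_fraction, digits = 17)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("x,y,z,value", con)
  writeLines(paste(format(dt$x, digits = 17, trim = TRUE),
                   format(dt$y, digits = 17, trim = TRUE),
                   format(dt$z, digits = 17, trim = TRUE),
                   format(dt$value, digits = 17, trim = TRUE), sep = ","),
             con)
  invisible(path)
}

#' Read an energy-density grid from CSV
#'
#' @param path file written by [writeEnergyDensity()]
#' @return an [EnergyDensityGrid-class]
#' @export
readEnergyDensity <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  getf <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop("missing header field: ", key)
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", ln[1]), " ")[[1]])
  }
  extent <- getf("extent_mm"); voxel <- getf("voxel_mm")
  n_photons <- getf("n_photons"); seed <- getf("seed")
  escaped <- getf("escaped_fraction")
  body <- lines[!is_hdr]
  cols <- strsplit(body[1], ",")[[1]]
  if (length(cols) != 4 || !identical(cols, c("x", "y", "z", "value")))
    stop("parse error at line ", which(!is_hdr)[1],
         ": expected header 'x,y,z,value'")
  dt <- data.table::fread(text = body, header = TRUE)
  if (ncol(dt) != 4)
    stop("parse error: expected 4 columns, found ", ncol(dt))
  grid <- voxelGrid(extent = extent, voxel = voxel)
  d <- gridDims(grid)
  if (nrow(dt) != prod(d))
    stop("parse error: expected ", prod(d), " rows, found ", nrow(dt))
  ## rows are written x-fastest, then y, then z
  vals <- array(dt$value, dim = d)
  new("EnergyDensityGrid", grid = grid, values = vals,
      escaped_fraction = escaped, n_photons = n_photons,
      seed = as.integer(seed))
}
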