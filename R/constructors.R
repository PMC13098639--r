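#' Construct optical properties
#' @param mu_a absorption coefficient, 1/mm
#' @param mu_s scattering coefficient, 1/mm
#' @param g anisotropy factor in \[-1, 1\]
#' @return an [OpticalProperties-class]
#' @examples
#' opticalProperties()           # porcine liver at 750 nm
#' opticalProperties(mu_s = 0)   # pure absorber (Beer-Lambert limit)
#' @export
opticalProperties <- function(mu_a = 0.1, mu_s = 6.14, g = 0.9) {
  new("OpticalProperties", mu_a = mu_a, mu_s = mu_s, g = g)
}

#' Construct a flat-top beam specification
#' @param diameter beam diameter, mm
#' @param center (x, y) position of the beam axis on the entry face, mm;
#'   defaults to the face center of `grid`
#' @param grid optional [VoxelGrid-class] used for the default center and the
#'   containment check
#' @return a [BeamSpec-class]
#' @export
beamSpec <- function(diameter = 5, center = NULL, grid = NULL) {
  if (is.null(center)) {
    center <- if (is.null(grid)) c(10, 10) else grid@extent[1:2] / 2
  }
  b <- new("BeamSpec", diameter = diameter, center = center,
           entry_face = "z0")
  if (!is.null(grid)) {
    r <- diameter / 2
    if (any(center - r < 0) || any(center + r > grid@extent[1:2]))
      stop("beam disk extends outside the entry face")
  }
  b
}

#' Construct a pulse train
#' @param pulse_energy energy per pulse, J
#' @param pulse_duration pulse width, s
#' @param rep_rate repetition rate, Hz
#' @param exposure_time total irradiation time, s
#' @return a [PulseTrain-class]
#' @export
pulseTrain <- function(pulse_energy = 0.073, pulse_duration = 5e-9,
                       rep_rate = 10, exposure_time = 1200) {
  new("PulseTrain", pulse_energy = pulse_energy,
      pulse_duration = pulse_duration, rep_rate = rep_rate,
      exposure_time = exposure_time)
}

#' Construct a voxel grid
#' @param extent block edge lengths, mm (recycled to 3)
#' @param voxel voxel edge, mm
#' @return a [VoxelGrid-class]
#' @export
voxelGrid <- function(extent = 20, voxel = 0.5) {
  new("VoxelGrid", extent = rep_len(extent, 3), voxel = voxel)
}

#' Construct thermal properties (constant or temperature-dependent)
#'
#' Numbers are wrapped into constant functions; functions of T (K) are used
#' as-is. Defaults are constant literature values for liver: rho = 1079
#' kg/m^3, cp = 3540 J/(kg K), k = 0.52 W/(m K).
#'
#' @param rho density, kg/m^3, number or function of T
#' @param cp specific heat, J/(kg K), number or function of T
#' @param k_cond thermal conductivity, W/(m K), number or function of T
#' @return a [ThermalProperties-class]
#' @export
thermalProperties <- function(rho = 1079, cp = 3540, k_cond = 0.52) {
  wrap <- function(v) if (is.function(v)) v else {
    force(v); function(T) rep_len(v, length(T))
  }
  new("ThermalProperties", rho = wrap(rho), cp = wrap(cp),
      k_cond = wrap(k_cond))
}

#' Construct blood perfusion parameters
#' @param omega_b blood perfusion rate, 1/s
#' @param c_b blood specific heat, J/(kg K)
#' @param rho_b blood density, kg/m^3
#' @param T_b arterial blood temperature, K
#' @return a [PerfusionParams-class]
#' @export
perfusionParams <- function(omega_b = 0.0175, c_b = 3617, rho_b = 1050,
                            T_b = 310.15) {
  new("PerfusionParams", omega_b = omega_b, c_b = c_b, rho_b = rho_b,
      T_b = T_b)
}

#' Construct boundary conditions
#' @param h_conv free-convection coefficient of the irradiated face,
#'   W/(m^2 K)
#' @param T_ambient ambient air temperature, K
#' @param dirichlet_T fixed temperature of the five remaining faces, K
#' @return a [BoundarySpec-class]
#' @export
boundarySpec <- function(h_conv = 10, T_ambient = 293.15,
                         dirichlet_T = 293.15) {
  new("BoundarySpec", convective_face = "z0", h_conv = h_conv,
      T_ambient = T_ambient, dirichlet_T = dirichlet_T)
}

#' Construct a laser heat source specification
#' @param density an [EnergyDensityGrid-class] from [runPhotonTransport()]
#' @param pulse_train a [PulseTrain-class]
#' @param mode `"average"` (default: time-averaged power, suitable for long
#'   exposures) or `"pulsed"` (instantaneous peak power gated by the on/off
#'   square wave; short verification horizons)
#' @param Q_met metabolic heat source, W/m^3
#' @return a [HeatSourceSpec-class]
#' @export
heatSourceSpec <- function(density, pulse_train = pulseTrain(),
                           mode = c("average", "pulsed"), Q_met = 0) {
  mode <- match.arg(mode)
  new("HeatSourceSpec", mode = mode, pulse_train = pulse_train,
      density = density, Q_met = Q_met)
}

#' Construct Arrhenius kinetics parameters
#' @param A frequency factor, 1/s
#' @param dE activation energy, J/mol
#' @param n polynomial order (>= 1)
#' @return an [ArrheniusParams-class]
#' @export
arrheniusParams <- function(A = 5.51e41, dE = 2.77e5, n = 3) {
  new("ArrheniusParams", A = A, dE = dE, n = n, R = 8.314)
}

#' Construct a temperature trace
#' @param times seconds, strictly increasing
#' @param temperature K
#' @param probe_index voxel index (i, j, k), 1-based
#' @return a [TemperatureTrace-class]
#' @export
temperatureTrace <- function(times, temperature,
                             probe_index = c(1L, 1L, 1L)) {
  new("TemperatureTrace", times = as.numeric(times),
      temperature = as.numeric(temperature),
      probe_index = as.integer(probe_index))
}

#' Construct a section image from a pixel array
#' @param pixels height x width x 3 array, 0-255 RGB
#' @param um_per_px microns per pixel
#' @param depth_um depth below the sample surface, microns
#' @param section_id identifier
#' @return a [SectionImage-class]
#' @export
sectionImage <- function(pixels, um_per_px = 0.23, depth_um = 0,
                         section_id = "section") {
  new("SectionImage", pixels = pixels, um_per_px = um_per_px,
      depth_um = depth_um, section_id = section_id)
}

#' Construct RGB classification rules
#' @param brown_r brown R range c(min, max)
#' @param brown_g_max,brown_b_max brown G and B upper bounds
#' @param blue_r blue R range c(min, max)
#' @param blue_g_min,blue_b_min blue G and B lower bounds
#' @return a [CellClassRules-class]
#' @export
cellClassRules <- function(brown_r = c(60, 210), brown_g_max = 151,
                           brown_b_max = 130, blue_r = c(150, 186),
                           blue_g_min = 155, blue_b_min = 160) {
  new("CellClassRules", brown_r = brown_r, brown_g_max = brown_g_max,
      brown_b_max = brown_b_max, blue_r = blue_r, blue_g_min = blue_g_min,
      blue_b_min = blue_b_min)
}

#' Construct a necrosis map
#' @param values matrix of percentages in \[0, 100\]
#' @param patch_um patch edge, microns
#' @param depth_um section depth, microns
#' @param section_id identifier
#' @return a [NecrosisMap-class]
#' @export
necrosisMap <- function(values, patch_um = 200, depth_um = 0,
                        section_id = "map") {
  new("NecrosisMap", values = values, patch_um = patch_um,
      depth_um = depth_um, section_id = section_id)
}

#' Construct a rigid transform
#' @param rotation degrees, counter-clockwise in raster coordinates
#' @param translation (dx, dy)
#' @param center rotation center (x, y); raster center by convention
#' @return a [RigidTransform-class]
#' @export
rigidTransform <- function(rotation = 0, translation = c(0, 0),
                           center = c(0, 0)) {
  new("RigidTransform", rotation = rotation, translation = translation,
      center = center)
}
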