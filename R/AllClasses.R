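#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib necrotherm, .registration = TRUE
NULL

## ---------------------------------------------------------------- optics ---

#' Optical properties of a homogeneous tissue block
#'
#' Absorption coefficient, scattering coefficient (both 1/mm) and the
#' Henyey-Greenstein anisotropy factor g. Defaults are porcine liver at
#' 750 nm: mu_a = 0.1/mm, mu_s = 6.14/mm, g = 0.9.
#'
#' @slot mu_a absorption coefficient, 1/mm
#' @slot mu_s scattering coefficient, 1/mm
#' @slot g scattering anisotropy, dimensionless, in \[-1, 1\]
#' @exportClass OpticalProperties
setClass("OpticalProperties",
  representation(mu_a = "numeric", mu_s = "numeric", g = "numeric"),
  prototype(mu_a = 0.1, mu_s = 6.14, g = 0.9))

setValidity("OpticalProperties", function(object) {
  if (object@mu_a < 0 || object@mu_s < 0) return("mu_a and mu_s must be >= 0")
  if (object@mu_a + object@mu_s <= 0) return("mu_a + mu_s must be > 0")
  if (abs(object@g) > 1) return("g must lie in [-1, 1]")
  TRUE
})

#' Flat-top laser beam specification
#'
#' A uniform (flat-top) disk beam entering the block normally through one
#' face. Only the z = 0 (irradiated) face is supported as entry face.
#'
#' @slot diameter beam diameter, mm
#' @slot center beam center on the entry face, mm (x, y)
#' @slot entry_face face identifier, currently `"z0"`
#' @exportClass BeamSpec
setClass("BeamSpec",
  representation(diameter = "numeric", center = "numeric",
                 entry_face = "character"),
  prototype(diameter = 5, center = c(10, 10), entry_face = "z0"))

setValidity("BeamSpec", function(object) {
  if (object@diameter <= 0) return("diameter must be > 0")
  if (length(object@center) != 2) return("center must be length-2 (x, y) mm")
  if (!identical(object@entry_face, "z0"))
    return("only entry through the z = 0 face is supported")
  TRUE
})

#' Pulse train of a Q-switched laser source
#'
#' @slot pulse_energy energy per pulse, J
#' @slot pulse_duration pulse width, s
#' @slot rep_rate repetition rate, Hz
#' @slot exposure_time total irradiation time, s
#' @exportClass PulseTrain
setClass("PulseTrain",
  representation(pulse_energy = "numeric", pulse_duration = "numeric",
                 rep_rate = "numeric", exposure_time = "numeric"),
  prototype(pulse_energy = 0.073, pulse_duration = 5e-9, rep_rate = 10,
            exposure_time = 1200))

setValidity("PulseTrain", function(object) {
  v <- c(object@pulse_energy, object@pulse_duration, object@rep_rate,
         object@exposure_time)
  if (any(v <= 0)) return("all pulse-train fields must be > 0")
  if (object@pulse_duration * object@rep_rate > 1)
    return("duty cycle exceeds 1 (pulse_duration * rep_rate > 1)")
  TRUE
})

#' Uniform voxel grid over the tissue block
#'
#' Cube (or box) of tissue with voxel centers at (i + 0.5) * voxel mm,
#' 0-based indexing, axis order (x, y, z), z increasing into the tissue from
#' the irradiated face at z = 0.
#'
#' @slot extent block edge lengths, mm (x, y, z)
#' @slot voxel voxel edge, mm
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(extent = "numeric", voxel = "numeric"),
  prototype(extent = c(20, 20, 20), voxel = 0.5))

setValidity("VoxelGrid", function(object) {
  if (length(object@extent) != 3 || any(object@extent <= 0))
    return("extent must be 3 positive lengths (mm)")
  if (object@voxel <= 0) return("voxel size must be > 0")
  n <- object@extent / object@voxel
  if (any(abs(n - round(n)) > 1e-8))
    return("extent must be divisible by voxel size")
  if (any(round(n) < 4)) return("grid must have >= 4 voxels per axis")
  TRUE
})

#' Normalized absorbed-energy density on a voxel grid
#'
#' `values[i,j,k]` is the fraction of launched energy absorbed in voxel
#' (i,j,k) divided by the voxel volume (1/m^3), i.e. multiplying by a source
#' power in W yields a volumetric heat source in W/m^3.
#'
#' @slot grid the [VoxelGrid-class] the simulation ran on
#' @slot values 3D array, 1/m^3
#' @slot escaped_fraction fraction of launched energy not deposited
#' @slot n_photons photons launched
#' @slot seed RNG seed used
#' @exportClass EnergyDensityGrid
setClass("EnergyDensityGrid",
  representation(grid = "VoxelGrid", values = "array",
                 escaped_fraction = "numeric", n_photons = "numeric",
                 seed = "integer"))

setValidity("EnergyDensityGrid", function(object) {
  if (any(object@values < 0)) return("energy density values must be >= 0")
  vv <- voxelVolume(object@grid)  # m^3
  tot <- sum(object@values) * vv + object@escaped_fraction
  if (abs(tot - 1) > 1e-6)
    return(sprintf("energy not conserved: deposited + escaped = %.8f", tot))
  TRUE
})

## --------------------------------------------------------------- bioheat ---

#' Thermal properties of the tissue
#'
#' Each slot is a function of absolute temperature (K) returning the property
#' value, which lets users plug in temperature-dependent curves. The
#' constructor [thermalProperties()] wraps plain numbers into constant
#' functions; defaults are constant literature liver values.
#'
#' @slot rho density, kg/m^3
#' @slot cp specific heat, J/(kg K)
#' @slot k_cond thermal conductivity, W/(m K)
#' @exportClass ThermalProperties
setClass("ThermalProperties",
  representation(rho = "function", cp = "function", k_cond = "function"))

setValidity("ThermalProperties", function(object) {
  Ts <- c(273, 310, 400)
  for (f in c(object@rho, object@cp, object@k_cond)) {
    v <- vapply(Ts, f, numeric(1))
    if (any(!is.finite(v)) || any(v <= 0))
      return("properties must be positive and finite over 273-400 K")
  }
  TRUE
})

#' Blood perfusion parameters of the Pennes equation
#'
#' Defaults are the porcine-liver values: omega_b = 0.0175 1/s,
#' c_b = 3617 J/(kg K), rho_b = 1050 kg/m^3, T_b = 310.15 K.
#'
#' @slot omega_b blood perfusion rate, 1/s
#' @slot c_b blood specific heat, J/(kg K)
#' @slot rho_b blood density, kg/m^3
#' @slot T_b arterial blood temperature, K
#' @exportClass PerfusionParams
setClass("PerfusionParams",
  representation(omega_b = "numeric", c_b = "numeric", rho_b = "numeric",
                 T_b = "numeric"),
  prototype(omega_b = 0.0175, c_b = 3617, rho_b = 1050, T_b = 310.15))

setValidity("PerfusionParams", function(object) {
  if (object@omega_b < 0) return("omega_b must be >= 0")
  if (any(c(object@c_b, object@rho_b, object@T_b) <= 0))
    return("c_b, rho_b, T_b must be > 0")
  TRUE
})

#' Boundary conditions for the bioheat solver
#'
#' The irradiated (z = 0) face exchanges heat with ambient air by free
#' convection (Robin condition, coefficient `h_conv`); the five remaining
#' faces are held at `dirichlet_T`.
#'
#' @slot convective_face face identifier, `"z0"`
#' @slot h_conv convection coefficient, W/(m^2 K)
#' @slot T_ambient ambient air temperature, K
#' @slot dirichlet_T fixed temperature of the other faces, K
#' @exportClass BoundarySpec
setClass("BoundarySpec",
  representation(convective_face = "character", h_conv = "numeric",
                 T_ambient = "numeric", dirichlet_T = "numeric"),
  prototype(convective_face = "z0", h_conv = 10, T_ambient = 293.15,
            dirichlet_T = 293.15))

setValidity("BoundarySpec", function(object) {
  if (object@h_conv < 0) return("h_conv must be >= 0")
  if (object@T_ambient < 273 || object@T_ambient > 400 ||
      object@dirichlet_T < 273 || object@dirichlet_T > 400)
    return("boundary temperatures must lie in 273-400 K")
  TRUE
})

#' Volumetric laser heat source specification
#'
#' In `"average"` mode the source is the time-constant field
#' `average power x energy density`; in `"pulsed"` mode the instantaneous
#' field is `peak power x energy density x onoff(t)`. The per-period time
#' integral is identical in both modes.
#'
#' @slot mode `"average"` or `"pulsed"`
#' @slot pulse_train a [PulseTrain-class]
#' @slot density an [EnergyDensityGrid-class]
#' @slot Q_met metabolic heat source, W/m^3 (0 for ex-situ liver)
#' @exportClass HeatSourceSpec
setClass("HeatSourceSpec",
  representation(mode = "character", pulse_train = "PulseTrain",
                 density = "EnergyDensityGrid", Q_met = "numeric"),
  prototype(mode = "average", Q_met = 0))

setValidity("HeatSourceSpec", function(object) {
  if (!object@mode %in% c("average", "pulsed"))
    return("mode must be 'average' or 'pulsed'")
  TRUE
})

#' Probe temperature trace
#'
#' @slot times seconds, strictly increasing
#' @slot temperature K at the probe voxel
#' @slot probe_index voxel index (i, j, k), 1-based
#' @exportClass TemperatureTrace
setClass("TemperatureTrace",
  representation(times = "numeric", temperature = "numeric",
                 probe_index = "integer"))

setValidity("TemperatureTrace", function(object) {
  if (length(object@times) != length(object@temperature))
    return("times and temperature must have equal length")
  if (length(object@times) && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(!is.finite(object@temperature)))
    return("temperatures must be finite")
  TRUE
})

#' Temperature field snapshot
#' @slot grid the solver [VoxelGrid-class]
#' @slot temperature 3D array, K
#' @slot time snapshot time, s
#' @exportClass TemperatureField
setClass("TemperatureField",
  representation(grid = "VoxelGrid", temperature = "array", time = "numeric"))

## ---------------------------------------------------------------- damage ---

#' Arrhenius damage kinetics parameters
#'
#' Defaults correspond to the onset of irreversible thermal damage in swine
#' liver: A = 5.51e41 1/s, dE = 2.77e5 J/mol, polynomial order n = 3. The
#' damage rate is A * exp(-dE / (R T)).
#'
#' @slot A frequency factor, 1/s
#' @slot dE activation energy, J/mol
#' @slot n polynomial order of the kinetics, dimensionless
#' @slot R universal gas constant, J/(mol K)
#' @exportClass ArrheniusParams
setClass("ArrheniusParams",
  representation(A = "numeric", dE = "numeric", n = "numeric", R = "numeric"),
  prototype(A = 5.51e41, dE = 2.77e5, n = 3, R = 8.314))

setValidity("ArrheniusParams", function(object) {
  if (object@A <= 0 || object@dE <= 0) return("A and dE must be > 0")
  if (object@n < 1) return("n must be >= 1")
  TRUE
})

#' Damage trace: degree of injury and necrotic fraction over time
#'
#' @slot times seconds
#' @slot alpha degree of tissue injury (non-decreasing, may exceed 1)
#' @slot theta_d alpha clamped to \[0, 1\]
#' @exportClass DamageTrace
setClass("DamageTrace",
  representation(times = "numeric", alpha = "numeric", theta_d = "numeric"))

setValidity("DamageTrace", function(object) {
  if (length(object@alpha) && any(diff(object@alpha) < -1e-9))
    return("alpha must be non-decreasing")
  if (any(object@theta_d < -1e-12) || any(object@theta_d > 1 + 1e-12))
    return("theta_d must lie in [0, 1]")
  TRUE
})

## ------------------------------------------------------------- histology ---

#' A digitized IHC section
#'
#' @slot pixels numeric array `[row, col, channel]` with 8-bit RGB values in
#'   0-255; row 1 is the top of the raster
#' @slot um_per_px microns per pixel
#' @slot depth_um section depth below the sample surface, microns
#' @slot section_id identifier
#' @exportClass SectionImage
setClass("SectionImage",
  representation(pixels = "array", um_per_px = "numeric",
                 depth_um = "numeric", section_id = "character"),
  prototype(um_per_px = 0.23, depth_um = 0, section_id = "section"))

setValidity("SectionImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3)
    return("pixels must be a height x width x 3 array")
  if (d[1] < 1 || d[2] < 1) return("raster must be at least 1 x 1")
  if (object@um_per_px <= 0) return("um_per_px must be > 0")
  TRUE
})

#' Power-of-two mosaic decomposition plan
#'
#' @slot mosaic_cols,mosaic_rows number of tiles per dimension (powers of two)
#' @slot tile_w,tile_h tile size, px (edge tiles may be smaller)
#' @slot byte_bound per-tile storage bound, bytes (4 bytes/pixel accounting)
#' @slot width,height section size, px
#' @exportClass MosaicPlan
setClass("MosaicPlan",
  representation(mosaic_cols = "integer", mosaic_rows = "integer",
                 tile_w = "integer", tile_h = "integer",
                 byte_bound = "numeric", width = "integer",
                 height = "integer"))

setValidity("MosaicPlan", function(object) {
  p2 <- function(x) x >= 1 && abs(log2(x) - round(log2(x))) < 1e-9
  if (!p2(object@mosaic_cols) || !p2(object@mosaic_rows))
    return("mosaic dimensions must be powers of two")
  if (as.double(object@tile_w) * object@tile_h * 4 > object@byte_bound)
    return("tile exceeds the byte bound")
  TRUE
})

#' Cell segmentation of a raster
#'
#' @slot labels integer matrix, 0 = background, 1..n = cells
#' @slot cells data.frame with one row per cell: `label`, `area_px`,
#'   `area_um2`, `mean_r`, `mean_g`, `mean_b`, `cx`, `cy` (pixel centroids,
#'   x = column, y = row) and, after [classifyCells()], `class`
#' @slot um_per_px microns per pixel
#' @exportClass CellSegmentation
setClass("CellSegmentation",
  representation(labels = "matrix", cells = "data.frame",
                 um_per_px = "numeric"))

#' RGB box rules for DAB-brown / hematoxylin-blue cell classification
#'
#' Defaults are the empirical boxes: brown if 60 <= R <= 210, G <= 151,
#' B <= 130; blue if 150 <= R <= 186, G >= 155, B >= 160. The G ranges make
#' the boxes disjoint.
#'
#' @slot brown_r,brown_g_max,brown_b_max brown box bounds
#' @slot blue_r,blue_g_min,blue_b_min blue box bounds
#' @exportClass CellClassRules
setClass("CellClassRules",
  representation(brown_r = "numeric", brown_g_max = "numeric",
                 brown_b_max = "numeric", blue_r = "numeric",
                 blue_g_min = "numeric", blue_b_min = "numeric"),
  prototype(brown_r = c(60, 210), brown_g_max = 151, brown_b_max = 130,
            blue_r = c(150, 186), blue_g_min = 155, blue_b_min = 160))

setValidity("CellClassRules", function(object) {
  if (object@brown_g_max >= object@blue_g_min)
    return("brown and blue G ranges must not overlap (disjoint boxes)")
  TRUE
})

#' Patchwise blue/brown area statistics
#'
#' One row per 200-um (default) patch: truncated edge patches carry their
#' true area. `gamma` is NA when the patch holds no classified cell.
#'
#' @slot stats data.frame: `row`, `col`, `blue_area_um2`, `brown_area_um2`,
#'   `patch_area_um2`, `gamma`, `rho`
#' @slot patch_um patch edge, microns
#' @slot decay_k exponential decay constant of the necrosis score
#' @exportClass PatchStats
setClass("PatchStats",
  representation(stats = "data.frame", patch_um = "numeric",
                 decay_k = "numeric"),
  prototype(patch_um = 200, decay_k = 100))

#' Patch-grid necrosis map of one section
#'
#' @slot values matrix of necrosis percentages in `\[0, 100\]`,
#'   `[patch row, patch col]`
#' @slot patch_um patch edge, microns
#' @slot depth_um section depth, microns
#' @slot section_id identifier
#' @exportClass NecrosisMap
setClass("NecrosisMap",
  representation(values = "matrix", patch_um = "numeric",
                 depth_um = "numeric", section_id = "character"),
  prototype(patch_um = 200, depth_um = 0, section_id = "map"))

setValidity("NecrosisMap", function(object) {
  if (any(object@values < -1e-9) || any(object@values > 100 + 1e-9))
    return("necrosis values must lie in [0, 100]")
  TRUE
})

#' Result of the stage-2 artifact filter
#'
#' @slot map filtered [NecrosisMap-class] (zero outside the kept object)
#' @slot kept_label label of the surviving component (NA if none)
#' @slot centroid stage-1 reference centroid (x, y) in patch coordinates
#' @slot empty TRUE when no object survived the solidity filter
#' @exportClass FilterResult
setClass("FilterResult",
  representation(map = "NecrosisMap", kept_label = "integer",
                 centroid = "numeric", empty = "logical"))

## ------------------------------------------------------------- volumetry ---

#' Rigid (rotation + translation) 2D transform
#'
#' Maps a point p of the moving frame to `R(theta) (p - c) + c + t` in the
#' fixed frame, with c the raster center and angles in degrees
#' (counter-clockwise in x-right / y-down raster coordinates).
#'
#' @slot rotation degrees
#' @slot translation (dx, dy), pixels (or patch units for maps)
#' @slot center rotation center (x, y)
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric",
                 center = "numeric"),
  prototype(rotation = 0, translation = c(0, 0), center = c(0, 0)))

#' A registered stack of necrosis maps
#'
#' @slot maps list of [NecrosisMap-class], ordered by depth
#' @slot transforms list of [RigidTransform-class] mapping each map into the
#'   reference frame (identity at the reference index)
#' @slot reference index of the reference section
#' @slot spacing_um inter-section spacing, microns
#' @slot flags per-pair low-confidence registration flags
#' @exportClass RegisteredStack
setClass("RegisteredStack",
  representation(maps = "list", transforms = "list", reference = "integer",
                 spacing_um = "numeric", flags = "logical"),
  prototype(spacing_um = 40))

setValidity("RegisteredStack", function(object) {
  if (length(object@maps) != length(object@transforms))
    return("one transform per map required")
  if (object@spacing_um <= 0) return("spacing must be > 0")
  r <- object@reference
  if (r < 1 || r > length(object@maps)) return("reference index out of range")
  tr <- object@transforms[[r]]
  if (abs(tr@rotation) > 1e-9 || any(abs(tr@translation) > 1e-9))
    return("reference transform must be the identity")
  TRUE
})

#' Depth-interpolated necrosis volume
#'
#' @slot values 3D array `[patch row, patch col, depth level]`, percent
#' @slot patch_um in-plane patch edge, microns
#' @slot step_um depth step, microns
#' @slot depths_um depth of each level, microns
#' @exportClass NecrosisVolume
setClass("NecrosisVolume",
  representation(values = "array", patch_um = "numeric", step_um = "numeric",
                 depths_um = "numeric"),
  prototype(patch_um = 200, step_um = 4))

setValidity("NecrosisVolume", function(object) {
  if (any(object@values < -1e-9) || any(object@values > 100 + 1e-9))
    return("necrosis values must lie in [0, 100]")
  TRUE
})
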