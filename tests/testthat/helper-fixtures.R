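## Shared fixtures, memoized so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixtures)) assign(name, fun(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## full-size transport density used by bioheat-level tests (modest photon
## count; the acceptance run uses 1e6)
liverDensity <- function() fixture("liver_density", function() {
  g <- voxelGrid(20, 0.5)
  runPhotonTransport(opticalProperties(), beamSpec(grid = g), g,
                     n_photons = 2e5, seed = 101)
})

## small synthetic section shared by histology tests
smallSection <- function() fixture("small_section", function() {
  p <- synthSectionParams(canvas_um = 1000, um_per_px = 0.5,
                          radius_um = 300, ring_width_um = 60)
  genSection(p, seed = 7)
})

## independent-section stack (fresh cells per level, shared lesion and
## parenchyma) for the end-to-end pipeline tests
pipelineStack <- function() fixture("pipeline_stack", function() {
  p <- synthSectionParams(canvas_um = 1400, um_per_px = 0.5,
                          radius_um = 350, ring_width_um = 60)
  genStack(p, n_sections = 3, spacing_um = 40, radius_growth = 0.5,
           jitter_rot_sd = 1, jitter_trans_sd = 3,
           parenchyma_amp = 0.6, parenchyma_wavelength_um = 350, seed = 3)
})

pipelineMaps <- function() fixture("pipeline_maps", function() {
  lapply(pipelineStack()$sections, quantifySection)
})

## toy cell segmentation built directly from a cell table (no rendering)
fakeSegmentation <- function(cells, um_per_px = 1, dim_px = c(400, 400)) {
  new("CellSegmentation",
      labels = matrix(0L, dim_px[1], dim_px[2]),
      cells = cells, um_per_px = um_per_px)
}

## analytic product-of-slabs cooling solution for a cube with five
## Dirichlet faces and one insulated face (h = 0), uniform initial
## temperature; independent oracle for the diffusion core of the solver
slabSeriesCube <- function(xyz_mm, L_mm, alpha_mm2_s, t, n_terms = 200) {
  m <- seq_len(n_terms) - 1
  uD <- function(xi) {  # Dirichlet both ends, unit IC
    lam <- (2 * m + 1) * pi / L_mm
    sum(4 / ((2 * m + 1) * pi) * sin(lam * xi) * exp(-alpha_mm2_s * lam^2 * t))
  }
  uN <- function(xi) {  # Neumann at 0, Dirichlet at L, unit IC
    lam <- (2 * m + 1) * pi / (2 * L_mm)
    cm <- 2 * (-1)^m / (lam * L_mm)
    sum(cm * cos(lam * xi) * exp(-alpha_mm2_s * lam^2 * t))
  }
  uD(xyz_mm[1]) * uD(xyz_mm[2]) * uN(xyz_mm[3])
}

## closed-form Arrhenius damage at constant temperature
alphaClosedForm <- function(T, t, params = arrheniusParams()) {
  k <- arrheniusRate(T, params)
  n <- params@n
  if (n == 1) 1 - exp(-k * t)
  else 1 - (1 + (n - 1) * k * t)^(-1 / (n - 1))
}

## brute-force Euler integration of the damage ODE at constant T
alphaEuler <- function(T, t, params = arrheniusParams(), steps = 2e5) {
  k <- arrheniusRate(T, params)
  dt <- t / steps
  a <- 0
  for (i in seq_len(steps)) a <- a + dt * (1 - a)^params@n * k
  a
}

## exhaustive multilevel Otsu oracle in plain R on a small histogram
otsuOracle <- function(counts, n_thresholds) {
  B <- length(counts)
  P <- c(0, cumsum(counts))
  S <- c(0, cumsum(counts * (seq_len(B) - 1)))
  cls <- function(a, b) {
    w <- P[b + 1] - P[a + 1]
    if (w <= 0) return(0)
    mu <- (S[b + 1] - S[a + 1]) / w
    w * mu^2
  }
  best <- -Inf; bt <- NULL
  if (n_thresholds == 1) {
    for (t1 in 1:(B - 1)) {
      v <- cls(0, t1) + cls(t1, B)
      if (v > best) { best <- v; bt <- t1 }
    }
  } else if (n_thresholds == 3) {
    for (t1 in 1:(B - 3)) for (t2 in (t1 + 1):(B - 2))
      for (t3 in (t2 + 1):(B - 1)) {
        v <- cls(0, t1) + cls(t1, t2) + cls(t2, t3) + cls(t3, B)
        if (v > best) { best <- v; bt <- c(t1, t2, t3) }
      }
  }
  bt
}

## full-scale reference protocol shared by the simulation-anchor checks
protocolRun <- function() fixture("protocol_run", function() {
  simulateLiverProtocol(energies_mJ = c(73, 30),
                        durations_min = c(1, 10, 20),
                        n_photons = 1e6, seed = 20260924)
})
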