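test_that("source assembly matches the average/pulsed definitions", {
  dens <- liverDensity()
  pt <- pulseTrain(0.073, 5e-9, 10, 1200)
  avg <- heatSourceSpec(dens, pt, mode = "average")
  pls <- heatSourceSpec(dens, pt, mode = "pulsed")
  expect_equal(assembleSource(avg), 0.73 * values(dens))
  expect_equal(assembleSource(pls, t = 2e-9), 1.46e7 * values(dens))
  expect_equal(assembleSource(pls, t = 0.05), 0 * values(dens))
  ## equal per-period energy: peak x duration == average x period
  expect_equal(sum(assembleSource(pls, 1e-9)) * 5e-9,
               sum(assembleSource(avg)) * 0.1)
})

test_that("uniform equilibrium is a fixed point of the solver", {
  g <- voxelGrid(10, 1)
  dens <- runPhotonTransport(opticalProperties(),
                             beamSpec(diameter = 4, grid = g), g, 1e4, 1)
  Tb <- 310.15
  src <- heatSourceSpec(dens, pulseTrain(1e-12, 5e-9, 10, 60))  # ~zero power
  tr <- solvePennes(g, thermalProperties(), perfusionParams(T_b = Tb), src,
                    boundarySpec(h_conv = 10, T_ambient = Tb,
                                 dirichlet_T = Tb),
                    T0 = Tb, t_end = 30, dt = 0.2)
  expect_true(all(abs(traceTemperature(tr) - Tb) < 1e-6))
})

test_that("pure-diffusion cooling matches the separable Fourier series", {
  ## cube, five Dirichlet faces at 300 K, insulated top (h = 0), uniform
  ## 330 K start, no source, no perfusion; oracle: product of 1D slab series
  g <- voxelGrid(10, 0.5)
  dens <- runPhotonTransport(opticalProperties(),
                             beamSpec(diameter = 4, grid = g), g, 1e4, 1)
  src <- heatSourceSpec(dens, pulseTrain(1e-12, 5e-9, 10, 60))
  th <- thermalProperties(rho = 1000, cp = 4000, k_cond = 0.5)
  tr <- solvePennes(g, th, perfusionParams(omega_b = 0), src,
                    boundarySpec(h_conv = 0, T_ambient = 300,
                                 dirichlet_T = 300),
                    T0 = 330, t_end = 60, dt = 0.1,
                    probe = c(10L, 10L, 1L))
  alpha <- 0.5 / (1000 * 4000) * 1e6  # mm^2/s
  xyz <- (c(10, 10, 1) - 0.5) * 0.5
  ## z measured from the insulated face: uN has Neumann at 0
  u <- slabSeriesCube(c(xyz[1], xyz[2], xyz[3]), 10, alpha, t = 60)
  expect_equal(traceTemperature(tr)[61], 300 + 30 * u, tolerance = 0.1)
})

test_that("unstable time steps are rejected with the bound stated", {
  g <- voxelGrid(10, 0.5)
  dens <- runPhotonTransport(opticalProperties(),
                             beamSpec(diameter = 4, grid = g), g, 1e4, 1)
  src <- heatSourceSpec(dens, pulseTrain(0.073, 5e-9, 10, 60))
  expect_error(
    solvePennes(g, thermalProperties(), perfusionParams(), src,
                boundarySpec(), t_end = 10, dt = 5),
    "stability bound")
})

test_that("average and pulsed source modes agree over a short horizon", {
  g <- voxelGrid(10, 1)
  dens <- runPhotonTransport(opticalProperties(),
                             beamSpec(diameter = 4, grid = g), g, 5e4, 4)
  pt <- pulseTrain(0.073, 5e-9, 10, 2)
  trA <- solvePennes(g, thermalProperties(), perfusionParams(),
                     heatSourceSpec(dens, pt, "average"), boundarySpec(),
                     t_end = 2, dt = 0.01, out_every = 0.1)
  trP <- solvePennes(g, thermalProperties(), perfusionParams(),
                     heatSourceSpec(dens, pt, "pulsed"), boundarySpec(),
                     t_end = 2, dt = 0.01, out_every = 0.1)
  dT_pulse <- perPulseTemperatureRise(fluence(73, 5), 0.1)
  iA <- length(traceTimes(trA)); iP <- length(traceTimes(trP))
  expect_lt(abs(traceTemperature(trA)[iA] - traceTemperature(trP)[iP]),
            dT_pulse + 1e-3)
})

test_that("plateau temperature summarises the trailing window", {
  tr <- temperatureTrace(0:600, rep(300, 601))
  p <- plateauTemperature(tr, 120)
  expect_equal(as.numeric(p), 300)
  expect_true(attr(p, "converged"))
  rising <- temperatureTrace(0:600, 300 + (0:600) * 0.01)
  expect_warning(p2 <- plateauTemperature(rising, 120), "not converged")
  expect_false(attr(p2, "converged"))
  expect_error(plateauTemperature(temperatureTrace(0:10, rep(300, 11)), 120),
               "shorter")
})

test_that("per-pulse adiabatic rise is sub-kelvin at the reference fluence", {
  dT <- perPulseTemperatureRise(371.79, 0.1)
  expect_lt(dT, 1)
  expect_gt(dT, 0.01)
  expect_equal(perPulseTemperatureRise(2 * 371.79, 0.1), 2 * dT)
  expect_equal(perPulseTemperatureRise(0.0001, 0.1), 0, tolerance = 1e-6)
})

test_that("plateau rises monotonically with pulse energy", {
  g <- voxelGrid(10, 1)
  dens <- runPhotonTransport(opticalProperties(),
                             beamSpec(diameter = 4, grid = g), g, 5e4, 4)
  plat <- vapply(c(0.03, 0.073, 0.15), function(E) {
    src <- heatSourceSpec(dens, pulseTrain(E, 5e-9, 10, 120))
    tr <- solvePennes(g, thermalProperties(), perfusionParams(), src,
                      boundarySpec(), t_end = 120, dt = 0.2)
    suppressWarnings(as.numeric(plateauTemperature(tr, 30)))
  }, numeric(1))
  expect_true(all(diff(plat) > 0))
})

test_that("perfusion drives an unheated block toward blood temperature", {
  g <- voxelGrid(10, 1)
  dens <- runPhotonTransport(opticalProperties(),
                             beamSpec(diameter = 4, grid = g), g, 1e4, 1)
  src <- heatSourceSpec(dens, pulseTrain(1e-12, 5e-9, 10, 60))
  ## start above Tb with all boundaries held at the hot temperature: only
  ## the perfusion sink can pull the interior down
  hot <- 330
  base <- list(g, thermalProperties(), src)
  trP <- solvePennes(g, thermalProperties(),
                     perfusionParams(omega_b = 0.0175, T_b = 310.15), src,
                     boundarySpec(h_conv = 0, T_ambient = hot,
                                  dirichlet_T = hot),
                     T0 = hot, t_end = 60, dt = 0.2,
                     probe = c(5L, 5L, 5L))
  tr0 <- solvePennes(g, thermalProperties(),
                     perfusionParams(omega_b = 0), src,
                     boundarySpec(h_conv = 0, T_ambient = hot,
                                  dirichlet_T = hot),
                     T0 = hot, t_end = 60, dt = 0.2,
                     probe = c(5L, 5L, 5L))
  expect_lt(traceTemperature(trP)[61], hot - 0.5)
  expect_equal(traceTemperature(tr0)[61], hot, tolerance = 1e-9)
})

test_that("grid and step refinement leave the probe trace stable", {
  ## scaled-down refinement check on a 10 mm block over 2 min
  probe_T <- function(voxel, dt) {
    g <- voxelGrid(10, voxel)
    dens <- runPhotonTransport(opticalProperties(),
                               beamSpec(diameter = 4, grid = g), g, 2e5, 4)
    src <- heatSourceSpec(dens, pulseTrain(0.073, 5e-9, 10, 120))
    tr <- solvePennes(g, thermalProperties(), perfusionParams(), src,
                      boundarySpec(), t_end = 120, dt = dt)
    traceTemperature(tr)[c(31, 61, 121)]
  }
  coarse <- probe_T(0.5, 0.1)
  fine <- probe_T(0.25, 0.05)
  expect_true(all(abs(coarse - fine) < 0.5))
})

test_that("temperature-dependent property hook engages the chunked solver", {
  g <- voxelGrid(10, 1)
  dens <- runPhotonTransport(opticalProperties(),
                             beamSpec(diameter = 4, grid = g), g, 5e4, 4)
  src <- heatSourceSpec(dens, pulseTrain(0.073, 5e-9, 10, 60))
  th_var <- thermalProperties(k_cond = function(T) 0.52 + 0.001 * (T - 310))
  tr <- solvePennes(g, th_var, perfusionParams(), src, boundarySpec(),
                    t_end = 60, dt = 0.2, property_update_s = 10)
  tr0 <- solvePennes(g, thermalProperties(), perfusionParams(), src,
                     boundarySpec(), t_end = 60, dt = 0.2)
  expect_equal(length(traceTimes(tr)), length(traceTimes(tr0)))
  expect_false(identical(traceTemperature(tr), traceTemperature(tr0)))
})

test_that("trace CSV round-trips", {
  tr <- temperatureTrace(c(0, 1, 2.5), c(293.15, 300, 305.5))
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, path)
  tr2 <- readTrace(path)
  expect_equal(traceTimes(tr2), traceTimes(tr))
  expect_equal(traceTemperature(tr2), traceTemperature(tr))
})
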