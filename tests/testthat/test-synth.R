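test_that("section generation is seed-deterministic", {
  p <- synthSectionParams(canvas_um = 600, um_per_px = 1, radius_um = 200,
                          ring_width_um = 50)
  a <- genSection(p, seed = 5)
  b <- genSection(p, seed = 5)
  cc <- genSection(p, seed = 6)
  expect_identical(values(a$section), values(b$section))
  expect_identical(values(a$truth), values(b$truth))
  expect_false(identical(values(a$section), values(cc$section)))
})

test_that("a blue-only interior yields 100% ground-truth patches", {
  p <- synthSectionParams(canvas_um = 600, um_per_px = 1, radius_um = 250,
                          ring_width_um = 40, brown_in_base = 0,
                          brown_out_density = 0)
  g <- genSection(p, seed = 2)
  ## central patch lies fully inside the lesion: blue cells only
  tv <- values(g$truth)
  ctr <- tv[2, 2]
  expect_equal(ctr, 100)
})

test_that("interior ground truth falls as irradiation time shortens", {
  mk <- function(t_min) {
    p <- synthSectionParams(canvas_um = 600, um_per_px = 1,
                            radius_um = 250, ring_width_um = 40,
                            irradiation_min = t_min, brown_in_base = 600)
    g <- genSection(p, seed = 4)
    values(g$truth)[2, 2]
  }
  ## inside-brown density is inversely proportional to irradiation time,
  ## so short exposures score lower interior necrosis
  expect_gt(mk(20), mk(1))
})

test_that("unrealistic cell coverage is rejected", {
  p <- synthSectionParams(canvas_um = 300, um_per_px = 1, radius_um = 80,
                          density_out = 60000, density_in = 500,
                          cell_radius_um = c(4, 5))
  expect_error(genSection(p, seed = 1), "unrealistic")
})

test_that("rendered sections classify back to their generating classes", {
  ## cell counts are not preserved (touching same-class cells can merge),
  ## but class AREAS are what the necrosis model consumes
  g <- smallSection()
  seg <- classifyCells(segmentCells(g$section))
  ct <- cellTable(seg)
  area <- function(df, cls, col = "area_um2")
    sum(df[[col]][df$class == cls])
  truth <- g$cells
  truth$area_um2 <- pi * truth$r_um^2
  expect_equal(area(ct, "blue"), area(truth, "blue"), tolerance = 0.15)
  expect_equal(area(ct, "brown"), area(truth, "brown"), tolerance = 0.15)
  expect_lt(area(ct, "unclassified") / sum(ct$area_um2), 0.1)
})

test_that("stack lesions grow with depth like the generating cone", {
  p <- synthSectionParams(canvas_um = 2400, um_per_px = 2,
                          radius_um = 1000, ring_width_um = 60,
                          brown_in_base = 0, brown_out_density = 2000,
                          density_out = 1500, density_in = 500)
  stk <- genStack(p, n_sections = 5, spacing_um = 40, radius_growth = 1,
                  jitter_rot_sd = 0, jitter_trans_sd = 0,
                  parenchyma_amp = 0, seed = 8)
  ## zero jitter: recorded transforms are (numerically) the identity
  expect_true(all(vapply(stk$jitters, function(t)
    abs(t@rotation) < 1e-9 && all(abs(t@translation) < 1e-9), logical(1))))
  ## interior (brown-free, blue-only) patch area per level, mm^2
  areas <- vapply(stk$truth_maps, function(m)
    sum(values(m) >= 99) * 0.2^2, numeric(1))
  expect_true(all(diff(areas) > 0))
  ## growth ratio tracks the squared radius ratio (patch-eroded radii)
  r0 <- 1000 - 100; r1 <- 1000 + 4 * 40 - 100
  expect_equal(areas[5] / areas[1], (r1 / r0)^2, tolerance = 0.2)
})

test_that("piecewise temperature traces drive the damage model sensibly", {
  ## constant body temperature: negligible damage over 20 min
  flat <- genTemperatureTrace(data.frame(time_min = c(0, 20),
                                         kelvin = c(310.15, 310.15)),
                              step_s = 5)
  ## direct evaluation: rate(310.15 K) x 1200 s ~ 1.4e-2
  a_flat <- damageAlpha(integrateDamage(flat))[length(traceTimes(flat))]
  expect_lt(a_flat, 0.02)
  expect_equal(a_flat, arrheniusRate(310.15) * 1200, tolerance = 0.02)
  ## the three-phase heating curve accumulates tens of percent
  tr <- genTemperatureTrace(step_s = 2)
  a_end <- necroticFraction(integrateDamage(tr))
  a_end <- a_end[length(a_end)]
  expect_gt(100 * a_end, 10)
  ## sampling-step refinement barely moves the integral
  tr_fine <- genTemperatureTrace(step_s = 0.5)
  a_fine <- necroticFraction(integrateDamage(tr_fine))
  expect_lt(abs(a_fine[length(a_fine)] - a_end), 1e-3)
  ## invalid breakpoints
  expect_error(genTemperatureTrace(data.frame(time_min = c(0, 0),
                                              kelvin = c(300, 310))),
               "increasing")
  expect_error(genTemperatureTrace(data.frame(time_min = c(0, 5),
                                              kelvin = c(300, 500))),
               "273-400")
})

test_that("section images round-trip through PNG and TIFF", {
  g <- smallSection()
  px <- values(g$section)[1:64, 1:64, , drop = FALSE]
  sec <- sectionImage(px, um_per_px = 0.5, depth_um = 80)
  for (ext in c(".png", ".tif")) {
    path <- withr::local_tempfile(fileext = ext)
    writeSection(sec, path)
    back <- readSection(path, um_per_px = 0.5, depth_um = 80)
    expect_equal(values(back), px, tolerance = 0.51)  # 8-bit quantization
    expect_equal(umPerPx(back), 0.5)
  }
})
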