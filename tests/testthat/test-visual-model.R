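test_that("pigment_template obeys the normalisation contract", {
  s563 <- pigment_template(563)
  expect_equal(max(s563$sensitivity), 1)
  expect_equal(GRID[which.max(s563$sensitivity)], 563)
  expect_true(all(s563$sensitivity >= 0))

  # unimodal alpha-band dominance for a UV pigment
  s371 <- pigment_template(371)
  expect_gt(s371$sensitivity[GRID == 371], s371$sensitivity[GRID == 500])

  expect_error(pigment_template(250), "\\[300, 700\\]")
})

test_that("pigment_template matches a direct evaluation of the A1 nomogram", {
  # frozen values: alpha + beta template at lambda_max = 503, evaluated by
  # hand at 400, 503 and 600 nm and normalised over the same grid
  s <- pigment_template(503)
  expect_equal(s$sensitivity[GRID == 400], 0.2078808617, tolerance = 1e-9)
  expect_equal(s$sensitivity[GRID == 503], 1.0, tolerance = 1e-12)
  expect_equal(s$sensitivity[GRID == 600], 0.0326379401, tolerance = 1e-9)
})

test_that("quantum_catch is the trapezoidal integral with a positivity floor", {
  ideal <- illuminant("ideal")
  # constant sensitivity 1/400 has unit trapezoidal area over 300..700
  unit_cone <- structure(list(wl = GRID, sensitivity = rep(1 / 400, 401),
                              lambda_max = 500), class = "cone_sensitivity")
  expect_equal(quantum_catch(flat_spectrum(1), unit_cone, ideal), 1,
               tolerance = 1e-12)
  expect_equal(quantum_catch(flat_spectrum(0), unit_cone, ideal), 1e-12)

  # linearity in reflectance
  cone <- pigment_template(503)
  d65 <- illuminant("D65")
  expect_equal(quantum_catch(flat_spectrum(0.5), cone, d65),
               quantum_catch(flat_spectrum(1), cone, d65) / 2,
               tolerance = 1e-12)
})

test_that("catch_vector produces positive, deterministic catches", {
  v <- bluetit_viewer()
  q <- catch_vector(flat_spectrum(0.5), v)
  expect_named(q, c("UV", "SW", "MW", "LW", "DD"))
  expect_true(all(q > 0))
  expect_identical(q, catch_vector(flat_spectrum(0.5), v))

  # a green-peaked spectrum excites MW relative to LW more than a
  # long-wave-rising brown spectrum does
  qg <- catch_vector(make_dowel_spectrum("green"), v)
  qb <- catch_vector(make_dowel_spectrum("brown"), v)
  expect_gt(qg[["MW"]] / qg[["LW"]], qb[["MW"]] / qb[["LW"]])
})

test_that("greenness is the MW opponent ratio", {
  expect_equal(greenness(manual_catch(1, 1, 2, 2)), 0.5)
  expect_equal(greenness(manual_catch(1, 1, 3, 1)), 0.75)
  # monotone in MW with LW fixed
  g <- sapply(c(1, 2, 4, 8), function(m) greenness(manual_catch(1, 1, m, 5)))
  expect_true(all(diff(g) > 0))
  v <- bluetit_viewer()
  expect_gt(greenness(catch_vector(make_dowel_spectrum("green"), v)),
            greenness(catch_vector(make_dowel_spectrum("brown"), v)))
})

test_that("luminance is the DD catch and scales with the spectrum", {
  expect_equal(luminance(manual_catch(1, 1, 1, 1, dd = 0.42)), 0.42)
  v <- bluetit_viewer()
  expect_equal(luminance(catch_vector(flat_spectrum(0.4), v)),
               2 * luminance(catch_vector(flat_spectrum(0.2), v)),
               tolerance = 1e-12)
  expect_gt(luminance(catch_vector(flat_spectrum(0.6), v)),
            luminance(catch_vector(flat_spectrum(0.05), v)))
})

test_that("tetra_coords maps the catch simplex into the tetrahedron", {
  origin <- tetra_coords(manual_catch(1, 1, 1, 1))
  expect_equal(unclass(origin), c(x = 0, y = 0, z = 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  # pure-UV stimulation maps to the UV vertex on +z at the circumradius
  uv_vertex <- tetra_coords(manual_catch(1, 1e-12, 1e-12, 1e-12))
  expect_equal(uv_vertex[["z"]], 0.75, tolerance = 1e-9)
  expect_equal(sqrt(sum(uv_vertex^2)), 0.75, tolerance = 1e-9)

  # every simplex point stays within the circumradius, and midpoints of
  # relative-catch vectors map to midpoints of points (affinity)
  set.seed(5)
  for (i in 1:200) {
    r1 <- as.numeric(stats::rgamma(4, 1)); r1 <- r1 / sum(r1)
    r2 <- as.numeric(stats::rgamma(4, 1)); r2 <- r2 / sum(r2)
    p1 <- tetra_coords(manual_catch(r1[1], r1[2], r1[3], r1[4]))
    p2 <- tetra_coords(manual_catch(r2[1], r2[2], r2[3], r2[4]))
    expect_lte(sqrt(sum(p1^2)), 0.75 + 1e-12)
    rm12 <- (r1 + r2) / 2
    pm <- tetra_coords(manual_catch(rm12[1], rm12[2], rm12[3], rm12[4]))
    expect_equal(unclass(pm), (unclass(p1) + unclass(p2)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("D65 illuminant is quantal, positive and on the shared grid", {
  d65 <- illuminant("D65")
  expect_length(d65$irradiance, 401L)
  expect_true(all(d65$irradiance >= 0))
  expect_equal(max(d65$irradiance), 1)
  # quantal conversion weights long wavelengths: in quanta the 450 nm
  # region no longer dominates the 650 nm region as strongly as in energy
  expect_gt(d65$irradiance[GRID == 650] / d65$irradiance[GRID == 450],
            80.0268 * 650 / (117.008 * 450) - 1e-9)
  flat <- illuminant("ideal")
  expect_equal(flat$irradiance, rep(1, 401))
})

test_that("perceptual_summary returns one tidy row per individual", {
  v <- bluetit_viewer()
  specs <- list(a = flat_spectrum(0.3, "a"), b = make_dowel_spectrum("green"))
  ps <- perceptual_summary(specs, v)
  expect_equal(nrow(ps), 2L)
  expect_named(ps, c("individual_id", "greenness", "luminance",
                     "tetra_x", "tetra_y", "tetra_z"))
  expect_true(all(ps$greenness > 0 & ps$greenness < 1))
  expect_true(all(ps$luminance > 0))
})
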