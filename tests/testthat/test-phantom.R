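test_that("phantom rasterisation matches analytic volumes and keeps labels disjoint", {
  g <- grid_geometry(c(32, 32, 32), c(1, 1, 1))
  # empty spec
  p0 <- make_susceptibility_phantom(phantom_spec(g, list(), brain_radius = 12))
  expect_equal(p0$chi, array(0, c(32, 32, 32)))
  expect_equal(sum(p0$labels), 0)
  # voxel count of a sphere within 5% of (4/3) pi r^3
  sp <- phantom_spec(g, list(phantom_shape("sphere", c(0, 0, 0), 8, 0.1, "a")),
                     brain_radius = 12)
  p1 <- make_susceptibility_phantom(sp)
  expect_equal(sum(p1$labels == 1), 4 / 3 * pi * 8^3, tolerance = 0.05)
  expect_equal(unique(p1$chi[p1$labels == 1]), 0.1)
  # two disjoint spheres -> disjoint labels
  sp2 <- phantom_spec(g, list(
    phantom_shape("sphere", c(-6, 0, 0), 3, 0.1, "a"),
    phantom_shape("sphere", c(6, 0, 0), 3, 0.2, "b")), brain_radius = 12)
  p2 <- make_susceptibility_phantom(sp2)
  expect_equal(sum(p2$labels == 1) + sum(p2$labels == 2),
               sum(p2$labels > 0))
  expect_equal(attr(p2$labels, "region_names"), c("a", "b"))
})

test_that("shapes outside the grid or background sources touching the brain are rejected", {
  g <- grid_geometry(c(16, 16, 16), c(1, 1, 1))
  expect_error(make_susceptibility_phantom(
    phantom_spec(g, list(phantom_shape("sphere", c(6, 0, 0), 4, 0.1, "out")),
                 brain_radius = 6)), "outside grid")
  expect_error(make_susceptibility_phantom(
    phantom_spec(g, list(), brain_radius = 5,
                 background_sources = list(
                   phantom_shape("sphere", c(5, 0, 0), 2, 1, "bg")))),
    "intersects the brain")
})

test_that("analytic sphere field follows the Lorentz-sphere solution", {
  g <- grid_geometry(c(32, 32, 32), c(1, 1, 1))
  a <- 4; chi <- 0.3
  f <- analytic_sphere_field(radius = a, chi = chi, grid = g)
  co <- seq_len(32) - 16.5                    # voxel-centre coordinates
  # every interior point is shifted by exactly 0 ppm
  expect_equal(f$values[16, 16, 16], 0)
  expect_equal(f$values[17, 16, 18], 0)
  # independent evaluation of (chi/3)(a/r)^3 (3 cos^2 theta - 1)
  oracle <- function(i, j, k) {
    d <- c(co[i], co[j], co[k]); r <- sqrt(sum(d^2))
    chi / 3 * (a / r)^3 * (3 * (d[3] / r)^2 - 1)
  }
  for (v in list(c(16, 16, 24), c(24, 16, 16), c(20, 20, 22)))
    expect_equal(f$values[v[1], v[2], v[3]], oracle(v[1], v[2], v[3]),
                 tolerance = 1e-12)
  # canonical values: r = 2a on the axis gives chi/3 * 1/8 * 2 = 0.025 ppm,
  # and -0.0125 ppm on the equator (3cos^2 - 1 = -1); the nearest voxels
  # bracket them with the right signs and decay
  expect_gt(f$values[16, 16, 24], 0)          # near-axial, positive
  expect_lt(f$values[24, 16, 16], 0)          # near-equatorial, negative
  expect_error(analytic_sphere_field(-1, 0.3, g), "radius")
})

test_that("padded forward simulation agrees with the analytic sphere oracle", {
  n <- 64
  g <- grid_geometry(c(n, n, n), c(1, 1, 1))
  sp <- phantom_spec(g, list(phantom_shape("sphere", c(0, 0, 0), 10, 0.3, "s")),
                     brain_radius = 24)
  ph <- make_susceptibility_phantom(sp)
  sim_db <- forward_dipole_field(ph$chi, g)
  ana <- analytic_sphere_field(10, 0.3, g)$values
  co <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(outer(co^2, co^2, `+`), co^2, `+`))
  far <- abs(r - 10) > 2
  expect_lt(sqrt(mean((sim_db[far] - ana[far])^2)) / 0.3, 0.05)
  expect_lt(abs(mean(sim_db[r < 8])), 0.003)
})

test_that("acquisition phase scaling matches gamma * B0 * te and is deterministic", {
  g <- grid_geometry(c(16, 16, 16), c(1, 1, 1))
  spec <- phantom_spec(g, list(), brain_radius = 6)
  acq <- acquisition_params()
  # 0.1 ppm at 3 T, 20 ms -> ~1.60 rad
  phi <- acq$gamma_rad_per_t_s * acq$b0_tesla * 1e-7 * acq$te_s
  expect_equal(phi, 1.60, tolerance = 0.01)
  # chi == 0, no noise -> zero phase
  sim0 <- simulate_acquisition(array(0, c(16, 16, 16)), acq, spec)
  expect_equal(sim0$phase, array(0, c(16, 16, 16)), tolerance = 1e-12)
  # same seed twice -> identical volumes
  specn <- phantom_spec(g, list(), brain_radius = 6, noise_sigma = 0.05,
                        seed = 42)
  s1 <- simulate_acquisition(array(0, c(16, 16, 16)), acq, specn)
  s2 <- simulate_acquisition(array(0, c(16, 16, 16)), acq, specn)
  expect_identical(s1$magnitude, s2$magnitude)
  expect_identical(s1$phase, s2$phase)
  # different seed -> different noise
  specn$seed <- 43L
  s3 <- simulate_acquisition(array(0, c(16, 16, 16)), acq, specn)
  expect_false(identical(s1$phase, s3$phase))
})

test_that("phase noise scales inversely with magnitude (weighting premise)", {
  g <- grid_geometry(c(24, 24, 24), c(1, 1, 1))
  spec <- phantom_spec(g, list(), brain_radius = 10, noise_sigma = 0.02,
                       bias_amplitude = 0, seed = 5)
  acq <- acquisition_params()
  sim <- simulate_acquisition(array(0, c(24, 24, 24)), acq, spec)
  brain <- sim$brain_mask > 0
  # high SNR: sd(phase) ~ noise_sigma / magnitude (~1 in the brain)
  expect_equal(sd(sim$phase[brain]), 0.02, tolerance = 0.15)
})

test_that("background source fields are harmonic inside the brain", {
  s <- small_study(background = TRUE)
  b_ext <- forward_dipole_field(s$ph$chi_background, s$grid)
  lap <- fourier_laplacian(b_ext, s$grid)
  interior <- erode_mask(s$ph$brain_mask, 5) > 0
  # Laplacian inside the brain is tiny relative to the field's own scale
  # (rasterisation of the source adds some high-k content, so compare the
  # typical interior Laplacian against the field amplitude)
  expect_lt(mean(abs(lap[interior])), 0.02 * max(abs(b_ext[interior])))
  expect_lt(max(abs(lap[interior])), 0.2 * max(abs(b_ext[interior])))
})

test_that("cohorts carry group effects in their susceptibility truths", {
  base <- default_phantom_spec(n = 24)
  co <- cohort_spec(n_per_group = 2, seed = 1)
  subs <- make_cohort(co, base, signal = FALSE)
  expect_length(subs, 4)
  expect_equal(vapply(subs, `[[`, "", "group"), c("A", "A", "B", "B"))
  expect_error(
    make_cohort(cohort_spec(2, effect_regions = c(nope = 0.1)), base),
    "unknown effect region")
  # effect + jitter: truth medians separate by ~the effect size
  co2 <- cohort_spec(n_per_group = 8,
                     effect_regions = c(putamen = 0.05),
                     between_subject_sd = 0.005, seed = 3)
  st <- cohort_truth_stats(co2, base)
  put <- st[st$region == "putamen", ]
  gap <- median(put$median_ppm[put$group == "B"]) -
    median(put$median_ppm[put$group == "A"])
  expect_equal(gap, 0.05, tolerance = 0.15)
  # no effect entry -> exchangeable truths for the pallidum
  pal <- st[st$region == "pallidum", ]
  gap2 <- median(pal$median_ppm[pal$group == "B"]) -
    median(pal$median_ppm[pal$group == "A"])
  expect_lt(abs(gap2), 0.01)
})
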