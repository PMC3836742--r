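test_that("zero local field yields the zero map in one iteration", {
  s <- small_study()
  zero <- field_map(array(0, s$grid$dims), s$grid, "local")
  inv <- dipole_inversion(zero, s$w, s$mg, s$kernel,
                          solver_config(norm_p = 2, lam = 1250))
  expect_equal(inv$chi, array(0, s$grid$dims))
  expect_equal(inv$iterations, 1L)
  expect_true(inv$converged)
  expect_error(solver_config(lam = -5), "positive")
  expect_error(solver_config(norm_p = 3), "1 or 2")
})

test_that("analytic cost gradient matches central finite differences", {
  g <- grid_geometry(c(8, 8, 8))
  k <- build_dipole_kernel(g)
  set.seed(9)
  b <- rand_vol(c(8, 8, 8), 10) * 0.01
  w <- abs(rand_vol(c(8, 8, 8), 11))
  m <- (rand_vol(c(8, 8, 8), 12) > 0) * 1
  chi <- rand_vol(c(8, 8, 8), 13) * 0.01
  for (p in c(2, 1)) {
    lam <- 500; eps <- 1e-6
    E <- function(x) {
      gf <- gradient_field(x)
      lam * sum((w * (apply_dipole(k, x) - b))^2) +
        qsmr:::reg_value(gf$x, gf$y, gf$z, m, p, eps)
    }
    grad <- 2 * lam * apply_dipole(k, w^2 * (apply_dipole(k, chi) - b)) +
      qsmr:::reg_gradient(chi, m, p, eps)
    h <- 1e-6
    idx <- cbind(c(1, 3, 5, 8, 2), c(2, 4, 8, 1, 7), c(3, 8, 2, 5, 6))
    for (r in seq_len(nrow(idx))) {
      e <- array(0, c(8, 8, 8)); e[idx[r, , drop = FALSE]] <- h
      num <- (E(chi + e) - E(chi - e)) / (2 * h)
      expect_equal(grad[idx[r, , drop = FALSE]], num,
                   tolerance = 1e-4, label = sprintf("p=%d grad", p))
    }
  }
})

test_that("noiseless inversion recovers compartment susceptibilities with monotone cost", {
  s <- small_study()
  inv <- dipole_inversion(s$b_local_true, s$w, s$mg, s$kernel,
                          solver_config(norm_p = 2, lam = 1250))
  expect_true(inv$converged)
  expect_true(all(diff(inv$cost_history) <= 1e-12))
  chi <- reference_normalize(inv$chi, s$ref)
  st <- extract_region_stats(chi, s$ph$labels)$stats
  # pallidum boundary is edge-protected: tight recovery; putamen has no
  # magnitude contrast so its boundary is regularised (looser)
  expect_equal(st$median_ppm[st$region == "pallidum"], 0.15,
               tolerance = 0.15)
  expect_equal(st$median_ppm[st$region == "putamen"], 0.10,
               tolerance = 0.30)
  # the converged solution is at least as faithful as the zero map
  expect_lte(inv$fidelity_residual,
             fidelity_residual(array(0, s$grid$dims), s$b_local_true,
                               s$w, s$kernel))
})

test_that("heavy regularisation attenuates the solution", {
  s <- small_study()
  i200 <- dipole_inversion(s$b_local_true, s$w, s$mg, s$kernel,
                           solver_config(2, 200))
  i1250 <- dipole_inversion(s$b_local_true, s$w, s$mg, s$kernel,
                            solver_config(2, 1250))
  put <- s$ph$labels == 1
  expect_lt(median(abs(i200$chi[put])), median(abs(i1250$chi[put])))
})

test_that("fidelity_residual evaluates the weighted misfit", {
  s <- small_study()
  expect_equal(fidelity_residual(array(0, s$grid$dims), s$b_local_true,
                                 s$w, s$kernel),
               sum((s$w * s$b_local_true$values)^2))
  # a chi that solves a consistent noiseless system has ~zero residual:
  # use the field generated by a known map on the unpadded grid
  set.seed(3)
  chi0 <- rand_vol(s$grid$dims, 14) * 0.01
  b0 <- field_map(apply_dipole(s$kernel, chi0), s$grid, "local")
  expect_lt(fidelity_residual(chi0, b0, s$w, s$kernel),
            1e-20 * sum(chi0^2))
})

test_that("lambda sweep uses the standard grid and tabulates diagnostics", {
  expect_equal(qsm_lambda_grid(),
               c(200, 300, 500, 750, 1250, 1750, 2250, 2750, 3250, 1e4))
  s <- small_study()
  one <- lambda_sweep(s$b_local_true, s$w, s$mg, s$kernel, lambdas = 750,
                      labels = s$ph$labels, reference_mask = s$ref)
  expect_equal(nrow(one), 1L)
  expect_true(all(c("lambda", "fidelity_residual", "median_putamen") %in%
                  names(one)))
  expect_error(lambda_sweep(s$b_local_true, s$w, s$mg, s$kernel,
                            lambdas = numeric(0)), "non-empty")
})

test_that("median susceptibility is non-decreasing in lambda (attenuation trend)", {
  s <- small_study()   # noiseless
  sw <- lambda_sweep(s$b_local_true, s$w, s$mg, s$kernel,
                     labels = s$ph$labels, reference_mask = s$ref)
  expect_true(all(diff(abs(sw$median_putamen)) >= -1e-9))
})

test_that("L1 matching calibrates lambda and yields lower total variation", {
  s <- small_study(noise_sigma = 0.02)
  l2 <- dipole_inversion(s$b_local, s$w, s$mg, s$kernel,
                         solver_config(2, 1250))
  chi2 <- reference_normalize(l2$chi, s$ref)
  target <- median(chi2[s$ph$labels == 1])
  sw1 <- lambda_sweep(s$b_local, s$w, s$mg, s$kernel,
                      cfg = solver_config(norm_p = 1),
                      labels = s$ph$labels, reference_mask = s$ref,
                      keep_fits = TRUE)
  lam1 <- calibrate_matching_lambda(target, sw1, "putamen")
  i <- which(sw1$lambda == lam1)
  # calibration round-trip: matched region medians within 5%
  expect_equal(sw1$median_putamen[i], target, tolerance = 0.05)
  # matched L1 map is better compartmentalised (lower total variation)
  tv1 <- total_variation(attr(sw1, "fits")[[i]]$chi, s$eroded)
  tv2 <- total_variation(l2$chi, s$eroded)
  expect_lte(tv1, tv2)
  # exact-attainment and out-of-range contracts
  expect_equal(calibrate_matching_lambda(sw1$median_putamen[3], sw1,
                                         "putamen"), sw1$lambda[3])
  expect_error(calibrate_matching_lambda(10, sw1, "putamen"),
               "outside the swept range")
})

test_that("inversion results expose standard model-object methods", {
  s <- small_study()
  inv <- dipole_inversion(s$b_local_true, s$w, s$mg, s$kernel,
                          solver_config(2, 1250))
  expect_s3_class(inv, "qsm_inversion")
  expect_identical(coef(inv), inv$chi)
  ft <- fitted(inv)
  expect_s3_class(ft, "qsm_field_map")
  res <- residuals(inv)
  expect_equal(sum(res^2), inv$fidelity_residual, tolerance = 1e-10)
  expect_output(print(inv), "dipole inversion")
  expect_output(print(summary(inv)), "quartiles")
})
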