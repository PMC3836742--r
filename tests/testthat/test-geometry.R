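test_that("grid geometry validates its invariants", {
  g <- grid_geometry(c(16, 16, 16), c(1, 1, 2))
  expect_equal(sqrt(sum(g$b0_dir^2)), 1, tolerance = 1e-12)
  expect_error(grid_geometry(c(16, 16, 15)), "even")
  expect_error(grid_geometry(c(6, 16, 16)), "even|>= 8")
  expect_error(grid_geometry(c(16, 16, 16), c(1, 0, 1)), "invalid geometry")
  expect_error(grid_geometry(c(16, 16, 16), b0_dir = c(0, 0, 0)), "non-zero")
})

test_that("dipole kernel takes its characteristic values on axis, in plane and at the magic angle", {
  g <- grid_geometry(c(16, 16, 16), c(1, 1, 1))
  k <- build_dipole_kernel(g)
  expect_equal(k$values[1, 1, 2], -2 / 3)   # k parallel to B0
  expect_equal(k$values[2, 1, 1], 1 / 3)    # k orthogonal to B0
  expect_equal(k$values[1, 2, 1], 1 / 3)
  # kx = ky = kz on an isotropic grid: (k.b0)^2 = |k|^2 / 3
  expect_equal(k$values[2, 2, 2], 0, tolerance = 1e-14)
  expect_equal(k$values[1, 1, 1], 0)        # imposed DC value
  expect_true(all(k$values >= -2 / 3 - 1e-12 & k$values <= 1 / 3 + 1e-12))
  # even symmetry under k -> -k
  flip <- k$values[c(1, 16:2), c(1, 16:2), c(1, 16:2)]
  expect_equal(k$values, flip)
})

test_that("kernel trace vanishes and anisotropic voxels reshape the kernel", {
  g <- grid_geometry(c(64, 64, 64), c(1, 1, 1))
  k <- build_dipole_kernel(g)
  expect_lt(abs(mean(k$values[-1])), 0.01)
  ga <- grid_geometry(c(16, 16, 16), c(1, 1, 2))
  ka <- build_dipole_kernel(ga)
  # same integer bin is a different physical frequency along z
  expect_false(isTRUE(all.equal(ka$values[2, 1, 2], k$values[2, 1, 2])))
})

test_that("dipole operator is linear, self-adjoint and annihilates uniform volumes", {
  g <- grid_geometry(c(8, 8, 8))
  k <- build_dipole_kernel(g)
  u <- rand_vol(c(8, 8, 8), 1)
  v <- rand_vol(c(8, 8, 8), 2)
  expect_equal(apply_dipole(k, array(3.2, c(8, 8, 8))),
               array(0, c(8, 8, 8)), tolerance = 1e-12)
  expect_equal(sum(apply_dipole(k, u) * v), sum(u * apply_dipole(k, v)),
               tolerance = 1e-10)
  expect_equal(apply_dipole(k, 2 * u - 3 * v),
               2 * apply_dipole(k, u) - 3 * apply_dipole(k, v),
               tolerance = 1e-10)
  expect_error(apply_dipole(k, array(0, c(8, 8, 10))), "dimensions")
})

test_that("a compact source reproduces the continuous dipole far field", {
  # The voxelwise impulse response of the k-space-sampled kernel is not
  # the continuum point dipole (a known property of discrete dipole
  # kernels), but any compact source's far field is: use a 2-voxel-radius
  # sphere on a padded 64-cube against the continuous formula.
  n <- 64
  g <- grid_geometry(c(n, n, n), c(1, 1, 1))
  sp <- phantom_spec(g, list(phantom_shape("sphere", c(0, 0, 0), 2.2, 1,
                                           "s")), brain_radius = 20)
  ph <- make_susceptibility_phantom(sp)
  vol <- sum(ph$chi)                 # total moment: chi * voxel volume
  fld <- forward_dipole_field(ph$chi, g)
  dip <- function(dx, dy, dz) {
    r <- sqrt(dx^2 + dy^2 + dz^2)
    vol * (3 * (dz / r)^2 - 1) / (4 * pi * r^3)
  }
  c0 <- c(32, 32, 32)                # voxel at coordinate (0.5, 0.5, 0.5)
  co <- seq_len(n) - (n + 1) / 2
  for (r in c(6, 8, 12)) {
    expect_equal(fld[32, 32, 32 + r], dip(co[32], co[32], co[32 + r]),
                 tolerance = 0.1)
    expect_equal(fld[32 + r, 32, 32], dip(co[32 + r], co[32], co[32]),
                 tolerance = 0.1)
  }
  # field along b0 positive, in the transverse plane negative, with the
  # axial/equatorial ratio -> -2 at equal displacement
  expect_gt(fld[32, 32, 40], 0)
  expect_lt(fld[40, 32, 32], 0)
  expect_equal(fld[32, 32, 32 + 8] / fld[32 + 8, 32, 32], -2,
               tolerance = 0.1)
})

test_that("spectral Laplacian matches direct 7-point stencil convolution", {
  g <- grid_geometry(c(16, 16, 16), c(1, 1, 1))
  ii <- 0:15
  mode <- outer(cos(2 * pi * 3 * ii / 16), rep(1, 16)) # cosine mode along x
  v <- array(rep(mode, 16), c(16, 16, 16))
  lap <- fourier_laplacian(v, g)
  # direct stencil with periodic wrap as oracle
  sh <- function(x, ax, by) {
    idx <- ((seq_len(16) - 1 + by) %% 16) + 1
    switch(ax, x[idx, , ], x[, idx, ], x[, , idx])
  }
  oracle <- sh(v, 1, 1) + sh(v, 1, -1) + sh(v, 2, 1) + sh(v, 2, -1) +
    sh(v, 3, 1) + sh(v, 3, -1) - 6 * v
  expect_equal(lap, oracle, tolerance = 1e-12)
  expect_equal(fourier_laplacian(array(5, c(16, 16, 16)), g),
               array(0, c(16, 16, 16)), tolerance = 1e-12)
})

test_that("inverse Laplacian is exact off the DC mode and zero-mean", {
  g <- grid_geometry(c(8, 8, 8))
  v <- rand_vol(c(8, 8, 8), 3)
  out <- inverse_laplacian(fourier_laplacian(v, g), g)
  expect_equal(out, v - mean(v), tolerance = 1e-12)
  expect_equal(mean(inverse_laplacian(v, g)), 0, tolerance = 1e-13)
})

test_that("forward gradient and divergence satisfy the discrete integration-by-parts identity", {
  u <- rand_vol(c(8, 8, 8), 4)
  gf <- gradient_field(u)
  expect_equal(gradient_field(array(2, c(8, 8, 8)))$x,
               array(0, c(8, 8, 8)))
  # linear ramp along x: constant slope, zero elsewhere (interior)
  ramp <- array(rep(seq(0, 7) * 1.5, 8 * 8), c(8, 8, 8))
  gr <- gradient_field(ramp)
  expect_equal(gr$x[1:7, , ], array(1.5, c(7, 8, 8)))
  expect_equal(gr$x[8, , ], matrix(0, 8, 8))  # replicate boundary
  expect_equal(gr$y, array(0, c(8, 8, 8)))
  # adjoint identity <grad u, g> = <u, -div g> on random fields
  gv <- structure(list(x = rand_vol(c(8, 8, 8), 5),
                       y = rand_vol(c(8, 8, 8), 6),
                       z = rand_vol(c(8, 8, 8), 7)),
                  class = "qsm_gradient_field")
  lhs <- sum(gf$x * gv$x + gf$y * gv$y + gf$z * gv$z)
  expect_equal(lhs, sum(u * -divergence(gv)), tolerance = 1e-10)
})
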