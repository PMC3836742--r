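#' Acquisition parameters for a single-echo GRE experiment
#'
#' @param b0_tesla static field strength in tesla (default 3).
#' @param te_s echo time in seconds (default 0.020).
#' @param gamma_rad_per_t_s proton gyromagnetic ratio in rad/s/T
#'   (default 2*pi*42.577478518 MHz/T).
#' @param phase_sign sign convention relating field shift to accrued phase,
#'   +1 or -1; both occur on clinical scanners.
#' @return object of class `qsm_acq`.
#' @export
acquisition_params <- function(b0_tesla = 3, te_s = 0.020,
                               gamma_rad_per_t_s = 2 * pi * 42.577478518e6,
                               phase_sign = 1) {
  if (b0_tesla <= 0 || te_s <= 0 || gamma_rad_per_t_s <= 0)
    stop("field strength, echo time and gyromagnetic ratio must be positive")
  if (!phase_sign %in% c(-1, 1)) stop("'phase_sign' must be +1 or -1")
  structure(list(b0_tesla = b0_tesla, te_s = te_s,
                 gamma_rad_per_t_s = gamma_rad_per_t_s,
                 phase_sign = phase_sign),
            class = "qsm_acq")
}

#' Geometric primitive for phantom construction
#'
#' @param geometry one of "sphere", "cylinder" (axis along z), "ellipsoid".
#' @param centre centre in mm, relative to the grid centre.
#' @param size sphere: radius (mm); ellipsoid: three semi-axes (mm);
#'   cylinder: `c(radius, half_length)` (mm).
#' @param chi susceptibility of the compartment in ppm.
#' @param label region name used in the label volume.
#' @param magnitude relative GRE signal magnitude of the compartment
#'   (default 1; surrounding brain tissue is 1).
#' @export
phantom_shape <- function(geometry = c("sphere", "cylinder", "ellipsoid"),
                          centre, size, chi, label, magnitude = 1) {
  geometry <- match.arg(geometry)
  centre <- as.numeric(centre)
  size <- as.numeric(size)
  stopifnot(length(centre) == 3L, is.finite(chi), magnitude >= 0)
  need <- c(sphere = 1L, cylinder = 2L, ellipsoid = 3L)[[geometry]]
  if (length(size) != need || any(size <= 0))
    stop("invalid 'size' for geometry ", geometry)
  structure(list(geometry = geometry, centre = centre, size = size,
                 chi = chi, label = as.character(label),
                 magnitude = magnitude),
            class = "qsm_shape")
}

#' Synthetic phantom specification
#'
#' Describes a brain-like susceptibility distribution: compartments inside
#' a spherical "brain", optional extra-cerebral background sources, a
#' multiplicative polynomial bias field and complex Gaussian noise. This is
#' the package's stand-in for a 3 T gradient-echo acquisition of deep-nuclei
#' susceptibility anatomy.
#'
#' @param grid a [grid_geometry()].
#' @param shapes list of [phantom_shape()]s inside the brain.
#' @param brain_radius brain-sphere radius in mm.
#' @param background_sources list of [phantom_shape()]s lying wholly
#'   outside the brain sphere (e.g. air/tissue interfaces).
#' @param bias_order,bias_amplitude multiplicative bias field
#'   `1 + amplitude * mean((r/L)^order)` over the three axes (L = half
#'   field of view); amplitude 0 disables it.
#' @param noise_sigma complex noise standard deviation as a fraction of the
#'   mean brain magnitude.
#' @param seed integer RNG seed for the noise draw.
#' @export
phantom_spec <- function(grid, shapes = list(), brain_radius = NULL,
                         background_sources = list(),
                         bias_order = 2, bias_amplitude = 0,
                         noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(grid, "qsm_grid"))
  fov <- grid$dims * grid$voxel_size
  if (is.null(brain_radius)) brain_radius <- 0.35 * min(fov)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  for (s in c(shapes, background_sources))
    if (!inherits(s, "qsm_shape")) stop("shapes must be built with phantom_shape()")
  structure(list(grid = grid, shapes = shapes, brain_radius = brain_radius,
                 background_sources = background_sources,
                 bias_order = bias_order, bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "qsm_phantom_spec")
}

# voxel-centre world coordinates (mm, grid-centred), one 3D array per axis
coord_arrays <- function(grid) {
  d <- grid$dims; h <- grid$voxel_size
  cc <- function(n, dd) (seq_len(n) - (n + 1) / 2) * dd
  list(x = axis_array(cc(d[1], h[1]), d, 1L),
       y = axis_array(cc(d[2], h[2]), d, 2L),
       z = axis_array(cc(d[3], h[3]), d, 3L))
}

shape_mask <- function(shape, co) {
  dx <- co$x - shape$centre[1]
  dy <- co$y - shape$centre[2]
  dz <- co$z - shape$centre[3]
  switch(shape$geometry,
    sphere = dx^2 + dy^2 + dz^2 <= shape$size[1]^2,
    cylinder = (dx^2 + dy^2 <= shape$size[1]^2) & (abs(dz) <= shape$size[2]),
    ellipsoid = (dx / shape$size[1])^2 + (dy / shape$size[2])^2 +
      (dz / shape$size[3])^2 <= 1)
}

shape_extent_ok <- function(shape, grid) {
  half_fov <- grid$dims * grid$voxel_size / 2
  r <- switch(shape$geometry,
              sphere = rep(shape$size[1], 3),
              cylinder = c(shape$size[1], shape$size[1], shape$size[2]),
              ellipsoid = shape$size)
  all(abs(shape$centre) + r <= half_fov + 1e-9)
}

#' Rasterise a phantom specification
#'
#' Voxelises the specified shapes into a susceptibility truth volume; later
#' shapes overwrite earlier ones where they overlap. Background sources are
#' rasterised into a separate volume and must lie wholly outside the brain
#' sphere.
#'
#' @param spec a [phantom_spec()].
#' @return list with `chi` (internal truth, ppm), `chi_background` (ppm),
#'   `chi_total`, `brain_mask` (0/1), `labels` (integer array with a
#'   `region_names` attribute), and `grid`.
#' @export
make_susceptibility_phantom <- function(spec) {
  stopifnot(inherits(spec, "qsm_phantom_spec"))
  grid <- spec$grid
  co <- coord_arrays(grid)
  chi <- array(0, grid$dims)
  labels <- array(0L, grid$dims)
  brain <- (co$x^2 + co$y^2 + co$z^2 <= spec$brain_radius^2) * 1
  nm <- character(0)
  for (i in seq_along(spec$shapes)) {
    s <- spec$shapes[[i]]
    if (!shape_extent_ok(s, grid)) stop("shape '", s$label, "' outside grid")
    m <- shape_mask(s, co)
    chi[m] <- s$chi
    labels[m] <- i
    nm <- c(nm, s$label)
  }
  chi_bg <- array(0, grid$dims)
  for (s in spec$background_sources) {
    if (!shape_extent_ok(s, grid)) stop("background shape '", s$label,
                                        "' outside grid")
    m <- shape_mask(s, co)
    if (any(brain[m] > 0))
      stop("background source '", s$label, "' intersects the brain sphere")
    chi_bg[m] <- s$chi
  }
  attr(labels, "region_names") <- nm
  list(chi = chi, chi_background = chi_bg, chi_total = chi + chi_bg,
       brain_mask = brain, labels = labels, grid = grid)
}

#' Analytic field of a uniformly magnetised sphere
#'
#' Closed-form Lorentz-sphere solution used as a magnetostatic oracle: the
#' field shift is zero inside the sphere and
#' `(chi/3) * (a/r)^3 * (3 cos^2 theta - 1)` ppm outside, with theta
#' measured from the main-field direction.
#'
#' @param radius sphere radius a in mm (> 0).
#' @param chi sphere susceptibility in ppm.
#' @param grid a [grid_geometry()]; the sphere is centred in the grid.
#' @param b0_dir field direction (defaults to the grid's).
#' @return field map (class `qsm_field_map`, ppm of B0).
#' @export
analytic_sphere_field <- function(radius, chi, grid, b0_dir = grid$b0_dir) {
  if (radius <= 0) stop("'radius' must be positive")
  b0_dir <- b0_dir / sqrt(sum(b0_dir^2))
  co <- coord_arrays(grid)
  r2 <- co$x^2 + co$y^2 + co$z^2
  rb <- co$x * b0_dir[1] + co$y * b0_dir[2] + co$z * b0_dir[3]
  out <- array(0, grid$dims)
  ext <- r2 > radius^2
  cos2 <- rb[ext]^2 / r2[ext]
  out[ext] <- (chi / 3) * (radius^2 / r2[ext])^1.5 * (3 * cos2 - 1)
  field_map(out, grid, "total")
}

# zero-pad `vol` to 2x dims (original block in the corner is fine for
# circular convolution; we centre it for symmetry) and return with cropper
pad_double <- function(vol, grid) {
  d <- grid$dims
  big <- array(0, 2L * d)
  off <- d %/% 2L
  big[off[1] + 1:d[1], off[2] + 1:d[2], off[3] + 1:d[3]] <- vol
  big
}

crop_half <- function(big, grid) {
  d <- grid$dims
  off <- d %/% 2L
  big[off[1] + 1:d[1], off[2] + 1:d[2], off[3] + 1:d[3]]
}

#' Forward-simulate the dipole field of a susceptibility volume
#'
#' Convolves on a grid zero-padded to twice the phantom dimensions so that
#' the circular convolution does not wrap the long-range dipole tails back
#' into the field of view, then crops back.
#'
#' @param chi susceptibility volume (ppm).
#' @param grid the phantom grid.
#' @return field perturbation in ppm of B0 (plain array).
#' @export
forward_dipole_field <- function(chi, grid) {
  check_dims(chi, grid)
  big_grid <- grid_geometry(2L * grid$dims, grid$voxel_size, grid$b0_dir)
  kern <- build_dipole_kernel(big_grid)
  crop_half(apply_dipole(kern, pad_double(chi, grid)), grid)
}

#' Simulate a single-echo gradient-echo acquisition of a phantom
#'
#' Computes the dipole field of the total susceptibility distribution
#' (padded forward convolution), converts it to signal phase at the given
#' field strength and echo time, applies the multiplicative bias field to
#' the tissue magnitude (brain 1, exterior 0), adds complex Gaussian noise,
#' and returns magnitude and wrapped phase. Deterministic for a fixed spec
#' seed.
#'
#' @param chi_total total susceptibility volume in ppm (internal plus
#'   background sources).
#' @param acq [acquisition_params()].
#' @param spec the [phantom_spec()] (supplies grid, mask, bias, noise, seed).
#' @return list with `magnitude`, `phase` (wrapped, radians),
#'   `wrapped_phase` (class `qsm_wrapped_phase`), `field_ppm` (noise-free
#'   ground-truth field), `bias`, `brain_mask`.
#' @export
simulate_acquisition <- function(chi_total, acq, spec) {
  stopifnot(inherits(acq, "qsm_acq"), inherits(spec, "qsm_phantom_spec"))
  grid <- spec$grid
  check_dims(chi_total, grid)
  db <- forward_dipole_field(chi_total, grid)
  phi <- acq$phase_sign * acq$gamma_rad_per_t_s * acq$b0_tesla *
    db * 1e-6 * acq$te_s
  co <- coord_arrays(grid)
  brain <- (co$x^2 + co$y^2 + co$z^2 <= spec$brain_radius^2) * 1
  half_fov <- grid$dims * grid$voxel_size / 2
  bias <- 1 + spec$bias_amplitude *
    ((abs(co$x) / half_fov[1])^spec$bias_order +
     (abs(co$y) / half_fov[2])^spec$bias_order +
     (abs(co$z) / half_fov[3])^spec$bias_order) / 3
  # tissue magnitude: brain tissue 1, per-compartment contrast, plus a
  # smooth deterministic texture emulating anatomical signal variation
  tissue <- array(1, grid$dims)
  for (s in spec$shapes) tissue[shape_mask(s, co)] <- s$magnitude
  L <- grid$dims * grid$voxel_size
  texture <- 1 + 0.05 * (sin(6 * pi * co$x / L[1]) +
                         sin(6 * pi * co$y / L[2]) +
                         sin(6 * pi * co$z / L[3])) / 3
  mag0 <- brain * tissue * texture * bias
  sig <- mag0 * exp(1i * phi)
  if (spec$noise_sigma > 0) {
    sd_n <- spec$noise_sigma * mean(mag0[brain > 0])
    set.seed(spec$seed)
    n <- length(sig)
    sig <- sig + complex(real = stats::rnorm(n, 0, sd_n),
                         imaginary = stats::rnorm(n, 0, sd_n))
  }
  phase <- wrap_phase(Arg(sig))
  list(magnitude = array(Mod(sig), grid$dims),
       phase = array(phase, grid$dims),
       wrapped_phase = wrapped_phase_volume(array(phase, grid$dims), acq, grid),
       field_ppm = db, bias = bias, brain_mask = brain)
}

#' Cohort specification for two-group simulations
#'
#' Emulates a small case-control design: group A ("control") subjects carry
#' the base phantom susceptibilities; group B ("patient") subjects get an
#' additive offset in the named effect regions. Every subject additionally
#' receives an independent Normal(0, `between_subject_sd`) susceptibility
#' jitter per region.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param effect_regions named numeric vector: region label -> added chi
#'   (ppm) in group B. May be empty for a null cohort.
#' @param between_subject_sd per-region between-subject SD in ppm.
#' @param seed integer seed governing jitters and per-subject noise seeds.
#' @export
cohort_spec <- function(n_per_group = 8L, effect_regions = numeric(0),
                        between_subject_sd = 0.005, seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop("'n_per_group' must be >= 2")
  structure(list(n_per_group = n_per_group, effect_regions = effect_regions,
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed)),
            class = "qsm_cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' @param cohort a [cohort_spec()].
#' @param base a [phantom_spec()] describing the shared anatomy.
#' @param signal if TRUE (default), simulate magnitude/phase for each
#'   subject; if FALSE return susceptibility truths and masks only (used
#'   for statistics-level simulations).
#' @param acq [acquisition_params()] used when `signal = TRUE`.
#' @return list of subjects, each a list with `id`, `group` ("A"/"B"),
#'   `chi_truth`, `brain_mask`, `labels`, and (with `signal`) `magnitude`,
#'   `phase`, `wrapped_phase`.
#' @export
make_cohort <- function(cohort, base, signal = TRUE,
                        acq = acquisition_params()) {
  stopifnot(inherits(cohort, "qsm_cohort_spec"),
            inherits(base, "qsm_phantom_spec"))
  base_names <- vapply(base$shapes, function(s) s$label, character(1))
  eff <- cohort$effect_regions
  if (length(eff) && !all(names(eff) %in% base_names))
    stop("unknown effect region(s): ",
         paste(setdiff(names(eff), base_names), collapse = ", "))
  n <- cohort$n_per_group
  set.seed(cohort$seed)
  sub_seeds <- sample.int(2^30, 2L * n)
  subjects <- vector("list", 2L * n)
  for (s in seq_len(2L * n)) {
    grp <- if (s <= n) "A" else "B"
    shapes <- base$shapes
    jit <- stats::rnorm(length(shapes), 0, cohort$between_subject_sd)
    for (i in seq_along(shapes)) {
      shapes[[i]]$chi <- shapes[[i]]$chi + jit[i]
      if (grp == "B" && shapes[[i]]$label %in% names(eff))
        shapes[[i]]$chi <- shapes[[i]]$chi + eff[[shapes[[i]]$label]]
    }
    spec_s <- base
    spec_s$shapes <- shapes
    spec_s$seed <- sub_seeds[s]
    ph <- make_susceptibility_phantom(spec_s)
    subj <- list(id = sprintf("%s%02d", tolower(grp), ((s - 1L) %% n) + 1L),
                 group = grp, chi_truth = ph$chi,
                 brain_mask = ph$brain_mask, labels = ph$labels,
                 spec = spec_s)
    if (signal) {
      acq_out <- simulate_acquisition(ph$chi_total, acq, spec_s)
      subj$magnitude <- acq_out$magnitude
      subj$phase <- acq_out$phase
      subj$wrapped_phase <- acq_out$wrapped_phase
    }
    subjects[[s]] <- subj
  }
  subjects
}

#' Default brain-like phantom used in examples and validation
#'
#' A 0.35-FOV brain sphere holding two deep-nuclei-like spheres (putamen
#' and pallidum analogues), a CSF-like reference cylinder at 0 ppm, and one
#' extra-cerebral background source.
#'
#' @param n grid size per axis (even, >= 16).
#' @param noise_sigma complex noise fraction (default 0).
#' @param seed RNG seed.
#' @param background include the extra-cerebral source (default TRUE).
#' @export
default_phantom_spec <- function(n = 64, noise_sigma = 0, seed = 1L,
                                 background = TRUE) {
  grid <- grid_geometry(rep(n, 3), rep(1, 3) * 64 / n)
  fov <- min(grid$dims * grid$voxel_size)  # 64 mm
  R <- 0.42 * fov
  # deep-nuclei analogues are kept small relative to the brain radius: the
  # decaying tail of a source of radius a in a brain of radius b overlaps
  # interior harmonics by ~(a/b)^1.5, which is what exterior dipole fitting
  # can (wrongly) absorb -- as for real deep nuclei, a/b must stay small
  shapes <- list(
    # no magnitude contrast for the putamen analogue: its chi boundary is
    # invisible to the edge mask, as for iron-rich nuclei with weak T2*
    # magnitude contrast, so regularisation attenuates it (the pallidum
    # analogue below is magnitude-dark and edge-protected instead)
    phantom_shape("sphere", centre = c(-0.11, 0, 0) * fov,
                  size = 0.055 * fov, chi = 0.10, label = "putamen",
                  magnitude = 1),
    phantom_shape("sphere", centre = c(0.11, 0, 0) * fov,
                  size = 0.045 * fov, chi = 0.15, label = "pallidum",
                  magnitude = 0.75),
    phantom_shape("cylinder", centre = c(0, 0.14, 0) * fov,
                  size = c(0.05, 0.08) * fov, chi = 0, label = "reference",
                  magnitude = 1.3)
  )
  bg <- if (background)
    list(phantom_shape("sphere", centre = c(0, -0.46, 0) * fov,
                       size = 0.0375 * fov, chi = 2, label = "sinus"))
  else list()
  phantom_spec(grid, shapes, brain_radius = R, background_sources = bg,
               bias_order = 2, bias_amplitude = 0.1,
               noise_sigma = noise_sigma, seed = seed)
}

#' Single-sphere recovery phantom
#'
#' The parameter-recovery benchmark: one deep 0.10 ppm sphere (12 mm
#' diameter) centred in a 0.42-FOV brain, a reference cylinder at 0 ppm,
#' and one extra-cerebral background source. Used to validate end-to-end
#' susceptibility recovery through unwrapping, background removal and
#' inversion.
#'
#' @param n grid size per axis (64 mm field of view).
#' @param noise_sigma complex noise fraction.
#' @param seed RNG seed.
#' @export
sphere_recovery_spec <- function(n = 64, noise_sigma = 0, seed = 1L) {
  grid <- grid_geometry(rep(n, 3), rep(1, 3) * 64 / n)
  fov <- 64
  shapes <- list(
    phantom_shape("sphere", c(0, 0, 0), 6, chi = 0.10, label = "sphere",
                  magnitude = 0.85),
    phantom_shape("cylinder", c(0, 0.14, 0) * fov, c(0.05, 0.08) * fov,
                  chi = 0, label = "reference", magnitude = 1.3))
  bg <- list(phantom_shape("sphere", c(0, -0.46, 0) * fov, 0.0375 * fov,
                           chi = 2, label = "sinus"))
  phantom_spec(grid, shapes, brain_radius = 0.42 * fov,
               background_sources = bg, bias_order = 2,
               bias_amplitude = 0.1, noise_sigma = noise_sigma, seed = seed)
}

#' Reference-region mask of a rasterised phantom
#'
#' @param phantom result of [make_susceptibility_phantom()].
#' @param label region used as susceptibility reference (default
#'   "reference").
#' @export
phantom_reference_mask <- function(phantom, label = "reference") {
  nm <- attr(phantom$labels, "region_names")
  code <- match(label, nm)
  if (is.na(code)) stop("no region named '", label, "' in phantom labels")
  (phantom$labels == code) * 1
}
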