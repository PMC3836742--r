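# shared fixtures, built in code and memoised across test files

.qsm_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .qsm_cache)) assign(key, fn(), envir = .qsm_cache)
  get(key, envir = .qsm_cache)
}

rand_vol <- function(dims, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

# a processed 32^3 study: phantom, simulated acquisition, masks, weights,
# local field (from ground truth, so solver tests are isolated from the
# unwrap/PDF stages)
small_study <- function(noise_sigma = 0, seed = 7, background = FALSE) {
  key <- sprintf("study_%g_%d_%d", noise_sigma, seed, background)
  cached(key, function() {
    spec <- default_phantom_spec(n = 32, noise_sigma = noise_sigma,
                                 seed = seed, background = background)
    ph <- make_susceptibility_phantom(spec)
    acq <- acquisition_params()
    sim <- simulate_acquisition(ph$chi_total, acq, spec)
    g <- spec$grid
    eroded <- erode_mask(ph$brain_mask, 3)
    ref <- phantom_reference_mask(ph)
    magc <- sim$magnitude / sim$bias
    w <- compute_weight_map(magc, eroded, ref)
    mg <- compute_edge_mask(magc, eroded, 0.30)
    kern <- build_dipole_kernel(g)
    b_int <- forward_dipole_field(ph$chi, g)
    uw <- unwrap_laplacian(sim$wrapped_phase)
    b_total <- phase_to_field(uw, acq, g, "total")
    b_local <- field_map(b_total$values * (eroded > 0), g, "local")
    list(spec = spec, ph = ph, acq = acq, sim = sim, grid = g,
         eroded = eroded, ref = ref, magc = magc, w = w, mg = mg,
         kernel = kern, b_int = b_int, b_total = b_total,
         b_local = b_local,
         b_local_true = field_map(b_int * (eroded > 0), g, "local"))
  })
}

total_variation <- function(chi, mask) {
  gf <- gradient_field(chi)
  sum((abs(gf$x) + abs(gf$y) + abs(gf$z))[mask > 0])
}
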