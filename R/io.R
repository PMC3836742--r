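#' Read a 3D NIfTI volume
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param b0_dir main-field direction attached to the returned grid
#'   (world axes; the header does not store it).
#' @return list with `values` (double array) and `grid`
#'   ([grid_geometry()] from the header's pixdim).
#' @export
read_volume <- function(path, b0_dir = c(0, 0, 1)) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D volume, got ", length(d), "D: ", path)
  values <- array(as.double(img), d)
  if (any(!is.finite(values))) stop("non-finite values in ", path)
  vs <- RNifti::pixdim(img)[1:3]
  list(values = values, grid = grid_geometry(d, vs, b0_dir))
}

#' Write a 3D volume as NIfTI-1
#'
#' Values are stored as float32 (computation stays double precision in
#' memory); voxel sizes go to the header's pixdim.
#'
#' @param values real 3D array.
#' @param grid a [grid_geometry()].
#' @param path output path (.nii or .nii.gz).
#' @param description free-text header description (e.g. units).
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, grid, path, description = "") {
  check_dims(values, grid)
  if (any(!is.finite(values))) stop("refusing to write non-finite values")
  RNifti::pixdim(values) <- grid$voxel_size
  img <- RNifti::asNifti(values, datatype = "float")
  if (nzchar(description)) img$descrip <- description
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that volumes share a grid before any computation
#'
#' @param ... `(values, grid)` lists as returned by [read_volume()].
#' @export
assert_same_grid <- function(...) {
  vols <- list(...)
  g0 <- vols[[1]]$grid
  for (v in vols[-1]) {
    if (!identical(v$grid$dims, g0$dims) ||
        max(abs(v$grid$voxel_size - g0$voxel_size)) > 1e-6)
      stop("input volumes are on mismatched grids")
  }
  invisible(TRUE)
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f)
  unname(tools::md5sum(f))
}

#' Pipeline configuration
#'
#' @param phantom a [phantom_spec()] supplying synthetic inputs; or NULL
#'   with `inputs` naming NIfTI files.
#' @param inputs named list of paths (`magnitude`, `phase`, `brain_mask`,
#'   `labels`, `reference_mask`) used when `phantom` is NULL.
#' @param acq [acquisition_params()].
#' @param lambdas lambda values to reconstruct (default 1250 only).
#' @param norms subset of c(2, 1).
#' @param pdf_cfg a [pdf_config()].
#' @param solver base [solver_config()] (its `lam` is overridden per run).
#' @param erode_width brain-mask erosion width in voxels (default 6).
#' @param edge_fraction edge-mask fraction (default 0.30).
#' @param reference_label phantom region used as reference region.
#' @param run_pdf toggle for the background-removal stage (ablation).
#' @param correct_bias divide the simulated bias field out of the
#'   magnitude before weighting (ground truth is known for phantoms).
#' @param out_dir optional output directory for NIfTI/CSV/manifest files.
#' @param seed integer seed recorded in the manifest.
#' @export
pipeline_config <- function(phantom = NULL, inputs = NULL,
                            acq = acquisition_params(),
                            lambdas = 1250, norms = 2,
                            pdf_cfg = pdf_config(),
                            solver = solver_config(),
                            erode_width = 6L, edge_fraction = 0.30,
                            reference_label = "reference",
                            run_pdf = TRUE, correct_bias = TRUE,
                            out_dir = NULL, seed = 1L) {
  if (is.null(phantom)) {
    need <- c("magnitude", "phase", "brain_mask", "labels", "reference_mask")
    if (is.null(inputs) || !all(need %in% names(inputs)))
      stop("without a phantom, 'inputs' must name ",
           paste(need, collapse = ", "))
    missing <- !vapply(inputs[need], file.exists, logical(1))
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(inputs[need][missing]), collapse = ", "))
  }
  if (length(lambdas) < 1L) stop("lambda grid must be non-empty")
  structure(list(phantom = phantom, inputs = inputs, acq = acq,
                 lambdas = lambdas, norms = norms, pdf_cfg = pdf_cfg,
                 solver = solver, erode_width = as.integer(erode_width),
                 edge_fraction = edge_fraction,
                 reference_label = reference_label, run_pdf = run_pdf,
                 correct_bias = correct_bias, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "qsm_pipeline_config")
}

#' Run the full QSM processing chain
#'
#' Executes unwrap -> phase-to-field -> mask erosion / weighting / edge
#' mask -> PDF background removal -> background subtraction -> regularised
#' inversion (per lambda, per norm) -> reference normalisation -> regional
#' statistics, recording per-stage parameters, iteration counts and
#' residuals in a run manifest. Deterministic given the config seed. Any
#' stage failure aborts with the stage name.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `manifest` (config snapshot, input hashes, per-stage
#'   records, package version), `chi` (named list of normalised maps,
#'   "L<norm>_lambda<value>"), `stats` (region medians per map),
#'   `local_field`, `masks` (brain/eroded/reference/edge), `grid`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "qsm_pipeline_config"))
  stages <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }

  # -- inputs ---------------------------------------------------------
  if (!is.null(cfg$phantom)) {
    ph <- stage("phantom", make_susceptibility_phantom(cfg$phantom))
    sim <- stage("phantom", simulate_acquisition(ph$chi_total, cfg$acq,
                                                 cfg$phantom))
    grid <- cfg$phantom$grid
    magnitude <- sim$magnitude
    if (cfg$correct_bias) magnitude <- magnitude / sim$bias
    phase <- sim$phase
    brain_mask <- ph$brain_mask
    labels <- ph$labels
    reference_mask <- phantom_reference_mask(ph, cfg$reference_label)
    truth <- ph$chi
  } else {
    vols <- stage("read", lapply(cfg$inputs[c("magnitude", "phase",
                                              "brain_mask", "labels",
                                              "reference_mask")],
                                 read_volume))
    stage("read", do.call(assert_same_grid, vols))
    grid <- vols$magnitude$grid
    magnitude <- vols$magnitude$values
    phase <- vols$phase$values
    brain_mask <- (vols$brain_mask$values > 0) * 1
    labels <- vols$labels$values
    storage.mode(labels) <- "integer"
    attr(labels, "region_names") <-
      as.character(sort(unique(labels[labels > 0])))
    reference_mask <- (vols$reference_mask$values > 0) * 1
    truth <- NULL
  }
  input_hash <- md5_of(list(magnitude, phase, brain_mask, labels,
                            reference_mask))

  # -- phase processing -----------------------------------------------
  wp <- wrapped_phase_volume(wrap_phase(phase), cfg$acq, grid)
  unwrapped <- stage("unwrap", unwrap_laplacian(wp))
  b_total <- stage("phase_to_field",
                   phase_to_field(unwrapped, cfg$acq, grid, "total"))
  stages$unwrap <- list(zero_mean = mean(unwrapped))

  # -- masks and weights ----------------------------------------------
  eroded <- stage("masks", erode_mask(brain_mask, cfg$erode_width))
  w <- stage("masks", compute_weight_map(magnitude, eroded, reference_mask))
  mg <- stage("masks", compute_edge_mask(magnitude, eroded,
                                         cfg$edge_fraction))
  stages$masks <- list(erode_width = cfg$erode_width,
                       edge_fraction = attr(mg, "achieved_fraction"),
                       n_brain = sum(eroded))

  # -- background removal ---------------------------------------------
  kernel <- build_dipole_kernel(grid)
  if (cfg$run_pdf) {
    fit <- stage("pdf", pdf_fit(b_total, brain_mask, w, kernel, cfg$pdf_cfg))
    b_local <- stage("pdf", subtract_background(b_total, fit$b_bg, eroded))
    stages$pdf <- list(iterations = fit$iterations,
                       cg_relative_residual = fit$cg_relative_residual,
                       converged = fit$converged)
  } else {
    b_local <- field_map(b_total$values * (eroded > 0), grid, "local")
    stages$pdf <- list(skipped = TRUE)
  }

  # -- inversion, normalisation, statistics ---------------------------
  chi_maps <- list()
  stats_rows <- list()
  for (p in cfg$norms) for (lam in cfg$lambdas) {
    cfg_i <- cfg$solver
    cfg_i$norm_p <- p
    cfg_i$lam <- lam
    key <- sprintf("L%d_lambda%g", p, lam)
    inv <- stage("invert", dipole_inversion(b_local, w, mg, kernel, cfg_i,
                                            brain_mask = eroded))
    chi <- stage("normalize", reference_normalize(inv$chi, reference_mask))
    chi_maps[[key]] <- chi
    st <- stage("stats", extract_region_stats(chi, labels,
                                              subject = key)$stats)
    st$lambda <- lam
    st$norm_p <- p
    stats_rows[[key]] <- st
    stages[[paste0("invert_", key)]] <-
      list(lambda = lam, norm = p, iterations = inv$iterations,
           converged = inv$converged,
           fidelity_residual = inv$fidelity_residual)
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL

  manifest <- list(package_version = as.character(utils::packageVersion("qsmr")),
                   seed = cfg$seed, input_hash = input_hash,
                   config = cfg[setdiff(names(cfg), c("phantom"))],
                   phantom_hash = if (!is.null(cfg$phantom)) md5_of(cfg$phantom),
                   stages = stages,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(chi_maps))
      write_volume(chi_maps[[key]], grid,
                   file.path(cfg$out_dir, paste0("chi_", key, ".nii")),
                   description = "chi [ppm]")
    write_volume(b_local$values, grid,
                 file.path(cfg$out_dir, "local_field.nii"),
                 description = "local field [ppm]")
    utils::write.csv(stats, file.path(cfg$out_dir, "region_stats.csv"),
                     row.names = FALSE)
    # written atomically: serialise to a temp file, then rename
    tmp <- file.path(cfg$out_dir, ".manifest.json.tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    file.rename(tmp, file.path(cfg$out_dir, "manifest.json"))
  }

  list(manifest = manifest, chi = chi_maps, stats = stats,
       local_field = b_local, truth = truth,
       masks = list(brain = brain_mask, eroded = eroded,
                    reference = reference_mask, edge = mg),
       grid = grid)
}
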