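#' Experiment configuration
#'
#' Bundles everything one scripted experiment needs: the phantom (either a
#' ready [image_grid()] or lung-phantom parameters), the acquisition
#' geometry, the noise model, and the reconstruction configurations to
#' compare. All randomness is pinned by explicit seeds, so a configuration
#' fully determines its outputs.
#'
#' @param phantom an [image_grid()], or a list
#'   `list(kind = "lung", grid_size =, seed =)` rendered at run time.
#' @param angles view angles in degrees.
#' @param recon_configs named list of [recon_config()]s to run; names label
#'   the report rows.
#' @param noise a [noise_config()] or `NULL` for a noiseless acquisition.
#' @param beam_model system-matrix beam model.
#' @param metrics character vector of metric names to report.
#' @param snapshot_sweeps sweeps at which iterative methods store images.
#' @param output_dir directory for images/CSV/manifest, or `NULL` to skip
#'   writing.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(phantom, angles, recon_configs, noise = NULL,
                              beam_model = "strip",
                              metrics = c("mse", "emse", "psnr", "ssim"),
                              snapshot_sweeps = integer(0),
                              output_dir = NULL) {
  if (length(recon_configs) == 0) stop("need at least one recon_config")
  if (is.null(names(recon_configs)) || any(names(recon_configs) == ""))
    stop("recon_configs must be a named list")
  structure(list(phantom = phantom, angles = as.numeric(angles),
                 recon_configs = recon_configs, noise = noise,
                 beam_model = beam_model, metrics = metrics,
                 snapshot_sweeps = as.integer(snapshot_sweeps),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Study protocol: limited-angle low-dose lung acquisition
#'
#' The default protocol for the comparison and convergence experiments: a
#' lung phantom, strip-model acquisition over a 90-degree angular range,
#' and Poisson low-dose noise. Two readings of a "90-degree projection
#' angle" acquisition are provided: `"limited"` (the primary one) uses
#' views 0..89 degrees at 1-degree steps, a true limited-angle problem;
#' `"sparse"` uses 90 views spread over [0, 180), a sparse-view problem.
#'
#' @param grid_size phantom side in pixels.
#' @param phantom_seed,noise_seed the two RNG seeds.
#' @param angle_mode `"limited"` or `"sparse"`.
#' @param incident_count photon count per bin at zero attenuation.
#' @param art_sweeps ART sweep budget.
#' @param relaxation ART relaxation factor.
#' @param output_dir passed through to [experiment_config()].
#' @return an [experiment_config()] comparing ART against FBP.
#' @export
bo_protocol <- function(grid_size = 64, phantom_seed = 7L, noise_seed = 11L,
                        angle_mode = c("limited", "sparse"),
                        incident_count = 1e5, art_sweeps = 30L,
                        relaxation = 1.0, output_dir = NULL) {
  angle_mode <- match.arg(angle_mode)
  angles <- if (angle_mode == "limited") seq(0, 89) else seq(0, 178, by = 2)
  experiment_config(
    phantom = list(kind = "lung", grid_size = grid_size, seed = phantom_seed),
    angles = angles,
    recon_configs = list(
      ART = recon_config("ART", relaxation = relaxation,
                         max_sweeps = art_sweeps, stop_tol = 0),
      FBP = recon_config("FBP")),
    noise = noise_config(incident_count = incident_count, seed = noise_seed),
    snapshot_sweeps = seq_len(art_sweeps),
    output_dir = output_dir)
}

resolve_phantom <- function(phantom) {
  if (is_image_grid(phantom)) return(phantom)
  if (is.list(phantom) && identical(phantom$kind, "lung"))
    return(make_lung_phantom(phantom$grid_size, phantom$seed))
  stop("phantom must be an image_grid or list(kind = 'lung', grid_size, seed)")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

reconstruct_one <- function(sino, sm, rc, original) {
  switch(rc$algorithm,
    ART = art_reconstruct(sino, sm, rc),
    SIRT = sirt_reconstruct(sino, sm, rc),
    RLS = rls_reconstruct(sino, sm, rc),
    FBP = {
      img <- fbp_reconstruct(sino, original, filter = rc$fbp_filter)
      new_recon_result(img, numeric(0), list(), rc, TRUE, NA_real_)
    })
}

experiment_manifest <- function(config, phantom) {
  list(
    toolkit = "arttomo",
    version = as.character(utils::packageVersion("arttomo")),
    grid_size = grid_size(phantom),
    pixel_size = pixel_size(phantom),
    phantom = if (is.list(config$phantom) && !is_image_grid(config$phantom))
      config$phantom else list(kind = "provided image"),
    angles = config$angles,
    beam_model = config$beam_model,
    noise = if (is.null(config$noise)) "none" else unclass(config$noise),
    recon = lapply(config$recon_configs, function(rc)
      unclass(rc)[c("algorithm", "relaxation", "max_sweeps", "stop_tol",
                    "incompatible_mode", "fbp_filter", "ray_order", "seed")]))
}

#' Run a reconstruction comparison experiment
#'
#' The full pipeline: render the phantom, build the system matrix, forward
#' project, inject noise (if configured), reconstruct with every configured
#' algorithm, and score each result against the original. With an
#' `output_dir` it also writes the images (PNG + lossless text dump), a
#' long-format metrics CSV (one row per algorithm-metric pair) and a YAML
#' manifest of every parameter and seed, from which the run can be
#' regenerated exactly.
#'
#' @param config an [experiment_config()].
#' @return list with `phantom`, `sinogram` (clean), `noisy_sinogram`
#'   (or `NULL`), `results` (named list of `recon_result`s), `reports`
#'   (named list of [metrics_report()]s) and `metrics` (long-format data
#'   frame: algorithm, metric, value).
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  phantom <- run_stage("phantom", resolve_phantom(config$phantom))
  geom <- default_geometry(phantom, angles = config$angles,
                           beam_model = config$beam_model)
  sm <- run_stage("system_matrix", build_system_matrix(phantom, geom))
  clean <- run_stage("forward_project", forward_project(phantom, sm))
  sino <- if (is.null(config$noise)) clean else
    run_stage("noise", add_poisson_noise(clean, config$noise,
                                         pixel_size = pixel_size(phantom)))
  results <- list(); reports <- list()
  for (nm in names(config$recon_configs)) {
    rc <- config$recon_configs[[nm]]
    if (length(config$snapshot_sweeps) && rc$algorithm %in% c("ART", "SIRT"))
      rc$snapshot_sweeps <- config$snapshot_sweeps
    results[[nm]] <- run_stage(paste0("recon:", nm),
                               reconstruct_one(sino, sm, rc, phantom))
    reports[[nm]] <- run_stage(paste0("metrics:", nm),
                               metrics_report(phantom, results[[nm]]$image))
  }
  long <- do.call(rbind, lapply(names(reports), function(nm) {
    rep_ <- reports[[nm]]
    data.frame(algorithm = nm, metric = config$metrics,
               value = vapply(config$metrics, function(m) rep_[[m]], numeric(1)),
               row.names = NULL)
  }))
  out <- list(phantom = phantom, sinogram = clean,
              noisy_sinogram = if (is.null(config$noise)) NULL else sino,
              results = results, reports = reports, metrics = long)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    write_image(phantom, file.path(od, "phantom.png"))
    write_image(phantom, file.path(od, "phantom.txt"))
    for (nm in names(results)) {
      write_image(results[[nm]]$image, file.path(od, paste0("recon_", nm, ".png")))
      write_image(results[[nm]]$image, file.path(od, paste0("recon_", nm, ".txt")))
    }
    utils::write.csv(long, file.path(od, "metrics.csv"), row.names = FALSE)
    yaml::write_yaml(experiment_manifest(config, phantom),
                     file.path(od, "manifest.yaml"))
    man <- phantom_manifest(phantom)
    if (!is.null(man)) utils::write.csv(man, file.path(od, "phantom_manifest.csv"),
                                        row.names = FALSE)
  }
  out
}

#' Trace per-sweep reconstruction quality (semi-convergence study)
#'
#' Runs the iterative reconstruction with snapshots at every sweep, on both
#' the noisy and the noiseless version of the same acquisition, and scores
#' each snapshot against the original. With noisy limited-angle data the
#' MSE curve typically falls, bottoms out at some sweep k*, then rises
#' again as iterations start fitting the noise (semi-convergence); the
#' noiseless control keeps decreasing.
#'
#' @param config an [experiment_config()] whose first ART/SIRT entry is
#'   traced.
#' @return data frame with columns `variant` ("noisy"/"noiseless"),
#'   `sweep`, `mse`, `ssim`; written as `convergence.csv` when the config
#'   has an `output_dir`.
#' @export
run_convergence_study <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  iter_names <- names(config$recon_configs)[vapply(config$recon_configs,
    function(rc) rc$algorithm %in% c("ART", "SIRT"), logical(1))]
  if (length(iter_names) == 0)
    stop("config must contain an ART or SIRT recon_config")
  rc <- config$recon_configs[[iter_names[1]]]
  rc$snapshot_sweeps <- seq_len(rc$max_sweeps)
  rc$stop_tol <- 0  # run the full sweep budget so the curve is complete

  phantom <- resolve_phantom(config$phantom)
  geom <- default_geometry(phantom, angles = config$angles,
                           beam_model = config$beam_model)
  sm <- build_system_matrix(phantom, geom)
  clean <- forward_project(phantom, sm)
  variants <- list(noiseless = clean)
  if (!is.null(config$noise))
    variants$noisy <- add_poisson_noise(clean, config$noise,
                                        pixel_size = pixel_size(phantom))
  curves <- lapply(names(variants), function(vn) {
    res <- if (rc$algorithm == "ART") art_reconstruct(variants[[vn]], sm, rc)
           else sirt_reconstruct(variants[[vn]], sm, rc)
    sweeps <- as.integer(names(res$iterate_snapshots))
    data.frame(variant = vn, sweep = sweeps,
               mse = vapply(res$iterate_snapshots, function(im) mse(phantom, im),
                            numeric(1)),
               ssim = vapply(res$iterate_snapshots, function(im) ssim(phantom, im),
                             numeric(1)),
               row.names = NULL)
  })
  out <- do.call(rbind, curves)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$output_dir, "convergence.csv"),
                     row.names = FALSE)
  }
  out
}
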