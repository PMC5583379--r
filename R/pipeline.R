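# Configuration, full-chain runner, and overlay rendering.

#' Default pipeline configuration
#'
#' Nested configuration consumed by [run_pipeline()]; the defaults encode the
#' emulated acquisition and treatment: 64 x 64 pixels over 30 mm, 0.5 mm
#' needles 1.2-3.3 mm apart at 700 V, 8 x 100 us pulses at 5 kHz, and up to
#' 20% tumor conductivity heterogeneity.
#'
#' @param seed Master seed.
#' @return Nested list with sections `grid`, `electrodes`, `protocol`,
#'   `phantom`, `solver`, `noise`, `analysis`, plus `seed`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    grid = list(n = 64L, fov_mm = 30),
    electrodes = list(diameter_mm = 0.5, voltage = 700,
                      gaps_mm = seq(1.2, 3.3, length.out = 9)),
    protocol = list(n_pulses = 8L, t_p_us = 100, rep_freq_hz = 5000),
    phantom = list(sigma_background = 0.2, sigma_tumor = 0.4,
                   tumor_radius_mm = seq(1.9, 2.6, length.out = 9),
                   heterogeneity_cv = 0, correlation_len_mm = 1.5),
    solver = list(tol = 1e-8, recon_tol = 1e-4, recon_max_iter = 50L),
    noise = list(snr = Inf),
    analysis = list(p_grid = c(0.1, 0.2, 0.3), true_level = 0.2,
                    area_noise_sd = 0.1, n_replicates = 100L),
    seed = as.integer(seed)
  )
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration and overlays it on [default_pipeline_config()];
#' every supplied key must exist in the default schema and basic physical
#' constraints are checked before any compute starts.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param seed Optional seed override.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL, seed = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_pipeline_config: no such file: ", path)
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (!sec %in% names(cfg))
        stop("read_pipeline_config: unknown config section '", sec, "'")
      if (is.list(cfg[[sec]])) {
        for (key in names(user[[sec]])) {
          if (!key %in% names(cfg[[sec]]))
            stop(sprintf("read_pipeline_config: unknown key '%s.%s'", sec, key))
          cfg[[sec]][[key]] <- user[[sec]][[key]]
        }
      } else cfg[[sec]] <- user[[sec]]
    }
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  with(cfg, {
    if (grid$n < 3L || grid$fov_mm <= 0) stop("config: invalid grid section")
    if (any(electrodes$gaps_mm < electrodes$diameter_mm))
      stop("config: electrode gap smaller than electrode diameter")
    if (phantom$sigma_background <= 0 || phantom$sigma_tumor <= 0)
      stop("config: conductivities must be positive")
    if (phantom$heterogeneity_cv < 0 || phantom$heterogeneity_cv >= 1)
      stop("config: heterogeneity_cv must be in [0, 1)")
    if (any(analysis$p_grid <= 0) || any(analysis$p_grid >= 1))
      stop("config: p_grid levels must be in (0, 1)")
    if (!analysis$true_level %in% analysis$p_grid)
      stop("config: true_level must be among p_grid")
    if (noise$snr <= 0) stop("config: snr must be positive (or .inf)")
  })
  invisible(cfg)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full prediction-and-validation pipeline
#'
#' Executes phantom generation, the forward measurement simulation, the CDI
#' inversion, the J-substitution reconstruction, Peleg-Fermi damage mapping,
#' and the agreement analysis for every case in the configuration, then
#' writes the result bundle to `outdir`: reconstructed maps (NIfTI), the
#' paired-area table (CSV), agreement statistics (JSON), per-case convergence
#' logs (JSON) and a run manifest carrying the seed, the full configuration
#' and its hash. Identical configuration and seed yield identical outputs.
#'
#' @param config Configuration from [read_pipeline_config()] /
#'   [default_pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param write_maps Write per-case NIfTI maps (default `TRUE`).
#' @return The [synthetic_study()] result, invisibly, with an added
#'   `outputs` element listing the files written.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir,
                         write_maps = TRUE) {
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n_cases <- length(config$electrodes$gaps_mm)

  study <- with_stage("study", synthetic_study(
    n_cases = n_cases,
    grid = grid_spec(config$grid$n, fov_mm = config$grid$fov_mm),
    voltage = config$electrodes$voltage,
    gaps_mm = config$electrodes$gaps_mm,
    tumor_radius_mm = config$phantom$tumor_radius_mm,
    sigma_background = config$phantom$sigma_background,
    sigma_tumor = config$phantom$sigma_tumor,
    heterogeneity_cv = config$phantom$heterogeneity_cv,
    correlation_len_mm = config$phantom$correlation_len_mm,
    protocol = pulse_protocol(config$protocol$n_pulses,
                              config$protocol$t_p_us * 1e-6,
                              config$electrodes$voltage,
                              config$protocol$rep_freq_hz),
    p_grid = config$analysis$p_grid,
    true_level = config$analysis$true_level,
    area_noise_sd = config$analysis$area_noise_sd,
    n_replicates = config$analysis$n_replicates,
    snr = config$noise$snr,
    # encoding window holds four pulses of current-on time per shot
    tc_s = 4 * config$protocol$t_p_us * 1e-6,
    recon_tol = config$solver$recon_tol,
    recon_max_iter = config$solver$recon_max_iter,
    solver_tol = config$solver$tol,
    seed = config$seed,
    keep_maps = write_maps))

  outputs <- character(0)
  if (write_maps) {
    with_stage("write-maps", for (i in seq_along(study$maps)) {
      m <- study$maps[[i]]
      base <- file.path(outdir, sprintf("case_%02d", i))
      write_map(m$phantom$sigma_true, paste0(base, "_sigma_true.nii.gz"))
      write_map(m$sigma_recon, paste0(base, "_sigma_recon.nii.gz"))
      write_map(m$e_recon, paste0(base, "_efield_recon.nii.gz"))
      write_map(m$death, paste0(base, "_death_prob.nii.gz"))
      outputs <<- c(outputs, paste0(base, c("_sigma_true.nii.gz",
        "_sigma_recon.nii.gz", "_efield_recon.nii.gz", "_death_prob.nii.gz")))
    })
  }

  areas_csv <- file.path(outdir, "areas.csv")
  with_stage("write-areas", utils::write.csv(
    study$records[, c("case_id", "p", "a_ire_mm2", "a_he_mm2")],
    areas_csv, row.names = FALSE))

  stats_json <- file.path(outdir, "stats.json")
  with_stage("write-stats", jsonlite::write_json(list(
    level_stats = study$level_stats_noise_free,
    best_level = study$best_noise_free,
    selection_rate = study$selection_rate,
    true_level = study$true_level
  ), stats_json, auto_unbox = TRUE, digits = NA))

  conv_json <- file.path(outdir, "convergence.json")
  with_stage("write-convergence", jsonlite::write_json(
    lapply(study$recon_logs, unclass), conv_json, auto_unbox = TRUE, digits = NA))

  config_json <- file.path(outdir, "config.json")
  jsonlite::write_json(config, config_json, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = config$seed,
    config = config,
    config_hash = unname(tools::md5sum(config_json)),
    snr = config$noise$snr,
    n_cases = n_cases,
    package_version = as.character(utils::packageVersion("mreitire"))
  )
  manifest_json <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_json, auto_unbox = TRUE, digits = NA)

  study$outputs <- c(outputs, areas_csv, stats_json, conv_json,
                     config_json, manifest_json)
  invisible(study)
}

#' Render a contour or region overlay on a base map
#'
#' Writes a PNG of the base map in grayscale with either a filled
#' death-probability region (logical overlay) or electric-field contours
#' (numeric overlay with `levels`, drawn in ascending order with a fixed
#' color ramp) on top.
#'
#' @param base_map An [ep_map()] used as the grayscale background.
#' @param overlay Logical matrix (region fill) or numeric [ep_map()]/matrix
#'   (contours).
#' @param path Output PNG path.
#' @param levels Contour levels for a numeric overlay (ascending; default
#'   quartiles of the overlay range).
#' @return `path`, invisibly.
#' @export
render_overlay <- function(base_map, overlay, path, levels = NULL) {
  grid <- map_grid(base_map)
  ov <- if (inherits(overlay, "ep_map")) {
    check_same_grid(grid, map_grid(overlay), "base and overlay maps")
    map_data(overlay)
  } else overlay
  if (!all(dim(ov) == c(grid$n_y, grid$n_x)))
    stop("render_overlay: overlay grid mismatch")
  pc <- pixel_centers(grid)
  # image() draws rows along x, so transpose to put x on the horizontal axis
  base_img <- t(map_data(base_map))
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 4, 2, 6))
  graphics::image(pc$x, pc$y, base_img, col = grDevices::gray.colors(256),
                  asp = 1, xlab = "x (mm)", ylab = "y (mm)")
  if (is.logical(ov)) {
    if (any(ov)) {
      fill <- matrix(NA_real_, grid$n_y, grid$n_x)
      fill[ov] <- 1
      graphics::image(pc$x, pc$y, t(fill),
                      col = grDevices::adjustcolor("red", alpha.f = 0.45),
                      add = TRUE)
    }
    graphics::legend("topright", inset = c(-0.15, 0), xpd = TRUE,
                     fill = grDevices::adjustcolor("red", alpha.f = 0.45),
                     legend = "region", bty = "n")
  } else {
    if (is.null(levels))
      levels <- stats::quantile(ov, c(0.25, 0.5, 0.75), names = FALSE)
    levels <- sort(unique(levels))
    cols <- grDevices::hcl.colors(max(length(levels), 2L), "Viridis")[seq_along(levels)]
    graphics::contour(pc$x, pc$y, t(ov), levels = levels, col = cols,
                      add = TRUE, lwd = 2)
    graphics::legend("topright", inset = c(-0.15, 0), xpd = TRUE, col = cols,
                     lwd = 2, legend = sprintf("%.3g", levels), bty = "n")
  }
  invisible(path)
}
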