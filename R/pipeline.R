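#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with a `geometry` block
#' (see [acquisition_geometry()]), an input block (`input$path` for a TIFF,
#' or `simulate` with [scene_params()] fields), an optional `mask` block
#' (`mode`, `k`, `neighborhood`), per-analysis blocks (`rics`, `tics`,
#' `ticcs`, `pearson`), a `seed` and an `output` directory. Every run writes
#' the resolved configuration and seed next to its results.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$geometry))
    stop("config validation error: missing 'geometry' block")
  req <- c("pixel_size", "focal_waist", "modality")
  miss <- setdiff(req, names(config$geometry))
  if (length(miss))
    stop("config validation error: geometry block missing field(s): ",
         paste(miss, collapse = ", "))
  if (is.null(config$input) && is.null(config$simulate))
    stop("config validation error: need an 'input' or 'simulate' block")
  config$seed <- config$seed %||% 1L
  config$output <- config$output %||% "pentafluct-results"
  class(config) <- c("pipeline_config", "list")
  config
}

config_geometry <- function(config) {
  g <- config$geometry
  acquisition_geometry(g$pixel_size, g$focal_waist, g$modality,
                       pixel_dwell = g$pixel_dwell,
                       line_time = g$line_time,
                       frame_time = g$frame_time,
                       channels = g$channels %||% 1L)
}

#' Run the simulate -> mask -> analyze -> report pipeline
#'
#' Executes the stages a configuration requests in dependency order,
#' persists intermediate artifacts (mask TIFF, correlation CSVs, fit JSONs)
#' in the output directory and writes a manifest linking inputs, outputs and
#' seeds. Stage randomness uses independent per-stage substreams of the run
#' seed, so adding one analysis never perturbs another's draws.
#'
#' @param config A [pipeline_config()] (or list/path coercible to one).
#' @param verbose Print stage progress.
#' @return A results list (invisibly written to `config$output`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  config <- pipeline_config(config)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  geometry <- config_geometry(config)
  results <- list()
  manifest <- list(package_version =
                     as.character(utils::packageVersion("pentafluct")),
                   seed = config$seed,
                   config_hash = sum(utf8ToInt(paste(
                     deparse(unclass(config)), collapse = ""))),
                   stages = list())
  stage <- function(name, fun) {
    say("stage: ", name)
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(done = TRUE)
    out
  }

  series <- stage("input", function() {
    if (!is.null(config$input)) {
      read_image_series(config$input$path, geometry)
    } else {
      s <- config$simulate
      sp <- scene_params(box_size = s$box_size, density = s$density,
                         D = s$D, brightness = s$brightness,
                         background = s$background %||% 0,
                         q = s$q %||% 0, p_m = s$p_m %||% 1)
      dim <- s$dim %||% c(256L, 256L)
      nf <- s$n_frames %||% 50L
      if (geometry$modality == "raster") {
        dur <- nf * (geometry$frame_time %||% (dim[1] * geometry$line_time))
        tr <- simulate_trajectories(sp, dur, geometry$line_time,
                                    config$seed, store = "lazy")
        render_confocal_series(tr, geometry, nf, config$seed, dim = dim)
      } else {
        dur <- nf * geometry$frame_time
        tr <- simulate_trajectories(sp, dur, geometry$frame_time,
                                    config$seed, store = "lazy")
        render_camera_series(tr, geometry, nf, config$seed, dim = dim)
      }
    }
  })

  # the series geometry may carry fields the config left implicit (e.g. the
  # effective frame time of a rendered raster series)
  geometry <- series$geometry
  pre <- if (geometry$modality == "raster") {
    moving_average_correct(series, config$rics$delta_f %||% 1L)
  } else detrend_frames(series)

  mask <- stage("mask", function() {
    mb <- config$mask %||% list()
    m <- cluster_mask(series, mode = mb$mode %||% "static",
                      k = mb$k %||% 3, neighborhood = mb$neighborhood %||% 5L)
    if (!m$static) m <- intersect_masks(m)
    m
  })

  if (!is.null(config$rics) || geometry$modality == "raster") {
    results$rics <- stage("rics", function() {
      acf <- spatial_correlate(pre, mask)
      fit <- fit_rics(acf, geometry)
      br <- tryCatch(brightness(series, mask, fit,
                                config$rics$delta_f %||% 1L),
                     error = function(e) NULL)
      utils::write.csv(acf$G, file.path(config$output, "rics_acf.csv"))
      list(N = fit$N, D = fit$D, epsilon = br$epsilon,
           F_khz = br$F_khz)
    })
  }
  if (geometry$modality == "camera" &&
      (!is.null(config$tics) || is.null(config$pearson))) {
    results$tics <- stage("tics", function() {
      cf <- temporal_correlate(pre, mask = mask)
      fit <- fit_tics(cf, geometry,
                      config$tics$max_lag %||% 12L)
      utils::write.csv(data.frame(lag_s = cf$lag_s, G = cf$G,
                                  ci95 = cf$ci95),
                       file.path(config$output, "tics_acf.csv"),
                       row.names = FALSE)
      out <- list(A_D = fit$A_D, D = fit$D, A_0 = fit$A_0)
      if (length(pre$data) == 2L) {
        cf2 <- temporal_correlate(pre, mask = mask, channel_1 = 2L)
        cfx <- temporal_correlate(pre, mask = mask, channel_1 = 1L,
                                  channel_2 = 2L)
        f2 <- fit_tics(cf2, geometry, config$tics$max_lag %||% 12L)
        fx <- fit_tics(cfx, geometry, config$tics$max_lag %||% 12L)
        out$rel_cc <- relative_cc(fx, fit, f2)$rel_cc
      }
      out
    })
  }
  if (!is.null(config$pearson) && length(pre$data) == 2L) {
    results$pearson <- stage("pearson", function() {
      pm <- pearson_map(series, mask,
                        n_avg_frames = config$pearson$avg_frames %||% 5L,
                        max_shift = config$pearson$max_shift %||% 20L)
      utils::write.csv(pm$rho, file.path(config$output, "pearson_map.csv"))
      list(rho0 = pm$rho0)
    })
  }

  manifest$results <- results
  jsonlite::write_json(manifest, file.path(config$output, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  yaml::write_yaml(unclass(config),
                   file.path(config$output, "resolved_config.yaml"))
  invisible(results)
}
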