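#' Preset synthetic population specifications
#'
#' Two ready-made population mixes for end-to-end runs. `"wt_like"` mimics
#' a population in which most organelles are diffusive or tethered and only
#' a minority undergo directed transport; `"knockdown_like"` mimics a
#' population with a much larger directional fraction moving faster, as seen
#' when retrograde dynein transport is impaired. Component parameters were
#' chosen once so that quantized per-trajectory total distances fall in the
#' 11-24 micron range typical of 5-minute melanosome recordings.
#'
#' @param type `"wt_like"` or `"knockdown_like"`.
#' @param n Population size (default 75 trajectories).
#' @return A population spec usable with [generate_population()].
#' @export
population_presets <- function(type = c("wt_like", "knockdown_like"), n = 75) {
  type <- match.arg(type)
  frac <- function(p) as.integer(round(n * p))
  ns <- 0.01
  if (type == "wt_like") {
    counts <- c(frac(0.6), frac(0.2), n - frac(0.6) - frac(0.2))
    list(
      list(params = sim_params("brownian", D = 1e-4, noise_sigma = ns),
           count = counts[1]),
      list(params = sim_params("tethered", D = 1e-3, k = 1, noise_sigma = ns),
           count = counts[2]),
      list(params = sim_params("directional", V = 0.02, heading = pi / 4,
                               noise_sigma = ns), count = counts[3])
    )
  } else {
    counts <- c(frac(0.53), frac(0.4), n - frac(0.53) - frac(0.4))
    list(
      list(params = sim_params("directional", V = 0.05, heading = pi / 4,
                               noise_sigma = ns), count = counts[1]),
      list(params = sim_params("brownian", D = 5e-4, noise_sigma = ns),
           count = counts[2]),
      list(params = sim_params("tethered", D = 1e-3, k = 1, noise_sigma = ns),
           count = counts[3])
    )
  }
}

sim_params_from_config <- function(cfg) {
  sim_params(
    process = cfg$process,
    D = cfg$D %||% 0, V = cfg$V %||% 0, heading = cfg$heading %||% 0,
    k = cfg$k %||% 0, box_side = cfg$box_side,
    noise_sigma = cfg$noise_sigma %||% 0,
    origin = unlist(cfg$origin %||% c(0, 0))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full trajectory-analysis pipeline
#'
#' Orchestrates reading or simulating trajectory populations, kinematic
#' descriptors, MSD exponent distributions, Brownian-reference frontier
#' calibration and directional classification, optional perinuclear
#' quantification, and pairwise group statistics. The run is a pure
#' function of the configuration and its root seed: identical configs give
#' bit-identical outputs.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognized fields: `seed`; `settings` (`frame_interval`,
#'   `n_frames`, `pixel_size`); `quantize` (pixel-quantize simulated
#'   trajectories before analysis, default TRUE); `nucleus_center`;
#'   `populations` (list, each with `label` and one of `preset`, `tracks`
#'   (file path), or `simulate` (list of component specs with `process`,
#'   parameters and `count`)); `msd` (`max_lag_fraction`, `weighting`);
#'   `classify` (`tau_S`, `tau_L`, `q_low`, `q_high`, `n_reference`, `D`,
#'   `noise_sigma`); `spatial` (`geometry` with radii/offset/band width,
#'   `particles` CSV path with columns x, y, size, `min_size`);
#'   `output_dir`.
#' @param output_dir Overrides `config$output_dir`; when non-NULL, all
#'   tables are written there as delimited text plus a JSON run manifest.
#' @return A list of class `pipeline_report` with per-population
#'   descriptors, alpha distributions, classification counts, frontiers,
#'   comparisons, optional spatial results and the manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1)
  sc <- config$settings %||% list()
  settings <- stage("settings", acq_settings(
    frame_interval = sc$frame_interval %||% 0.5,
    n_frames = sc$n_frames %||% 601,
    pixel_size = sc$pixel_size %||% 0.16))
  quantize <- config$quantize %||% TRUE
  if (is.null(config$populations) || !length(config$populations)) {
    stop("config must name at least one population", call. = FALSE)
  }

  populations <- stage("input", {
    out <- list()
    for (i in seq_along(config$populations)) {
      pc <- config$populations[[i]]
      label <- pc$label %||% sprintf("population%d", i)
      trajs <-
        if (!is.null(pc$tracks)) {
          read_tracks(pc$tracks, settings = settings)
        } else if (!is.null(pc$preset)) {
          generate_population(population_presets(pc$preset, pc$n %||% 75),
                              settings, seed = child_seed(seed, 1000L + i),
                              id_prefix = paste0(label, "-"))
        } else if (!is.null(pc$simulate)) {
          spec <- lapply(pc$simulate, function(comp) {
            list(params = sim_params_from_config(comp),
                 count = comp$count %||% 75)
          })
          generate_population(spec, settings, seed = child_seed(seed, 1000L + i),
                              id_prefix = paste0(label, "-"))
        } else {
          stop(sprintf("population '%s' has no tracks, preset or simulate entry",
                       label), call. = FALSE)
        }
      if (length(trajs) == 0) {
        stop(sprintf("population '%s' is empty", label), call. = FALSE)
      }
      if (quantize) trajs <- lapply(trajs, quantize_to_pixels)
      out[[label]] <- trajs
    }
    out
  })
  labels <- names(populations)
  nucleus_center <- unlist(config$nucleus_center %||% c(0, 0))

  descriptors <- stage("descriptors", lapply(populations, summarize_population,
                                             nucleus_center = nucleus_center))

  mc <- config$msd %||% list()
  alphas <- stage("msd", {
    out <- list()
    for (label in labels) {
      out[[label]] <- alpha_distribution(
        populations[[label]], label = label,
        max_lag_fraction = mc$max_lag_fraction %||% 0.25,
        weighting = mc$weighting %||% "none")
    }
    out
  })

  cc <- config$classify %||% list()
  frontiers <- stage("classify", calibrate_frontiers(
    settings = settings,
    tau_S = cc$tau_S %||% 5, tau_L = cc$tau_L %||% 40,
    q_low = cc$q_low %||% 0.5, q_high = cc$q_high %||% 0.95,
    n_reference = cc$n_reference %||% 2000,
    D = cc$D %||% 0.01, noise_sigma = cc$noise_sigma %||% 0.01,
    quantize = quantize, seed = child_seed(seed, 2L)))
  classification <- stage("classify",
    lapply(populations, count_directional, frontiers = frontiers))

  comparisons <- stage("statistics", {
    rows <- list()
    if (length(labels) >= 2) {
      pairs <- utils::combn(labels, 2, simplify = FALSE)
      for (pr in pairs) {
        da <- descriptors[[pr[1]]]$tracks
        db <- descriptors[[pr[2]]]$tracks
        for (col in c("total_distance", "euclidean_distance", "pause_fraction")) {
          cmpr <- compare_groups(da[[col]], db[[col]], "mann_whitney", labels = pr)
          rows[[length(rows) + 1]] <- data.frame(
            group_a = pr[1], group_b = pr[2], quantity = col,
            mean_a = cmpr$mean[1], mean_b = cmpr$mean[2],
            statistic = cmpr$statistic, p_value = cmpr$p_value,
            test = "mann_whitney", stringsAsFactors = FALSE)
        }
        ca <- compare_alpha(alphas[[pr[1]]], alphas[[pr[2]]])
        rows[[length(rows) + 1]] <- data.frame(
          group_a = pr[1], group_b = pr[2], quantity = "alpha",
          mean_a = ca$mean[1], mean_b = ca$mean[2],
          statistic = ca$statistic, p_value = ca$p_value,
          test = "mann_whitney", stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  spatial_result <- NULL
  if (!is.null(config$spatial)) {
    spatial_result <- stage("spatial", {
      spc <- config$spatial
      gc <- spc$geometry
      geom <- generate_cell_geometry(
        nucleus_radius = gc$nucleus_radius, cell_radius = gc$cell_radius,
        nucleus_offset = gc$nucleus_offset %||% 0,
        band_width = gc$band_width %||% 2)
      particles <- utils::read.csv(spc$particles)
      dens <- perinuclear_density(particles, geom,
                                  min_size = spc$min_size %||% 150)
      c(dens, list(n_particles_total = nrow(particles)))
    })
  }

  manifest <- list(
    package = "melanokin",
    version = as.character(utils::packageVersion("melanokin")),
    seed = seed,
    settings = unclass(settings),
    quantize = quantize,
    populations = lapply(labels, function(l) list(label = l, n = length(populations[[l]]))),
    frontiers = list(c_low = frontiers$c_low, c_high = frontiers$c_high,
                     q_low = frontiers$q_low, q_high = frontiers$q_high,
                     tau_S = frontiers$tau_S, tau_L = frontiers$tau_L,
                     n_reference = frontiers$n_reference, seed = frontiers$seed)
  )

  report <- structure(
    list(populations = populations, descriptors = descriptors, alphas = alphas,
         frontiers = frontiers, classification = classification,
         comparisons = comparisons, spatial = spatial_result,
         manifest = manifest),
    class = "pipeline_report")

  output_dir <- output_dir %||% config$output_dir
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (label in names(report$descriptors)) {
    utils::write.csv(report$descriptors[[label]]$tracks,
                     file.path(output_dir, paste0("descriptors_", label, ".csv")),
                     row.names = FALSE)
    utils::write.csv(report$alphas[[label]]$fits,
                     file.path(output_dir, paste0("msd_fits_", label, ".csv")),
                     row.names = FALSE)
  }
  cls <- do.call(rbind, lapply(names(report$classification), function(l) {
    k <- report$classification[[l]]
    data.frame(population = l, n = k$n, n_D = k$n_D,
               n_intermediate = k$n_intermediate, n_ND = k$n_ND,
               range_low = k$range[1], range_high = k$range[2],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(cls, file.path(output_dir, "classification.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparisons)) {
    utils::write.csv(report$comparisons,
                     file.path(output_dir, "comparisons.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Trajectory-analysis report\n")
  for (label in names(x$descriptors)) {
    agg <- x$descriptors[[label]]$aggregate
    k <- x$classification[[label]]
    cat(sprintf(
      "  %s: n = %d, mean total %.2f um, mean pause %.2f, directional %d-%d\n",
      label, agg$n, agg$mean_total_distance, agg$mean_pause_fraction,
      k$range[1], k$range[2]))
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("  %d pairwise comparisons computed\n", nrow(x$comparisons)))
  }
  invisible(x)
}
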