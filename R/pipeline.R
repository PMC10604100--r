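# Pipeline orchestration: structured configuration, staged execution and a
# run manifest that makes every output traceable and reproducible.

.config_schema <- list(
  seed = NULL,
  geometry = c("diameter", "metal_thickness", "overmill_depth", "taper_angle"),
  fluorophore = NULL,
  optics = c("mode", "tirf_angle", "n_medium", "propagating"),
  fcs = c("concentration", "diffusion_um2_s", "dt_us", "duration_s", "bin_ms",
          "brightness_cpms", "reservoir_depth_nm", "reservoir_side_nm",
          "open_volume"),
  lifetime = c("tau_ns", "amplitudes", "irf_fwhm_ps", "n_photons", "bin_ps",
               "window_ns", "n_components"),
  cells = c("n_rows", "n_cols", "pitch_px", "n_frames", "covered_fraction",
            "high_photons", "spike_photons", "k_sigma", "switch_margin"),
  hmm = c("frame_interval_s"))

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with sections `seed`, `geometry`, `fluorophore`,
#' `optics`, `fcs`, `lifetime`, `cells`, `hmm`. Unknown sections or keys
#' are an error (no silent ignoring); missing sections fall back to
#' defaults at run time. `write_config()` serializes a configuration such
#' that parse -> serialize -> parse is the identity.
#'
#' @param path YAML file path.
#' @return Named list (class `nanowell_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- .config_schema[[sec]]
    if (!is.null(allowed) && is.list(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), allowed)
      if (length(bad))
        stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    }
  }
  structure(cfg, class = c("nanowell_config", "list"))
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.cfg_get <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

.cfg_geometry <- function(cfg) {
  nanowell_geometry(.cfg_get(cfg, "geometry", "diameter", 200),
                    .cfg_get(cfg, "geometry", "metal_thickness", 100),
                    .cfg_get(cfg, "geometry", "overmill_depth", 100),
                    .cfg_get(cfg, "geometry", "taper_angle", 0))
}

.cfg_fluor <- function(cfg) {
  fl <- cfg$fluorophore
  if (is.null(fl)) fl <- "Alexa488"
  if (is.character(fl)) fluorophore_preset(fl) else
    fluorophore(fl$label, fl$quantum_yield, fl$lifetime_ns, fl$lambda_ex, fl$lambda_em)
}

.cfg_sim <- function(cfg, seed) {
  sim_config(seed = seed,
             concentration = .cfg_get(cfg, "fcs", "concentration", 500e-9),
             diffusion_um2_s = .cfg_get(cfg, "fcs", "diffusion_um2_s", 400),
             dt_us = .cfg_get(cfg, "fcs", "dt_us", 0.5),
             duration_s = .cfg_get(cfg, "fcs", "duration_s", 2),
             bin_ms = .cfg_get(cfg, "fcs", "bin_ms", 1),
             brightness_cpms = .cfg_get(cfg, "fcs", "brightness_cpms", 30),
             reservoir_depth_nm = .cfg_get(cfg, "fcs", "reservoir_depth_nm", 400),
             reservoir_side_nm = .cfg_get(cfg, "fcs", "reservoir_side_nm", 800))
}

#' Run a pipeline stage
#'
#' Executes one stage of the analysis pipeline against a configuration and
#' writes its outputs and a run manifest (config snapshot, seed, package
#' version, thresholds applied, MD5 hashes of every output) into
#' `out_dir`. Identical configuration and seed reproduce identical outputs.
#'
#' Subcommands: `simulate-optics` (profiles + signal model),
#' `simulate-fcs` (Brownian photon trace), `fit-fcs` (correlation + model
#' fit + brightness/volume), `simulate-lifetime` (TCSPC decay),
#' `fit-lifetime` (reconvolution fit), `simulate-cells` (movie +
#' ground truth + no-cell control), `analyze-cells` (localization, traces,
#' classification, occupancy), `hmm` (two-state analysis of the
#' single-molecule channel), `report` (heatmap aggregation of fit outputs
#' found in `out_dir`).
#'
#' @param config Path to a YAML configuration or a list from
#'   [read_config()].
#' @param subcommand Stage name (see Details).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the configured seed.
#' @return The manifest, invisibly. Side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config, subcommand, out_dir = ".", seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  subcommands <- c("simulate-optics", "simulate-fcs", "fit-fcs",
                   "simulate-lifetime", "fit-lifetime", "simulate-cells",
                   "analyze-cells", "hmm", "report")
  if (!subcommand %in% subcommands)
    stop("unknown subcommand: ", subcommand)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outputs <- character()
  thresholds <- list()
  geom <- .cfg_geometry(config)
  fluor <- .cfg_fluor(config)
  path <- function(f) file.path(out_dir, f)

  if (subcommand == "simulate-optics") {
    pr <- make_optics_profiles(geom, fluor,
                               mode = .cfg_get(config, "optics", "mode", "widefield"),
                               n_medium = .cfg_get(config, "optics", "n_medium", 1.335),
                               tirf_angle = .cfg_get(config, "optics", "tirf_angle", 70),
                               propagating = .cfg_get(config, "optics", "propagating", "error"))
    model <- signal_model(geom, fluor, pr$excitation, pr$emission)
    outputs <- c(write_profile_csv(pr$excitation, path("excitation.csv")),
                 path("excitation.csv.json"),
                 write_profile_csv(model, path("signal_model.csv")),
                 path("signal_model.csv.json"))
    jsonlite::write_json(list(zeta_bar = average_enhancement(model),
                              tau_avg_ns = signal_averaged_lifetime(model)),
                         path("optics_summary.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, path("optics_summary.json"))
  } else if (subcommand == "simulate-fcs") {
    scfg <- .cfg_sim(config, seed)
    model <- if (.cfg_get(config, "fcs", "open_volume", FALSE)) NULL else {
      pr <- make_optics_profiles(geom, fluor, propagating = "transmit")
      signal_model(geom, fluor, pr$excitation, pr$emission)
    }
    tr <- simulate_photon_trace(geom, scfg, model)
    outputs <- write_trace_csv(tr, path("trace.csv"))
  } else if (subcommand == "fit-fcs") {
    tr <- read_trace_csv(path("trace.csv"))
    curve <- autocorrelate(tr)
    fit <- fit_fcs(curve)
    conc <- .cfg_get(config, "fcs", "concentration", 500e-9)
    bv <- brightness_volume(fit, tr, conc)
    utils::write.csv(data.frame(lag_ms = curve$lag_ms, g = curve$g),
                     path("correlation.csv"), row.names = FALSE)
    jsonlite::write_json(list(N = fit$N, t_D_ms = fit$t_D_ms, p = fit$p,
                              N_se = fit$N_se, t_D_se = fit$t_D_se,
                              epsilon_cpms = bv$epsilon_cpms,
                              v_fcs_l = bv$v_fcs_l,
                              mean_intensity_cpms = mean_intensity(tr),
                              d_nm = geom$diameter, h_nm = geom$overmill_depth),
                         path("fcs_fit.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(path("correlation.csv"), path("fcs_fit.json"))
  } else if (subcommand == "simulate-lifetime") {
    d <- make_tcspc(.cfg_get(config, "lifetime", "tau_ns", fluor$lifetime_ns),
                    .cfg_get(config, "lifetime", "amplitudes", NULL),
                    .cfg_get(config, "lifetime", "irf_fwhm_ps", 200),
                    .cfg_get(config, "lifetime", "n_photons", 1e6),
                    .cfg_get(config, "lifetime", "bin_ps", 25),
                    .cfg_get(config, "lifetime", "window_ns", 50),
                    seed = seed)
    outputs <- write_decay_csv(d, path("decay.csv"))
  } else if (subcommand == "fit-lifetime") {
    d <- read_decay_csv(path("decay.csv"))
    fit <- fit_reconvolution(d, .cfg_get(config, "lifetime", "n_components", 1))
    jsonlite::write_json(list(tau_ns = fit$tau_ns, amplitudes = fit$amplitudes,
                              tau_mean_ns = fit$tau_mean_ns,
                              tau_intensity_ns = fit$tau_intensity_ns,
                              chisq_red = fit$chisq_red),
                         path("lifetime_fit.json"), auto_unbox = TRUE, digits = NA)
    outputs <- path("lifetime_fit.json")
  } else if (subcommand == "simulate-cells") {
    scfg <- .cfg_sim(config, seed)
    layout <- pore_array_layout(.cfg_get(config, "cells", "n_rows", 8),
                                .cfg_get(config, "cells", "n_cols", 8),
                                .cfg_get(config, "cells", "pitch_px", 12))
    mv <- make_cell_movie(layout, scfg,
                          n_frames = .cfg_get(config, "cells", "n_frames", 200),
                          covered_fraction = .cfg_get(config, "cells", "covered_fraction", 0.6),
                          high_photons = .cfg_get(config, "cells", "high_photons", 400),
                          spike_photons = .cfg_get(config, "cells", "spike_photons", 250))
    ctrl_cfg <- scfg; ctrl_cfg$seed <- scfg$seed + 1000L
    ctrl <- make_cell_movie(layout, ctrl_cfg,
                            n_frames = .cfg_get(config, "cells", "n_frames", 200),
                            covered_fraction = 0)
    write_movie_tiff(mv$brightfield, path("brightfield.tif"))
    write_movie_tiff(mv$bfp, path("bfp.tif"))
    write_movie_tiff(mv$halo, path("halo.tif"))
    write_movie_tiff(ctrl$bfp, path("control_bfp.tif"))
    utils::write.csv(layout$pores, path("layout.csv"), row.names = FALSE)
    utils::write.csv(mv$truth, path("truth.csv"), row.names = FALSE)
    utils::write.csv(mv$spikes, path("truth_spikes.csv"), row.names = FALSE)
    outputs <- path(c("brightfield.tif", "bfp.tif", "halo.tif",
                      "control_bfp.tif", "layout.csv", "truth.csv",
                      "truth_spikes.csv"))
  } else if (subcommand == "analyze-cells") {
    layout_df <- utils::read.csv(path("layout.csv"))
    layout <- structure(list(pores = layout_df,
                             markers = data.frame(x_px = numeric(), y_px = numeric()),
                             pixel_nm = .cfg_get(config, "cells", "pixel_nm", 130),
                             dim_px = dim(read_movie_tiff(path("brightfield.tif"))[[1]])),
                        class = "pore_layout")
    bf <- read_movie_tiff(path("brightfield.tif"))[[1]]
    centers <- detect_pores(bf, layout)
    bfp <- read_movie_tiff(path("bfp.tif"))
    ctrl <- read_movie_tiff(path("control_bfp.tif"))
    traces <- extract_pore_traces(bfp, centers)
    ctrl_traces <- extract_pore_traces(ctrl, centers)
    k_sigma <- .cfg_get(config, "cells", "k_sigma", 3)
    cls <- classify_pores(traces, ctrl_traces, k_sigma = k_sigma,
                          switch_margin = .cfg_get(config, "cells", "switch_margin", 10))
    occ <- occupancy_by_size(cls, layout)
    utils::write.csv(cls$classes, path("classes.csv"), row.names = FALSE)
    utils::write.csv(occ, path("occupancy.csv"), row.names = FALSE)
    thresholds <- list(bfp_positive_threshold = cls$threshold, k_sigma = k_sigma)
    outputs <- path(c("classes.csv", "occupancy.csv"))
  } else if (subcommand == "hmm") {
    halo <- read_movie_tiff(path("halo.tif"))
    layout_df <- utils::read.csv(path("layout.csv"))
    centers <- data.frame(id = layout_df$id, x_px = layout_df$x_px,
                          y_px = layout_df$y_px)
    traces <- extract_pore_traces(halo, centers)
    res <- lapply(split(traces$intensity, traces$id), function(x) {
      hm <- fit_two_state_hmm(x)
      st <- spike_stats(hm, x, .cfg_get(config, "hmm", "frame_interval_s", 0.1))
      list(peak = st$peak, sigma = st$sigma, snr = st$snr,
           n_events = st$n_events, path = hm$path)
    })
    summ <- data.frame(id = as.integer(names(res)),
                       peak = vapply(res, function(r) r$peak %||% NA_real_, 0),
                       sigma = vapply(res, function(r) r$sigma, 0),
                       snr = vapply(res, function(r) r$snr %||% NA_real_, 0),
                       n_events = vapply(res, function(r) r$n_events, 0L))
    utils::write.csv(summ, path("hmm_summary.csv"), row.names = FALSE)
    states <- do.call(cbind, lapply(res, function(r) r$path))
    utils::write.csv(states, path("hmm_states.csv"), row.names = FALSE)
    outputs <- path(c("hmm_summary.csv", "hmm_states.csv"))
  } else if (subcommand == "report") {
    fits <- list.files(out_dir, pattern = "fcs_fit.*\\.json$", full.names = TRUE,
                       recursive = TRUE)
    if (length(fits) == 0) stop("report: no fcs_fit JSON outputs found in ", out_dir)
    df <- do.call(rbind, lapply(fits, function(f) {
      j <- jsonlite::read_json(f, simplifyVector = TRUE)
      data.frame(d_nm = j$d_nm, h_nm = j$h_nm, N = j$N,
                 epsilon_cpms = j$epsilon_cpms, v_fcs_l = j$v_fcs_l)
    }))
    utils::write.csv(heatmap_long(df), path("heatmap.csv"), row.names = FALSE)
    outputs <- path("heatmap.csv")
  }

  manifest <- list(subcommand = subcommand,
                   seed = seed,
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("nanowell")),
                   thresholds = thresholds,
                   outputs = as.list(stats::setNames(
                     vapply(outputs, function(f) unname(tools::md5sum(f)), ""),
                     basename(outputs))),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path(paste0("manifest_", subcommand, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
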