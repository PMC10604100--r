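# Brownian-dynamics photon simulation: confined diffusion in the nanowell
# coupled to a bulk reservoir, with Poisson photon emission weighted by the
# axial detected-signal profile.

#' Simulation configuration
#'
#' Collects the physical and sampling parameters of the Brownian photon
#' simulation. Defaults reflect the in-vitro free-dye experiments the
#' simulation emulates: 500 nM dye, D = 400 um^2/s (small organic dye in
#' water), 1 ms binning.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param concentration Fluorophore concentration (mol/L).
#' @param diffusion_um2_s Diffusion coefficient (um^2/s).
#' @param dt_us Time step (us). The RMS step per axis is
#'   `sqrt(2 D dt)`; it should stay below d/10 for faithful wall collisions.
#' @param duration_s Simulated duration (s).
#' @param bin_ms Photon binning (ms).
#' @param brightness_cpms Detected counts per ms per molecule at unit
#'   detected-signal (sets the overall count rate scale).
#' @param reservoir_depth_nm,reservoir_side_nm Reservoir slab depth and
#'   lateral box side (nm).
#' @param camera Optional list of camera parameters (used by
#'   [make_cell_movie()]): `pixel_nm`, `gain`, `read_noise_sd`,
#'   `frame_interval_s`.
#' @param trace Optional list of trace parameters (used by
#'   [make_cell_movie()]): `k_on_hz`, `k_off_hz`, `spike_rate_hz`,
#'   `high_fraction`, `low_scale`, `switching_fraction`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       concentration = 500e-9,
                       diffusion_um2_s = 400,
                       dt_us = 0.5,
                       duration_s = 2,
                       bin_ms = 1,
                       brightness_cpms = 30,
                       reservoir_depth_nm = 400,
                       reservoir_side_nm = 800,
                       camera = list(pixel_nm = 130, gain = 30,
                                     read_noise_sd = 10, frame_interval_s = 0.1),
                       trace = list(k_on_hz = 0.15, k_off_hz = 0.15,
                                    spike_rate_hz = 0.5, high_fraction = 0.5,
                                    low_scale = 0.08, switching_fraction = 0.15)) {
  stopifnot(concentration >= 0, diffusion_um2_s > 0, dt_us > 0,
            duration_s > 0, bin_ms > 0, brightness_cpms >= 0,
            reservoir_depth_nm > 0, reservoir_side_nm > 0)
  structure(list(seed = as.integer(seed), concentration = concentration,
                 diffusion_um2_s = diffusion_um2_s, dt_us = dt_us,
                 duration_s = duration_s, bin_ms = bin_ms,
                 brightness_cpms = brightness_cpms,
                 reservoir_depth_nm = reservoir_depth_nm,
                 reservoir_side_nm = reservoir_side_nm,
                 camera = camera, trace = trace),
            class = "sim_config")
}

# domain bookkeeping shared by the simulation entry points
.sim_domain <- function(geometry, config) {
  R <- geometry$diameter / 2
  h <- geometry$overmill_depth
  tm <- geometry$metal_thickness
  L <- config$reservoir_side_nm
  zbot <- -tm - config$reservoir_depth_nm
  v_cyl_nm3 <- pi * R^2 * (h + tm)
  v_res_nm3 <- L^2 * config$reservoir_depth_nm
  v_total_l <- (v_cyl_nm3 + v_res_nm3) * 1e-24
  n_expected <- config$concentration * .N_AVOGADRO * v_total_l
  step_sd <- sqrt(2 * config$diffusion_um2_s * 1e6 * config$dt_us * 1e-6)  # nm
  if (step_sd > geometry$diameter / 10)
    warning(sprintf("RMS step %.1f nm exceeds d/10 = %.1f nm; reduce dt_us",
                    step_sd, geometry$diameter / 10))
  list(R = R, h = h, tm = tm, L = L, zbot = zbot,
       n_particles = max(0L, as.integer(round(n_expected))),
       n_expected = n_expected,
       step_sd = step_sd,
       v_well_l = pi * R^2 * h * 1e-24,
       v_cyl_l = v_cyl_nm3 * 1e-24)
}

#' Simulate confined Brownian diffusion in a nanowell
#'
#' Particles diffuse in the aperture + well cylinder and a coupled bulk
#' reservoir slab; the aperture is the only exchange path between well and
#' bulk. The total particle number is set from the configured concentration
#' and the domain volume, so the long-run mean count in any subvolume V is
#' `c * N_A * V`. Walls reflect; the reservoir is laterally periodic.
#'
#' @param geometry A [nanowell_geometry()].
#' @param config A [sim_config()].
#' @param record_every Record positions every this many steps (default 20).
#' @return List of class `nanowell_trajectories`: position matrices `x`,
#'   `y`, `z` (snapshots x particles, nm), per-snapshot `well_count`,
#'   snapshot interval `dt_rec_us`, the geometry and config.
#' @export
simulate_nanowell_diffusion <- function(geometry, config, record_every = 20L) {
  stopifnot(inherits(geometry, "nanowell_geometry"), inherits(config, "sim_config"))
  dom <- .sim_domain(geometry, config)
  n_steps <- as.integer(round(config$duration_s * 1e6 / config$dt_us))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (dom$n_particles == 0L) {
    n_rec <- n_steps %/% record_every + 1L
    out <- list(x = matrix(0, n_rec, 0), y = matrix(0, n_rec, 0),
                z = matrix(0, n_rec, 0), well_count = integer(n_rec))
  } else {
    out <- .cpp_diffuse_record(dom$n_particles, n_steps, as.integer(record_every),
                               dom$step_sd, dom$R, dom$h, dom$tm, dom$zbot, dom$L)
  }
  structure(c(out, list(dt_rec_us = config$dt_us * record_every,
                        geometry = geometry, config = config)),
            class = "nanowell_trajectories")
}

#' Emit a binned photon trace from particle trajectories
#'
#' Per-bin counts are Poisson with mean
#' `brightness * sum_particles S(z_i) * dt` accumulated over the recorded
#' snapshots in the bin, where `S(z)` is the detected-signal profile of the
#' supplied [signal_model()] (laterally uniform).
#'
#' @param trajectories A `nanowell_trajectories` object.
#' @param model A [signal_model()] covering the simulated z range.
#' @param config A [sim_config()]; defaults to the one stored in
#'   `trajectories`.
#' @return A [photon_trace()].
#' @export
emit_photon_trace <- function(trajectories, model, config = trajectories$config) {
  stopifnot(inherits(trajectories, "nanowell_trajectories"),
            inherits(model, "signal_model"))
  p <- model$profile
  dt_ms <- trajectories$dt_rec_us / 1000
  n_rec <- nrow(trajectories$z)
  rate <- numeric(n_rec)  # expected counts per snapshot interval
  if (ncol(trajectories$z) > 0) {
    s_of_z <- stats::approxfun(p$z, p$s, rule = 2)
    rate <- rowSums(matrix(s_of_z(trajectories$z), nrow = n_rec)) *
      config$brightness_cpms * dt_ms
  }
  per_bin <- max(1L, as.integer(round(config$bin_ms / dt_ms)))
  n_bins <- length(rate) %/% per_bin
  lam <- colSums(matrix(rate[seq_len(n_bins * per_bin)], nrow = per_bin))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  photon_trace(stats::rpois(n_bins, lam), config$bin_ms)
}

#' One-pass Brownian photon-trace simulation
#'
#' Combines [simulate_nanowell_diffusion()] and [emit_photon_trace()]
#' without storing trajectories, stepping and accumulating the photon rate
#' in compiled code; use this for FCS-scale runs (seconds of trace at
#' sub-microsecond steps).
#'
#' @inheritParams simulate_nanowell_diffusion
#' @param model A [signal_model()] covering the z range, or `NULL` for a
#'   uniform unit signal inside the cylinder region (ideal open-volume
#'   control; particles in the reservoir contribute nothing).
#' @return A [photon_trace()] with attribute `mean_well` (per-bin mean
#'   particle count in the well) and `n_particles`.
#' @export
simulate_photon_trace <- function(geometry, config, model = NULL) {
  stopifnot(inherits(geometry, "nanowell_geometry"), inherits(config, "sim_config"))
  dom <- .sim_domain(geometry, config)
  steps_per_bin <- max(1L, as.integer(round(config$bin_ms * 1000 / config$dt_us)))
  n_bins <- as.integer(floor(config$duration_s * 1000 / config$bin_ms))
  n_steps <- n_bins * steps_per_bin
  if (is.null(model)) {
    s_z <- c(-dom$tm, dom$h)
    s_val <- c(1, 1)
    # uniform detection inside the cylinder only: emulate by a profile that
    # is 1 for z in (-tm, h] and 0 in the reservoir
    s_z <- c(dom$zbot, -dom$tm - 1e-9, -dom$tm, dom$h)
    s_val <- c(0, 0, 1, 1)
  } else {
    stopifnot(inherits(model, "signal_model"))
    s_z <- model$profile$z
    s_val <- model$profile$s
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (config$concentration == 0) {
    tr <- photon_trace(integer(n_bins), config$bin_ms)
    attr(tr, "mean_well") <- numeric(n_bins)
    attr(tr, "n_particles") <- 0L
    return(tr)
  }
  # grand-canonical ensemble: Poisson initial count, bath flux at the far
  # boundary maintains the concentration
  rho_nm3 <- config$concentration * .N_AVOGADRO * 1e-24
  n0 <- stats::rpois(1, dom$n_expected)
  out <- .cpp_diffuse_photons(n0, n_steps, config$dt_us,
                              steps_per_bin, dom$step_sd,
                              dom$R, dom$h, dom$tm, dom$zbot, dom$L,
                              s_z, s_val, config$brightness_cpms, rho_nm3)
  tr <- photon_trace(out$counts, config$bin_ms)
  attr(tr, "mean_well") <- out$mean_well
  attr(tr, "n_particles") <- n0
  tr
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
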