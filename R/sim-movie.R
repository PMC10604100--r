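# Synthetic pore-array movies: bright-field reference image plus two-channel
# EMCCD fluorescence stacks with the bimodal (high/low) pore-intensity
# structure, switching pores and single-molecule spikes, with ground truth.

#' Pore-array layout
#'
#' Rectangular grid of pores with diameters varying by column group and
#' depths by row group (mirroring arrays milled with a design grid), plus
#' corner marker holes used to anchor registration.
#'
#' @param n_rows,n_cols Grid size.
#' @param pitch_px Pore pitch (pixels).
#' @param margin_px Margin from the image border to the first pore (pixels).
#' @param diameters_nm Diameters cycled across column groups.
#' @param depths_nm Depths cycled across row groups.
#' @param pixel_nm Pixel size (nm/px).
#' @return An object of class `pore_layout`: data frame `pores` (`id`,
#'   `row`, `col`, `x_px`, `y_px`, `d_nm`, `h_nm`), `markers` (x/y px),
#'   `pixel_nm`, and the implied image size `dim_px`.
#' @export
pore_array_layout <- function(n_rows = 8, n_cols = 8, pitch_px = 12,
                              margin_px = 14,
                              diameters_nm = c(100, 160, 220, 280),
                              depths_nm = c(0, 50, 100, 200),
                              pixel_nm = 130) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch_px >= 7)
  rc <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  pores <- data.frame(
    id = seq_len(nrow(rc)), row = rc$row, col = rc$col,
    x_px = margin_px + (rc$col - 1) * pitch_px,
    y_px = margin_px + (rc$row - 1) * pitch_px,
    d_nm = diameters_nm[(rc$col - 1) %% length(diameters_nm) + 1],
    h_nm = depths_nm[(rc$row - 1) %% length(depths_nm) + 1])
  side_x <- margin_px * 2 + (n_cols - 1) * pitch_px
  side_y <- margin_px * 2 + (n_rows - 1) * pitch_px
  markers <- data.frame(
    x_px = c(5, side_x - 6, 5),
    y_px = c(5, 5, side_y - 6))
  if (min(diff(sort(unique(pores$x_px)))) < 7)
    stop("layout error: pores overlap at this pitch/pixel size")
  structure(list(pores = pores, markers = markers, pixel_nm = pixel_nm,
                 dim_px = c(side_y, side_x)),
            class = "pore_layout")
}

#' @export
print.pore_layout <- function(x, ...) {
  cat(sprintf("pore layout: %d pores, image %d x %d px, %g nm/px\n",
              nrow(x$pores), x$dim_px[1], x$dim_px[2], x$pixel_nm))
  invisible(x)
}

# add an integrated-amplitude Gaussian spot to an image (in place)
.add_spot <- function(img, x0, y0, amp, sigma) {
  ix <- round(x0); iy <- round(y0)
  w <- ceiling(4 * sigma)
  xs <- max(1, ix - w):min(ncol(img), ix + w)
  ys <- max(1, iy - w):min(nrow(img), iy + w)
  gx <- exp(-((xs - x0)^2) / (2 * sigma^2))
  gy <- exp(-((ys - y0)^2) / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + amp * outer(gy, gx) / (2 * pi * sigma^2)
  img
}

# EMCCD readout: gain-scaled Poisson photon counting + Gaussian read noise
.emccd <- function(photon_img, gain, read_sd, offset = 100) {
  n <- length(photon_img)
  matrix(gain * stats::rpois(n, pmax(photon_img, 0)) +
           stats::rnorm(n, 0, read_sd) + offset,
         nrow = nrow(photon_img))
}

#' Synthetic two-channel pore-array movie with ground truth
#'
#' Generates the data the live-cell pipeline consumes: a bright-field image
#' (pores and marker holes as dark spots), a cytoplasm-marker channel in
#' which each cell-covered pore belongs to a high- or a low-intensity
#' population (low mean a small fraction of high, bimodal as in membrane
#' protrusion vs mere coverage), a configurable fraction of pores switching
#' between the two levels as a two-state telegraph process, and a
#' single-molecule channel with exponential-dwell intensity spikes on
#' high-population pores only. EMCCD noise is modeled as gain-scaled
#' Poisson plus Gaussian read noise. The generator emits its own truth
#' tables for validation.
#'
#' @param layout A [pore_array_layout()].
#' @param config A [sim_config()]; uses `seed`, `camera` and `trace`
#'   entries.
#' @param n_frames Frames per channel.
#' @param covered_fraction Fraction of pores covered by cells (0 = no
#'   cells; all pores then carry only background).
#' @param high_photons Mean photons/frame collected from a high-population
#'   pore (low = `trace$low_scale` times this).
#' @param spike_photons Mean photons/frame added during a single-molecule
#'   spike.
#' @param psf_sigma_px PSF sigma (pixels).
#' @return List of class `cell_movie`: `brightfield` (matrix), `bfp` and
#'   `halo` (frame-lists), `truth` (per-pore data frame: `covered`,
#'   `population`, `switching` = telegraph propensity, `switched` =
#'   realized level change within the movie), `states` (pores x frames matrix of the
#'   telegraph level, 1 = high), `spikes` (data frame of spike intervals),
#'   plus layout and parameters.
#' @export
make_cell_movie <- function(layout, config, n_frames = 200,
                            covered_fraction = 0.6,
                            high_photons = 400, spike_photons = 250,
                            psf_sigma_px = 1.3) {
  stopifnot(inherits(layout, "pore_layout"), inherits(config, "sim_config"))
  cam <- config$camera
  trc <- config$trace
  np <- nrow(layout$pores)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  covered <- stats::runif(np) < covered_fraction
  population <- ifelse(covered,
                       ifelse(stats::runif(np) < trc$high_fraction, "high", "low"),
                       "none")
  switching <- covered & stats::runif(np) < trc$switching_fraction
  dt <- cam$frame_interval_s
  # telegraph level per pore/frame: 1 = at the pore's high level
  states <- matrix(1, np, n_frames)
  for (i in seq_len(np)) {
    if (!covered[i]) { states[i, ] <- 0; next }
    base <- if (population[i] == "high") 1 else 0
    if (!switching[i]) { states[i, ] <- base; next }
    s <- base
    for (f in seq_len(n_frames)) {
      rate <- if (s == 1) trc$k_off_hz else trc$k_on_hz
      if (stats::runif(1) < 1 - exp(-rate * dt)) s <- 1 - s
      states[i, f] <- s
    }
  }
  # single-molecule spikes on high-population pores
  spike_rows <- list()
  spike_on <- matrix(0, np, n_frames)
  dwell_frames <- max(1, round(2 / dt / 10))  # mean dwell 1/5 s at 0.1 s frames
  for (i in which(population == "high")) {
    f <- 1
    while (f <= n_frames) {
      gap <- stats::rgeom(1, prob = min(trc$spike_rate_hz * dt, 0.9)) + 1
      f <- f + gap
      if (f > n_frames) break
      len <- 1 + stats::rgeom(1, prob = 1 / (1 + dwell_frames))
      to <- min(f + len - 1, n_frames)
      spike_on[i, f:to] <- 1
      spike_rows[[length(spike_rows) + 1]] <-
        data.frame(id = i, start_frame = f, end_frame = to)
      f <- to + 1
    }
  }
  spikes <- if (length(spike_rows)) do.call(rbind, spike_rows) else
    data.frame(id = integer(), start_frame = integer(), end_frame = integer())

  dim_px <- layout$dim_px
  blank <- matrix(0, dim_px[1], dim_px[2])
  # bright-field: bright metal background, dark pores/markers
  bf <- blank + 1000
  for (i in seq_len(np)) {
    amp <- -1800 * (layout$pores$d_nm[i] / 280)  # larger pores are darker
    bf <- .add_spot(bf, layout$pores$x_px[i], layout$pores$y_px[i], amp, psf_sigma_px)
  }
  for (i in seq_len(nrow(layout$markers))) {
    bf <- .add_spot(bf, layout$markers$x_px[i], layout$markers$y_px[i], -9000, 2.2)
  }
  bf <- bf + matrix(stats::rnorm(length(bf), 0, 4), nrow(bf))

  low_photons <- trc$low_scale * high_photons
  bfp <- vector("list", n_frames)
  halo <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    ph_b <- blank
    ph_h <- blank
    for (i in seq_len(np)) {
      lvl <- if (!covered[i]) 0 else if (states[i, f] == 1) high_photons else low_photons
      if (lvl > 0)
        ph_b <- .add_spot(ph_b, layout$pores$x_px[i], layout$pores$y_px[i],
                          lvl, psf_sigma_px)
      if (spike_on[i, f] == 1)
        ph_h <- .add_spot(ph_h, layout$pores$x_px[i], layout$pores$y_px[i],
                          spike_photons, psf_sigma_px)
    }
    bfp[[f]] <- .emccd(ph_b, cam$gain, cam$read_noise_sd)
    halo[[f]] <- .emccd(ph_h, cam$gain, cam$read_noise_sd)
  }
  structure(list(brightfield = bf, bfp = bfp, halo = halo,
                 truth = data.frame(id = layout$pores$id, covered = covered,
                                    population = population, switching = switching,
                                    switched = apply(states, 1, function(r)
                                      length(unique(r)) > 1)),
                 states = states, spikes = spikes, layout = layout,
                 params = list(n_frames = n_frames, high_photons = high_photons,
                               spike_photons = spike_photons,
                               covered_fraction = covered_fraction,
                               psf_sigma_px = psf_sigma_px, camera = cam,
                               trace = trc, seed = config$seed)),
            class = "cell_movie")
}

#' @export
print.cell_movie <- function(x, ...) {
  cat(sprintf("cell movie: %d pores, %d frames, %d x %d px; %d high / %d low / %d uncovered\n",
              nrow(x$truth), x$params$n_frames, nrow(x$brightfield),
              ncol(x$brightfield), sum(x$truth$population == "high"),
              sum(x$truth$population == "low"), sum(!x$truth$covered)))
  invisible(x)
}
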