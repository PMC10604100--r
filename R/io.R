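# File interchange: CSV profiles and traces with JSON metadata sidecars,
# multi-page TIFF movies, long-format heatmap tables.

#' Write / read an axial profile as CSV with a JSON sidecar
#'
#' The CSV holds `z_nm` and one column per profile quantity; the sidecar
#' (`<path>.json`) carries wavelength, mode and geometry metadata.
#'
#' @param profile An [excitation_profile()] or [signal_model()].
#' @param path CSV output path.
#' @param meta Extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, meta = list()) {
  if (inherits(profile, "excitation_profile")) {
    df <- data.frame(z_nm = profile$z, intensity = profile$intensity)
    meta <- c(meta, list(type = "excitation", mode = profile$mode,
                         wavelength_nm = profile$wavelength))
  } else if (inherits(profile, "signal_model")) {
    df <- profile$profile
    names(df)[names(df) == "z"] <- "z_nm"
    meta <- c(meta, list(type = "signal_model",
                         fluorophore = profile$fluor$label,
                         eta0 = profile$eta0,
                         diameter_nm = profile$geometry$diameter,
                         overmill_nm = profile$geometry$overmill_depth,
                         metal_nm = profile$geometry$metal_thickness))
  } else stop("unsupported profile type")
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_csv
#' @return For `read_profile_csv`: list with `data` (data frame) and
#'   `meta`.
#' @export
read_profile_csv <- function(path) {
  data <- utils::read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  list(data = data, meta = meta)
}

#' Write / read a photon trace as CSV
#'
#' Columns `time_ms`, `counts`.
#'
#' @param trace A [photon_trace()].
#' @param path CSV path.
#' @return `path` invisibly; for the reader, a [photon_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  utils::write.csv(data.frame(time_ms = (seq_along(trace$counts) - 1) * trace$bin_ms,
                              counts = trace$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_ms", "counts") %in% names(df)))
  bin <- if (nrow(df) > 1) df$time_ms[2] - df$time_ms[1] else 1
  photon_trace(df$counts, bin)
}

#' Write / read a TCSPC decay (with IRF) as CSV
#'
#' Columns `time_ps`, `counts`, `irf`.
#'
#' @param decay A [tcspc_decay()].
#' @param path CSV path.
#' @return `path` invisibly; for the reader, a [tcspc_decay()].
#' @export
write_decay_csv <- function(decay, path) {
  stopifnot(inherits(decay, "tcspc_decay"))
  utils::write.csv(data.frame(time_ps = decay$time_ps, counts = decay$counts,
                              irf = decay$irf),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_ps", "counts", "irf") %in% names(df)))
  bin <- if (nrow(df) > 1) df$time_ps[2] - df$time_ps[1] else 25
  tcspc_decay(df$counts, df$irf, bin)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Images are stored as 32-bit float TIFF pages; intensities are written
#' unchanged.
#'
#' @param frames A matrix or list of matrices.
#' @param path TIFF path.
#' @return `path` invisibly; for the reader, a list of matrices.
#' @export
write_movie_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  tiff::writeTIFF(lapply(frames, function(m) {
    storage.mode(m) <- "double"
    m
  }), path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Long-format heatmap table over a (diameter, depth) grid
#'
#' Reshapes per-condition results into the long CSV format
#' `d_nm, h_nm, quantity, value` used for heatmap export.
#'
#' @param results Data frame with `d_nm`, `h_nm` and one column per
#'   quantity.
#' @return Long data frame.
#' @export
heatmap_long <- function(results) {
  stopifnot(all(c("d_nm", "h_nm") %in% names(results)))
  qcols <- setdiff(names(results), c("d_nm", "h_nm"))
  do.call(rbind, lapply(qcols, function(q) {
    data.frame(d_nm = results$d_nm, h_nm = results$h_nm,
               quantity = q, value = results[[q]])
  }))
}
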