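# Pore-array image analysis: localization on bright-field images, windowed
# trace extraction with local background subtraction, bimodal high/low
# classification against a no-cell control, and occupancy statistics.

# separable Gaussian smoothing with replicated edges
.smooth2d <- function(img, sigma) {
  w <- ceiling(3 * sigma)
  k <- stats::dnorm(-w:w, 0, sigma)
  k <- k / sum(k)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
  conv1 <- function(m) {
    mp <- pad(m, w)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Locate pores on a bright-field image
#'
#' Pores appear as dark spots on the bright metal film. The image is
#' inverted and lightly smoothed, local maxima above a robust threshold are
#' collected, the global translation between the declared layout and the
#' detections is estimated (median offset over mutual nearest neighbours;
#' the large marker holes participate and anchor the registration), and
#' each layout pore is then assigned the detection nearest its registered
#' position, refined to sub-pixel precision by local centroiding. Pores
#' with no detection within `match_radius_px` are flagged missing.
#'
#' @param brightfield Numeric matrix (rows = y).
#' @param layout A [pore_array_layout()].
#' @param sigma_px Smoothing sigma (pixels).
#' @param match_radius_px Maximum detection-to-grid distance (pixels).
#' @return Data frame: `id`, `x_px`, `y_px` (sub-pixel centers), `missing`.
#' @export
detect_pores <- function(brightfield, layout, sigma_px = 1.2,
                         match_radius_px = 4) {
  stopifnot(is.matrix(brightfield), inherits(layout, "pore_layout"))
  inv <- max(brightfield) - brightfield
  sm <- .smooth2d(inv, sigma_px)
  thr <- stats::median(sm) + 3 * stats::mad(sm)
  # 3x3 local maxima above threshold
  nr <- nrow(sm); nc <- ncol(sm)
  core <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & core >= sm[2:(nr - 1) + dy, 2:(nc - 1) + dx]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("registration failed: no pore-like features detected")
  det <- data.frame(x = idx[, 2] + 1, y = idx[, 1] + 1)
  # translation: median offset of nearest detections to layout + markers
  ref <- rbind(data.frame(x = layout$pores$x_px, y = layout$pores$y_px),
               data.frame(x = layout$markers$x_px, y = layout$markers$y_px))
  nn <- vapply(seq_len(nrow(ref)), function(i) {
    d2 <- (det$x - ref$x[i])^2 + (det$y - ref$y[i])^2
    which.min(d2)
  }, 0L)
  dx <- det$x[nn] - ref$x
  dy <- det$y[nn] - ref$y
  near <- abs(dx - stats::median(dx)) <= match_radius_px &
    abs(dy - stats::median(dy)) <= match_radius_px
  if (sum(near) < 3)
    stop("registration failed: fewer than 3 anchors matched the layout")
  tx <- stats::median(dx[near])
  ty <- stats::median(dy[near])
  # assign each layout pore its nearest detection, refine by 3x3 centroid
  out <- layout$pores[, c("id", "x_px", "y_px")]
  out$x_px <- out$x_px + tx
  out$y_px <- out$y_px + ty
  out$missing <- FALSE
  for (i in seq_len(nrow(out))) {
    d2 <- (det$x - out$x_px[i])^2 + (det$y - out$y_px[i])^2
    j <- which.min(d2)
    if (d2[j] > match_radius_px^2) { out$missing[i] <- TRUE; next }
    cx <- det$x[j]; cy <- det$y[j]
    if (cx > 1 && cx < nc && cy > 1 && cy < nr) {
      win <- sm[(cy - 1):(cy + 1), (cx - 1):(cx + 1)]
      win <- win - min(win)
      s <- sum(win)
      if (s > 0) {
        cx <- cx + sum(win %*% (-1:1)) / s
        cy <- cy + sum((-1:1) %*% win) / s
      }
    }
    out$x_px[i] <- cx
    out$y_px[i] <- cy
  }
  out
}

#' Extract background-subtracted pore intensity traces
#'
#' For each pore and frame: the mean intensity of the 7 x 7 pixel window
#' centred on the pore minus the mean of the window's outer one-pixel ring
#' (24 pixels), which serves as the local background. The subtraction makes
#' traces exactly invariant to global additive offsets. Pores within 3
#' pixels of the image border are excluded with a warning.
#'
#' @param frames List of image matrices (or a single matrix).
#' @param centers Data frame with `id`, `x_px`, `y_px` (e.g. from
#'   [detect_pores()]); `missing` pores are skipped.
#' @param half_width Window half width (default 3, i.e. 7 x 7).
#' @param frame_interval_s Frame interval used for the time axis.
#' @return Data frame of class `pore_traces`: `id`, `frame`, `time_s`,
#'   `intensity`.
#' @export
extract_pore_traces <- function(frames, centers, half_width = 3,
                                frame_interval_s = 0.1) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(all(c("id", "x_px", "y_px") %in% names(centers)))
  if (!is.null(centers$missing)) centers <- centers[!centers$missing, ]
  hw <- half_width
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  cx <- round(centers$x_px); cy <- round(centers$y_px)
  ok <- cx - hw >= 1 & cx + hw <= nc & cy - hw >= 1 & cy + hw <= nr
  if (any(!ok))
    warning(sum(!ok), " pore(s) within ", hw, " px of the border excluded")
  centers <- centers[ok, ]; cx <- cx[ok]; cy <- cy[ok]
  ring <- function(win) {
    n <- nrow(win)
    edge <- c(win[1, ], win[n, ], win[2:(n - 1), 1], win[2:(n - 1), n])
    mean(edge)
  }
  rows <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    vals <- vapply(seq_along(cx), function(i) {
      win <- img[(cy[i] - hw):(cy[i] + hw), (cx[i] - hw):(cx[i] + hw)]
      mean(win) - ring(win)
    }, 0)
    rows[[f]] <- data.frame(id = centers$id, frame = f,
                            time_s = (f - 1) * frame_interval_s,
                            intensity = vals)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pore_traces", class(out))
  out
}

# two-level step score: BIC improvement of a two-state hidden Markov fit
# over a single Gaussian. The HMM likelihood rewards temporal persistence of
# the levels, so white noise around a constant level scores negative while a
# telegraph trace scores strongly positive.
.step_score <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(-Inf)
  hm <- suppressWarnings(fit_two_state_hmm(x))
  if (hm$degenerate || !is.finite(hm$log_lik)) return(-Inf)
  if (min(table(factor(hm$path, levels = 1:2))) < 3) return(-Inf)
  ll1 <- sum(stats::dnorm(x, mean(x), stats::sd(x) * sqrt((n - 1) / n), log = TRUE))
  # HMM adds 4 parameters (second mean/sd, two transition rates)
  2 * (hm$log_lik - ll1) - 4 * log(n)
}

#' Classify pores against a no-cell control
#'
#' Pores are called positive when their mean trace intensity exceeds the
#' control mean by `k_sigma` control standard deviations (the threshold
#' taken from pores where no cells were present). Positive pores are split
#' into high and low populations by a two-component one-dimensional
#' Gaussian mixture on the per-pore means; a pore is labelled `switching`
#' when a two-level step fit improves on a constant fit by more than
#' `switch_margin` BIC units, otherwise `stable`.
#'
#' @param traces A `pore_traces` data frame ([extract_pore_traces()]).
#' @param control_traces Control traces from cell-free pores (required; no
#'   silent default threshold).
#' @param k_sigma Threshold stringency (default 3).
#' @param switch_margin BIC margin for the switching call (default 10).
#' @return List of class `pore_classes`: data frame `classes` (`id`,
#'   `mean`, `sd`, `label` in negative/low/high, `stability`,
#'   `step_score`), the `threshold` used, and the mixture fit.
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_pores <- function(traces, control_traces, k_sigma = 3,
                           switch_margin = 10) {
  if (missing(control_traces) || is.null(control_traces))
    stop("control traces from cell-free pores are required to set the threshold")
  agg <- function(tr) {
    sp <- split(tr$intensity, tr$id)
    data.frame(id = as.integer(names(sp)),
               mean = vapply(sp, mean, 0),
               sd = vapply(sp, stats::sd, 0),
               step_score = vapply(sp, .step_score, 0))
  }
  po <- agg(traces)
  ctrl <- agg(control_traces)
  # spread across control pores; with a single control pore, its frame-to-
  # frame noise divided by sqrt(frames) is the spread of its mean
  ctrl_spread <- if (nrow(ctrl) > 1) stats::sd(ctrl$mean) else
    ctrl$sd[1] / sqrt(sum(control_traces$id == ctrl$id[1]))
  threshold <- mean(ctrl$mean) + k_sigma * ctrl_spread
  positive <- po$mean > threshold
  label <- rep("negative", nrow(po))
  mix <- NULL
  if (sum(positive) >= 4) {
    vals <- po$mean[positive]
    mix <- tryCatch(
      mclust::Mclust(vals, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(mix) && !is.null(mix$classification)) {
      hi_comp <- which.max(mix$parameters$mean)
      label[positive] <- ifelse(mix$classification == hi_comp, "high", "low")
    } else {
      label[positive] <- "high"
    }
  } else if (any(positive)) {
    label[positive] <- "high"
  }
  stability <- ifelse(po$step_score > switch_margin, "switching", "stable")
  stability[label == "negative"] <- "stable"
  structure(list(classes = data.frame(po[, c("id", "mean", "sd")],
                                      label = label, stability = stability,
                                      step_score = po$step_score),
                 threshold = threshold, k_sigma = k_sigma,
                 switch_margin = switch_margin, mixture = mix),
            class = "pore_classes")
}

#' @export
print.pore_classes <- function(x, ...) {
  tab <- table(x$classes$label)
  cat(sprintf("pore classes (threshold %.3g): %s\n", x$threshold,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Occupancy fraction by pore size
#'
#' Fraction of BFP-positive pores (label high or low) per (diameter,
#' depth) bin, with exact binomial confidence intervals. Empty bins are
#' omitted with a note attribute.
#'
#' @param classes A `pore_classes` result.
#' @param layout The [pore_array_layout()] the pores came from.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame: `d_nm`, `h_nm`, `n`, `n_positive`, `fraction`,
#'   `ci_lo`, `ci_hi`.
#' @export
occupancy_by_size <- function(classes, layout, conf_level = 0.95) {
  stopifnot(inherits(classes, "pore_classes"), inherits(layout, "pore_layout"))
  df <- merge(classes$classes, layout$pores[, c("id", "d_nm", "h_nm")], by = "id")
  df$positive <- df$label != "negative"
  out <- do.call(rbind, lapply(split(df, list(df$d_nm, df$h_nm), drop = TRUE),
    function(g) {
      bt <- stats::binom.test(sum(g$positive), nrow(g), conf.level = conf_level)
      data.frame(d_nm = g$d_nm[1], h_nm = g$h_nm[1], n = nrow(g),
                 n_positive = sum(g$positive),
                 fraction = sum(g$positive) / nrow(g),
                 ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2])
    }))
  rownames(out) <- NULL
  out[order(out$d_nm, out$h_nm), ]
}

#' Compare wide-field and TIRF pore intensities by class
#'
#' For matched pores imaged under both illuminations, reports the mean and
#' SD of per-pore trace means for the high and low classes in each
#' condition and their TIRF/WF ratios. Classes are taken from the
#' wide-field condition. Empty classes yield `NaN` with `flag = "empty"`.
#'
#' @param traces_wf,traces_tirf `pore_traces` for the two conditions
#'   (identical pore id sets required).
#' @param classes A `pore_classes` result (from the WF condition).
#' @return Data frame: `label`, `n`, `wf_mean`, `wf_sd`, `tirf_mean`,
#'   `tirf_sd`, `ratio`, `flag`.
#' @export
wf_tirf_compare <- function(traces_wf, traces_tirf, classes) {
  ids_wf <- sort(unique(traces_wf$id))
  ids_ti <- sort(unique(traces_tirf$id))
  if (!identical(ids_wf, ids_ti))
    stop("unmatched pore sets between WF and TIRF conditions")
  mn <- function(tr) vapply(split(tr$intensity, tr$id), mean, 0)
  m_wf <- mn(traces_wf)
  m_ti <- mn(traces_tirf)
  cl <- classes$classes
  out <- do.call(rbind, lapply(c("high", "low"), function(lab) {
    ids <- as.character(cl$id[cl$label == lab])
    ids <- intersect(ids, names(m_wf))
    if (length(ids) == 0) {
      return(data.frame(label = lab, n = 0L, wf_mean = NaN, wf_sd = NaN,
                        tirf_mean = NaN, tirf_sd = NaN, ratio = NaN,
                        flag = "empty"))
    }
    data.frame(label = lab, n = length(ids),
               wf_mean = mean(m_wf[ids]), wf_sd = stats::sd(m_wf[ids]),
               tirf_mean = mean(m_ti[ids]), tirf_sd = stats::sd(m_ti[ids]),
               ratio = mean(m_ti[ids]) / mean(m_wf[ids]), flag = "ok")
  }))
  rownames(out) <- NULL
  out
}
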