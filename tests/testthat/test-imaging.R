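# pore localization, trace extraction, classification, occupancy

lay6 <- pore_array_layout(6, 6)

test_that("pores are localized to sub-pixel accuracy and shifts are tracked", {
  mv <- make_cell_movie(lay6, sim_config(seed = 3), n_frames = 5)
  cen <- detect_pores(mv$brightfield, lay6)
  expect_equal(nrow(cen), 36)
  expect_false(any(cen$missing))
  expect_lt(max(abs(cen$x_px - lay6$pores$x_px)), 0.5)
  expect_lt(max(abs(cen$y_px - lay6$pores$y_px)), 0.5)
  # integer translation of the image moves every center accordingly
  bf <- mv$brightfield
  sh <- bf
  sh[] <- stats::median(bf)
  sh[4:nrow(bf), 3:ncol(bf)] <- bf[1:(nrow(bf) - 3), 1:(ncol(bf) - 2)]
  cen2 <- detect_pores(sh, lay6)
  keep <- !cen2$missing
  expect_equal(cen2$x_px[keep] - cen$x_px[keep], rep(2, sum(keep)), tolerance = 0.2)
  expect_equal(cen2$y_px[keep] - cen$y_px[keep], rep(3, sum(keep)), tolerance = 0.2)
  # blank image: registration error
  expect_error(detect_pores(matrix(5, 80, 80), lay6), "registration")
})

test_that("trace extraction is the 7x7 mean minus the edge-ring mean", {
  img <- matrix(10, 60, 60)
  centers <- data.frame(id = 1, x_px = 30, y_px = 25)
  # uniform image -> exactly zero
  expect_equal(extract_pore_traces(img, centers)$intensity, 0)
  # a known spot: forward-model the window arithmetic
  img2 <- img
  img2[23:27, 28:32] <- img2[23:27, 28:32] + 8  # 5x5 block inside the 7x7
  tr <- extract_pore_traces(img2, centers)
  expect_equal(tr$intensity, 8 * 25 / 49)  # ring untouched
  # additive offsets cancel exactly
  tr2 <- extract_pore_traces(img2 + 123.4, centers)
  expect_equal(tr2$intensity, tr$intensity)
  # border pores are excluded with a warning
  expect_warning(out <- extract_pore_traces(img, data.frame(id = 1:2,
                                                            x_px = c(2, 30),
                                                            y_px = c(2, 25))),
                 "border")
  expect_equal(unique(out$id), 2L)
})

test_that("classification separates the bimodal populations near-perfectly", {
  # pooled accuracy over several generator seeds (10:1 separation)
  correct <- 0L; total <- 0L
  for (s in c(11, 12, 13, 14)) {
    mv <- make_cell_movie(lay6, sim_config(seed = s), n_frames = 80)
    cen <- detect_pores(mv$brightfield, lay6)
    tr <- extract_pore_traces(mv$bfp, cen)
    ctl <- make_cell_movie(lay6, sim_config(seed = s + 500), n_frames = 80,
                           covered_fraction = 0)
    ctr <- extract_pore_traces(ctl$bfp, cen)
    cls <- classify_pores(tr, ctr)
    truth_lab <- c(none = "negative", low = "low", high = "high")[mv$truth$population]
    # switching pores legitimately sit between classes; score the stable ones
    stable <- !mv$truth$switched
    correct <- correct + sum(cls$classes$label[stable] == truth_lab[stable])
    total <- total + sum(stable)
  }
  expect_gte(correct / total, 0.99)
})

test_that("classification degenerate inputs behave as specified", {
  mv <- make_cell_movie(lay6, sim_config(seed = 19), n_frames = 60,
                        covered_fraction = 0)
  cen <- detect_pores(mv$brightfield, lay6)
  tr <- extract_pore_traces(mv$bfp, cen)
  cls <- classify_pores(tr, tr)  # all-control input
  expect_true(all(cls$classes$label == "negative"))
  expect_error(classify_pores(tr, NULL), "control")
})

test_that("stability labels separate constant from telegraph archetypes", {
  frames <- 150
  const <- data.frame(id = 1, frame = 1:frames, time_s = (1:frames) * 0.1,
                      intensity = withr::with_seed(2, 100 + rnorm(frames, 0, 8)))
  tg <- make_telegraph(frames, peak = 100, sigma = 8, p_switch = 0.03, seed = 5)
  sw <- data.frame(id = 2, frame = 1:frames, time_s = (1:frames) * 0.1,
                   intensity = 20 + tg$x)
  both <- rbind(const, sw)
  ctrl <- data.frame(id = 3, frame = 1:frames, time_s = (1:frames) * 0.1,
                     intensity = withr::with_seed(3, rnorm(frames, 0, 8)))
  cls <- classify_pores(both, ctrl)
  expect_equal(cls$classes$stability[cls$classes$id == 1], "stable")
  expect_equal(cls$classes$stability[cls$classes$id == 2], "switching")
})

test_that("occupancy fractions and their CIs follow the truth table", {
  mv <- make_cell_movie(lay6, sim_config(seed = 29), n_frames = 60,
                        covered_fraction = 1)
  cen <- detect_pores(mv$brightfield, lay6)
  tr <- extract_pore_traces(mv$bfp, cen)
  ctl <- make_cell_movie(lay6, sim_config(seed = 529), n_frames = 60,
                         covered_fraction = 0)
  cls <- classify_pores(tr, extract_pore_traces(ctl$bfp, cen))
  occ <- occupancy_by_size(cls, lay6)
  expect_true(all(occ$fraction == 1))  # everything covered -> all positive
  mv0 <- make_cell_movie(lay6, sim_config(seed = 31), n_frames = 60,
                         covered_fraction = 0)
  tr0 <- extract_pore_traces(mv0$bfp, cen)
  cls0 <- classify_pores(tr0, extract_pore_traces(ctl$bfp, cen))
  occ0 <- occupancy_by_size(cls0, lay6)
  expect_true(all(occ0$fraction == 0))
  expect_true(all(occ0$ci_lo >= 0 & occ0$ci_hi <= 1))
})

test_that("occupancy estimation is unbiased against the generating fraction", {
  fr <- vapply(1:8, function(s) {
    mv <- make_cell_movie(lay6, sim_config(seed = 200 + s), n_frames = 40,
                          covered_fraction = 0.5)
    cen <- detect_pores(mv$brightfield, lay6)
    tr <- extract_pore_traces(mv$bfp, cen)
    ctl <- make_cell_movie(lay6, sim_config(seed = 700 + s), n_frames = 40,
                           covered_fraction = 0)
    cls <- classify_pores(tr, extract_pore_traces(ctl$bfp, cen))
    mean(cls$classes$label != "negative")
  }, 0)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 0.01)
})

test_that("WF/TIRF comparison recovers a configured per-class scale change", {
  mv <- make_cell_movie(lay6, sim_config(seed = 43), n_frames = 60)
  cen <- detect_pores(mv$brightfield, lay6)
  tr_wf <- extract_pore_traces(mv$bfp, cen)
  ctl <- make_cell_movie(lay6, sim_config(seed = 543), n_frames = 60,
                         covered_fraction = 0)
  cls <- classify_pores(tr_wf, extract_pore_traces(ctl$bfp, cen))
  # identical inputs: all ratios 1
  same <- wf_tirf_compare(tr_wf, tr_wf, cls)
  expect_equal(same$ratio[same$flag == "ok"],
               rep(1, sum(same$flag == "ok")))
  # synthetic TIRF: low-class pores scaled by 0.5
  tr_ti <- tr_wf
  low_ids <- cls$classes$id[cls$classes$label == "low"]
  sel <- tr_ti$id %in% low_ids
  tr_ti$intensity[sel] <- tr_ti$intensity[sel] * 0.5
  cmp <- wf_tirf_compare(tr_wf, tr_ti, cls)
  expect_equal(cmp$ratio[cmp$label == "low"], 0.5, tolerance = 1e-9)
  expect_equal(cmp$ratio[cmp$label == "high"], 1, tolerance = 1e-9)
  # unmatched pore sets are an error; empty classes flagged NaN
  expect_error(wf_tirf_compare(tr_wf, tr_wf[tr_wf$id != 1, ], cls), "unmatched")
  cls_empty <- cls
  cls_empty$classes$label[cls_empty$classes$label == "low"] <- "high"
  cmp2 <- wf_tirf_compare(tr_wf, tr_wf, cls_empty)
  expect_true(is.nan(cmp2$ratio[cmp2$label == "low"]))
  expect_equal(cmp2$flag[cmp2$label == "low"], "empty")
})
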