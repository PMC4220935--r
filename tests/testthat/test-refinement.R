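flat_mic <- function(n_c, row) structure(rep(as.integer(row), n_c),
                                         class = "mic_curve")

test_that("brightness constraint counts bright MIC pixels", {
  px <- matrix(0, 20, 30)
  px[5, 1:30] <- 255
  pol <- polar_image(px, g_max = 255)
  mic <- flat_mic(30, 5)
  seg <- angular_segment(3, 12, 30)
  cfg <- constraint_config(t_gray = 100, rate_min = 0.5)
  expect_true(constraint_brightness(pol, mic, seg, cfg)$pass)
  px[5, ] <- 0
  pol0 <- polar_image(px, g_max = 255)
  r <- constraint_brightness(pol0, mic, seg, cfg)
  expect_false(r$pass)
  expect_equal(r$rate, 0)
  # 6 of 10 columns bright -> rate 0.6
  px[5, 3:8] <- 255
  pol6 <- polar_image(px, g_max = 255)
  r6 <- constraint_brightness(pol6, mic, seg, cfg)
  expect_equal(r6$rate, 0.6)
  expect_true(r6$pass)
})

test_that("slope constraint is wrap-aware and passes degenerate segments", {
  n_c <- 40
  mic <- structure(rep(10L, n_c), class = "mic_curve")
  cfg <- constraint_config(slope_max = 1)
  seg <- angular_segment(5, 14, n_c)
  expect_true(constraint_slope(mic, seg, cfg)$pass)       # flat
  mic2 <- mic; mic2[14] <- 40L                            # 30 rows / 10 cols
  r <- constraint_slope(mic2, seg, cfg)
  expect_false(r$pass)
  expect_equal(r$slope, 3.0)
  # wrapping segment spanning columns 38,39,40,1,2,3: arc length 6
  segw <- angular_segment(n_c - 2, 3, n_c)
  expect_equal(segw$length, 6L)
  micw <- mic; micw[n_c - 2] <- 10L; micw[3] <- 16L
  expect_equal(constraint_slope(micw, segw, cfg)$slope, 1.0)
  expect_true(constraint_slope(micw, segw, cfg)$pass)
  seg1 <- angular_segment(7, 7, n_c)
  expect_true(constraint_slope(mic2, seg1, cfg)$pass)     # by convention
})

test_that("angular length constraint is an inclusive band", {
  cfg <- constraint_config(ang_len_max = 120, ang_len_min = 4)
  expect_true(constraint_length(angular_segment(1, 10, 360), cfg)$pass)
  expect_true(constraint_length(angular_segment(1, 120, 360), cfg)$pass)
  expect_false(constraint_length(angular_segment(1, 121, 360), cfg)$pass)
  expect_false(constraint_length(angular_segment(1, 2, 360), cfg)$pass)
  expect_warning(full <- segments_from_binary(rep(1, 360)))
  expect_false(constraint_length(full[[1]],
                                 constraint_config(ang_len_min = 1),
                                 n_c = 360)$pass)
})

test_that("shadow contrast constraint compares shadow and flank regions", {
  n_r <- 40; n_c <- 60
  px <- matrix(80, n_r, n_c)
  seg <- angular_segment(20, 29, n_c)
  px[11:n_r, 20:29] <- 10                 # dark shadow under the segment
  pol <- polar_image(px, g_max = 255)
  mic <- flat_mic(n_c, 10)
  cfg <- constraint_config(shadow_margin = 20, flank_depth = 15,
                           flank_width = 5)
  r <- constraint_shadow_darker(pol, mic, seg, cfg)
  expect_true(r$pass)
  expect_equal(r$shadow_mean, 10)
  expect_equal(r$left_mean, 80)
  # uniform image fails any positive margin, passes margin 0
  polu <- polar_image(matrix(70, n_r, n_c), g_max = 255)
  expect_false(constraint_shadow_darker(polu, mic, seg, cfg)$pass)
  cfg0 <- constraint_config(shadow_margin = 0, flank_depth = 15,
                            flank_width = 5)
  expect_true(constraint_shadow_darker(polu, mic, seg, cfg0)$pass)
})

test_that("shadow shape constraint measures rectangle fill fractions", {
  n_r <- 40; n_c <- 30
  mask <- matrix(0L, n_r, n_c)
  seg <- angular_segment(11, 20, n_c)
  mic <- flat_mic(n_c, 8)
  dark <- list(mask = mask)
  cfg <- constraint_config(close_band = 10, rho_close = 0.7, rho_rect = 0.5)
  r0 <- constraint_shadow_shape(dark, mic, seg, cfg)
  expect_false(r0$pass)
  expect_equal(r0$frac_close, 0)
  mask2 <- mask; mask2[8:n_r, 11:20] <- 1L     # dark from the anchor row on
  r1 <- constraint_shadow_shape(list(mask = mask2), mic, seg, cfg)
  expect_true(r1$pass)
  expect_equal(r1$frac_close, 1)
  expect_equal(r1$frac_rect, 1)
  expect_equal(r1$r_star, 8)
  # dark only strictly below the MIC: the anchor row itself is bright
  mask2b <- mask; mask2b[9:n_r, 11:20] <- 1L
  r1b <- constraint_shadow_shape(list(mask = mask2b), mic, seg, cfg)
  expect_true(r1b$pass)
  expect_equal(r1b$frac_close, 0.9)
  # half-filled closeness band: passes at rho 0.4, fails at 0.8
  mask3 <- mask; mask3[13:n_r, 11:20] <- 1L    # top 5 of 10 band rows empty
  r2 <- constraint_shadow_shape(list(mask = mask3), mic, seg,
                                constraint_config(close_band = 10,
                                                  rho_close = 0.4,
                                                  rho_rect = 0.5))
  expect_true(r2$pass)
  expect_equal(r2$frac_close, 0.5)
  r3 <- constraint_shadow_shape(list(mask = mask3), mic, seg,
                                constraint_config(close_band = 10,
                                                  rho_close = 0.8,
                                                  rho_rect = 0.5))
  expect_false(r3$pass)
})

test_that("refinement accepts the plaque and rejects distractors end to end", {
  ph <- plaque_phantom(seed = 21)
  det <- detect_frame(ph$polar, run_config())
  expect_equal(det$status, "found")
  expect_length(det$plaques, 1)
  seg <- det$plaques[[1]]$segment
  expect_lte(abs(seg$c_l - 40), 2)
  expect_lte(abs(seg$c_r - 80), 2)
  # collagen-like bright arc without shadow on the far side
  ph2 <- generate_phantom(phantom_spec(
    plaque = list(c1 = 40, c2 = 80, r0 = 56, thickness = 10),
    distractors = list(list(type = "no_shadow_arc", c1 = 140, c2 = 160)),
    seed = 22))
  det2 <- detect_frame(ph2$polar, run_config())
  expect_equal(det2$status, "found")
  for (p in det2$plaques) {
    cols <- segment_columns(p$segment)
    expect_lt(length(intersect(cols, 140:160)) / length(cols), 0.2)
  }
  # adventitia-like full-circle bright ring
  ph3 <- generate_phantom(phantom_spec(
    distractors = list(list(type = "long_ring")), seed = 23))
  det3 <- detect_frame(ph3$polar, run_config())
  expect_equal(det3$status, "none")
})

test_that("empty candidate lists refine to empty output", {
  ph <- plaque_phantom(seed = 24)
  pol <- ph$polar
  mic <- compute_mic(pol)
  fit <- fit_rmm(pol, em_config())
  lab <- map_classify(pol, fit$gamma)
  dark <- extract_dark_region(lab, mic)
  out <- refine_candidates(list(), pol, mic, dark)
  expect_length(out$accepted, 0)
  expect_length(out$candidates, 0)
})

test_that("short-circuit and full evaluation accept the same candidates", {
  ph <- plaque_phantom(seed = 25)
  pol <- ph$polar
  mic <- compute_mic(pol)
  fit <- fit_rmm(pol, em_config())
  lab <- map_classify(pol, fit$gamma)
  dark <- extract_dark_region(lab, mic)
  segs <- list(angular_segment(40, 80, 180), angular_segment(100, 120, 180),
               angular_segment(1, 3, 180), angular_segment(170, 20, 180))
  a <- refine_candidates(segs, pol, mic, dark, short_circuit = TRUE)
  b <- refine_candidates(segs, pol, mic, dark, short_circuit = FALSE)
  key <- function(x) vapply(x, function(cand)
    paste(cand$segment$c_l, cand$segment$c_r), character(1))
  expect_equal(key(a$accepted), key(b$accepted))
  # full evaluation fills every flag
  expect_true(all(vapply(b$candidates, function(cand)
    !anyNA(cand$constraint_flags), logical(1))))
})

test_that("relaxing brightness or contrast thresholds never shrinks the accepted set", {
  ph <- plaque_phantom(seed = 26)
  pol <- ph$polar
  mic <- compute_mic(pol)
  fit <- fit_rmm(pol, em_config())
  lab <- map_classify(pol, fit$gamma)
  dark <- extract_dark_region(lab, mic)
  segs <- binarize_segments(run_bp(cbind(
    column_prior(column_factors(pol, mic, dark), 128, 255),
    1 - column_prior(column_factors(pol, mic, dark), 128, 255))))
  key <- function(x) vapply(x, function(cand)
    paste(cand$segment$c_l, cand$segment$c_r), character(1))
  strict <- refine_candidates(segs, pol, mic, dark,
                              constraint_config(rate_min = 0.7,
                                                shadow_margin = 30))
  for (cfg in list(constraint_config(rate_min = 0.4, shadow_margin = 30),
                   constraint_config(rate_min = 0.7, shadow_margin = 5),
                   constraint_config(rate_min = 0.4, shadow_margin = 5))) {
    loose <- refine_candidates(segs, pol, mic, dark, cfg)
    expect_true(all(key(strict$accepted) %in% key(loose$accepted)))
  }
})
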