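#' Constraint thresholds for plaque refinement
#'
#' Every threshold screens one anatomical property of a true calcified
#' plaque with acoustic shadowing; all are expressed relative to the
#' image scale where sensible and are fully config-exposed.
#'
#' @param t_gray Minimum gray value counted as bright on the MIC
#'   (constraint 1); default `0.55 * g_max`, resolved at evaluation time
#'   when `NULL`.
#' @param rate_min Minimum fraction of bright MIC pixels (constraint 1).
#' @param slope_max Maximum |row difference| / arc length between the
#'   segment endpoints on the MIC (constraint 2), rows per column.
#' @param ang_len_max Maximum angular length in columns (constraint 3);
#'   default `2 n_c / 3`, resolved at evaluation time when `NULL`.
#' @param ang_len_min Minimum angular length in columns (constraint 3);
#'   segments shorter than this are speckle-scale, not plaque-scale
#'   (default 4).
#' @param shadow_margin Minimum gray-level gap between the shadow region
#'   and the darker flank (constraint 4); default `0.08 * g_max`.
#' @param flank_width Width of the left/right flank regions in columns;
#'   default `max(5, len / 4)` resolved per segment when `NULL`.
#' @param flank_depth Depth of the shadow/flank regions below the MIC in
#'   rows; default `0.3 * n_r`, resolved at evaluation time when `NULL`.
#' @param close_band Height of the closeness rectangle (constraint 5)
#'   in rows; default `0.25 * n_r`, resolved at evaluation time when
#'   `NULL`. It must exceed the plaque band's extent below the MIC, so
#'   it scales with the radial sampling rather than being a fixed row
#'   count.
#' @param rho_close,rho_rect Minimum dark-pixel fractions of the
#'   closeness and extent rectangles (constraint 5); `rho_close`
#'   tolerates the bright plaque band occupying the top of the
#'   closeness rectangle.
#' @return A list of class `constraint_config`.
#' @export
constraint_config <- function(t_gray = NULL, rate_min = 0.5, slope_max = 1,
                              ang_len_max = NULL, ang_len_min = 4,
                              shadow_margin = NULL,
                              flank_width = NULL, flank_depth = NULL,
                              close_band = NULL, rho_close = 0.5,
                              rho_rect = 0.5) {
  stopifnot(rate_min >= 0, rate_min <= 1, slope_max >= 0,
            rho_close >= 0, rho_close <= 1, rho_rect >= 0, rho_rect <= 1,
            is.null(close_band) || close_band >= 1)
  structure(list(t_gray = t_gray, rate_min = rate_min,
                 slope_max = slope_max, ang_len_max = ang_len_max,
                 ang_len_min = ang_len_min,
                 shadow_margin = shadow_margin, flank_width = flank_width,
                 flank_depth = flank_depth, close_band = close_band,
                 rho_close = rho_close, rho_rect = rho_rect),
            class = "constraint_config")
}

## Resolve NULL thresholds against the image geometry.
resolve_constraints <- function(cfg, n_r, n_c, g_max) {
  if (is.null(cfg$t_gray)) cfg$t_gray <- 0.55 * g_max
  if (is.null(cfg$ang_len_max)) cfg$ang_len_max <- floor(2 * n_c / 3)
  if (is.null(cfg$shadow_margin)) cfg$shadow_margin <- 0.08 * g_max
  if (is.null(cfg$flank_depth)) cfg$flank_depth <- round(0.3 * n_r)
  if (is.null(cfg$close_band)) cfg$close_band <- round(0.25 * n_r)
  cfg
}

#' Constraint 1: the plaque is bright on the MIC
#'
#' Fraction of MIC pixels inside the segment whose gray value exceeds
#' `t_gray`; passes when the fraction reaches `rate_min`.
#'
#' @param polar A [polar_image()].
#' @param mic MIC curve.
#' @param seg An [angular_segment()].
#' @param cfg A [constraint_config()] (resolved thresholds).
#' @return List `(pass, rate)`.
#' @export
constraint_brightness <- function(polar, mic, seg, cfg) {
  cfg <- resolve_constraints(cfg, nrow(polar$pixels), ncol(polar$pixels),
                             polar$g_max)
  cols <- segment_columns(seg)
  vals <- polar$pixels[cbind(as.integer(mic[cols]), cols)]
  rate <- mean(vals > cfg$t_gray)
  list(pass = rate >= cfg$rate_min, rate = rate)
}

#' Constraint 2: the plaque grows along the vessel wall
#'
#' The absolute slope of the MIC between the two segment endpoints,
#' |rows| per column of arc length (wrap-aware), must not exceed
#' `slope_max`. Single-column segments pass by convention.
#'
#' @inheritParams constraint_brightness
#' @return List `(pass, slope)`.
#' @export
constraint_slope <- function(mic, seg, cfg) {
  if (seg$length < 2) return(list(pass = TRUE, slope = NA_real_))
  slope <- abs(mic[seg$c_r] - mic[seg$c_l]) / seg$length
  list(pass = slope <= cfg$slope_max, slope = slope)
}

#' Constraint 3: bounded angular length
#'
#' The segment's arc length in columns must lie in
#' `[ang_len_min, ang_len_max]` (inclusive); full-circle bright rings
#' such as the adventitia fail the upper bound, isolated speckle-scale
#' columns the lower.
#'
#' @inheritParams constraint_brightness
#' @param n_c,g_max,n_r Image geometry used to resolve a `NULL`
#'   `ang_len_max`.
#' @return List `(pass, length)`.
#' @export
constraint_length <- function(seg, cfg, n_r = NULL, n_c = seg$n_c,
                              g_max = NULL) {
  cfg <- resolve_constraints(cfg, n_r %||% 1, n_c, g_max %||% 1)
  list(pass = seg$length <= cfg$ang_len_max &&
         seg$length >= cfg$ang_len_min, length = seg$length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Rows (mic[c], mic[c] + depth] clipped to the image, per column.
region_mean_below_mic <- function(polar, mic, cols, depth) {
  n_r <- nrow(polar$pixels)
  vals <- unlist(lapply(cols, function(cc) {
    lo <- as.integer(mic[cc]) + 1L
    hi <- min(as.integer(mic[cc]) + depth, n_r)
    if (hi < lo) return(numeric(0))
    polar$pixels[lo:hi, cc]
  }))
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Constraint 4: the shadow is darker than its flanks
#'
#' Mean gray value of the shadow region (segment columns, rows up to
#' `flank_depth` below the MIC) must undercut both flank regions
#' (`flank_width` columns on either side, same depth below their own
#' MIC) by at least `shadow_margin`.
#'
#' @inheritParams constraint_brightness
#' @return List `(pass, shadow_mean, left_mean, right_mean)`.
#' @export
constraint_shadow_darker <- function(polar, mic, seg, cfg) {
  n_r <- nrow(polar$pixels); n_c <- ncol(polar$pixels)
  cfg <- resolve_constraints(cfg, n_r, n_c, polar$g_max)
  w <- cfg$flank_width %||% max(5L, ceiling(seg$length / 4))
  d <- cfg$flank_depth
  cols <- segment_columns(seg)
  left_cols <- ((seg$c_l - 1 - seq_len(w)) %% n_c) + 1L
  right_cols <- ((seg$c_r - 1 + seq_len(w)) %% n_c) + 1L
  left_cols <- setdiff(left_cols, cols)
  right_cols <- setdiff(right_cols, cols)
  shadow_mean <- region_mean_below_mic(polar, mic, cols, d)
  left_mean <- region_mean_below_mic(polar, mic, left_cols, d)
  right_mean <- region_mean_below_mic(polar, mic, right_cols, d)
  if (is.na(left_mean) || is.na(right_mean) || is.na(shadow_mean))
    return(list(pass = FALSE, shadow_mean = shadow_mean,
                left_mean = left_mean, right_mean = right_mean))
  pass <- shadow_mean <= min(left_mean, right_mean) - cfg$shadow_margin
  list(pass = pass, shadow_mean = shadow_mean, left_mean = left_mean,
       right_mean = right_mean)
}

#' Constraint 5: the shadow hugs the plaque and is rectangle-like
#'
#' Anchored at `r_star = max(mic[c_l], mic[c_r])`, the closeness
#' rectangle (segment columns, `close_band` rows from `r_star`) and the
#' extent rectangle (segment columns, `r_star` to the last row) must
#' both be filled with dark-mask pixels to at least `rho_close` and
#' `rho_rect`.
#'
#' @param dark An [extract_dark_region()] result.
#' @inheritParams constraint_brightness
#' @return List `(pass, r_star, frac_close, frac_rect)`.
#' @export
constraint_shadow_shape <- function(dark, mic, seg, cfg) {
  n_r <- nrow(dark$mask); n_c <- ncol(dark$mask)
  cfg <- resolve_constraints(cfg, n_r, n_c, 1)
  r_star <- max(as.integer(mic[seg$c_l]), as.integer(mic[seg$c_r]))
  cols <- segment_columns(seg)
  hi_close <- min(r_star + cfg$close_band - 1L, n_r)
  if (hi_close < r_star || r_star > n_r)
    return(list(pass = FALSE, r_star = r_star, frac_close = NA_real_,
                frac_rect = NA_real_))
  sub_close <- dark$mask[r_star:hi_close, cols, drop = FALSE]
  sub_rect <- dark$mask[r_star:n_r, cols, drop = FALSE]
  frac_close <- mean(sub_close)
  frac_rect <- mean(sub_rect)
  list(pass = frac_close >= cfg$rho_close && frac_rect >= cfg$rho_rect,
       r_star = r_star, frac_close = frac_close, frac_rect = frac_rect)
}

#' Refine candidate plaques by the five constraints
#'
#' Evaluates brightness, slope, angular length, shadow contrast and
#' shadow shape in order (short-circuiting by default) and keeps only
#' candidates passing all five. Each returned candidate carries its
#' flags and the measured statistics for diagnostics.
#'
#' @param segments List of [angular_segment()] candidates.
#' @param polar A [polar_image()].
#' @param mic MIC curve.
#' @param dark An [extract_dark_region()] result.
#' @param cfg A [constraint_config()].
#' @param short_circuit Stop at the first failing constraint (default);
#'   when FALSE all five are evaluated (the accepted set is identical).
#' @return List with `accepted` (list of `plaque_candidate`) and
#'   `candidates` (all, with flags).
#' @export
refine_candidates <- function(segments, polar, mic, dark,
                              cfg = constraint_config(),
                              short_circuit = TRUE) {
  out <- lapply(segments, function(seg) {
    flags <- rep(NA, 5)
    stats <- list()
    r1 <- constraint_brightness(polar, mic, seg, cfg)
    flags[1] <- r1$pass; stats$rate <- r1$rate
    if (r1$pass || !short_circuit) {
      r2 <- constraint_slope(mic, seg, cfg)
      flags[2] <- r2$pass; stats$slope <- r2$slope
    }
    if ((isTRUE(flags[1]) && isTRUE(flags[2])) || !short_circuit) {
      r3 <- constraint_length(seg, cfg, n_r = nrow(polar$pixels),
                              g_max = polar$g_max)
      flags[3] <- r3$pass
    }
    if (all(flags[1:3] %in% TRUE) || !short_circuit) {
      r4 <- constraint_shadow_darker(polar, mic, seg, cfg)
      flags[4] <- r4$pass
      stats$shadow_mean <- r4$shadow_mean
      stats$left_mean <- r4$left_mean
      stats$right_mean <- r4$right_mean
    }
    if (all(flags[1:4] %in% TRUE) || !short_circuit) {
      r5 <- constraint_shadow_shape(dark, mic, seg, cfg)
      flags[5] <- r5$pass
      stats$r_star <- r5$r_star
      stats$frac_close <- r5$frac_close
      stats$frac_rect <- r5$frac_rect
    }
    structure(list(segment = seg, constraint_flags = flags,
                   accepted = all(flags %in% TRUE), stats = stats),
              class = "plaque_candidate")
  })
  list(accepted = Filter(function(x) x$accepted, out), candidates = out)
}

#' @export
print.plaque_candidate <- function(x, ...) {
  cat(sprintf("<plaque_candidate> columns %d..%d, %s (flags: %s)\n",
              x$segment$c_l, x$segment$c_r,
              if (x$accepted) "accepted" else "rejected",
              paste(ifelse(is.na(x$constraint_flags), ".",
                           ifelse(x$constraint_flags, "T", "F")),
                    collapse = "")))
  invisible(x)
}
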