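#' Quantitative plaque measurements
#'
#' Five location/size measurements of a traced plaque: angular length
#' (AL, degrees), angular center (AC, degrees, circular midpoint of the
#' two border angles), plaque area (PA, mm^2, polar integral
#' `sum int rho drho dtheta` between the two paths), plaque thickness
#' (PT, mm, mean radial gap) and distance to catheter (DC, mm, mean
#' leading-edge radius).
#'
#' @param contour A `plaque_contour` from [assemble_contour()] (or any
#'   list with `upper$rows`, `lower$rows`, `segment`).
#' @param polar A [polar_image()] supplying `dr_mm` and `dtheta_deg`.
#' @return A one-row data frame with columns `AL`, `AC`, `PA`, `PT`,
#'   `DC`.
#' @export
measure_plaque <- function(contour, polar) {
  seg <- contour$segment
  up <- contour$upper$rows; lo <- contour$lower$rows
  if (is.null(up) || is.null(lo) || any(lo < up))
    stop("invalid contour: lower border must lie below the upper border")
  dtheta <- polar$dtheta_deg
  dr <- polar$dr_mm
  AL <- seg$length * dtheta
  th1 <- (seg$c_l - 1) * dtheta
  # circular midpoint of the arc from th1 spanning AL degrees
  AC <- (th1 + AL / 2) %% 360
  r_up <- (up - 1) * dr
  r_lo <- (lo - 1) * dr
  PA <- sum(0.5 * (r_lo^2 - r_up^2) * (dtheta * pi / 180))
  PT <- mean(r_lo - r_up)
  DC <- mean(r_up)
  data.frame(AL = AL, AC = AC, PA = PA, PT = PT, DC = DC)
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#'
#' @param counts List or vector with `TP`, `FP`, `TN`, `FN`.
#' @return List `(sensitivity, specificity)`.
#' @export
sens_spec <- function(counts) {
  counts <- as.list(counts)
  with(counts, {
    if (TP + FN <= 0 || TN + FP <= 0)
      stop("undefined rate: empty positive or negative class")
    list(sensitivity = TP / (TP + FN), specificity = TN / (TN + FP))
  })
}

#' Pixel-level confusion counts between two binary masks
#'
#' @param mask_auto Binary matrix of detected pixels.
#' @param mask_manual Binary matrix of reference (truth) pixels.
#' @return List with `TP`, `FP`, `TN`, `FN`.
#' @export
pixel_overlap <- function(mask_auto, mask_manual) {
  if (!identical(dim(mask_auto), dim(mask_manual)))
    stop("mask shapes differ")
  a <- mask_auto != 0; m <- mask_manual != 0
  list(TP = sum(a & m), FP = sum(a & !m), TN = sum(!a & !m),
       FN = sum(!a & m))
}

#' Least-squares regression between two measurement series
#'
#' Fits `y ~ x` by [stats::lm()] and reports the slope, intercept,
#' Pearson correlation and the root-mean-square residual.
#'
#' @param x,y Numeric vectors (length >= 3).
#' @return List `(slope, intercept, r, RMSE)`.
#' @export
fit_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("degenerate fit: x has zero variance")
  if (stats::var(y) == 0) stop("degenerate fit: y has zero variance")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y),
       RMSE = sqrt(mean(stats::residuals(fit)^2)))
}

#' Bland-Altman agreement indices
#'
#' Differences `d_i = a_i - b_i` against means `m_i = (a_i + b_i) / 2`;
#' the agreement interval is `mean(d) +/- 2 sd(d)`. Also reports the
#' ratio indices `d_ratio = mean(d) / mean(m)` and `dmax_ratio =
#' max|d| / mean(m)`, and the percentage of points outside the interval.
#'
#' @param a,b Numeric vectors of paired measurements (length >= 3).
#' @return List of class `bland_altman`: `d_mean`, `d_std`, `CI_low`,
#'   `CI_high`, `d_ratio`, `dmax_ratio`, `pct_outside_CI`, `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  m <- (a + b) / 2
  d_mean <- mean(d)
  d_std <- stats::sd(d)
  ci <- c(d_mean - 2 * d_std, d_mean + 2 * d_std)
  mm <- mean(m)
  structure(list(
    d_mean = d_mean, d_std = d_std, CI_low = ci[1], CI_high = ci[2],
    d_ratio = if (mm == 0) NA_real_ else d_mean / mm,
    dmax_ratio = if (mm == 0) NA_real_ else max(abs(d)) / mm,
    pct_outside_CI = 100 * mean(d < ci[1] | d > ci[2]),
    n = length(a)), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, d = %.4g +/- %.4g, CI [%.4g, %.4g], %.1f%% outside\n",
              x$n, x$d_mean, x$d_std, x$CI_low, x$CI_high,
              x$pct_outside_CI))
  invisible(x)
}
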