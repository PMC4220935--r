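#' Construct a Cartesian IVUS frame
#'
#' Wraps a grayscale pixel matrix together with the catheter-centre
#' coordinates and the physical pixel spacing. Row/column indices are
#' 1-based throughout the package.
#'
#' @param pixels Numeric matrix of intensities in `[0, g_max]`.
#' @param center Length-2 numeric `(row, col)` of the catheter centre;
#'   defaults to the frame centre.
#' @param pixel_size_mm Physical edge length of one pixel in mm.
#' @param g_max Maximum representable gray level.
#' @return An object of class `cartesian_image`.
#' @export
cartesian_image <- function(pixels, center = NULL, pixel_size_mm = 0.02,
                            g_max = 255) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("degenerate image: both dimensions must be >= 2")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > g_max)
    stop("intensities must lie in [0, g_max]")
  if (is.null(center))
    center <- c((nrow(pixels) + 1) / 2, (ncol(pixels) + 1) / 2)
  center <- as.numeric(center)
  if (length(center) != 2L || center[1] < 1 || center[1] > nrow(pixels) ||
      center[2] < 1 || center[2] > ncol(pixels))
    stop("center must lie inside the pixel grid")
  structure(list(pixels = pixels, center = center,
                 pixel_size_mm = pixel_size_mm, g_max = g_max),
            class = "cartesian_image")
}

#' Construct a polar IVUS image
#'
#' Rows index radius (row 1 is the catheter centre, radius grows
#' downward), columns index angle counterclockwise from the +x axis;
#' column `c` maps to angle `(c - 1) * dtheta_deg`.
#'
#' @param pixels Numeric matrix, `n_r` radius samples by `n_c` angle
#'   samples.
#' @param dr_px Radial step in Cartesian pixels.
#' @param pixel_size_mm Physical pixel size in mm (`dr_mm = dr_px *
#'   pixel_size_mm`).
#' @param g_max Maximum representable gray level.
#' @param center Catheter centre `(row, col)` in the source Cartesian
#'   frame, kept for the inverse transform.
#' @return An object of class `polar_image` with fields `pixels`,
#'   `dr_px`, `dr_mm`, `dtheta_deg`, `g_max`, `center`.
#' @export
polar_image <- function(pixels, dr_px = 1, pixel_size_mm = 0.02,
                        g_max = 255, center = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 4L)
    stop("polar image needs >= 2 radius rows and >= 4 angle columns")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > g_max)
    stop("intensities must lie in [0, g_max]")
  structure(list(pixels = pixels, dr_px = dr_px,
                 dr_mm = dr_px * pixel_size_mm,
                 pixel_size_mm = pixel_size_mm,
                 dtheta_deg = 360 / ncol(pixels),
                 g_max = g_max, center = center),
            class = "polar_image")
}

#' @export
print.cartesian_image <- function(x, ...) {
  cat(sprintf("<cartesian_image> %d x %d, center (%.1f, %.1f), %.3f mm/px, g_max %g\n",
              nrow(x$pixels), ncol(x$pixels), x$center[1], x$center[2],
              x$pixel_size_mm, x$g_max))
  invisible(x)
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("<polar_image> %d radius x %d angle, dr %.3f px (%.4f mm), dtheta %.2f deg\n",
              nrow(x$pixels), ncol(x$pixels), x$dr_px, x$dr_mm, x$dtheta_deg))
  invisible(x)
}

## Vectorised bilinear lookup; coordinates outside the grid return `outside`.
bilinear_sample <- function(mat, r, c, outside = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  val <- numeric(length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  val[!ok] <- outside
  if (any(ok)) {
    r0k <- pmin(r0[ok], nr - 1L); c0k <- pmin(c0[ok], nc - 1L)
    frk <- r[ok] - r0k; fck <- c[ok] - c0k
    i00 <- cbind(r0k,     c0k)
    i10 <- cbind(r0k + 1, c0k)
    i01 <- cbind(r0k,     c0k + 1)
    i11 <- cbind(r0k + 1, c0k + 1)
    val[ok] <- (1 - frk) * (1 - fck) * mat[i00] +
      frk * (1 - fck) * mat[i10] +
      (1 - frk) * fck * mat[i01] +
      frk * fck * mat[i11]
  }
  val
}

nearest_sample <- function(mat, r, c, outside = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- round(r); ci <- round(c)
  val <- rep(outside, length(r))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  val[ok] <- mat[cbind(ri[ok], ci[ok])]
  val
}

#' Resample a Cartesian frame onto the polar grid
#'
#' Polar row `rho` (1-based) and column `c` sample the Cartesian point
#' `center + (rho - 1) * dr * (cos theta_c, sin theta_c)` with
#' `theta_c = (c - 1) * 360 / n_c` degrees. The radial step `dr` is
#' chosen so that the last row reaches the nearest image edge. Samples
#' falling outside the Cartesian grid are 0.
#'
#' @param img A [cartesian_image()].
#' @param n_r,n_c Number of radius and angle samples (defaults 256, 360).
#' @param interp `"bilinear"` (default) or `"nearest"`.
#' @return A [polar_image()].
#' @export
to_polar <- function(img, n_r = 256, n_c = 360,
                     interp = c("bilinear", "nearest")) {
  stopifnot(inherits(img, "cartesian_image"))
  interp <- match.arg(interp)
  if (n_r < 2 || n_c < 4) stop("n_r must be >= 2 and n_c >= 4")
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  cy <- img$center[1]; cx <- img$center[2]
  edge <- min(cy - 1, nr - cy, cx - 1, nc - cx)
  if (edge <= 0) stop("catheter center sits on the image edge")
  dr <- edge / (n_r - 1)
  theta <- (seq_len(n_c) - 1) * 2 * pi / n_c
  rho <- (seq_len(n_r) - 1) * dr
  # sample grid: rows vary over rho, cols over theta
  rr <- outer(rho, sin(theta)) + cy
  cc <- outer(rho, cos(theta)) + cx
  sampler <- if (interp == "bilinear") bilinear_sample else nearest_sample
  px <- matrix(sampler(img$pixels, as.vector(rr), as.vector(cc)),
               nrow = n_r, ncol = n_c)
  px <- pmin(pmax(px, 0), img$g_max)
  polar_image(px, dr_px = dr, pixel_size_mm = img$pixel_size_mm,
              g_max = img$g_max, center = img$center)
}

#' Resample a polar image back to the Cartesian grid
#'
#' Inverse of [to_polar()]: each Cartesian pixel looks up its radius and
#' angle in the polar grid (bilinear, with angular wrap-around); points
#' outside the sampled disc are 0.
#'
#' @param polar A [polar_image()].
#' @param shape Length-2 `(rows, cols)` of the output frame.
#' @param center Catheter centre in the output frame; defaults to the
#'   stored centre, else the frame centre.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return A [cartesian_image()].
#' @export
to_cartesian <- function(polar, shape = NULL, center = NULL,
                         interp = c("bilinear", "nearest")) {
  stopifnot(inherits(polar, "polar_image"))
  interp <- match.arg(interp)
  n_r <- nrow(polar$pixels); n_c <- ncol(polar$pixels)
  if (is.null(shape)) {
    side <- 2 * ceiling((n_r - 1) * polar$dr_px) + 1
    shape <- c(side, side)
  }
  if (is.null(center)) center <- (shape + 1) / 2
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  rad <- sqrt(yy^2 + xx^2)
  rho_row <- rad / polar$dr_px + 1
  th <- atan2(yy, xx) %% (2 * pi)
  col_f <- th / (2 * pi) * n_c + 1
  # pad one wrapped column so bilinear interpolation crosses theta = 0
  pxp <- cbind(polar$pixels, polar$pixels[, 1])
  sampler <- if (interp == "bilinear") bilinear_sample else nearest_sample
  out <- matrix(sampler(pxp, as.vector(rho_row), as.vector(col_f)),
                shape[1], shape[2])
  out[rad > (n_r - 1) * polar$dr_px] <- 0
  out <- pmin(pmax(out, 0), polar$g_max)
  cartesian_image(out, center = center,
                  pixel_size_mm = polar$pixel_size_mm, g_max = polar$g_max)
}

#' Map polar coordinates to Cartesian points
#'
#' Exact coordinate mapping used by contour export: polar `(row, col)`
#' maps to `center + (row - 1) * dr * (cos theta, sin theta)`.
#'
#' @param polar A [polar_image()].
#' @param rows,cols Polar coordinates (may be fractional).
#' @param center Cartesian centre `(row, col)`.
#' @return A two-column matrix of Cartesian `(row, col)` points.
#' @export
polar_to_cart_points <- function(polar, rows, cols, center) {
  theta <- (cols - 1) * 2 * pi / ncol(polar$pixels)
  rad <- (rows - 1) * polar$dr_px
  cbind(row = center[1] + rad * sin(theta),
        col = center[2] + rad * cos(theta))
}

#' Maximum intensity curve
#'
#' Per-column row index of the brightest pixel of the polar image. The
#' first `ringdown_rows` rows are excluded so the catheter ring-down
#' artifact near zero radius cannot win. Ties break toward the smallest
#' row (closest to the catheter).
#'
#' @param polar A [polar_image()].
#' @param ringdown_rows Number of leading radius rows to ignore
#'   (default 8).
#' @return Integer vector of length `n_c`, class `mic_curve`.
#' @export
compute_mic <- function(polar, ringdown_rows = 8) {
  stopifnot(inherits(polar, "polar_image"))
  n_r <- nrow(polar$pixels)
  skip <- min(max(ringdown_rows, 0), n_r - 1)
  sub <- polar$pixels[(skip + 1):n_r, , drop = FALSE]
  m <- max.col(t(sub), ties.method = "first") + skip
  structure(as.integer(m), class = "mic_curve", ringdown_rows = skip)
}
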