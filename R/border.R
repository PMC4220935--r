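## 1-D Gaussian smoothing along the radius (columns smoothed
## independently) with reflective boundaries; sigma in rows.
smooth_radial <- function(mat, sigma) {
  if (is.null(sigma) || sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(mat)
  idx <- c(rev(seq_len(half) + 1L), seq_len(nr), nr - seq_len(half))
  padded <- mat[idx, , drop = FALSE]
  out <- apply(padded, 2, function(col)
    stats::filter(col, k, sides = 2))
  out[(half + 1):(half + nr), , drop = FALSE]
}

## Central radial difference with reflective end rows.
central_diff_rows <- function(mat) {
  nr <- nrow(mat)
  up <- mat[c(2:nr, nr - 1), , drop = FALSE]
  dn <- mat[c(2, 1:(nr - 1)), , drop = FALSE]
  up - dn
}

make_cost_grid <- function(costs, row_offset, cols, valid = NULL) {
  stopifnot(nrow(costs) >= 1, ncol(costs) >= 1)
  costs <- costs - min(costs)
  if (!is.null(valid) && any(!valid)) {
    penalty <- max(costs) * ncol(costs) + 1
    costs[!valid] <- costs[!valid] + penalty
  }
  structure(list(costs = costs, row_offset = row_offset, cols = cols),
            class = "cost_grid")
}

#' Cost grid for the leading (upper) plaque border
#'
#' Rectangular window over the segment columns spanning the rows between
#' the ring-down band and the MIC. After optional Gaussian smoothing the
#' cost is the negated central radial difference, shifted to be
#' non-negative, so minima sit on dark-to-bright transitions (lumen
#' above, calcium below). Cells at or below a column's MIC are penalised
#' out of reach.
#'
#' @param polar A [polar_image()].
#' @param mic MIC curve.
#' @param seg An [angular_segment()].
#' @param smooth_sigma Radial Gaussian sigma in rows (default 1).
#' @param ringdown_rows Leading rows excluded from the search (default 8).
#' @return A `cost_grid` (fields `costs`, `row_offset`, `cols`).
#' @export
upper_cost <- function(polar, mic, seg, smooth_sigma = 1,
                       ringdown_rows = 8) {
  cols <- segment_columns(seg)
  top <- ringdown_rows + 1L
  bot <- max(as.integer(mic[cols])) - 1L
  if (bot < top) stop("empty upper border region")
  sm <- smooth_radial(polar$pixels[, cols, drop = FALSE], smooth_sigma)
  g <- central_diff_rows(sm)
  win <- -g[top:bot, , drop = FALSE]
  rows_abs <- top:bot
  valid <- outer(rows_abs, as.integer(mic[cols]), `<`)
  make_cost_grid(win, row_offset = top, cols = cols, valid = valid)
}

#' Cost grid for the trailing (lower) plaque border
#'
#' Window over the segment columns from just below the MIC down to
#' `r_star + h_sub` (clipped at the image). Cost is the positive central
#' radial difference shifted non-negative: minima sit on bright-to-dark
#' transitions (calcium above, shadow below).
#'
#' @inheritParams upper_cost
#' @param r_star Anchor row (typically from constraint 5).
#' @param h_sub Depth of the subregion below `r_star` in rows
#'   (default 15).
#' @return A `cost_grid`.
#' @export
lower_cost <- function(polar, mic, seg, r_star, h_sub = 15,
                       smooth_sigma = 1) {
  cols <- segment_columns(seg)
  n_r <- nrow(polar$pixels)
  top <- min(as.integer(mic[cols])) + 1L
  bot <- min(r_star + h_sub, n_r)
  if (bot < top) stop("empty lower border region")
  sm <- smooth_radial(polar$pixels[, cols, drop = FALSE], smooth_sigma)
  g <- central_diff_rows(sm)
  win <- g[top:bot, , drop = FALSE]
  rows_abs <- top:bot
  valid <- outer(rows_abs, as.integer(mic[cols]), `>`)
  make_cost_grid(win, row_offset = top, cols = cols, valid = valid)
}

#' Free-endpoint minimal-cost path across a cost grid
#'
#' Dynamic program over columns left to right with row transitions
#' limited to `|delta row| <= step_max`; start and end rows are
#' unconstrained, so the returned path attains the global minimum cost
#' sum. Ties break toward the smaller row at the final column and at
#' every backtrack step.
#'
#' @param grid A `cost_grid` from [upper_cost()]/[lower_cost()], or a
#'   bare matrix.
#' @param step_max Maximum row step between adjacent columns (default 1).
#' @return A list of class `border_path`: `rows` (absolute row indices,
#'   one per column), `cols`, `total_cost`.
#' @export
min_cost_path <- function(grid, step_max = 1) {
  if (is.matrix(grid))
    grid <- structure(list(costs = grid, row_offset = 1L,
                           cols = seq_len(ncol(grid))),
                      class = "cost_grid")
  costs <- grid$costs
  nr <- nrow(costs); nc <- ncol(costs)
  stopifnot(step_max >= 1)
  D <- matrix(Inf, nr, nc)
  from <- matrix(NA_integer_, nr, nc)
  D[, 1] <- costs[, 1]
  if (nc > 1) for (cc in 2:nc) {
    for (r in seq_len(nr)) {
      lo <- max(1L, r - step_max); hi <- min(nr, r + step_max)
      prev <- D[lo:hi, cc - 1]
      k <- which.min(prev)            # smallest row among minima
      D[r, cc] <- costs[r, cc] + prev[k]
      from[r, cc] <- lo + k - 1L
    }
  }
  rows <- integer(nc)
  rows[nc] <- which.min(D[, nc])
  if (nc > 1) for (cc in nc:2) rows[cc - 1] <- from[rows[cc], cc]
  structure(list(rows = rows + grid$row_offset - 1L, cols = grid$cols,
                 total_cost = D[rows[nc], nc]),
            class = "border_path")
}

#' Assemble the closed plaque contour
#'
#' Joins the traced upper (leading) and lower (trailing) border paths
#' into a closed polygon in polar coordinates and maps it to Cartesian
#' points. If the paths cross, the lower path is pushed to at least one
#' row below the upper path.
#'
#' @param upper,lower `border_path` objects over the same columns.
#' @param seg An [angular_segment()].
#' @param polar A [polar_image()].
#' @param center Cartesian centre for the mapped polygon (defaults to
#'   the stored centre or the disc centre).
#' @return A list of class `plaque_contour`: `upper`, `lower`, `segment`,
#'   `polygon_polar` (closed `(row, col)` matrix), `polygon_cart`.
#' @export
assemble_contour <- function(upper, lower, seg, polar, center = NULL) {
  stopifnot(identical(upper$cols, lower$cols))
  lo <- pmax(lower$rows, upper$rows + 1L)
  n <- length(upper$cols)
  # unrolled column positions keep wrapping segments contiguous
  ucols <- upper$cols
  unroll <- cumsum(c(ucols[1], (diff(ucols) %% seg$n_c)))
  poly_polar <- rbind(
    cbind(upper$rows, unroll),
    cbind(seq(upper$rows[n], lo[n]), unroll[n]),
    cbind(rev(lo), rev(unroll)),
    cbind(rev(seq(upper$rows[1], lo[1])), unroll[1]))
  poly_polar <- poly_polar[!duplicated(poly_polar), , drop = FALSE]
  poly_polar <- rbind(poly_polar, poly_polar[1, ])
  colnames(poly_polar) <- c("row", "col")
  if (is.null(center))
    center <- polar$center %||% rep(ceiling((nrow(polar$pixels) - 1) *
                                              polar$dr_px) + 1, 2)
  poly_cart <- polar_to_cart_points(polar, poly_polar[, 1],
                                    ((poly_polar[, 2] - 1) %% seg$n_c) + 1,
                                    center)
  structure(list(upper = upper,
                 lower = structure(list(rows = lo, cols = lower$cols,
                                        total_cost = lower$total_cost),
                                   class = "border_path"),
                 segment = seg, polygon_polar = poly_polar,
                 polygon_cart = poly_cart),
            class = "plaque_contour")
}

#' Rasterise a plaque contour to a binary polar mask
#'
#' @param contour A `plaque_contour`.
#' @param n_r,n_c Mask dimensions (the polar grid).
#' @return Binary matrix with 1 between the upper and lower paths
#'   (inclusive) in the segment columns.
#' @export
contour_mask <- function(contour, n_r, n_c) {
  mask <- matrix(0L, n_r, n_c)
  cols <- contour$upper$cols
  for (k in seq_along(cols)) {
    r1 <- contour$upper$rows[k]; r2 <- contour$lower$rows[k]
    mask[max(1, r1):min(n_r, r2), cols[k]] <- 1L
  }
  mask
}
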