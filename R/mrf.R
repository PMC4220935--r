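#' Dark region below the maximum intensity curve
#'
#' The two labelled classes with the smallest mean gray values form a
#' binary mask (the hypoechoic family: blood speckle and acoustic
#' shadow). The per-column upper border `u(c)` is the smallest row
#' strictly below the MIC at which the mask is set; columns with no dark
#' pixel below the MIC fall back to the last row.
#'
#' Because speckle scatters isolated dark-class pixels through brighter
#' tissue, the border is anchored at the first *run* of at least
#' `dark_run` consecutive dark rows (a single outlier pixel is not the
#' upper border of a region); a run touching the last row also counts.
#'
#' @param labeling A `pixel_labeling` computed on the polar grid.
#' @param mic A [compute_mic()] curve of matching length.
#' @param dark_run Minimum consecutive dark rows starting the region
#'   (default 4; 1 reproduces the first-dark-pixel rule).
#' @return A list of class `dark_region`: `mask` (binary matrix),
#'   `upper_border` (integer per column), `dark_classes`.
#' @export
extract_dark_region <- function(labeling, mic, dark_run = 4) {
  stopifnot(inherits(labeling, "pixel_labeling"))
  lab <- labeling$labels
  n_r <- nrow(lab); n_c <- ncol(lab)
  stopifnot(length(mic) == n_c)
  means <- labeling$class_means
  live <- which(!is.na(means))
  if (length(live) < 3)
    stop("degenerate labeling: need at least 3 non-empty classes")
  dark <- live[order(means[live])][1:2]
  mask <- matrix(lab %in% dark, n_r, n_c) * 1L
  u <- integer(n_c)
  for (cc in seq_len(n_c)) {
    m0 <- as.integer(mic[cc])
    u[cc] <- n_r
    if (m0 + 1L > n_r) next
    seg <- mask[(m0 + 1L):n_r, cc]
    r <- rle(seg)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values == 1L &
                   (r$lengths >= dark_run | ends == length(seg)))
    if (length(hit)) u[cc] <- m0 + starts[hit[1]]
  }
  structure(list(mask = mask, upper_border = u, dark_classes = dark),
            class = "dark_region")
}

#' Per-column factors feeding the MRF prior
#'
#' For each angle column: `f1` the distance from the dark region's upper
#' border to the edge of the imaging area (rows), `f2` the distance from
#' that border down from the MIC (rows), and `f3` the mean gray value in
#' the open interval between the MIC and the border (0 when empty). A
#' column backed by acoustic shadow has a large `f1` and small `f2`,
#' `f3`.
#'
#' @param polar A [polar_image()].
#' @param mic A [compute_mic()] curve.
#' @param dark An [extract_dark_region()] result.
#' @return A data frame with columns `f1`, `f2`, `f3`.
#' @export
column_factors <- function(polar, mic, dark) {
  n_r <- nrow(polar$pixels); n_c <- ncol(polar$pixels)
  stopifnot(length(mic) == n_c, length(dark$upper_border) == n_c)
  u <- dark$upper_border
  f1 <- n_r - u
  f2 <- u - as.integer(mic)
  f3 <- vapply(seq_len(n_c), function(cc) {
    lo <- mic[cc] + 1L; hi <- u[cc] - 1L
    if (hi < lo) 0 else mean(polar$pixels[lo:hi, cc])
  }, numeric(1))
  data.frame(f1 = f1, f2 = f2, f3 = f3)
}

#' Column prior for the plaque/no-plaque field
#'
#' Normalised linear score `s(c) = l1 f1/N_r - l2 f2/N_r - l3 f3/G_max`
#' squashed by a logistic centred at the midpoint of the per-image score
#' range, so shadow-backed columns map near 1 and bright-floor columns
#' near 0 while the output stays strictly inside (0, 1).
#'
#' @param factors Data frame from [column_factors()].
#' @param n_r,g_max Normalising constants of the source polar image.
#' @param lambda Length-3 non-negative weights; default `c(1, 1, 0.5)`:
#'   the bright-tissue range of `f3/G_max` spans roughly twice the
#'   realistic span of the two geometric factors, so halving its weight
#'   brings the three terms to the same order of magnitude.
#' @param gain Logistic gain (default 6).
#' @return Numeric vector of per-column probabilities in (0, 1).
#' @export
column_prior <- function(factors, n_r, g_max, lambda = c(1, 1, 0.5),
                         gain = 6) {
  stopifnot(length(lambda) == 3, all(lambda >= 0))
  s <- lambda[1] * factors$f1 / n_r -
    lambda[2] * factors$f2 / n_r -
    lambda[3] * factors$f3 / g_max
  mid <- (min(s) + max(s)) / 2
  stats::plogis(gain * (s - mid))
}

#' Sum-product belief propagation on the angular column field
#'
#' Binary states (+1 plaque, -1 background) on a chain or ring over the
#' angle columns. Messages start uniform; synchronous damped updates
#' `m_{i->j}(x_j) propto sum_{x_i} phi_i(x_i) psi(x_i, x_j)
#' prod_{k in N(i) \ j} m_{k->i}(x_i)` run until the largest absolute
#' belief change drops below `eps`. On an acyclic chain the fixed point
#' is exact.
#'
#' @param evidence N x 2 matrix of strictly positive local evidence,
#'   column 1 for state +1, column 2 for state -1 (a probability vector
#'   `p` can be passed as `cbind(p, 1 - p)`).
#' @param compat 2 x 2 strictly positive compatibility matrix; default
#'   `[[q, 1-q], [1-q, q]]` with `q = 0.7`.
#' @param topology `"ring"` (angular axis is periodic; default) or
#'   `"chain"`.
#' @param eps Convergence threshold on beliefs (default 0.001).
#' @param max_iter Maximum iterations.
#' @param damping Message damping in [0, 1) (default 0.5); aids
#'   convergence on the ring.
#' @return A list of class `column_field` with `beliefs` (N x 2, rows
#'   sum to 1), `converged`, `iterations`.
#' @export
run_bp <- function(evidence, compat = NULL, topology = c("ring", "chain"),
                   eps = 0.001, max_iter = 500, damping = 0.5) {
  topology <- match.arg(topology)
  if (is.null(compat)) {
    q <- 0.7
    compat <- matrix(c(q, 1 - q, 1 - q, q), 2, 2)
  }
  evidence <- as.matrix(evidence)
  stopifnot(ncol(evidence) == 2, all(evidence > 0), all(compat > 0))
  n <- nrow(evidence)
  stopifnot(n >= 2)
  ring <- topology == "ring"
  # msg_fwd[i, ]: message i -> i+1; msg_bwd[i, ]: message i -> i-1
  msg_fwd <- matrix(0.5, n, 2)
  msg_bwd <- matrix(0.5, n, 2)
  prev_idx <- c(if (ring) n else NA, seq_len(n - 1))
  next_idx <- c(2:n, if (ring) 1 else NA)
  ones <- matrix(1, 1, 2)
  in_from_prev <- function() {  # message arriving at i from i-1
    out <- matrix(1, n, 2)
    ok <- !is.na(prev_idx)
    out[ok, ] <- msg_fwd[prev_idx[ok], , drop = FALSE]
    out
  }
  in_from_next <- function() {
    out <- matrix(1, n, 2)
    ok <- !is.na(next_idx)
    out[ok, ] <- msg_bwd[next_idx[ok], , drop = FALSE]
    out
  }
  beliefs_of <- function() {
    b <- evidence * in_from_prev() * in_from_next()
    b / rowSums(b)
  }
  beliefs <- beliefs_of()
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    ip <- in_from_prev(); nx <- in_from_next()
    # new i -> i+1 uses everything at i except what came from i+1
    new_fwd <- (evidence * ip) %*% compat
    new_bwd <- (evidence * nx) %*% compat
    if (!ring) {                       # endpoints send nothing outward
      new_fwd[n, ] <- 1
      new_bwd[1, ] <- 1
    }
    new_fwd <- new_fwd / rowSums(new_fwd)
    new_bwd <- new_bwd / rowSums(new_bwd)
    msg_fwd <- damping * msg_fwd + (1 - damping) * new_fwd
    msg_bwd <- damping * msg_bwd + (1 - damping) * new_bwd
    msg_fwd <- msg_fwd / rowSums(msg_fwd)
    msg_bwd <- msg_bwd / rowSums(msg_bwd)
    b_new <- beliefs_of()
    delta <- max(abs(b_new - beliefs))
    beliefs <- b_new
    if (delta < eps) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("belief propagation did not converge in %d iterations",
                    max_iter))
  structure(list(beliefs = beliefs, evidence = evidence, compat = compat,
                 topology = topology, converged = converged,
                 iterations = it),
            class = "column_field")
}

#' Binarise beliefs into angular segments
#'
#' Labels a column plaque when its +1 belief reaches `threshold`, then
#' groups maximal runs of labelled columns into segments; a run crossing
#' column 1 on a ring becomes a single wrapping segment.
#'
#' @param beliefs N x 2 belief matrix (column 1 = state +1) or a
#'   `column_field`.
#' @param threshold Belief threshold (default 0.5).
#' @param wrap Treat the column axis as periodic (default TRUE).
#' @return List of `angular_segment` objects, each with `c_l`, `c_r`
#'   (1-based columns), `wraps`, `n_c` and `length`.
#' @export
binarize_segments <- function(beliefs, threshold = 0.5, wrap = TRUE) {
  if (inherits(beliefs, "column_field")) beliefs <- beliefs$beliefs
  z <- as.integer(beliefs[, 1] >= threshold)
  segments_from_binary(z, wrap = wrap)
}

#' @rdname binarize_segments
#' @param z Binary vector of per-column labels.
#' @export
segments_from_binary <- function(z, wrap = TRUE) {
  n <- length(z)
  if (all(z == 1L)) {
    warning("all columns labelled plaque: returning one full-circle segment")
    return(list(angular_segment(1L, n, n)))
  }
  if (!any(z == 1L)) return(list())
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- lapply(which(r$values == 1L), function(k)
    angular_segment(starts[k], ends[k], n))
  if (wrap && z[1] == 1L && z[n] == 1L && length(segs) > 1) {
    first <- segs[[1]]; last <- segs[[length(segs)]]
    segs <- segs[-c(1, length(segs))]
    segs <- c(segs, list(angular_segment(last$c_l, first$c_r, n)))
  }
  segs
}

#' Angular segment
#'
#' @param c_l,c_r Left and right border columns (1-based, inclusive).
#' @param n_c Total number of angle columns.
#' @return An object of class `angular_segment`; `wraps` is TRUE when
#'   the segment crosses column 1.
#' @export
angular_segment <- function(c_l, c_r, n_c) {
  stopifnot(c_l >= 1, c_r >= 1, c_l <= n_c, c_r <= n_c)
  wraps <- c_l > c_r
  len <- if (wraps) n_c - c_l + 1L + c_r else c_r - c_l + 1L
  structure(list(c_l = as.integer(c_l), c_r = as.integer(c_r),
                 wraps = wraps, n_c = as.integer(n_c),
                 length = as.integer(len)),
            class = "angular_segment")
}

#' Columns covered by an angular segment
#'
#' @param seg An [angular_segment()].
#' @return Integer vector of 1-based column indices in angular order.
#' @export
segment_columns <- function(seg) {
  if (seg$wraps) c(seg$c_l:seg$n_c, 1:seg$c_r) else seg$c_l:seg$c_r
}

#' @export
print.angular_segment <- function(x, ...) {
  cat(sprintf("<angular_segment> columns %d..%d of %d (%d cols%s)\n",
              x$c_l, x$c_r, x$n_c, x$length,
              if (x$wraps) ", wraps" else ""))
  invisible(x)
}
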