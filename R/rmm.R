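#' EM configuration for the Rayleigh mixture model
#'
#' @param K Number of mixture components (default 5: the hyperechoic and
#'   hypoechoic tissue families plus intermediate echogenicities).
#' @param weight_a,weight_b Shape parameters of the per-pixel weight that
#'   discounts pixels deviating from their neighbourhood mean.
#' @param weight_beta Exponent sharpening the neighbourhood-aggregated
#'   weight before normalisation.
#' @param learn_rate Steepest-ascent step size `eta` of the M-step.
#' @param max_descent_steps Maximum accepted gradient steps per M-step.
#' @param em_tol Convergence threshold on the maximum absolute change of
#'   any mode/translation, in gray-level units.
#' @param em_max_iter Maximum EM iterations.
#' @param update_translation Re-estimate the translation by gradient
#'   (default) or hold it at its initial value.
#' @param eps_s Lower floor for the Rayleigh mode.
#' @param support_eps Support margin in gray levels (default 0.5):
#'   pixels closer than this to a component's translation are excluded
#'   from that component's likelihood term and gradient. Intensities are
#'   only meaningful to about one quantization step, and the shifted
#'   Rayleigh's `-1/(x - t)` gradient term is singular at the support
#'   boundary, so the margin both regularises and stabilises the
#'   steepest-ascent M-step.
#' @param seed Optional integer seed (reserved for stochastic
#'   initialisers; the default quantile-seeded k-means is deterministic).
#' @return A list of class `em_config`.
#' @export
em_config <- function(K = 5, weight_a = 1, weight_b = 1, weight_beta = 2,
                      learn_rate = 1e-3, max_descent_steps = 10,
                      em_tol = 1e-3, em_max_iter = 100,
                      update_translation = TRUE, eps_s = 1e-3,
                      support_eps = 0.5, seed = NULL) {
  stopifnot(K >= 2, learn_rate > 0, em_tol > 0, em_max_iter >= 1,
            weight_beta > 0, eps_s > 0, support_eps >= 0)
  structure(list(K = as.integer(K), weight_a = weight_a,
                 weight_b = weight_b, weight_beta = weight_beta,
                 learn_rate = learn_rate,
                 max_descent_steps = as.integer(max_descent_steps),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 update_translation = isTRUE(update_translation),
                 eps_s = eps_s, support_eps = support_eps, seed = seed),
            class = "em_config")
}

#' Shifted Rayleigh probability density
#'
#' Density `((x - t) / s^2) exp(-(x - t)^2 / (2 s^2))` for `x > t`, 0
#' otherwise; `s` is the mode (the density peaks at `x = t + s`) and `t`
#' the translation.
#'
#' @param x Intensities.
#' @param mode Rayleigh mode `s > 0`.
#' @param translation Shift `t >= 0`.
#' @param log Return log densities (`-Inf` off support).
#' @export
rayleigh_pdf <- function(x, mode, translation = 0, log = FALSE) {
  stopifnot(mode > 0, translation >= 0)
  d <- x - translation
  if (log) {
    out <- rep(-Inf, length(x))
    ok <- d > 0
    out[ok] <- base::log(d[ok]) - 2 * base::log(mode) - d[ok]^2 / (2 * mode^2)
  } else {
    out <- numeric(length(x))
    ok <- d > 0
    out[ok] <- d[ok] / mode^2 * exp(-d[ok]^2 / (2 * mode^2))
  }
  out
}

## Sample a shifted Rayleigh by inversion.
rrayleigh <- function(n, mode, translation = 0) {
  translation + mode * sqrt(-2 * log(stats::runif(n)))
}

as_pixel_matrix <- function(pixels) {
  if (inherits(pixels, "polar_image") || inherits(pixels, "cartesian_image"))
    return(pixels$pixels)
  if (is.null(dim(pixels))) matrix(pixels, nrow = 1) else as.matrix(pixels)
}

## Truncated-window neighbourhood mean/sum over a 3 x 3 (8-connected)
## window, boundary windows truncated.  Returns list(sum, count, mean).
.nbr_cache <- new.env(parent = emptyenv())

neighborhood_stats <- function(mat, include_center = TRUE) {
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mat
  s <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (!include_center && dr == 0 && dc == 0) next
    s <- s + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  key <- sprintf("%d_%d_%d", nr, nc, include_center)
  n <- .nbr_cache[[key]]
  if (is.null(n)) {           # window sizes depend only on the grid shape
    cnt <- matrix(0, nr + 2, nc + 2)
    cnt[2:(nr + 1), 2:(nc + 1)] <- 1
    n <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (!include_center && dr == 0 && dc == 0) next
      n <- n + cnt[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    }
    .nbr_cache[[key]] <- n
  }
  list(sum = s, count = n, mean = s / n)
}

#' Initialise the Rayleigh mixture
#'
#' K-means on gray intensity (deterministic quantile-seeded centres)
#' gives cluster means `mu_j`; the translation is the cluster minimum and
#' the mode follows from the shifted-Rayleigh mean identity
#' `mu = t + s * sqrt(pi / 2)`, floored at `eps_s`. Pixel priors start
#' uniform at `1/K`.
#'
#' @param pixels Numeric matrix/vector or an image object.
#' @param cfg An [em_config()].
#' @return A list of class `rayleigh_mixture` with `K`, `components`
#'   (data frame of `mode`, `translation`), and `priors` (N x K).
#' @export
init_mixture <- function(pixels, cfg = em_config()) {
  px <- as_pixel_matrix(pixels)
  x <- as.vector(px)
  ux <- unique(x)
  if (length(ux) < cfg$K)
    stop("need at least K distinct gray values to initialise")
  centers <- stats::quantile(x, probs = (seq_len(cfg$K) - 0.5) / cfg$K,
                             names = FALSE)
  if (anyDuplicated(centers))
    centers <- sort(ux)[round(seq(1, length(ux), length.out = cfg$K))]
  km <- suppressWarnings(
    stats::kmeans(x, centers = matrix(centers, ncol = 1), iter.max = 50))
  comp <- lapply(seq_len(cfg$K), function(j) {
    xs <- x[km$cluster == j]
    mu <- mean(xs); tj <- min(xs)
    sj <- max((mu - tj) * sqrt(2 / pi), cfg$eps_s)
    c(mode = sj, translation = tj)
  })
  comp <- as.data.frame(do.call(rbind, comp))
  ord <- order(comp$translation + comp$mode)  # sort by implied mean
  comp <- comp[ord, , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(K = cfg$K, components = comp,
                 priors = matrix(1 / cfg$K, length(x), cfg$K),
                 shape = dim(px)),
            class = "rayleigh_mixture")
}

#' @export
print.rayleigh_mixture <- function(x, ...) {
  cat(sprintf("<rayleigh_mixture> K = %d\n", x$K))
  print(x$components)
  invisible(x)
}

#' Posterior responsibilities (E-step)
#'
#' `gamma_ij = pi_ij p(x_i | theta_j) / sum_k pi_ik p(x_i | theta_k)`,
#' computed in log space; pixels at which every component has zero
#' density get uniform responsibilities.
#'
#' @param pixels Pixel matrix/vector or image object.
#' @param mixture A `rayleigh_mixture`.
#' @return N x K matrix of responsibilities (rows sum to 1).
#' @export
e_step <- function(pixels, mixture) {
  x <- as.vector(as_pixel_matrix(pixels))
  K <- mixture$K
  lp <- vapply(seq_len(K), function(j)
    rayleigh_pdf(x, mixture$components$mode[j],
                 mixture$components$translation[j], log = TRUE),
    numeric(length(x)))
  lp <- lp + log(pmax(mixture$priors, 1e-300))
  mx <- lp[, 1]
  if (K > 1) for (j in 2:K) mx <- pmax(mx, lp[, j])
  dead <- !is.finite(mx)
  mx[dead] <- 0
  w <- exp(lp - mx)
  w[dead, ] <- 1
  w / rowSums(w)
}

## Per-pixel contrast weight exp(-a delta^2 / b): depends only on the image.
pixel_contrast_weight <- function(px, cfg, g_max) {
  xbar <- neighborhood_stats(px)$mean
  delta <- (px - xbar) / g_max
  as.vector(exp(-cfg$weight_a * delta^2 / cfg$weight_b))
}

## Prior-term of the EM surrogate: sum_ij gamma_ij log pi_ij
prior_term <- function(gamma, priors) {
  sum(gamma * log(pmax(priors, 1e-300)))
}

#' Neighbourhood-aware prior update
#'
#' Three-step construction of per-pixel component priors from the current
#' responsibilities: (1) a per-pixel weight discounting pixels whose
#' intensity deviates from their 3 x 3 neighbourhood mean,
#' `w_ij = gamma_ij * exp(-a * delta_i^2 / b)` with
#' `delta_i = (x_i - xbar_i) / g_max`; (2) aggregation of the weights
#' over the neighbourhood, raised to `beta` to control sharpness;
#' (3) normalisation over components. A safeguard blends the result
#' toward the responsibilities just enough that the surrogate's prior
#' term never decreases, keeping the whole loop a generalized EM.
#'
#' @param pixels Pixel matrix/vector or image object.
#' @param gamma N x K responsibilities.
#' @param cfg An [em_config()].
#' @param g_max Gray-level scale of the image (normalises the local
#'   contrast).
#' @param prev_priors Optional previous priors; when given, the
#'   monotonicity safeguard is applied against them.
#' @param pixel_weight Optional precomputed per-pixel contrast weight
#'   (it depends only on the image, so [fit_rmm()] caches it).
#' @return N x K matrix of priors, rows summing to 1.
#' @export
spatial_priors <- function(pixels, gamma, cfg = em_config(), g_max = NULL,
                           prev_priors = NULL, pixel_weight = NULL) {
  px <- as_pixel_matrix(pixels)
  if (is.null(g_max)) g_max <- max(px, 1)
  n <- length(px); K <- ncol(gamma)
  stopifnot(nrow(gamma) == n)
  wpix <- pixel_weight %||% pixel_contrast_weight(px, cfg, g_max)
  w <- gamma * wpix
  W <- matrix(0, n, K)
  for (j in seq_len(K)) {
    st <- neighborhood_stats(matrix(w[, j], nrow(px), ncol(px)))
    W[, j] <- as.vector(st$sum / st$count)
  }
  W <- pmax(W, 1e-300)^cfg$weight_beta
  pri <- W / rowSums(W)
  if (!is.null(prev_priors)) {
    ref <- prior_term(gamma, prev_priors)
    alpha <- 0
    while (prior_term(gamma, pri) < ref - 1e-10 && alpha < 1) {
      alpha <- min(1, alpha + 0.25)
      pri <- (1 - alpha) * pri + alpha * gamma
    }
  }
  pri
}

## Parameter term of the EM surrogate:
## Q(theta) = sum_j sum_{i: x_i > t_j} gamma_ij log p(x_i | s_j, t_j).
## Pixels off a component's support are excluded from that component's sum.
rmm_q_param <- function(x, gamma, modes, translations, support_eps = 0.5) {
  q <- 0
  for (j in seq_along(modes)) {
    d <- x - translations[j]
    ok <- d > support_eps
    if (!any(ok)) next
    dk <- d[ok]; gk <- gamma[ok, j]
    q <- q + sum(gk * log(dk)) - 2 * log(modes[j]) * sum(gk) -
      sum(gk * dk * dk) / (2 * modes[j]^2)
  }
  q
}

## Analytic gradient of rmm_q_param wrt (s_j, t_j), masked consistently.
rmm_q_grad <- function(x, gamma, modes, translations, support_eps = 0.5) {
  K <- length(modes)
  gs <- numeric(K); gt <- numeric(K)
  for (j in seq_len(K)) {
    d <- x - translations[j]
    ok <- d > support_eps
    if (!any(ok)) next
    s <- modes[j]
    gs[j] <- sum(gamma[ok, j] * (-2 / s + d[ok]^2 / s^3))
    gt[j] <- sum(gamma[ok, j] * (-1 / d[ok] + d[ok] / s^2))
  }
  list(mode = gs, translation = gt)
}

#' M-step: steepest-ascent update of the component parameters
#'
#' Gradient ascent `theta <- theta + eta * grad Q` on every mode and
#' (optionally) translation, using the analytic partial derivatives of
#' the surrogate's parameter term. Each step is backtracked (halving
#' `eta`) until the surrogate does not decrease; modes are floored at
#' `eps_s` and translations projected into `[0, min x assigned to the
#' component]`.
#'
#' @param pixels Pixel matrix/vector or image object.
#' @param gamma N x K responsibilities.
#' @param mixture Current `rayleigh_mixture`.
#' @param cfg An [em_config()].
#' @return The mixture with updated `components` and an attribute
#'   `q_trace` of accepted surrogate values.
#' @export
m_step <- function(pixels, gamma, mixture, cfg = em_config()) {
  x <- as.vector(as_pixel_matrix(pixels))
  s <- mixture$components$mode
  t <- mixture$components$translation
  K <- mixture$K
  assign <- max.col(gamma, ties.method = "first")
  tmax <- vapply(seq_len(K), function(j) {
    xs <- x[assign == j]
    if (length(xs)) min(xs) else Inf
  }, numeric(1))
  # pixels with (numerically) zero responsibility for a component
  # contribute nothing to that component\'s Q or gradient
  active <- lapply(seq_len(K), function(j) which(gamma[, j] > 1e-12))
  xs_j <- lapply(active, function(ix) x[ix])
  gs_j <- lapply(seq_len(K), function(j) gamma[active[[j]], j])
  q_of <- function(modes, translations) {
    q <- 0
    for (j in seq_len(K)) {
      d <- xs_j[[j]] - translations[j]
      ok <- d > cfg$support_eps
      if (!any(ok)) next
      dk <- d[ok]; gk <- gs_j[[j]][ok]
      q <- q + sum(gk * log(dk)) - 2 * log(modes[j]) * sum(gk) -
        sum(gk * dk * dk) / (2 * modes[j]^2)
    }
    q
  }
  grad_of <- function(modes, translations) {
    gs <- numeric(K); gt <- numeric(K)
    for (j in seq_len(K)) {
      d <- xs_j[[j]] - translations[j]
      ok <- d > cfg$support_eps
      if (!any(ok)) next
      dk <- d[ok]; gk <- gs_j[[j]][ok]
      sj <- modes[j]
      gs[j] <- -2 / sj * sum(gk) + sum(gk * dk * dk) / sj^3
      gt[j] <- -sum(gk / dk) + sum(gk * dk) / sj^2
    }
    list(mode = gs, translation = gt)
  }
  q_old <- q_of(s, t)
  q_trace <- q_old
  # remember the last accepted step size across calls so backtracking
  # does not restart from scratch every EM iteration
  eta0 <- attr(mixture, "eta_state") %||% cfg$learn_rate
  for (step in seq_len(cfg$max_descent_steps)) {
    g <- grad_of(s, t)
    if (!all(is.finite(g$mode)) || !all(is.finite(g$translation)))
      stop(sprintf("non-finite gradient in component %d",
                   which(!is.finite(g$mode) | !is.finite(g$translation))[1]))
    if (!cfg$update_translation) g$translation[] <- 0
    gn <- sqrt(sum(g$mode^2) + sum(g$translation^2))
    if (gn < 1e-10) break
    eta <- eta0 * 2
    accepted <- FALSE
    for (bt in seq_len(60)) {
      s_new <- pmax(s + eta * g$mode, cfg$eps_s)
      t_new <- pmin(pmax(t + eta * g$translation, 0), tmax)
      q_new <- q_of(s_new, t_new)
      if (is.finite(q_new) && q_new >= q_old - 1e-8) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break
    eta0 <- eta
    if (max(abs(s_new - s), abs(t_new - t)) < 1e-12) { s <- s_new; t <- t_new; break }
    s <- s_new; t <- t_new; q_old <- q_new
    q_trace <- c(q_trace, q_new)
  }
  mixture$components$mode <- s
  mixture$components$translation <- t
  attr(mixture, "q_trace") <- q_trace
  attr(mixture, "eta_state") <- eta0
  mixture
}

#' Fit the Rayleigh mixture by EM
#'
#' Alternates [e_step()], [spatial_priors()] and [m_step()] until the
#' largest absolute change of any mode or translation falls below
#' `em_tol`, or `em_max_iter` is reached. The trace records the
#' (density-floored) observed-data log-likelihood after every iteration.
#'
#' @param pixels Pixel matrix/vector or image object.
#' @param cfg An [em_config()].
#' @param g_max Gray scale for the prior's contrast normalisation
#'   (defaults to the image `g_max` or the data maximum).
#' @return A list of class `rmm_fit`: `mixture`, `gamma`, `trace`
#'   (log-likelihood per iteration), `iterations`, `converged`.
#' @export
fit_rmm <- function(pixels, cfg = em_config(), g_max = NULL) {
  px <- as_pixel_matrix(pixels)
  if (is.null(g_max))
    g_max <- if (inherits(pixels, c("polar_image", "cartesian_image")))
      pixels$g_max else max(px, 1)
  x <- as.vector(px)
  mixture <- init_mixture(px, cfg)
  trace <- numeric(0)
  converged <- FALSE
  gamma <- NULL
  wpix <- pixel_contrast_weight(px, cfg, g_max)
  for (it in seq_len(cfg$em_max_iter)) {
    gamma <- e_step(px, mixture)
    mixture$priors <- spatial_priors(px, gamma, cfg, g_max = g_max,
                                     prev_priors = mixture$priors,
                                     pixel_weight = wpix)
    s_old <- mixture$components$mode
    t_old <- mixture$components$translation
    comps_old <- mixture$components
    mixture <- m_step(px, gamma, mixture, cfg)
    l_prev <- if (length(trace)) trace[length(trace)] else -Inf
    l_now <- rmm_loglik(x, mixture)
    if (l_now < l_prev - 1e-9 * max(1, abs(l_prev))) {
      # the masked surrogate accepted a step that lowers the observed
      # likelihood (support-boundary effect); skip this M-step
      mixture$components <- comps_old
    }
    if (cfg$update_translation) mixture <- extend_support(x, mixture)
    trace <- c(trace, rmm_loglik(x, mixture))
    delta <- max(abs(mixture$components$mode - s_old),
                 abs(mixture$components$translation - t_old))
    if (delta < cfg$em_tol) { converged <- TRUE; break }
  }
  gamma <- e_step(px, mixture)
  structure(list(mixture = mixture, gamma = gamma, trace = trace,
                 iterations = length(trace), converged = converged),
            class = "rmm_fit")
}

## Support-extension step: the masked likelihood cannot pull a
## component's translation below the smallest pixel it currently covers
## (off-support pixels have zero responsibility, so the gradient never
## sees them).  Propose lowering each translation by fractions of the
## mode and keep the best move that raises the observed-data
## log-likelihood: a monotone generalized-EM block.
extend_support <- function(x, mixture, fractions = c(0.05, 0.1, 0.2, 0.4)) {
  K <- mixture$K
  dens <- vapply(seq_len(K), function(j)
    rayleigh_pdf(x, mixture$components$mode[j],
                 mixture$components$translation[j]), numeric(length(x)))
  mix <- rowSums(mixture$priors * dens)
  base <- sum(log(pmax(mix, 1e-300)))
  for (j in seq_len(K)) {
    t0 <- mixture$components$translation[j]
    if (t0 <= 0) next
    best <- base; best_t <- t0; best_dj <- dens[, j]
    for (f in fractions) {
      tc <- max(0, t0 - f * mixture$components$mode[j])
      dj <- rayleigh_pdf(x, mixture$components$mode[j], tc)
      ll <- sum(log(pmax(mix + mixture$priors[, j] * (dj - dens[, j]),
                         1e-300)))
      if (ll > best) { best <- ll; best_t <- tc; best_dj <- dj }
    }
    if (best_t != t0) {
      mix <- mix + mixture$priors[, j] * (best_dj - dens[, j])
      dens[, j] <- best_dj
      mixture$components$translation[j] <- best_t
      base <- best
    }
  }
  mixture
}

## Observed-data log-likelihood with a density floor (keeps pixels that
## sit exactly on a support boundary finite).
rmm_loglik <- function(x, mixture) {
  dens <- rep(0, length(x))
  for (j in seq_len(mixture$K)) {
    dens <- dens + mixture$priors[, j] *
      rayleigh_pdf(x, mixture$components$mode[j],
                   mixture$components$translation[j])
  }
  sum(log(pmax(dens, 1e-300)))
}

#' @export
print.rmm_fit <- function(x, ...) {
  cat(sprintf("<rmm_fit> K = %d, %d iterations, %s\n", x$mixture$K,
              x$iterations,
              if (x$converged) "converged" else "max iterations reached"))
  print(x$mixture$components)
  invisible(x)
}

#' MAP pixel labelling
#'
#' Assigns every pixel to the component with the largest posterior
#' responsibility (ties to the smallest index) and records the mean gray
#' value of each labelled class.
#'
#' @param pixels Pixel matrix/vector or image object.
#' @param gamma N x K responsibilities (e.g. from [fit_rmm()]).
#' @return A list of class `pixel_labeling`: `labels` (matrix shaped
#'   like the input), `class_means` (length K, `NA` for empty classes),
#'   `K`.
#' @export
map_classify <- function(pixels, gamma) {
  px <- as_pixel_matrix(pixels)
  K <- ncol(gamma)
  lab <- max.col(gamma, ties.method = "first")
  means <- vapply(seq_len(K), function(j) {
    xs <- px[lab == j]
    if (length(xs)) mean(xs) else NA_real_
  }, numeric(1))
  structure(list(labels = matrix(lab, nrow(px), ncol(px)),
                 class_means = means, K = K),
            class = "pixel_labeling")
}
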