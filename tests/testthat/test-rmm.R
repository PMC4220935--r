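test_that("shifted Rayleigh density has the right support, mode and mass", {
  expect_equal(rayleigh_pdf(5, mode = 3, translation = 5), 0)
  expect_equal(rayleigh_pdf(4, mode = 3, translation = 5), 0)
  xs <- seq(5, 25, by = 1e-3)
  dens <- rayleigh_pdf(xs, mode = 3, translation = 5)
  expect_equal(xs[which.max(dens)], 5 + 3, tolerance = 1e-2)
  mass <- stats::integrate(rayleigh_pdf, 5, 5 + 20 * 3,
                           mode = 3, translation = 5,
                           rel.tol = 1e-9)$value
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("initialisation follows the Rayleigh mean-mode identity", {
  # two clearly separated value groups; group means/minima known exactly
  x <- c(rep(0, 50), rep(20, 50), rep(100, 60), rep(140, 40))
  mix <- init_mixture(x, em_config(K = 2))
  # cluster 1 = {0,20}: mean 10, min 0 -> s = 10 * sqrt(2/pi)
  expect_equal(mix$components$mode[1], 10 * sqrt(2 / pi), tolerance = 1e-6)
  expect_equal(mix$components$mode[1], 7.9788, tolerance = 1e-4)
  expect_equal(mix$components$translation[1], 0)
  expect_rows_sum_to_one(mix$priors)
  expect_true(all(mix$priors == 0.5))
})

test_that("a degenerate cluster gets the mode floor and K is honoured", {
  x <- c(rep(5, 80), rep(200, 80))
  mix <- init_mixture(x, em_config(K = 2, eps_s = 1e-3))
  expect_equal(mix$components$mode[1], 1e-3)
  set.seed(3)
  mix5 <- init_mixture(runif(5000, 0, 255), em_config())
  expect_equal(mix5$K, 5L)
  expect_equal(nrow(mix5$components), 5L)
  expect_error(init_mixture(rep(c(1, 2), 50), em_config(K = 5)), "distinct")
})

test_that("spatial priors are uniform under full symmetry and always normalised", {
  px <- matrix(42, 10, 10)
  gam <- matrix(1 / 3, 100, 3)
  pri <- spatial_priors(px, gam, em_config(K = 3), g_max = 255)
  expect_true(all(abs(pri - 1 / 3) < 1e-12))
  set.seed(4)
  px2 <- matrix(runif(60, 0, 255), 6, 10)
  gam2 <- matrix(runif(180), 60, 3)
  gam2 <- gam2 / rowSums(gam2)
  pri2 <- spatial_priors(px2, gam2, em_config(K = 3), g_max = 255)
  expect_rows_sum_to_one(pri2)
  expect_true(all(pri2 >= 0))
})

test_that("two-pixel prior construction matches hand evaluation", {
  # 1 x 2 image; neighbourhood of each pixel is both pixels
  px <- matrix(c(100, 160), 1, 2)
  gam <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  cfg <- em_config(K = 2, weight_a = 1, weight_b = 1, weight_beta = 2)
  g_max <- 200
  xbar <- c(130, 130)
  w <- gam * exp(-((c(100, 160) - xbar) / g_max)^2)   # step 1
  W <- rbind(colMeans(w), colMeans(w))^2              # step 2 (beta = 2)
  byhand <- W / rowSums(W)                            # step 3
  got <- spatial_priors(px, gam, cfg, g_max = g_max)
  expect_equal(got, byhand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("responsibilities follow Bayes' rule", {
  x <- c(10, 80)
  mix <- structure(list(
    K = 2,
    components = data.frame(mode = c(8, 20), translation = c(0, 60)),
    priors = matrix(0.5, 2, 2)), class = "rayleigh_mixture")
  gam <- e_step(x, mix)
  expect_rows_sum_to_one(gam)
  expect_gt(gam[1, 1], 0.99)      # pixel at first component's mode
  expect_gt(gam[2, 2], 0.99)
  mix1 <- structure(list(
    K = 1, components = data.frame(mode = 10, translation = 0),
    priors = matrix(1, 5, 1)), class = "rayleigh_mixture")
  expect_true(all(e_step(c(1, 5, 9, 14, 40), mix1) == 1))
})

test_that("pixels off every support get uniform responsibilities", {
  mix <- structure(list(
    K = 2,
    components = data.frame(mode = c(5, 5), translation = c(50, 80)),
    priors = matrix(0.5, 2, 2)), class = "rayleigh_mixture")
  gam <- e_step(c(10, 55), mix)
  expect_equal(gam[1, ], c(0.5, 0.5))
})

test_that("analytic M-step gradient matches central finite differences", {
  set.seed(5)
  for (i in 1:20) {
    n <- 60
    x <- runif(n, 30, 250)
    K <- sample(2:3, 1)
    gam <- matrix(runif(n * K), n, K)
    gam <- gam / rowSums(gam)
    s <- runif(K, 5, 40)
    t <- runif(K, 0, 20)           # well below min(x): stable mask
    g <- ivuscalc:::rmm_q_grad(x, gam, s, t)
    h <- 1e-5
    for (j in 1:K) {
      sp <- s; sm <- s; sp[j] <- s[j] + h; sm[j] <- s[j] - h
      fd_s <- (ivuscalc:::rmm_q_param(x, gam, sp, t) -
                 ivuscalc:::rmm_q_param(x, gam, sm, t)) / (2 * h)
      expect_equal(g$mode[j], fd_s, tolerance = 1e-4)
      tp <- t; tm <- t; tp[j] <- t[j] + h; tm[j] <- t[j] - h
      fd_t <- (ivuscalc:::rmm_q_param(x, gam, s, tp) -
                 ivuscalc:::rmm_q_param(x, gam, s, tm)) / (2 * h)
      expect_equal(g$translation[j], fd_t, tolerance = 1e-4)
    }
  }
})

test_that("the M-step surrogate never decreases and stalls at a stationary point", {
  set.seed(6)
  n <- 2000
  x <- ivuscalc:::rrayleigh(n, mode = 20, translation = 10)
  gam <- matrix(1, n, 1)
  # start at the maximum-likelihood mode for fixed t: gradient ~ 0
  s_hat <- sqrt(sum((x - 10)^2) / (2 * n))
  mix <- structure(list(
    K = 1, components = data.frame(mode = s_hat, translation = 10),
    priors = matrix(1, n, 1)), class = "rayleigh_mixture")
  cfg <- em_config(K = 2, update_translation = FALSE)
  cfg$K <- 1L
  out <- m_step(x, gam, mix, cfg)
  expect_lt(abs(out$components$mode - s_hat), 0.05)
  qt <- attr(out, "q_trace")
  expect_true(all(diff(qt) >= -1e-8))
  # far from the optimum the surrogate strictly improves
  mix$components$mode <- s_hat * 3
  out2 <- m_step(x, gam, mix, cfg)
  qt2 <- attr(out2, "q_trace")
  expect_true(all(diff(qt2) >= -1e-8))
  expect_gt(max(qt2), qt2[1])
})

test_that("EM recovers a three-component shifted Rayleigh mixture", {
  set.seed(7)
  x <- c(ivuscalc:::rrayleigh(3000, 15, 0),
         ivuscalc:::rrayleigh(3000, 60, 20),
         ivuscalc:::rrayleigh(3000, 140, 80))
  fit <- fit_rmm(x, em_config(K = 3))
  comp <- fit$mixture$components
  ord <- order(comp$translation + comp$mode * sqrt(pi / 2))
  err <- abs(comp$mode[ord] - c(15, 60, 140)) / c(15, 60, 140)
  expect_lte(median(err), 0.10)
  rel <- diff(fit$trace) / pmax(1, abs(fit$trace[-length(fit$trace)]))
  expect_true(all(rel >= -1e-6))
})

test_that("a two-level phantom is split into classes straddling the levels", {
  set.seed(8)
  px <- matrix(ivuscalc:::rrayleigh(4000, 12, 0), 50, 80)
  px[20:35, ] <- ivuscalc:::rrayleigh(16 * 80, 40, 120)
  fit <- fit_rmm(px, em_config())
  lab <- map_classify(px, fit$gamma)
  bright <- which(lab$class_means > 80)
  dark <- which(lab$class_means <= 80)
  in_band <- lab$labels[20:35, ]
  out_band <- lab$labels[c(1:19, 36:50), ]
  acc <- (sum(in_band %in% bright) + sum(out_band %in% dark)) /
    length(px)
  expect_gte(acc, 0.95)
})

test_that("MAP labelling takes the row argmax with ties to the first class", {
  gam <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0), c(1 / 3, 1 / 3, 1 / 3))
  lab <- map_classify(c(10, 20, 30), gam)
  expect_equal(as.vector(lab$labels), c(2, 1, 1))
  set.seed(9)
  gam2 <- matrix(runif(400), 100, 4)
  gam2 <- gam2 / rowSums(gam2)
  lab2 <- map_classify(runif(100), gam2)
  expect_equal(as.vector(lab2$labels), apply(gam2, 1, which.max))
  expect_true(all(is.finite(lab2$class_means[unique(as.vector(lab2$labels))])))
})

test_that("spatial smoothing keeps an isolated flipped pixel with its region", {
  # bright region speckle with one pixel whose intensity favours the
  # dark class on likelihood alone; the neighbourhood-aggregated prior
  # must keep it with its region
  mix <- structure(list(
    K = 2,
    components = data.frame(mode = c(15, 35), translation = c(10, 40)),
    priors = matrix(0.5, 81, 2)), class = "rayleigh_mixture")
  px <- matrix(90, 9, 9)
  px[5, 5] <- 45          # p_dark(45) > p_bright(45), ratio ~ 2.5
  g1 <- e_step(px, mix)
  expect_equal(which.max(g1[41, ]), 1L)      # flat prior: dark wins
  cfg <- em_config(K = 2)
  pri <- spatial_priors(px, g1, cfg, g_max = 255)
  mix$priors <- pri
  g2 <- e_step(px, mix)
  expect_equal(which.max(g2[41, ]), 2L)      # smoothed prior: region wins
})
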