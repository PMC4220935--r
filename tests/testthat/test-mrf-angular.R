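make_labeling <- function(labels, means = NULL) {
  K <- max(labels)
  if (is.null(means))
    means <- vapply(seq_len(K), function(j) mean(labels[labels == j]) * 10,
                    numeric(1))
  structure(list(labels = labels, class_means = means, K = K),
            class = "pixel_labeling")
}

test_that("dark region mask covers the two lowest-mean classes", {
  lab <- matrix(3L, 12, 6)
  lab[1:4, ] <- 1L              # lumen-like
  lab[9:12, 3:4] <- 2L          # shadow wedge below the MIC
  lbl <- make_labeling(lab, means = c(15, 6, 80))
  mic <- structure(rep(6L, 6), class = "mic_curve")
  dark <- extract_dark_region(lbl, mic, dark_run = 3)
  expect_setequal(dark$dark_classes, c(1, 2))
  expect_equal(dark$upper_border[3:4], c(9L, 9L))
  expect_equal(dark$upper_border[c(1, 2, 5, 6)], rep(12L, 4))
})

test_that("dark region everywhere below the MIC gives u = m + 1", {
  lab <- matrix(1L, 10, 4)
  lab[1:3, ] <- 2L; lab[4, ] <- 3L
  lbl <- make_labeling(lab, means = c(5, 20, 200))
  mic <- structure(rep(4L, 4), class = "mic_curve")
  dark <- extract_dark_region(lbl, mic)
  expect_true(all(dark$upper_border == 5L))
})

test_that("a single dark speckle pixel does not anchor the border", {
  lab <- matrix(3L, 20, 2)
  lab[1:2, ] <- 1L; lab[3, ] <- 2L
  lab[8, 1] <- 1L                       # isolated outlier below MIC
  lab[15:20, 1] <- 1L                   # the true dark region
  lbl <- make_labeling(lab, means = c(5, 12, 90))
  mic <- structure(rep(3L, 2), class = "mic_curve")
  expect_equal(extract_dark_region(lbl, mic, dark_run = 3)$upper_border,
               c(15L, 20L))
  expect_equal(extract_dark_region(lbl, mic, dark_run = 1)$upper_border,
               c(8L, 20L))
})

test_that("degenerate labelings are rejected", {
  lab <- matrix(1L, 8, 4); lab[1, 1] <- 2L
  lbl <- make_labeling(lab, means = c(10, 20))
  mic <- structure(rep(2L, 4), class = "mic_curve")
  expect_error(extract_dark_region(lbl, mic), "degenerate")
})

test_that("column factors match hand computation on a small grid", {
  px <- matrix(c(
    10, 10, 10, 10,
    90, 80, 90, 80,
    40, 60,  5, 70,
    30, 50,  5, 60,
     5, 40,  5, 50,
     5, 30,  5,  5,
     5, 20,  5,  5,
     5,  5,  5,  5), 8, 4, byrow = TRUE)
  pol <- polar_image(px, g_max = 100)
  mic <- structure(rep(2L, 4), class = "mic_curve")
  dark <- list(upper_border = c(5L, 8L, 3L, 6L))
  f <- column_factors(pol, mic, dark)
  expect_equal(f$f1, 8 - c(5, 8, 3, 6))
  expect_equal(f$f2, c(3, 6, 1, 4))
  expect_equal(f$f3, c(mean(c(40, 30)), mean(c(60, 50, 40, 30, 20)),
                       0, mean(c(70, 60, 50))))
  expect_true(all(f$f1 + dark$upper_border == 8))
})

test_that("u = m + 1 yields f2 = 1 and an empty bright interval", {
  pol <- polar_image(matrix(50, 10, 4), g_max = 255)
  mic <- structure(rep(4L, 4), class = "mic_curve")
  f <- column_factors(pol, mic, list(upper_border = rep(5L, 4)))
  expect_true(all(f$f2 == 1))
  expect_true(all(f$f3 == 0))
})

test_that("column prior favours shadow-like columns", {
  fac <- data.frame(f1 = c(100, 100, 10), f2 = c(3, 3, 40),
                    f3 = c(10, 10, 180))
  p <- column_prior(fac, n_r = 128, g_max = 255)
  expect_equal(p[1], p[2])              # identical factors, identical p
  expect_gt(p[1], p[3])                 # shadow beats bright floor
  expect_true(all(p > 0 & p < 1))
  p0 <- column_prior(fac, 128, 255, lambda = c(0, 0, 0))
  expect_true(all(p0 == 0.5))
})

test_that("belief propagation on chains equals exhaustive enumeration", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    ev <- matrix(runif(2 * n, 0.1, 1), n, 2)
    q <- runif(1, 0.55, 0.9)
    psi <- matrix(c(q, 1 - q, 1 - q, q), 2, 2)
    field <- run_bp(ev, psi, topology = "chain", eps = 1e-12,
                    max_iter = 2000, damping = 0)
    exact <- enumerate_marginals(ev, psi, "chain")
    expect_lt(max(abs(field$beliefs - exact)), 1e-6)
  }
})

test_that("uninformative compatibility decouples the chain", {
  ev <- cbind(c(0.9, 0.2, 0.6), c(0.1, 0.8, 0.4))
  psi <- matrix(0.5, 2, 2)
  field <- run_bp(ev, psi, topology = "chain", eps = 1e-10, max_iter = 500)
  expect_equal(field$beliefs, ev / rowSums(ev), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("symmetric evidence yields symmetric beliefs on the ring", {
  ev <- matrix(0.5, 10, 2)
  field <- run_bp(ev, eps = 1e-10)
  expect_true(all(abs(field$beliefs - 0.5) < 1e-9))
  expect_rows_sum_to_one(field$beliefs, tol = 1e-12)
})

test_that("raising a column's evidence never lowers its belief", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    p <- runif(n, 0.1, 0.9)
    ev <- cbind(p, 1 - p)
    j <- sample(n, 1)
    b0 <- run_bp(ev, eps = 1e-10, max_iter = 2000)$beliefs[j, 1]
    ev2 <- ev
    ev2[j, 1] <- min(ev2[j, 1] * 1.5, 0.99)
    b1 <- run_bp(ev2, eps = 1e-10, max_iter = 2000)$beliefs[j, 1]
    expect_gte(b1, b0 - 1e-9)
  }
})

test_that("binarisation groups runs into angular segments", {
  segs <- segments_from_binary(c(0, 1, 1, 1, 0, 0, 1, 0))
  expect_length(segs, 2)
  expect_equal(c(segs[[1]]$c_l, segs[[1]]$c_r), c(2L, 4L))
  expect_equal(c(segs[[2]]$c_l, segs[[2]]$c_r), c(7L, 7L))
  wrap <- segments_from_binary(c(1, 1, 0, 0, 0, 0, 0, 1))
  expect_length(wrap, 1)
  expect_true(wrap[[1]]$wraps)
  expect_equal(c(wrap[[1]]$c_l, wrap[[1]]$c_r), c(8L, 2L))
  expect_equal(wrap[[1]]$length, 3L)
  expect_equal(segment_columns(wrap[[1]]), c(8L, 1L, 2L))
  expect_warning(full <- segments_from_binary(rep(1, 6)), "full-circle")
  expect_equal(full[[1]]$length, 6L)
  expect_length(segments_from_binary(rep(0, 6)), 0)
})

test_that("segment extraction agrees with a brute-force run scanner", {
  set.seed(13)
  for (i in 1:100) {
    z <- sample(0:1, 30, TRUE)
    segs <- segments_from_binary(z, wrap = FALSE)
    runs <- scan_runs(z)
    expect_length(segs, length(runs))
    for (k in seq_along(runs))
      expect_equal(c(segs[[k]]$c_l, segs[[k]]$c_r), as.integer(runs[[k]]))
  }
})

test_that("beliefs stay normalised through the iterations", {
  set.seed(14)
  p <- runif(40, 0.05, 0.95)
  field <- run_bp(cbind(p, 1 - p), eps = 1e-9, max_iter = 3000)
  expect_rows_sum_to_one(field$beliefs, tol = 1e-12)
  expect_true(field$converged)
})
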