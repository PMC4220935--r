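#' Full run configuration
#'
#' Collects every tunable of the detection pipeline: polar sampling, the
#' EM mixture settings, the angular-field weights, the refinement
#' thresholds and the border-tracing parameters. Round-trips losslessly
#' through YAML ([write_config()] / [read_config()]).
#'
#' @param n_r,n_c Polar sampling (radius rows, angle columns) used when
#'   the input is a Cartesian frame.
#' @param ringdown_rows Leading radius rows excluded from the MIC and
#'   the upper border search.
#' @param em An [em_config()].
#' @param lambda Length-3 weights of the column-prior factors.
#' @param gain Logistic gain of the column prior.
#' @param q Agreement probability of the pairwise compatibility.
#' @param damping Belief-propagation message damping.
#' @param bp_eps,bp_max_iter Belief-propagation convergence controls.
#' @param belief_threshold Binarisation threshold on the +1 belief.
#' @param topology `"ring"` or `"chain"` column neighbourhood.
#' @param dark_run Minimum consecutive dark rows anchoring the dark
#'   region border (see [extract_dark_region()]).
#' @param constraints A [constraint_config()].
#' @param step_max Maximum row step of the border path.
#' @param smooth_sigma Radial Gaussian sigma before differencing.
#' @param h_sub Depth of the trailing-border subregion (rows).
#' @param pixel_size_mm Pixel spacing when the input format has none.
#' @param seed Master seed (threads to the phantom generator; the
#'   detector itself is deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_r = 256, n_c = 360, ringdown_rows = 8,
                       em = em_config(), lambda = c(1, 1, 0.5), gain = 6,
                       q = 0.7, damping = 0.5, bp_eps = 0.001,
                       bp_max_iter = 500, belief_threshold = 0.5,
                       topology = "ring", dark_run = 4,
                       constraints = constraint_config(), step_max = 1,
                       smooth_sigma = 1, h_sub = 15, pixel_size_mm = 0.02,
                       seed = 1) {
  structure(list(n_r = n_r, n_c = n_c, ringdown_rows = ringdown_rows,
                 em = em, lambda = lambda, gain = gain, q = q,
                 damping = damping, bp_eps = bp_eps,
                 bp_max_iter = bp_max_iter,
                 belief_threshold = belief_threshold, topology = topology,
                 dark_run = dark_run,
                 constraints = constraints, step_max = step_max,
                 smooth_sigma = smooth_sigma, h_sub = h_sub,
                 pixel_size_mm = pixel_size_mm, seed = seed),
            class = "run_config")
}

#' Detect calcified plaque in one frame
#'
#' Runs the full coarse-to-fine pipeline: Rayleigh-mixture pixel
#' classification, polar transform and MIC, belief propagation over the
#' angular columns, five-constraint refinement, and minimal-cost border
#' tracing of every accepted candidate.
#'
#' A Cartesian frame is classified in the Cartesian domain and the label
#' image transformed to polar with nearest-neighbour sampling; a polar
#' frame is classified directly on the polar grid.
#'
#' @param frame A [cartesian_image()] or [polar_image()].
#' @param config A [run_config()].
#' @return A list of class `ivus_detection`: `status` (`"found"` or
#'   `"none"`), `plaques` (accepted candidates, each with `contour` and
#'   `measurements`), `candidates` (all, with constraint flags),
#'   `diagnostics` (per-column data frame), plus the intermediate
#'   `polar`, `mic`, `labeling`, `dark`.
#' @export
detect_frame <- function(frame, config = run_config()) {
  if (inherits(frame, "cartesian_image")) {
    fit <- fit_rmm(frame, config$em)
    labels_cart <- map_classify(frame, fit$gamma)
    polar <- to_polar(frame, config$n_r, config$n_c)
    lab_img <- cartesian_image(labels_cart$labels, center = frame$center,
                               pixel_size_mm = frame$pixel_size_mm,
                               g_max = max(labels_cart$labels))
    lab_polar <- to_polar(lab_img, config$n_r, config$n_c,
                          interp = "nearest")
    labeling <- relabel_polar(lab_polar$pixels, polar$pixels,
                              labels_cart$K)
  } else if (inherits(frame, "polar_image")) {
    polar <- frame
    fit <- fit_rmm(polar, config$em)
    labeling <- map_classify(polar, fit$gamma)
  } else stop("frame must be a cartesian_image or polar_image")

  mic <- compute_mic(polar, config$ringdown_rows)
  dark <- extract_dark_region(labeling, mic, config$dark_run)
  factors <- column_factors(polar, mic, dark)
  p <- column_prior(factors, nrow(polar$pixels), polar$g_max,
                    config$lambda, config$gain)
  compat <- matrix(c(config$q, 1 - config$q, 1 - config$q, config$q), 2, 2)
  field <- run_bp(cbind(p, 1 - p), compat, topology = config$topology,
                  eps = config$bp_eps, max_iter = config$bp_max_iter,
                  damping = config$damping)
  segments <- binarize_segments(field, config$belief_threshold,
                                wrap = config$topology == "ring")
  ref <- refine_candidates(segments, polar, mic, dark, config$constraints)
  plaques <- lapply(ref$accepted, function(cand) {
    seg <- cand$segment
    ug <- upper_cost(polar, mic, seg, config$smooth_sigma,
                     config$ringdown_rows)
    r_star <- cand$stats$r_star %||%
      max(as.integer(mic[seg$c_l]), as.integer(mic[seg$c_r]))
    lg <- lower_cost(polar, mic, seg, r_star, config$h_sub,
                     config$smooth_sigma)
    contour <- assemble_contour(min_cost_path(ug, config$step_max),
                                min_cost_path(lg, config$step_max),
                                seg, polar)
    cand$contour <- contour
    cand$measurements <- measure_plaque(contour, polar)
    cand
  })
  diagnostics <- data.frame(column = seq_len(ncol(polar$pixels)),
                            angle_deg = (seq_len(ncol(polar$pixels)) - 1) *
                              polar$dtheta_deg,
                            mic = as.integer(mic),
                            factors, prior = p,
                            belief_plaque = field$beliefs[, 1],
                            label = as.integer(field$beliefs[, 1] >=
                                                 config$belief_threshold))
  structure(list(status = if (length(plaques)) "found" else "none",
                 plaques = plaques, candidates = ref$candidates,
                 diagnostics = diagnostics, polar = polar, mic = mic,
                 labeling = labeling, dark = dark, field = field),
            class = "ivus_detection")
}

## Map a nearest-resampled polar label image back into a pixel_labeling
## (class means recomputed over the polar intensity image).
relabel_polar <- function(lab_polar, intens_polar, K) {
  lab <- round(lab_polar)
  lab[lab < 1] <- 1
  means <- vapply(seq_len(K), function(j) {
    xs <- intens_polar[lab == j]
    if (length(xs)) mean(xs) else NA_real_
  }, numeric(1))
  structure(list(labels = lab, class_means = means, K = K),
            class = "pixel_labeling")
}

#' @export
print.ivus_detection <- function(x, ...) {
  cat(sprintf("<ivus_detection> status: %s, %d accepted / %d candidate segment(s)\n",
              x$status, length(x$plaques), length(x$candidates)))
  for (p in x$plaques) {
    cat(sprintf("  columns %d..%d  AL %.1f deg, AC %.1f deg, PA %.4f mm^2, PT %.4f mm, DC %.4f mm\n",
                p$segment$c_l, p$segment$c_r, p$measurements$AL,
                p$measurements$AC, p$measurements$PA, p$measurements$PT,
                p$measurements$DC))
  }
  invisible(x)
}

#' Detection mask on the polar grid
#'
#' Union of the rasterised contours of all accepted plaques.
#'
#' @param detection An `ivus_detection`.
#' @return Binary matrix of the polar grid.
#' @export
detection_mask <- function(detection) {
  n_r <- nrow(detection$polar$pixels); n_c <- ncol(detection$polar$pixels)
  mask <- matrix(0L, n_r, n_c)
  for (p in detection$plaques)
    mask <- pmax(mask, contour_mask(p$contour, n_r, n_c))
  mask
}

#' Evaluate detections against phantom ground truth
#'
#' Frame-level confusion (plaque present / absent), pixel-level overlap
#' on true-positive frames, border localisation errors, and regression
#' plus Bland-Altman agreement of the five measurements against truth.
#'
#' @param detections List of `ivus_detection` results.
#' @param phantoms Matching list of `phantom` objects.
#' @return A list of class `suite_evaluation`.
#' @export
evaluate_suite <- function(detections, phantoms) {
  stopifnot(length(detections) == length(phantoms))
  frame <- list(TP = 0, FP = 0, TN = 0, FN = 0)
  pix <- list(TP = 0, FP = 0, TN = 0, FN = 0)
  lead_err <- c(); trail_err <- c()
  meas_auto <- NULL; meas_true <- NULL
  distractor_frames <- 0L; distractor_rejected <- 0L
  for (i in seq_along(detections)) {
    det <- detections[[i]]; truth <- phantoms[[i]]$truth
    found <- det$status == "found"
    if (truth$has_plaque) {
      if (found) {
        frame$TP <- frame$TP + 1
        ov <- pixel_overlap(detection_mask(det), truth$plaque_mask)
        for (k in names(pix)) pix[[k]] <- pix[[k]] + ov[[k]]
        best <- det$plaques[[which.max(vapply(det$plaques, function(p)
          p$segment$length, numeric(1)))]]
        lead_err <- c(lead_err,
                      mean(best$contour$upper$rows) - truth$leading_row)
        trail_err <- c(trail_err,
                       mean(best$contour$lower$rows) - truth$trailing_row)
        meas_auto <- rbind(meas_auto, best$measurements)
        meas_true <- rbind(meas_true, truth$measurements)
      } else frame$FN <- frame$FN + 1
    } else {
      if (length(truth$distractor_masks)) {
        distractor_frames <- distractor_frames + 1L
        if (!found) distractor_rejected <- distractor_rejected + 1L
      }
      if (found) frame$FP <- frame$FP + 1 else frame$TN <- frame$TN + 1
    }
  }
  agreement <- NULL
  if (!is.null(meas_auto) && nrow(meas_auto) >= 3) {
    agreement <- lapply(names(meas_auto), function(v) {
      x <- meas_auto[[v]]; y <- meas_true[[v]]
      list(regression = tryCatch(fit_regression(x, y),
                                 error = function(e) NULL),
           bland_altman = bland_altman(x, y))
    })
    names(agreement) <- names(meas_auto)
  }
  structure(list(frame_counts = frame,
                 frame_rates = sens_spec(frame),
                 pixel_counts = pix,
                 pixel_rates = if (pix$TP + pix$FN > 0) sens_spec(pix),
                 leading_err_rows = lead_err,
                 trailing_err_rows = trail_err,
                 distractor_frames = distractor_frames,
                 distractor_rejected = distractor_rejected,
                 measurements_auto = meas_auto,
                 measurements_true = meas_true,
                 agreement = agreement),
            class = "suite_evaluation")
}

#' @export
print.suite_evaluation <- function(x, ...) {
  cat(sprintf("<suite_evaluation> frame sens %.3f spec %.3f",
              x$frame_rates$sensitivity, x$frame_rates$specificity))
  if (!is.null(x$pixel_rates))
    cat(sprintf(", pixel sens %.3f spec %.3f",
                x$pixel_rates$sensitivity, x$pixel_rates$specificity))
  cat(sprintf("\n  distractor-only frames rejected: %d / %d\n",
              x$distractor_rejected, x$distractor_frames))
  invisible(x)
}
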