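#' Read a grayscale frame from PNG or TIFF
#'
#' 8- and 16-bit grayscale images are preserved (`g_max` set to the
#' format's full scale); RGB input is converted by channel-mean
#' luminance with a warning. Pixel spacing comes from `pixel_size_mm`
#' since neither format carries calibrated spacing.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param center Optional catheter centre `(row, col)`; defaults to the
#'   frame centre.
#' @param pixel_size_mm Physical pixel size in mm.
#' @return A [cartesian_image()].
#' @export
read_frame <- function(path, center = NULL, pixel_size_mm = 0.02) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    g_max <- 255          # readPNG rescales to [0,1]; 16-bit kept below
    attr_depth <- attr(arr, "bit.depth")
    if (!is.null(attr_depth) && attr_depth == 16) g_max <- 65535
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    arr <- tiff::readTIFF(path)
    g_max <- 255
  } else stop(sprintf("unsupported format '%s' (PNG/TIFF supported)", ext))
  if (length(dim(arr)) == 3) {
    warning("color input converted to grayscale by channel mean")
    arr <- apply(arr[, , 1:min(3, dim(arr)[3]), drop = FALSE], c(1, 2), mean)
  }
  cartesian_image(round(arr * g_max), center = center,
                  pixel_size_mm = pixel_size_mm, g_max = g_max)
}

#' Write a grayscale image or binary mask as PNG
#'
#' @param pixels Matrix of intensities, or an image object.
#' @param path Output path.
#' @param g_max Scale used to normalise intensities (default: the image
#'   `g_max` or the matrix maximum).
#' @export
write_frame_png <- function(pixels, path, g_max = NULL) {
  if (inherits(pixels, c("cartesian_image", "polar_image"))) {
    g_max <- g_max %||% pixels$g_max
    pixels <- pixels$pixels
  }
  g_max <- g_max %||% max(pixels, 1)
  png::writePNG(pmin(pmax(pixels / g_max, 0), 1), path)
  invisible(path)
}

#' Serialise / restore a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  em_args <- y$em[!vapply(y$em, is.null, logical(1))]
  cons_args <- y$constraints
  y$em <- NULL; y$constraints <- NULL
  for (k in names(y)) cfg[[k]] <- y[[k]]
  cfg$em <- do.call(em_config, em_args)
  cfg$constraints <- do.call(constraint_config, cons_args)
  cfg
}

#' Write the outputs of one detection
#'
#' Emits, per frame: the contour(s) as JSON (polar and Cartesian point
#' lists plus measurements), the detection mask as PNG, a one-row
#' measurements CSV and the per-column diagnostics CSV. All coordinates
#' are 1-based; angles are also given in degrees. Outputs are
#' byte-deterministic for identical inputs.
#'
#' @param detection An `ivus_detection`.
#' @param out_dir Output directory (created if needed).
#' @param stem File-name stem (default `"frame"`).
#' @return Invisibly, the list of files written.
#' @export
write_detection <- function(detection, out_dir, stem = "frame") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  status <- list(status = detection$status,
                 n_candidates = length(detection$candidates),
                 n_accepted = length(detection$plaques))
  contours <- lapply(detection$plaques, function(p) list(
    c_l = p$segment$c_l, c_r = p$segment$c_r, wraps = p$segment$wraps,
    upper_rows = p$contour$upper$rows, lower_rows = p$contour$lower$rows,
    columns = p$contour$upper$cols,
    angles_deg = (p$contour$upper$cols - 1) * detection$polar$dtheta_deg,
    polygon_polar = unname(apply(p$contour$polygon_polar, 1, as.numeric,
                                 simplify = FALSE)),
    polygon_cart = unname(apply(p$contour$polygon_cart, 1, as.numeric,
                                simplify = FALSE)),
    measurements = as.list(p$measurements)))
  json_path <- file.path(out_dir, paste0(stem, "_contours.json"))
  jsonlite::write_json(list(status = status, plaques = contours),
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, json_path)
  mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
  write_frame_png(detection_mask(detection), mask_path, g_max = 1)
  files <- c(files, mask_path)
  meas <- do.call(rbind, lapply(detection$plaques, `[[`, "measurements"))
  csv_path <- file.path(out_dir, paste0(stem, "_measurements.csv"))
  if (is.null(meas))
    meas <- data.frame(AL = numeric(0), AC = numeric(0), PA = numeric(0),
                       PT = numeric(0), DC = numeric(0))
  utils::write.csv(meas, csv_path, row.names = FALSE)
  files <- c(files, csv_path)
  diag_path <- file.path(out_dir, paste0(stem, "_columns.csv"))
  utils::write.csv(detection$diagnostics, diag_path, row.names = FALSE)
  files <- c(files, diag_path)
  invisible(files)
}

#' Run the detector over a directory or list of frames
#'
#' @param inputs Either a character vector of image paths, a directory
#'   containing PNG/TIFF frames, or a list of image objects.
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given,
#'   [write_detection()] runs per frame and a `summary.csv` is written.
#' @return List of `ivus_detection` (failed frames carry class
#'   `ivus_detection_error`).
#' @export
detect_frames <- function(inputs, config = run_config(), out_dir = NULL) {
  if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE)
  if (is.character(inputs)) {
    names <- tools::file_path_sans_ext(basename(inputs))
    inputs <- lapply(inputs, read_frame,
                     pixel_size_mm = config$pixel_size_mm)
  } else {
    names <- sprintf("frame%03d", seq_along(inputs))
  }
  out <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    out[[i]] <- tryCatch(detect_frame(inputs[[i]], config),
                         error = function(e)
                           structure(list(status = "failed",
                                          message = conditionMessage(e)),
                                     class = c("ivus_detection_error",
                                               "ivus_detection")))
    if (!is.null(out_dir) && out[[i]]$status != "failed")
      write_detection(out[[i]], out_dir, names[i])
  }
  if (!is.null(out_dir)) {
    summary <- data.frame(
      frame = names,
      status = vapply(out, `[[`, "", "status"),
      n_plaques = vapply(out, function(d)
        length(d$plaques %||% list()), integer(1)))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}
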