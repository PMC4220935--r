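#' Specification of a synthetic IVUS speckle phantom
#'
#' Describes a polar-domain phantom of a circular vessel: Rayleigh
#' speckle per tissue class (blood-filled lumen, vessel wall,
#' adventitia), optionally a bright calcified arc lying along the wall
#' with a dark rectangle-like acoustic shadow radially behind it, and
#' optional bright distractors that a correct detector must reject.
#'
#' Tissue levels are `(translation, mode)` pairs of the shifted Rayleigh
#' speckle model on a 0..255 gray scale; defaults emulate weak blood
#' speckle, a near-black shadow, mid-gray adventitia, a brighter wall
#' ring and a strongly echogenic calcium arc.
#'
#' @param n_r,n_c Polar grid size (radius rows, angle columns).
#' @param wall_row Leading row of the vessel wall ring.
#' @param wall_thickness Wall ring thickness in rows.
#' @param plaque Either `NULL` (control frame) or a list with `c1`, `c2`
#'   (angle columns, inclusive, may wrap), `r0` (leading row) and
#'   `thickness` (rows).
#' @param levels Named list of `(translation, mode)` pairs for `lumen`,
#'   `wall`, `adventitia`, `plaque`, `shadow`.
#' @param distractors List of distractor descriptors, each a list with
#'   `type` in `no_shadow_arc`, `guidewire`, `long_ring` and optional
#'   placement fields (`c1`, `c2`, `r0`, `thickness`).
#' @param g_max Gray scale (default 255).
#' @param pixel_size_mm Physical size of one Cartesian pixel (default
#'   0.02 mm, a 10 mm imaging diameter at 512 px would give 0.02).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_r = 128, n_c = 180, wall_row = 56,
                         wall_thickness = 18, plaque = NULL,
                         levels = NULL, distractors = list(),
                         g_max = 255, pixel_size_mm = 0.02, seed = 1) {
  default_levels <- list(lumen = c(10, 15), wall = c(40, 35),
                         adventitia = c(25, 25), plaque = c(120, 40),
                         shadow = c(0, 5))
  if (!is.null(levels)) default_levels[names(levels)] <- levels
  levels <- default_levels
  stopifnot(levels$plaque[1] + levels$plaque[2] >
              levels$wall[1] + levels$wall[2],
            levels$wall[1] + levels$wall[2] >
              levels$shadow[1] + levels$shadow[2])
  if (!is.null(plaque)) {
    stopifnot(plaque$c1 >= 1, plaque$c1 <= n_c, plaque$c2 >= 1,
              plaque$c2 <= n_c, plaque$r0 >= 2,
              plaque$r0 + plaque$thickness < n_r)
  }
  structure(list(n_r = as.integer(n_r), n_c = as.integer(n_c),
                 wall_row = as.integer(wall_row),
                 wall_thickness = as.integer(wall_thickness),
                 plaque = plaque, levels = levels,
                 distractors = distractors, g_max = g_max,
                 pixel_size_mm = pixel_size_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Draw shifted-Rayleigh speckle for a logical region mask into img.
fill_region <- function(img, region, level) {
  n <- sum(region)
  if (n) img[region] <- rrayleigh(n, mode = level[2], translation = level[1])
  img
}

#' Generate one synthetic phantom frame
#'
#' Every tissue region is drawn independently from its shifted Rayleigh
#' speckle distribution on the polar grid; the acoustic shadow replaces
#' everything radially behind the plaque arc, making it rectangle-like
#' in polar coordinates. The Cartesian frame is produced by
#' [to_cartesian()]. Deterministic for a fixed spec (seeded internally).
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `polar` ([polar_image()]), `cart`
#'   ([cartesian_image()]), `truth` (list with `plaque_mask`, `segment`,
#'   `leading_row`, `trailing_row`, `measurements`, `distractor_masks`,
#'   `has_plaque`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  n_r <- spec$n_r; n_c <- spec$n_c
  rows <- matrix(seq_len(n_r), n_r, n_c)
  cols <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
  wall_end <- spec$wall_row + spec$wall_thickness - 1L
  img <- matrix(0, n_r, n_c)
  img <- fill_region(img, rows < spec$wall_row, spec$levels$lumen)
  img <- fill_region(img, rows >= spec$wall_row & rows <= wall_end,
                     spec$levels$wall)
  img <- fill_region(img, rows > wall_end, spec$levels$adventitia)

  in_arc <- function(c1, c2) {
    if (c1 <= c2) cols >= c1 & cols <= c2 else cols >= c1 | cols <= c2
  }
  occupied <- matrix(FALSE, n_r, n_c)
  plaque_mask <- matrix(0L, n_r, n_c)
  segment <- NULL
  if (!is.null(spec$plaque)) {
    p <- spec$plaque
    band <- in_arc(p$c1, p$c2) & rows >= p$r0 &
      rows <= p$r0 + p$thickness - 1L
    shadow <- in_arc(p$c1, p$c2) & rows > p$r0 + p$thickness - 1L
    img <- fill_region(img, band, spec$levels$plaque)
    img <- fill_region(img, shadow, spec$levels$shadow)
    plaque_mask[band] <- 1L
    occupied <- occupied | band | shadow
    segment <- angular_segment(p$c1, p$c2, n_c)
  }
  distractor_masks <- list()
  for (d in spec$distractors) {
    dm <- switch(d$type,
      no_shadow_arc = {
        c1 <- d$c1 %||% 1; c2 <- d$c2 %||% 30
        r0 <- d$r0 %||% (wall_end + 8L); th <- d$thickness %||% 8L
        in_arc(c1, c2) & rows >= r0 & rows <= r0 + th - 1L
      },
      guidewire = {
        c1 <- d$c1 %||% 1; c2 <- d$c2 %||% (c1 + 2L)
        r0 <- d$r0 %||% 20L; th <- d$thickness %||% 10L
        in_arc(c1, c2) & rows >= r0 & rows <= r0 + th - 1L
      },
      long_ring = {
        r0 <- d$r0 %||% spec$wall_row; th <- d$thickness %||% 10L
        ring <- rows >= r0 & rows <= r0 + th - 1L
        img <- fill_region(img, rows > r0 + th - 1L, spec$levels$shadow)
        ring
      },
      stop(sprintf("unknown distractor type '%s'", d$type)))
    if (any(dm & occupied))
      stop("distractor placement overlaps an existing structure")
    img <- fill_region(img, dm, spec$levels$plaque)
    occupied <- occupied | dm
    distractor_masks[[d$type]] <- dm * 1L
  }
  img <- pmin(img, spec$g_max)
  polar <- polar_image(img, dr_px = 1, pixel_size_mm = spec$pixel_size_mm,
                       g_max = spec$g_max)
  cart <- to_cartesian(polar)
  measurements <- NULL
  if (!is.null(segment)) {
    truth_contour <- list(
      upper = list(rows = rep(spec$plaque$r0, segment$length)),
      lower = list(rows = rep(spec$plaque$r0 + spec$plaque$thickness - 1L,
                              segment$length)),
      segment = segment)
    measurements <- measure_plaque(truth_contour, polar)
  }
  structure(list(polar = polar, cart = cart,
                 truth = list(plaque_mask = plaque_mask, segment = segment,
                              leading_row = spec$plaque$r0,
                              trailing_row = if (!is.null(spec$plaque))
                                spec$plaque$r0 + spec$plaque$thickness - 1L,
                              measurements = measurements,
                              distractor_masks = distractor_masks,
                              has_plaque = !is.null(segment)),
                 spec = spec),
            class = "phantom")
}

#' Seeded suite of phantoms
#'
#' Generates `n` phantoms with randomised plaque position and extent:
#' angular length uniform in `arc_deg` (default 20-100 degrees), leading
#' row on the wall, thickness uniform in `thickness_rows`. Half the
#' frames (alternating) are controls without plaque; distractor-only
#' frames of each type are injected among the controls, and some plaque
#' frames carry a no-shadow distractor arc as well.
#'
#' @param n Number of phantoms.
#' @param seed Master seed; each frame derives its own sub-seed.
#' @param base_spec Template [phantom_spec()] supplying geometry and
#'   tissue levels.
#' @param arc_deg Range of plaque angular length in degrees.
#' @param thickness_rows Range of plaque thickness in rows.
#' @return List of `phantom` objects.
#' @export
phantom_suite <- function(n = 50, seed = 1,
                          base_spec = phantom_spec(),
                          arc_deg = c(20, 100),
                          thickness_rows = c(8, 12)) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  dtheta <- 360 / base_spec$n_c
  distractor_cycle <- c("none", "no_shadow_arc", "guidewire", "long_ring")
  lapply(seq_len(n), function(i) {
    has_plaque <- i %% 2L == 1L
    plaque <- NULL
    distractors <- list()
    if (has_plaque) {
      len_cols <- round(stats::runif(1, arc_deg[1], arc_deg[2]) / dtheta)
      c1 <- sample.int(base_spec$n_c, 1)
      c2 <- ((c1 - 1 + len_cols - 1) %% base_spec$n_c) + 1L
      plaque <- list(c1 = c1, c2 = c2,
                     r0 = base_spec$wall_row,
                     thickness = sample(thickness_rows[1]:thickness_rows[2], 1))
      if (i %% 6L == 1L) {
        # far side of the vessel, inside the adventitia: no shadow behind
        far <- ((c1 - 1 + round(base_spec$n_c / 2)) %% base_spec$n_c) + 1L
        distractors <- list(list(type = "no_shadow_arc", c1 = far,
                                 c2 = ((far - 1 + 14) %% base_spec$n_c) + 1L))
      }
    } else {
      kind <- distractor_cycle[(i / 2 - 1) %% 4 + 1]
      if (kind == "no_shadow_arc") {
        c1 <- sample.int(base_spec$n_c, 1)
        distractors <- list(list(type = "no_shadow_arc", c1 = c1,
                                 c2 = ((c1 - 1 + 14) %% base_spec$n_c) + 1L))
      } else if (kind == "guidewire") {
        c1 <- sample.int(base_spec$n_c, 1)
        distractors <- list(list(type = "guidewire", c1 = c1,
                                 c2 = ((c1 + 1) %% base_spec$n_c) + 1L))
      } else if (kind == "long_ring") {
        distractors <- list(list(type = "long_ring"))
      }
    }
    sp <- base_spec
    sp$plaque <- plaque
    sp$distractors <- distractors
    sp$seed <- sub_seeds[i]
    class(sp) <- "phantom_spec"
    generate_phantom(sp)
  })
}
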