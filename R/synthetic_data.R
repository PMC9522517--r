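#' Synthetic tongue-scene specification
#'
#' Recipe for a seeded synthetic tongue image with full ground truth,
#' emulating images from a closed acquisition box: a pinkish tongue blob on
#' a dark background, a whitish coating thickening toward root and center,
#' small reddish prickles (a few pixels each, biased toward tip and
#' margin), dark crack-fragment distractors in root/center, and darker
#' purple petechia-like spot distractors. All sizes are in pixels; all
#' colors are 8-bit RGB.
#'
#' Prickles and petechiae are rendered as radially decaying disks with a
#' steep logistic edge (blend weight `1 / (1 + exp((d - r) / (softness *
#' r)))`), so their dark cores are stable across a wide band of gray
#' thresholds. Cracks are rendered as chains of separated elongated dark
#' beads -- the fragments a thresholded crack decomposes into -- aligned
#' with a mostly vertical polyline.
#'
#' @param seed integer seed; every stage (tongue, coating, prickles,
#'   cracks, petechiae, noise, degradation) draws from its own derived
#'   substream, so e.g. changing the crack count does not reshuffle
#'   prickle placement.
#' @param image_size `(H, W)` in pixels. The acquisition device this
#'   emulates produces 576 x 768 frames (the default); `scene_preset("fast")`
#'   gives the scaled-down 192 x 256 variant used for quick experiments.
#' @param tongue,coating,prickles,cracks,petechiae,mask_degradation named
#'   lists overriding individual defaults (see the function body for the
#'   full set).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(seed = 1L, image_size = c(576L, 768L),
                       tongue = list(), coating = list(), prickles = list(),
                       cracks = list(), petechiae = list(),
                       mask_degradation = list()) {
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  if (H < 48L || W < 48L) stop("image_size too small for a tongue scene")
  merge_defaults <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown field(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  spec <- list(
    seed = as.integer(seed),
    image_size = c(H, W),
    tongue = merge_defaults(list(
      half_axes = c(0.42 * H, 0.32 * W),   # (rows, cols)
      exponent_root = 2.6, exponent_tip = 1.7,
      wobble_frac = 0.02,                  # lateral midline wobble, of ax
      base_rgb = c(200, 120, 120), noise_sd = 2.5), tongue),
    coating = merge_defaults(list(
      color = c(225, 215, 205), opacity = 0.5,
      lateral_sigma = 0.45), coating),     # fraction of the column half-axis
    prickles = merge_defaults(list(
      n = 15L, radius_range = c(2.9, 3.4), edge_softness = 0.22,
      color = c(120, 30, 45), color_sd = 6,
      tip_margin_frac = 0.7, min_separation = 14), prickles),
    cracks = merge_defaults(list(
      n = 2L, n_beads = c(3L, 5L), bead_spacing = 13,
      bead_short = c(2.4, 2.8), bead_aspect = c(1.5, 1.75),
      color = c(110, 45, 55)), cracks),
    petechiae = merge_defaults(list(
      n = 2L, radius_range = c(3.2, 4.0), edge_softness = 0.2,
      color = c(60, 30, 95), color_sd = 5), petechiae),
    mask_degradation = merge_defaults(list(
      n_holes = 3L, hole_radius = c(3, 6),
      n_speckles = 5L, speckle_radius = c(2, 4)), mask_degradation))
  for (fld in c("prickles", "cracks", "petechiae"))
    if (spec[[fld]]$n < 0L) stop(fld, " count must be >= 0")
  if (spec$tongue$half_axes[1] > H / 2 || spec$tongue$half_axes[2] > W / 2)
    stop("tongue larger than image")
  structure(spec, class = "scene_spec")
}

#' @rdname scene_spec
#' @param preset `"paper-size"` (576 x 768) or `"fast"` (192 x 256).
#' @param ... passed on to [scene_spec()].
#' @export
scene_preset <- function(preset = c("fast", "paper-size"), ...) {
  preset <- match.arg(preset)
  size <- if (preset == "fast") c(192L, 256L) else c(576L, 768L)
  scene_spec(image_size = size, ...)
}

# Derived per-stage substream seed (kept well below 2^31).
stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 1048576L) * 1009L + stage
}

# 0-based coordinate grids for an H x W image.
coord_grids <- function(H, W) {
  list(yy = matrix(rep(0:(H - 1L), W), H, W),
       xx = matrix(rep(0:(W - 1L), each = H), H, W))
}

# Blend `color` into the image over a local window with per-pixel weight w.
blend_patch <- function(image, rows, cols, w, color) {
  for (ch in 1:3) {
    patch <- image[rows, cols, ch]
    image[rows, cols, ch] <- patch * (1 - w) + color[ch] * w
  }
  image
}

# Soft-edged disk/ellipse blend weights on a window around (cy, cx); axes
# (ry, rx) in pixels, rotated by theta. d is the normalized elliptical
# radius; weight = plogis(-(d - 1) * r_eff / edge).
soft_spot_window <- function(H, W, cy, cx, ry, rx, theta, edge) {
  ext <- ceiling(max(ry, rx) + 4 * edge + 1)
  rows <- max(1L, floor(cy) + 1L - ext):min(H, floor(cy) + 1L + ext)
  cols <- max(1L, floor(cx) + 1L - ext):min(W, floor(cx) + 1L + ext)
  dy <- (rows - 1L) - cy
  dx <- (cols - 1L) - cx
  gy <- matrix(dy, length(rows), length(cols))
  gx <- matrix(dx, length(rows), length(cols), byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  ru <- gy * ct + gx * st      # along the ry axis
  rv <- -gy * st + gx * ct     # along the rx axis
  d <- sqrt((ru / ry)^2 + (rv / rx)^2)
  r_eff <- sqrt(ry * rx)
  w <- stats::plogis(-(d - 1) * r_eff / edge)
  list(rows = rows, cols = cols, w = w)
}

# Rejection-sample `n` centers (0-based y,x) from `allowed` (logical matrix),
# requiring an all-TRUE square of half-size `margin` in `support` around
# each center and pairwise distance >= min_sep from `taken` and each other.
sample_centers <- function(n, allowed, support, margin, min_sep, taken,
                           what = "object") {
  idx <- which(allowed)
  if (length(idx) == 0L && n > 0L) stop("no room to place ", what)
  H <- nrow(allowed)
  out <- matrix(numeric(0), 0L, 2L)
  pts <- taken
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in 1:500) {
      k <- idx[sample.int(length(idx), 1L)]
      r0 <- (k - 1L) %% H + 1L; c0 <- (k - 1L) %/% H + 1L
      rs <- (r0 - margin):(r0 + margin); cs <- (c0 - margin):(c0 + margin)
      if (min(rs) < 1L || min(cs) < 1L || max(rs) > H || max(cs) > ncol(allowed))
        next
      if (!all(support[rs, cs])) next
      y <- r0 - 1; x <- c0 - 1
      if (nrow(pts) > 0L &&
          min((pts[, 1L] - y)^2 + (pts[, 2L] - x)^2) < min_sep^2) next
      out <- rbind(out, c(y, x)); pts <- rbind(pts, c(y, x))
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place ", what, " ", i,
                      ": scene too crowded for the requested counts")
  }
  out
}

square_box <- function(y, x, half, label, region = NA_character_) {
  data.frame(x_min = round_half_up(x) - half, y_min = round_half_up(y) - half,
             x_max = round_half_up(x) + half + 1,
             y_max = round_half_up(y) + half + 1,
             label = label, region = region, stringsAsFactors = FALSE)
}

empty_boxes <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), label = character(0), region = character(0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic tongue scene with ground truth
#'
#' Deterministic under the spec's seed. Returns the rendered image, the
#' clean tongue mask, a degraded mask (holes punched and exterior speckles
#' added, for exercising [refine_mask()]), the region map of the clean
#' mask under the default partition fractions, ground-truth bounding boxes
#' for prickles and both distractor classes (one box per crack bead, the
#' unit a thresholded crack decomposes into), and the planted prickle peak
#' colors (usable as reference colors for the chromatic filter).
#'
#' @param spec a [scene_spec()].
#' @return a `scene_truth` list: `image` (H x W x 3 integer array),
#'   `clean_mask`, `degraded_mask`, `region_map`, `prickle_boxes`,
#'   `crack_boxes`, `petechia_boxes`, `prickle_colors` (n x 3 matrix),
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("`spec` must be a scene_spec")
  H <- spec$image_size[1]; W <- spec$image_size[2]
  g <- coord_grids(H, W)

  # --- tongue mask (stage 1) ---------------------------------------------
  set.seed(stage_seed(spec$seed, 1L))
  ay <- spec$tongue$half_axes[1]; ax <- spec$tongue$half_axes[2]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  tnorm <- pmin(1, pmax(0, (g$yy - (cy - ay)) / (2 * ay)))
  wob_phase <- runif(1, 0, 2 * pi)
  cx_row <- cx + spec$tongue$wobble_frac * ax * sin(2 * pi * tnorm + wob_phase)
  nexp <- spec$tongue$exponent_root +
    (spec$tongue$exponent_tip - spec$tongue$exponent_root) * tnorm
  inside <- (abs((g$xx - cx_row) / ax)^nexp +
             abs((g$yy - cy) / ay)^nexp) <= 1
  clean_mask <- inside
  region_map <- partition_tongue(clean_mask)

  # --- base colors and coating (stage 2) ---------------------------------
  set.seed(stage_seed(spec$seed, 2L))
  bg_rgb <- c(28, 22, 24)
  image <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    image[, , ch] <- ifelse(clean_mask, spec$tongue$base_rgb[ch], bg_rgb[ch])
  coat_w <- spec$coating$opacity * (1 - tnorm) *
    exp(-0.5 * ((g$xx - cx_row) / (spec$coating$lateral_sigma * ax))^2)
  coat_w[!clean_mask] <- 0
  for (ch in 1:3)
    image[, , ch] <- image[, , ch] * (1 - coat_w) +
      spec$coating$color[ch] * coat_w

  # --- prickles (stage 3) ------------------------------------------------
  set.seed(stage_seed(spec$seed, 3L))
  pk <- spec$prickles
  taken <- matrix(numeric(0), 0L, 2L)
  prickle_boxes <- empty_boxes()
  prickle_colors <- matrix(numeric(0), 0L, 3L,
                           dimnames = list(NULL, c("r", "g", "b")))
  if (pk$n > 0L) {
    n_tm <- round(pk$tip_margin_frac * pk$n)
    in_tm <- region_map == REGION_CODES[["tip"]] |
             region_map == REGION_CODES[["margin"]]
    in_rc <- region_map == REGION_CODES[["root"]] |
             region_map == REGION_CODES[["center"]]
    margin_px <- ceiling(max(pk$radius_range)) + 3L
    pts_tm <- sample_centers(n_tm, in_tm, clean_mask, margin_px,
                             pk$min_separation, taken, "prickle")
    pts <- rbind(pts_tm,
                 sample_centers(pk$n - n_tm, in_rc, clean_mask, margin_px,
                                pk$min_separation, pts_tm, "prickle"))
    for (i in seq_len(pk$n)) {
      r <- runif(1, pk$radius_range[1], pk$radius_range[2])
      col <- pmin(255, pmax(0, pk$color + rnorm(3, 0, pk$color_sd)))
      sw <- soft_spot_window(H, W, pts[i, 1L], pts[i, 2L], r, r, 0,
                             pk$edge_softness * r)
      image <- blend_patch(image, sw$rows, sw$cols, sw$w, col)
      code <- region_map[round_half_up(pts[i, 1L]) + 1L,
                         round_half_up(pts[i, 2L]) + 1L]
      prickle_boxes <- rbind(prickle_boxes,
                             square_box(pts[i, 1L], pts[i, 2L], ceiling(r),
                                        "prickle", region_name(code)))
      prickle_colors <- rbind(prickle_colors, round_half_up(col))
    }
    taken <- pts
  }

  # --- crack fragments (stage 4) -----------------------------------------
  set.seed(stage_seed(spec$seed, 4L))
  ck <- spec$cracks
  crack_boxes <- empty_boxes()
  if (ck$n > 0L) {
    in_rc <- region_map == REGION_CODES[["root"]] |
             region_map == REGION_CODES[["center"]]
    for (i in seq_len(ck$n)) {
      n_beads <- sample(seq(ck$n_beads[1], ck$n_beads[2]), 1L)
      start <- sample_centers(1L, in_rc, clean_mask, 8L,
                              ck$bead_spacing, taken, "crack")
      theta <- rnorm(1, 0, pi / 10)       # mostly vertical
      py <- start[1L, 1L]; px <- start[1L, 2L]
      for (b in seq_len(n_beads)) {
        short <- runif(1, ck$bead_short[1], ck$bead_short[2])
        long <- short * runif(1, ck$bead_aspect[1], ck$bead_aspect[2])
        rr <- round_half_up(py) + 1L; cc <- round_half_up(px) + 1L
        ok <- rr >= 1L && rr <= H && cc >= 1L && cc <= W && in_rc[rr, cc] &&
          (nrow(taken) == 0L ||
           min((taken[, 1L] - py)^2 + (taken[, 2L] - px)^2) >=
             ck$bead_spacing^2)
        if (ok) {
          col <- pmin(255, pmax(0, ck$color + rnorm(3, 0, 4)))
          sw <- soft_spot_window(H, W, py, px, long, short, theta,
                                 0.18 * sqrt(long * short))
          image <- blend_patch(image, sw$rows, sw$cols, sw$w, col)
          crack_boxes <- rbind(crack_boxes,
                               square_box(py, px, ceiling(long), "crack",
                                          region_name(in_region_code(region_map, py, px))))
          taken <- rbind(taken, c(py, px))
        }
        theta <- theta + rnorm(1, 0, pi / 18)
        py <- py + ck$bead_spacing * cos(theta)
        px <- px + ck$bead_spacing * sin(theta)
      }
    }
  }

  # --- petechiae (stage 5) -----------------------------------------------
  set.seed(stage_seed(spec$seed, 5L))
  pt <- spec$petechiae
  petechia_boxes <- empty_boxes()
  if (pt$n > 0L) {
    in_rc <- region_map == REGION_CODES[["root"]] |
             region_map == REGION_CODES[["center"]]
    margin_px <- ceiling(max(pt$radius_range)) + 3L
    pts2 <- sample_centers(pt$n, in_rc, clean_mask, margin_px,
                           spec$prickles$min_separation, taken, "petechia")
    for (i in seq_len(pt$n)) {
      r <- runif(1, pt$radius_range[1], pt$radius_range[2])
      col <- pmin(255, pmax(0, pt$color + rnorm(3, 0, pt$color_sd)))
      sw <- soft_spot_window(H, W, pts2[i, 1L], pts2[i, 2L], r, r, 0,
                             pt$edge_softness * r)
      image <- blend_patch(image, sw$rows, sw$cols, sw$w, col)
      petechia_boxes <- rbind(petechia_boxes,
                              square_box(pts2[i, 1L], pts2[i, 2L], ceiling(r),
                                         "petechia",
                                         region_name(in_region_code(region_map, pts2[i, 1L], pts2[i, 2L]))))
    }
    taken <- rbind(taken, pts2)
  }

  # --- sensor noise (stage 6) --------------------------------------------
  set.seed(stage_seed(spec$seed, 6L))
  if (spec$tongue$noise_sd > 0) {
    noise <- array(rnorm(H * W * 3, 0, spec$tongue$noise_sd), c(H, W, 3))
    image <- image + noise
  }
  image <- round_half_up(image)
  image[image < 0] <- 0; image[image > 255] <- 255
  storage.mode(image) <- "integer"

  # --- degraded mask (stage 7) -------------------------------------------
  degraded <- degrade_mask(clean_mask, spec$mask_degradation,
                           seed = stage_seed(spec$seed, 7L))

  structure(list(image = image, clean_mask = clean_mask,
                 degraded_mask = degraded, region_map = region_map,
                 prickle_boxes = prickle_boxes, crack_boxes = crack_boxes,
                 petechia_boxes = petechia_boxes,
                 prickle_colors = prickle_colors, spec = spec),
            class = "scene_truth")
}

in_region_code <- function(region_map, y, x) {
  region_map[round_half_up(y) + 1L, round_half_up(x) + 1L]
}

#' Degrade a clean mask with holes and speckles
#'
#' Punches interior holes (disks of background inside the tongue, kept
#' clear of the true boundary) and adds exterior speckles (disks of
#' foreground in the background, kept clear of the tongue), producing a
#' fixture whose [refine_mask()] result is exactly the clean mask again --
#' provided holes and speckles are smaller than half the tongue, which the
#' placement constraints guarantee for sane settings.
#'
#' @param mask clean single-component logical matrix.
#' @param degradation list with `n_holes`, `hole_radius` (range),
#'   `n_speckles`, `speckle_radius` (range); see [scene_spec()].
#' @param seed integer seed.
#' @return degraded logical matrix.
#' @export
degrade_mask <- function(mask, degradation, seed = 1L) {
  assert_mask(mask)
  set.seed(seed)
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  dg <- degradation
  if (max(dg$hole_radius) * 2 + 2 > min(H, W) ||
      sum(mask) <= pi * max(dg$hole_radius)^2 * 2)
    stop("hole larger than mask allows")
  if (dg$n_speckles > 0L &&
      pi * max(dg$speckle_radius)^2 >= sum(mask))
    stop("speckle larger than tongue not allowed")
  g <- coord_grids(H, W)
  if (dg$n_holes > 0L) {
    m <- ceiling(max(dg$hole_radius)) + 2L
    ctr <- sample_centers(dg$n_holes, mask, mask, m, 2 * min(dg$hole_radius),
                          matrix(numeric(0), 0, 2), "hole")
    for (i in seq_len(dg$n_holes)) {
      r <- runif(1, dg$hole_radius[1], dg$hole_radius[2])
      hit <- (g$yy - ctr[i, 1L])^2 + (g$xx - ctr[i, 2L])^2 <= r^2
      out[hit] <- FALSE
    }
  }
  if (dg$n_speckles > 0L) {
    m <- ceiling(max(dg$speckle_radius)) + 2L
    bg <- !mask
    ctr <- sample_centers(dg$n_speckles, bg, bg, m,
                          2 * max(dg$speckle_radius) + 3,
                          matrix(numeric(0), 0, 2), "speckle")
    for (i in seq_len(dg$n_speckles)) {
      r <- runif(1, dg$speckle_radius[1], dg$speckle_radius[2])
      hit <- (g$yy - ctr[i, 1L])^2 + (g$xx - ctr[i, 2L])^2 <= r^2
      out[hit] <- TRUE
    }
  }
  out
}

#' Generate a suite of synthetic scenes
#'
#' Scene `i` uses `seed + i`, so suites with overlapping seed ranges share
#' scenes and disjoint ranges share nothing. With `out_dir` set, writes
#' the on-disk layout consumed by the command-line interface: `images/`,
#' `masks/`, `masks_degraded/`, `regions/` (PNG), `truth/*.json` (Labelme
#' rectangles for the planted prickles) and `truth/colors.yaml` (per-scene
#' planted prickle colors).
#'
#' @param n_scenes number of scenes (>= 1).
#' @param base_spec template [scene_spec()]; defaults to the fast preset.
#' @param seed base seed.
#' @param out_dir optional output directory.
#' @return invisible list of `scene_truth` objects.
#' @export
generate_suite <- function(n_scenes, base_spec = scene_preset("fast"),
                           seed = 7L, out_dir = NULL) {
  stopifnot(n_scenes >= 1L)
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- base_spec
    sp$seed <- as.integer(seed + i)
    scenes[[i]] <- generate_scene(sp)
  }
  if (!is.null(out_dir)) {
    for (d in c("images", "masks", "masks_degraded", "regions", "truth"))
      dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
    colors <- list()
    for (i in seq_len(n_scenes)) {
      nm <- sprintf("scene_%03d", i)
      sc <- scenes[[i]]
      png::writePNG(aperm(array(as.numeric(sc$image) / 255,
                                dim(sc$image)), c(1, 2, 3)),
                    file.path(out_dir, "images", paste0(nm, ".png")))
      write_mask_png(sc$clean_mask,
                     file.path(out_dir, "masks", paste0(nm, ".png")))
      write_mask_png(sc$degraded_mask,
                     file.path(out_dir, "masks_degraded", paste0(nm, ".png")))
      write_region_png(sc$region_map,
                       file.path(out_dir, "regions", paste0(nm, ".png")))
      export_labelme(sc$prickle_boxes, paste0("../images/", nm, ".png"),
                     dim(sc$image)[1:2],
                     file = file.path(out_dir, "truth", paste0(nm, ".json")))
      colors[[nm]] <- lapply(seq_len(nrow(sc$prickle_colors)),
                             function(j) as.integer(sc$prickle_colors[j, ]))
    }
    yaml::write_yaml(colors, file.path(out_dir, "truth", "colors.yaml"))
  }
  invisible(scenes)
}
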