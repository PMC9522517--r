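# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: labeling via breadth-first flood fill, grouping
# via igraph connected components, matching via igraph maximum bipartite
# matching.

# Raster-order flood-fill labeling; labels numbered by first encounter, so
# the result is directly comparable to two_pass_label().
flood_fill_label <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8L) {
    dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dy <- c(-1L, 0L, 0L, 1L); dx <- c(0L, -1L, 1L, 0L)
  }
  n <- 0L
  qy <- integer(h * w); qx <- integer(h * w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!mask[y, x] || lab[y, x] != 0L) next
    n <- n + 1L
    head <- 1L; tail <- 1L
    qy[1L] <- y; qx[1L] <- x
    lab[y, x] <- n
    while (head <= tail) {
      cy <- qy[head]; cx <- qx[head]; head <- head + 1L
      for (k in seq_along(dy)) {
        ny <- cy + dy[k]; nx <- cx + dx[k]
        if (ny >= 1L && ny <= h && nx >= 1L && nx <= w &&
            mask[ny, nx] && lab[ny, nx] == 0L) {
          lab[ny, nx] <- n
          tail <- tail + 1L
          qy[tail] <- ny; qx[tail] <- nx
        }
      }
    }
  }
  list(labels = lab, n_components = n)
}

# Independent multi-threshold blob detector: BFS flood-fill labeling, own
# centroid/area accounting, igraph single-link grouping, own median-member
# selection. Shape metrics come from pricklr::shape_scores (they are
# validated separately against closed forms).
oracle_detect_blobs <- function(gray, params) {
  ts <- seq(params$min_threshold, params$max_threshold - 1e-9,
            by = params$threshold_step)
  cand <- list()
  for (t in ts) {
    bin <- if (params$polarity == "dark") gray < t else gray > t
    lab <- flood_fill_label(bin, 8L)$labels
    if (max(lab) == 0L) next
    px <- which(lab > 0L)
    coords_by_label <- split(px, lab[px])
    for (grp in coords_by_label) {
      a <- length(grp)
      if (a < params$min_area || a > params$max_area) next
      co <- cbind((grp - 1L) %% nrow(gray), (grp - 1L) %/% nrow(gray))
      s <- pricklr::shape_scores(co)
      if (s$circularity < params$min_circularity ||
          s$convexity < params$min_convexity ||
          s$inertia_ratio < params$min_inertia_ratio) next
      cand[[length(cand) + 1L]] <-
        c(threshold = t, cy = mean(co[, 1L]), cx = mean(co[, 2L]),
          area = a, circularity = s$circularity, convexity = s$convexity,
          inertia_ratio = s$inertia_ratio)
    }
  }
  if (length(cand) == 0L) return(NULL)
  m <- do.call(rbind, cand)
  n <- nrow(m)
  d <- as.matrix(stats::dist(m[, c("cy", "cx"), drop = FALSE]))
  adj <- d <= params$min_dist_between_blobs
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  out <- list()
  for (gid in unique(comp)) {
    ix <- which(comp == gid)
    k <- length(ix)
    if (k < params$min_repeatability) next
    mm <- m[ix, , drop = FALSE]
    mm <- mm[order(mm[, "threshold"], mm[, "cy"], mm[, "cx"]), ,
             drop = FALSE]
    med <- mm[floor((k + 1) / 2), ]
    out[[length(out) + 1L]] <-
      data.frame(x = mean(mm[, "cx"]), y = mean(mm[, "cy"]),
                 diameter = 2 * sqrt(med[["area"]] / pi),
                 area = med[["area"]], circularity = med[["circularity"]],
                 convexity = med[["convexity"]],
                 inertia_ratio = med[["inertia_ratio"]],
                 repeatability = k, threshold = med[["threshold"]])
  }
  if (length(out) == 0L) return(NULL)
  out <- do.call(rbind, out)
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Flat dark disks planted on a bright background; returns the gray image
# and the planted centers/radii.
plant_disks <- function(seed, h = 64L, w = 64L, n = 10L,
                        radius_range = c(2, 5), fg = 40L, bg = 180L) {
  set.seed(seed)
  gray <- matrix(bg, h, w)
  centers <- matrix(numeric(0), 0L, 2L)
  radii <- numeric(0)
  guard <- 0L
  while (nrow(centers) < n && guard < 5000L) {
    guard <- guard + 1L
    r <- runif(1, radius_range[1], radius_range[2])
    cy <- runif(1, r + 3, h - 1 - r - 3)
    cx <- runif(1, r + 3, w - 1 - r - 3)
    if (nrow(centers) > 0L &&
        min(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)) <
          r + max(radii) + 6) next
    centers <- rbind(centers, c(cy, cx)); radii <- c(radii, r)
  }
  for (i in seq_len(nrow(centers))) {
    ys <- pmax(1, floor(centers[i, 1] - radii[i])):pmin(h, ceiling(centers[i, 1] + radii[i] + 2))
    xs <- pmax(1, floor(centers[i, 2] - radii[i])):pmin(w, ceiling(centers[i, 2] + radii[i] + 2))
    for (y in ys) for (x in xs)
      if ((y - 1 - centers[i, 1])^2 + (x - 1 - centers[i, 2])^2 <= radii[i]^2)
        gray[y, x] <- fg
  }
  list(gray = gray, centers = centers, radii = radii)
}

# Pixel coordinate matrix (0-based y, x) of a rasterized disk.
disk_coords <- function(R, cy = 0, cx = 0) {
  r <- ceiling(R)
  g <- expand.grid(y = (cy - r):(cy + r), x = (cx - r):(cx + r))
  g <- g[(g$y - cy)^2 + (g$x - cx)^2 <= R^2, ]
  as.matrix(g)
}

# Paint a filled disk / axis-aligned square / ellipse into a gray matrix
# (values, 1-based center row/col).
paint_disk <- function(gray, row, col, R, value) {
  co <- disk_coords(R, row - 1L, col - 1L)
  gray[cbind(co[, 1L] + 1L, co[, 2L] + 1L)] <- value
  gray
}

paint_square <- function(gray, row, col, s, value) {
  gray[row:(row + s - 1L), col:(col + s - 1L)] <- value
  gray
}

paint_ellipse <- function(gray, row, col, ry, rx, value) {
  r <- ceiling(max(ry, rx))
  for (y in (row - r):(row + r)) for (x in (col - r):(col + r))
    if (((y - row) / ry)^2 + ((x - col) / rx)^2 <= 1)
      gray[y, x] <- value
  gray
}

# Maximum one-to-one matching cardinality at an IoU threshold, via igraph
# maximum bipartite matching (the optimal-assignment oracle).
max_matching_tp <- function(gt, pred, thr) {
  ng <- nrow(gt); np <- nrow(pred)
  if (ng == 0L || np == 0L) return(0L)
  iou <- matrix(0, ng, np)
  for (i in seq_len(ng)) for (j in seq_len(np))
    iou[i, j] <- bbox_iou(gt[i, ], pred[j, ])
  edges <- which(iou >= thr, arr.ind = TRUE)
  if (nrow(edges) == 0L) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, ng), rep(TRUE, np)),
    edges = as.vector(t(cbind(edges[, 1L], edges[, 2L] + ng))))
  igraph::max_bipartite_match(g)$matching_size
}

random_boxes <- function(n, size = 48L, side = c(4L, 7L), jitter = 2) {
  grid_pts <- expand.grid(y = seq(4, size - 12, by = 12),
                          x = seq(4, size - 12, by = 12))
  pick <- grid_pts[sample.int(nrow(grid_pts), n), ]
  s <- sample(seq(side[1], side[2]), n, replace = TRUE)
  x_min <- pick$x + round(runif(n, -jitter, jitter))
  y_min <- pick$y + round(runif(n, -jitter, jitter))
  data.frame(x_min = x_min, y_min = y_min,
             x_max = x_min + s, y_max = y_min + s,
             label = "prickle", region = NA_character_)
}
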