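#' Default annotation configuration
#'
#' The packaged per-region detector parameters: thresholds 60-100 step 2
#' everywhere; root/center tighter than tip/margin (repeatability 8 vs 4,
#' area 4-25 vs 2-40, circularity/convexity 0.8 vs 0.4, inertia 0.5 vs
#' 0.4, max aberration 85 vs 100) so that coated, crack-prone areas are
#' filtered harder. Also carries the partition fractions, the reference
#' prickle colors for the chromatic filter, and pipeline settings (box
#' padding, evaluation IoU threshold).
#'
#' Reference colors are site-specific by nature (they are sampled from
#' prickles of the acquisition device in use); the packaged set matches
#' the synthetic scene generator's prickle color distribution: the peak
#' prickle color plus two blends toward the tongue body, covering the
#' appearance of a detected blob's disk mean.
#'
#' @return nested configuration list with `partition`, `detector`,
#'   `reference_colors`, `pipeline`.
#' @export
default_config <- function() {
  ref <- rbind(c(120, 30, 45), c(140, 60, 70), c(165, 95, 95))
  list(
    partition = list(f_root = 0.25, f_tip = 0.20, f_margin = 0.20,
                     orientation = "root-top"),
    detector = list(
      root_center = blob_params(60, 100, 2, 8, 4, 25, 0.8, 0.8, 0.5,
                                85, 10, "dark"),
      tip = blob_params(60, 100, 2, 4, 2, 40, 0.4, 0.4, 0.4,
                        100, 10, "dark"),
      margin = blob_params(60, 100, 2, 4, 2, 40, 0.4, 0.4, 0.4,
                           100, 10, "dark")),
    reference_colors = list(root_center = ref, tip = ref, margin = ref),
    pipeline = list(pad = 1, iou_threshold = 0.5))
}

#' Generator-matched configuration
#'
#' [default_config()] with the two circularity/inertia bounds translated
#' to this package's perimeter convention. The default circularity bounds
#' assume contour-polygon semantics, under which small round blobs score
#' near 1; this package's pixel-count/boundary-path convention (exact
#' `4 s` for squares) caps an ideal digitized disk of area `A <= 25` px at
#' circularity about 0.72, so a 0.8 bound would reject every small true
#' spot. The translation lowers the circularity bounds (root/center 0.8 ->
#' 0.55, tip/margin 0.4 -> 0.3; the same geometry caps small-disk
#' convexity near 0.76, so root/center min_convexity 0.8 -> 0.7) and
#' moves the round-vs-elongated discrimination onto the inertia ratio
#' (root/center 0.5 -> 0.6, tip/margin 0.4 -> 0.35), which is
#' size-unbiased. All other values are unchanged.
#'
#' @return configuration list as in [default_config()].
#' @export
generator_matched_config <- function() {
  cfg <- default_config()
  cfg$detector$root_center$min_circularity <- 0.55
  cfg$detector$root_center$min_convexity <- 0.7
  cfg$detector$root_center$min_inertia_ratio <- 0.6
  cfg$detector$tip$min_circularity <- 0.3
  cfg$detector$tip$min_inertia_ratio <- 0.35
  cfg$detector$margin$min_circularity <- 0.3
  cfg$detector$margin$min_inertia_ratio <- 0.35
  cfg
}

#' Read and write configuration YAML
#'
#' The on-disk format mirrors the configuration list: `partition:`,
#' `detector: {root_center:, tip:, margin:}`, `reference_colors:` (lists
#' of `[r, g, b]` triples) and `pipeline:`. A packaged copy of the default
#' lives at `system.file("extdata", "default_config.yaml", package =
#' "pricklr")`.
#'
#' @param path YAML file path.
#' @return `read_config()`: configuration list with validated
#'   [blob_params()] entries.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(raw$partition))
    cfg$partition <- utils::modifyList(cfg$partition, raw$partition)
  if (!is.null(raw$detector)) {
    for (g in names(raw$detector)) {
      base <- if (!is.null(cfg$detector[[g]])) unclass(cfg$detector[[g]])
              else unclass(cfg$detector$margin)
      cfg$detector[[g]] <- do.call(blob_params,
                                   utils::modifyList(base, raw$detector[[g]]))
    }
  }
  if (!is.null(raw$reference_colors))
    cfg$reference_colors <- lapply(raw$reference_colors,
                                   function(x) do.call(rbind, x))
  if (!is.null(raw$pipeline))
    cfg$pipeline <- utils::modifyList(cfg$pipeline, raw$pipeline)
  cfg
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  out <- config
  out$detector <- lapply(config$detector, function(p) unclass(p))
  out$reference_colors <- lapply(config$reference_colors, function(m) {
    m <- rgb_matrix(m)
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
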