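#' Partition the ROI into one Voronoi tile per nucleus
#'
#' Labels every ROI pixel (at its pixel-centre coordinate) with the id of the
#' Euclidean-nearest nucleus centroid, the discrete Voronoi rule. Tile
#' borders are therefore equidistant between neighbouring nuclei and each
#' tile contains exactly one nucleus. Exact distance ties are broken toward
#' the smallest nucleus id so the labelling is fully deterministic.
#' Background pixels (outside the ROI) keep label 0.
#'
#' @param nuclei a [nucleus_set()] with at least one nucleus; every centroid
#'   must round to an ROI pixel.
#' @param roi_mask a [region_mask()]; the ROI is its nonzero pixels.
#' @return a [tile_label_image()] with `n_tiles == nrow(nuclei)`.
#' @export
voronoi_label <- function(nuclei, roi_mask) {
  labs <- roi_mask$labels
  if (nrow(nuclei) == 0) stop("no nuclei: cannot tessellate an empty nucleus set")
  pr <- as.integer(round(nuclei$row)); pc <- as.integer(round(nuclei$col))
  inside <- pr >= 1 & pr <= nrow(labs) & pc >= 1 & pc <= ncol(labs)
  inside[inside] <- labs[cbind(pr[inside], pc[inside])] > 0
  if (!all(inside))
    stop("centroid outside ROI: nucleus id(s) ",
         paste(nuclei$id[!inside], collapse = ", "))
  ord <- order(nuclei$id)
  out <- voronoi_label_cpp(labs, nuclei$row[ord], nuclei$col[ord],
                           as.integer(nuclei$id[ord]))
  tile_label_image(out, n_tiles = nrow(nuclei))
}

# Brute-force oracle: exhaustive per-pixel nearest-centroid scan in plain R,
# kept independent of the compiled path so the two can be compared exactly.
voronoi_label_bruteforce <- function(nuclei, roi_mask) {
  labs <- roi_mask$labels
  out <- matrix(0L, nrow(labs), ncol(labs))
  ord <- order(nuclei$id)
  cr <- nuclei$row[ord]; cc <- nuclei$col[ord]; ids <- nuclei$id[ord]
  idx <- which(labs > 0, arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    d2 <- (idx[p, 1] - cr)^2 + (idx[p, 2] - cc)^2
    out[idx[p, 1], idx[p, 2]] <- ids[which.min(d2)]
  }
  tile_label_image(out, n_tiles = nrow(nuclei))
}

#' Assign each tile to a tissue region
#'
#' Gives every Voronoi tile a region (lining or sub-lining), either from the
#' region at the pixel containing its nucleus (`nucleus_position`, the
#' default: a cell's identity is where its nucleus sits) or from the region
#' label covering the majority of its pixels (`majority_pixel`; ties fall
#' back to the nucleus pixel's region).
#'
#' @param tiles a [tile_label_image()].
#' @param region_mask a [region_mask()] congruent with `tiles`.
#' @param nuclei the [nucleus_set()] that seeded `tiles`.
#' @param rule `"nucleus_position"` (default) or `"majority_pixel"`.
#' @return a `data.frame` with one row per tile: `tile_id`, `region`
#'   (`"lining"`/`"sublining"`), `area` (pixels), `nucleus_id`. Areas sum to
#'   the ROI pixel count.
#' @export
assign_tile_regions <- function(tiles, region_mask, nuclei,
                                rule = c("nucleus_position", "majority_pixel")) {
  rule <- match.arg(rule)
  stopifnot(all(dim(tiles$labels) == dim(region_mask$labels)))
  ids <- sort(nuclei$id)
  roi <- tiles$labels > 0
  area <- tabulate(tiles$labels[roi], nbins = max(ids))[ids]
  nuc_reg <- region_mask$labels[cbind(as.integer(round(nuclei$row)),
                                      as.integer(round(nuclei$col)))]
  nuc_reg <- nuc_reg[order(nuclei$id)]
  if (rule == "nucleus_position") {
    reg <- nuc_reg
  } else {
    # per-tile pixel counts within each region label
    tl <- tiles$labels[roi]; rl <- region_mask$labels[roi]
    cnt <- vapply(1:2, function(r)
      tabulate(tl[rl == r], nbins = max(ids))[ids], numeric(length(ids)))
    if (length(ids) == 1) cnt <- matrix(cnt, nrow = 1)
    reg <- ifelse(cnt[, 1] > cnt[, 2], 1L, ifelse(cnt[, 2] > cnt[, 1], 2L, nuc_reg))
  }
  data.frame(tile_id = ids, region = region_names[reg],
             area = as.integer(area), nucleus_id = ids)
}
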