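#' Nucleus detection parameters
#'
#' @param smoothing_sd Gaussian pre-smoothing sd in pixels (0 = none).
#' @param threshold_method `"otsu"` (computed over ROI pixels) or `"fixed"`.
#' @param fixed_threshold intensity threshold when `threshold_method` is
#'   `"fixed"`.
#' @param min_distance minimum separation of watershed peaks in pixels
#'   (>= 1); merged nuclear blobs closer than this are not split.
#' @param min_blob_area minimum component area in pixels (>= 1).
#' @param watershed_tolerance minimum intensity depth between two local
#'   maxima for them to count as separate objects; on the simulator's
#'   0-100 intensity scale the default 2 ignores residual noise bumps
#'   after smoothing while still splitting touching nuclei.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(smoothing_sd = 1, threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NA_real_, min_distance = 3,
                             min_blob_area = 4, watershed_tolerance = 2) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(smoothing_sd >= 0, min_distance >= 1, min_blob_area >= 1,
            watershed_tolerance >= 0)
  if (threshold_method == "fixed" && !is.finite(fixed_threshold))
    stop("fixed_threshold must be given with threshold_method = 'fixed'")
  structure(list(smoothing_sd = smoothing_sd,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_distance = min_distance, min_blob_area = min_blob_area,
                 watershed_tolerance = watershed_tolerance),
            class = "detection_params")
}

#' Detect nucleus centroids in a DAPI channel
#'
#' Classical deterministic pipeline: Gaussian smoothing, foreground
#' thresholding over ROI pixels (Otsu or fixed), connected components with a
#' minimum area, a seeded-watershed split of merged blobs (local maxima at
#' least `min_distance` apart and `watershed_tolerance` deep), and one
#' intensity-weighted centroid per final component. Centroids falling
#' outside the ROI are discarded; ids are assigned in (row, col)
#' lexicographic order of the centroids so the output is rank-stable.
#'
#' @param dapi a [channel_image()] with the nuclear stain.
#' @param roi_mask a [region_mask()] of the same dimensions; must have at
#'   least one ROI pixel.
#' @param params a [detection_params()].
#' @return a [nucleus_set()]; empty if the DAPI channel is all zero.
#' @export
detect_nuclei <- function(dapi, roi_mask, params = detection_params()) {
  stopifnot(all(dim(dapi$values) == dim(roi_mask$labels)))
  roi <- roi_mask$labels > 0
  if (!any(roi)) stop("empty ROI: cannot detect nuclei")
  x <- dapi$values
  if (all(x == 0)) return(nucleus_set())
  sm <- if (params$smoothing_sd > 0)
    as.matrix(EBImage::gblur(x, sigma = params$smoothing_sd)) else x
  thr <- if (params$threshold_method == "otsu") otsu_threshold(sm[roi])
         else params$fixed_threshold
  fg <- (sm > thr) & roi
  if (!any(fg)) return(nucleus_set())
  # watershed on the masked smooth intensity splits touching blobs at
  # saddle points; ext controls the peak-separation neighbourhood
  lab <- EBImage::watershed(EBImage::Image(sm * fg),
                            tolerance = params$watershed_tolerance,
                            ext = params$min_distance)
  lab <- as.matrix(EBImage::imageData(lab))
  keep_area <- tabulate(lab[lab > 0])
  keep <- which(keep_area >= params$min_blob_area)
  if (length(keep) == 0) return(nucleus_set())
  idx <- which(lab > 0 & matrix(lab %in% keep, nrow(lab)), arr.ind = TRUE)
  l <- lab[idx]
  wgt <- sm[idx]
  swr <- rowsum(wgt * idx[, 1], l)
  swc <- rowsum(wgt * idx[, 2], l)
  sw <- rowsum(wgt, l)
  cr <- swr / sw; cc <- swc / sw
  # drop centroids whose pixel lies outside the ROI
  pr <- as.integer(round(cr)); pc <- as.integer(round(cc))
  inroi <- pr >= 1 & pr <= nrow(roi) & pc >= 1 & pc <= ncol(roi)
  inroi[inroi] <- roi[cbind(pr[inroi], pc[inroi])]
  cr <- cr[inroi]; cc <- cc[inroi]
  ord <- order(cr, cc)
  nucleus_set(cr[ord], cc[ord])
}

#' Score detected nuclei against ground truth
#'
#' Greedy nearest-neighbour matching: detections and truth nuclei are paired
#' in increasing order of distance, each at most once, accepting pairs within
#' `max_dist` pixels. Reports precision, recall and F1.
#'
#' @param detected,truth [nucleus_set()]-like tables with `row`, `col`.
#' @param max_dist matching radius in pixels (default 3).
#' @return list with `n_matched`, `precision`, `recall`, `f1`.
#' @export
match_nuclei <- function(detected, truth, max_dist = 3) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(n_matched = 0L, precision = ifelse(nd == 0, NA, 0),
                recall = ifelse(nt == 0, NA, 0), f1 = 0))
  d2 <- outer(detected$row, truth$row, "-")^2 + outer(detected$col, truth$col, "-")^2
  cand <- which(d2 <= max_dist^2, arr.ind = TRUE)
  cand <- cand[order(d2[cand]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt); m <- 0L
  for (i in seq_len(nrow(cand))) {
    di <- cand[i, 1]; ti <- cand[i, 2]
    if (!used_d[di] && !used_t[ti]) {
      used_d[di] <- TRUE; used_t[ti] <- TRUE; m <- m + 1L
    }
  }
  prec <- m / nd; rec <- m / nt
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(n_matched = m, precision = prec, recall = rec, f1 = f1)
}
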