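#' Multi-channel fluorescence image
#'
#' Container for a channel-stacked 2-D intensity raster: an ordered list of
#' equally sized non-negative matrices, one per channel, with unique channel
#' names (exactly one designated nuclear/DAPI channel) and a physical pixel
#' size.
#'
#' @param channels named list of numeric matrices, all the same dimension,
#'   all values >= 0. Names are the channel names.
#' @param pixel_size pixel edge length in micrometres per pixel (> 0).
#' @param dapi name of the nuclear channel; defaults to `"DAPI"` if present,
#'   otherwise the first channel.
#' @return an object of class `multiplex_image` with elements `channels`,
#'   `channel_names`, `pixel_size`, `dapi`.
#' @export
multiplex_image <- function(channels, pixel_size, dapi = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1)
  nm <- names(channels)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm))
    stop("channels must have unique non-empty names")
  dims <- vapply(channels, dim, integer(2))
  if (!all(dims == dims[, 1]))
    stop("all channels must share the same dimensions")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("channel intensities must be non-negative")
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0)
  if (is.null(dapi)) dapi <- if ("DAPI" %in% nm) "DAPI" else nm[1]
  if (!dapi %in% nm) stop("dapi channel '", dapi, "' not among channel names")
  structure(
    list(channels = channels, channel_names = nm,
         pixel_size = pixel_size, dapi = dapi),
    class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multiplex_image> %d x %d px, %.3g um/px, %d channels: %s (DAPI = %s)\n",
              d[1], d[2], x$pixel_size, length(x$channels),
              paste(x$channel_names, collapse = ", "), x$dapi))
  invisible(x)
}

#' Marker names of a multiplex image (all channels except DAPI)
#' @param image a [multiplex_image()]
#' @return character vector of marker channel names, in storage order.
#' @export
marker_names <- function(image) {
  setdiff(image$channel_names, image$dapi)
}

#' Single channel image
#'
#' A 2-D intensity raster with its channel name and a flag recording whether
#' it has been normalized to \[0, 1\] (see [normalize_channel()]).
#'
#' @param values numeric matrix of intensities.
#' @param name channel name.
#' @param normalized logical; if `TRUE`, all values must lie in \[0, 1\].
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(values, name, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (normalized && (any(values < 0) || any(values > 1)))
    stop("a normalized channel must have all values in [0, 1]")
  structure(list(values = values, name = as.character(name),
                 normalized = isTRUE(normalized)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> '%s' %d x %d px, range [%.4g, %.4g]%s\n",
              x$name, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Tissue region mask
#'
#' Integer raster labelling each pixel as background (0, outside the ROI),
#' lining (1) or sub-lining (2). The ROI is the set of nonzero pixels.
#'
#' @param labels integer matrix with values in \{0, 1, 2\}.
#' @param pixel_size micrometres per pixel (> 0).
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(labels, pixel_size) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2)) stop("region mask labels must be in {0, 1, 2}")
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0)
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  tb <- tabulate(x$labels + 1L, 3L)
  cat(sprintf("<region_mask> %d x %d px, %.3g um/px; background %d, lining %d, sub-lining %d px\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size, tb[1], tb[2], tb[3]))
  invisible(x)
}

# region code -> name used throughout tables
region_names <- c("lining", "sublining")

#' Nucleus centroid set
#'
#' Ordered set of nucleus centroids at 1-based pixel-centre (row, col)
#' coordinates, with ids contiguous from 1 in list order. Seeds of the
#' Voronoi tessellation.
#'
#' @param row,col numeric vectors of equal length; centroid coordinates.
#' @return a `data.frame` of class `nucleus_set` with columns `id`, `row`,
#'   `col`.
#' @export
nucleus_set <- function(row = numeric(0), col = numeric(0)) {
  stopifnot(length(row) == length(col))
  n <- length(row)
  if (n > 1 && anyDuplicated(cbind(round(row), round(col))))
    stop("no two centroids may occupy the identical pixel")
  structure(data.frame(id = seq_len(n), row = as.numeric(row),
                       col = as.numeric(col)),
            class = c("nucleus_set", "data.frame"))
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Tile label image
#'
#' Integer raster assigning every ROI pixel to exactly one tile; 0 outside
#' the ROI, the owning nucleus id inside.
#'
#' @param labels integer matrix of tile ids (0 = background).
#' @param n_tiles number of tiles (= number of nuclei).
#' @return an object of class `tile_label_image`.
#' @export
tile_label_image <- function(labels, n_tiles) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, n_tiles = as.integer(n_tiles)),
            class = "tile_label_image")
}

#' @export
print.tile_label_image <- function(x, ...) {
  cat(sprintf("<tile_label_image> %d x %d px, %d tiles covering %d ROI px\n",
              nrow(x$labels), ncol(x$labels), x$n_tiles, sum(x$labels > 0)))
  invisible(x)
}
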