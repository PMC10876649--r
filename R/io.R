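#' Write / read a multiplex image as multi-page TIFF with a sidecar YAML
#'
#' One 32-bit float TIFF page per channel. Because baseline TIFF writers
#' store floats in \[0, 1\], intensities are divided by a recorded scale
#' factor on write and multiplied back on read; the scale, channel names,
#' DAPI designation and pixel size travel in a sidecar YAML next to the
#' image (`<path>.yaml`).
#'
#' @param image a [multiplex_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_multiplex <- function(image, path) {
  scale <- max(1, vapply(image$channels, max, numeric(1)))
  pages <- lapply(image$channels, function(ch) pmin(ch / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(channel_names = as.list(image$channel_names),
               dapi = image$dapi, pixel_size = image$pixel_size,
               scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_multiplex
#' @export
read_multiplex <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nm <- unlist(meta$channel_names)
  stopifnot(length(pages) == length(nm))
  channels <- setNames(lapply(pages, function(p) p * meta$scale), nm)
  multiplex_image(channels, meta$pixel_size, dapi = meta$dapi)
}

#' Write / read a region mask as single-channel 8-bit TIFF
#'
#' Labels \{0, 1, 2\} are stored as `label / 255`, which is exact in 8 bits;
#' the pixel size travels in a sidecar YAML.
#'
#' @param mask a [region_mask()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_region_mask <- function(mask, path) {
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8L,
                  compression = "deflate", reduce = FALSE)
  yaml::write_yaml(list(pixel_size = mask$pixel_size), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_region_mask
#' @param pixel_size pixel size in um/px; if `NULL`, read from the sidecar
#'   YAML.
#' @export
read_region_mask <- function(path, pixel_size = NULL) {
  if (is.null(pixel_size))
    pixel_size <- yaml::read_yaml(paste0(path, ".yaml"))$pixel_size
  labs <- round(tiff::readTIFF(path) * 255)
  region_mask(matrix(as.integer(labs), nrow(labs)), pixel_size)
}

#' Write / read nucleus centroids as CSV (`id,row,col`)
#'
#' The CSV interchange lets an externally produced centroid set bypass
#' detection, so tessellation and typing can run on their own.
#'
#' @param nuclei a [nucleus_set()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_nuclei <- function(nuclei, path) {
  write.csv(as.data.frame(nuclei)[, c("id", "row", "col")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuclei
#' @export
read_nuclei <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("id", "row", "col") %in% names(d)))
  d <- d[order(d$id), ]
  stopifnot(identical(as.integer(d$id), seq_len(nrow(d))))
  nucleus_set(d$row, d$col)
}

#' Write a tile label image as 16-bit single-channel TIFF
#'
#' @param tiles a [tile_label_image()] with at most 65535 tiles.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tile_labels <- function(tiles, path) {
  stopifnot(max(tiles$labels) <= 65535)
  tiff::writeTIFF(tiles$labels / 65535, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  invisible(path)
}

#' @rdname write_tile_labels
#' @export
read_tile_labels <- function(path) {
  labs <- round(tiff::readTIFF(path) * 65535)
  labs <- matrix(as.integer(labs), nrow(labs))
  tile_label_image(labs, n_tiles = length(setdiff(unique(as.vector(labs)), 0L)))
}
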