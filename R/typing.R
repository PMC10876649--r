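#' Aggregate normalized marker intensity per tile
#'
#' Builds the tile-by-marker feature matrix: entry (t, c) is the aggregate
#' (`mean`, `median` or `max`) of normalized channel c over tile t's pixels.
#' The mean is the default: the simulator's signal is constant over a tile,
#' so any of the three recovers it, and the mean is robust to single hot
#' pixels. The DAPI channel marks all cells and is excluded by callers.
#'
#' @param tiles a [tile_label_image()].
#' @param channels named list of normalized [channel_image()]s (markers
#'   only); an unnormalized channel is an error since cross-channel argmax
#'   is meaningless on raw scales.
#' @param statistic `"mean"`, `"median"` or `"max"`.
#' @return numeric matrix, rows = tiles (rownames = tile ids), columns =
#'   marker channels; all values in \[0, 1\].
#' @export
tile_intensity_matrix <- function(tiles, channels,
                                  statistic = c("mean", "median", "max")) {
  statistic <- match.arg(statistic)
  if (any(!vapply(channels, function(ch) isTRUE(ch$normalized), logical(1))))
    stop("channels must be normalized before tile aggregation")
  roi <- tiles$labels > 0
  lab <- tiles$labels[roi]
  ids <- sort(unique(lab))
  stopifnot(length(ids) == tiles$n_tiles)   # every tile has >= 1 pixel
  out <- matrix(NA_real_, length(ids), length(channels),
                dimnames = list(ids, names(channels)))
  for (ch in names(channels)) {
    v <- channels[[ch]]$values[roi]
    out[, ch] <- switch(statistic,
      mean = as.vector(rowsum(v, lab) / as.vector(rowsum(rep(1, length(v)), lab))),
      median = vapply(split(v, lab), median, numeric(1)),
      max = vapply(split(v, lab), max, numeric(1)))
  }
  out
}

#' Call one cell type per tile by highest normalized intensity
#'
#' Per tile, the called type is the marker channel with the highest
#' aggregated normalized intensity (argmax across the feature-matrix row).
#' Exact ties are resolved by the earliest channel in `tie_order`. A tile
#' whose winning score falls below `min_score` is called `"unassigned"`;
#' the default `min_score = 0` assigns every tile one of the marker types,
#' the exhaustive three-way call used for capsule tissue (CD31+/CD68+/DKK3+).
#'
#' @param matrix tile feature matrix from [tile_intensity_matrix()].
#' @param tile_regions tile-region table from [assign_tile_regions()].
#' @param min_score minimum winning score in \[0, 1\]; default 0.
#' @param tie_order permutation of the matrix columns used to break exact
#'   ties; defaults to column order.
#' @return `data.frame`: `tile_id`, `called_type`, `winning_score`,
#'   `region`; attribute `type_levels` records the full type alphabet.
#' @export
call_tile_types <- function(matrix, tile_regions, min_score = 0,
                            tie_order = colnames(matrix)) {
  stopifnot(setequal(tie_order, colnames(matrix)),
            length(tie_order) == ncol(matrix),
            min_score >= 0, min_score <= 1)
  m <- matrix[, tie_order, drop = FALSE]   # argmax ties -> earliest in tie_order
  win <- max.col(m, ties.method = "first")
  score <- m[cbind(seq_len(nrow(m)), win)]
  type <- tie_order[win]
  type[score < min_score] <- "unassigned"
  ids <- as.integer(rownames(matrix))
  reg <- tile_regions$region[match(ids, tile_regions$tile_id)]
  out <- data.frame(tile_id = ids, called_type = type,
                    winning_score = as.numeric(score), region = reg)
  attr(out, "type_levels") <- c(colnames(matrix), "unassigned")
  out
}

#' Tabulate tile-type composition by region
#'
#' Counts called tiles per cell type within each region (lining, sub-lining)
#' and combined, and expresses them as percentages of that region's tile
#' total. Types with zero tiles are kept as explicit zero rows.
#'
#' @param types tile-type table from [call_tile_types()].
#' @param sample_id sample name recorded in the output.
#' @return `data.frame`: `sample`, `region` (`"lining"`, `"sublining"`,
#'   `"combined"`), `type`, `count`, `proportion_pct`, `n_tiles` (tile total
#'   of that region). Within each region, proportions sum to 100.
#' @export
composition_table <- function(types, sample_id) {
  if (nrow(types) == 0) stop("no tiles: cannot tabulate composition")
  lev <- attr(types, "type_levels")
  if (is.null(lev)) lev <- sort(unique(types$called_type))
  rows <- list()
  for (rg in c("lining", "sublining", "combined")) {
    sel <- if (rg == "combined") rep(TRUE, nrow(types)) else types$region == rg
    n <- sum(sel)
    cnt <- table(factor(types$called_type[sel], levels = lev))
    rows[[rg]] <- data.frame(
      sample = sample_id, region = rg, type = lev,
      count = as.integer(cnt),
      proportion_pct = if (n > 0) 100 * as.integer(cnt) / n else NA_real_,
      n_tiles = n, row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
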