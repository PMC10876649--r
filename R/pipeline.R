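#' Pipeline run configuration
#'
#' Collects every stage parameter of the quantification pipeline in one
#' object so a run is fully reproducible from (inputs, config, seed).
#'
#' @param despeckle_radius median despeckle radius in pixels (default 0.5,
#'   the 5-pixel cross; 0 disables).
#' @param p_low,p_high normalization percentiles (defaults 1 and 99).
#' @param detection a [detection_params()].
#' @param region_rule tile-region rule, `"nucleus_position"` (default) or
#'   `"majority_pixel"`.
#' @param statistic per-tile aggregation statistic (default `"mean"`).
#' @param min_score minimum winning score for a type call (default 0:
#'   exhaustive assignment).
#' @param tie_order marker order for breaking exact argmax ties; `NULL` =
#'   channel storage order.
#' @param use_true_nuclei if `TRUE` and samples carry ground truth, seed the
#'   tessellation with the true centroids instead of detecting them
#'   (isolates downstream stages from detection quality).
#' @param adjust add Benjamini-Hochberg adjusted p-values to comparisons.
#' @return an object of class `run_config`.
#' @export
run_config <- function(despeckle_radius = 0.5, p_low = 1, p_high = 99,
                       detection = detection_params(),
                       region_rule = c("nucleus_position", "majority_pixel"),
                       statistic = c("mean", "median", "max"),
                       min_score = 0, tie_order = NULL,
                       use_true_nuclei = FALSE, adjust = FALSE) {
  structure(list(despeckle_radius = despeckle_radius,
                 p_low = p_low, p_high = p_high, detection = detection,
                 region_rule = match.arg(region_rule),
                 statistic = match.arg(statistic),
                 min_score = min_score, tie_order = tie_order,
                 use_true_nuclei = isTRUE(use_true_nuclei),
                 adjust = isTRUE(adjust)),
            class = "run_config")
}

#' Quantify a single multiplexed sample
#'
#' Runs preprocess -> detect -> tessellate -> type -> tabulate on one sample:
#' median-despeckles every channel, detects nuclei in the DAPI channel (or
#' takes supplied centroids), partitions the ROI into Voronoi tiles,
#' normalizes the marker channels over the ROI, aggregates per-tile
#' intensities, calls one type per tile and tabulates region-stratified
#' composition and cellularity.
#'
#' @param image a [multiplex_image()].
#' @param mask a [region_mask()] congruent with `image`.
#' @param config a [run_config()].
#' @param sample_id sample name used in output tables.
#' @param nuclei optional [nucleus_set()]; if given, detection is skipped.
#' @return list with `nuclei`, `tiles`, `tile_regions`, `types`,
#'   `composition`, `cellularity`, `qc` (one-row data.frame).
#' @export
quantify_sample <- function(image, mask, config = run_config(),
                            sample_id = "sample", nuclei = NULL) {
  stopifnot(inherits(image, "multiplex_image"), inherits(mask, "region_mask"),
            all(dim(image$channels[[1]]) == dim(mask$labels)))
  degeneracies <- character(0)
  collect <- function(expr) withCallingHandlers(expr,
    tilecyte_degenerate = function(w) {
      degeneracies <<- c(degeneracies, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  chans <- lapply(image$channel_names, function(nm)
    median_despeckle(channel_image(image$channels[[nm]], nm),
                     config$despeckle_radius))
  names(chans) <- image$channel_names
  if (is.null(nuclei))
    nuclei <- detect_nuclei(chans[[image$dapi]], mask, config$detection)
  cel <- cellularity(nuclei, mask, sample_id)
  markers <- marker_names(image)
  norm <- lapply(chans[markers], function(ch)
    collect(normalize_channel(ch, mask, config$p_low, config$p_high)))
  qnt <- t(vapply(norm, function(ch) attr(ch, "quantiles"), numeric(2)))
  if (nrow(nuclei) == 0) {
    warning("no nuclei in sample '", sample_id,
            "': composition undefined", call. = FALSE)
    tiles <- NULL; tile_regions <- NULL; types <- NULL; comp <- NULL
    unassigned_frac <- NA_real_; mean_area <- NA_real_
  } else {
    tiles <- voronoi_label(nuclei, mask)
    tile_regions <- assign_tile_regions(tiles, mask, nuclei, config$region_rule)
    feats <- tile_intensity_matrix(tiles, norm, config$statistic)
    tie_order <- if (is.null(config$tie_order)) markers else config$tie_order
    types <- call_tile_types(feats, tile_regions, config$min_score, tie_order)
    comp <- composition_table(types, sample_id)
    unassigned_frac <- mean(types$called_type == "unassigned")
    mean_area <- mean(tile_regions$area)
  }
  qc <- data.frame(sample = sample_id,
                   n_nuclei = nrow(nuclei),
                   n_tiles = if (is.null(tiles)) 0L else tiles$n_tiles,
                   mean_tile_area = mean_area,
                   unassigned_fraction = unassigned_frac,
                   n_degeneracy_warnings = length(degeneracies))
  for (m in markers) {
    qc[[paste0("q_low_", m)]] <- qnt[m, 1]
    qc[[paste0("q_high_", m)]] <- qnt[m, 2]
  }
  list(nuclei = nuclei, tiles = tiles, tile_regions = tile_regions,
       types = types, composition = comp, cellularity = cel, qc = qc,
       degeneracies = degeneracies)
}

#' Run the full two-group study pipeline
#'
#' Orchestrates simulate (optional) -> quantify each sample -> stack
#' composition/cellularity tables -> compare the two groups endpoint by
#' endpoint with the exact two-sided Mann-Whitney test. All outputs are
#' deterministic functions of (inputs, config, seed); if `out_dir` is given
#' the tables are written there as CSV (byte-identical across repeated runs)
#' together with the serialized configuration and a plain-text run log.
#'
#' @param samples either `NULL` (then `simulation` is used) or a named list
#'   of samples, each a list with `image` ([multiplex_image()]), `mask`
#'   ([region_mask()]), `sample_id`, and optionally `group` and `truth`.
#' @param simulation arguments for [simulate_study()] (a list; may be empty
#'   for the defaults), used when `samples` is `NULL`.
#' @param config a [run_config()].
#' @param seed master seed for the simulation stage.
#' @param out_dir optional output directory.
#' @return list with `composition`, `cellularity`, `comparisons` (or `NULL`
#'   if fewer than two groups), `qc`, `samples` (per-sample stage results).
#' @export
run_pipeline <- function(samples = NULL, simulation = list(),
                         config = run_config(), seed = 1, out_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  if (is.null(samples)) {
    say("simulating study (seed %d)", seed)
    samples <- do.call(simulate_study, c(simulation, list(seed = seed)))
  }
  results <- list()
  for (s in samples) {
    sid <- s$sample_id
    if (is.null(s$image) || is.null(s$mask))
      stop("sample '", sid, "': image and mask are required")
    t0 <- proc.time()[["elapsed"]]
    nuc <- if (config$use_true_nuclei && !is.null(s$truth))
      nucleus_set(s$truth$row, s$truth$col) else NULL
    res <- tryCatch(
      quantify_sample(s$image, s$mask, config, sid, nuclei = nuc),
      error = function(e)
        stop("stage 'quantify' failed for sample '", sid, "': ",
             conditionMessage(e), call. = FALSE))
    res$group <- s$group
    results[[sid]] <- res
    say("sample %s: %d tiles, %.1f s", sid, res$qc$n_tiles,
        proc.time()[["elapsed"]] - t0)
  }
  comp <- do.call(rbind, c(lapply(results, function(r) {
    if (is.null(r$composition)) return(NULL)
    cbind(r$composition, group = r$group %||% NA_character_)
  }), make.row.names = FALSE))
  cel <- do.call(rbind, c(lapply(results, function(r)
    cbind(r$cellularity, group = r$group %||% NA_character_)),
    make.row.names = FALSE))
  qc <- do.call(rbind, c(lapply(results, `[[`, "qc"),
                         make.row.names = FALSE))
  comparisons <- NULL
  grps <- unique(stats::na.omit(cel$group))
  if (length(grps) == 2 && !is.null(comp)) {
    extra <- data.frame(
      endpoint = paste0("cellularity_", cel$region),
      group = cel$group, value = cel$density_per_mm2)
    comparisons <- compare_compositions(comp, extra = extra,
                                        adjust = config$adjust)
    say("compared %d endpoints between groups %s and %s",
        nrow(comparisons), grps[1], grps[2])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(comp))
      write.csv(comp, file.path(out_dir, "composition.csv"), row.names = FALSE)
    write.csv(cel, file.path(out_dir, "cellularity.csv"), row.names = FALSE)
    write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE)
    nucs <- do.call(rbind, c(lapply(names(results), function(sid)
      cbind(sample = sid, as.data.frame(results[[sid]]$nuclei))),
      make.row.names = FALSE))
    write.csv(nucs, file.path(out_dir, "nuclei.csv"), row.names = FALSE)
    yaml::write_yaml(serialize_config(config, seed),
                     file.path(out_dir, "run_config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(composition = comp, cellularity = cel, comparisons = comparisons,
       qc = qc, samples = results, log = log_lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

serialize_config <- function(config, seed) {
  c(unclass(config)[setdiff(names(unclass(config)), "detection")],
    list(detection = unclass(config$detection), seed = seed))
}

#' Group-mean composition from a pipeline run
#'
#' Convenience summary: mean per-sample proportion per (group, region, type).
#'
#' @param composition the `composition` table of [run_pipeline()].
#' @return `data.frame` with `group`, `region`, `type`,
#'   `mean_proportion_pct`.
#' @export
group_mean_composition <- function(composition) {
  ag <- aggregate(proportion_pct ~ group + region + type,
                  data = composition, FUN = mean)
  names(ag)[names(ag) == "proportion_pct"] <- "mean_proportion_pct"
  ag[order(ag$group, ag$region, ag$type), ]
}
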