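#' Simulation configuration for synthetic tissue images
#'
#' Describes one synthetic multiplexed tissue sample: image geometry, a
#' lining band of fixed depth along the top edge (the rest of the image is
#' sub-lining), a hard-core nucleus point process, per-region cell-type
#' composition, and a simple intensity model. The intensity model is the
#' simplest one under which the highest-normalized-intensity typing rule is
#' Bayes-optimal, so recovery tests against ground truth are meaningful:
#'
#' * DAPI channel: sum of isotropic Gaussian blobs (sd = `nucleus_radius/2`),
#'   each scaled to peak `dapi_peak`, plus zero-mean Gaussian noise.
#' * each marker channel: `background_level` plus
#'   `signal_mean[true_type, channel]` over the nucleus's whole Voronoi cell,
#'   plus zero-mean Gaussian noise; all intensities clipped at 0
#'   (photon-like counts are non-negative).
#'
#' @param image_height,image_width image size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param lining_depth depth in pixels of the lining band along the top edge.
#' @param n_nuclei number of nuclei to place.
#' @param min_spacing hard-core distance between nucleus centroids (pixels).
#' @param nucleus_radius apparent nucleus radius in pixels (DAPI blob
#'   sd = `nucleus_radius / 2`).
#' @param composition_by_region named list with elements `lining` and
#'   `sublining`, each a named probability vector over cell types
#'   (names must match the marker channels; each sums to 1 within 1e-9).
#' @param channel_names ordered channel names, first entry the DAPI channel.
#' @param signal_mean numeric matrix, rows = cell types, columns = marker
#'   channels: mean added intensity of each type on each marker.
#' @param background_level named per-channel background (markers only;
#'   DAPI has no background term).
#' @param noise_sd named per-channel Gaussian noise sd (including DAPI).
#' @param dapi_peak peak intensity of one nuclear blob.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(image_height = 384, image_width = 384,
                       pixel_size = 0.65,
                       lining_depth = 48,
                       n_nuclei = 1000,
                       min_spacing = 6,
                       nucleus_radius = 2,
                       composition_by_region = tilted_composition(
                         c(DKK3 = 0.67, CD68 = 0.19, CD31 = 0.14),
                         lining_frac = lining_depth / image_height),
                       channel_names = c("DAPI", "CD31", "CD68", "DKK3"),
                       signal_mean = default_signal_mean(channel_names),
                       background_level = setNames(
                         rep(10, length(channel_names) - 1), channel_names[-1]),
                       noise_sd = setNames(
                         c(4, rep(10, length(channel_names) - 1)), channel_names),
                       dapi_peak = 100) {
  types <- rownames(signal_mean)
  for (rg in c("lining", "sublining")) {
    p <- composition_by_region[[rg]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9)
      stop("composition_by_region$", rg, " must sum to 1")
    if (!setequal(names(p), types))
      stop("composition types must match signal_mean rows")
  }
  stopifnot(image_height >= 1, image_width >= 1, pixel_size > 0,
            lining_depth >= 0, lining_depth <= image_height,
            n_nuclei >= 0, min_spacing >= 0, nucleus_radius > 0,
            identical(colnames(signal_mean), channel_names[-1]),
            all(signal_mean >= 0), all(background_level >= 0),
            all(noise_sd >= 0), dapi_peak > 0)
  structure(list(image_height = image_height, image_width = image_width,
                 pixel_size = pixel_size, lining_depth = lining_depth,
                 n_nuclei = n_nuclei, min_spacing = min_spacing,
                 nucleus_radius = nucleus_radius,
                 composition_by_region = composition_by_region,
                 channel_names = channel_names, cell_types = types,
                 signal_mean = signal_mean,
                 background_level = background_level, noise_sd = noise_sd,
                 dapi_peak = dapi_peak),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d x %d px, %d nuclei (spacing >= %g px), lining depth %d px\n",
              x$image_height, x$image_width, x$n_nuclei, x$min_spacing,
              x$lining_depth))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  for (rg in names(x$composition_by_region))
    cat(sprintf("  %s composition: %s\n", rg,
                paste(sprintf("%s=%.3f", names(x$composition_by_region[[rg]]),
                              x$composition_by_region[[rg]]), collapse = " ")))
  invisible(x)
}

# one marker per type: each cell type lights up only its own marker channel
default_signal_mean <- function(channel_names, signal = 60) {
  markers <- channel_names[-1]
  m <- diag(signal, length(markers))
  dimnames(m) <- list(markers, markers)
  m
}

#' Per-region compositions with lining/sub-lining enrichment
#'
#' Builds `composition_by_region` vectors whose area-weighted mixture equals
#' a target overall composition while enriching macrophage-like types in the
#' lining and vessel-like types in the sub-lining, mirroring the spatial
#' structure of synovial-like capsule tissue. The lining composition is the
#' overall one tilted by `tilt` (then renormalized); the sub-lining
#' composition is solved from the mixture constraint
#' `lining_frac * lining + (1 - lining_frac) * sublining = overall`, so with
#' uniform nucleus placement the expected overall composition is exactly the
#' target.
#'
#' @param overall named probability vector over cell types.
#' @param lining_frac expected fraction of ROI area (hence nuclei) in the
#'   lining region.
#' @param tilt named multiplicative tilt applied to the lining composition;
#'   values > 1 enrich a type in the lining. Types missing from `tilt`
#'   keep factor 1.
#' @return list with named probability vectors `lining` and `sublining`.
#' @export
tilted_composition <- function(overall, lining_frac,
                               tilt = c(CD68 = 2.5, CD31 = 0.5, DKK3 = 0.6)) {
  stopifnot(abs(sum(overall) - 1) < 1e-9, lining_frac > 0, lining_frac < 1)
  f <- rep(1, length(overall)); names(f) <- names(overall)
  f[names(tilt)[names(tilt) %in% names(f)]] <-
    tilt[names(tilt) %in% names(f)]
  lining <- overall * f / sum(overall * f)
  sublining <- (overall - lining_frac * lining) / (1 - lining_frac)
  if (any(sublining < 0))
    stop("tilt too strong: derived sub-lining composition would be negative")
  list(lining = lining, sublining = sublining)
}

#' Rectangular region mask with a lining band along the top edge
#'
#' @param config a [sim_config()].
#' @return a [region_mask()] whose first `lining_depth` rows are lining (1)
#'   and remaining rows sub-lining (2); the whole image is ROI.
#' @export
make_region_mask <- function(config) {
  m <- matrix(2L, config$image_height, config$image_width)
  if (config$lining_depth > 0) m[seq_len(config$lining_depth), ] <- 1L
  region_mask(m, config$pixel_size)
}

#' Place nucleus centroids by hard-core rejection sampling
#'
#' Draws centroids uniformly from ROI pixels, rejecting any candidate closer
#' than `min_spacing` (Euclidean) to an accepted centroid, until `n_nuclei`
#' are placed or the attempt budget (10000 * n_nuclei) is exhausted. Ids are
#' assigned 1..n in placement order; output is reproducible from `seed`.
#'
#' @param region_mask a [region_mask()] with at least one ROI pixel.
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param min_spacing hard-core distance in pixels (>= 0).
#' @param seed integer RNG seed.
#' @return a [nucleus_set()].
#' @export
place_nuclei <- function(region_mask, n_nuclei, min_spacing, seed) {
  stopifnot(n_nuclei >= 0, min_spacing >= 0)
  roi_idx <- which(region_mask$labels > 0)
  if (length(roi_idx) == 0) stop("empty ROI: region mask has no nonzero pixel")
  if (n_nuclei == 0) return(nucleus_set())
  set.seed(seed)
  H <- nrow(region_mask$labels)
  rows <- numeric(n_nuclei); cols <- numeric(n_nuclei)
  # spatial hash over grid cells of side min_spacing for neighbour queries
  cell <- max(min_spacing, 1)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  bkey <- function(r, c) paste(r %/% cell, c %/% cell)
  placed <- 0L
  attempts <- 0L
  budget <- 10000 * n_nuclei
  while (placed < n_nuclei && attempts < budget) {
    attempts <- attempts + 1L
    k <- roi_idx[sample.int(length(roi_idx), 1L)]
    r <- ((k - 1L) %% H) + 1L
    c <- ((k - 1L) %/% H) + 1L
    ok <- TRUE
    if (min_spacing > 0) {
      for (gr in (r %/% cell + -1:1)) for (gc in (c %/% cell + -1:1)) {
        nb <- buckets[[paste(gr, gc)]]
        if (!is.null(nb) &&
            any((rows[nb] - r)^2 + (cols[nb] - c)^2 < min_spacing^2)) {
          ok <- FALSE
        }
      }
    } else if (placed > 0 && any(rows[seq_len(placed)] == r &
                                 cols[seq_len(placed)] == c)) {
      ok <- FALSE   # never two nuclei on the identical pixel
    }
    if (ok) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
      key <- bkey(r, c)
      buckets[[key]] <- c(buckets[[key]], placed)
    }
  }
  if (placed < n_nuclei)
    stop(sprintf("placement infeasible: placed %d of %d nuclei within the attempt budget",
                 placed, n_nuclei))
  nucleus_set(rows, cols)
}

#' Draw ground-truth cell types for placed nuclei
#'
#' Each nucleus's type is drawn independently from its region's composition
#' vector, so sample-level type counts are multinomial draws from the
#' configured composition.
#'
#' @param nuclei a [nucleus_set()].
#' @param region_mask a [region_mask()].
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return ground-truth `data.frame`: `id`, `row`, `col`, `region`
#'   (`"lining"`/`"sublining"`), `true_type`.
#' @export
assign_true_types <- function(nuclei, region_mask, config, seed) {
  set.seed(seed)
  reg <- region_mask$labels[cbind(as.integer(round(nuclei$row)),
                                  as.integer(round(nuclei$col)))]
  types <- character(nrow(nuclei))
  for (rg in 1:2) {
    sel <- reg == rg
    if (!any(sel)) next
    p <- config$composition_by_region[[region_names[rg]]][config$cell_types]
    types[sel] <- sample(config$cell_types, sum(sel), replace = TRUE, prob = p)
  }
  data.frame(id = nuclei$id, row = nuclei$row, col = nuclei$col,
             region = region_names[reg], true_type = types)
}

#' Render a synthetic multiplex image from placed nuclei and ground truth
#'
#' Implements the simulator's intensity model (see [sim_config()]): Gaussian
#' DAPI blobs, tile-constant marker signal over each nucleus's Voronoi cell,
#' per-channel Gaussian noise, all clipped at zero. Deterministic per seed.
#'
#' @param nuclei a [nucleus_set()].
#' @param truth ground-truth table covering every nucleus id (from
#'   [assign_true_types()]).
#' @param config a [sim_config()].
#' @param seed integer RNG seed for the noise.
#' @return a [multiplex_image()].
#' @export
render_multiplex <- function(nuclei, truth, config, seed) {
  if (nrow(nuclei) > 0) {
    if (!all(nuclei$id %in% truth$id))
      stop("truth table must cover every nucleus id")
    if (!all(truth$true_type %in% config$cell_types))
      stop("unknown type in truth table: ",
           paste(setdiff(truth$true_type, config$cell_types), collapse = ", "))
  }
  H <- config$image_height; W <- config$image_width
  mask <- make_region_mask(config)
  set.seed(seed)
  dapi <- matrix(0, H, W)
  if (nrow(nuclei) > 0) {
    sd_blob <- config$nucleus_radius / 2
    w <- ceiling(4 * sd_blob)
    for (i in seq_len(nrow(nuclei))) {
      r0 <- round(nuclei$row[i]); c0 <- round(nuclei$col[i])
      rr <- max(1, r0 - w):min(H, r0 + w)
      cc <- max(1, c0 - w):min(W, c0 + w)
      g <- exp(-outer((rr - nuclei$row[i])^2, (cc - nuclei$col[i])^2, "+") /
                 (2 * sd_blob^2))
      dapi[rr, cc] <- dapi[rr, cc] + config$dapi_peak * g
    }
  }
  channels <- vector("list", length(config$channel_names))
  names(channels) <- config$channel_names
  ns <- config$noise_sd[config$channel_names[1]]
  if (ns > 0) dapi <- dapi + rnorm(H * W, 0, ns)
  channels[[1]] <- pmax(dapi, 0)
  type_of <- if (nrow(nuclei) > 0)
    setNames(truth$true_type, truth$id) else character(0)
  tile_labels <- if (nrow(nuclei) > 0) voronoi_label(nuclei, mask)$labels
                 else matrix(0L, H, W)
  for (ch in config$channel_names[-1]) {
    img <- matrix(config$background_level[ch], H, W)
    if (nrow(nuclei) > 0) {
      sig <- config$signal_mean[, ch]             # per-type signal on ch
      px_type <- type_of[as.character(tile_labels)]
      add <- sig[px_type]
      add[is.na(add)] <- 0                         # background pixels
      img <- img + matrix(add, H, W)
    }
    ns <- config$noise_sd[ch]
    if (ns > 0) img <- img + rnorm(H * W, 0, ns)
    channels[[ch]] <- pmax(img, 0)
  }
  multiplex_image(channels, config$pixel_size, dapi = config$channel_names[1])
}

#' Simulate one complete sample (mask, nuclei, truth, image)
#'
#' @param config a [sim_config()].
#' @param seed integer master seed for this sample; placement, type
#'   assignment and rendering use streams derived from it.
#' @return list with `mask`, `nuclei`, `truth`, `image`.
#' @export
simulate_sample <- function(config, seed) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  mask <- make_region_mask(config)
  nuclei <- place_nuclei(mask, config$n_nuclei, config$min_spacing, seeds[1])
  truth <- assign_true_types(nuclei, mask, config, seeds[2])
  image <- render_multiplex(nuclei, truth, config, seeds[3])
  list(mask = mask, nuclei = nuclei, truth = truth, image = image)
}

#' Simulate a two-group study
#'
#' Generates `n_samples_per_group` samples under the comparator configuration
#' and the same number under the disease configuration, with per-sample seeds
#' derived deterministically from the master seed, so the whole bundle is
#' reproducible from `(configs, seed)`.
#'
#' @param config_comparator,config_disease [sim_config()] objects; defaults
#'   emulate non-inflamed comparator capsule (67% DKK3+ fibroblasts,
#'   19% CD68+ macrophages, 14% CD31+ endothelium) versus inflamed tissue
#'   (50.3/27.1/22.6), with CD68 enriched in the lining and CD31 in the
#'   sub-lining region.
#' @param n_samples_per_group samples per group (>= 1).
#' @param seed integer master seed.
#' @return list of samples; each element is a [simulate_sample()] result plus
#'   `sample_id` (e.g. `"comparator_1"`) and `group`.
#' @export
simulate_study <- function(config_comparator = sim_config(),
                           config_disease = sim_config(
                             composition_by_region = tilted_composition(
                               c(DKK3 = 0.503, CD68 = 0.271, CD31 = 0.226),
                               lining_frac = 48 / 384)),
                           n_samples_per_group = 5,
                           seed = 1) {
  stopifnot(n_samples_per_group >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2 * n_samples_per_group)
  out <- list()
  i <- 0
  for (grp in c("comparator", "disease")) {
    cfg <- if (grp == "comparator") config_comparator else config_disease
    for (s in seq_len(n_samples_per_group)) {
      i <- i + 1
      smp <- simulate_sample(cfg, seeds[i])
      smp$sample_id <- paste0(grp, "_", s)
      smp$group <- grp
      out[[smp$sample_id]] <- smp
    }
  }
  out
}
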