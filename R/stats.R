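#' Region-stratified cellularity
#'
#' Counts nuclei per tissue region (at each nucleus's pixel position) and
#' converts region pixel areas to mm^2 using the mask's pixel size, giving
#' cell densities in cells/mm^2 for lining, sub-lining and total ROI.
#'
#' @param nuclei a [nucleus_set()].
#' @param region_mask a [region_mask()] with known pixel size.
#' @param sample_id sample name recorded in the output.
#' @return `data.frame`: `sample`, `region` (`"lining"`, `"sublining"`,
#'   `"total"`), `count`, `area_mm2`, `density_per_mm2` (`NA` for a
#'   zero-area region, which is flagged with a warning if it has nuclei).
#' @export
cellularity <- function(nuclei, region_mask, sample_id = "sample") {
  px_area_mm2 <- (region_mask$pixel_size^2) / 1e6
  if (nrow(nuclei) > 0) {
    reg <- region_mask$labels[cbind(as.integer(round(nuclei$row)),
                                    as.integer(round(nuclei$col)))]
    counts <- tabulate(reg, 2L)
  } else counts <- c(0L, 0L)
  areas_px <- c(sum(region_mask$labels == 1L), sum(region_mask$labels == 2L))
  stopifnot(all(areas_px > 0 | counts == 0))   # nuclei imply area
  counts <- c(counts, sum(counts))
  areas <- c(areas_px, sum(areas_px)) * px_area_mm2
  data.frame(sample = sample_id,
             region = c("lining", "sublining", "total"),
             count = as.integer(counts),
             area_mm2 = areas,
             density_per_mm2 = ifelse(areas > 0, counts / areas, NA_real_))
}

#' Percent-area immunopositivity, normalized to nuclei count
#'
#' Quantifies chromogenic (DAB-style) staining as the percentage of ROI
#' pixels whose intensity exceeds a threshold, and additionally normalizes
#' the positive area to the number of counterstained nuclei in the field of
#' view. If no threshold is given, Otsu's threshold over ROI pixels is used.
#'
#' @param stain a [channel_image()] with the stain intensity.
#' @param roi_mask a [region_mask()]; must have at least one ROI pixel.
#' @param threshold positivity threshold (strictly exceeded); default
#'   `NULL` = Otsu over the ROI.
#' @param nuclei_count number of nuclei in the field (>= 0).
#' @param sample_id sample name recorded in the output.
#' @return `data.frame` with one row: `sample`, `percent_area_positive`,
#'   `nuclei_count`, `positive_area_per_nucleus_um2` (`NA` when
#'   `nuclei_count` is 0), `threshold`.
#' @export
percent_area_positive <- function(stain, roi_mask, threshold = NULL,
                                  nuclei_count = 0, sample_id = "sample") {
  stopifnot(nuclei_count >= 0)
  roi <- roi_mask$labels > 0
  if (!any(roi)) stop("empty ROI: cannot quantify immunopositivity")
  v <- stain$values[roi]
  if (is.null(threshold)) threshold <- otsu_threshold(v)
  npos <- sum(v > threshold)
  data.frame(
    sample = sample_id,
    percent_area_positive = 100 * npos / length(v),
    nuclei_count = as.integer(nuclei_count),
    positive_area_per_nucleus_um2 = if (nuclei_count > 0)
      npos * roi_mask$pixel_size^2 / nuclei_count else NA_real_,
    threshold = threshold)
}

#' Exact tie-aware two-sided Mann-Whitney U test
#'
#' Computes the Mann-Whitney statistic for group `a`,
#' `U = #\{(i, j): a_i > b_j\} + 0.5 * #ties`, and a two-sided p-value.
#' When the pooled sample size is at most `exact_max` (default 20) the
#' p-value is exact: all `choose(n1 + n2, n1)` assignments of the pooled
#' (tie-aware) values to groups are enumerated and the two-sided p is the
#' probability mass of assignments at least as far from the null mean
#' `n1 * n2 / 2` as the observed U (the reflection rule, which stays correct
#' when ties make the permutation distribution asymmetric). For larger
#' samples the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric vectors, each non-empty.
#' @param exact_max pooled-size cutoff for the exact path (default 20).
#' @return object of class `mann_whitney`: list with `U`, `p_value`,
#'   `method` (`"exact"`/`"normal_approximation"`), `n1`, `n2`,
#'   `median_a`, `median_b`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))                       # midranks handle ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    sets <- combn(n, n1)
    ranksums <- colSums(matrix(r[sets], nrow = n1))
    Us <- ranksums - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal_approximation"
  }
  structure(list(U = U, p_value = p, method = method, n1 = n1, n2 = n2,
                 median_a = median(a), median_b = median(b)),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  cat(sprintf("  medians: %g vs %g\n", x$median_a, x$median_b))
  invisible(x)
}

#' Two-group comparison of per-sample endpoint values
#'
#' Runs one two-sided Mann-Whitney test per endpoint on per-sample values.
#' Unadjusted p-values are the primary output (matching routine practice for
#' small imaging cohorts); a Benjamini-Hochberg adjusted column can be added.
#'
#' @param values long `data.frame` with columns `endpoint`, `group`, `value`
#'   (one row per sample per endpoint) and exactly two group levels.
#' @param adjust if `TRUE`, append a `p_adj` column (Benjamini-Hochberg).
#' @return `data.frame`: `endpoint`, `n1`, `n2`, `median1`, `median2`, `U`,
#'   `p`, `method` (groups ordered alphabetically).
#' @export
compare_endpoints <- function(values, adjust = FALSE) {
  stopifnot(all(c("endpoint", "group", "value") %in% names(values)))
  grps <- sort(unique(values$group))
  if (length(grps) != 2) stop("exactly two groups are required")
  res <- lapply(split(values, values$endpoint), function(d) {
    va <- d$value[d$group == grps[1]]
    vb <- d$value[d$group == grps[2]]
    mw <- mann_whitney_u(va, vb)
    data.frame(endpoint = d$endpoint[1], n1 = mw$n1, n2 = mw$n2,
               median1 = mw$median_a, median2 = mw$median_b,
               U = mw$U, p = mw$p_value, method = mw$method)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out <- out[order(out$endpoint), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust) out$p_adj <- p.adjust(out$p, "BH")
  out
}

#' Compare tile compositions (and optional scalar endpoints) between groups
#'
#' Builds one endpoint per (region, cell type) from stacked per-sample
#' composition tables and tests each with the two-sided Mann-Whitney test on
#' the per-sample proportions. Extra per-sample scalar endpoints (e.g.
#' lining cellularity, % area immunopositive) can be appended through
#' `extra`.
#'
#' @param compositions stacked [composition_table()] rows with an added
#'   `group` column (two levels).
#' @param extra optional `data.frame` with columns `endpoint`, `group`,
#'   `value`, appended as additional endpoints.
#' @param adjust passed to [compare_endpoints()].
#' @return `data.frame` as [compare_endpoints()], plus columns `region` and
#'   `type` parsed back out of the composition endpoints (`NA` for extras).
#' @export
compare_compositions <- function(compositions, extra = NULL, adjust = FALSE) {
  stopifnot(all(c("sample", "region", "type", "proportion_pct", "group")
                %in% names(compositions)))
  comp <- compositions[!is.na(compositions$proportion_pct), ]
  vals <- data.frame(endpoint = paste(comp$region, comp$type, sep = "|"),
                     group = comp$group, value = comp$proportion_pct)
  if (!is.null(extra)) {
    stopifnot(all(c("endpoint", "group", "value") %in% names(extra)))
    vals <- rbind(vals, extra[, c("endpoint", "group", "value")])
  }
  out <- compare_endpoints(vals, adjust = adjust)
  parts <- strsplit(out$endpoint, "|", fixed = TRUE)
  is_comp <- lengths(parts) == 2
  out$region <- ifelse(is_comp, vapply(parts, `[`, "", 1), NA_character_)
  out$type <- ifelse(is_comp, vapply(parts, `[`, "", 2), NA_character_)
  out
}
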