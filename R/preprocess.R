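#' Median despeckle filter
#'
#' Replaces each pixel by the median over its disc neighbourhood, using the
#' standard imaging convention for fractional radii: the neighbourhood of
#' radius `r = max(radius, 0.5)` contains the centre plus all pixels whose
#' squared centre-to-centre distance is at most `floor(r^2) + 1`. Radius 0.5
#' therefore gives the classical 5-pixel cross (centre + 4-neighbours) used
#' as an outlier filter on single-marker greyscale images; radius 0 is the
#' identity. Borders are handled by edge reflection, and output dimensions
#' equal input dimensions.
#'
#' @param channel a [channel_image()].
#' @param radius neighbourhood radius in pixels (>= 0).
#' @return the filtered [channel_image()] (same name and normalized flag).
#' @export
median_despeckle <- function(channel, radius) {
  stopifnot(radius >= 0)
  if (radius == 0) return(channel)
  r <- max(radius, 0.5)
  d2max <- floor(r^2) + 1
  w <- ceiling(sqrt(d2max))
  off <- expand.grid(dr = -w:w, dc = -w:w)
  off <- off[off$dr^2 + off$dc^2 <= d2max, ]
  x <- channel$values
  H <- nrow(x); W <- ncol(x)
  # reflect-pad by w (no repeated edge pixel), then gather the shifted
  # neighbourhood as columns of a (H*W) x k matrix
  refl <- function(n, w) {
    i <- (1 - w):(n + w)
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 2 - i[i < 1]
      i[i > n] <- 2 * n - i[i > n]
    }
    i
  }
  ri <- refl(H, w); ci <- refl(W, w)
  pad <- x[ri, ci, drop = FALSE]
  k <- nrow(off)
  stack <- matrix(0, H * W, k)
  for (j in seq_len(k)) {
    stack[, j] <- pad[w + off$dr[j] + seq_len(H), w + off$dc[j] + seq_len(W)]
  }
  med <- if (k == 5) median5(stack[, 1], stack[, 2], stack[, 3], stack[, 4], stack[, 5])
         else apply(stack, 1, median)
  channel_image(matrix(med, H, W), channel$name, channel$normalized)
}

# vectorized exact median of five values (classic elimination network):
# drop the smaller pair-minimum and larger pair-maximum, then median of 3.
median5 <- function(a, b, c, d, e) {
  lo <- pmax(pmin(a, b), pmin(c, d))
  hi <- pmin(pmax(a, b), pmax(c, d))
  pmax(pmin(lo, hi), pmin(pmax(lo, hi), e))
}

#' Robust percentile normalization of a channel over the ROI
#'
#' Computes the `p_low` and `p_high` percentiles of the channel over ROI
#' pixels only (linear-interpolation percentile definition, i.e.
#' `stats::quantile` type 7) and rescales the whole image as
#' `clip((x - q_low) / (q_high - q_low), 0, 1)`. This makes channels with
#' different dynamic ranges comparable before the per-tile argmax type call,
#' and makes the call invariant to per-channel affine transforms
#' `a*x + b` with `a > 0`.
#'
#' If the channel is constant over the ROI (`q_high == q_low`) the output is
#' all zeros and a degeneracy warning of class `tilecyte_degenerate` is
#' raised (collected into the QC report by the pipeline).
#'
#' @param channel a [channel_image()].
#' @param roi_mask a [region_mask()]; percentiles use its nonzero pixels.
#' @param p_low,p_high percentiles in \[0, 100\], `p_low < p_high`.
#'   Defaults 1 and 99.
#' @return a normalized [channel_image()] with attribute `quantiles`
#'   (named vector `q_low`, `q_high`).
#' @export
normalize_channel <- function(channel, roi_mask, p_low = 1, p_high = 99) {
  stopifnot(p_low >= 0, p_high <= 100, p_low < p_high)
  roi <- roi_mask$labels > 0
  if (!any(roi)) stop("empty ROI: cannot normalize")
  q <- unname(quantile(channel$values[roi], c(p_low, p_high) / 100,
                       type = 7, names = FALSE))
  if (q[2] <= q[1]) {
    warning(warningCondition(
      sprintf("channel '%s' is constant over the ROI; normalized to all zeros",
              channel$name),
      class = "tilecyte_degenerate"))
    out <- channel_image(matrix(0, nrow(channel$values), ncol(channel$values)),
                         channel$name, normalized = TRUE)
  } else {
    v <- pmin(pmax((channel$values - q[1]) / (q[2] - q[1]), 0), 1)
    out <- channel_image(v, channel$name, normalized = TRUE)
  }
  attr(out, "quantiles") <- c(q_low = q[1], q_high = q[2])
  out
}

# Otsu threshold on a plain vector of intensities (maximizes between-class
# variance over a binned histogram). Written in-package so it can run over
# ROI pixels only; EBImage's otsu() thresholds whole rectangular images.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  mids[k]
}
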