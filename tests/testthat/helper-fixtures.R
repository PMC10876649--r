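# Shared fixtures: all fixtures are generated in code at test time.

# all-ROI rectangular mask (every pixel sub-lining unless lining_depth > 0)
all_roi_mask <- function(h, w, pixel_size = 1, lining_depth = 0) {
  m <- matrix(2L, h, w)
  if (lining_depth > 0) m[seq_len(lining_depth), ] <- 1L
  region_mask(m, pixel_size)
}

# random blobby ROI: union of a few random discs (works at any image size)
random_mask <- function(h, w, seed) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  rr <- row(m); cc <- col(m)
  for (i in 1:3) {
    ctr <- c(runif(1, 1, h), runif(1, 1, w))
    rad <- runif(1, min(h, w) / 4, min(h, w) / 2)
    m[(rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2] <- 2L
  }
  if (sum(m) == 0) m[1, 1] <- 2L
  region_mask(m, 1)
}

# random nucleus set on distinct ROI pixels
random_nuclei_on <- function(mask, n, seed) {
  set.seed(seed)
  idx <- which(mask$labels > 0)
  pick <- sample(idx, min(n, length(idx)))
  h <- nrow(mask$labels)
  nucleus_set(row = ((pick - 1) %% h) + 1, col = ((pick - 1) %/% h) + 1)
}

# small simulation config for fast tests
small_config <- function(n_nuclei = 150, h = 128, w = 128, lining_depth = 16,
                         overall = c(DKK3 = 0.67, CD68 = 0.19, CD31 = 0.14),
                         ...) {
  sim_config(image_height = h, image_width = w, lining_depth = lining_depth,
             n_nuclei = n_nuclei,
             composition_by_region = tilted_composition(overall, lining_depth / h),
             ...)
}

# Independent Mann-Whitney oracle: full enumeration with U computed by
# direct pair counting (never via ranks, unlike the implementation).
oracle_mann_whitney <- function(a, b) {
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  cmb <- combn(n, n1)
  Us <- apply(cmb, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  U_obs <- u_of(a, b)
  mu <- n1 * (n - n1) / 2
  list(U = U_obs, p = mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9))
}
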