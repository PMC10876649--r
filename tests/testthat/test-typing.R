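make_feature_fixture <- function() {
  # 1x4 strip, two tiles of two pixels each, three marker channels
  mask <- region_mask(matrix(2L, 1, 4), 1)
  nuc <- nucleus_set(row = c(1, 1), col = c(1, 4))
  tiles <- voronoi_label(nuc, mask)
  ch <- function(v, nm) channel_image(matrix(v, 1, 4), nm, normalized = TRUE)
  list(mask = mask, nuc = nuc, tiles = tiles, ch = ch)
}

test_that("tile aggregation implements mean, median and max per tile", {
  f <- make_feature_fixture()
  chans <- list(CD31 = f$ch(c(0.2, 0.4, 0.1, 0.3), "CD31"))
  expect_equal(unname(tile_intensity_matrix(f$tiles, chans, "mean")[, 1]),
               c(0.3, 0.2))
  expect_equal(unname(tile_intensity_matrix(f$tiles, chans, "max")[, 1]),
               c(0.4, 0.3))
  expect_equal(unname(tile_intensity_matrix(f$tiles, chans, "median")[, 1]),
               c(0.3, 0.2))
  zero <- list(CD31 = f$ch(rep(0, 4), "CD31"), CD68 = f$ch(rep(0, 4), "CD68"))
  expect_true(all(tile_intensity_matrix(f$tiles, zero) == 0))
  raw <- list(CD31 = channel_image(matrix(1, 1, 4), "CD31"))
  expect_error(tile_intensity_matrix(f$tiles, raw), "must be normalized")
})

test_that("type calls are the argmax with deterministic tie and threshold rules", {
  m <- rbind(c(0.9, 0.1, 0.2), c(0.1, 0.8, 0.05))
  dimnames(m) <- list(1:2, c("CD31", "CD68", "DKK3"))
  tr <- data.frame(tile_id = 1:2, region = c("lining", "sublining"))
  tt <- call_tile_types(m, tr)
  expect_equal(tt$called_type, c("CD31", "CD68"))
  expect_equal(tt$winning_score, c(0.9, 0.8))
  expect_equal(tt$region, c("lining", "sublining"))
  # exact tie resolved by tie_order
  m2 <- matrix(c(0.5, 0.5, 0.2), 1, dimnames = list(1, c("CD31", "CD68", "DKK3")))
  tr1 <- data.frame(tile_id = 1, region = "lining")
  expect_equal(call_tile_types(m2, tr1)$called_type, "CD31")
  expect_equal(call_tile_types(m2, tr1,
                 tie_order = c("CD68", "CD31", "DKK3"))$called_type, "CD68")
  # sub-threshold winner becomes unassigned
  m3 <- matrix(c(0.05, 0.02, 0.01), 1,
               dimnames = list(1, c("CD31", "CD68", "DKK3")))
  expect_equal(call_tile_types(m3, tr1, min_score = 0.1)$called_type,
               "unassigned")
  expect_equal(call_tile_types(m3, tr1)$called_type, "CD31")
})

test_that("composition tables count, normalize to 100% and keep zero types", {
  tt <- data.frame(tile_id = 1:4,
                   called_type = c("CD31", "CD68", "DKK3", "DKK3"),
                   winning_score = 1, region = "sublining")
  attr(tt, "type_levels") <- c("CD31", "CD68", "DKK3", "unassigned")
  comp <- composition_table(tt, "s1")
  cmb <- comp[comp$region == "combined", ]
  expect_equal(cmb$proportion_pct[match(c("CD31", "CD68", "DKK3"), cmb$type)],
               c(25, 25, 50))
  for (rg in c("sublining", "combined")) {
    sel <- comp$region == rg
    expect_equal(sum(comp$proportion_pct[sel]), 100)
    expect_equal(sum(comp$count[sel]), 4)
  }
  expect_true(all(is.na(comp$proportion_pct[comp$region == "lining"])))
  expect_error(composition_table(tt[0, ], "s1"), "no tiles")
})

test_that("noise-free simulated tiles win on their true type's channel", {
  cfg <- small_config(n_nuclei = 40, h = 64, w = 64, lining_depth = 8,
                      noise_sd = c(DAPI = 0, CD31 = 0, CD68 = 0, DKK3 = 0))
  s <- simulate_sample(cfg, 9)
  tiles <- voronoi_label(s$nuclei, s$mask)
  tr <- assign_tile_regions(tiles, s$mask, s$nuclei)
  norm <- lapply(c("CD31", "CD68", "DKK3"), function(nm)
    normalize_channel(channel_image(s$image$channels[[nm]], nm), s$mask))
  names(norm) <- c("CD31", "CD68", "DKK3")
  feats <- tile_intensity_matrix(tiles, norm)
  tt <- call_tile_types(feats, tr)
  expect_equal(tt$called_type[match(s$truth$id, tt$tile_id)], s$truth$true_type)
})

test_that("conservation: counts over types and regions equal the tile total", {
  cfg <- small_config(n_nuclei = 120)
  s <- simulate_sample(cfg, 21)
  res <- quantify_sample(s$image, s$mask, run_config(use_true_nuclei = TRUE),
                         "s", nuclei = s$nuclei)
  comp <- res$composition
  expect_equal(sum(comp$count[comp$region != "combined"]), 120)
  expect_equal(sum(comp$count[comp$region == "combined"]), 120)
  expect_equal(sum(res$tile_regions$area), sum(s$mask$labels > 0))
})
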