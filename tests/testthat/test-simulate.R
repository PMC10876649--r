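test_that("place_nuclei respects the hard-core constraint and the empty case", {
  mask <- all_roi_mask(64, 64)
  expect_equal(nrow(place_nuclei(mask, 0, 5, seed = 1)), 0)
  nuc <- place_nuclei(mask, 60, min_spacing = 5, seed = 1)
  expect_equal(nuc$id, 1:60)
  expect_true(all(mask$labels[cbind(round(nuc$row), round(nuc$col))] > 0))
  d <- as.matrix(dist(cbind(nuc$row, nuc$col)))
  expect_gte(min(d[upper.tri(d)]), 5)
})

test_that("place_nuclei is reproducible per seed and differs across seeds", {
  mask <- all_roi_mask(256, 256)
  a1 <- place_nuclei(mask, 500, 6, seed = 11)
  a2 <- place_nuclei(mask, 500, 6, seed = 11)
  b <- place_nuclei(mask, 500, 6, seed = 12)
  expect_identical(a1, a2)
  expect_false(identical(a1, b))
  d <- as.matrix(dist(cbind(b$row, b$col)))
  expect_gte(min(d[upper.tri(d)]), 6)
})

test_that("infeasible placement errors and names the achieved count", {
  mask <- all_roi_mask(10, 10)
  expect_error(place_nuclei(mask, 50, min_spacing = 8, seed = 1),
               "placement infeasible: placed \\d+ of 50")
})

test_that("render_multiplex: background-only and single-nucleus cases", {
  cfg <- small_config(n_nuclei = 0, h = 32, w = 32, lining_depth = 4,
                      background_level = c(CD31 = 10, CD68 = 10, DKK3 = 10),
                      noise_sd = c(DAPI = 0, CD31 = 0, CD68 = 0, DKK3 = 0))
  img <- render_multiplex(nucleus_set(), data.frame(), cfg, seed = 1)
  expect_true(all(img$channels$DAPI == 0))
  for (m in c("CD31", "CD68", "DKK3")) expect_true(all(img$channels[[m]] == 10))

  nuc <- nucleus_set(16, 16)
  truth <- data.frame(id = 1L, row = 16, col = 16, region = "sublining",
                      true_type = "CD31")
  img1 <- render_multiplex(nuc, truth, cfg, seed = 1)
  sig <- cfg$signal_mean["CD31", "CD31"]
  expect_true(all(img1$channels$CD31 == 10 + sig))  # single tile covers ROI
  expect_true(all(img1$channels$CD68 == 10))
  expect_true(all(img1$channels$DKK3 == 10))
  expect_error(render_multiplex(nuc, transform(truth, true_type = "XYZ"), cfg, 1),
               "unknown type")
})

test_that("rendered channel means match the analytic expectation", {
  cfg <- small_config(n_nuclei = 100, h = 128, w = 128,
                      noise_sd = c(DAPI = 2, CD31 = 2, CD68 = 2, DKK3 = 2))
  s <- simulate_sample(cfg, 5)
  tiles <- voronoi_label(s$nuclei, s$mask)
  areas <- tabulate(tiles$labels[tiles$labels > 0], nbins = 100)
  npix <- sum(s$mask$labels > 0)
  type_of <- setNames(s$truth$true_type, s$truth$id)
  for (m in c("CD31", "CD68", "DKK3")) {
    expected <- cfg$background_level[m] +
      sum(cfg$signal_mean[type_of[as.character(1:100)], m] * areas) / npix
    se <- 2 / sqrt(npix)
    expect_lt(abs(mean(s$image$channels[[m]]) - expected), 3 * se)
  }
})

test_that("simulate_study is deterministic and reflects its group compositions", {
  cfgA <- small_config(n_nuclei = 200)
  cfgB <- small_config(n_nuclei = 200,
                       overall = c(DKK3 = 0.503, CD68 = 0.271, CD31 = 0.226))
  s1 <- simulate_study(cfgA, cfgB, n_samples_per_group = 2, seed = 3)
  s2 <- simulate_study(cfgA, cfgB, n_samples_per_group = 2, seed = 3)
  expect_identical(s1, s2)
  frac <- function(s) mean(s$truth$true_type == "DKK3")
  dkk3 <- vapply(s1, frac, numeric(1))
  grp <- vapply(s1, `[[`, "", "group")
  expect_gt(mean(dkk3[grp == "comparator"]), mean(dkk3[grp == "disease"]))
})

test_that("per-sample DKK3 fraction lies in a 99% binomial interval of the target", {
  cfg <- small_config(n_nuclei = 1000, h = 384, w = 384, lining_depth = 48)
  mask <- make_region_mask(cfg)
  lim <- qbinom(c(0.005, 0.995), 1000, 0.67) / 1000
  for (seed in 1:3) {
    nuc <- place_nuclei(mask, 1000, cfg$min_spacing, seed)
    truth <- assign_true_types(nuc, mask, cfg, seed + 100)
    f <- mean(truth$true_type == "DKK3")
    expect_gte(f, lim[1]); expect_lte(f, lim[2])
    expect_true(all(truth$region ==
      c("lining", "sublining")[mask$labels[cbind(nuc$row, nuc$col)]]))
  }
})

test_that("truth-label proportions calibrate to the configured composition", {
  cfg <- sim_config()   # study conditions: 1000 nuclei, 67/19/14 overall
  mask <- make_region_mask(cfg)
  overall <- c(DKK3 = 0.67, CD68 = 0.19, CD31 = 0.14)
  props <- matrix(0, 20, 3, dimnames = list(NULL, names(overall)))
  lin_cd68 <- sub_cd68 <- numeric(20)
  for (r in 1:20) {
    nuc <- place_nuclei(mask, cfg$n_nuclei, cfg$min_spacing, 1000 + r)
    truth <- assign_true_types(nuc, mask, cfg, 2000 + r)
    props[r, ] <- prop.table(table(factor(truth$true_type,
                                          names(overall))))[names(overall)]
    lin_cd68[r] <- mean(truth$true_type[truth$region == "lining"] == "CD68")
    sub_cd68[r] <- mean(truth$true_type[truth$region == "sublining"] == "CD68")
  }
  expect_true(all(abs(colMeans(props) - overall) < 0.02))
  expect_gt(mean(lin_cd68), mean(sub_cd68))  # configured lining enrichment
})

test_that("tilted_composition preserves the overall mixture and enrichment", {
  overall <- c(DKK3 = 0.67, CD68 = 0.19, CD31 = 0.14)
  cb <- tilted_composition(overall, lining_frac = 0.125)
  mix <- 0.125 * cb$lining + 0.875 * cb$sublining
  expect_equal(unname(mix), unname(overall), tolerance = 1e-12)
  expect_gt(cb$lining["CD68"], cb$sublining["CD68"])
  expect_lt(cb$lining["CD31"], cb$sublining["CD31"])
  expect_error(tilted_composition(overall, 0.5, tilt = c(CD68 = 10)),
               "tilt too strong")
})
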