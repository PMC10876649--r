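test_that("cellularity counts nuclei per region and converts areas", {
  # 1000 x 1000 px at 1 um/px = exactly 1 mm^2 of ROI
  mask <- all_roi_mask(1000, 1000, pixel_size = 1)
  nuc <- random_nuclei_on(mask, 10, 3)
  cel <- cellularity(nuc, mask, "s")
  tot <- cel[cel$region == "total", ]
  expect_equal(tot$count, 10L)
  expect_equal(tot$area_mm2, 1)
  expect_equal(tot$density_per_mm2, 10)
  expect_equal(cel$count[1] + cel$count[2], cel$count[3])
  empty <- cellularity(nucleus_set(), mask)
  expect_true(all(empty$count == 0))
})

test_that("simulated cellularity equals the ground-truth region tallies", {
  cfg <- small_config(n_nuclei = 300)
  s <- simulate_sample(cfg, 31)
  cel <- cellularity(s$nuclei, s$mask, "s")
  expect_equal(cel$count[cel$region == "lining"],
               sum(s$truth$region == "lining"))
  expect_equal(cel$count[cel$region == "sublining"],
               sum(s$truth$region == "sublining"))
})

test_that("percent-area positivity handles the all/none/checkerboard cases", {
  mask <- all_roi_mask(8, 8, pixel_size = 2)
  hi <- channel_image(matrix(10, 8, 8), "DAB")
  expect_equal(percent_area_positive(hi, mask, threshold = 5,
                                     nuclei_count = 4)$percent_area_positive, 100)
  expect_equal(percent_area_positive(hi, mask, threshold = 5,
                 nuclei_count = 4)$positive_area_per_nucleus_um2, 64 * 4 / 4)
  expect_equal(percent_area_positive(hi, mask,
                                     threshold = 20)$percent_area_positive, 0)
  chk <- channel_image(matrix(c(1, 9), 8, 8), "DAB")   # exact checkerboard
  expect_equal(percent_area_positive(chk, mask,
                                     threshold = 5)$percent_area_positive, 50)
  expect_true(is.na(percent_area_positive(hi, mask, threshold = 5,
                      nuclei_count = 0)$positive_area_per_nucleus_um2))
  expect_error(percent_area_positive(hi, region_mask(matrix(0L, 8, 8), 1), 5),
               "empty ROI")
})

test_that("percent-area positivity is non-increasing in the threshold", {
  set.seed(5)
  mask <- random_mask(30, 30, 11)
  st <- channel_image(matrix(rexp(900, 1 / 20), 30, 30), "DAB")
  pcts <- vapply(c(0, 5, 10, 20, 40, 80), function(th)
    percent_area_positive(st, mask, th)$percent_area_positive, numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("worked Mann-Whitney examples reproduce the enumeration exactly", {
  mw1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw1$U, 0)
  expect_equal(mw1$p_value, 1 / 3)
  expect_equal(mw1$method, "exact")
  mw2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(mw2$U, 1)
  expect_equal(mw2$p_value, 2 / 3)
  # complete tie: degenerate distribution centred at n1*n2/2
  mw3 <- mann_whitney_u(5, 5)
  expect_equal(mw3$U, 0.5)
  expect_equal(mw3$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact path equals the full-enumeration oracle on tied samples", {
  set.seed(6)
  for (k in 1:40) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    a <- sample(0:4, n1, TRUE)   # heavy ties
    b <- sample(0:4, n2, TRUE)
    got <- mann_whitney_u(a, b)
    want <- oracle_mann_whitney(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p)
    # symmetry: swapping groups reflects U and preserves p
    rev <- mann_whitney_u(b, a)
    expect_equal(rev$U, n1 * n2 - got$U)
    expect_equal(rev$p_value, got$p_value)
  }
})

test_that("normal approximation tracks the exact p for tie-free samples", {
  set.seed(7)
  for (k in 1:10) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    exact <- mann_whitney_u(a, b, exact_max = 20)
    approx <- mann_whitney_u(a, b, exact_max = 0)
    expect_equal(approx$method, "normal_approximation")
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
    # independent cross-check of the approximate path
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(approx$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(exact$method, "exact")
  }
})

test_that("endpoint comparison is consistent with the unit test statistic", {
  comp <- rbind(
    data.frame(sample = c("a1", "a2"), region = "combined", type = "DKK3",
               count = 0, proportion_pct = c(65, 66), n_tiles = 100,
               group = "comparator"),
    data.frame(sample = c("b1", "b2"), region = "combined", type = "DKK3",
               count = 0, proportion_pct = c(50, 51), n_tiles = 100,
               group = "disease"))
  out <- compare_compositions(comp)
  direct <- mann_whitney_u(c(65, 66), c(50, 51))
  expect_equal(out$p, direct$p_value)
  expect_equal(out$U, direct$U)
  expect_equal(out$method, "exact")
  expect_equal(out$region, "combined"); expect_equal(out$type, "DKK3")
  # identical group vectors give p = 1 for every endpoint
  same <- transform(comp, proportion_pct = rep(c(60, 61), 2),
                    group = rep(c("g1", "g2"), each = 2))
  expect_equal(compare_compositions(same)$p, 1)
})

test_that("a configured DKK3 shift is detected in nearly all replicate studies", {
  # Monte-Carlo over ground-truth tables: fixed geometry, 7 samples/group,
  # per-sample type draws from 67/19/14 vs 50.3/27.1/22.6 compositions
  cfgA <- small_config(n_nuclei = 1000, h = 384, w = 384, lining_depth = 48)
  cfgB <- small_config(n_nuclei = 1000, h = 384, w = 384, lining_depth = 48,
                       overall = c(DKK3 = 0.503, CD68 = 0.271, CD31 = 0.226))
  mask <- make_region_mask(cfgA)
  nucA <- place_nuclei(mask, 1000, cfgA$min_spacing, seed = 41)
  nucB <- place_nuclei(mask, 1000, cfgB$min_spacing, seed = 42)
  hits <- 0
  for (r in 1:100) {
    fa <- vapply(1:7, function(i) mean(assign_true_types(
      nucA, mask, cfgA, seed = 10000 + 7 * r + i)$true_type == "DKK3"),
      numeric(1))
    fb <- vapply(1:7, function(i) mean(assign_true_types(
      nucB, mask, cfgB, seed = 20000 + 7 * r + i)$true_type == "DKK3"),
      numeric(1))
    if (mann_whitney_u(fa, fb)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
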