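test_that("voxel volume conversion is exact", {
  expect_equal(voxel_volume_liters(c(10, 10, 10)), 0.001)
  expect_equal(voxel_volume_liters(c(1, 1, 1)), 1e-6)
  expect_equal(voxel_volume_liters(c(0.7, 0.7, 1.25)), 6.125e-7)
  expect_error(voxel_volume_liters(c(0, 1, 1)), "positive")
})

test_that("density_mask agrees with a naive triple-loop count", {
  set.seed(31)
  for (rep in 1:20) {
    d <- sample(3:8, 3, replace = TRUE)
    hu <- array(sample(-1024:200, prod(d), replace = TRUE), dim = d)
    mask <- array(stats::runif(prod(d)) < 0.7, dim = d)
    ct <- ct_volume(hu, c(1, 1, 1))
    for (w in 1:5) {
      lo <- sample(-1024:(-100), 1)
      hi <- lo + sample(1:500, 1)
      dm <- density_mask(ct, mask, c(lo, hi))
      expect_identical(dm$count, oracle_density_count(hu, mask, lo, hi))
    }
  }
})

test_that("WAL/LAA boundary convention: -950 is WAL, not LAA; -750 is WAL", {
  hu <- array(c(-960, -951, -950, -850, -750, -749, -400, 100), dim = c(2, 2, 2))
  ct <- ct_volume(hu, c(10, 10, 10))
  lobes <- lobe_label_map(array(1L, c(2, 2, 2)), c(10, 10, 10))
  q <- quantify_lobes(ct, lobes)
  # WAL (closed [-950, -750]): exactly -950, -850, -750
  expect_identical(q$total$n_wal, 3L)
  # LAA (strictly < -950): -960 and -951 only
  expect_identical(q$total$n_laa, 2L)
  expect_equal(q$total$wal_l, 0.003)
  expect_equal(q$total$laa_l, 0.002)
  expect_equal(q$pct_laa, 100 * 2 / 8)
})

test_that("quantify_lobes reproduces a hand-counted single-lobe example", {
  # 100 voxels: 20 at -980, 70 at -850, 10 at -400, spacing 10 mm
  hu <- array(c(rep(-980, 20), rep(-850, 70), rep(-400, 10), rep(-1000, 25)),
              dim = c(5, 5, 5))
  labels <- array(c(rep(1L, 100), rep(0L, 25)), dim = c(5, 5, 5))
  q <- quantify_lobes(ct_volume(hu, c(10, 10, 10)),
                      lobe_label_map(labels, c(10, 10, 10)))
  expect_equal(q$lobes$wal_l[1], 0.070)
  expect_equal(q$lobes$laa_l[1], 0.020)
  expect_equal(q$pct_laa, 20)
})

test_that("whole-lung counts are lobe sums and windows are monotone", {
  ph <- make_phantom(phantom_spec(grid_shape = c(24, 24, 24), seed = 21))
  q <- quantify_lobes(ph$ct, ph$lobes)
  expect_identical(q$total$n_wal, sum(q$lobes$n_wal))
  expect_identical(q$total$n_voxels, sum(q$lobes$n_voxels))
  expect_true(q$total$n_wal + q$total$n_laa <= q$total$n_voxels)
  mask <- unclass(ph$lobes) > 0
  narrow <- density_mask(ph$ct, mask, c(-950, -750))
  wide <- density_mask(ph$ct, mask, c(-1000, -700))
  expect_gte(wide$count, narrow$count)
  expect_error(quantify_lobes(ph$ct,
                              lobe_label_map(array(0L, c(24, 24, 24)), c(2, 2, 2))),
               "all background")
})

test_that("noise_reduce is a median filter with identity at radius 0", {
  ph <- make_phantom(phantom_spec(grid_shape = c(16, 16, 16), seed = 5))
  expect_identical(noise_reduce(ph$ct, 0L), ph$ct)
  const <- ct_volume(array(-500L, c(5, 5, 5)), c(1, 1, 1))
  expect_identical(unclass(noise_reduce(const, 2L)), unclass(const))
  # lone bright voxel in a dark neighbourhood is replaced by the median
  hu <- array(-850L, c(3, 3, 3)); hu[2, 2, 2] <- -400L
  sm <- noise_reduce(ct_volume(hu, c(1, 1, 1)), 1L)
  expect_identical(sm[2, 2, 2], -850L)
  # brute-force check of an interior voxel on a random volume
  set.seed(9)
  hu2 <- array(sample(-1000:0, 125, replace = TRUE), dim = c(5, 5, 5))
  sm2 <- noise_reduce(ct_volume(hu2, c(1, 1, 1)), 1L)
  expect_identical(sm2[3, 3, 3], as.integer(stats::median(hu2[2:4, 2:4, 2:4])))
  # output range contained in input range
  expect_gte(min(sm2), min(hu2))
  expect_lte(max(sm2), max(hu2))
  expect_error(noise_reduce(ph$ct, -1), "non-negative")
})

test_that("segment_lungs recovers phantom lungs and handles degenerate volumes", {
  # aerated-only phantom: every lung voxel is below the -300 HU threshold,
  # so the threshold + connected-components route must recover the lungs
  # exactly
  comp <- default_composition()
  comp$f_emph <- 0.05; comp$f_nonaer <- 0; comp$f_wal <- 0.95
  ph <- make_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                  composition = comp, seed = 13))
  mask <- segment_lungs(ph$ct)
  truth_mask <- unclass(ph$lobes) > 0
  dice <- 2 * sum(mask & truth_mask) / (sum(mask) + sum(truth_mask))
  expect_equal(dice, 1.0)
  expect_identical(oracle_component_count(mask), 2L)
  # all-tissue volume: nothing below threshold inside a body
  solid <- ct_volume(array(40L, c(16, 16, 16)), c(2, 2, 2))
  expect_error(segment_lungs(solid), "segmentation failed")
  # one lung removed -> single component with a warning
  hu <- unclass(ph$ct)
  hu[unclass(ph$lobes) %in% c(4L, 5L)] <- 40L  # fill the left lung with tissue
  one <- ct_volume(hu, spacing_mm(ph$ct))
  expect_warning(m1 <- segment_lungs(one), "one lung")
  expect_identical(oracle_component_count(m1), 1L)
})
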