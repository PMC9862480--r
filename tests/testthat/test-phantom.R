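test_that("phantom ground truth is an exact voxel partition", {
  comp <- default_composition()
  comp$f_emph <- c(0.10, 0, 0.25, 0, 0)
  comp$f_nonaer <- c(0.10, 0.08, 0.05, 0.30, 0)
  comp$f_wal <- 1 - comp$f_emph - comp$f_nonaer
  ph <- make_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                  composition = comp, seed = 11))
  tr <- ph$truth$lobes
  # floor allocation, remainder to WAL
  expect_identical(tr$n_emph, as.integer(floor(tr$n_voxels * comp$f_emph + 1e-9)))
  expect_identical(tr$n_nonaer, as.integer(floor(tr$n_voxels * comp$f_nonaer + 1e-9)))
  expect_identical(tr$n_wal, tr$n_voxels - tr$n_emph - tr$n_nonaer)
  # whole-lung = sum of lobes, exactly, every field
  for (cl in c("n_voxels", "n_emph", "n_wal", "n_nonaer", "vol_l", "wal_l", "laa_l")) {
    expect_identical(ph$truth$total[[cl]], sum(tr[[cl]]))
  }
  # volumes = counts x voxel volume
  vv <- voxel_volume_liters(c(2, 2, 2))
  expect_identical(tr$wal_l, tr$n_wal * vv)
  # realized compartments verified by brute-force counting over the arrays
  hu <- as.vector(unclass(ph$ct))
  lv <- as.vector(unclass(ph$lobes))
  for (i in seq_len(5)) {
    h <- hu[lv == i]
    expect_identical(sum(h < -950), tr$n_emph[i])
    expect_identical(sum(h >= -950 & h <= -750), tr$n_wal[i])
    expect_identical(sum(h > -750), tr$n_nonaer[i])
  }
})

test_that("single-compartment phantoms hit the trivial limits", {
  comp <- default_composition()
  comp$f_emph <- 0; comp$f_nonaer <- 0; comp$f_wal <- 1
  ph <- make_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                  composition = comp, seed = 2))
  expect_identical(ph$truth$pct_laa, 0)
  expect_identical(ph$truth$total$wal_l, ph$truth$total$vol_l)

  comp2 <- default_composition()
  comp2$f_emph <- c(1, 0, 0, 0, 0)
  comp2$f_wal <- c(0, 1, 1, 1, 1)
  comp2$f_nonaer <- 0
  ph2 <- make_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                   composition = comp2, seed = 3))
  rul <- ph2$truth$lobes[ph2$truth$lobes$lobe == "RUL", ]
  expect_identical(ph2$truth$total$laa_l,
                   rul$n_voxels * ph2$truth$voxel_volume_l)
})

test_that("phantoms are bit-identical under a fixed seed and lobes are disjoint/nonempty", {
  spec <- phantom_spec(grid_shape = c(20, 20, 24), seed = 99)
  ph1 <- make_phantom(spec)
  ph2 <- make_phantom(spec)
  expect_identical(unclass(ph1$ct), unclass(ph2$ct))
  expect_identical(unclass(ph1$lobes), unclass(ph2$lobes))
  counts <- tabulate(ph1$lobes[ph1$lobes > 0], nbins = 5)
  expect_true(all(counts > 0))
})

test_that("phantom spec validation rejects bad fractions and small grids", {
  comp <- default_composition()
  comp$f_wal[1] <- 0.5  # row no longer sums to 1
  expect_error(phantom_spec(composition = comp), "sum to 1")
  comp2 <- default_composition()
  comp2$f_emph[2] <- -0.1
  comp2$f_wal[2] <- 1.1
  expect_error(phantom_spec(composition = comp2), "\\[0, 1\\]")
  expect_error(phantom_spec(grid_shape = c(8, 64, 64)), "geometry")
})

test_that("sample_lobe_hu respects compartment boundaries after integer casting", {
  for (case in list(list(cmp = "emphysema", lo = -1024, hi = -951),
                    list(cmp = "wal", lo = -950, hi = -750),
                    list(cmp = "nonaerated", lo = -749, hi = 3071))) {
    x <- sample_lobe_hu(case$cmp, mean = -850, sd = 400, n = 1e5, seed = 5)
    expect_true(is.integer(x))
    expect_gte(min(x), case$lo)
    expect_lte(max(x), case$hi)
  }
  expect_identical(sample_lobe_hu("wal", -850, 40, 0), integer(0))
  expect_error(sample_lobe_hu("fat", -850, 40, 10), "unknown compartment")
  # mean far outside the interval still yields admissible values
  x <- sample_lobe_hu("emphysema", mean = 500, sd = 1, n = 100, seed = 1)
  expect_true(all(x < -950))
})
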