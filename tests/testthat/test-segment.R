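px <- 0.325

test_that("an all-zero W1 yields zero nuclei and a saturated W1 is flagged", {
  z <- matrix(0, 96, 96)
  f <- matrix_field(z, z, px)
  nuc <- segment_nuclei(f)
  expect_equal(nuc$nuclei_count, 0)
  expect_true(nuc$usable)
  sat <- matrix_field(matrix(60000, 96, 96), z, px)
  nuc2 <- segment_nuclei(sat)
  expect_false(nuc2$usable)
  expect_true(is.na(nuc2$nuclei_count))
})

test_that("planted disjoint nuclei are counted exactly, matching flood fill", {
  w1 <- matrix(0, 512, 512)
  centers <- expand.grid(r = seq(30, 450, by = 60), c = seq(30, 450, by = 70))
  centers <- centers[seq_len(50), ]
  for (k in seq_len(50)) {
    r <- centers$r[k]; c <- centers$c[k]
    w1[r:(r + 13), c:(c + 13)] <- 10000  # 14x14 px = 20.7 um2 block
  }
  f <- matrix_field(w1, matrix(0, 512, 512), px)
  nuc <- segment_nuclei(f)
  expect_equal(nuc$nuclei_count, 50)
  expect_equal(max(oracle_label(w1 > 4000)), 50)
})

test_that("touching nucleus blobs are split by the watershed", {
  w1 <- matrix(0, 128, 128)
  # two overlapping disks, union area above the single-nucleus maximum
  for (ctr in list(c(60, 50), c(60, 76))) {
    for (i in 1:128) for (j in 1:128) {
      if ((i - ctr[1])^2 + (j - ctr[2])^2 <= 15^2) w1[i, j] <- 10000
    }
  }
  f <- matrix_field(w1, matrix(0, 128, 128), px)
  nuc <- segment_nuclei(f)
  expect_equal(nuc$nuclei_count, 2)
})

test_that("an empty W2 yields an empty detection table", {
  f <- matrix_field(matrix(0, 96, 96), matrix(0, 96, 96), px)
  out <- detect_cilia_tf(f)
  expect_equal(nrow(out), 0)
  expect_true(attr(out, "usable"))
})

test_that("the size band excludes bars outside it and keeps bars inside", {
  w2 <- matrix(0, 256, 256)
  w2 <- plant_bar_um(w2, 20, 20, 12, px)   # too long
  w2 <- plant_bar_um(w2, 60, 20, 0.5, px)  # too short
  w2 <- plant_bar_um(w2, 100, 20, 4, px)   # in band
  f <- matrix_field(matrix(0, 256, 256), w2, px)
  out <- detect_cilia_tf(f, tf_params(min_size_um = 1, max_size_um = 11))
  expect_equal(nrow(out), 1)
  expect_gt(out$feret_um, 3.5)
  expect_lt(out$feret_um, 4.5)
})

test_that("detection equals the brute-force oracle on planted fields", {
  for (s in 1:10) {
    w2 <- planted_w2(s)
    f <- matrix_field(matrix(0, 128, 128), w2, px)
    params <- tf_params(min_size_um = 0.4, max_size_um = 20)
    out <- detect_cilia_tf(f, params)
    oracle <- oracle_detect(w2, params$cilia_intensity_threshold, px,
                            params$min_size_um, params$max_size_um)
    expect_equal(nrow(out), oracle$count)
    expect_equal(sort(out$area_um2), oracle$areas_um2)
  }
})

test_that("raising the threshold never increases total stained area", {
  fg <- generate_field(sim_profile("smo_moderate_bg", cells_per_field = 20),
                       seed = 3, dim = c(256, 256))
  thresholds <- intensity_8bit(c(40, 60, 78, 100, 140, 200))
  area <- vapply(thresholds, function(thr) {
    sum(detect_cilia_tf(fg$field, tf_params(
      cilia_intensity_threshold = thr,
      min_size_um = 0.05, max_size_um = 200))$area_um2)
  }, numeric(1))
  expect_true(all(diff(area) <= 0))
})

test_that("raising the threshold never increases counts of unimodal objects", {
  # uniform-amplitude planted bars cannot split as the threshold rises:
  # each either survives whole or disappears
  w2 <- matrix(0, 192, 192)
  amps <- c(12000, 18000, 25000, 33000, 42000)
  for (k in seq_along(amps)) {
    w2[k * 30 + (0:1), 30:45] <- amps[k]
  }
  f <- matrix_field(matrix(0, 192, 192), w2, px)
  counts <- vapply(intensity_8bit(c(30, 50, 78, 110, 150, 180)), function(thr) {
    nrow(detect_cilia_tf(f, tf_params(cilia_intensity_threshold = thr,
                                      min_size_um = 1, max_size_um = 11)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 5)
  expect_equal(counts[6], 0)
})

test_that("border objects are retained by default and droppable by config", {
  w2 <- matrix(0, 128, 128)
  w2[1:2, 40:52] <- 30000  # bar on the top border
  f <- matrix_field(matrix(0, 128, 128), w2, px)
  keep <- detect_cilia_tf(f, tf_params(min_size_um = 1, max_size_um = 11))
  expect_equal(nrow(keep), 1)
  expect_true(keep$on_border)
  drop <- detect_cilia_tf(f, tf_params(min_size_um = 1, max_size_um = 11,
                                       include_border = FALSE))
  expect_equal(nrow(drop), 0)
})

test_that("micron measurements agree across pixel sizes within one pixel", {
  for (L in c(2, 4, 6)) {
    ferets <- vapply(c(0.1625, 0.325, 0.65), function(p) {
      w2 <- plant_bar_um(matrix(0, 256, 256), 50, 50, L, p)
      f <- matrix_field(matrix(0, 256, 256), w2, p)
      detect_cilia_tf(f, tf_params(min_size_um = 0.4, max_size_um = 20))$feret_um
    }, numeric(1))
    expect_lt(max(ferets) - min(ferets), 0.65 + 1e-9)
    expect_lt(abs(mean(ferets) - L), 0.65)
  }
})

test_that("MWS scoring measures planted areas exactly and flags empty fields", {
  w1 <- matrix(0, 128, 128)
  w1[20:33, 20:33] <- 10000
  w2 <- matrix(0, 128, 128)
  w2[22:25, 40:55] <- 30000  # 4 x 16 px = 64 px planted object
  f <- matrix_field(w1, w2, px)
  nuc <- segment_nuclei(f)
  m <- score_mws(f, nuc, mws_params(min_size_um = 1, max_size_um = 11,
                                    min_stained_area = 0.5))
  expect_true(m$usable)
  expect_equal(m$positive_stained_area, 64 * px^2)
  expect_equal(m$n_objects, 1)
  expect_equal(m$pct_positive_w2, 100)
  # zero W2: zero area, zero percent, undefined mean stain area
  f0 <- matrix_field(w1, matrix(0, 128, 128), px)
  m0 <- score_mws(f0, segment_nuclei(f0), mws_params())
  expect_equal(m0$positive_stained_area, 0)
  expect_equal(m0$pct_positive_w2, 0)
  expect_true(is.na(m0$mean_stain_area))
  # no nuclei: percent undefined, field flagged
  fn <- matrix_field(matrix(0, 128, 128), w2, px)
  mn <- score_mws(fn, segment_nuclei(fn), mws_params())
  expect_false(mn$usable)
  expect_true(is.na(mn$pct_positive_w2))
})

test_that("8-connected labeling joins diagonal pixels", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1; m[3, 3] <- 1; m[4, 4] <- 1  # diagonal chain
  m[6, 6] <- 1                              # separate
  lab <- ciliascreen:::label_components(m > 0)
  expect_equal(max(lab), 2)
  expect_equal(max(oracle_label(m > 0)), 2)
})
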