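prof_small <- sim_profile("arl13b_low_bg", cells_per_field = 15)

test_that("identical seeds give bit-identical fields and truth", {
  a <- generate_field(prof_small, seed = 42, dim = c(128, 128))
  b <- generate_field(prof_small, seed = 42, dim = c(128, 128))
  expect_identical(a$field$w1, b$field$w1)
  expect_identical(a$field$w2, b$field$w2)
  expect_identical(a$truth, b$truth)
  c <- generate_field(prof_small, seed = 43, dim = c(128, 128))
  expect_false(identical(a$field$w2, c$field$w2))
})

test_that("a field with no cilia and no vesicles has an object-free W2", {
  prof <- sim_profile("arl13b_low_bg", cells_per_field = 15,
                      ciliation_fraction = 0, background_vesicles_per_cell = 0)
  fg <- generate_field(prof, seed = 7, dim = c(128, 128))
  expect_equal(fg$truth$n_ciliated, 0)
  expect_equal(fg$truth$n_background, 0)
  expect_equal(nrow(detect_cilia_tf(fg$field)), 0)
  # intensities never approach the detection threshold (offset + noise only)
  expect_lt(max(fg$field$w2), intensity_8bit(78))
})

test_that("ciliated counts are binomial around ciliation_fraction x cells", {
  prof <- sim_profile("arl13b_low_bg", cells_per_field = 60)
  tall <- vapply(1:200, function(s) {
    generate_field(prof, seed = s, dim = c(512, 512), render = FALSE)$truth$n_ciliated
  }, numeric(1))
  # E = 0.85 * 60 = 51; se of the mean over 200 seeds is about 0.5
  expect_lt(abs(mean(tall) - 51), 1.6)
})

test_that("high-background profile produces more background objects at every seed", {
  for (s in 1:20) {
    a <- generate_field(sim_profile("arl13b_low_bg", cells_per_field = 30),
                        seed = s, dim = c(256, 256), render = FALSE)
    m <- generate_field(sim_profile("mchr1_high_bg", cells_per_field = 30),
                        seed = s, dim = c(256, 256), render = FALSE)
    expect_gt(m$truth$n_background, a$truth$n_background)
  }
})

test_that("invalid geometry is rejected with an explicit message", {
  expect_error(generate_field(prof_small, seed = 1, dim = c(0, 128)),
               "dimensions")
  expect_error(generate_field(prof_small, seed = 1, dim = c(128, 128),
                              pixel_size_um = -0.3), "pixel_size_um")
})

test_that("IR1/IR2 pairs share the nucleus layout", {
  pair <- generate_site_pair(prof_small, perturbation(0), seed = 5,
                             dim = c(128, 128), render = FALSE)
  expect_identical(pair$ir1$truth$cells, pair$ir2$truth$cells)
  pair2 <- generate_site_pair(prof_small, perturbation(0.5), seed = 5,
                              dim = c(128, 128), render = FALSE)
  expect_equal(pair2$ir1$truth$cells$x, pair2$ir2$truth$cells$x)
  expect_equal(pair2$ir1$truth$cells$y, pair2$ir2$truth$cells$y)
  expect_equal(pair2$ir1$truth$n_cells, pair2$ir2$truth$n_cells)
})

test_that("larger disassembly fractions never increase IR2 ciliated counts", {
  for (s in c(3, 11, 29)) {
    counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(d) {
      generate_site_pair(prof_small, perturbation(d), seed = s,
                         dim = c(128, 128), render = FALSE)$ir2$truth$n_ciliated
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[6], 0)
  }
})

test_that("serum-level disassembly removes the planted fraction of cilia", {
  prof <- sim_profile("arl13b_low_bg", cells_per_field = 60)
  r <- vapply(1:100, function(s) {
    p <- generate_site_pair(prof, perturbation(0.4), seed = s,
                            dim = c(512, 512), render = FALSE)
    c(p$ir1$truth$n_ciliated, p$ir2$truth$n_ciliated)
  }, numeric(2))
  expect_lt(abs(sum(r[2, ]) / sum(r[1, ]) - 0.6), 0.03)
})

test_that("cell-loss corruption removes at least half of the IR2 cells", {
  for (s in 1:5) {
    p <- generate_site_pair(prof_small, perturbation(0), seed = s,
                            dim = c(128, 128), corruption = "cell_loss",
                            render = FALSE)
    expect_lte(p$ir2$truth$n_cells, 0.5 * p$ir1$truth$n_cells)
    expect_equal(p$ir2$truth$corruption, "cell_loss")
  }
})

test_that("haze corruption brightens W2 broadly without touching ground truth", {
  clean <- generate_site_pair(prof_small, perturbation(0), seed = 9,
                              dim = c(128, 128))
  hazed <- generate_site_pair(prof_small, perturbation(0), seed = 9,
                              dim = c(128, 128), corruption = "haze")
  expect_equal(hazed$ir2$truth$n_ciliated, clean$ir2$truth$n_ciliated)
  expect_gt(mean(hazed$ir2$field$w2), mean(clean$ir2$field$w2) * 1.5)
})
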