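test_that("site metrics implement the per-cell normalization arithmetic", {
  # 30 objects totalling 90 um2 over 60 nuclei
  m <- compute_site_metrics(fake_nuclei(60), fake_cilia(rep(3, 30)))
  expect_equal(m$vesicle_count_per_cell, 0.5)
  expect_equal(m$vesicle_area_per_cell, 1.5)
  expect_equal(m$total_vesicle_area_um2, 90)
  expect_true(m$usable)
  # no objects over 40 nuclei
  m0 <- compute_site_metrics(fake_nuclei(40), fake_cilia(numeric(0)))
  expect_equal(m0$vesicle_count_per_cell, 0)
  expect_equal(m0$total_vesicle_area_um2, 0)
})

test_that("fields with no nuclei are unusable with absent ratios", {
  m <- compute_site_metrics(fake_nuclei(0), fake_cilia(c(2, 3)))
  expect_false(m$usable)
  expect_true(is.na(m$vesicle_count_per_cell))
  expect_true(is.na(m$vesicle_area_per_cell))
  flagged <- fake_nuclei(NA_integer_, usable = FALSE)
  m2 <- compute_site_metrics(flagged, fake_cilia(c(2)))
  expect_false(m2$usable)
})

test_that("well summaries average usable sites only", {
  sites <- fake_sites("A01", "IR1", rep(0.4, 9))
  sites$usable[9] <- FALSE
  sites$vesicle_count_per_cell[9] <- 0
  s <- summarize_wells(sites)
  expect_equal(s$vesicle_count_per_cell, 0.4)
  expect_equal(s$n_sites_used, 8)
  expect_equal(s$n_sites_total, 9)
  expect_equal(s$vesicle_count_per_cell_sum, 0.4 * 8)
  # identical sites: mean equals the common value, sum is 9x
  all_ok <- fake_sites("B01", "IR1", rep(0.7, 9))
  s2 <- summarize_wells(all_ok)
  expect_equal(s2$vesicle_count_per_cell, 0.7)
  expect_equal(s2$vesicle_count_per_cell_sum, 6.3)
})

test_that("wells with zero usable sites are excluded with a message", {
  sites <- dplyr::bind_rows(
    fake_sites("A01", "IR1", rep(0.5, 3)),
    within(fake_sites("B01", "IR1", rep(0.5, 3)), usable <- FALSE)
  )
  expect_message(s <- summarize_wells(sites), "B01")
  expect_equal(s$well_id, "A01")
})

test_that("summaries are invariant to site order and bounded by site values", {
  set.seed(4)
  vals <- runif(9, 0.2, 0.9)
  sites <- fake_sites("A01", "IR2", vals)
  shuffled <- sites[sample(9), ]
  expect_equal(summarize_wells(sites), summarize_wells(shuffled))
  s <- summarize_wells(sites)
  expect_gte(s$vesicle_count_per_cell, min(vals))
  expect_lte(s$vesicle_count_per_cell, max(vals))
})

test_that("site CSV round-trips reproduce summaries exactly", {
  sites <- dplyr::bind_rows(
    fake_sites("A01", "IR1", c(0.81, 0.77, 0.9)),
    fake_sites("A01", "IR2", c(0.52, 0.48, 0.61))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sites, path)
  reread <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(summarize_wells(reread), summarize_wells(sites))
})

test_that("measured vesicle count per cell tracks true ciliation on rendered fields", {
  prof <- sim_profile("arl13b_low_bg", cells_per_field = 40)
  errs <- vapply(1:15, function(s) {
    fg <- generate_field(prof, seed = 500 + s, dim = c(512, 512))
    m <- analyze_field(fg$field)
    truth_ratio <- fg$truth$n_ciliated / fg$truth$n_cells
    abs(m$vesicle_count_per_cell - truth_ratio) / truth_ratio
  }, numeric(1))
  expect_lt(mean(errs), 0.08)
})
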