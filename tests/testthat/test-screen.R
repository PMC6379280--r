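# Metric-level screen fixtures built from fabricated site tables.
make_summary_sites <- function(vcpc_by_well, run, sites = 3) {
  dplyr::bind_rows(purrr::imap(vcpc_by_well, function(v, w) {
    fake_sites(w, run, rep(v, sites))
  }))
}

test_that("normalization divides sample IR2 by the control IR1 mean", {
  sites <- dplyr::bind_rows(
    make_summary_sites(c(A01 = 0.8, B01 = 0.8, C01 = 0.8), "IR1"),
    make_summary_sites(c(A01 = 0.8, B01 = 0.4, C01 = 0), "IR2")
  )
  s <- summarize_wells(sites)
  sc <- normalize_disassembly(s, control_wells = "A01")
  expect_equal(sc$normalized_score[sc$well_id == "A01"], 1)
  expect_equal(sc$normalized_score[sc$well_id == "B01"], 0.5)
  expect_equal(sc$normalized_score[sc$well_id == "C01"], 0)
})

test_that("a zero or missing control baseline invalidates the screen", {
  sites <- dplyr::bind_rows(
    make_summary_sites(c(A01 = 0, B01 = 0.5), "IR1"),
    make_summary_sites(c(A01 = 0, B01 = 0.5), "IR2")
  )
  s <- summarize_wells(sites)
  expect_error(normalize_disassembly(s, control_wells = "A01"), "zero")
  expect_error(normalize_disassembly(s, control_wells = "Z99"), "control")
})

test_that("normalized scores are invariant to a common scale factor", {
  sites <- dplyr::bind_rows(
    make_summary_sites(c(A01 = 0.85, B01 = 0.84), "IR1"),
    make_summary_sites(c(A01 = 0.83, B01 = 0.51), "IR2")
  )
  scaled <- dplyr::mutate(sites,
                          vesicle_count_per_cell = vesicle_count_per_cell * 3)
  s1 <- normalize_disassembly(summarize_wells(sites), "A01")
  s2 <- normalize_disassembly(summarize_wells(scaled), "A01")
  expect_equal(s1$normalized_score, s2$normalized_score)
})

test_that("paired-site QC flags cell loss, outliers, and missing partners", {
  ir1 <- fake_sites("A01", "IR1", rep(0.8, 9))
  ir2 <- fake_sites("A01", "IR2", rep(0.8, 9))
  # identical pairs: ratio 1, all ok
  qc <- qc_pair_sites(dplyr::bind_rows(ir1, ir2))
  expect_true(all(qc$flag == "ok"))
  expect_true(all(qc$area_ratio == 1))
  # site 3 loses 60% of nuclei
  ir2b <- ir2
  ir2b$nuclei_count[3] <- 20
  qc2 <- qc_pair_sites(dplyr::bind_rows(ir1, ir2b))
  expect_equal(qc2$flag[qc2$site_index == 3], "cell_loss")
  # site 5 has a wildly different vesicle area
  ir2c <- ir2
  ir2c$total_vesicle_area_um2 <- ir2c$total_vesicle_area_um2 * c(1, 1.05, 0.95, 1.02, 8, 0.98, 1.01, 0.97, 1.03)
  qc3 <- qc_pair_sites(dplyr::bind_rows(ir1, ir2c))
  expect_equal(qc3$flag[qc3$site_index == 5], "poor_quality")
  expect_true(all(qc3$flag[qc3$site_index != 5] == "ok"))
  # missing IR2 partner for site 9
  qc4 <- qc_pair_sites(dplyr::bind_rows(ir1, ir2[1:8, ]))
  expect_equal(qc4$flag[qc4$site_index == 9], "poor_quality")
})

test_that("hit calling respects the screen direction and never both at once", {
  wells <- c(paste0("A0", 1:4), "B01", "B02", "C01", "C02")
  roles <- c(rep("vehicle", 4), rep("down", 2), rep("up", 2))
  scores <- tibble::tibble(
    well_id = wells,
    compound_id = c(rep(NA, 4), "down_cmpd", "down_cmpd", "up_cmpd", "up_cmpd"),
    score_after_qc = c(1.00, 1.01, 0.99, 1.00, 0.60, 0.62, 1.40, 1.38)
  )
  ind <- call_hits(scores, "induce_disassembly", alpha = 0.05,
                   reference_wells = wells[1:4])
  blk <- call_hits(scores, "block_disassembly", alpha = 0.05,
                   reference_wells = wells[1:4])
  expect_true(ind$hit[ind$compound_id == "down_cmpd"])
  expect_false(ind$hit[ind$compound_id == "up_cmpd"])
  expect_true(blk$hit[blk$compound_id == "up_cmpd"])
  expect_false(blk$hit[blk$compound_id == "down_cmpd"])
  expect_equal(ind$rank[ind$compound_id == "down_cmpd"], 1)
})

test_that("compounds with fewer than two observations are reported, not tested", {
  scores <- tibble::tibble(
    well_id = c("A01", "A02", "B01"),
    compound_id = c(NA, NA, "solo"),
    score_after_qc = c(1, 1.02, 0.5)
  )
  out <- call_hits(scores, "induce_disassembly", alpha = 0.05,
                   reference_wells = c("A01", "A02"))
  expect_equal(out$status[out$compound_id == "solo"], "insufficient data")
  expect_true(is.na(out$p_value[out$compound_id == "solo"]))
  expect_false(out$hit[out$compound_id == "solo"])
})

test_that("run_screen recomputes post-QC scores from retained pairs only", {
  pd <- plate_design(
    data.frame(well = c("A01", "A02", "B01", "B02"),
               role = c("vehicle_starved", "vehicle_starved",
                        "compound", "compound"),
               compound_id = c(NA, NA, "cmpd", "cmpd")),
    sites_per_well = 5, seed = 1
  )
  vcpc1 <- c(A01 = 0.8, A02 = 0.82, B01 = 0.8, B02 = 0.81)
  sites <- dplyr::bind_rows(
    make_summary_sites(vcpc1, "IR1", sites = 5),
    make_summary_sites(vcpc1, "IR2", sites = 5)
  )
  # corrupt one site of B01 in IR2: nuclei collapse and vcpc drops
  bad <- sites$well_id == "B01" & sites$run_index == "IR2" & sites$site_index == 3
  sites$nuclei_count[bad] <- 10
  sites$vesicle_count_per_cell[bad] <- 0.2
  sites$total_vesicle_area_um2[bad] <- 5
  scr <- run_screen(sites, pd, "induce_disassembly")
  b01 <- scr$scores[scr$scores$well_id == "B01", ]
  expect_equal(b01$qc_removed_sites[[1]], 3L)
  # post-QC score equals a by-hand recomputation over the retained sites
  kept <- sites[!(sites$well_id == "B01" & sites$site_index == 3), ]
  ctrl <- mean(kept$vesicle_count_per_cell[kept$well_id %in% c("A01", "A02") &
                                             kept$run_index == "IR1"])
  manual <- mean(kept$vesicle_count_per_cell[kept$well_id == "B01" &
                                               kept$run_index == "IR2"]) / ctrl
  expect_equal(b01$score_after_qc, manual)
  # QC never increases the number of usable site pairs
  expect_lte(sum(scr$qc$flag == "ok"), nrow(scr$qc))
})

test_that("screen objects expose tidy, glance and autoplot interfaces", {
  pd <- plate_design(
    data.frame(well = c("A01", "A02", "B01", "B02"),
               role = c("vehicle_starved", "vehicle_starved",
                        "serum_control", "serum_control")),
    sites_per_well = 3, seed = 2
  )
  sites <- dplyr::bind_rows(
    make_summary_sites(c(A01 = 0.85, A02 = 0.83, B01 = 0.86, B02 = 0.84), "IR1"),
    make_summary_sites(c(A01 = 0.84, A02 = 0.86, B01 = 0.50, B02 = 0.53), "IR2")
  )
  scr <- run_screen(sites, pd, "induce_disassembly")
  expect_s3_class(tidy(scr), "tbl_df")
  g <- glance(scr)
  expect_equal(g$n_wells, 4)
  expect_s3_class(ggplot2::autoplot(scr), "ggplot")
  expect_s3_class(plot_screen_ranks(scr), "ggplot")
  expect_output(print(scr), "cilia_screen")
})
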