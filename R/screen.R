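#' Normalize post-perturbation summaries to the starved-vehicle baseline
#'
#' Implements the screen's first evaluation step: every well's IR2 summary
#' of the primary metric (vesicle count per cell by default) is divided by
#' the mean IR1 summary of the starved-vehicle control wells, which
#' represent maximal ciliation. A score of 1 means ciliation unchanged
#' from the baseline; serum typically drives scores to roughly 0.4--0.8.
#'
#' The printed convention uses the control wells' baseline run (IR1) as
#' the denominator; `denominator = "control_ir2"` instead divides by the
#' controls' own IR2 summaries, which additionally cancels any drift the
#' controls show between runs.
#'
#' @param summaries Well summaries from [summarize_wells()] (both runs).
#' @param control_wells Character vector of starved-vehicle control well ids.
#' @param metric Summary column to normalize (default
#'   `"vesicle_count_per_cell"`).
#' @param denominator `"control_ir1"` (default) or `"control_ir2"`.
#' @return A tibble with one row per well holding `normalized_score` and
#'   the control mean used.
#' @export
normalize_disassembly <- function(summaries, control_wells,
                                  metric = "vesicle_count_per_cell",
                                  denominator = c("control_ir1", "control_ir2")) {
  denominator <- match.arg(denominator)
  stopifnot(metric %in% names(summaries))
  ctrl_run <- if (denominator == "control_ir1") "IR1" else "IR2"
  ctrl <- summaries %>%
    filter(.data$well_id %in% control_wells, .data$run_index == ctrl_run)
  if (nrow(ctrl) == 0) {
    abort("Screen invalid: no usable starved-vehicle control well summaries.")
  }
  control_mean <- mean(ctrl[[metric]])
  if (!is.finite(control_mean) || control_mean <= 0) {
    abort("Screen invalid: starved-vehicle control mean is zero or undefined.")
  }
  summaries %>%
    filter(.data$run_index == "IR2") %>%
    mutate(normalized_score = .data[[metric]] / control_mean,
           control_mean = control_mean, metric = metric) %>%
    select("plate_id", "well_id", "normalized_score", "control_mean", "metric")
}

#' Pair IR1/IR2 sites and flag outlier image pairs
#'
#' The second evaluation step reviews each well's paired fields: for every
#' site the between-run ratios of total vesicle area and of nuclei count
#' are computed, and sites showing significant cell loss
#' (`nuclei_ratio < cell_loss_cutoff`) or poor image quality (area ratio
#' outside median +/- `mad_k` * MAD among the well's sites, or a missing /
#' unusable partner field) are flagged for exclusion. This automates the
#' manual outlier-image review step of the assay with a reproducible
#' robust rule.
#'
#' @param sites Site-metrics tibble containing both runs.
#' @param cell_loss_cutoff Nuclei-ratio cutoff below which a pair is
#'   flagged `cell_loss` (default 0.5).
#' @param mad_k Robust outlier multiplier for the within-well area-ratio
#'   rule (default 3.5).
#' @return A tibble with one row per (well, site): `area_ratio`,
#'   `nuclei_ratio`, `flag` (`ok`, `cell_loss`, `poor_quality`).
#' @export
qc_pair_sites <- function(sites, cell_loss_cutoff = 0.5, mad_k = 3.5) {
  wide <- sites %>%
    select("plate_id", "well_id", "site_index", "run_index",
           "nuclei_count", "total_vesicle_area_um2", "usable") %>%
    tidyr::pivot_wider(names_from = "run_index",
                       values_from = c("nuclei_count", "total_vesicle_area_um2",
                                       "usable"))
  need <- c("nuclei_count_IR1", "nuclei_count_IR2",
            "total_vesicle_area_um2_IR1", "total_vesicle_area_um2_IR2",
            "usable_IR1", "usable_IR2")
  for (col in need) if (!col %in% names(wide)) wide[[col]] <- NA
  ratio <- function(a, b) {
    dplyr::case_when(
      is.na(a) | is.na(b) ~ NA_real_,
      b > 0 ~ a / b,
      a == 0 ~ 1,
      TRUE ~ Inf
    )
  }
  wide <- wide %>%
    mutate(
      area_ratio = ratio(.data$total_vesicle_area_um2_IR2,
                         .data$total_vesicle_area_um2_IR1),
      nuclei_ratio = ratio(as.numeric(.data$nuclei_count_IR2),
                           as.numeric(.data$nuclei_count_IR1)),
      pair_ok = !is.na(.data$usable_IR1) & !is.na(.data$usable_IR2) &
        .data$usable_IR1 & .data$usable_IR2
    )
  wide %>%
    group_by(.data$plate_id, .data$well_id) %>%
    mutate(
      med = median(.data$area_ratio[.data$pair_ok & is.finite(.data$area_ratio)]),
      madv = mad(.data$area_ratio[.data$pair_ok & is.finite(.data$area_ratio)]),
      flag = dplyr::case_when(
        !.data$pair_ok ~ "poor_quality",
        .data$nuclei_ratio < cell_loss_cutoff ~ "cell_loss",
        !is.finite(.data$area_ratio) ~ "poor_quality",
        abs(.data$area_ratio - .data$med) > mad_k * .data$madv ~ "poor_quality",
        TRUE ~ "ok"
      )
    ) %>%
    ungroup() %>%
    select("plate_id", "well_id", "site_index", "area_ratio", "nuclei_ratio",
           "flag")
}

#' Rank compounds and call screening hits
#'
#' Compares each compound's normalized scores against the reference wells
#' with a two-sample t-test, one-sided in the direction of the screen's
#' declared mode: `induce_disassembly` calls compounds whose score falls
#' below the reference (enhanced disassembly), `block_disassembly` calls
#' compounds whose score stays above it (resistance to disassembly). The
#' two classes are never called in the same run. Compounds are ranked by
#' directional effect size, then p-value; Benjamini-Hochberg adjusted
#' p-values are reported alongside, but the hit call uses the raw p-value
#' threshold by default.
#'
#' @param scores Per-observation tibble with columns `well_id`,
#'   `compound_id` and the score column named by `score_col`. One row per
#'   experimental unit (replicate well by default; site-level rows are
#'   pseudo-replication and should be labeled as such by the caller).
#' @param mode `"induce_disassembly"` or `"block_disassembly"`.
#' @param alpha Significance level for the hit call (default 0.05).
#' @param reference_wells Well ids of the comparison group (vehicle wells
#'   for induction screens; serum-treated vehicle wells for blocking
#'   screens).
#' @param score_col Name of the score column (default `"score_after_qc"`).
#' @param var_equal Use the classic pooled-variance t-test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return A tibble ranked by effect size then p: one row per compound with
#'   `effect_size` (directional: positive means an effect in the screen's
#'   direction), `p_value`, `adjusted_p`, `hit`, `n_obs`, `status`.
#' @export
call_hits <- function(scores, mode = c("induce_disassembly", "block_disassembly"),
                      alpha = 0.05, reference_wells, score_col = "score_after_qc",
                      var_equal = TRUE) {
  mode <- match.arg(mode)
  stopifnot(score_col %in% names(scores), length(reference_wells) > 0)
  ref <- scores[[score_col]][scores$well_id %in% reference_wells]
  ref <- ref[is.finite(ref)]
  test_tbl <- scores %>%
    filter(!.data$well_id %in% reference_wells, !is.na(.data$compound_id))
  if (length(ref) < 2) abort("Need at least 2 reference observations for hit calling.")
  alt <- if (mode == "induce_disassembly") "less" else "greater"
  per_compound <- test_tbl %>%
    group_by(.data$compound_id) %>%
    summarise(
      n_obs = sum(is.finite(.data[[score_col]])),
      mean_score = mean(.data[[score_col]][is.finite(.data[[score_col]])]),
      .groups = "drop"
    )
  stats_list <- purrr::map(per_compound$compound_id, function(cid) {
    x <- test_tbl[[score_col]][test_tbl$compound_id == cid]
    x <- x[is.finite(x)]
    if (length(x) < 2) {
      return(tibble(p_value = NA_real_, status = "insufficient data"))
    }
    ht <- t.test(x, ref, alternative = alt, var.equal = var_equal)
    tibble(p_value = ht$p.value, status = "tested")
  })
  out <- dplyr::bind_cols(per_compound, dplyr::bind_rows(stats_list)) %>%
    mutate(
      reference_mean = mean(ref),
      effect_size = if (mode == "induce_disassembly") {
        .data$reference_mean - .data$mean_score
      } else {
        .data$mean_score - .data$reference_mean
      },
      adjusted_p = p.adjust(.data$p_value, method = "BH"),
      hit = .data$status == "tested" & .data$effect_size > 0 &
        !is.na(.data$p_value) & .data$p_value <= alpha,
      mode = mode
    ) %>%
    arrange(desc(.data$effect_size), .data$p_value) %>%
    mutate(rank = dplyr::row_number()) %>%
    select("rank", "compound_id", "n_obs", "mean_score", "reference_mean",
           "effect_size", "p_value", "adjusted_p", "hit", "status", "mode")
  out
}

#' Run the full screen analysis over site metrics
#'
#' Ties together the analysis stages of a disassembly screen: well
#' summaries, baseline normalization, paired-site QC, post-QC
#' re-normalization, and ranked hit calling. Returns a `cilia_screen`
#' object with [tidy()]/[glance()] methods and an [ggplot2::autoplot()]
#' plate heat map.
#'
#' @param sites Site-metrics tibble for both runs ([analyze_plate()] or
#'   [truth_site_metrics()]).
#' @param design The [plate_design()] describing well roles.
#' @param mode Screen direction (see [call_hits()]). Defaults to
#'   `"induce_disassembly"`.
#' @param alpha Hit-call significance level.
#' @param metric Primary metric (default `"vesicle_count_per_cell"`).
#' @param qc Apply paired-site QC before scoring (default `TRUE`).
#' @param denominator Normalization denominator (see
#'   [normalize_disassembly()]).
#' @param cell_loss_cutoff,mad_k QC parameters (see [qc_pair_sites()]).
#' @return A `cilia_screen` object: `scores` (per well), `hits` (ranked
#'   compound table), `qc` (per site pair), `params`.
#' @export
run_screen <- function(sites, design,
                       mode = c("induce_disassembly", "block_disassembly"),
                       alpha = 0.05, metric = "vesicle_count_per_cell",
                       qc = TRUE, denominator = "control_ir1",
                       cell_loss_cutoff = 0.5, mad_k = 3.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "plate_design"))
  wells <- design$wells
  control_wells <- wells$well[wells$role == "vehicle_starved"]
  summaries <- summarize_wells(sites)
  raw_scores <- normalize_disassembly(summaries, control_wells,
                                      metric = metric,
                                      denominator = denominator)
  qc_tbl <- qc_pair_sites(sites, cell_loss_cutoff = cell_loss_cutoff,
                          mad_k = mad_k)
  if (qc) {
    flagged <- qc_tbl %>% filter(.data$flag != "ok")
    sites_kept <- sites %>%
      dplyr::anti_join(flagged, by = c("plate_id", "well_id", "site_index"))
    summaries_qc <- summarize_wells(sites_kept)
  } else {
    summaries_qc <- summaries
  }
  qc_scores <- normalize_disassembly(summaries_qc, control_wells,
                                     metric = metric,
                                     denominator = denominator) %>%
    rename(score_after_qc = "normalized_score") %>%
    select("well_id", "score_after_qc")
  scores <- raw_scores %>%
    left_join(qc_scores, by = "well_id") %>%
    left_join(wells %>% rename(well_id = "well"), by = "well_id") %>%
    left_join(
      qc_tbl %>%
        filter(.data$flag != "ok") %>%
        group_by(.data$well_id) %>%
        summarise(qc_removed_sites = list(sort(.data$site_index)),
                  .groups = "drop"),
      by = "well_id"
    ) %>%
    mutate(qc_removed_sites = purrr::map(.data$qc_removed_sites,
                                         ~ if (is.null(.x)) integer(0) else .x))
  reference_role <- if (mode == "induce_disassembly") "vehicle_starved" else "serum_control"
  reference_wells <- wells$well[wells$role == reference_role]
  if (!length(reference_wells)) {
    abort(paste0("Hit calling in mode '", mode, "' needs wells with role '",
                 reference_role, "'."))
  }
  hit_input <- scores %>%
    mutate(compound_id = ifelse(.data$well_id %in% reference_wells,
                                NA_character_, .data$compound_id))
  hits <- call_hits(hit_input, mode = mode, alpha = alpha,
                    reference_wells = reference_wells,
                    score_col = if (qc) "score_after_qc" else "normalized_score")
  structure(
    list(scores = scores, hits = hits, qc = qc_tbl,
         params = list(mode = mode, alpha = alpha, metric = metric, qc = qc,
                       denominator = denominator,
                       cell_loss_cutoff = cell_loss_cutoff, mad_k = mad_k,
                       control_wells = control_wells,
                       reference_wells = reference_wells)),
    class = "cilia_screen"
  )
}

#' @export
print.cilia_screen <- function(x, ...) {
  cat("<cilia_screen> mode ", x$params$mode, ", ", nrow(x$scores), " wells, ",
      nrow(x$hits), " compounds, ", sum(x$hits$hit), " hit(s) at alpha ",
      x$params$alpha, "\n", sep = "")
  flagged <- sum(x$qc$flag != "ok")
  cat("  QC: ", flagged, "/", nrow(x$qc), " site pairs flagged\n", sep = "")
  invisible(x)
}

#' @describeIn run_screen Ranked per-compound hit table as a tibble.
#' @param x A `cilia_screen`.
#' @param ... Unused.
#' @method tidy cilia_screen
#' @export
tidy.cilia_screen <- function(x, ...) x$hits

#' @describeIn run_screen One-row screen summary.
#' @method glance cilia_screen
#' @export
glance.cilia_screen <- function(x, ...) {
  tibble(
    mode = x$params$mode,
    alpha = x$params$alpha,
    metric = x$params$metric,
    n_wells = nrow(x$scores),
    n_compounds = nrow(x$hits),
    n_hits = sum(x$hits$hit),
    n_sites_flagged = sum(x$qc$flag != "ok"),
    n_site_pairs = nrow(x$qc)
  )
}
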