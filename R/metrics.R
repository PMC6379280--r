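#' Site-level ciliation metrics from detections
#'
#' Converts per-field detections into the site-level ("site data") metric
#' row used throughout the screen: nuclei count, cilium-object ("vesicle")
#' count, vesicle count per cell (the primary ciliation metric, cilium
#' number normalized to nuclei number), total vesicle area and vesicle
#' area per cell, plus MWS scores when available. A field with no nuclei
#' or flagged during segmentation is marked unusable and its ratios are
#' left absent.
#'
#' @param nuclei Result of [segment_nuclei()].
#' @param cilia Tibble from [detect_cilia_tf()].
#' @param mws Optional one-row tibble from [score_mws()].
#' @param plate_id,well_id,site_index,run_index Field identity.
#' @return A one-row tibble of site metrics.
#' @export
compute_site_metrics <- function(nuclei, cilia, mws = NULL,
                                 plate_id = "P1", well_id = "A01",
                                 site_index = 1L, run_index = "IR1") {
  usable <- isTRUE(nuclei$usable) && isTRUE(attr(cilia, "usable")) &&
    !is.na(nuclei$nuclei_count) && nuclei$nuclei_count > 0
  n_nuc <- if (is.na(nuclei$nuclei_count)) NA_integer_ else nuclei$nuclei_count
  n_ves <- nrow(cilia)
  total_area <- sum(cilia$area_um2)
  tibble(
    plate_id = plate_id, well_id = well_id,
    site_index = as.integer(site_index), run_index = run_index,
    nuclei_count = n_nuc,
    vesicle_count = n_ves,
    vesicle_count_per_cell = if (usable) n_ves / n_nuc else NA_real_,
    total_vesicle_area_um2 = total_area,
    vesicle_area_per_cell = if (usable) total_area / n_nuc else NA_real_,
    pct_positive_w2 = if (!is.null(mws)) mws$pct_positive_w2 else NA_real_,
    positive_stained_area = if (!is.null(mws)) mws$positive_stained_area else NA_real_,
    mean_stain_area = if (!is.null(mws)) mws$mean_stain_area else NA_real_,
    usable = usable
  )
}

#' Segment and score one field end to end
#'
#' Runs nucleus segmentation, TF-mode cilium detection and (optionally)
#' MWS-mode scoring on a field and returns its site-metrics row.
#'
#' @param field A `field_image`.
#' @param tf A [tf_params()] object.
#' @param mws An [mws_params()] object, or `NULL` to skip MWS scoring.
#' @return A one-row site-metrics tibble (see [compute_site_metrics()]).
#' @export
analyze_field <- function(field, tf = tf_params(), mws = NULL) {
  nuc <- segment_nuclei(field, tf)
  cil <- detect_cilia_tf(field, tf)
  mws_row <- if (!is.null(mws)) score_mws(field, nuc, mws) else NULL
  compute_site_metrics(nuc, cil, mws_row,
                       plate_id = field$plate_id, well_id = field$well_id,
                       site_index = field$site_index,
                       run_index = field$run_index)
}

#' Segment and score every field of a plate dataset
#'
#' @param plate A rendered `plate_dataset` (in memory or on disk).
#' @inheritParams analyze_field
#' @return A site-metrics tibble, one row per (well, site, run).
#' @export
analyze_plate <- function(plate, tf = tf_params(), mws = NULL) {
  stopifnot(inherits(plate, "plate_dataset"))
  ids <- dplyr::distinct(plate$manifest, .data$well, .data$site, .data$run)
  purrr::pmap(ids, function(well, site, run) {
    analyze_field(plate_field(plate, well, site, run), tf = tf, mws = mws)
  }) %>% dplyr::bind_rows()
}

#' Idealized site metrics from simulator ground truth
#'
#' Converts a simulated plate's ground truth directly into site metrics,
#' as if detection were perfect: nuclei count is the true cell count and
#' vesicle count the true ciliated count. This is the fast metric-level
#' route for statistical simulations (power, type-I error) where rendering
#' and re-detecting thousands of fields adds nothing but sampling noise
#' that is already modeled.
#'
#' @param plate A `plate_dataset` (rendering not required).
#' @return A site-metrics tibble matching [compute_site_metrics()] columns.
#' @export
truth_site_metrics <- function(plate) {
  stopifnot(inherits(plate, "plate_dataset"))
  plate$truth %>%
    mutate(
      nuclei_count = .data$n_cells,
      vesicle_count = .data$n_ciliated,
      vesicle_count_per_cell = ifelse(.data$n_cells > 0,
                                      .data$n_ciliated / .data$n_cells, NA_real_),
      total_vesicle_area_um2 = .data$total_cilium_area_um2,
      vesicle_area_per_cell = ifelse(.data$n_cells > 0,
                                     .data$total_cilium_area_um2 / .data$n_cells,
                                     NA_real_),
      pct_positive_w2 = ifelse(.data$n_cells > 0,
                               100 * .data$n_ciliated / .data$n_cells, NA_real_),
      positive_stained_area = .data$total_cilium_area_um2,
      mean_stain_area = ifelse(.data$n_ciliated > 0,
                               .data$total_cilium_area_um2 / .data$n_ciliated,
                               NA_real_),
      usable = .data$n_cells > 0
    ) %>%
    select("plate_id", "well_id", "site_index", "run_index", "nuclei_count",
           "vesicle_count", "vesicle_count_per_cell", "total_vesicle_area_um2",
           "vesicle_area_per_cell", "pct_positive_w2", "positive_stained_area",
           "mean_stain_area", "usable")
}

SITE_METRIC_COLS <- c("nuclei_count", "vesicle_count", "vesicle_count_per_cell",
                      "total_vesicle_area_um2", "vesicle_area_per_cell",
                      "pct_positive_w2", "positive_stained_area",
                      "mean_stain_area")

#' Well-level summaries over usable sites
#'
#' Aggregates site metrics to "summary data": the per-well mean (and sum)
#' of each metric over the usable sites of each run. Wells with no usable
#' site in a run are excluded with a message. The mean is the default
#' summary statistic reported under the metric's own column name; sums are
#' kept under `*_sum`.
#'
#' @param sites A site-metrics tibble ([analyze_plate()],
#'   [truth_site_metrics()], or a re-read site CSV).
#' @return A tibble with one row per (plate, well, run).
#' @export
summarize_wells <- function(sites) {
  stopifnot(all(c("plate_id", "well_id", "run_index", "usable") %in% names(sites)))
  dropped <- sites %>%
    group_by(.data$plate_id, .data$well_id, .data$run_index) %>%
    summarise(n_used = sum(.data$usable), .groups = "drop") %>%
    filter(.data$n_used == 0)
  if (nrow(dropped)) {
    inform(paste0("Excluding ", nrow(dropped),
                  " well-run(s) with no usable site: ",
                  paste(unique(paste0(dropped$well_id, "/", dropped$run_index)),
                        collapse = ", ")))
  }
  metric_cols <- intersect(SITE_METRIC_COLS, names(sites))
  sites %>%
    group_by(.data$plate_id, .data$well_id, .data$run_index) %>%
    summarise(
      n_sites_total = dplyr::n(),
      n_sites_used = sum(.data$usable),
      across(all_of(metric_cols),
             list(mean = ~ mean(.x[.data$usable], na.rm = TRUE),
                  sum = ~ sum(.x[.data$usable], na.rm = TRUE)),
             .names = "{.col}_{.fn}"),
      .groups = "drop"
    ) %>%
    filter(.data$n_sites_used > 0) %>%
    rename_summary_means(metric_cols)
}

# mean columns carry the plain metric name; sums keep a _sum suffix.
rename_summary_means <- function(tbl, metric_cols) {
  for (m in metric_cols) {
    names(tbl)[names(tbl) == paste0(m, "_mean")] <- m
  }
  tbl
}
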