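#' Build a reproducible run configuration
#'
#' Collects every parameter of a simulate-segment-analyze run in one
#' serializable object: plate layout, imaging geometry, simulation profile,
#' analysis settings, QC rules and the seed. The configuration round-trips
#' through YAML losslessly ([write_run_config()] / [read_run_config()]),
#' and its hash is stamped on every output file so results can be traced
#' to the exact settings that produced them.
#'
#' @param seed Integer master seed for the run.
#' @param mode Screen direction (see [call_hits()]).
#' @param plate_map Optional path to a plate-map CSV; `NULL` uses the
#'   default 96-well layout of [design_screen_96()].
#' @param sites_per_well Imaged sites per well.
#' @param profile_name,profile_overrides Simulation profile selector and
#'   named overrides (see [sim_profile()]).
#' @param dim Field size in pixels `c(rows, cols)`.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param tf,mws Named lists of overrides for [tf_params()] and
#'   [mws_params()]; `mws = NULL` skips MWS scoring.
#' @param analysis_module `"TF"`, `"MWS"` or `"both"` (MWS scores are
#'   carried alongside TF metrics when requested).
#' @param qc Apply paired-site QC (default `TRUE`).
#' @param cell_loss_cutoff,mad_k QC rule parameters.
#' @param alpha Hit-call significance level.
#' @param denominator Normalization denominator (see
#'   [normalize_disassembly()]).
#' @param images_dir Directory for simulated TIFFs (`NULL` keeps fields in
#'   memory -- only sensible for small test plates).
#' @param out_dir Directory for result CSVs, the heat map and the run log.
#' @param corrupted Optional corrupted-sites data frame (see
#'   [plate_design()]).
#' @return A `run_config` object (a validated named list).
#' @export
run_config <- function(seed = 1, mode = "induce_disassembly",
                       plate_map = NULL, sites_per_well = 9,
                       profile_name = "arl13b_low_bg",
                       profile_overrides = list(),
                       dim = c(1024, 1024), pixel_size_um = 0.325,
                       tf = list(), mws = NULL,
                       analysis_module = c("TF", "both", "MWS"),
                       qc = TRUE, cell_loss_cutoff = 0.5, mad_k = 3.5,
                       alpha = 0.05, denominator = "control_ir1",
                       images_dir = NULL, out_dir = "ciliascreen_results",
                       corrupted = NULL) {
  analysis_module <- match.arg(analysis_module)
  mode <- match.arg(mode, c("induce_disassembly", "block_disassembly"))
  cfg <- list(
    seed = as.integer(seed), mode = mode, plate_map = plate_map,
    sites_per_well = as.integer(sites_per_well),
    profile_name = profile_name, profile_overrides = profile_overrides,
    dim = as.integer(dim), pixel_size_um = pixel_size_um,
    tf = tf, mws = mws, analysis_module = analysis_module,
    qc = qc, cell_loss_cutoff = cell_loss_cutoff, mad_k = mad_k,
    alpha = alpha, denominator = denominator,
    images_dir = images_dir, out_dir = out_dir,
    corrupted = corrupted
  )
  # constructing the parameter objects validates their invariants
  do.call(sim_profile, c(list(profile_name = profile_name), profile_overrides))
  do.call(tf_params, tf)
  if (!is.null(mws)) do.call(mws_params, mws)
  check_field_geometry(cfg$dim, cfg$pixel_size_um)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed ", x$seed, ", mode ", x$mode, ", profile ",
      x$profile_name, ", ", paste(x$dim, collapse = "x"), " px @ ",
      x$pixel_size_um, " um/px\n", sep = "")
  cat("  hash: ", config_hash(x), "\n", sep = "")
  invisible(x)
}

# Output locations do not alter results, so they are excluded from the hash.
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$images_dir <- NULL
  rlang::hash(x)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("Unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$corrupted)) {
    raw$corrupted <- dplyr::bind_rows(lapply(raw$corrupted, as_tibble))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  if (!is.null(out$corrupted)) {
    out$corrupted <- lapply(seq_len(nrow(out$corrupted)),
                            function(i) as.list(out$corrupted[i, ]))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", name, "] ", conditionMessage(e)))
  })
}

#' Run the full simulate-segment-analyze pipeline
#'
#' Executes the configured stages in order -- plate simulation, per-field
#' segmentation and metrics, screen analysis -- and writes
#' `site_metrics.csv`, `well_summaries.csv`, `qc_report.csv`,
#' `screen_results.csv`, a plate heat map PNG and a `run_log.yaml`
#' recording the seed, the configuration and its hash, and per-stage
#' counts. Identical configuration and inputs produce identical outputs.
#' Any stage failure aborts with a stage-tagged message.
#'
#' @param config A [run_config()].
#' @param stages Character subset of `c("simulate", "analyze", "screen")`.
#'   `"analyze"` without `"simulate"` reads TIFFs from
#'   `config$images_dir`.
#' @return Invisibly, a list with the `plate_dataset` (when simulated),
#'   the site metrics, the `cilia_screen` result and the output paths.
#' @export
run_pipeline <- function(config, stages = c("simulate", "analyze", "screen")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  hash <- config_hash(config)
  log <- list(config_hash = hash, seed = config$seed, stages = stages,
              counts = list())
  design <- pipeline_stage("design", {
    if (!is.null(config$plate_map)) {
      read_plate_map(config$plate_map, sites_per_well = config$sites_per_well,
                     corrupted = config$corrupted, seed = config$seed)
    } else {
      design_screen_96(mode = config$mode,
                       sites_per_well = config$sites_per_well,
                       corrupted = config$corrupted, seed = config$seed)
    }
  })
  profile <- do.call(sim_profile, c(list(profile_name = config$profile_name),
                                    config$profile_overrides))
  plate <- NULL
  if ("simulate" %in% stages) {
    plate <- pipeline_stage("simulate", {
      generate_plate(design, profile, dim = config$dim,
                     pixel_size_um = config$pixel_size_um,
                     dir = config$images_dir)
    })
    log$counts$fields_simulated <-
      nrow(dplyr::distinct(plate$manifest, .data$well, .data$site, .data$run))
  }
  sites <- screen <- NULL
  paths <- list()
  if ("analyze" %in% stages) {
    sites <- pipeline_stage("analyze", {
      if (is.null(plate)) {
        if (is.null(config$images_dir)) {
          abort("analyze without simulate requires images_dir.")
        }
        plate <- plate_from_dir(config$images_dir, design,
                                pixel_size_um = config$pixel_size_um,
                                profile = profile)
      }
      tf <- do.call(tf_params, config$tf)
      mws <- if (config$analysis_module %in% c("MWS", "both") ||
                 !is.null(config$mws)) {
        do.call(mws_params, if (is.null(config$mws)) list() else config$mws)
      } else NULL
      analyze_plate(plate, tf = tf, mws = mws)
    })
    paths$site_metrics <- file.path(config$out_dir, "site_metrics.csv")
    readr::write_csv(sites, paths$site_metrics)
    log$counts$sites_analyzed <- nrow(sites)
  }
  if ("screen" %in% stages) {
    screen <- pipeline_stage("screen", {
      if (is.null(sites)) abort("screen requires the analyze stage output.")
      run_screen(sites, design, mode = config$mode, alpha = config$alpha,
                 qc = config$qc, denominator = config$denominator,
                 cell_loss_cutoff = config$cell_loss_cutoff,
                 mad_k = config$mad_k)
    })
    paths$well_summaries <- file.path(config$out_dir, "well_summaries.csv")
    readr::write_csv(summarize_wells(sites), paths$well_summaries)
    paths$qc_report <- file.path(config$out_dir, "qc_report.csv")
    readr::write_csv(screen$qc, paths$qc_report)
    paths$screen_results <- file.path(config$out_dir, "screen_results.csv")
    readr::write_csv(screen_results_table(screen, hash), paths$screen_results)
    paths$heatmap <- file.path(config$out_dir, "plate_heatmap.png")
    suppressMessages(ggplot2::ggsave(paths$heatmap, autoplot(screen),
                                     width = 8, height = 5, dpi = 120))
    log$counts$wells_scored <- nrow(screen$scores)
    log$counts$hits <- sum(screen$hits$hit)
    log$counts$site_pairs_flagged <- sum(screen$qc$flag != "ok")
  }
  log$r_version <- as.character(getRversion())
  log$package_version <- as.character(utils::packageVersion("ciliascreen"))
  log$config <- unclass(config)
  if (!is.null(log$config$corrupted)) {
    log$config$corrupted <- lapply(seq_len(nrow(log$config$corrupted)),
                                   function(i) as.list(log$config$corrupted[i, ]))
  }
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  invisible(list(plate = plate, sites = sites, screen = screen,
                 paths = paths, config_hash = hash))
}

# Flatten a screen result for CSV export; every row carries the config hash.
screen_results_table <- function(screen, hash) {
  hit_cols <- screen$hits %>%
    select("compound_id", "p_value", "adjusted_p", "hit", "rank", "status")
  screen$scores %>%
    left_join(hit_cols, by = "compound_id") %>%
    mutate(
      mode = screen$params$mode,
      qc_removed_sites = purrr::map_chr(.data$qc_removed_sites,
                                        ~ paste(.x, collapse = ";")),
      config_hash = hash
    ) %>%
    select("well_id", "compound_id", "role", "mode", "normalized_score",
           "score_after_qc", "p_value", "adjusted_p", "hit",
           "qc_removed_sites", "config_hash") %>%
    arrange(.data$well_id)
}

# Reconstruct a plate_dataset view over an existing TIFF directory.
plate_from_dir <- function(dir, design, pixel_size_um, profile) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    abort(paste0("No manifest.csv in ", dir))
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  } else NULL
  structure(
    list(manifest = manifest, truth = truth, fields = NULL,
         design = design, profile = profile, dim = NULL,
         pixel_size_um = pixel_size_um, dir = dir),
    class = "plate_dataset"
  )
}
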