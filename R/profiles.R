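#' Reporter cell-line simulation profiles
#'
#' A simulation profile describes one ciliary reporter cell line as seen in a
#' live two-channel high-content imaging assay: how many adherent cells a
#' field holds, what fraction carry a primary cilium after serum starvation,
#' the physical size of the cilium, and -- critically for automated counting
#' -- how much labeled vesicular background the reporter produces in the
#' cytoplasm. Three built-in profiles mirror the behaviour of the commonly
#' used reporters:
#'
#' * `arl13b_low_bg` -- Arl13b-EGFP: bright, clean ciliary signal with almost
#'   no cytoplasmic vesicles; the preferred line for automated screening.
#' * `smo_moderate_bg` -- SMO-EGFP: usable signal with a moderate level of
#'   background vesicles.
#' * `mchr1_high_bg` -- MCHR1-tdTomato: many bright cytoplasmic vesicles that
#'   confound threshold-based cilium counting, especially after serum
#'   addition (serum boosts the vesicular signal in this line only).
#'
#' All lengths are in micrometres and intensities on the raw 16-bit camera
#' scale (see [intensity_8bit()] for the 8-bit convention used by analysis
#' settings).
#'
#' @param profile_name One of `"arl13b_low_bg"`, `"smo_moderate_bg"`,
#'   `"mchr1_high_bg"`.
#' @param ... Named overrides for any profile field (e.g.
#'   `cells_per_field = 30`, `ciliation_fraction = 0.7`).
#'
#' @return An object of class `sim_profile`: a named list with fields
#'   `profile_name`, `cells_per_field` (expected cells per field; actual
#'   counts are Poisson), `ciliation_fraction`, `cilium_length_um`
#'   (`mean`, `sd`, `min`, `max` of a truncated normal), `cilium_width_um`,
#'   `background_vesicles_per_cell`, `background_vesicle_size_um`
#'   (truncated-normal spec), `background_vesicle_amplitude`
#'   (`mean`, `sd`), `cilium_amplitude`, `nucleus_amplitude`,
#'   `nucleus_diameter_um`, `min_center_distance_um`, `background_offset`,
#'   `noise_sd`, `shot_scale`, `boost_on_serum`, `bit_depth`.
#' @examples
#' sim_profile("arl13b_low_bg")
#' sim_profile("mchr1_high_bg", cells_per_field = 40)
#' @export
sim_profile <- function(profile_name = c("arl13b_low_bg", "smo_moderate_bg",
                                         "mchr1_high_bg"), ...) {
  profile_name <- match.arg(profile_name)
  base <- list(
    profile_name = profile_name,
    cells_per_field = 60,
    ciliation_fraction = 0.85,
    cilium_length_um = list(mean = 4, sd = 1.2, min = 2, max = 6),
    cilium_width_um = 0.5,
    cilium_amplitude = 40000,
    nucleus_amplitude = 10000,
    nucleus_diameter_um = 10,
    min_center_distance_um = 10.5,
    background_offset = 800,
    noise_sd = 150,
    shot_scale = 2,
    bit_depth = 16L,
    boost_on_serum = FALSE
  )
  line <- switch(profile_name,
    arl13b_low_bg = list(
      background_vesicles_per_cell = 0.05,
      background_vesicle_size_um = list(mean = 1.2, sd = 0.4, min = 0.5, max = 2.5),
      background_vesicle_amplitude = list(mean = 8000, sd = 2500)
    ),
    smo_moderate_bg = list(
      background_vesicles_per_cell = 0.5,
      background_vesicle_size_um = list(mean = 1.6, sd = 0.5, min = 0.6, max = 3),
      background_vesicle_amplitude = list(mean = 15000, sd = 5000),
      noise_sd = 200
    ),
    mchr1_high_bg = list(
      background_vesicles_per_cell = 3,
      background_vesicle_size_um = list(mean = 2.2, sd = 0.7, min = 0.8, max = 4),
      background_vesicle_amplitude = list(mean = 30000, sd = 8000),
      noise_sd = 250,
      boost_on_serum = TRUE
    )
  )
  prof <- modifyList(base, line)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(prof))
    if (length(bad)) {
      abort(paste0("Unknown sim_profile field(s): ", paste(bad, collapse = ", ")))
    }
    prof <- modifyList(prof, dots)
  }
  validate_sim_profile(prof)
  structure(prof, class = "sim_profile")
}

validate_sim_profile <- function(p) {
  stopifnot(
    p$cells_per_field > 0,
    p$ciliation_fraction >= 0, p$ciliation_fraction <= 1,
    p$cilium_width_um > 0,
    p$cilium_length_um$min > 0,
    p$cilium_length_um$min <= p$cilium_length_um$max,
    p$background_vesicles_per_cell >= 0,
    p$nucleus_diameter_um > 0,
    p$noise_sd >= 0,
    p$bit_depth >= 8
  )
  invisible(p)
}

#' @export
print.sim_profile <- function(x, ...) {
  cat("<sim_profile> ", x$profile_name, "\n", sep = "")
  cat("  cells/field (expected): ", x$cells_per_field,
      ", ciliation fraction: ", x$ciliation_fraction, "\n", sep = "")
  cat("  cilium length: ", x$cilium_length_um$mean, " um (sd ",
      x$cilium_length_um$sd, ", range ", x$cilium_length_um$min, "-",
      x$cilium_length_um$max, "), width ", x$cilium_width_um, " um\n", sep = "")
  cat("  background vesicles/cell: ", x$background_vesicles_per_cell, "\n", sep = "")
  invisible(x)
}

#' Perturbation applied between the two imaging runs
#'
#' Describes what a well's treatment (serum, compound, or vehicle) does to
#' the ciliated cell population between the baseline imaging run (IR1) and
#' the post-perturbation run (IR2).
#'
#' @param disassembly_fraction Fraction in `[0, 1]` of ciliated cells that
#'   fully lose their cilium between runs. Serum typically produces a
#'   measured change of roughly 20--60% in this assay format.
#' @param length_shrink_factor Multiplicative factor in `(0, 1]` applied to
#'   the length of cilia that survive the perturbation.
#' @param background_boost Multiplicative factor `>= 1` on cytoplasmic
#'   vesicle intensity in IR2. Only applied when the profile has
#'   `boost_on_serum = TRUE` (the MCHR1 reporter), where serum visibly
#'   increases intracellular signal.
#'
#' @return An object of class `perturbation`.
#' @examples
#' serum <- perturbation(disassembly_fraction = 0.4, length_shrink_factor = 0.85)
#' vehicle <- perturbation(0)
#' @export
perturbation <- function(disassembly_fraction = 0, length_shrink_factor = 1,
                         background_boost = 1) {
  stopifnot(
    disassembly_fraction >= 0, disassembly_fraction <= 1,
    length_shrink_factor > 0, length_shrink_factor <= 1,
    background_boost >= 1
  )
  structure(
    list(disassembly_fraction = disassembly_fraction,
         length_shrink_factor = length_shrink_factor,
         background_boost = background_boost),
    class = "perturbation"
  )
}

#' @export
print.perturbation <- function(x, ...) {
  cat("<perturbation> disassembly ", x$disassembly_fraction,
      ", length shrink ", x$length_shrink_factor,
      ", background boost ", x$background_boost, "\n", sep = "")
  invisible(x)
}

#' Convert an 8-bit analysis setting to the raw 16-bit intensity scale
#'
#' Threshold settings in high-content analysis software are commonly quoted
#' on a 0--255 display scale even when images are acquired at 16 bits. This
#' package stores pixel data on the raw 16-bit scale; `intensity_8bit()`
#' maps an 8-bit setting `s` to `s * 257`, so that 255 corresponds to 65535.
#'
#' @param x Numeric setting(s) on the 0--255 scale.
#' @return The equivalent raw 16-bit intensity.
#' @examples
#' intensity_8bit(78)   # the low end of typical cilium-intensity settings
#' @export
intensity_8bit <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0), all(x <= 255))
  x * 257
}
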