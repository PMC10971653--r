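#' Analysis configuration for the hydrostatic-weighing pipeline
#'
#' Collects the protocol tolerances and physical constants used by
#' [compute_cohort()] and [hw_run()]. Defaults reproduce the field protocol:
#' girth pairs must agree within 5 mm, three in-water trials within 100 g are
#' averaged, load-cell windows of 100 +/- 2 samples are selected, and trials
#' are capped at 7 for total-lung-capacity conditions and 5 at residual
#' volume.
#'
#' @param girth_tolerance_mm Girth pair agreement tolerance, mm.
#' @param trial_tolerance_kg Trial consistency tolerance, kg (0.100 = 100 g).
#' @param sample_target,sample_slack Load-cell window size target and slack.
#' @param max_trials_tlc,max_trials_rv Trial caps per condition. Values above
#'   the protocol caps (7 and 5) are accepted with a warning.
#' @param water_temp_c Default tank temperature in Celsius, used when a
#'   participant record carries none. Default 32.5, the midpoint of the
#'   31--34 degree operating band.
#' @param water_density_kg_l Optional fixed water density override (kg/L).
#'   When `NULL`, density is computed from temperature via [water_density()].
#' @param gi_gas_l Gastrointestinal gas allowance subtracted from body
#'   volume, litres. Default 0.1.
#' @param belt_mass_kg Mass of the weighted belt worn during
#'   total-lung-capacity trials. The default 0 assumes the acquisition
#'   system tares the belt; set a positive mass for systems that do not, and
#'   the belt's net in-water weight `belt_mass_kg * (1 - DW / belt_density)`
#'   is subtracted from TLC-condition readings.
#' @param belt_density_kg_l Belt material density, kg/L (default 7.8, steel).
#' @param strict_quality If `TRUE`, conditions whose weight came from only
#'   two consistent trials (quality `"pair"`) are excluded from analysis;
#'   by default they are retained with their quality tier recorded.
#' @param loa_multiplier Multiplier for Bland-Altman limits of agreement
#'   (default 1.96, the 95% limits).
#' @return A list of class `hw_config`.
#' @export
hw_config <- function(girth_tolerance_mm = 5,
                      trial_tolerance_kg = 0.100,
                      sample_target = 100,
                      sample_slack = 2,
                      max_trials_tlc = 7,
                      max_trials_rv = 5,
                      water_temp_c = 32.5,
                      water_density_kg_l = NULL,
                      gi_gas_l = 0.1,
                      belt_mass_kg = 0,
                      belt_density_kg_l = 7.8,
                      strict_quality = FALSE,
                      loa_multiplier = 1.96) {
  stopifnot(girth_tolerance_mm > 0, trial_tolerance_kg > 0,
            sample_target > 0, sample_slack >= 0,
            max_trials_tlc >= 1, max_trials_rv >= 1,
            gi_gas_l >= 0, belt_mass_kg >= 0, belt_density_kg_l > 0,
            loa_multiplier > 0)
  if (max_trials_tlc > 7 || max_trials_rv > 5) {
    warn("trial caps exceed the protocol maxima (7 TLC, 5 RV)")
  }
  structure(
    list(girth_tolerance_mm = girth_tolerance_mm,
         trial_tolerance_kg = trial_tolerance_kg,
         sample_target = sample_target,
         sample_slack = sample_slack,
         max_trials_tlc = max_trials_tlc,
         max_trials_rv = max_trials_rv,
         water_temp_c = water_temp_c,
         water_density_kg_l = water_density_kg_l,
         gi_gas_l = gi_gas_l,
         belt_mass_kg = belt_mass_kg,
         belt_density_kg_l = belt_density_kg_l,
         strict_quality = strict_quality,
         loa_multiplier = loa_multiplier),
    class = "hw_config"
  )
}

condition_cap <- function(condition, config) {
  ifelse(condition == "HBW_RV", config$max_trials_rv, config$max_trials_tlc)
}

check_condition <- function(condition) {
  bad <- setdiff(unique(condition), HW_CONDITIONS)
  if (length(bad) > 0) {
    abort(paste0("unknown condition label(s): ", paste(bad, collapse = ", "),
                 "; expected ", paste(HW_CONDITIONS, collapse = ", ")))
  }
  condition
}
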