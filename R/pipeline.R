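#' Run the full hydrostatic-weighing analysis from CSV inputs
#'
#' Reads a directory of input tables, validates their schemas, computes
#' per-participant, per-condition body composition, runs the three-way
#' method comparison, and (optionally) writes the result tables and a run
#' log. Participant-level failures (girth QC failures, no consistent
#' trials, impossible volumes) are recorded in the log and the run
#' continues; schema violations abort with itemised messages.
#'
#' Expected inputs in `input_dir`:
#' \describe{
#'   \item{participants.csv}{`id`, `sex`, `age`, `height_cm`, `mass_kg`,
#'     optionally `water_temp_c`.}
#'   \item{girths.csv}{`participant_id`, `site` (HG/FG), `trial_index`,
#'     `value_mm`.}
#'   \item{trials.csv}{`participant_id`, `condition` (HAW_TLC / HBW_TLC /
#'     HBW_RV), `trial_index`, `weight_kg`. Alternatively `samples.csv`
#'     (`participant_id`, `condition`, `trial_index`, `sample_index`,
#'     `reading_kg`) with raw load-cell streams, collapsed to trial weights
#'     via [select_sample_window()].}
#' }
#'
#' @param input_dir Directory containing the input CSVs.
#' @param out_dir Optional output directory; when given, `results.csv`,
#'   `agreement_report.csv`, `bland_altman_points.csv` and `run_log.txt`
#'   are written there.
#' @param config An [hw_config()].
#' @return Invisibly, a list with `results` (per-participant tibble, see
#'   [compute_cohort()]), `report` (the [run_comparisons()] tibble),
#'   `diagnostics` and `log` (character vector of log lines).
#' @export
hw_run <- function(input_dir, out_dir = NULL, config = hw_config()) {
  paths <- list(
    participants = file.path(input_dir, "participants.csv"),
    girths = file.path(input_dir, "girths.csv"),
    trials = file.path(input_dir, "trials.csv"),
    samples = file.path(input_dir, "samples.csv")
  )
  for (nm in c("participants", "girths")) {
    if (!file.exists(paths[[nm]])) {
      abort(paste0("missing input file: ", paths[[nm]]))
    }
  }
  participants <- readr::read_csv(paths$participants, show_col_types = FALSE)
  girths <- readr::read_csv(paths$girths, show_col_types = FALSE)
  validate_schema(participants, "participants.csv",
                  c(id = "character", sex = "character", age = "numeric",
                    height_cm = "numeric", mass_kg = "numeric"))
  validate_schema(girths, "girths.csv",
                  c(participant_id = "character", site = "character",
                    trial_index = "numeric", value_mm = "numeric"))

  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  if (file.exists(paths$trials)) {
    trials <- readr::read_csv(paths$trials, show_col_types = FALSE)
  } else if (file.exists(paths$samples)) {
    samples <- readr::read_csv(paths$samples, show_col_types = FALSE)
    validate_schema(samples, "samples.csv",
                    c(participant_id = "character", condition = "character",
                      trial_index = "numeric", sample_index = "numeric",
                      reading_kg = "numeric"))
    validate_conditions(samples, "samples.csv")
    note("trials.csv absent; collapsing samples.csv streams (",
         config$sample_target, " +/- ", config$sample_slack,
         " sample windows)")
    trials <- samples |>
      dplyr::group_by(.data$participant_id, .data$condition,
                      .data$trial_index) |>
      dplyr::summarise(weight_kg = select_sample_window(
        .data$reading_kg, target_n = config$sample_target,
        slack = config$sample_slack)$mean_kg, .groups = "drop")
  } else {
    abort(paste0("missing input file: ", paths$trials,
                 " (or samples.csv with raw streams)"))
  }
  validate_schema(trials, "trials.csv",
                  c(participant_id = "character", condition = "character",
                    trial_index = "numeric", weight_kg = "numeric"))
  validate_conditions(trials, "trials.csv")

  orphans <- setdiff(
    unique(c(girths$participant_id, trials$participant_id)),
    participants$id)
  if (length(orphans) > 0) {
    abort(paste0("girths/trials reference unknown participant id(s): ",
                 paste(orphans, collapse = ", ")))
  }

  note("participants: ", nrow(participants), "; girth rows: ",
       nrow(girths), "; trial rows: ", nrow(trials))

  results <- compute_cohort(participants, girths, trials, config)
  diagnostics <- attr(results, "diagnostics")
  for (i in seq_len(nrow(diagnostics))) {
    note("participant ", diagnostics$participant_id[i], ": ",
         diagnostics$message[i])
  }
  note("computed ", nrow(results), " condition results for ",
       dplyr::n_distinct(results$participant_id), " participants")
  n_pair <- sum(results$quality == "pair")
  if (n_pair > 0) {
    note(n_pair, " condition result(s) rest on two consistent trials",
         if (config$strict_quality) " (excluded: strict mode)" else
           " (retained; quality tier recorded)")
  }

  report <- withCallingHandlers(
    run_comparisons(results, participants,
                    strict = config$strict_quality,
                    multiplier = config$loa_multiplier),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(results, file.path(out_dir, "results.csv"))
    readr::write_csv(as.data.frame(report),
                     file.path(out_dir, "agreement_report.csv"))
    readr::write_csv(attr(report, "points"),
                     file.path(out_dir, "bland_altman_points.csv"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(list(results = results, report = report,
                 diagnostics = diagnostics, log = log_lines))
}

#' Simulate a study fixture to disk
#'
#' Thin wrapper over [make_study_fixture()] for the simulate entry point.
#'
#' @param config An [cohort_config()].
#' @param out_dir Directory to write the fixture bundle to.
#' @param seed Optional integer overriding `config$seed`.
#' @return Invisibly, the files written.
#' @export
hw_simulate <- function(config = cohort_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  make_study_fixture(config, out_dir)
}

validate_schema <- function(df, file, cols) {
  problems <- character()
  for (nm in names(cols)) {
    if (!nm %in% names(df)) {
      problems <- c(problems, paste0("missing column `", nm, "`"))
    } else if (cols[[nm]] == "numeric" && !is.numeric(df[[nm]])) {
      problems <- c(problems,
                    paste0("column `", nm, "` must be numeric"))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("schema violations in ", file, ":\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  invisible(df)
}

validate_conditions <- function(df, file) {
  bad <- which(!df$condition %in% HW_CONDITIONS)
  if (length(bad) > 0) {
    abort(paste0(
      file, ": unknown condition label '", df$condition[bad[1]],
      "' at row ", bad[1],
      if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)") else "",
      "; expected ", paste(HW_CONDITIONS, collapse = ", ")))
  }
  invisible(df)
}
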