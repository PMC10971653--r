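#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort with known ground truth from which girth measurements
#' and in-water weights are forward-simulated, so the whole pipeline can be
#' verified by parameter recovery. Demographic defaults are the study-style
#' marginals of a mixed university cohort (64 males, 58 females; sex-specific
#' height, mass, age and head/face girth means and SDs); true percent body
#' fat is drawn per sex and converted to body density, and true lung and
#' head volumes are the anthropometric predictions plus configurable
#' deviations, so method disagreement can be injected explicitly and is
#' never present by default.
#'
#' All per-sex parameters are length-2 vectors named `male`, `female`.
#'
#' @param n_male,n_female Cohort sizes.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param height_mean_cm,height_sd_cm,mass_mean_kg,mass_sd_kg Per-sex
#'   demographic moments.
#' @param age_mean_yr,age_sd_yr,age_range_yr Per-sex age moments and the
#'   truncation range (adults only).
#' @param hg_mean_cm,hg_sd_cm,fg_mean_cm,fg_sd_cm Per-sex head-girth and
#'   face-girth moments (true circumferences; stored to the nearest mm).
#' @param pbf_mean,pbf_sd,pbf_range True percent-body-fat distribution per
#'   sex, truncated to `pbf_range`.
#' @param hv_bias_l,hv_sd_l True head volume is the girth-based prediction
#'   plus `hv_bias_l` plus N(0, `hv_sd_l`) scatter. A negative bias means
#'   the prediction overstates the true head volume.
#' @param tlc_offset_l,rv_offset_l True lung volumes are the height/age
#'   predictions plus these offsets (true = predicted + offset); a negative
#'   offset means participants hold less gas than predicted.
#' @param trial_noise_kg SD of iid per-trial noise on simulated in-water
#'   masses (default 0.030 kg).
#' @param girth_noise_mm SD of iid technician error per girth measurement
#'   (default 2 mm); measurements are recorded to the nearest mm and the
#'   repeat-measurement protocol (third/fourth trial on disagreement) is
#'   simulated.
#' @param n_trials_tlc,n_trials_rv Trials simulated per condition; must
#'   respect the protocol caps (7 and 5).
#' @param water_temp_c Tank temperature, Celsius.
#' @param simulate_streams If `TRUE`, raw load-cell sample streams are
#'   simulated per trial instead of summary weights being exact.
#' @param samples_per_trial,sample_noise_kg Stream length and iid sample
#'   noise when `simulate_streams` is `TRUE`.
#' @return A list of class `hw_cohort_config`.
#' @export
cohort_config <- function(n_male = 64, n_female = 58, seed = 1,
                          height_mean_cm = c(male = 182.1, female = 168.7),
                          height_sd_cm = c(male = 7.9, female = 6.2),
                          mass_mean_kg = c(male = 90.6, female = 68.5),
                          mass_sd_kg = c(male = 14.7, female = 12.1),
                          age_mean_yr = c(male = 25.3, female = 22.9),
                          age_sd_yr = c(male = 10.7, female = 8.4),
                          age_range_yr = c(18, 70),
                          hg_mean_cm = c(male = 58.3, female = 56.2),
                          hg_sd_cm = c(male = 1.6, female = 1.6),
                          fg_mean_cm = c(male = 67.7, female = 63.0),
                          fg_sd_cm = c(male = 2.1, female = 2.1),
                          pbf_mean = c(male = 18, female = 28),
                          pbf_sd = c(male = 6, female = 7),
                          pbf_range = c(3, 50),
                          hv_bias_l = 0, hv_sd_l = 0.15,
                          tlc_offset_l = 0, rv_offset_l = 0,
                          trial_noise_kg = 0.030, girth_noise_mm = 2,
                          n_trials_tlc = 5, n_trials_rv = 4,
                          water_temp_c = 32.5,
                          simulate_streams = FALSE,
                          samples_per_trial = 150,
                          sample_noise_kg = 0.050) {
  cfg <- as.list(environment())
  sds <- c(cfg$height_sd_cm, cfg$mass_sd_kg, cfg$age_sd_yr, cfg$hg_sd_cm,
           cfg$fg_sd_cm, cfg$pbf_sd, hv_sd_l, trial_noise_kg,
           girth_noise_mm, sample_noise_kg)
  if (any(sds < 0)) abort("all standard deviations must be >= 0")
  if (n_male < 0 || n_female < 0) abort("cohort sizes must be >= 0")
  if (n_trials_tlc < 1 || n_trials_tlc > 7 ||
      n_trials_rv < 1 || n_trials_rv > 5) {
    abort("n_trials must respect the protocol caps (TLC <= 7, RV <= 5)")
  }
  for (nm in c("height_mean_cm", "height_sd_cm", "mass_mean_kg",
               "mass_sd_kg", "age_mean_yr", "age_sd_yr", "hg_mean_cm",
               "hg_sd_cm", "fg_mean_cm", "fg_sd_cm", "pbf_mean", "pbf_sd")) {
    if (!all(c("male", "female") %in% names(cfg[[nm]]))) {
      abort(paste0("`", nm, "` must be named with 'male' and 'female'"))
    }
  }
  structure(cfg, class = "hw_cohort_config")
}

# normal truncated to [lo, hi] by rejection; exact at sd = 0
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean < lo || mean > hi) abort("degenerate mean outside range")
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws recorded demographics (rounded to instrument resolution: height
#' 0.1 cm, mass 0.1 kg, age whole years, girths whole mm), then builds the
#' latent truth from the recorded values: true percent body fat per sex
#' (converted to density by the inverse Brozek transform), true lung volumes
#' as the height/age predictions plus the configured offsets, and true head
#' volume as the girth-based prediction plus the configured bias and
#' scatter. Girth measurement sessions are simulated under the repeat
#' protocol (two technicians, a third measurement on >5 mm disagreement, a
#' fourth if no pair agrees).
#'
#' @param config An [cohort_config()].
#' @return A list with tibbles `participants` (`id`, `sex`, `age`,
#'   `height_cm`, `mass_kg`, `water_temp_c`), `girths` (measurement rows)
#'   and `truth` (`participant_id`, `pbf_true`, `db_true`, `hv_true_l`,
#'   `hg_true_mm`, `fg_true_mm`, `tlc_true_l`, `rv_true_l`,
#'   `body_volume_l`). Deterministic given `config$seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "hw_cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  per_sex <- purrr::map(c(male = "male", female = "female"), function(s) {
    n <- if (s == "male") config$n_male else config$n_female
    if (n == 0) return(NULL)
    tibble::tibble(
      sex = s,
      age = round(rnorm_trunc(n, config$age_mean_yr[[s]],
                              config$age_sd_yr[[s]],
                              config$age_range_yr[1], config$age_range_yr[2])),
      height_cm = round(rnorm_trunc(n, config$height_mean_cm[[s]],
                                    config$height_sd_cm[[s]], 120, 230), 1),
      mass_kg = round(rnorm_trunc(n, config$mass_mean_kg[[s]],
                                  config$mass_sd_kg[[s]], 35, 200), 1),
      hg_true_mm = round(10 * rnorm_trunc(n, config$hg_mean_cm[[s]],
                                          config$hg_sd_cm[[s]], 45, 70)),
      fg_true_mm = round(10 * rnorm_trunc(n, config$fg_mean_cm[[s]],
                                          config$fg_sd_cm[[s]], 50, 80)),
      pbf_true = rnorm_trunc(n, config$pbf_mean[[s]], config$pbf_sd[[s]],
                             config$pbf_range[1], config$pbf_range[2])
    )
  })
  cohort <- dplyr::bind_rows(per_sex)
  if (nrow(cohort) == 0) {
    return(list(participants = empty_participants(),
                girths = empty_girths(), truth = empty_truth()))
  }
  cohort$id <- sprintf("P%03d", seq_len(nrow(cohort)))

  cohort <- cohort |>
    dplyr::mutate(
      db_true = pbf_to_density(.data$pbf_true),
      body_volume_l = .data$mass_kg / .data$db_true,
      tlc_true_l = predict_tlc(.data$sex, .data$height_cm / 100) +
        config$tlc_offset_l,
      rv_true_l = predict_rv(.data$sex, .data$height_cm / 100, .data$age) +
        config$rv_offset_l,
      hv_true_l = predict_head_volume(.data$sex, .data$hg_true_mm / 10,
                                      .data$fg_true_mm / 10, .data$mass_kg) +
        config$hv_bias_l +
        if (config$hv_sd_l > 0) rnorm(dplyr::n(), 0, config$hv_sd_l) else 0
    )

  girths <- purrr::map2(
    rep(cohort$id, each = 2), rep(c("HG", "FG"), times = nrow(cohort)),
    function(id, site) {
      truth <- if (site == "HG") {
        cohort$hg_true_mm[cohort$id == id]
      } else {
        cohort$fg_true_mm[cohort$id == id]
      }
      m <- simulate_girth_session(truth, config$girth_noise_mm)
      tibble::tibble(participant_id = id, site = site,
                     trial_index = seq_along(m), value_mm = m)
    }) |>
    dplyr::bind_rows()

  list(
    participants = cohort |>
      dplyr::mutate(water_temp_c = config$water_temp_c) |>
      dplyr::select("id", "sex", "age", "height_cm", "mass_kg",
                    "water_temp_c"),
    girths = girths,
    truth = cohort |>
      dplyr::select(participant_id = "id", "pbf_true", "db_true",
                    "hv_true_l", "hg_true_mm", "fg_true_mm", "tlc_true_l",
                    "rv_true_l", "body_volume_l")
  )
}

# two technicians measure; a third measurement follows >tolerance
# disagreement, a fourth if still no pair agrees (protocol cap 4)
simulate_girth_session <- function(truth_mm, noise_mm, tolerance_mm = 5) {
  draw <- function() round(truth_mm + rnorm(1, 0, noise_mm))
  m <- c(draw(), draw())
  while (length(m) < 4 &&
         qc_girth(m, tolerance_mm)$status == "needs_measurement") {
    m <- c(m, draw())
  }
  m
}

#' Forward-simulate in-water weighing trials
#'
#' Inverts the density equations: the true in-water mass in each condition
#' is the dry mass minus the weight of water displaced by the body volume,
#' the lung gas held, and the gastrointestinal gas allowance, with the true
#' head volume staying dry in the head-above-water condition:
#' `MW_HBW = MA - DW * (V_body + V_lung + 0.1)`,
#' `MW_HAW = MA - DW * (V_body - HV_true + V_lung + 0.1)`.
#' Per-trial iid noise of SD `trial_noise_kg` is added. Negative in-water
#' masses (buoyant participants) pass through unchanged. Deterministic
#' given `config$seed` (an independent stream from [generate_cohort()]).
#'
#' @param participants,truth As returned by [generate_cohort()].
#' @param config An [cohort_config()].
#' @return A tibble of trials (`participant_id`, `condition`, `trial_index`,
#'   `weight_kg`); when `config$simulate_streams` is `TRUE`, a list of
#'   `trials` and `samples` (`participant_id`, `condition`, `trial_index`,
#'   `sample_index`, `reading_kg`), where each trial's `weight_kg` is the
#'   steadiest-window mean of its stream.
#' @export
simulate_weighing <- function(participants, truth, config = cohort_config()) {
  stopifnot(inherits(config, "hw_cohort_config"))
  check_columns(participants, c("id", "water_temp_c"), "participants")
  check_columns(truth, c("participant_id", "body_volume_l", "hv_true_l",
                         "tlc_true_l", "rv_true_l"), "truth")
  withr::with_seed(config$seed + 1L,
                   simulate_weighing_impl(participants, truth, config))
}

simulate_weighing_impl <- function(participants, truth, config) {
  dat <- dplyr::left_join(participants, truth,
                          by = c(id = "participant_id"))
  gi <- 0.1
  trials <- purrr::map(seq_len(nrow(dat)), function(i) {
    d <- dat[i, ]
    dw <- water_density(d$water_temp_c)
    mw_true <- c(
      HAW_TLC = d$mass_kg - dw * (d$body_volume_l - d$hv_true_l +
                                    d$tlc_true_l + gi),
      HBW_TLC = d$mass_kg - dw * (d$body_volume_l + d$tlc_true_l + gi),
      HBW_RV = d$mass_kg - dw * (d$body_volume_l + d$rv_true_l + gi)
    )
    n_tr <- c(HAW_TLC = config$n_trials_tlc, HBW_TLC = config$n_trials_tlc,
              HBW_RV = config$n_trials_rv)
    purrr::map(HW_CONDITIONS, function(cond) {
      w <- mw_true[[cond]] +
        if (config$trial_noise_kg > 0) {
          rnorm(n_tr[[cond]], 0, config$trial_noise_kg)
        } else {
          numeric(n_tr[[cond]])
        }
      tibble::tibble(participant_id = d$id, condition = cond,
                     trial_index = seq_len(n_tr[[cond]]), weight_kg = w)
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  if (nrow(trials) == 0) {
    trials <- tibble::tibble(participant_id = character(),
                             condition = character(),
                             trial_index = integer(), weight_kg = double())
  }
  if (!config$simulate_streams) return(trials)

  samples <- purrr::map(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    noise <- if (config$sample_noise_kg > 0) {
      rnorm(config$samples_per_trial, 0, config$sample_noise_kg)
    } else {
      numeric(config$samples_per_trial)
    }
    tibble::tibble(participant_id = tr$participant_id,
                   condition = tr$condition, trial_index = tr$trial_index,
                   sample_index = seq_len(config$samples_per_trial),
                   reading_kg = tr$weight_kg + noise)
  }) |>
    dplyr::bind_rows()
  # trial weights become the steadiest-window means of their own streams
  window_means <- samples |>
    dplyr::group_by(.data$participant_id, .data$condition,
                    .data$trial_index) |>
    dplyr::summarise(
      w = select_sample_window(.data$reading_kg)$mean_kg, .groups = "drop")
  trials$weight_kg <- trials |>
    dplyr::select(-"weight_kg") |>
    dplyr::left_join(window_means,
                     by = c("participant_id", "condition", "trial_index")) |>
    dplyr::pull("w")
  list(trials = trials, samples = samples)
}

#' Write a complete synthetic study fixture to disk
#'
#' Generates a cohort, simulates its weighing trials, and writes
#' `participants.csv`, `girths.csv`, `trials.csv` and `truth.csv` (plus
#' `samples.csv` when streams are simulated) to `dir`, ready to run through
#' [hw_run()].
#'
#' @param config An [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
make_study_fixture <- function(config = cohort_config(), dir) {
  cohort <- generate_cohort(config)
  sim <- simulate_weighing(cohort$participants, cohort$truth, config)
  trials <- if (is.data.frame(sim)) sim else sim$trials
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    girths = file.path(dir, "girths.csv"),
    trials = file.path(dir, "trials.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(cohort$participants, paths[["participants"]])
  readr::write_csv(cohort$girths, paths[["girths"]])
  readr::write_csv(trials, paths[["trials"]])
  readr::write_csv(cohort$truth, paths[["truth"]])
  if (!is.data.frame(sim)) {
    paths <- c(paths, samples = file.path(dir, "samples.csv"))
    readr::write_csv(sim$samples, paths[["samples"]])
  }
  invisible(paths)
}

empty_participants <- function() {
  tibble::tibble(id = character(), sex = character(), age = double(),
                 height_cm = double(), mass_kg = double(),
                 water_temp_c = double())
}
empty_girths <- function() {
  tibble::tibble(participant_id = character(), site = character(),
                 trial_index = integer(), value_mm = double())
}
empty_truth <- function() {
  tibble::tibble(participant_id = character(), pbf_true = double(),
                 db_true = double(), hv_true_l = double(),
                 hg_true_mm = double(), fg_true_mm = double(),
                 tlc_true_l = double(), rv_true_l = double(),
                 body_volume_l = double())
}
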