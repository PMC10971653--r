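#' Density of pure water at a given temperature
#'
#' Kell's (1975) polynomial for the density of air-free water at standard
#' pressure, in kg/L. Used to convert the in-water mass deficit to displaced
#' volume; weighing tanks run warm (31--34 C), where density is about
#' 0.994-0.995 kg/L rather than 1.
#'
#' @param temp_c Water temperature in Celsius, in (0, 40).
#' @return Water density in kg/L; monotonically decreasing above 4 C.
#' @examples
#' water_density(4)   # ~1.0000, the physical maximum
#' water_density(33)  # ~0.9947
#' @export
water_density <- function(temp_c) {
  if (any(!is.finite(temp_c)) || any(temp_c <= 0) || any(temp_c >= 40)) {
    abort("temp_c must lie in (0, 40) degrees Celsius")
  }
  t <- temp_c
  num <- 999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
    46.170461e-6 * t^3 + 105.56302e-9 * t^4 - 280.54253e-12 * t^5
  num / (1 + 16.879850e-3 * t) / 1000
}

#' Select the steadiest window of load-cell samples
#'
#' The acquisition software reports an in-water mass as the mean of roughly
#' one hundred consecutive load-cell samples chosen to best represent the
#' steady weight. This reproduces that choice: among all contiguous windows
#' of `target_n` plus or minus `slack` samples, the window with the smallest
#' within-window standard deviation wins; ties break to the longer window,
#' then the earlier start.
#'
#' @param samples Numeric vector of load-cell readings in kg, in time order.
#' @param target_n Target window length (default 100 samples).
#' @param slack Allowed deviation from `target_n` (default 2).
#' @return A list with `mean_kg`, `start`, `length` and `sd_kg`.
#' @export
select_sample_window <- function(samples, target_n = 100, slack = 2) {
  stopifnot(target_n >= 2, slack >= 0, slack < target_n)
  n <- length(samples)
  if (n < target_n - slack) {
    abort(paste0("sample stream has ", n, " readings; at least ",
                 target_n - slack, " are required"))
  }
  if (any(!is.finite(samples))) abort("samples must be finite")

  cs <- c(0, cumsum(samples))
  cs2 <- c(0, cumsum(samples^2))
  best <- NULL
  # longer windows first so that on sd ties the longer window is kept
  for (len in seq(min(target_n + slack, n), target_n - slack)) {
    starts <- seq_len(n - len + 1)
    s <- cs[starts + len] - cs[starts]
    s2 <- cs2[starts + len] - cs2[starts]
    v <- pmax((s2 - s^2 / len) / (len - 1), 0)
    i <- which.min(v)  # earliest start on ties
    cand <- list(mean_kg = s[i] / len, start = i, length = len,
                 sd_kg = sqrt(v[i]))
    # strict improvement only: ties keep the longer (earlier-seen) window
    if (is.null(best) || cand$sd_kg < best$sd_kg - 1e-15) best <- cand
  }
  best
}

#' Select consistent weighing trials
#'
#' A condition's in-water weight is the mean of three trials whose readings
#' agree within `tolerance_kg` (100 g under the protocol). All 3-subsets are
#' enumerated; among those with range (max - min) within tolerance, the
#' subset with the smallest range wins, ties breaking to the earliest index
#' triple in lexicographic order. When no triple qualifies, the same search
#' runs over pairs (quality `"pair"`); when no pair qualifies the condition
#' has no usable weight (quality `"none"`).
#'
#' @param weights Numeric vector of per-trial in-water masses in kg, in
#'   acquisition order. Negative values are permitted (buoyant
#'   participants).
#' @param tolerance_kg Agreement tolerance in kg (default 0.100).
#' @return A list with `indices` (into `weights`, or `NULL`), `mean_kg` (or
#'   `NA`) and `quality` (`"triple"`, `"pair"` or `"none"`).
#' @examples
#' select_consistent_trials(c(3.50, 3.62, 3.55, 3.58))
#' @export
select_consistent_trials <- function(weights, tolerance_kg = 0.100) {
  if (length(weights) < 1) abort("at least one trial weight is required")
  if (any(!is.finite(weights))) abort("trial weights must be finite")
  stopifnot(tolerance_kg > 0)

  for (k in c(3, 2)) {
    if (length(weights) < k) next
    sets <- combn(seq_along(weights), k)
    rng <- apply(sets, 2, function(i) max(weights[i]) - min(weights[i]))
    ok <- rng <= tolerance_kg
    if (any(ok)) {
      best <- which(ok)[which.min(rng[ok])]  # combn order is lexicographic
      idx <- sets[, best]
      return(list(indices = idx, mean_kg = mean(weights[idx]),
                  quality = if (k == 3) "triple" else "pair"))
    }
  }
  list(indices = NULL, mean_kg = NA_real_, quality = "none")
}

#' Body density from Archimedes' principle
#'
#' The volume of water displaced by the submerged body is the in-air /
#' in-water mass difference divided by water density. Body volume corrects
#' that for the gas spaces that are weighed but are not tissue: the lung
#' volume held during the trial, a 0.1 L gastrointestinal gas allowance,
#' and -- when the head stays above water -- the predicted head volume that
#' never displaced water is added back.
#'
#' For head-below-water (HBW) conditions:
#' `Db = MA / ((MA - MW) / DW - V_L - gi_gas)`.
#' For the head-above-water (HAW) condition:
#' `Db = MA / ((MA - MW) / DW + HV_pred - V_L - gi_gas)`.
#'
#' @param condition One of `"HAW_TLC"`, `"HBW_TLC"`, `"HBW_RV"`.
#' @param ma_kg Dry body mass in air, kg.
#' @param mw_kg Selected in-water mass, kg (may be negative); must be less
#'   than `ma_kg`.
#' @param dw_kg_l Water density, kg/L.
#' @param lung_volume_l Lung gas volume during the trial (TLC or RV), litres.
#' @param hv_pred_l Predicted head volume, litres. Required for the HAW
#'   condition and must be absent for HBW conditions.
#' @param gi_gas_l Gastrointestinal gas allowance, litres (default 0.1).
#' @return Body density in kg/L.
#' @examples
#' body_density("HBW_RV", ma_kg = 80, mw_kg = 3.0, dw_kg_l = 1.0000,
#'              lung_volume_l = 1.7)  # 80 / 75.2
#' @export
body_density <- function(condition, ma_kg, mw_kg, dw_kg_l, lung_volume_l,
                         hv_pred_l = NULL, gi_gas_l = 0.1) {
  check_condition(condition)
  stopifnot(length(condition) == 1)
  if (!is.finite(ma_kg) || ma_kg <= 0) abort("ma_kg must be positive")
  if (!is.finite(mw_kg) || mw_kg >= ma_kg) {
    abort("in-water mass must be finite and less than dry mass")
  }
  if (!is.finite(dw_kg_l) || dw_kg_l <= 0) abort("dw_kg_l must be positive")
  if (!is.finite(lung_volume_l) || lung_volume_l <= 0) {
    abort("lung_volume_l must be positive")
  }
  is_haw <- condition == "HAW_TLC"
  if (is_haw && is.null(hv_pred_l)) {
    abort("hv_pred_l is required for the head-above-water condition")
  }
  if (!is_haw && !is.null(hv_pred_l)) {
    abort("hv_pred_l must not be supplied for head-below-water conditions")
  }

  denom <- (ma_kg - mw_kg) / dw_kg_l - lung_volume_l - gi_gas_l
  if (is_haw) denom <- denom + hv_pred_l
  if (denom <= 0) {
    abort(paste0(
      "non-positive body volume (", format(denom), " L) for condition ",
      condition, ": displaced volume ", format((ma_kg - mw_kg) / dw_kg_l),
      " L does not exceed lung volume ", format(lung_volume_l),
      " L + GI gas ", format(gi_gas_l), " L",
      if (is_haw) paste0(" - head volume ", format(hv_pred_l), " L") else ""
    ))
  }
  ma_kg / denom
}

#' Percent body fat from body density (Brozek transform)
#'
#' `PBF = (4.570 / Db - 4.142) * 100`, strictly decreasing in density.
#'
#' @param db Body density in kg/L, positive.
#' @return Percent body fat (%).
#' @examples
#' percent_body_fat(1.0638298)
#' percent_body_fat(4.570 / 4.142)  # 0: the transform's root
#' @export
percent_body_fat <- function(db) {
  if (any(!is.finite(db)) || any(db <= 0)) abort("db must be positive")
  (BROZEK_A / db - BROZEK_B) * 100
}

#' Invert the Brozek transform
#'
#' @param pbf Percent body fat (%).
#' @return Body density in kg/L such that [percent_body_fat()] returns `pbf`.
#' @export
pbf_to_density <- function(pbf) {
  BROZEK_A / (pbf / 100 + BROZEK_B)
}

#' Compute body composition for one participant
#'
#' Chains the full per-participant pipeline: girth QC and head-volume
#' prediction, lung-volume prediction, consistent-trial selection, body
#' density and percent body fat, one output row per weighing condition with
#' a usable weight.
#'
#' @param participant A one-row data frame (or list) with `id`, `sex`,
#'   `age`, `height_cm`, `mass_kg` and optionally `water_temp_c`.
#' @param girths Girth measurement rows for this participant (see
#'   [qc_girths()] for the schema); may be empty, in which case the
#'   head-above-water condition cannot be computed.
#' @param trials Trial rows for this participant with columns `condition`,
#'   `trial_index`, `weight_kg`.
#' @param config An [hw_config()].
#' @return A tibble with one row per computable condition: `participant_id`,
#'   `condition`, `n_trials`, `quality`, `selected_mean_kg`, `hv_pred_l`,
#'   `lung_volume_l`, `db`, `pbf`. Conditions with no consistent trials
#'   (quality `"none"`) are omitted.
#' @export
compute_participant <- function(participant, girths, trials,
                                config = hw_config()) {
  p <- as.list(participant)
  for (f in c("id", "sex", "age", "height_cm", "mass_kg")) {
    if (is.null(p[[f]]) || is.na(p[[f]])) {
      abort(paste0("participant record is missing `", f, "`"))
    }
  }
  p$sex <- check_sex(p$sex)
  if (p$mass_kg <= 0) abort(paste0("participant ", p$id, ": non-positive dry mass"))

  temp <- p$water_temp_c %||% config$water_temp_c
  if (is.na(temp)) temp <- config$water_temp_c
  dw <- config$water_density_kg_l %||% water_density(temp)

  tlc <- predict_tlc(p$sex, p$height_cm / 100)
  rv <- predict_rv(p$sex, p$height_cm / 100, p$age)

  # head volume needs QC-passed girths at both sites
  hv_pred <- NA_real_
  if (nrow(girths) > 0) {
    qc <- qc_girths(girths, tolerance_mm = config$girth_tolerance_mm)
    hg <- qc$value_cm[qc$site == "HG" & qc$status == "ok"]
    fg <- qc$value_cm[qc$site == "FG" & qc$status == "ok"]
    if (length(hg) == 1 && length(fg) == 1) {
      hv_pred <- predict_head_volume(p$sex, hg, fg, p$mass_kg)
    }
  }

  check_columns(trials, c("condition", "trial_index", "weight_kg"), "trials")
  check_condition(trials$condition)

  conditions <- intersect(HW_CONDITIONS, unique(trials$condition))
  rows <- purrr::map(conditions, function(cond) {
    tr <- trials[trials$condition == cond, , drop = FALSE]
    tr <- tr[order(tr$trial_index), , drop = FALSE]
    cap <- condition_cap(cond, config)
    if (nrow(tr) > cap) {
      abort(paste0("participant ", p$id, ", condition ", cond, ": ",
                   nrow(tr), " trials exceed the cap of ", cap))
    }
    w <- tr$weight_kg
    if (cond != "HBW_RV" && config$belt_mass_kg > 0) {
      # net in-water weight of a non-tared belt worn during TLC trials
      w <- w - config$belt_mass_kg * (1 - dw / config$belt_density_kg_l)
    }
    sel <- select_consistent_trials(w, tolerance_kg = config$trial_tolerance_kg)
    if (sel$quality == "none") return(NULL)
    is_haw <- cond == "HAW_TLC"
    if (is_haw && is.na(hv_pred)) {
      abort(paste0("participant ", p$id,
                   ": head-above-water condition requires QC-passed head ",
                   "and face girths for head-volume prediction"))
    }
    vl <- if (cond == "HBW_RV") rv else tlc
    db <- body_density(cond, ma_kg = p$mass_kg, mw_kg = sel$mean_kg,
                       dw_kg_l = dw, lung_volume_l = vl,
                       hv_pred_l = if (is_haw) hv_pred else NULL,
                       gi_gas_l = config$gi_gas_l)
    tibble::tibble(
      participant_id = p$id, condition = cond, n_trials = nrow(tr),
      quality = sel$quality, selected_mean_kg = sel$mean_kg,
      hv_pred_l = if (is_haw) hv_pred else NA_real_,
      lung_volume_l = vl, db = db, pbf = percent_body_fat(db)
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    abort(paste0("participant ", p$id,
                 ": no condition produced a consistent weight"))
  }
  dplyr::bind_rows(rows)
}

#' Compute body composition for a whole cohort
#'
#' Applies [compute_participant()] across a participant table, recording
#' per-participant failures as diagnostics instead of aborting the run.
#'
#' @param participants Data frame with `id`, `sex`, `age`, `height_cm`,
#'   `mass_kg` and optionally `water_temp_c`.
#' @param girths Girth measurement table (see [qc_girths()]).
#' @param trials Trial table with `participant_id`, `condition`,
#'   `trial_index`, `weight_kg`.
#' @param config An [hw_config()].
#' @return A tibble of per-participant, per-condition results (the schema of
#'   [compute_participant()]), with a `diagnostics` attribute: a tibble of
#'   `participant_id`, `message` rows for participants or conditions that
#'   could not be computed.
#' @export
compute_cohort <- function(participants, girths, trials,
                           config = hw_config()) {
  check_columns(participants, c("id", "sex", "age", "height_cm", "mass_kg"),
                "participants")
  check_columns(girths, c("participant_id", "site", "trial_index", "value_mm"),
                "girths")
  check_columns(trials,
                c("participant_id", "condition", "trial_index", "weight_kg"),
                "trials")
  check_condition(trials$condition)

  diagnostics <- list()
  rows <- purrr::map(seq_len(nrow(participants)), function(i) {
    p <- participants[i, , drop = FALSE]
    g <- girths[girths$participant_id == p$id, , drop = FALSE]
    tr <- trials[trials$participant_id == p$id, , drop = FALSE]
    if (nrow(tr) == 0) {
      diagnostics[[length(diagnostics) + 1]] <<-
        tibble::tibble(participant_id = p$id, message = "no trials recorded")
      return(NULL)
    }
    tryCatch(
      compute_participant(p, g, tr, config),
      error = function(e) {
        diagnostics[[length(diagnostics) + 1]] <<-
          tibble::tibble(participant_id = p$id,
                         message = conditionMessage(e))
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      participant_id = character(), condition = character(),
      n_trials = integer(), quality = character(),
      selected_mean_kg = double(), hv_pred_l = double(),
      lung_volume_l = double(), db = double(), pbf = double()
    )
  }
  attr(out, "diagnostics") <- if (length(diagnostics) == 0) {
    tibble::tibble(participant_id = character(), message = character())
  } else {
    dplyr::bind_rows(diagnostics)
  }
  out
}
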