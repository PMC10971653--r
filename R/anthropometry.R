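#' Quality-control a series of repeated girth measurements
#'
#' Circumference measurements (head girth or face girth) are taken by two
#' technicians; a third is taken when the first two disagree by more than the
#' tolerance, and a fourth on the rare occasion no two agree. The value used
#' downstream is the mean of the closest pair of measurements that agree
#' within the tolerance.
#'
#' Among all pairs within tolerance, the pair with the smallest absolute
#' difference wins; ties break to the earliest pair in acquisition order.
#' With no qualifying pair the outcome is `"needs_measurement"` while fewer
#' than four measurements exist, and `"fail"` once four have been taken.
#'
#' @param measurements Numeric vector of 2--4 circumferences in millimetres,
#'   in acquisition order. All must be positive.
#' @param tolerance_mm Maximum absolute difference (mm) for a pair to qualify.
#'   Default 5 mm, the field protocol.
#' @return An object of class `hw_girth_qc`: a list with `measurements`,
#'   `status` (`"ok"`, `"needs_measurement"` or `"fail"`), `pair` (indices of
#'   the averaged measurements, or `NULL`), and `value_mm` (their mean, or
#'   `NA`).
#' @examples
#' qc_girth(c(583, 585))       # ok: mean 584
#' qc_girth(c(583, 590, 586))  # ok: closest pair is (1, 3)
#' qc_girth(c(560, 570, 580, 590))  # fail: no two within 5 mm
#' @export
qc_girth <- function(measurements, tolerance_mm = 5) {
  if (length(measurements) < 2) {
    abort("at least two girth measurements are required")
  }
  if (length(measurements) > 4) {
    abort("at most four girth measurements are taken under the protocol")
  }
  if (any(!is.finite(measurements)) || any(measurements <= 0)) {
    abort("girth measurements must be positive and finite")
  }
  stopifnot(is.numeric(tolerance_mm), tolerance_mm > 0)

  pairs <- combn(seq_along(measurements), 2)
  diffs <- abs(measurements[pairs[1, ]] - measurements[pairs[2, ]])
  ok <- diffs <= tolerance_mm

  if (!any(ok)) {
    status <- if (length(measurements) == 4) "fail" else "needs_measurement"
    out <- list(measurements = measurements, status = status,
                pair = NULL, value_mm = NA_real_)
  } else {
    # combn enumerates pairs in lexicographic acquisition order, so the first
    # minimum is the protocol tie-break
    best <- which(ok)[which.min(diffs[ok])]
    pair <- pairs[, best]
    out <- list(measurements = measurements, status = "ok",
                pair = pair, value_mm = mean(measurements[pair]))
  }
  structure(out, class = "hw_girth_qc")
}

#' @export
print.hw_girth_qc <- function(x, ...) {
  cat("<hw_girth_qc> status:", x$status, "\n")
  cat("  measurements (mm):", paste(x$measurements, collapse = ", "), "\n")
  if (x$status == "ok") {
    cat("  pair:", paste(x$pair, collapse = ","),
        " value:", x$value_mm, "mm\n")
  }
  invisible(x)
}

#' Quality-control all girth series in a measurement table
#'
#' Data-frame interface to [qc_girth()]: one row per measurement in, one row
#' per participant-by-site series out.
#'
#' @param girths Data frame with columns `participant_id`,
#'   `site` (`"HG"` head girth or `"FG"` face girth), `trial_index`
#'   (1-based acquisition order) and `value_mm`.
#' @inheritParams qc_girth
#' @return A tibble with `participant_id`, `site`, `n_measurements`,
#'   `status`, `value_mm` and `value_cm` (NA unless status is `"ok"`).
#' @export
qc_girths <- function(girths, tolerance_mm = 5) {
  check_columns(girths, c("participant_id", "site", "trial_index", "value_mm"),
                "girths")
  bad_site <- setdiff(unique(girths$site), c("HG", "FG"))
  if (length(bad_site) > 0) {
    abort(paste0("unknown girth site label(s): ",
                 paste(bad_site, collapse = ", ")))
  }
  girths |>
    dplyr::arrange(.data$participant_id, .data$site, .data$trial_index) |>
    dplyr::group_by(.data$participant_id, .data$site) |>
    dplyr::summarise(
      qc = list(qc_girth(.data$value_mm, tolerance_mm = tolerance_mm)),
      n_measurements = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      status = purrr::map_chr(.data$qc, "status"),
      value_mm = purrr::map_dbl(.data$qc, "value_mm"),
      value_cm = .data$value_mm / 10
    ) |>
    dplyr::select(-"qc")
}

# sex-specific head volume regression coefficients (girths in cm, mass in kg,
# output in litres): intercept, head girth, face girth, dry mass
HV_COEF <- list(
  male   = c(-5.7506, 0.1294, 0.0299, 0.0055),
  female = c(-7.3181, 0.1314, 0.0504, 0.0094)
)

#' Predict head volume from head girth, face girth and dry mass
#'
#' Sex-specific linear regression replacing head submersion when weighing
#' with the head above water. Inputs are the QC-averaged head girth (HG) and
#' face girth (FG) in centimetres and dry body mass in air (MA) in
#' kilograms; output is in litres. Adult head volumes are expected in
#' roughly 2--7 L; a warning is raised outside that range.
#'
#' @param sex `"male"` or `"female"` (recycled against the girth vectors).
#' @param hg_cm Head girth in cm.
#' @param fg_cm Face girth in cm.
#' @param ma_kg Dry body mass in air, kg.
#' @return Predicted head volume in litres (numeric vector).
#' @examples
#' predict_head_volume("male", hg_cm = 58.3, fg_cm = 67.7, ma_kg = 90.6)
#' @export
predict_head_volume <- function(sex, hg_cm, fg_cm, ma_kg) {
  sex <- check_sex(sex)
  n <- max(length(sex), length(hg_cm), length(fg_cm), length(ma_kg))
  sex <- rep_len(sex, n)
  hg_cm <- rep_len(hg_cm, n); fg_cm <- rep_len(fg_cm, n)
  ma_kg <- rep_len(ma_kg, n)
  if (any(!is.finite(hg_cm)) || any(hg_cm <= 0) ||
      any(!is.finite(fg_cm)) || any(fg_cm <= 0) ||
      any(!is.finite(ma_kg)) || any(ma_kg <= 0)) {
    abort("girths and dry mass must be positive and finite")
  }
  b <- do.call(rbind, HV_COEF[sex])
  hv <- b[, 1] + b[, 2] * hg_cm + b[, 3] * fg_cm + b[, 4] * ma_kg
  hv <- unname(hv)
  if (any(hv < 2 | hv > 7)) {
    warn("predicted head volume outside the typical adult range of 2-7 L")
  }
  hv
}

check_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  bad <- setdiff(unique(sex), c("male", "female"))
  if (length(bad) > 0) {
    abort(paste0("sex must be 'male' or 'female'; got: ",
                 paste(bad, collapse = ", ")))
  }
  sex
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) abort(paste0("`", what, "` must be a data frame"))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("`", what, "` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}
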