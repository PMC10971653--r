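# Quanjer-style reference equations for adult lung volumes, as used when no
# spirometer is available: sex-specific linear predictions in litres from
# standing height (m) and, for residual volume, age (years).
TLC_COEF <- list(male = c(-7.08, 7.99), female = c(-5.79, 6.60))
RV_COEF  <- list(male = c(-1.232, 1.31, 0.022), female = c(-2.003, 1.812, 0.016))

#' Predict total lung capacity from height
#'
#' @param sex `"male"` or `"female"`.
#' @param height_m Standing height in metres; must lie in (1, 2.5), the adult
#'   range the predictions were derived for.
#' @return Total lung capacity (TLC) in litres.
#' @examples
#' predict_tlc("male", 1.80)    # 7.302 L
#' predict_tlc("female", 1.687)
#' @export
predict_tlc <- function(sex, height_m) {
  sex <- check_sex(sex)
  check_height(height_m)
  b <- do.call(rbind, TLC_COEF[sex])
  unname(b[, 1] + b[, 2] * height_m)
}

#' Predict residual volume from height and age
#'
#' @inheritParams predict_tlc
#' @param age_yr Age in years, 18--100 (adult range).
#' @return Residual volume (RV) in litres.
#' @examples
#' predict_rv("male", 1.80, 25)  # 1.676 L
#' @export
predict_rv <- function(sex, height_m, age_yr) {
  sex <- check_sex(sex)
  check_height(height_m)
  if (any(!is.finite(age_yr)) || any(age_yr < 18) || any(age_yr > 100)) {
    abort("age_yr must lie in [18, 100]")
  }
  b <- do.call(rbind, RV_COEF[sex])
  unname(b[, 1] + b[, 2] * height_m + b[, 3] * age_yr)
}

check_height <- function(height_m) {
  if (any(!is.finite(height_m)) || any(height_m <= 1) || any(height_m >= 2.5)) {
    abort("height_m must lie in (1, 2.5) metres; heights arrive in cm at the I/O boundary and are converted with height_cm / 100")
  }
  invisible(height_m)
}

#' Add predicted lung volumes to a participant table
#'
#' Heights are supplied in centimetres (stadiometer convention) and converted
#' to metres internally; predictions warn if TLC does not exceed RV, which
#' does not occur over the adult input range.
#'
#' @param participants Data frame with columns `id`, `sex`, `age`,
#'   `height_cm`.
#' @return The input as a tibble with `tlc_l` and `rv_l` columns appended.
#' @export
predict_lung_volumes <- function(participants) {
  check_columns(participants, c("id", "sex", "age", "height_cm"),
                "participants")
  out <- participants |>
    tibble::as_tibble() |>
    dplyr::mutate(
      tlc_l = predict_tlc(.data$sex, .data$height_cm / 100),
      rv_l = predict_rv(.data$sex, .data$height_cm / 100, .data$age)
    )
  if (any(out$tlc_l <= out$rv_l)) {
    warn("predicted TLC does not exceed predicted RV for some participants")
  }
  out
}
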