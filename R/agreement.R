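#' Paired t-test on two matched series
#'
#' Classical paired t on `d = a - b`, testing whether the mean difference is
#' zero. When the differences have zero variance the statistic is degenerate:
#' the p-value is reported as 0 for a nonzero mean difference (the data are
#' incompatible with the null exactly) and 1 for identical series, with a
#' `degenerate` flag set.
#'
#' @param a,b Numeric vectors of equal length (n >= 2), pairwise complete.
#' @return A list with `t`, `df`, `p`, `mean_diff`, `sd_diff`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  check_paired(a, b, min_n = 2)
  d <- a - b
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    m <- mean(d)
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1,
                p = if (m == 0) 1 else 0,
                mean_diff = m, sd_diff = 0, degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), sd_diff = s, degenerate = FALSE)
}

#' Bland-Altman analysis of two matched series
#'
#' Differences `a - b` are summarised against pair means `(a + b) / 2`; the
#' limits of agreement are the mean difference plus or minus
#' `multiplier` standard deviations of the differences (n - 1 denominator).
#'
#' @inheritParams paired_t
#' @param multiplier Limits-of-agreement multiplier (default 1.96, the 95%
#'   limits).
#' @return A list with `points` (a tibble of `a`, `b`, `mean`, `diff`),
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b, multiplier = 1.96) {
  check_paired(a, b, min_n = 3)
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  s <- sd(d)
  list(points = tibble::tibble(a = a, b = b, mean = m, diff = d),
       mean_diff = md, sd_diff = s,
       loa_low = md - multiplier * s, loa_high = md + multiplier * s)
}

#' Test for proportional bias between two matched series
#'
#' Ordinary least squares of the pairwise difference on the pairwise mean
#' (the Bland-Altman regression); a slope significantly different from zero
#' indicates the disagreement between methods grows or shrinks with the
#' magnitude of the quantity measured.
#'
#' @inheritParams paired_t
#' @return A list with `slope`, `intercept` and `slope_p` (two-sided t-test
#'   on the slope).
#' @export
proportional_bias <- function(a, b) {
  check_paired(a, b, min_n = 3)
  d <- a - b
  m <- (a + b) / 2
  if (var(m) == 0) {
    abort("pair means are constant: proportional bias is not identifiable")
  }
  fit <- lm(d ~ m)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  p <- sm$coefficients[2, 4]
  if (!is.finite(p)) p <- if (abs(slope) > 0) 0 else 1  # perfect fit
  list(slope = slope, intercept = unname(coef(fit)[1]), slope_p = p)
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two series as the Pearson correlation
#' penalised for location and scale shift:
#' `rho_c = 2 * s_ab / (s_a^2 + s_b^2 + (mean(a) - mean(b))^2)`,
#' with biased (1/n) moment estimators, Lin's (1989) convention.
#'
#' @inheritParams paired_t
#' @return The concordance coefficient in `[-1, 1]`.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
lin_ccc <- function(a, b) {
  check_paired(a, b, min_n = 2)
  ma <- mean(a); mb <- mean(b)
  sa2 <- mean((a - ma)^2)
  sb2 <- mean((b - mb)^2)
  if (sa2 == 0 && sb2 == 0) {
    abort("both series are constant: concordance is undefined")
  }
  sab <- mean((a - ma) * (b - mb))
  2 * sab / (sa2 + sb2 + (ma - mb)^2)
}

#' Leave-one-out sensitivity of the proportional-bias test
#'
#' Recomputes the proportional-bias slope p-value with each pair left out in
#' turn, exposing results driven by a single influential participant (e.g.
#' a significance that disappears when one outlier is omitted).
#'
#' @inheritParams paired_t
#' @return Numeric vector of length `n`: the slope p-value with pair `i`
#'   omitted.
#' @export
loo_sensitivity <- function(a, b) {
  check_paired(a, b, min_n = 4)
  vapply(seq_along(a), function(i) {
    proportional_bias(a[-i], b[-i])$slope_p
  }, numeric(1))
}

#' Full agreement summary for one method pair
#'
#' Bundles the paired t-test, Bland-Altman limits of agreement,
#' proportional-bias regression and Lin's concordance coefficient for one
#' pair of matched measurement series.
#'
#' @inheritParams bland_altman
#' @param label Optional label for the comparison (e.g.
#'   `"HBW@TLC - HAW@TLC"`).
#' @return An object of class `hw_agreement` supporting [tidy()],
#'   [glance()] and `ggplot2::autoplot()`.
#' @export
agreement_stats <- function(a, b, label = NULL, multiplier = 1.96) {
  check_paired(a, b, min_n = 3)
  ba <- bland_altman(a, b, multiplier = multiplier)
  tt <- paired_t(a, b)
  pb <- proportional_bias(a, b)
  structure(
    list(label = label %||% "a - b", n = length(a),
         mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
         loa_low = ba$loa_low, loa_high = ba$loa_high,
         t_stat = tt$t, df = tt$df, p_paired = tt$p,
         slope = pb$slope, intercept = pb$intercept, slope_p = pb$slope_p,
         lccc = lin_ccc(a, b), points = ba$points,
         multiplier = multiplier),
    class = "hw_agreement"
  )
}

#' @export
print.hw_agreement <- function(x, ...) {
  cat("<hw_agreement>", x$label, " (n =", x$n, ")\n")
  cat(sprintf("  mean diff %.3f  [LoA %.3f, %.3f]  paired p = %.4g\n",
              x$mean_diff, x$loa_low, x$loa_high, x$p_paired))
  cat(sprintf("  proportional-bias slope %.4f (p = %.4g)  Lin's CCC %.4f\n",
              x$slope, x$slope_p, x$lccc))
  invisible(x)
}

#' Tidy an agreement summary
#'
#' @param x An `hw_agreement` object.
#' @param ... Unused.
#' @return A tibble with one row per statistic (`term`, `estimate`).
#' @export
tidy.hw_agreement <- function(x, ...) {
  tibble::tibble(
    term = c("mean_diff", "sd_diff", "loa_low", "loa_high", "t_stat",
             "p_paired", "slope", "slope_p", "lccc"),
    estimate = c(x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$t_stat,
                 x$p_paired, x$slope, x$slope_p, x$lccc)
  )
}

#' Glance at an agreement summary
#'
#' @param x An `hw_agreement` object.
#' @param ... Unused.
#' @return A one-row tibble of all agreement statistics.
#' @export
glance.hw_agreement <- function(x, ...) {
  tibble::tibble(
    label = x$label, n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, t_stat = x$t_stat,
    df = x$df, p_paired = x$p_paired, slope = x$slope,
    slope_p = x$slope_p, lccc = x$lccc
  )
}

#' Bland-Altman plot of an agreement summary
#'
#' @param object An `hw_agreement` object (or `hw_agreement_report` for the
#'   faceted variant).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hw_agreement <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (% body fat)",
                  y = "Difference (% body fat)",
                  title = object$label,
                  subtitle = sprintf(
                    "mean diff %.2f, LoA [%.2f, %.2f], Lin's CCC %.3f",
                    object$mean_diff, object$loa_low, object$loa_high,
                    object$lccc)) +
    ggplot2::theme_minimal()
}

# the three method comparisons, each difference oriented as a - b
HW_COMPARISONS <- tibble::tibble(
  comparison = c("HBW@TLC - HAW@TLC", "HBW@RV - HBW@TLC",
                 "HBW@RV - HAW@TLC"),
  a = c("HBW_TLC", "HBW_RV", "HBW_RV"),
  b = c("HAW_TLC", "HBW_TLC", "HAW_TLC")
)

#' Run the three-way method comparison
#'
#' Compares percent body fat between the three weighing conditions --
#' head position at total lung capacity (HBW\@TLC vs HAW\@TLC), lung volume
#' with the head submerged (HBW\@RV vs HBW\@TLC), and the combined change
#' (HBW\@RV vs HAW\@TLC) -- for the combined cohort and separately by
#' self-reported sex. Each comparison uses its pairwise-complete
#' participants; a participant missing one condition still contributes to
#' the comparisons not involving it.
#'
#' @param results Per-participant, per-condition results as returned by
#'   [compute_cohort()] (columns `participant_id`, `condition`, `quality`,
#'   `pbf`; a `sex` column is used if present).
#' @param participants Optional participant table with `id` and `sex`, used
#'   to stratify when `results` carries no `sex` column.
#' @param strict If `TRUE`, rows whose weight came from only two consistent
#'   trials (quality `"pair"`) are excluded before pairing.
#' @param multiplier Limits-of-agreement multiplier (default 1.96).
#' @return A tibble of class `hw_agreement_report`: one row per comparison
#'   and stratum (combined, male, female) with n, mean difference, SD,
#'   limits of agreement, paired t statistics, proportional-bias slope and
#'   p, and Lin's CCC. Strata with fewer than 3 complete pairs are skipped
#'   with a warning. Bland-Altman points are attached as the `points`
#'   attribute.
#' @export
run_comparisons <- function(results, participants = NULL, strict = FALSE,
                            multiplier = 1.96) {
  check_columns(results, c("participant_id", "condition", "pbf"), "results")
  check_condition(results$condition)
  if (!"sex" %in% names(results)) {
    if (is.null(participants)) {
      abort("supply `participants` (id, sex) or a `sex` column in `results`")
    }
    check_columns(participants, c("id", "sex"), "participants")
    results <- dplyr::left_join(
      results, dplyr::select(participants, participant_id = "id", "sex"),
      by = "participant_id")
  }
  results$sex <- check_sex(results$sex)
  if (strict && "quality" %in% names(results)) {
    results <- results[results$quality != "pair", , drop = FALSE]
  }

  wide <- results |>
    dplyr::select("participant_id", "sex", "condition", "pbf") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "pbf") |>
    dplyr::arrange(.data$participant_id)  # stable under input row order
  for (cond in HW_CONDITIONS) {
    if (!cond %in% names(wide)) wide[[cond]] <- NA_real_
  }

  grid <- tidyr::expand_grid(
    HW_COMPARISONS, stratum = c("combined", "male", "female"))
  rows <- purrr::pmap(grid, function(comparison, a, b, stratum) {
    dat <- wide
    if (stratum != "combined") dat <- dat[dat$sex == stratum, , drop = FALSE]
    dat <- dat[stats::complete.cases(dat[, c(a, b)]), , drop = FALSE]
    if (nrow(dat) < 3) {
      warn(paste0("stratum '", stratum, "' of comparison '", comparison,
                  "' has fewer than 3 complete pairs; skipped"))
      return(NULL)
    }
    pa <- dat[[a]]
    pb <- dat[[b]]
    ag <- agreement_stats(pa, pb, label = comparison,
                          multiplier = multiplier)
    pts <- tibble::tibble(comparison = comparison, stratum = stratum,
                          participant_id = dat$participant_id,
                          sex = dat$sex, a = pa, b = pb,
                          mean = (pa + pb) / 2, diff = pa - pb)
    list(summary = dplyr::mutate(glance(ag), comparison = comparison,
                                 stratum = stratum, .before = 1,
                                 .keep = "all") |>
           dplyr::select(-"label"),
         points = pts)
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) abort("no comparison stratum had 3 complete pairs")
  report <- dplyr::bind_rows(purrr::map(rows, "summary"))
  attr(report, "points") <- dplyr::bind_rows(purrr::map(rows, "points"))
  class(report) <- c("hw_agreement_report", class(report))
  report
}

#' @rdname autoplot.hw_agreement
#' @exportS3Method ggplot2::autoplot
autoplot.hw_agreement_report <- function(object, ...) {
  pts <- attr(object, "points")
  lines <- object |>
    dplyr::select("comparison", "stratum", "mean_diff", "loa_low",
                  "loa_high") |>
    tidyr::pivot_longer(c("mean_diff", "loa_low", "loa_high"),
                        names_to = "line", values_to = "y")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(colour = "steelblue", size = 0.8) +
    ggplot2::geom_hline(
      data = lines,
      ggplot2::aes(yintercept = .data$y,
                   linetype = .data$line == "mean_diff")) +
    ggplot2::facet_grid(stratum ~ comparison) +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "Mean of methods (% body fat)",
                  y = "Difference (% body fat)") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.hw_agreement
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname glance.hw_agreement
#' @export
glance <- function(x, ...) UseMethod("glance")

check_paired <- function(a, b, min_n) {
  if (length(a) != length(b)) abort("a and b must have equal length")
  if (length(a) < min_n) {
    abort(paste0("at least ", min_n, " pairs are required"))
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("paired series must be complete and finite")
  }
  invisible(NULL)
}
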