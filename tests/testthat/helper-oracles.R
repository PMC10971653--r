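# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package.

# exhaustive pair search for the girth QC rule
oracle_girth_pair <- function(m, tol = 5) {
  best <- NULL
  best_diff <- Inf
  for (i in seq_along(m)) {
    for (j in seq_along(m)) {
      if (i < j) {
        d <- abs(m[i] - m[j])
        if (d <= tol && d < best_diff) {
          best <- c(i, j)
          best_diff <- d
        }
      }
    }
  }
  best
}

# exhaustive k-subset search for trial consistency
oracle_trial_subset <- function(w, k, tol = 0.100) {
  best <- NULL
  best_range <- Inf
  idx <- utils::combn(seq_along(w), k)
  for (c in seq_len(ncol(idx))) {
    i <- idx[, c]
    r <- max(w[i]) - min(w[i])
    if (r <= tol && r < best_range) {
      best <- i
      best_range <- r
    }
  }
  best
}

# Lin's concordance coefficient written out from its definition with
# explicit 1/n sums
oracle_lin_ccc <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sab <- sum((a - ma) * (b - mb)) / n
  sa2 <- sum((a - ma)^2) / n
  sb2 <- sum((b - mb)^2) / n
  2 * sab / (sa2 + sb2 + (ma - mb)^2)
}

# hand-built, internally consistent weighing inputs for one participant:
# trials are simulated from a known density by Archimedes' principle
manual_participant <- function(id = "T01", sex = "male", age = 25,
                               height_cm = 180, mass_kg = 80,
                               pbf_true = 20, water_temp_c = 32.5,
                               hg_mm = 583, fg_mm = 677) {
  db <- 4.570 / (pbf_true / 100 + 4.142)
  vb <- mass_kg / db
  dw <- water_density(water_temp_c)
  tlc <- predict_tlc(sex, height_cm / 100)
  rv <- predict_rv(sex, height_cm / 100, age)
  hv <- predict_head_volume(sex, hg_mm / 10, fg_mm / 10, mass_kg)
  mw <- c(HAW_TLC = mass_kg - dw * (vb - hv + tlc + 0.1),
          HBW_TLC = mass_kg - dw * (vb + tlc + 0.1),
          HBW_RV = mass_kg - dw * (vb + rv + 0.1))
  list(
    participant = tibble::tibble(id = id, sex = sex, age = age,
                                 height_cm = height_cm, mass_kg = mass_kg,
                                 water_temp_c = water_temp_c),
    girths = tibble::tibble(
      participant_id = id, site = rep(c("HG", "FG"), each = 2),
      trial_index = rep(1:2, 2), value_mm = c(hg_mm, hg_mm, fg_mm, fg_mm)),
    trials = tibble::tibble(
      participant_id = id, condition = rep(names(mw), each = 3),
      trial_index = rep(1:3, 3), weight_kg = rep(unname(mw), each = 3)),
    truth = list(db = db, pbf = pbf_true, hv = hv, tlc = tlc, rv = rv,
                 mw = mw, dw = dw)
  )
}
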