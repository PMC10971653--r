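test_that("water density matches published values and decreases with warmth", {
  expect_equal(water_density(4), 1.0000, tolerance = 1e-4)
  d33 <- water_density(33)
  expect_gt(d33, 0.9940)
  expect_lt(d33, 0.9950)
  expect_gt(water_density(31), water_density(34))
  # monotone over the whole warm range
  t <- seq(4, 39.5, by = 0.5)
  expect_true(all(diff(water_density(t)) < 0))
  expect_error(water_density(-1), "temp")
  expect_error(water_density(45), "temp")
})

test_that("sample window selection finds the steadiest stretch", {
  # constant stream: any window works, mean is exact
  r <- select_sample_window(rep(3.5, 150))
  expect_equal(r$mean_kg, 3.5)
  expect_equal(r$sd_kg, 0)

  # steady first 100 samples, then oscillation: the window stays inside
  # the steady stretch (verified by brute force over all windows)
  stream <- c(rep(3.5, 100), rep(c(3.3, 3.7), 25))
  r <- select_sample_window(stream)
  expect_lte(r$start + r$length - 1, 100)
  expect_equal(r$mean_kg, 3.5)

  expect_error(select_sample_window(rep(3.5, 97)), "at least 98")
})

test_that("sample window selection matches brute force on noisy streams", {
  withr::with_seed(21, {
    for (i in 1:10) {
      stream <- 3.5 + cumsum(rnorm(120, 0, 0.02))
      got <- select_sample_window(stream)
      # brute force over every admissible window
      best <- NULL
      for (len in 98:102) {
        for (s in seq_len(length(stream) - len + 1)) {
          w <- stream[s:(s + len - 1)]
          cand <- list(sd = sd(w), start = s, len = len, mean = mean(w))
          if (is.null(best) || cand$sd < best$sd ||
              (cand$sd == best$sd &&
               (cand$len > best$len ||
                (cand$len == best$len && cand$start < best$start)))) {
            best <- cand
          }
        }
      }
      expect_equal(got$mean_kg, best$mean)
      expect_equal(got$start, best$start)
      expect_equal(got$length, best$len)
    }
  })
})

test_that("trial selection picks the tightest consistent triple, then pair", {
  r <- select_consistent_trials(c(3.50, 3.62, 3.55, 3.58))
  expect_equal(r$indices, c(2L, 3L, 4L))
  expect_equal(r$mean_kg, mean(c(3.62, 3.55, 3.58)))
  expect_equal(r$quality, "triple")

  r <- select_consistent_trials(c(3.5, 3.5, 3.5))
  expect_equal(r$mean_kg, 3.5)
  expect_equal(r$quality, "triple")

  # no triple but a pair within 100 g
  r <- select_consistent_trials(c(3.0, 3.40, 3.45))
  expect_equal(r$quality, "pair")
  expect_equal(r$indices, c(2L, 3L))
  expect_equal(r$mean_kg, 3.425)

  # nothing consistent at all
  r <- select_consistent_trials(c(3.0, 3.2, 3.4))
  expect_equal(r$quality, "none")
  expect_true(is.na(r$mean_kg))

  expect_error(select_consistent_trials(numeric(0)), "at least one")
})

test_that("trial selection agrees with exhaustive enumeration on a grid", {
  grid <- c(3.00, 3.06, 3.13, 3.21)
  withr::with_seed(31, {
    for (len in 1:7) {
      # all sequences for short lengths; sampled sequences for longer ones
      seqs <- if (len <= 4) {
        as.matrix(expand.grid(rep(list(grid), len)))
      } else {
        matrix(sample(grid, 200 * len, replace = TRUE), ncol = len)
      }
      for (r in seq_len(nrow(seqs))) {
        w <- seqs[r, ]
        got <- select_consistent_trials(w)
        want3 <- if (len >= 3) oracle_trial_subset(w, 3) else NULL
        want2 <- if (len >= 2) oracle_trial_subset(w, 2) else NULL
        if (!is.null(want3)) {
          expect_equal(got$quality, "triple")
          expect_equal(got$mean_kg, mean(w[want3]))
        } else if (!is.null(want2)) {
          expect_equal(got$quality, "pair")
          expect_equal(got$mean_kg, mean(w[want2]))
        } else if (len == 1) {
          expect_equal(got$quality, "none")
        } else {
          expect_equal(got$quality, "none")
        }
      }
    }
  })
})

test_that("body density matches the hand-computed substitution", {
  expect_equal(body_density("HBW_RV", ma_kg = 80, mw_kg = 3.0,
                            dw_kg_l = 1.0000, lung_volume_l = 1.7),
               80 / 75.2, tolerance = 1e-12)
})

test_that("head-above and head-below densities agree when they should", {
  # if the head-above in-water mass differs from the submerged one exactly
  # by the buoyancy of the head, the two expressions must cancel
  ma <- 85; dw <- 0.9947; vl <- 6.2; hv <- 4.3; mw_hbw <- 1.2
  mw_haw <- mw_hbw + dw * hv
  expect_equal(
    body_density("HAW_TLC", ma, mw_haw, dw, vl, hv_pred_l = hv),
    body_density("HBW_TLC", ma, mw_hbw, dw, vl),
    tolerance = 1e-12)
})

test_that("body density enforces its input contract", {
  expect_error(body_density("HBW_RV", 80, 3, 1, 1.7, hv_pred_l = 4.3),
               "must not be supplied")
  expect_error(body_density("HAW_TLC", 80, 3, 1, 6), "required")
  expect_error(body_density("HBW_RV", 80, 81, 1, 1.7), "less than dry mass")
  expect_error(body_density("SITTING", 80, 3, 1, 1.7), "condition")
  # boundary: displaced volume swallowed by gas volumes
  expect_error(body_density("HAW_TLC", 80, 79.99, 1, 6, hv_pred_l = 4.3),
               "non-positive body volume")
})

test_that("percent body fat is the Brozek transform and inverts exactly", {
  expect_equal(percent_body_fat(4.570 / 4.142), 0, tolerance = 1e-9)
  expect_equal(percent_body_fat(80 / 75.2), 15.380, tolerance = 1e-9)
  expect_equal(percent_body_fat(1.000), 42.800, tolerance = 1e-9)
  expect_error(percent_body_fat(0), "positive")

  # round trip with the inverse over a density grid
  db <- seq(0.98, 1.12, by = 0.001)
  expect_equal(pbf_to_density(percent_body_fat(db)), db, tolerance = 1e-12)
})

test_that("density is recovered from simulated weights (Archimedes inverse)", {
  withr::with_seed(41, {
    for (i in 1:100) {
      db_true <- runif(1, 0.99, 1.10)
      ma <- runif(1, 45, 130)
      vl <- runif(1, 1.2, 8)
      hv <- runif(1, 2.5, 6)
      dw <- runif(1, 0.992, 1.000)
      vb <- ma / db_true
      mw_hbw <- ma - dw * (vb + vl + 0.1)
      mw_haw <- ma - dw * (vb - hv + vl + 0.1)
      expect_equal(body_density("HBW_TLC", ma, mw_hbw, dw, vl), db_true,
                   tolerance = 1e-9)
      expect_equal(body_density("HAW_TLC", ma, mw_haw, dw, vl,
                                hv_pred_l = hv), db_true, tolerance = 1e-9)
    }
  })
})

test_that("density rises with in-water mass and falls with lung volume", {
  mw <- seq(0, 4, by = 0.25)
  db <- vapply(mw, function(m) body_density("HBW_RV", 80, m, 0.995, 1.7),
               numeric(1))
  expect_true(all(diff(db) > 0))
  expect_true(all(diff(percent_body_fat(db)) < 0))

  vl <- seq(1.2, 7, by = 0.25)
  db <- vapply(vl, function(v) body_density("HBW_TLC", 80, 1, 0.995, v),
               numeric(1))
  expect_true(all(diff(db) > 0))  # less assumed gas => denser body
})

test_that("compute_participant reproduces a hand-built consistent chain", {
  fix <- manual_participant()
  out <- compute_participant(fix$participant, fix$girths, fix$trials)
  expect_equal(nrow(out), 3)
  expect_setequal(out$condition, c("HAW_TLC", "HBW_TLC", "HBW_RV"))
  expect_equal(out$quality, rep("triple", 3))
  expect_equal(out$pbf, rep(fix$truth$pbf, 3), tolerance = 1e-9)
  expect_equal(out$hv_pred_l[out$condition == "HAW_TLC"], fix$truth$hv)
  expect_equal(out$lung_volume_l[out$condition == "HBW_RV"], fix$truth$rv)
})

test_that("compute_participant omits conditions without consistent trials", {
  fix <- manual_participant()
  # scatter the residual-volume trials beyond any 100 g agreement
  fix$trials$weight_kg[fix$trials$condition == "HBW_RV"] <-
    fix$trials$weight_kg[fix$trials$condition == "HBW_RV"] + c(0, 0.4, 0.8)
  out <- compute_participant(fix$participant, fix$girths, fix$trials)
  expect_setequal(out$condition, c("HAW_TLC", "HBW_TLC"))
})

test_that("compute_participant enforces trial caps and girth prerequisites", {
  fix <- manual_participant()
  extra <- fix$trials[fix$trials$condition == "HBW_RV", ][1:3, ]
  extra$trial_index <- 4:6
  expect_error(
    compute_participant(fix$participant, fix$girths,
                        rbind(fix$trials, extra)),
    "exceed the cap")
  # unusable girths block only the head-above-water condition
  bad_girths <- fix$girths
  bad_girths$value_mm <- c(560, 570, 650, 680)
  expect_error(
    compute_participant(fix$participant, bad_girths, fix$trials),
    "head-above-water")
  out <- compute_participant(
    fix$participant, bad_girths,
    fix$trials[fix$trials$condition != "HAW_TLC", ])
  expect_setequal(out$condition, c("HBW_TLC", "HBW_RV"))
})

test_that("compute_cohort records failures as diagnostics and continues", {
  fix1 <- manual_participant("A")
  fix2 <- manual_participant("B", sex = "female", height_cm = 168.7,
                             mass_kg = 68.5, age = 23, pbf_true = 28,
                             hg_mm = 562, fg_mm = 630)
  participants <- rbind(fix1$participant, fix2$participant)
  girths <- rbind(fix1$girths, fix2$girths)
  # break participant B's trials entirely
  fix2$trials$weight_kg <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  trials <- rbind(fix1$trials, fix2$trials)
  res <- compute_cohort(participants, girths, trials)
  expect_equal(sort(unique(res$participant_id)), "A")
  diag <- attr(res, "diagnostics")
  expect_equal(diag$participant_id, "B")
  expect_match(diag$message, "no condition")
})

test_that("a non-tared belt correction shifts TLC conditions only", {
  fix <- manual_participant()
  cfg <- hw_config(belt_mass_kg = 2.1, belt_density_kg_l = 7.8)
  base <- compute_participant(fix$participant, fix$girths, fix$trials)
  corr <- compute_participant(fix$participant, fix$girths, fix$trials, cfg)
  expect_equal(corr$db[corr$condition == "HBW_RV"],
               base$db[base$condition == "HBW_RV"])
  # belt buoyancy-corrected weight is lower, so density drops at TLC
  expect_lt(corr$db[corr$condition == "HBW_TLC"],
            base$db[base$condition == "HBW_TLC"])
})
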