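test_that("indirect and direct calorimetry conversions are correct", {
  # zero oxygen extraction, zero flux, zero signal all give zero watts
  expect_equal(heat_production(0.21, 0.21, 1.5), 0)
  expect_equal(evaporative_heat_loss(0), 0)
  expect_equal(dry_heat_loss(0), 0)

  # hand-checked unit conversion: RQ 1, VO2 = 1 L/min
  expect_equal(heat_production(1, 0, 1, rq = 1), (3.815 + 1.232) * 4184 / 60)
  # 10 mg/min at 2.41 J/mg
  expect_equal(evaporative_heat_loss(10, 2.41), 10 * 2.41 / 60)

  # monotone in the O2 deficit; linear in flux; proportional to signal
  o2d <- seq(0, 0.02, by = 0.002)
  expect_true(all(diff(heat_production(0.21, 0.21 - o2d, 1.5)) > 0))
  expect_equal(evaporative_heat_loss(3) + evaporative_heat_loss(4),
               evaporative_heat_loss(7))
  expect_equal(dry_heat_loss(4, 0.2), 2 * dry_heat_loss(2, 0.2))

  expect_error(heat_production(0.20, 0.21, 1.5), "inversion")
  expect_error(evaporative_heat_loss(-1), "condensation")
  expect_error(heat_production(0.2, 0.19, 1.5, rq = 0.5), "rq")
})

test_that("6-min binning matches a brute-force windowed mean", {
  cfg <- test_config()
  rat <- list(mass_g = 150, baseline_tc = 37.2, hp_response_gain = 0.2,
              hl_drug_effect = 0.35)
  ses <- simulate_thermal_session(rat, cfg, seed = 5)
  prof <- bin_profile(ses)
  expect_equal(nrow(prof), 17)                    # 102 min / 6 min
  # Tc bins hold 24 of the 15-s samples
  expect_equal(sum(ses$tc$time_s >= 0 & ses$tc$time_s < 360), 24)
  expect_equal(prof$tc, oracle_bin_means(ses$tc$tc, ses$tc$time_s, 360)[1:17])
  hp <- heat_production(ses$signals$o2_in, ses$signals$o2_out, ses$flow_lpm,
                        cfg$rq)
  expect_equal(prof$hp, oracle_bin_means(hp, ses$signals$time_s, 360))
  # constant channels bin to the constant
  ses2 <- ses
  ses2$signals$gradient_mv <- 3
  expect_equal(bin_profile(ses2)$dhl,
               rep(dry_heat_loss(3, cfg$gradient_calibration), 17))
  # the first two N2O bins carry the HP artifact flag
  n2o_bins <- which(prof$phase == "n2o")
  expect_equal(which(prof$hp_artifact), n2o_bins[1:2])
})

test_that("baseline deltas are zero for a flat profile and track steps", {
  cfg <- test_config(hp_onset_lag_s = 0)
  rat <- list(mass_g = 150, baseline_tc = 37.2, hp_response_gain = 0.35,
              hl_drug_effect = 0.35)
  ses <- simulate_thermal_session(rat, cfg, noise = FALSE)
  d <- delta_from_baseline(bin_profile(ses))
  expect_equal(d$bins$dtc, rep(0, nrow(d$bins)))
  expect_equal(d$summary$dtc, rep(0, 3))

  # a pure step in Tc appears as that step in every N2O bin
  prof <- bin_profile(ses)
  prof$tc[prof$phase == "n2o"] <- prof$tc[prof$phase == "n2o"] - 2
  d2 <- delta_from_baseline(prof)
  expect_equal(d2$bins$dtc[prof$phase == "n2o"],
               rep(-2, sum(prof$phase == "n2o")))
  expect_equal(d2$tc_nadir, -2)
})

test_that("hourly HP deltas exclude the artifact window", {
  cfg <- test_config(hp_onset_lag_s = 0)
  rat <- list(mass_g = 150, baseline_tc = 37.2, hp_response_gain = 0.3,
              hl_drug_effect = 0.3)
  ses <- simulate_thermal_session(rat, cfg, noise = FALSE)
  prof <- bin_profile(ses)
  # corrupt the artifact bins; the hourly mean must not see them
  prof$hp[prof$hp_artifact] <- 100
  h <- hp_hourly_deltas(prof)
  expect_equal(length(h), 1L)                    # one full N2O hour
  expect_equal(h, 0.3, tolerance = 1e-10)
})

test_that("hp_increase_counts tabulates groups correctly", {
  hd <- data.frame(rat_id = letters[1:6], group = rep(c("II", "IS"), each = 3),
                   h1 = c(1, 2, 3, 1, 2, 3), h2 = c(1, -1, 1, -1, -1, -1),
                   h3 = rep(-1, 6))
  expect_equal(unname(hp_increase_counts(hd, 1)),
               matrix(c(3L, 3L, 0L, 0L), 2))
  expect_equal(unname(hp_increase_counts(hd, 2)),
               matrix(c(2L, 0L, 1L, 3L), 2))
  expect_equal(unname(hp_increase_counts(hd, 3)),
               matrix(c(0L, 0L, 3L, 3L), 2))
})

test_that("z-score screening selects squad extremes deterministically", {
  s <- data.frame(rat_id = sprintf("r%02d", 1:8), squad_id = 1,
                  sensitivity = c(-3, -2.5, -1, -0.5, 0, 0.2, 0.4, 0.6))
  out <- zscore_select(s)
  expect_equal(out$selected_group,
               c("IS", "IS", rep("none", 4), "II", "II"))
  expect_equal(mean(out$z), 0)
  expect_equal(sd(out$z), 1)

  # symmetric summaries give antisymmetric z-scores
  sym <- data.frame(rat_id = sprintf("r%02d", 1:6), squad_id = 1,
                    sensitivity = c(-3, -2, -1, 1, 2, 3))
  expect_equal(zscore_select(sym)$z, -rev(zscore_select(sym)$z))

  # affine rescaling leaves z and the selection unchanged
  resc <- s
  resc$sensitivity <- 5 * s$sensitivity + 2
  expect_equal(zscore_select(resc)$z, out$z)
  expect_equal(zscore_select(resc)$selected_group, out$selected_group)

  expect_error(zscore_select(s[1:3, ]), "smaller")
  s0 <- s
  s0$sensitivity <- 1
  expect_error(zscore_select(s0), "variance")
})

test_that("screening recovers planted extremes from simulated squads", {
  # full-length phases: the 3-h exposure expresses most of the steady-state
  # Tc drop, and the drug's heat-loss effect is held at its consistent
  # population value so the HP response is the only phenotype determinant
  cfg <- cohort_config()
  set.seed(314)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    rats <- simulate_cohort(cohort_config(n_squads = 1L, rats_per_squad = 8L),
                            "screen")
    # plant 2 strong and 2 absent responders among the 8
    rats$hp_response_gain <- c(0.35, 0.36, rep(0.18, 4), 0.0, 0.01)
    rats$hl_drug_effect <- 0.35
    sens <- vapply(seq_len(nrow(rats)), function(i) {
      ses <- simulate_thermal_session(rats[i, ], cfg)
      d <- delta_from_baseline(suppressWarnings(bin_profile(ses)))
      d$summary$dtc[d$summary$phase == "n2o"]
    }, numeric(1))
    sel <- zscore_select(data.frame(rat_id = rats$rat_id, squad_id = 1,
                                    sensitivity = sens))
    ok_ii <- all(sel$selected_group[1:2] == "II")
    ok_is <- all(sel$selected_group[7:8] == "IS")
    hits <- hits + (ok_ii && ok_is)
  }
  expect_gte(hits / n_rep, 0.95)
})
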