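#' Cohort configuration
#'
#' Bundles every tunable parameter of the synthetic study: squad structure,
#' session/phase timing, the planted behavioural effects on the log
#' preference-ratio scale, and the physical constants used by the thermal
#' simulator and the calorimetric conversions.
#'
#' Timing defaults mirror the screening protocol (2-h control-air baseline,
#' 3 h of 60% N2O, 45-min recovery) and the self-administration schedule
#' (22-h daily access, eight 44-h dyads).  The planted group contrast
#' defaults to `log(3.68)`, the fold difference in mean N2O preference ratio
#' between initially insensitive (II) and initially sensitive (IS) rats that
#' the screening design is meant to expose.
#'
#' @param n_squads number of screening squads.
#' @param rats_per_squad rats screened per squad.
#' @param session_length_h length of one self-administration session (hours).
#' @param n_dyads number of 2-session dyads.
#' @param phase_baseline_min,phase_n2o_min,phase_recovery_min calorimetry
#'   phase lengths in minutes.
#' @param baseline_logratio mean log(N2O/control time) for IS rats at dyad 0.
#' @param group_effect_logratio planted II minus IS difference in mean log
#'   preference ratio.
#' @param dyad_slope common per-dyad drift of the mean log preference ratio.
#' @param within_rat_sd,between_rat_sd residual and rat-intercept standard
#'   deviations of the log preference ratio.
#' @param control_central_logratio,control_central_sd mean and SD of
#'   log(control/central time), fixing where the composition sits on the
#'   simplex.
#' @param hp_onset_lag_s lag (s) before the heat-production response engages
#'   after N2O onset.
#' @param evap_fraction fraction of the drug's heat-loss effect routed to the
#'   evaporative channel (remainder is dry).
#' @param thermal_feedback_w_per_c net heat-loss feedback (W/degC) on core
#'   temperature deviations from baseline.
#' @param c_body specific heat of body tissue (J/g/degC).
#' @param basal_hp_coef basal metabolic rate coefficient, W per kg^0.75.
#' @param rq respiratory quotient assumed for indirect calorimetry.
#' @param latent_heat latent heat of vaporisation (J/mg).
#' @param gradient_calibration gradient-layer calibration (W/mV).
#' @param flow_lpm chamber gas flow (L/min).
#' @param o2_in incurrent fractional O2 concentration.
#' @param ambient_c ambient temperature (degC).
#' @param tc_noise_sd,hp_noise_sd,dhl_noise_sd,ehl_noise_sd additive Gaussian
#'   measurement noise (degC for Tc, W-equivalent for the power channels).
#' @param zero_floor seconds substituted for zero compartment times
#'   downstream (half the 10-s detection limit).
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_squads = 8L,
                          rats_per_squad = 24L,
                          session_length_h = 22,
                          n_dyads = 8L,
                          phase_baseline_min = 120,
                          phase_n2o_min = 180,
                          phase_recovery_min = 45,
                          baseline_logratio = log(0.5),
                          group_effect_logratio = log(3.68),
                          dyad_slope = 0.08,
                          within_rat_sd = 0.5,
                          between_rat_sd = 0.5,
                          control_central_logratio = log(0.25),
                          control_central_sd = 0.3,
                          hp_onset_lag_s = 600,
                          evap_fraction = 0.6,
                          thermal_feedback_w_per_c = 0.1,
                          c_body = 3.47,
                          basal_hp_coef = 4.2,
                          rq = 0.85,
                          latent_heat = 2.41,
                          gradient_calibration = 0.2,
                          flow_lpm = 1.5,
                          o2_in = 0.2095,
                          ambient_c = 22,
                          tc_noise_sd = 0.02,
                          hp_noise_sd = 0.02,
                          dhl_noise_sd = 0.01,
                          ehl_noise_sd = 0.005,
                          zero_floor = 5) {
  cfg <- as.list(environment())
  counts <- c("n_squads", "rats_per_squad", "n_dyads")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop(sprintf("'%s' must be a single integer >= 1", nm), call. = FALSE)
    cfg[[nm]] <- as.integer(v)
  }
  durations <- c("session_length_h", "phase_baseline_min", "phase_n2o_min",
                 "phase_recovery_min")
  for (nm in durations) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive duration", nm),
           call. = FALSE)
  }
  numerics <- setdiff(names(cfg), c(counts, durations))
  for (nm in numerics) {
    if (length(cfg[[nm]]) != 1L || !is.finite(cfg[[nm]]))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (cfg$evap_fraction < 0 || cfg$evap_fraction > 1)
    stop("'evap_fraction' must lie in [0, 1]", call. = FALSE)
  if (cfg$rq < 0.7 || cfg$rq > 1.0)
    stop("'rq' must lie in [0.7, 1.0]", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  squads: %d x %d rats, %d dyads of 2 x %g-h sessions\n",
              x$n_squads, x$rats_per_squad, x$n_dyads, x$session_length_h))
  cat(sprintf("  calorimetry phases (min): baseline %g / n2o %g / recovery %g\n",
              x$phase_baseline_min, x$phase_n2o_min, x$phase_recovery_min))
  cat(sprintf("  planted group effect: log fold %.4f (fold %.2f)\n",
              x$group_effect_logratio, exp(x$group_effect_logratio)))
  invisible(x)
}

#' Session and dyad totals implied by a configuration
#'
#' @param config a [cohort_config()].
#' @return list with `session_s` (one 22-h session, seconds) and `dyad_s`
#'   (the fixed 44-h dyad total, 158,400 s by default).
#' @export
session_totals <- function(config) {
  s <- config$session_length_h * 3600
  list(session_s = s, dyad_s = 2 * s)
}

# Population parameters for rat-level physiology.  Masses echo the screened
# cohort (mean 160.2 g, SD 22.0 g); heat-response gains are phenotype
# dependent with II > IS in expectation, the drug's heat-loss effect is
# phenotype independent and strictly positive.
rat_population <- list(
  mass_mean = 160.2, mass_sd = 22.0, mass_min = 90,
  tc_mean = 37.5, tc_sd = 0.3,
  gain = list(IS = c(mean = 0.08, sd = 0.04),
              II = c(mean = 0.28, sd = 0.08),
              none = c(mean = 0.18, sd = 0.10)),
  gain_min = 0,
  hl_mean = 0.35, hl_sd = 0.05, hl_min = 0.05
)

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  pmax(x, lower)
}

#' Simulate a cohort of rats
#'
#' Draws per-rat physiology (mass, baseline core temperature, heat-production
#' response gain, drug heat-loss effect) and a behavioural random intercept on
#' the log preference-ratio scale.  With `phenotype = "balanced"` each squad
#' contributes 2 IS and 2 II rats (the post-screening study groups); with
#' `phenotype = "screen"` all `rats_per_squad` rats are generated unlabelled,
#' with a continuous distribution of response gains, for the screening
#' simulation.
#'
#' @param config a [cohort_config()].
#' @param phenotype `"balanced"` or `"screen"`.
#' @param seed optional integer seed; when given, the draw is reproducible.
#' @return data.frame with one row per rat: `rat_id`, `squad_id`, `phenotype`,
#'   `mass_g`, `baseline_tc`, `hp_response_gain`, `hl_drug_effect`,
#'   `pref_intercept`.
#' @export
simulate_cohort <- function(config, phenotype = c("balanced", "screen"),
                            seed = NULL) {
  phenotype <- match.arg(phenotype)
  if (!is.null(seed)) set.seed(seed)
  pop <- rat_population
  if (phenotype == "balanced") {
    per_squad <- 4L
    phen <- rep(c("IS", "IS", "II", "II"), config$n_squads)
  } else {
    per_squad <- config$rats_per_squad
    phen <- rep("none", config$n_squads * per_squad)
  }
  n <- config$n_squads * per_squad
  squad <- rep(seq_len(config$n_squads), each = per_squad)
  gain <- numeric(n)
  for (ph in unique(phen)) {
    idx <- phen == ph
    g <- pop$gain[[ph]]
    gain[idx] <- rtrunc_norm(sum(idx), g["mean"], g["sd"], pop$gain_min)
  }
  data.frame(
    rat_id = sprintf("S%02dR%02d", squad, stats::ave(squad, squad,
                                                     FUN = seq_along)),
    squad_id = squad,
    phenotype = phen,
    mass_g = rtrunc_norm(n, pop$mass_mean, pop$mass_sd, pop$mass_min),
    baseline_tc = stats::rnorm(n, pop$tc_mean, pop$tc_sd),
    hp_response_gain = gain,
    hl_drug_effect = rtrunc_norm(n, pop$hl_mean, pop$hl_sd, pop$hl_min),
    pref_intercept = stats::rnorm(n, 0, config$between_rat_sd),
    stringsAsFactors = FALSE
  )
}
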