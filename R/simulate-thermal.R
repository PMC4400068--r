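#' Simulate one total-calorimetry screening session
#'
#' Generates the raw signal streams a combined direct/indirect calorimetry
#' chamber would record for a single rat: telemetric core temperature (Tc) at
#' 15-s cadence, and O2 fractions, water-vapour flux and gradient-layer
#' millivolt signal at 10-s cadence, each labelled with the session phase
#' (baseline / n2o / recovery).
#'
#' Dynamics follow a single-compartment heat balance
#' \deqn{C\,dT_c/dt = HP - HL, \qquad C = c_{body} \cdot mass,}
#' with basal heat production \eqn{HP_0} set by allometric scaling and basal
#' heat loss equal to it (thermal equilibrium at baseline).  During the N2O
#' phase heat loss is raised by the rat's `hl_drug_effect` (split between the
#' dry and evaporative channels by `evap_fraction`) from phase onset, and heat
#' production is raised by `hp_response_gain` once `hp_onset_lag_s` has
#' elapsed.  Deviations of Tc from baseline feed back on dry heat loss with
#' slope `thermal_feedback_w_per_c`.  All powers are piecewise constant on the
#' 10-s logging grid and Tc is the exact integral of the balance, so with zero
#' noise the emitted signals close the heat balance to machine precision.
#'
#' @param rat one row of [simulate_cohort()] (or a list with fields `mass_g`,
#'   `baseline_tc`, `hp_response_gain`, `hl_drug_effect`).
#' @param config a [cohort_config()].
#' @param noise logical; add Gaussian measurement noise to each channel?
#' @param seed optional integer seed.
#' @return an object of class `calorimetry_session`: list with data.frames
#'   `tc` (`time_s`, `tc`, `phase`) and `signals` (`time_s`, `o2_in`,
#'   `o2_out`, `vapor_flux_mg_min`, `gradient_mv`, `phase`), plus `flow_lpm`,
#'   `params` and `rat`.
#' @export
simulate_thermal_session <- function(rat, config, noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("mass_g", "baseline_tc", "hp_response_gain", "hl_drug_effect")
  for (nm in need) {
    v <- rat[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("rat field '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  base_s <- config$phase_baseline_min * 60
  n2o_s <- config$phase_n2o_min * 60
  rec_s <- config$phase_recovery_min * 60
  total_s <- base_s + n2o_s + rec_s
  if (any(c(base_s, n2o_s, rec_s) %% 10 != 0))
    stop("phase lengths must be multiples of the 10-s logging interval",
         call. = FALSE)

  t10 <- seq(0, total_s - 10, by = 10)        # interval starts
  phase <- ifelse(t10 < base_s, "baseline",
                  ifelse(t10 < base_s + n2o_s, "n2o", "recovery"))
  in_n2o <- phase == "n2o"

  C <- config$c_body * rat$mass_g             # J/degC
  hp0 <- config$basal_hp_coef * (rat$mass_g / 1000)^0.75
  ehl0 <- 0.25 * hp0
  dhl0 <- hp0 - ehl0
  k <- config$thermal_feedback_w_per_c

  hp_extra <- ifelse(in_n2o & (t10 - base_s) >= config$hp_onset_lag_s,
                     rat$hp_response_gain, 0)
  hl_drug <- ifelse(in_n2o, rat$hl_drug_effect, 0)
  dry_drug <- (1 - config$evap_fraction) * hl_drug
  evap_drug <- config$evap_fraction * hl_drug

  n <- length(t10)
  tc_nodes <- numeric(n + 1L)                 # Tc at 10-s grid nodes
  tc_nodes[1L] <- rat$baseline_tc
  hp <- hp0 + hp_extra
  dhl <- numeric(n)
  ehl <- ehl0 + evap_drug
  for (i in seq_len(n)) {
    dev <- tc_nodes[i] - rat$baseline_tc
    dhl[i] <- dhl0 + k * dev + dry_drug[i]
    tc_nodes[i + 1L] <- tc_nodes[i] + 10 * (hp[i] - dhl[i] - ehl[i]) / C
  }

  # exact piecewise-linear sampling of Tc on the 15-s telemetry grid
  t15 <- seq(0, total_s, by = 15)
  tc15 <- stats::approx(x = seq(0, total_s, by = 10), y = tc_nodes,
                        xout = t15)$y
  phase15 <- ifelse(t15 < base_s, "baseline",
                    ifelse(t15 < base_s + n2o_s, "n2o", "recovery"))

  k_lusk <- lusk_equivalent_w(config$rq)      # W per (L O2 / min)
  hp_meas <- hp
  dhl_meas <- dhl
  ehl_meas <- ehl
  if (noise) {
    tc15 <- tc15 + stats::rnorm(length(tc15), 0, config$tc_noise_sd)
    hp_meas <- hp_meas + stats::rnorm(n, 0, config$hp_noise_sd)
    dhl_meas <- dhl_meas + stats::rnorm(n, 0, config$dhl_noise_sd)
    ehl_meas <- ehl_meas + stats::rnorm(n, 0, config$ehl_noise_sd)
  }
  o2_out <- config$o2_in - hp_meas / (k_lusk * config$flow_lpm)
  vapor <- ehl_meas * 60 / config$latent_heat          # mg/min
  grad_mv <- dhl_meas / config$gradient_calibration    # mV

  structure(list(
    tc = data.frame(time_s = t15, tc = tc15, phase = phase15,
                    stringsAsFactors = FALSE),
    signals = data.frame(time_s = t10, o2_in = config$o2_in, o2_out = o2_out,
                         vapor_flux_mg_min = vapor, gradient_mv = grad_mv,
                         phase = phase, stringsAsFactors = FALSE),
    flow_lpm = config$flow_lpm,
    params = list(rq = config$rq, latent_heat = config$latent_heat,
                  gradient_calibration = config$gradient_calibration,
                  c_body = config$c_body, mass_g = rat$mass_g,
                  baseline_s = base_s, n2o_s = n2o_s, recovery_s = rec_s),
    rat = rat
  ), class = "calorimetry_session")
}

#' @export
print.calorimetry_session <- function(x, ...) {
  cat(sprintf(
    "<calorimetry_session> %g s (%d Tc samples, %d signal records)\n",
    max(x$tc$time_s), nrow(x$tc), nrow(x$signals)))
  invisible(x)
}
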