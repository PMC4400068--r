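#' Lusk energy equivalent of oxygen
#'
#' Energy released per litre of O2 consumed, as a linear function of the
#' respiratory quotient (kcal/L = 3.815 + 1.232 RQ), expressed in watts per
#' (L O2 / min).
#'
#' @param rq respiratory quotient in `[0.7, 1.0]`.
#' @return watts per litre O2 per minute.
#' @export
lusk_equivalent_w <- function(rq) {
  if (any(rq < 0.7 | rq > 1.0)) stop("rq must lie in [0.7, 1.0]",
                                     call. = FALSE)
  (3.815 + 1.232 * rq) * 4184 / 60
}

#' Heat production from oxygen consumption (indirect calorimetry)
#'
#' `VO2 = flow * (o2_in - o2_out)` (L/min of O2 removed from the gas stream),
#' converted to power with the Lusk energy equivalent.
#'
#' @param o2_in,o2_out incurrent/excurrent fractional O2 concentrations.
#' @param flow gas flow in L/min.
#' @param rq assumed respiratory quotient.
#' @return heat production in watts (vectorised).
#' @export
heat_production <- function(o2_in, o2_out, flow, rq = 0.85) {
  if (any(flow <= 0)) stop("flow must be positive", call. = FALSE)
  if (any(o2_in < 0 | o2_in > 1 | o2_out < 0 | o2_out > 1))
    stop("O2 fractions must lie in [0, 1]", call. = FALSE)
  if (any(o2_out > o2_in))
    stop("o2_out exceeds o2_in: sensor inversion?", call. = FALSE)
  lusk_equivalent_w(rq) * flow * (o2_in - o2_out)
}

#' Evaporative heat loss from water-vapour flux
#'
#' @param vapor_flux water mass added to the excurrent stream, mg/min.
#' @param latent_heat latent heat of vaporisation, J/mg.
#' @return power in watts (vectorised).
#' @export
evaporative_heat_loss <- function(vapor_flux, latent_heat = 2.41) {
  if (any(vapor_flux < 0))
    stop("negative vapour flux: condensation or sensor fault", call. = FALSE)
  latent_heat * vapor_flux / 60
}

#' Dry heat loss from the gradient-layer signal
#'
#' The gradient-layer calorimeter emits a millivolt signal proportional to
#' the summed conductive, convective and radiative heat flow.
#'
#' @param gradient_signal signal in mV.
#' @param calibration calibration constant, W/mV (> 0).
#' @return power in watts (vectorised).
#' @export
dry_heat_loss <- function(gradient_signal, calibration = 0.2) {
  if (calibration <= 0) stop("calibration must be positive", call. = FALSE)
  calibration * gradient_signal
}

#' Bin a calorimetry session into 6-min thermal profile bins
#'
#' Derives HP, dry HL and evaporative HL from the raw signal streams, then
#' takes arithmetic means per 360-s bin of each power channel and of Tc.
#' A trailing partial bin is dropped with a warning.  The first two 6-min HP
#' bins of the N2O phase are flagged (`hp_artifact = TRUE`, not dropped):
#' starting N2O delivery transiently corrupts the indirect-calorimetry
#' signal, so those bins are excluded from hourly HP summaries.
#'
#' @param session a `calorimetry_session` (see [simulate_thermal_session()]),
#'   or any list with the same `tc`/`signals`/`flow_lpm`/`params` shape.
#' @return data.frame of class `thermal_profile`: `bin`, `bin_start`,
#'   `phase`, `tc`, `hp`, `dhl`, `ehl`, `hp_artifact`.
#' @export
bin_profile <- function(session) {
  sig <- session$signals
  tc <- session$tc
  p <- session$params
  total <- max(sig$time_s) + 10
  n_bins <- floor(total / 360)
  if (n_bins < 1) stop("session shorter than one 6-min bin", call. = FALSE)
  if (total %% 360 != 0)
    warning(sprintf("trailing partial bin (%g s) dropped", total %% 360),
            call. = FALSE)
  hp <- heat_production(sig$o2_in, sig$o2_out, session$flow_lpm, p$rq)
  dhl <- dry_heat_loss(sig$gradient_mv, p$gradient_calibration)
  ehl <- evaporative_heat_loss(sig$vapor_flux_mg_min, p$latent_heat)
  bin10 <- floor(sig$time_s / 360) + 1L
  bin15 <- floor(tc$time_s / 360) + 1L
  keep10 <- bin10 <= n_bins
  keep15 <- bin15 <= n_bins
  agg <- function(x, f) as.numeric(tapply(x, f, mean))
  bins <- data.frame(
    bin = seq_len(n_bins),
    bin_start = (seq_len(n_bins) - 1L) * 360,
    phase = as.character(tapply(sig$phase[keep10], bin10[keep10],
                                function(z) z[1])),
    tc = agg(tc$tc[keep15], bin15[keep15]),
    hp = agg(hp[keep10], bin10[keep10]),
    dhl = agg(dhl[keep10], bin10[keep10]),
    ehl = agg(ehl[keep10], bin10[keep10]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(bins$tc) | is.na(bins$hp)))
    stop("empty 6-min bin: data gap", call. = FALSE)
  n2o_bins <- which(bins$phase == "n2o")
  bins$hp_artifact <- bins$bin %in% n2o_bins[seq_len(min(2, length(n2o_bins)))]
  class(bins) <- c("thermal_profile", "data.frame")
  bins
}

#' Baseline-referenced deltas and phase summaries
#'
#' Subtracts the baseline-phase mean of each channel, giving per-bin deltas,
#' and summarises each phase by the mean delta of its bins.  HP summaries
#' exclude the flagged artifact bins.  Also reports the Tc nadir (most
#' negative per-bin delta during the N2O phase) and its time since N2O onset.
#'
#' @param profile a `thermal_profile` from [bin_profile()].
#' @return list with `bins` (per-bin `dtc`, `dhp`, `ddhl`, `dehl` added),
#'   `summary` (per-phase mean deltas), `tc_nadir` and `tc_nadir_min`
#'   (minutes after N2O onset).
#' @export
delta_from_baseline <- function(profile) {
  base <- profile$phase == "baseline"
  if (!any(base)) stop("baseline phase is empty", call. = FALSE)
  ref <- vapply(c("tc", "hp", "dhl", "ehl"),
                function(ch) mean(profile[[ch]][base]), numeric(1))
  bins <- profile
  bins$dtc <- profile$tc - ref["tc"]
  bins$dhp <- profile$hp - ref["hp"]
  bins$ddhl <- profile$dhl - ref["dhl"]
  bins$dehl <- profile$ehl - ref["ehl"]
  phases <- unique(profile$phase)
  summary <- do.call(rbind, lapply(phases, function(ph) {
    sel <- profile$phase == ph
    hp_sel <- sel & !profile$hp_artifact
    data.frame(phase = ph,
               dtc = mean(bins$dtc[sel]),
               dhp = if (any(hp_sel)) mean(bins$dhp[hp_sel]) else NA_real_,
               ddhl = mean(bins$ddhl[sel]),
               dehl = mean(bins$dehl[sel]),
               stringsAsFactors = FALSE)
  }))
  n2o <- profile$phase == "n2o"
  nadir <- if (any(n2o)) min(bins$dtc[n2o]) else NA_real_
  nadir_min <- if (any(n2o)) {
    (bins$bin_start[n2o][which.min(bins$dtc[n2o])] + 360 -
       min(bins$bin_start[n2o])) / 60
  } else NA_real_
  list(bins = bins, summary = summary, tc_nadir = nadir,
       tc_nadir_min = nadir_min)
}

#' Hourly heat-production deltas during the N2O phase
#'
#' Mean baseline-referenced HP per hour of the N2O phase, excluding the
#' flagged artifact bins (the first 12 min).
#'
#' @param profile a `thermal_profile`.
#' @return numeric vector of hourly mean HP deltas (one per full hour).
#' @export
hp_hourly_deltas <- function(profile) {
  d <- delta_from_baseline(profile)
  bins <- d$bins
  n2o <- which(bins$phase == "n2o")
  if (!length(n2o)) return(numeric(0))
  rel <- seq_along(n2o) - 1L                 # 6-min bins since N2O onset
  hour <- rel %/% 10L + 1L
  full <- tabulate(hour) == 10L
  out <- vapply(which(full), function(h) {
    sel <- n2o[hour == h]
    sel <- sel[!bins$hp_artifact[sel]]
    mean(bins$dhp[sel])
  }, numeric(1))
  out
}

#' Group-by-increase contingency table of HP responses
#'
#' Counts rats per group whose mean HP change from baseline during a given
#' hour of N2O administration is positive, returning the 2x2 table
#' (rows II, IS; columns increase, no increase) used by the exact Fisher
#' test.
#'
#' @param hourly_deltas data.frame with columns `rat_id`, `group`
#'   (`"IS"`/`"II"`) and `h1`, `h2`, `h3` hourly HP deltas (see
#'   [hp_hourly_deltas()]).
#' @param hour which hour (1, 2 or 3).
#' @return 2x2 integer matrix.
#' @export
hp_increase_counts <- function(hourly_deltas, hour = 1) {
  col <- paste0("h", hour)
  stopifnot(col %in% names(hourly_deltas))
  inc <- hourly_deltas[[col]] > 0
  tab <- matrix(0L, 2, 2,
                dimnames = list(group = c("II", "IS"),
                                hp = c("increase", "no_increase")))
  for (g in c("II", "IS")) {
    sel <- hourly_deltas$group == g
    tab[g, ] <- c(sum(inc[sel]), sum(!inc[sel]))
  }
  tab
}

#' Within-squad z-score screening for thermal extremes
#'
#' Standardises a Tc-sensitivity summary (here: mean Tc change from baseline
#' over the N2O phase, so large drops are strongly negative) within each
#' squad and selects the `n_extreme` most sensitive rats (lowest summaries)
#' as initially sensitive (IS) and the `n_extreme` least sensitive (highest)
#' as initially insensitive (II).  Ties break deterministically by `rat_id`.
#'
#' @param summaries data.frame with `rat_id`, `squad_id` and `sensitivity`
#'   (the Tc summary, degC).
#' @param n_extreme rats to select per tail per squad.
#' @return the input with `z` and `selected_group` (`"IS"`, `"II"`, `"none"`)
#'   columns added.
#' @export
zscore_select <- function(summaries, n_extreme = 2) {
  stopifnot(all(c("rat_id", "squad_id", "sensitivity") %in% names(summaries)))
  out <- summaries
  out$z <- NA_real_
  out$selected_group <- "none"
  for (sq in unique(out$squad_id)) {
    idx <- which(out$squad_id == sq)
    if (length(idx) < 2 * n_extreme)
      stop(sprintf("squad %s smaller than 2 * n_extreme", sq), call. = FALSE)
    x <- out$sensitivity[idx]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop(sprintf("squad %s has zero sensitivity variance", sq),
           call. = FALSE)
    out$z[idx] <- (x - mean(x)) / s
    ord <- idx[order(out$sensitivity[idx], out$rat_id[idx])]
    out$selected_group[ord[seq_len(n_extreme)]] <- "IS"
    out$selected_group[rev(ord)[seq_len(n_extreme)]] <- "II"
  }
  out
}

#' Heat-balance residual of a calorimetry session
#'
#' Verification helper: reconstructs HP, dry HL and evaporative HL from the
#' emitted signals, averages the net power over 30-s windows (the least
#' common multiple of the 10-s and 15-s cadences), and compares with
#' `C * dTc/dt` computed from the telemetry samples at the window edges.
#' On a noise-free simulated session the maximum absolute residual is at
#' numerical tolerance.
#'
#' @param session a `calorimetry_session`.
#' @return maximum absolute residual in watts.
#' @export
heat_balance_residual <- function(session) {
  sig <- session$signals
  p <- session$params
  hp <- heat_production(sig$o2_in, sig$o2_out, session$flow_lpm, p$rq)
  hl <- dry_heat_loss(sig$gradient_mv, p$gradient_calibration) +
    evaporative_heat_loss(sig$vapor_flux_mg_min, p$latent_heat)
  net <- hp - hl
  total <- max(sig$time_s) + 10
  n_win <- floor(total / 30)
  win <- rep(seq_len(n_win), each = 3)[seq_along(net)]
  net_mean <- as.numeric(tapply(net[win <= n_win], win[win <= n_win], mean))
  C <- p$c_body * p$mass_g
  tc_edges <- session$tc$tc[session$tc$time_s %% 30 == 0]
  dtc <- diff(tc_edges[seq_len(n_win + 1)]) / 30
  max(abs(net_mean - C * dtc))
}
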