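---
title: "Models and methods: occupancy scoring, heat-balance partitioning, and log-ratio GEE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaspref)
```

This vignette is the package's own account of its methods: the models, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the underlying protocol left things open.

## 1. Occupancy scoring

Side-chamber occupancy comes from five infrared beams logged as the set of
beams broken per 10-s interval; beam 1 sits 4 cm from the door, beams 2–5
deeper in the tube. `score_chamber_occupancy()` applies these rules:

* Any interval with an inner beam (2–5) broken puts the rat inside, entry at
  that interval's start.
* A maximal run of beam-1-only intervals immediately before it is also
  scored inside *iff* that inner-beam interval follows. A rat that pokes its
  nose past the door beam and retreats is never scored.
* While inside, any beam break keeps the rat inside; a single empty interval
  is indeterminate and resolves inside iff the next interval has a break;
  two consecutive empty intervals end the bout, exit at the end of the last
  qualifying interval.

Three situations are not fully determined by those rules; the package's
choices, each behind a documented surface:

* **Entry time for a back-scored beam-1 run.** Those intervals are "scored
  inside", so the entry time backs up to the start of the run. The stricter
  alternative (entry at the first inner-beam interval) is available via
  `entry_at_inner_beam = TRUE`; it changes entry times, never the inside/
  outside classification of the run.
* **Session end while inside.** The bout closes at the session boundary
  (gas is cleared then anyway); trailing empty intervals are not awaited.
* **A single trailing empty interval** while inside counts as inside: no
  next interval exists to disqualify it, which is symmetric with the exit
  rule's demand for *two* empty intervals.

Missing log records are treated as empty scans with a warning. The scorer is
verified two ways: against a literal per-sentence transcription oracle,
exhaustively over the scorer's effective alphabet (empty / beam-1-only /
inner) for all sequences to length 6 plus full 32-subset enumeration at
short lengths and random sampling beyond (the mask→class reduction is itself
asserted); and by round-tripping `synthesize_beam_scans()`, whose
single-interval dropouts the bridging rule must absorb exactly. Synthesized
bouts are kept ≥ 30 s with ≥ 20-s gaps so that dropout placement can never
interact with the two-empty exit rule — shorter bouts would make "interior"
intervals adjacent to bout edges.

## 2. Dyads, compositions, and zeros

Each pair of consecutive 22-h sessions with the N₂O side alternated is
summed into a 44-h dyad composition (t₍N₂O₎, t₍control₎, t₍central₎), total
158,400 s; central time is the remainder, so the data are compositional by
construction. Dyads missing a session are flagged, never zero-filled, and
excluded from fits (complete-available analysis);
`impute_missing_extremes()` refits under minimum- and maximum-preference
fills to bracket what the missing dyads could have changed.

Zeros (a side chamber never entered in 44 h) are replaced by 5 s — half the
10-s detection limit — additively on the zero cells only, per the protocol's
stated rule; the total is deliberately not re-closed, since a ≤ 10-s
perturbation of a 158,400-s total is far below the reader's ±10-s closure
tolerance. The floor is a parameter so robustness sweeps over values below
the detection limit can be run (`run_end_to_end()` does a {1, 2, 5, 9}-s
sweep automatically).

The compositional center per group × dyad is the component-wise geometric
mean re-closed to proportions. Ternary coordinates use the standard
barycentric map onto the unit-edge triangle. An exact identity ties the two
summaries together (and is tested as such): the log preference ratio of the
centered geometric mean equals the arithmetic mean of per-rat log ratios.
Whether ternary points should use proportions of the fixed 44-h total or of
summed *measured* time is ambiguous in the source protocol; proportions of
the fixed total are used, which is consistent with central time being
defined as the remainder.

## 3. The estimating-equation engine

The primary model is
log(t₍N₂O₎/t₍control₎) ~ group + dyad (dyad continuous, coded 1–4 or 5–8 as
printed, not centered), clustered on rat, fit by Gaussian GEE with identity
link. With an exchangeable working correlation the cluster inverse has the
closed form R⁻¹ = [I − α/(1+(n−1)α) J]/(1−α); β is iterated GLS with the
moment estimator for α (Pearson-residual cross-products over
Σnᵢ(nᵢ−1)/2 − p), to 1e-10 on β, max 100 iterations; non-convergence, rank
deficiency, and < 2 clusters are distinct errors. The covariance is the
Liang–Zeger sandwich, which is invariant to the residual scale, cluster
relabeling and record order (tested). Working correlation is not pinned by
the protocol text, so *exchangeable* is the default — it matches the
generator's random-intercept truth — with independence available, and the
pipeline reports both.

Choices and their consequences:

* **z-intervals, no small-sample correction.** Inference uses ±1.96 robust
  SEs. With 32 clusters the uncorrected sandwich is known to be slightly
  anticonservative; our own calibration (2000 synthetic cohorts) puts CI
  coverage near 92.9% and null rejection near 7.1% rather than 95%/5%.
  This is a property of the pinned convention, not of the implementation,
  which agrees with an independent GEE implementation to eight decimals.
  A DF-adjusted or bias-corrected sandwich would tighten calibration but is
  deliberately out of scope.
* **Natural logs throughout**; fold changes exponentiate the same base, so
  every reported fold is base-invariant.
* **Fisher test**: exact conditional enumeration; two-sided p by the
  sum-of-small-p rule (the dominant convention; mid-p not used), with a
  1e-7 relative guard on the point-probability comparison against
  floating-point ties. Empty margins return p = 1.

## 4. Calorimetric partitioning

* **HP** (indirect): VO₂ = flow·(o2_in − o2_out); energy equivalent
  3.815 + 1.232·RQ kcal per L O₂ (the Lusk linearisation), ×4184/60 to
  watts per L/min. The screening channels include no CO₂ analyzer, so RQ is
  a fixed configurable parameter, default 0.85 (mixed fuel); the specific
  "modified" coefficient set used by the original instrument chain is not
  printed in the protocol, so the standard Lusk coefficients are used and
  documented here.
* **EHL**: λ·vapor flux, λ default 2.41 J/mg (latent heat near calorimeter
  temperature), configurable.
* **DHL**: calibration (W/mV, default 0.2) × gradient-layer signal.
* **Binning**: arithmetic means per 360-s bin (24 Tc samples at 15 s, 36
  power samples at 10 s); trailing partial bins dropped with a warning. The
  first two 6-min HP bins after N₂O onset are *flagged*, not dropped —
  starting gas delivery transiently corrupts the O₂ signal — and hourly HP
  summaries exclude them.
* **Screening statistic**: mean baseline-referenced Tc over the 3-h N₂O
  phase, standardised within squad; two lowest z → IS, two highest → II,
  ties broken by rat id. The historically used criterion is referenced but
  not restated in the protocol; the phase-mean ΔTc is the quantity its
  summary figures display, and selection is invariant to affine rescaling
  of the statistic (tested), so any affinely equivalent summary selects
  identically. The 45-min recovery phase is binned but enters no summary.

## 5. The synthetic cohort generator

The generator is a stated world, not a tuning knob; its defaults encode the
study conditions and are not revisited against test outcomes.

**Thermal sessions.** One-compartment heat balance C·dTc/dt = HP − HL with
C = 3.47 J g⁻¹ °C⁻¹ × mass — the minimal physics linking Tc to its two
measured determinants. Baseline equilibrium sets HP₀ = HL₀ =
4.2·(mass/kg)^0.75 W (≈ 1.05 W at 160 g), split 75% dry / 25% evaporative.
During N₂O, HL rises by the rat's `hl_drug_effect` (population mean 0.35 W,
phenotype-independent and strictly positive — the drug's consistent
pharmacological effect), split 40/60 between dry and evaporative channels;
HP rises by `hp_response_gain` (II mean 0.28 W > IS mean 0.08 W — the
phenotype) after a 600-s onset lag. Tc deviations feed back on dry HL at
0.1 W/°C, a net thermal conductance chosen so an unopposed 0.35-W HL excess
asymptotes near −3.5 °C — the magnitude scale of the sensitive phenotype.
Powers are piecewise-constant on the 10-s grid and Tc is their exact
integral, so noise-free sessions close the heat balance to machine
precision; measurement noise is additive Gaussian per channel (Tc 0.02 °C;
power channels 0.005–0.02 W equivalent). Timing: 120-min baseline, 180-min
N₂O, 45-min recovery; flow 1.5 L/min; ambient 22 °C; masses ~N(160.2, 22²) g.
The generator makes no attempt to reproduce published curve *shapes* (e.g.
the 70-min IS nadir, or recovery dynamics driven by time-varying HP
recruitment); only effect directions and magnitudes are planted, and a green
thermal test establishes ordering and balance properties, not waveform
fidelity.

**Behaviour.** Per rat × dyad, the two log-ratios (log t₍N₂O₎/t₍central₎,
log t₍control₎/t₍central₎) are logistic-normal; their contrast — the log
preference ratio — has mean baseline + effect·1{II} + slope·dyad + rat
intercept. Defaults: baseline log(0.5) (IS rats below 1:1, as observed),
planted effect log(3.68) (the headline fold difference), slope 0.08/dyad,
control:central ratio log(0.25) (most time in the central tub). The
within-rat correlation magnitudes are *not* reported anywhere, so
`within_rat_sd = between_rat_sd = 0.5` (ICC 0.5, group-effect SE ≈ 0.2 at
16+16 × 4 dyads) are free parameters of the stated world, chosen once as
typical for repeated behavioural log-ratios and documented as such. The
generator is exchangeable by construction; it cannot test robustness to
misspecified correlation structure.

## 6. Degenerate inputs and numerical conventions

Zero within-squad screening variance, zero-residual GEE fits (α update
skipped, covariance collapses to zero), empty interval lists, empty Fisher
margins, and sessions shorter than one bin all have defined behaviour and
tests. α is clamped to (−1/(n_max−1), 1) for invertibility. The acceptance
machinery seeds every stochastic computation from a single `--seed`, and
identical seeds reproduce cohorts bit-for-bit.

## 7. Known limitations

* XLSX ingestion is unavailable (no reader in the dependency budget);
  deposited spreadsheets must be exported to CSV for `read_dyad_table()`.
* The sandwich calibration gap at 32 clusters (Section 3) is inherited from
  the pinned inference convention.
* The thermal model's single compartment and step-shaped responses are a
  deliberate simplification (Section 5).
* Training days, gas clearance intervals and bout truncation at the 22-h
  boundary are handled by fiat (truncate at session end), since the source
  protocol does not specify them.
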