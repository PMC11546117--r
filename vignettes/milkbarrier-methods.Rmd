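---
title: "Methods: estimating apparent permeability across an in vitro blood–milk barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating apparent permeability across an in vitro blood-milk barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkbarrier)
```

## The experimental system

Mammary epithelial cells grown on a permeable (transwell) support separate
an apical compartment — facing what would become milk — from a basolateral
compartment facing plasma. Once the monolayer is tight, a probe substrate is
dosed on one side and its appearance on the other side is followed over
time. The apparent permeability coefficient summarises how fast the
substrate crosses; comparing the apical-to-basolateral (A→B) and
basolateral-to-apical (B→A) directions reveals polarized, carrier-mediated
transport. `milkbarrier` implements the full analysis chain for this design,
with defaults matching a primary human mammary epithelial cell (hMEC) model:
0.3 cm² PET inserts with 0.4 µm pores, 0.5 mL apical and 1.2 mL basolateral
transport-phase volumes, 50 µM donors, receiver samples at 0.5, 1, 1.2 and
2 h, and a 5 nM limit of quantification (LOQ).

## Barrier-integrity QC

Two orthogonal gates decide whether an insert's kinetic data are usable.

**TEER.** Transepithelial electrical resistance is blank-corrected and
area-scaled:

$$\mathrm{TEER}\;(\Omega\,\mathrm{cm}^2) =
  (R_\mathrm{total} - \bar R_\mathrm{blank}) \times A_\mathrm{membrane}.$$

The blank is the mean over cell-free inserts measured the same day, falling
back to the global blank mean when a day has none (electrode drift handling
is not standardised across labs, so the per-day mean with a global fallback
is the least surprising choice). A negative corrected value is retained and
flagged rather than clipped — clipping would hide electrode faults from
audit. The default tightness threshold is 400 Ω·cm², the conventional cut
for a usable epithelial barrier; mature hMEC monolayers plateau around
700 Ω·cm² after five to six weeks.

**Tracer leakage.** Sodium fluorescein (2.66 mM donor) is quantified
against an ordinary least-squares calibration line with intercept
(`fit_calibration()`); the percentage transported corrects for the
compartment volumes,

$$\mathrm{transport\,\%} =
  \frac{C_\mathrm{sample}}{C_\mathrm{donor}} \times
  \frac{V_\mathrm{basolateral}}{V_\mathrm{apical}} \times 100\%,$$

with the volume ratio inverted when the basolateral side is dosed. Note
that the conventional percentage labels attached to calibration standards
(0.0078%–0.125% for 207.8 nM–3.325 µM) are plain concentration ratios to
the donor, i.e. the volume factor equals one there; both conventions are
available through `leakage_percent()`'s volume arguments. No published
acceptance cut-off exists for leakage, so the gate ceiling defaults to a
configurable 0.5%; tight monolayers in practice reach ~0.02%.

Calibration is unweighted and keeps its intercept: the assay's blank is
subtracted upstream and zero-forcing would bias low-end samples, which are
exactly the ones that matter for leakage.

## Apparent permeability

### Dilution-corrected cumulative transport

Intermediate receiver samples remove half the compartment volume and are
replaced with blank medium, so later concentrations are diluted. The
cumulative amount transported by sampling time $t_k$ is the amount
currently in the receiver plus everything previously removed:

$$Q(t_k) = C_k V_\mathrm{receiver} + \sum_{j<k} C_j V_{\mathrm{removed},j}.$$

This bookkeeping is exact mass balance, whatever the removal fractions are;
the removed volume comes from the schedule, never a hard-coded half.
Receiver volume is 1.2 mL (basolateral) for A→B and 0.5 mL (apical) for
B→A.

### Censoring and linearity trimming

Samples below the LOQ are flagged and excluded from slope fitting, but
their measured values are kept in the removed-amount sum — they remain the
best available estimate of what left the compartment. When *every* sample
is censored, no permeability can be estimated; instead the LOQ is
substituted for each sample and the terminal-time secant slope gives an
upper bound, reported as "≤ bound" (`loq_bound()`). The bound is linear in
the LOQ. The LOQ is interpreted in concentration units; for signal-based
data a configured signal-per-nM factor should be applied to the LOQ before
constructing the series.

The early part of a cumulative curve can show a lag (membrane loading,
esterase activation), so the fit window is trimmed from the front:
starting from all uncensored points *plus the origin* (0, 0) — at dose time
nothing has been transported, and including it gives the trimming rule a
point to discard during lag phases — an OLS line with intercept is fitted
and, while $R^2 < 0.970$, the earliest remaining point is dropped and the
fit repeated. Only leading points are ever removed. A fit is refused
(`insufficient_points`) when fewer than 3 points remain, i.e. more than two
points must support any accepted slope. $R^2$ is the ordinary coefficient
of determination of the fit with intercept; the threshold-capable "exactly
three nonlinear points" corner also ends as `insufficient_points`, because
a two-point line is trivially perfect and accepting it would launder
nonlinearity through the trimming rule. When censoring (not trimming)
leaves only two measured points, the origin-anchored estimate is computed
but flagged `two_point_estimate` rather than silently accepted or refused —
mirroring how such values are reported with a dagger in screening tables.

### The permeability coefficient

$$P_\mathrm{app}\;(\mathrm{cm/s}) =
  \frac{dQ/dt}{A_\mathrm{membrane}\, C_\mathrm{donor}},$$

with the slope in amount per second and the *measured dose* (donor
concentration per mL) in the same value unit as the receiver series, so
unit tags cancel — molar with molar, LC-MS signal with signal. Results are
reported in $10^{-6}$ cm/s. Per substrate and experiment, replicate inserts
collapse to directional medians (robust against the occasional leaky or
clogged insert) and the polarity (efflux) ratio
$P_\mathrm{app}^{B\to A} / P_\mathrm{app}^{A\to B}$ of those medians — the
same convention used for Caco-2 efflux ratios. The ratio is reported only
when both directional medians come from valid fits; bounds and flagged
estimates propagate as qualifiers instead. The terminal donor sample, when
present, feeds a recovery diagnostic only; the estimator always divides by
the dose measurement.

## Transporter expression profiling

Relative expression over an 84-gene transporter panel uses the ΔCt method
against a five-gene reference panel (ACTB, B2M, GAPDH, HPR1, RPLP0):
per replicate, $\Delta C_t = \overline{C_t}^\mathrm{ref} - C_t^\mathrm{gene}$,
then mean ± SD over replicates — per-replicate-first ordering is what makes
the reported SD meaningful. ΔCt is invariant to any plate-wide shift in
cycle numbers. A Ct above the detectability ceiling (default 35 cycles, the
common array convention) counts as undetermined; a gene is detectable when
determined in all replicates by default. Array software encodes
"undetermined" variously as a blank, a textual marker or a sentinel cycle
(40); `read_ct_csv()` accepts all three.

## Growth kinetics

Population doubling time assumes exponential growth,
$DT = \Delta t \,\ln 2 / \ln(n_1/n_0)$. Because labs disagree on whether to
summarise per flask or per passage interval, `summarize_doubling_time()`
reports both groupings (log-linear regression per flask, and the two-point
formula per consecutive interval).

## The transport simulator

The simulator exists so every stage of the analysis can be validated
against known truth without laboratory data. It integrates the
two-compartment mass balance

$$V_d \frac{dC_d}{dt} = -P A (C_d - C_r) \mp CL\, C_{(\cdot)},\qquad
  V_r \frac{dC_r}{dt} = +P A (C_d - C_r) \pm CL\, C_{(\cdot)},$$

where the optional clearance term $CL$ (mL/s) moves substrate
unidirectionally from basolateral to apical, emulating an apically directed
efflux pump. A single-concentration design cannot identify saturable
kinetics, so a first-order clearance is the honest level of detail. The
linear system is propagated *exactly* between sampling events through the
eigendecomposition of the 2×2 rate matrix (its sign structure guarantees a
real spectrum); a small-step explicit Euler integrator
(`simulate_transport_euler()`) exists purely as an independent cross-check
and agrees to well under 0.1% at 0.1 s steps. At each event the scheduled
volume is removed (recording the true sample concentration), blank medium
is added back, and the receiver concentration is diluted accordingly; the
terminal 2 h sample is drawn without replacement. Mass — donor plus
receiver plus everything removed — is conserved to floating-point
precision, because noise is applied to *observations*, never to the state.

Observation noise is multiplicative lognormal with unit mean and a
configurable CV (default 5%), the natural error model for LC-MS peak areas
whose variability is concentration-proportional. The same noise applies to
the dose measurement. The simulated TEER course is a logistic rise to a
~721 Ω·cm² plateau with midpoint near day 32 and a ~3-day time scale,
which reproduces barrier tightening at five weeks; simulated Ct tables put
reference genes near Ct 20 and spread target genes uniformly over Ct 22–34
with 0.25-cycle replicate noise, rendering a configurable gene subset
undetermined everywhere.

What the simulator deliberately omits: unstirred water layers,
membrane/filter retention, intracellular accumulation (a third
compartment), saturable transport, and pH/ionisation effects. Passing
recovery tests therefore shows the *estimator* is correct under the
two-compartment model, not that real monolayer data are free of those
phenomena.

## Known bias: donor depletion

The estimator divides the slope by the initial donor concentration, as the
standard formula prescribes. Over a 2 h window a fast substrate measurably
depletes a 0.5 mL donor (about 8% at $P_\mathrm{app} = 18 \times 10^{-6}$
cm/s on 0.3 cm²), and back-flux grows as the receiver fills, so the fitted
slope under-reports the true initial flux. The bias is downward and grows
with permeability: negligible below $1 \times 10^{-6}$ cm/s, about 1% at
$5 \times 10^{-6}$, and 3.5–4.6% at $18 \times 10^{-6}$ even with
noise-free data. This is a property of the estimator applied to any real
experiment of this design, not of the simulator; the recovery tests assert
a 2% envelope up to $5 \times 10^{-6}$ cm/s and a 5% envelope at the top of
the measured range, and `scripts/acceptance.R` recomputes the achieved
errors at run time.

## Numerical and design choices

- **Units.** Volumes mL, areas cm², culture time days, sampling time hours
  (converted to seconds only inside rate computations), concentrations
  tagged (`nM` ≡ pmol/mL, or `signal` per mL). nM × mL = pmol keeps the
  worked numbers human-readable.
- **Dilution factors** for donor solutions are computed from the declared
  stock compositions only; solvent topping-up between mixtures is not
  assumed. A solvent absent from every stock contributes 0%, not an error.
- **Ties and degenerate fits.** Sampling times are strictly increasing, so
  the "drop the earliest point" rule never faces a tie. A zero-variance
  response defines $R^2 = 1$ (a constant is a perfect line).
- **Gate ordering.** QC gating is applied to post-experiment TEER/leakage,
  retroactively excluding inserts from the permeability summary; pre- and
  post-experiment checks use the same `assess_barrier()`.
- **Determinism.** All simulators take integer seeds; identical
  configuration and seed give identical output, and `run_pipeline()` writes
  byte-identical result tables on reruns.

## Problem sizes

The test-suite and acceptance computations run at desk scale by design:
recovery uses 6 inserts per direction at four permeability levels
(0.3, 1, 5, 18 ×10⁻⁶ cm/s), the mass-balance oracle sweeps 1,000 random
schedules, the Euler cross-check integrates 7,200 s at 0.1 s steps, and the
expression fixture is the full 84 + 5 gene panel in triplicate. These sizes
make every check exhaustive for the model class while completing in
seconds.
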