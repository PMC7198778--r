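---
title: "Partitioning gross N2O production and consumption: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning gross N2O production and consumption: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2opart)
```

## The scientific problem

Net N2O emission from soil is the difference of two simultaneous microbial
processes: gross production (nitrification and denitrification up to N2O)
and gross consumption (reduction of N2O to N2 by nitrous oxide reductase).
Net flux measurements alone cannot tell whether a management practice that
raises emissions does so by producing more N2O or by reducing less of it,
and they say nothing about the temperature sensitivity of the two processes
separately. `n2opart` implements a complete desk-scale analysis pipeline for
microcosm studies that disentangle the two processes with the acetylene
(C2H2) inhibition design, estimate their temperature sensitivity, and relate
them to the community traits of the two clades of N2O reducers (nosZ clade
I, the canonical denitrifiers, and the "atypical" clade II).

## The acetylene partitioning estimator

Each fertilization x temperature x replicate cell is measured under three
headspace treatments for 24 h:

* 0 Pa C2H2 — undisturbed net rate, `r0 = P - C`;
* 10 Pa C2H2 — autotrophic nitrification blocked,
  `r10 = P(1 - f_nit) - C` where `f_nit` is the nitrification share of
  production;
* 10 kPa C2H2 — nitrification and N2O reduction both blocked,
  `r10k = P(1 - f_nit)`.

Differencing the paired rates of the same replicate gives the gross rates:

    consumption C = r10k - r10
    production  P = r10k - r10 + r0

so `production - consumption = net` holds exactly, per replicate, per cell
and in every bootstrap draw — the package treats this identity as an
invariant and tests it as such. The consumption/production ratio estimates
the denitrification product ratio N2/(N2O + N2).

Two aggregation modes are provided. The default, replicate-paired mode
computes the gross rates within each replicate and averages over
replicates; this absorbs shared field-plot (replicate) variation and is the
package's primary mode. The propagated mode computes the rates from
treatment-level means with standard errors combined in quadrature from the
contributing terms; it is retained as a documented alternative because both
conventions are in use.

### Inhibition-efficiency bias

The generator exposes inhibition efficiencies `eta_nit` (10 Pa) and
`eta_cons` (10 kPa). The bias algebra follows directly from the expected
rates above: imperfect consumption inhibition attenuates both estimators,
`E[C_hat] = eta_cons * C` and `E[P_hat] = P - (1 - eta_cons) * C`, while
imperfect nitrification inhibition biases *neither* gross estimator —
the nitrification term cancels between the 10 Pa and 10 kPa arms — but
attenuates the nitrification-share estimate, `E[r0 - r10] =
eta_nit * f_nit * P`. These closed forms are asserted against the generator
in the test suite. The package characterises this bias; it does not attempt
a mechanistic correction, which would require information the design does
not carry.

## Uncertainty: case bootstrap + Monte-Carlo noise

Because `P_hat = C_hat + r0`, the two estimators share sampling error, and
naive treatment-level standard errors overstate the confidence in their
difference. Inference therefore uses a case bootstrap over replicate
triplets within each cell, combined with additive Gaussian Monte-Carlo
measurement noise (`mc_sd`, in rate units) applied to each member rate of
each resampled triplet. Percentile intervals are reported, and pairwise
temperature contrasts within fertilization x day use the two-sided
bootstrap p-value `p = 2 * min(P(diff > 0), P(diff < 0))` with an add-one
correction, capped at 1. Defaults: `B = 1000`, percentile intervals, no
multiplicity adjustment (per-comparison reporting is the field convention
for the letter displays); Holm adjustment is available by flag. All
resampling is seedable and bit-reproducible.

Known limitation: the percentile bootstrap is an asymptotic procedure. With
n = 4 replicates per cell its two-sided size at nominal 5% is inflated
(roughly the t-versus-normal discrepancy at a handful of degrees of
freedom). The calibration suite therefore checks size and coverage in a
replicate-rich regime (n = 24-40 per cell, MC noise set to the known
measurement sd) where the method's first-order calibration applies, and
this caveat — not a claim of exact small-sample validity — is the package's
statement about the n = 4 study design.

## Temperature sensitivity (Q10)

Cumulative net emission over the incubation is computed by trapezoidal
integration of the net-rate series (day-0 rate extrapolated as the first
measured day's rate; a zero-at-day-0 alternative is available). Emissions
at 15/25/35 degC are fitted with the van't Hoff exponential
`R = alpha * exp(beta * t)` by ordinary least squares on the log scale, and
`Q10 = exp(10 * beta)`. The log-OLS fit is the default because it is exact
whenever the data lie on a true exponential (the package tests Q10 = 2
recovery on doubling data to machine precision); a raw-scale nonlinear fit
is available and agrees on noiseless data. Both pooled and per-replicate
fits are provided; group comparisons bootstrap the per-replicate Q10s.
Non-positive emissions are a hard error — the package never silently
offsets data to make logs defined.

## Community statistics

T-RFLP peak tables are processed with the standard cleaning rules: fragments
shorter than 50 bp are discarded (closed boundary: 50.0 bp is kept);
fragments are aligned by deterministic single-pass binning in which a bin is
seeded at the smallest unassigned length and collects everything in
`[seed, seed + 2 bp)`; bins present in no more than 2% of samples (strict
inequality) are dropped; heights (not areas) are summed within bins and
relativised within samples. Binning is seeded-single-pass because it is
deterministic and order-stable; re-processing an already-processed matrix
changes nothing (idempotence is tested). An optional minimum-height noise
filter is off by default since no threshold is standard.

Bray-Curtis dissimilarity, the permutation Mantel test (one-sided positive
association by default, matching the directional hypotheses of
community-rate coupling) and PERMANOVA are implemented in-package with
explicit permutation semantics: sampled p-values use the add-one
convention `(1 + #exceedances) / (permutations + 1)`, and the Mantel test
offers exhaustive enumeration over all `n!` relabelings for n <= 7, which
the test suite uses as an oracle. PERMANOVA follows the Gower-centred
inner-product formulation with sequential (Type I) terms and free
permutation of sample labels; it provably collapses to the classical
one-way ANOVA F on univariate Euclidean data, and the test suite checks
both that limit and agreement with `vegan::adonis2` to 1e-10. Bray-Curtis
is not metric; no triangle inequality is assumed anywhere. NMDS is not
implemented (it is visualization, with no numeric claims consumed
downstream); a principal-coordinates projection is provided for plotting.

## qPCR quantification

Standard curves are ordinary least squares of Cq on log10 copies;
amplification efficiency is `10^(-1/slope) - 1` (slope -3.3219 is a perfect
doubling). Quantification inverts the curve and scales by dilution, elution
/ template volume, and extracted dry mass. The elution volume is a required
parameter with no default — it is kit-specific and silently assuming one
would corrupt every abundance by a constant factor. A moisture fraction
converts the fresh extraction mass to a dry-mass basis so abundances share
units with the process rates. No-template behaviour is operationalised as
Cq absent or above a configurable cutoff (default 35), flagged per sample.
Simulated round-trips recover known copy numbers to machine precision.

## The synthetic study generator

No public dataset accompanies the underlying study design, so the package
ships a generator that emulates its statistical structure end to end: the
factorial design (3 fertilizations x 3 temperatures x 4 replicates, net
monitoring on days 1-30, acetylene campaigns on days 3/15/30), lognormal
replicate effects shared across the triplet of a field-plot replicate
(default CV 15%), additive Gaussian measurement noise (default 0.25 ng N
g^-1 d^-1), inversion of the ideal-gas flux arithmetic into headspace
concentration pairs, first-order NH4+/NO3- trajectories, Dirichlet T-RFLP
profiles whose concentration vectors shift strongly with fertilization for
nosZI and with sampling time for nosZII, and lognormal gene abundances with
treatment and time effects.

The default scenario's 27-cell truth table is calibrated once to the
anchors the design is known for: true consumption/production ratios span
0.48-0.75 with mean exactly 0.62; the CT regime's truth correlates
production with consumption at ~0.98; NPK's net-emission temperature
response (true Q10 ~1.75) clearly exceeds CT's (~1.21) while MNPK (~1.16)
is indistinguishable from CT; MNPK's gross rates peak at 25 degC; rates
decline over the incubation; and the NPK / 35 degC / day-15 cell carries a
large autotrophic-nitrification share (f_nit = 0.30 vs 0.05 elsewhere).
Between-replicate variance is unknowable from summary statistics alone, so
the replicate CV and noise sd were chosen so that the *estimated*
within-regime production-consumption correlation lands at ~0.98 — the
calibration the scenario is defined by.

What passing tests on synthetic data do and do not show: they demonstrate
that every algorithmic stage is correct (exact recovery at zero noise,
closed-form bias behaviour, oracle-equal permutation statistics) and that
the pipeline is well-calibrated under the generator's assumptions
(lognormal replicate effects, Gaussian measurement error, Dirichlet
profiles). Real T-RFLP data carry peak-calling artifacts, pseudo-replication
and detection limits the generator does not emulate, and real flux series
violate the 24-h linearity assumption to an unknown degree; results on real
data inherit those caveats.

## Numerical and design choices

* Units are fixed at ng N2O-N g^-1 dry soil d^-1 and carried in all CSV
  headers; whether literature rates are per dry or moist gram (and per hour
  or day) is often unstated, so the convention is made explicit here.
* Headspace volume defaults to bottle volume minus soil displacement at an
  assumed bulk density of 1.3 g cm^-3 (18 g soil in a 125 mL bottle gives
  0.1112 L), overridable per bottle.
* The ideal-gas conversion uses 28.013 g N per mol N2O; a 1000 ppbv mixing
  ratio in 0.1229 L at 298.15 K is 140.7 ng N.
* Negative gross estimates are flagged but never truncated in estimation
  (truncation biases means); only the nitrification share reports a
  zero-censored value alongside the raw one.
* Day-0 baseline samples are modelled as a separate arm with no temperature
  assignment; campaign bottles are fresh per campaign day by default, with
  a flag for the re-enclosure reading (`fresh_per_campaign = FALSE`).
* The total bottle count of the emulated design is never hard-coded; arms
  are enumerated independently and validated for balance.
* Printed nitrate-source percentages in the motivating literature are not
  always reproducible from their own printed concentrations; the package
  implements the stated formula `100 * (1 - initial_NH4 / delta_NO3)`
  (13.05 and 101 ug g^-1 give 87.1%, not 90%) and reports what the formula
  gives.
* Bootstrap statistics cover the rate family (production, consumption, net,
  ratio); Q10/beta inference uses the same resampling machinery through
  `compare_q10()` on per-replicate fits.

## Problem sizes

The shipped defaults are desk-scale by design: the default study is 540 gas
measurements, 120 community samples per gene with 40 T-RF bins, and 720
qPCR reactions; `B = 1000` bootstrap draws and 999-10000 permutations run
in seconds to a couple of minutes on one core. The calibration suites use
500 null repetitions per procedure with B = 399 draws / 199 permutations,
sizes at which the binomial error of an empirical size estimate at
alpha = 0.05 is about +/-0.029.
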