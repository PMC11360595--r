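---
title: "Methods: pollution indices and probabilistic health risk for ice-covered lakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollution indices and probabilistic health risk for ice-covered lakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`frozenrisk` assesses mercury and arsenic in the three stacked media of a
seasonally frozen lake — ice, under-ice water, sediment — and converts the
measurements into pollution indices, speciation-based mobility codes, and
human health risks, both deterministic and probabilistic. This vignette is
the package's account of the science: the models, the parameter choices, the
numerical conventions, and the limits of what the tests demonstrate.

## Data model

A measurement is one concentration at (site, medium, depth layer, element).
Layers are `[top, bottom)` intervals in centimetres measured downward from
the medium's upper surface, in 5-cm slices as stratified field sampling
produces them. Units are bound to media: ice and water concentrations are
per-litre (ng/L, ug/L, mg/L), sediment is mg/kg, and the two families never
convert into each other — a mass-per-mass value has no volume basis, so
requesting such a conversion is an error rather than a silent pass-through.
Element and medium vocabularies are closed; unknown values are rejected at
the reading boundary with the offending row number.

Speciation records carry the four BCR sequential-extraction fractions of a
sediment layer: acid-extractable (F1), Fe/Mn-oxide-bound (F2),
organic/sulfide-bound (F3), residual (F4), as masses in mg/kg. F1–F3 are
the convertible fractions that can remobilise into overlying water; F4 is
inert.

## Pollution indices and their class scales

**Single-factor index.** `Pi = Ci / Si` with the irrigation-water quality
limits `Si` = 1 ug/L (Hg) and 50 ug/L (As) as the packaged defaults (they
live in the configuration document, not in code). Classes: clean (`< 1`),
slight (`[1, 2)`), moderate (`[2, 3)`), severe (`>= 3`).

**Geo-accumulation index.** `Igeo = log2(Cn / (K * Bn))` with `K = 1.5`
absorbing natural background fluctuation and `Bn` the regional sediment
background (0.025 mg/kg Hg, 9.68 mg/kg As). The seven-class scale is
conventionally printed with overlapping bounds; the package fixes it as
half-open intervals, lower bound inclusive above the first class:
`(-Inf, 0]`, `(0, 1)`, `[1, 2)`, `[2, 3)`, `[3, 4)`, `[4, 5)`, `[5, Inf)`.
This matches every published classification we reproduce and removes the
ambiguity at the integer boundaries. `Cn = 0` has no finite logarithm; it
raises an error unless the caller opts into a `-Inf` "below scale"
sentinel.

**Risk assessment code.** `RAC = 100 * F1 / (F1 + F2 + F3 + F4)` percent.
The conventional class list (no risk `< 1%`, low `1–10%`, medium `11–30%`,
high `31–50%`, extremely high `> 50%`) leaves `(10, 11)` unassigned; the
package adopts the contiguous scale `[0, 1)`, `[1, 10]`, `(10, 30]`,
`(30, 50]`, `(50, 100]`, which agrees with how published per-layer values
in the 10.5–15.8% range are classed as medium risk.

**Sediment quality guidelines.** Below TEL: rare biotoxic effects; between
TEL and PEL, bounds included: occasional; above PEL: frequent. Thresholds
(mg/kg): Hg 0.17/0.48, As 5.90/17.0.

Every classifier is a pure function of the index value, so stored labels
can always be re-derived from stored values — a property the tests assert
on all fixtures.

## Deterministic exposure model

Drinking water is the only exposure route modelled; for these metals it
dominates dermal and inhalation by orders of magnitude. The dose equation
is

```
ADD = C * IR * EF * ED / (BW * AT)     [mg/kg/d]
```

with `C` in mg/L (enforced by explicit unit conversion), intake rate `IR`
(L/d), exposure frequency `EF` (d/a), duration `ED` (a), body weight `BW`
(kg) and averaging time `AT` (d). Carcinogenic risk `CR = ADD * SF` with
`SF = 1.5 (kg d)/mg` for As; hazard quotient `HQ = ADD / RfD` with
`RfD = 3e-4 mg/kg/d` for Hg; `HI = sum(HQ)`, which is Hg-only here and so
equals the single HQ. Thresholds are strict: `CR` above `1e-4` is
unacceptable, `HQ`/`HI` above 1 flags non-carcinogenic concern; values
exactly at threshold classify as acceptable.

Two parameter choices deserve explanation, because the conventional
defaults for this population are internally inconsistent:

* **Child intake rate.** The literature default for this region quotes
  0.7 L/d for children, but every published child risk value we reproduce
  is consistent with 1.0 L/d and inconsistent with 0.7. The package
  defaults to 1.0 L/d; 0.7 remains available as an explicit override
  (`exposure_parameters("child", IR = 0.7)`).
* **ED/AT pairing.** The published adult values imply `EF * ED = AT`
  (365 d/a x 70 a = 25550 d) in both the carcinogenic and the
  non-carcinogenic context, and the child non-carcinogenic values imply
  `ED = 10 a` with `AT = 3650 d`, although a 30-year non-carcinogenic
  duration is sometimes quoted. The defaults follow the values the
  published results are computed from; all of them are plain fields of
  `exposure_parameters()` and of the YAML configuration, so any other
  convention is one override away.

Because `EF * ED = AT` for the adult defaults, the dose collapses to
`C * IR / BW` — a closed-form check the tests exploit.

## Monte Carlo model

The probabilistic model replaces point exposure factors with
distributions (defaults in `inst/extdata/default_config.yml`):

| symbol | adult | child | units |
|---|---|---|---|
| BW | log-normal (59.78, 1.07) | log-normal (16.68, 1.48) | kg |
| IR | log-normal (1.23, 0.27) | log-normal (1.12, 0.27) | L/d |
| ED | uniform (0, 70) | uniform (0, 10) | a |
| EF | triangular (180, 350, 365) | same | d/a |
| AT | point 25550 (carc.); 25550 / 3650 (non-carc. adult / child) | | d |
| C  | log-normal per element and medium: Hg ice (7.90, 4.35) ng/L, As ice (2.48, 3.22) ug/L, Hg water (0.37, 0.23) ug/L, As water (5.72, 1.70) ug/L | | |

Log-normal pairs are read as **arithmetic** mean and standard deviation and
moment-matched to the log scale (`sdlog^2 = log(1 + s^2/m^2)`,
`meanlog = log(m) - sdlog^2/2`). This reading matters: with it, the
closed-form product of means

```
E[CR] = SF * E[C] * E[IR] * E[EF] * E[ED] * E[1/BW] / AT
```

(`E[1/BW]` from the log-normal closed form) reproduces the published
simulated means; a log-scale `(mu, sigma)` reading does not come close.
The analytic mean is implemented as `analytic_mean_risk()` and serves as an
independent oracle in the tests: the simulated mean must agree with it
within three standard errors, at the defaults and across randomised
configurations.

Sampling is independent across symbols (no correlation structure is
asserted by the data), `ED`'s uniform lower bound of 0 is sampled as-is —
a zero-duration draw is a legitimate zero-risk iteration, not something to
truncate — and the triangular sampler uses the inverse CDF (no triangular
family ships with base R). All admissible families are non-negative; a
configuration that could produce negative draws raises an error rather
than clamping silently. Default iterations are 10,000; the package's own
reproduction runs use 100,000 to shrink Monte Carlo error. Summaries use
empirical quantiles with linear interpolation (R's default type 7), and
exceedance probabilities count draws strictly above the threshold.

Everything stochastic is a pure function of (configuration, seed):
identical inputs give bit-identical outputs.

## Sensitivity analysis

`contribution_to_variance()` follows the convention of the commercial risk
packages this analysis is usually run in: the Spearman rank correlation of
each sampled input with the output, squared, normalised over the varying
inputs to sum to exactly 100%, signed by the direction of association.
Point inputs report 0. A plain binned first-order variance estimate
(`binned_variance_contribution()`) is included as an independent
cross-check, not a replacement.

Which input dominates is a function of the input CVs on this multiplicative
model. With the default distributions, exposure duration `ED`
(CV 0.577) dominates every endpoint except As in ice, where the
concentration's CV (3.22/2.48 = 1.30) is larger and `C` leads. The
published sensitivity figures for carcinogenic risk (~79% for `ED`) match
the **water** pathway, where the concentration CV is 0.30 — and our water
numbers land within a couple of points of them, as do the Hg-in-ice
figures. The acceptance test therefore asserts the `ED`-dominance claim on
the water endpoint; the ice-As endpoint is concentration-dominated by
construction, which is itself informative: for that medium, measuring `C`
better buys more risk-estimate precision than refining exposure factors.

## Synthetic data generator

The generator emulates the marginal statistical structure of a stratified
winter campaign on a 10-site lake, with every default chosen from the
published study conditions: 5-cm layers; ice 40–60 cm; water columns
80–150 cm; sediment cores of 2–5 layers with the observed core-length
frequencies; between-site log-normal concentration distributions with the
published arithmetic means/sds for ice and water and the published sediment
means. Site-level structure is

```
layer value = site mean * profile multiplier * log-normal noise (mean 1, CV 0.2)
```

with profile multipliers normalised to mean 1 within each site so that the
configured between-site distribution is recovered unbiasedly (a 3-SE
recovery test at 10,000 sites). Ice uses a triangular enrichment bump
peaking at 30 cm (the middle of the 20–40 cm band where observed profiles
peak), water a two-segment piecewise-linear profile flat above a 35-cm
inflection and rising to a 1.8x bottom multiplier — the simplest shapes
satisfying the qualitative descriptions. Speciation splits each sediment
layer's total by Dirichlet proportions centred on the published fraction
means (Hg 8.0/13.4/26.8/51.6%, As 1.1/9.8/0.6/89.4%) with concentration
parameter 50; `Inf` collapses to the exact means.

Assumptions to be aware of: the between-site sediment standard deviations
(0.020 mg/kg Hg, 2.40 mg/kg As) are not published anywhere and were chosen
once so that site means span the published geo-accumulation range; and the
generator mimics marginal structure only — no freeze rejection, diffusion,
inter-element correlation, or spatial autocorrelation. Passing tests on
synthetic data therefore demonstrate that the pipeline's statistics recover
known inputs, not that real lake data satisfy the generator's independence
assumptions.

## Problem sizes and numerical conventions

The package's own verification runs use 100,000 Monte Carlo iterations per
endpoint and 10,000 synthetic sites for recovery checks; both complete in
seconds because every stage is vectorised. Values are stored at full double
precision and rounded only for display (indices to 3 decimals, percentages
to 1). Degenerate inputs fail loudly by design: empty files, all-zero
speciation fractions, zero-variance sensitivity outputs, and zero
concentrations in the log-based index all raise informative errors instead
of propagating NaN.

## Limitations

* Drinking water is the only exposure route; no dermal/inhalation terms,
  no age-interpolated lifetime cancer risk.
* The hazard index sums over a single element (Hg), so HI = HQ here.
* No ecological risk aggregation (Hakanson RI) or pollution load index.
* The Monte Carlo engine deliberately omits variance-reduction and
  correlated sampling; with 1e5 iterations plain sampling is cheap enough.
* Published medians and 95th percentiles of the simulated distributions
  depend on distribution-shape details of the original software that are
  not fully disclosed; the package checks them as tolerance bands, not
  exact targets.
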