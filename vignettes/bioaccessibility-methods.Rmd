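---
title: "Methods: dialyzability-based bioaccessibility of trace elements in herbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dialyzability-based bioaccessibility of trace elements in herbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbdial)
```

## The measurement model

A dialyzability study digests a weighed herb sample in two enzymatic
stages (pepsin at gastric pH, then pancreatin/bile at intestinal pH)
inside a cellulose dialysis tube immersed in water. Low-molecular-weight
solutes — the proxy for what the intestinal villi could absorb — cross
the membrane into the dialysate; everything else stays in the tube. Two
fractions result per sample: the **dialyzable** fraction (outside the
tube) and the **nondialyzable** fraction (tube residue), both quantified
by ICP-MS alongside the **total** content of an undigested aliquot.

All package computations sit downstream of the wet chemistry: solution
concentrations (ng/mL) become per-gram contents via
`content_per_gram()` (c·V·f / (m·1000), μg/g), and per-vessel amounts
via `amount_in_fraction()` (content × sample mass). Default masses are
2.5 g (fresh, dried, supplement) and 0.5 g (lyophilizate, equivalent to
2.5 g fresh); default volumes are 15 mL pepsin solution, 5 mL
pancreatin/bile solution and 60 mL dialysate. The in-tube volume is not
directly observable; we take V_t = 15 + 5 = 20 mL — the only quantified
in-tube liquid additions — and ignore the bicarbonate titrant and sample
moisture. V_t is a plain parameter of `digestion_setup()`, so a user
with a measured tube volume can supply it.

## The bioaccessibility statistic

Let D be the dialyzable amount (μg), T the nondialyzable amount, and

$$D_r = D \cdot \frac{V_t}{V_d}$$

the amount of dialyzable species still *inside* the tube when
concentrations have equilibrated across the membrane: if D equilibrated
into V_d mL outside, the same concentration occupies V_t mL inside.

The package implements three algebraic forms of B% because D, D_r and T
admit more than one defensible combination, and published descriptions
of the corrected statistic do not always pin the algebra down:

* `corrected_share` (default): $B = 100\,(D + D_r)/(D + T)$. D_r is
  physically part of the residue T but is chemically dialyzable — it
  simply had nowhere left to go at equilibrium — so it counts toward the
  bioaccessible share. This is the only reading under which the
  correction raises B, which is what an "equilibrium correction" is for.
* `literal`: $B = 100\,D/(D_r + T)$.
* `uncorrected`: $B = 100\,D/(D + T)$ — the plain dialyzable share, the
  form whose ground truth in a synthetic study is exactly 100 p.

The choice is a genuine modelling decision, so the variant is mandatory
metadata on every result and survives the report writers; nothing in the
package ever silently defaults across variants. When D_r ≤ T the
corrected share cannot exceed 100 %; a value above 100 % indicates a
mass-balance inconsistency and raises a warning rather than a clamp.

SD on B is propagated by relative quadrature from the fraction-content
SDs; volume uncertainty is ignored (volumes are pipetted, contents are
the dominant noise source).

## Mass balance

Per cell, agreement (%) = 100·(D_content + T_content)/total_content,
with SDs combined in quadrature for the sum and relative quadrature for
the ratio. Agreements within [80, 120] % are flagged quantitative. A
below-LOQ fraction makes the balance *unavailable* — the cell is
reported blank and warned about, never imputed. Note that published
tables of this kind compute agreement from unrounded replicate data;
recomputing from rounded printed contents can differ by up to about one
percent, which is why the package's tests compare printed agreements
under interval arithmetic on the printed precision.

## Calibration and validation

Calibration is ordinary least squares of the analyte/internal-standard
signal ratio on concentration (`fit_calibration()`, via `lm()`), with
Pearson r as the linearity figure of merit. The internal standard
concentration is metadata; only the ratio enters the model. Weighted
regression and drift correction are out of scope.

LOD and LOQ read the blank mean + 3·SD (resp. 10·SD) signal through the
curve and are floored at zero. Only the "+" branch of blank ± 3 SD is
meaningful for a detection threshold. Predicted concentrations may be
negative (sub-blank signals); they are censored only at the reporting
boundary (`censor_below_loq()` keeps the numeric value), preserving
unbiasedness of downstream averages.

Repeatability CV pools all day × replicate CRM determinations into one
sample SD over the mean — the simplest reading of "expressed as the
CV" — with a `day_means` option for the stricter between-day variant.
Sample SDs use n − 1 everywhere. The trueness t-test takes its critical
value as a parameter (default 2.776); we deliberately do not resolve the
df convention behind that default, since published validation tables
sometimes quote df = 4 critical values for n = 3 recoveries.

The expanded uncertainty budget is U = k·√(u²(repeat.) + u²(R)) with
k = 2 and u(R) the standard error of the mean recovery. Published U
values for this kind of table are generally not reproducible from the
printed repeatability and recovery columns alone (the combined formula
may include bias terms); the package therefore computes its own budget
and asserts nothing against printed U values.

## Exposure and nutrition indices

All indices are linear in content and intake and inverse-linear in body
weight:

* PTMI% = 100·(content/1000 · intake · 30 / bw)/PTMI — a month is 30
  days, which reproduces the printed cadmium endpoint (115 ng/g →
  0.23 %).
* BMDL% = 100·(content/1000 · intake / bw)/BMDL, keyed by toxicological
  endpoint (Pb: kidney 0.63, cardiovascular 1.50 μg/kg/day).
* RDA% = 100·content·portion/RDA, keyed by sex.

The registry ships as an editable YAML (`reference_doses()`), so updated
regulatory values can be dropped in without code changes. Report
rounding is half-up at 2 significant figures (`signif_half_up()`),
matching the endpoint style of published summaries (19, 32, 0.23);
machine outputs always retain full precision. Risk is computed from
total contents, not bioaccessibility-adjusted contents — the
conservative convention for contaminants.

## Total phenolic content

TPC reuses the calibration machinery on a gallic-acid standard curve
(20–300 μg/mL, absorbance at 752 nm): c = (A − a)/b, then
TPC = c·f·V/(m·1000) mg GAE per g with the 50 mg / 5 mL extraction
defaults and 10-fold dilution for concentrated (non-fresh) extracts.
Predictions outside the standard range are flagged extrapolated rather
than refused. Fresh-herb TPC stays on a wet-mass basis (water dominates
fresh masses); `dry_basis()` converts when comparing across forms.

## The synthetic-study generator

`generate_study()` emulates the full measurement design: for each
(herb, form, element) cell with true total content and true dialyzable
fraction p, the latent D = p·total and T = (1 − p)·total are conserved
by construction; observed replicate contents add mean-preserving
multiplicative log-normal noise (σ_log from the CV; contents are
positive with roughly constant relative SD, which additive Gaussian
noise would violate at the low end). Calibration signals pass through a
latent line with relative noise; blanks are additive Gaussian; CRM
determinations scatter around certified values; TPC absorbances come
through the inverse assay chain.

Defaults are the study conditions: triplicates, per-element CVs of
3.7–9.9 % (the repeatability range), the printed per-cell totals and
fraction shares as latent truth, and certified CRM contents. The seed is
part of the configuration, and a fixed config regenerates the observed
block bit-identically.

What the generator does **not** emulate: membrane transport kinetics
(only the equilibrium endpoint is parameterized), matrix-dependent
interferences, between-day drift, and correlated noise between fractions
of the same vessel. Passing parameter-recovery tests therefore shows the
arithmetic chain is unbiased and correctly propagates independent
replicate noise — not that the digestion protocol itself is accurate.

## Numerical choices and edge cases

* Flat calibration responses get an exactly zero slope and are flagged
  non-quantitative; inverse prediction on them errors.
* CVs are undefined at zero mean (error, not NaN).
* A zero-SD recovery sample off the reference gives an infinite t and an
  automatic trueness fail.
* F statistics are larger-over-smaller variance, so F ≥ 1 and the test
  is symmetric in its groups; critical values (19.00, 2.776) are inputs,
  reproducing published decisions even where their df conventions are
  unstated, with distribution-based p-values as supplementary output.
* Uncertainty-range overlap uses closed intervals; boundary contact
  counts as overlap.
* `dialyzable_share(0, 0)` and zero-denominator bioaccessibility error
  explicitly.

## Problem sizes

The test suite and acceptance script use the study-scale design
throughout: the 59-cell panel (three herbs × four forms × five
elements, one censored cell), triplicate measurements, 100 random
instances for oracle-agreement checks, 500 generator seeds (200 in the
acceptance script) for the CV-5 % recovery property, and 2000 simulated
pairs for the t-test pass rate.

## Known limitations

* The corrected-share default is a modelling commitment, not a settled
  convention; cross-study comparisons should state the variant.
* Censored cells are excluded, not modelled; no maximum-likelihood
  treatment of <LOQ values is attempted.
* SD propagation assumes uncorrelated errors between fractions, which
  understates covariance from shared digestion vessels.
* Correlation analyses operate on whatever pairing the caller supplies;
  the package does not decide whether forms or replicates are the unit.
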