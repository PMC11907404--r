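# herbdial

Analysis toolkit for in vitro gastrointestinal **bioaccessibility of trace
elements in culinary herbs** (basil, peppermint, rosemary — fresh,
lyophilized, dried, and as dietary supplements), measured by ICP-MS after
a two-stage enzymatic digestion with an artificial dialysis membrane.

The package is written for analytical chemists and food scientists who run
dialyzability studies: it covers the computational side of the workflow
from instrument signals to health-risk statements, and ships a
ground-truth synthetic-study generator so the whole pipeline is testable
without instrument data.

## What it computes

* **Calibration & method validation** — internal-standard-ratio
  calibration curves (y = bx + a, Pearson r), LOD/LOQ from blank
  statistics (blank mean + 3·SD resp. 10·SD through the curve), precision
  CV ranges, pooled repeatability CV, CRM recovery with a trueness
  t-test, and a k-expanded uncertainty budget
  U = k·√(u²(repeat.) + u²(R)).
* **Fraction accounting & mass balance** — per-gram contents from
  solution concentrations, per-vessel amounts, and the agreement check
  agreement (%) = 100 · (dialyzable + nondialyzable) / total, with
  quadrature SD propagation and a [80, 120] % quantitative window.
* **Bioaccessibility** — the dialysis-equilibrium-corrected statistic.
  With D the dialyzable amount (μg), T the nondialyzable amount, and
  D_r = D · V_t / V_d the in-tube amount at membrane equilibrium
  (tube volume V_t = 20 mL, dialysate V_d = 60 mL by default), the
  default form is

      B% = 100 · (D + D_r) / (D + T)

  with `literal` (100·D/(D_r+T)) and `uncorrected` (100·D/(D+T))
  variants as first-class alternatives; every result carries its variant.
* **Exposure & nutrition indices** — PTMI% (Cd), BMDL% (As, Pb by
  endpoint), RDA coverage (Mn, Fe, Cu, Zn by sex), EU limit checks, for a
  configurable scenario (default: 60 kg adult, 1 g/day, 25 g pesto
  portion).
* **Total phenolic content** — Folin–Ciocâlteu gallic-acid-equivalent
  quantification with extraction/dilution accounting.
* **Statistical comparisons** — one-tailed F test, pooled two-sample
  t-test, Pearson correlation, expanded-uncertainty range overlap.
* **Synthetic studies** — `generate_study()` draws full observed blocks
  (fraction replicates, calibration signals, blanks, CRM, TPC
  absorbances) from known ground truth for parameter-recovery testing.

## Worked example

Copper in fresh rosemary, from the shipped study table (contents in μg/g,
n = 3):

```r
library(herbdial)
hp  <- herb_panel()
rec <- hp[hp$herb == "rosemary" & hp$form == "fresh" & hp$element == "Cu", ]

mb <- mass_balance(rec$dialyzable, rec$nondialyzable, rec$total,
                   rec$sd_dialyzable, rec$sd_nondialyzable, rec$sd_total)
#> sum 0.70 +/- 0.02 ug/g, agreement 107.7 +/- 6.0 %

bioaccess_table(rec)
#>       herb  form element   D   D_r T_amount  B sd_B censored         variant
#> 1 rosemary fresh      Cu 0.8 0.267     0.95 61 2.72    FALSE corrected_share
```

The fractions recover 107.7 % of the independently determined total —
inside the 80–120 % quantitative window, so no analyte was lost or
gained during digestion. Of the copper recovered, 0.80 μg dialyzed
through the membrane; adding the 0.27 μg still inside the tube at
membrane equilibrium gives a bioaccessibility of 61 ± 2.7 % under the
default corrected-share form.

Exposure indices from the maximal printed contents:

```r
ptmi_percent(115, "Cd")                    # 0.23  (% of PTMI, 60 kg adult, 1 g/day)
bmdl_percent(1148, "As", "skin_cancer")    # 31.9  (% of BMDL)
rda_percent(46.7, "Mn", "women", portion_g = 25)  # 64.9 (% of RDA, pesto portion)
```

A full synthetic run:

```r
st  <- generate_study(generator_config(seed = 1))
res <- run_pipeline(st$observed$fractions)
#> Bioaccessibility pipeline result: 59 cells, variant 'corrected_share'
#>   quantitative mass balance: 59 of 59 available cells
#>   no warnings
```

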