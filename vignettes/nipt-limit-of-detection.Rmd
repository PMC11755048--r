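---
title: "Fetal-fraction limits of low-depth NIPT: the models behind niptsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fetal-fraction limits of low-depth NIPT: the models behind niptsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptsim)
```

## The screening problem

Non-invasive prenatal testing (NIPT) screens for fetal trisomies by
shallow whole-genome sequencing of cell-free DNA (cfDNA) from maternal
plasma. Only a minority of that cfDNA — the *fetal fraction* (FF),
placental in origin — carries the fetal genotype. A trisomy-21 fetus adds
half an extra dose of chromosome 21 per fetal genome-equivalent, so the
expected share of reads mapping to chr21 is lifted by the factor

$$1 + \mathrm{FF}/2,$$

a relative excess of only 0.25% at FF = 0.5%··· 5% at FF = 10%. Whether
that excess is detectable against counting noise and run-to-run variation
is the central question for low-depth, PCR-free protocols: at roughly
1.5 million unique 45 bp single-end reads per sample (≈ 0.0195× coverage
after discarding the 6 bp barcode), the detection limit sits near FF = 5%,
and clinical cohorts contain a few percent of pregnancies below it —
disproportionately women of higher body weight, whose larger plasma volume
dilutes the placental signal.

`niptsim` implements that entire reasoning chain as a seeded, testable
pipeline: a generative read-count model, the z-score caller with its QC
gates, chrY-based FF estimation, an in-silico dilution/limit-of-detection
(LoD) experiment, fragment-length mixtures, and the cohort analytics that
relate FF to maternal weight and gestational age.

## The generative read-count model

A sample's reads are allocated over chr1–chr22, chrX, chrY by a single
multinomial draw of the read budget from a weight vector:

* baseline weights proportional to GRCh38 chromosome lengths (no
  mappability or GC weighting; a custom length vector can stand in for
  either);
* for a male fetus, the chrY weight is replaced by
  $p_Y \cdot \mathrm{FF} + b$, where $b$ (default $5\times10^{-4}$) is the
  female mis-mapping background — a female-fetus pregnancy keeps only $b$;
* the trisomic chromosome's weight is multiplied by
  $1 + \mathrm{FF}/2$;
* the vector is renormalised.

### Overdispersion and its calibration

Real runs vary more than multinomial sampling allows. We model the excess
as a per-sample gamma jitter of the weight vector with coefficient of
variation `overdispersion_cv`, giving a total ratio SD of approximately

$$\sigma_{\text{tot}}(r) = \sqrt{\frac{r(1-r)}{N} + \big(\mathrm{cv}\cdot
r(1-r)\big)^2}.$$

No direct estimate of the inter-run CV is available for this protocol; the
published LoD pattern — 50% detection in the 4–5% FF bin, 100% above 5% —
is the one constraint it leaves on the variance. We therefore calibrate
`overdispersion_cv` analytically so that the *expected* chr21 z score of a
T21 sample equals 3 at FF = 4.5% (the bin midpoint) under the default
budget. With GRCh38 lengths this lands at ≈ 0.35% extra CV, ≈ 0.75% total.
This calibration is an inference from the detection pattern, not a
measured quantity, and everything downstream of it (detection rates near
the limit) inherits that status.

Two second-order effects are deliberately left outside the analytic
calibration: the mixed-sex reference panel adds a small between-sex
component to the chr21 ratio SD (chrY reads renormalise the other
chromosomes; ≈ 0.1% CV), and a 412-sample panel estimates its SD with
≈ 3.5% relative error. Together they move the simulated 4–5%-bin detection
rate by a few points around 50% depending on the panel seed — visible in
the acceptance checks, which allow ±10 points for this quantity.

## The caller

The reference panel stores, per chromosome, the mean and (n−1) SD of the
chromosomal read ratio over euploid pregnancies (412 by default). A test
sample's z score is $(r - \mu_c)/\sigma_c$; **z ≥ 3 flags high risk**
(boundary inclusive). Two QC gates precede any call: fewer than 1.5 M
unique reads voids the sample (`insufficient_reads`), and a known FF
strictly below 3.5% raises `low_ff_alert` (FF exactly 3.5% passes; the
alert recommends blood re-collection and suppresses calls). Chromosomes
13, 18 and 21 are scored by default; any autosome can be requested.

FF itself comes from chrY for male fetuses: the chrY ratio is linear in FF
between the female background and the pure-male-genome ratio, and the
estimator inverts that line, clipping to [0, 1]. Both anchors default to
the simulator's own weights, making the estimator consistent with the
generative model up to renormalisation — the residual round-trip bias is
about +0.2 percentage points at FF = 10%, within the package's stated
±0.3-point contract. Proprietary FF models for *female* fetuses are out of
scope: female-fetus samples carry FF as metadata (known in simulation),
and the limitation is inherited by any analysis of real female-fetus data.
Fetal sex is confirmed when chrY's z against a female-only panel strictly
exceeds 15.

## The dilution and LoD experiment

Artificial mixtures dilute a T21 male library (concentration $C_1$, volume
$V_1$, fetal fraction $\mathrm{FF}_1$) with a euploid female library
($C_2$, $V_2$):

$$\mathrm{Expected\ FF} = \frac{C_1 V_1 \cdot \mathrm{FF}_1}
{C_1 V_1 + C_2 V_2}.$$

In silico, the mixture's weight vector is the mass-weighted average of the
two source vectors, so the chr21 lift and the chrY signal both scale to
the expected FF automatically. The LoD experiment draws target FFs
uniformly within each bin of the dilution design — <3%, 3–4%, 4–5%, 5–6%,
>8% (6–8% intentionally unsampled, mirroring the bench design; the
open-ended top bin draws from 8–15% by default) — solves the diluent
volume for each target, sequences and classifies each mixture, and tallies
chr21 detections. The reported LoD is the lowest bin at and above which
detection is 100%, *contiguously*: an isolated 100% bin below a failing
bin does not qualify. Sub-3.5% mixtures are QC-gated exactly as production
samples would be and count as not detected.

The bench experiment used six replicates per bin; whether those were six
distinct source patients or re-dilutions of the same positives is not
knowable from the design, and at the level of this simulator the two are
identical (each replicate draws fresh noise), so no switch is exposed.

## Fragment lengths

Fetal cfDNA runs shorter than maternal cfDNA: modal lengths 143 bp versus
166 bp. Lengths are drawn from a two-component mixture weighted by FF;
each component is a log-normal parameterised by its mode, with spread set
so the full width at half maximum is ≈ 20 bp (electropherogram-like
traces are published as figures, not distributions; log-normal gives the
right mild right skew for nucleosome-protected fragments). The *zone area
ratio* — the fraction of fragments inside a window bracketing the fetal
peak — uses [120, 155] bp by default: the published figure does not print
its zone bounds, so we chose the window that contains the 143 bp mode and
excludes 166 bp. The ratio's normalisation (total trace area) is likewise
our choice. Note the mixture's component spreads overlap: at 1 bp bins the
two integer bins adjacent to each mode differ by less than sampling noise
at n = 10⁵, so an empirical mode of 143 ± 1 or 166 ± 1 is the honest
contract.

The published group comparison at n = 5 found *no significant* zone-ratio
difference; the package therefore asserts monotonicity of the mean ratio
in FF at large simulated n, and makes no significance claim at n = 5.

## The synthetic cohort

`generate_cohort()` draws maternal weight ~ TruncNormal(56, 8) on
[40, 110] kg, gestational age (GA) ~ TruncNormal(16.5, 3) on [12, 40]
weeks, maternal age ~ TruncNormal(30.9, 4), fetal sex Bernoulli(0.5),
twins at 1.2% (flag only — no twin dosage model). FF follows a
per-GA-stratum line on the percent scale,

$$\mathrm{FF}\% = a_s + b_s\,w + \varepsilon,\qquad
\varepsilon \sim N(0, 3),$$

truncated to [0, 50]%. The default lines are anchored where the clinical
analysis put the 5% FF crossings — slope −0.12 %/kg in all three strata
(12–19, 20–22, ≥23 weeks) with intercepts fixed by crossings at 96, 93 and
162 kg respectively. Those anchors reproduce the qualitative GA profile
(flat to 19 weeks, slight dip at 20–22, rise from 23) and a negative
weight–FF correlation of r ≈ −0.28 at the default noise. They are the
generator's stated world: cohort-specific statistics of the original
clinical data (e.g. its median FF of 11.73%) are **not** targets and are
not reproducible without those data — a green cohort test establishes that
the analytics recover what the generator put in, nothing more.

Cohort analytics mirror standard practice: Welch's unpaired t test by
default (a pooled-variance switch exists, since the original analysis does
not specify), Pearson correlation for the weight–FF regressions, and
inverse prediction $w^\ast = (5 - a)/b$ for the 5%-crossing weight. The
"near the median" comparison group is undefined in the original analysis;
we default to FF within ±1 percentage point of the cohort median
(configurable). Inverse prediction reports the point estimate and warns
when the crossing extrapolates beyond the observed weights — which it does
by design in realistic cohorts (96 kg is far above the 56 kg mean), so the
warning marks honest extrapolation rather than an error.

## Numerical and interface choices

* **Seeds.** Every generator takes a mandatory seed; pipelines derive
  stage seeds from one top-level integer via `child_seed()` (a fixed LCG
  step, staying within 32-bit range). Identical seed ⇒ byte-identical
  output.
* **Boundaries.** z ≥ 3 is high risk (inclusive); FF < 3.5% alerts
  (exclusive); chrY z > 15 confirms male (strict); GA bins and strata are
  half-open [lo, hi).
* **"1.5 Mb"** of unique reads is read as 1.5 million reads, consistent
  with the 0.0195× depth arithmetic (1.5 M × 39 bp / 3 Gb), not 1.5
  megabases.
* **GA notation.** "17+3" parses as 17 + 3/7 ≈ 17.43 decimal weeks.
* **Degenerate inputs.** Zero-SD panels, single-profile references,
  zero-mass mixtures, empty length samples and constant covariates all
  raise informative errors (or warnings where a value is still
  defensible, e.g. a positive weight–FF slope).
* **Config files** are JSON (mandatory `seed`); tables are TSV with
  schema validation that names the missing column.

## Known limitations

* No GC or mappability bias, no mosaicism (the model cannot produce the
  confined-placental-mosaicism false negative seen clinically at
  FF = 8.13%), no raw reads or alignment.
* The overdispersion default is an inference from a published detection
  pattern, not a measurement; protocols with different library chemistry
  need recalibration.
* FF for female fetuses is metadata, not an estimate.
* Physical pooling constraints (95-plex pools, ≥10 pM libraries, 3 pM
  loading) surface only as QC warnings, not as simulation physics.
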