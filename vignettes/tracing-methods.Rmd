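---
title: "Carbon-resolved glucose tracing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon-resolved glucose tracing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotrace)
```

## The labeling model

`glucotrace` follows a positional ¹³C tracer on glucose through an
atom-mapped network of glycolysis and the TCA cycle. The state is a
*positional isotopomer pool*: a set of per-carbon label masks with
probability weights summing to one. Reactions are carbon maps — each
substrate carbon either moves to a named product position or is released as
CO₂ — and a reaction application is exact bookkeeping, not simulation:
product masks are assembled position by position, condensations take the
product measure of the substrate pools, and the weights of identical masks
are merged.

Model assumptions, each of which matters for the derived ion masses:

* **Triose phosphate isomerase equilibrates the trioses completely.** The
  pyruvate pool is the equal mixture of the two aldolase halves of glucose.
  For a uniformly labeled tracer this is invisible (both halves are fully
  labeled); for positional tracers such as [1,2-¹³C]glucose it produces the
  familiar 50 % M+2 / 50 % M+0 pyruvate pool.
* **Pyruvate dehydrogenase removes pyruvate C1**, so the acetyl group
  carries the old pyruvate C2/C3 — a uniformly labeled tracer yields
  [1,2-¹³C]acetyl-CoA.
* **Aconitase and isocitrate dehydrogenase are stereospecific.** The CO₂
  released at the IDH step derives from the oxaloacetate C1 carboxyl, and
  the one at the 2-oxoglutarate dehydrogenase step from the oxaloacetate C4
  carboxyl. Acetyl-derived carbons therefore survive to succinate in the
  first turn, which is what makes every first-turn intermediate M+2 and the
  first-turn CO₂ unlabeled.
* **Succinate and fumarate are 2-fold rotationally symmetric.** Each mask is
  replaced by an equal mixture of itself and its reversal (idempotent by
  construction). This is what scrambles first-turn oxaloacetate into 50 %
  [1,2-¹³C] / 50 % [3,4-¹³C] and hence splits second-turn 2-oxoglutarate
  into M+3 and M+4.
* **Second-turn condensation pairs labeled oxaloacetate with labeled
  acetyl-CoA only.** Dilution by unlabeled acetyl-CoA is deliberately not a
  parameter of the positional model; it is absorbed downstream into the
  *percent enrichment* scale, which measures labeled signal against the
  total (unlabeled + labeled) pool. The pools returned by `propagate()`
  therefore describe the labeled molecules, and enrichment fractions carry
  all dilution information.
* **Out of the label model**: the pentose phosphate shunt, pyruvate
  carboxylase anaplerosis, lactate/alanine exchange and amino-acid pools.
  Pyruvate carboxylase appears only as an enzyme-activity assay. 2- and
  3-phosphoglycerate are merged into one node (`PG23`) because they are
  measured combined.

The network ships as plain-text tables (`inst/extdata/metabolites.tsv`,
`carbon_maps.tsv`), one row per carbon mapping, and the loader enforces the
conservation invariants, so users can extend the map (e.g. add an
anaplerotic route) without touching code. Correctness of the propagation is
established in the test suite by comparison against an independent
brute-force enumeration of every positional path for all 64 glucose label
masks over two turns.

## From pools to the mass spectrometer

Labeled transition masses are computed **additively on nominal integer
bases**: the unlabeled instrument Q1/Q3 values are rounded to integers and
the mass shift (Q1) or retained-label count (Q3) is added. Fragment rules
are per analyte:

* *Phosphate-type fragments* (G6P, F6P, F16BP, DHAP, 2+3PG → 97 Da; PEP →
  79 Da): the product ion contains no carbon, so Q3 never moves with
  labeling.
* *Carboxyl loss* (pyruvate and all TCA acids): exactly one carboxyl is
  lost; where several carboxyls exist, every one is an allowed loss, and the
  emitted Q3 set is the distinct values of `base + (labels in mask) −
  (labels in lost set)` over all pool masks.

Two rule-derived values depart from commonly printed lists and are
intentional: aconitate first-turn products are 86/87 (additive +1/+2 on the
nominal base 85), and first-turn succinate products 74/75 are included even
though succinate is often omitted from first-turn product listings. Both
follow mechanically from the fragment rules; we emit the rule-derived values
rather than special-casing individual analytes.

Negative-mode [M−H]⁻ ionization is assumed throughout; retention times and
voltages (DP/CE/CXP) are taken to be label-invariant and are copied from the
unlabeled analyte. Isotope fine structure and high-resolution m/z are out of
scope — these are nominal-mass triple-quadrupole transitions.

## Quantification

Percent enrichment of turn *t* for a metabolite in a sample is

```
E_t = 100 · Σ areas(labeled transitions of turn t)
          / (unlabeled area + Σ areas of all monitored labeled transitions)
```

summed over both product ions where two are monitored. The denominator uses
every monitored channel, so `E_1 + E_2 ≤ 100` holds structurally and
enrichment is invariant to any uniform rescaling of a sample × analyte
block (ionization efficiency cancels). A missing unlabeled channel flags the
value as missing — it is never imputed as zero enrichment. A
natural-abundance correction hook exists (`na_correction` argument) but
defaults to off; no correction is applied anywhere in the defaults.

Total concentrations use the spiked internal standard:
`conc = (Σ all channel areas / IS area) · IS nmol / response factor / tissue
mass`, in nmol per g wet tissue. The internal-standard amount defaults to
4 nmol (4 µL of 1 mM azidothymidine); response factors default to 1 per
analyte and are config values — absolute concentrations are only as good as
the response calibration, but group comparisons are insensitive to it.

## Statistics

The battery mirrors standard practice for this design:

* `two_way_anova()` — full-factorial group × metabolite linear model, **type
  III sums of squares** computed by model comparison under sum-to-zero
  contrasts. Type III was chosen because the group sizes are unequal
  (11 vs 10) and it matches the behavior of the mainstream commercial
  packages used for such analyses; `ss_type = 2` is available. Empty cells
  are an error, not silently dropped.
* `fisher_lsd()` — uncorrected LSD posttests using the pooled residual mean
  square of the two-way model: `t = Δmean / sqrt(MS_resid (1/n₁ + 1/n₂))` on
  the residual df. No multiplicity correction anywhere, by design: the
  posttests are explicitly "uncorrected", and α = 0.05 throughout. With the
  pooled variance as `MS` and a single metabolite this reduces exactly to
  the pooled-variance t test (verified in the tests), and its type I error
  under the null is calibrated empirically at 0.05 ± 0.01 over 5000
  simulated datasets.
* `pearson_cor()` / `unpaired_t()` — two-sided Pearson correlation and
  pooled-variance Student's t, with degenerate inputs (constant vectors,
  zero pooled variance) flagged rather than erroring mid-pipeline.

Metabolite is treated as a fixed effect with animals as independent
replicates; no mixed models or repeated-measures structure is attempted.

## Assay calculations

*Spectrophotometric activities.* The rate is the absolute slope of the
longest initial linear window of the absorbance trace (minimum 5 points,
r² ≥ 0.98 — the window convention is this package's; a trace with no such
window is flagged, never extrapolated), converted by Beer–Lambert:
`activity = |slope AU/min| / (ε · ℓ) · volume · 1000 / protein` in
nmol · min⁻¹ · mg⁻¹. Extinction coefficients are configuration values with
defaults ε = 6.22 mM⁻¹cm⁻¹ (NAD(P)H, 340 nm) and 13.6 (TNB, 412 nm); the
MTT-formazan read-out of the PDH assay needs a per-assay calibration value
(default 17). Microplate assays have no 1-cm path, so the path length is an
explicit argument (the generator uses 0.55 cm, the approximate path of a
200 µL fill in a 96-well plate).

*Respirometry.* Every stage is nonmitochondrial-subtracted and
protein-normalized. ATP-linked respiration = state 3 ADP − state 4o
(state 4o identified with the post-oligomycin stage); RCR = state 3 ADP /
state 4o; coupling efficiency = ATP-linked / state 3 ADP; complex I-driven =
state 3u − post-rotenone; complex II-driven = post-succinate −
post-malonate. Parameters are invariant to a common offset on all stages
(including nonmito) and scale inversely with protein; negative derived
respiration is flagged, not clipped.

## The synthetic-data generator

`generate_cohort()` draws a full study: 11 control (No SE) + 10 SE tracing
animals, 8 + 8 enzyme animals, 7 + 7 mitochondrial preparations. It exists
so that every pipeline stage can be exercised and calibrated without animal
data, and its defaults *are* the study conditions the package targets.

**Enrichment structure.** Each tracing animal carries a latent glucose
uptake factor `u = exp(σ_u z − σ_u²/2)` (σ_u = 0.25) that multiplies all
glycolytic enrichments; per-metabolite extra noise (sdlog 0.04–0.21) sets
how tightly each intermediate tracks G6P. First-turn TCA log-enrichment in
controls loads on the standardized pyruvate log-enrichment with the
per-metabolite loadings (0.70–0.91) and, for 2-oxoglutarate and succinate,
on a shared mitochondrial factor (loadings 0.58 and 0.495). These loadings
were chosen analytically so that the *modeled observed* correlations — after
the small attenuation from measurement noise and the finite-sample bias of
r at n = 11 — sit at the targeted values (2OG–SUC ≈ 0.95 in controls). In SE
animals the pyruvate coupling is largely replaced by an independent
per-animal mitochondrial-capacity factor (loadings 0.35 / 0.45), which
destroys the pyruvate→TCA and 2OG–SUC correlations without changing means,
and the 2+3PG enrichment is decoupled from the uptake factor. Group means
are reduced by the effect table (`default_effect_table()`): e.g. G6P −22 %,
first-turn succinate −35 %, second-turn 2-oxoglutarate −47 %, PDH −33 %,
OGDH −55 %, all respirometry effects zero. Where published text and figure
legends disagree on an effect size (succinate turn 1 34 vs 35 %, turn 2 54
vs 55 %, malate turn 1), the defaults follow the figure legends; the table
is an ordinary tibble and fully switchable.

**Absolute baselines.** Absolute enrichment levels are free parameters (the
relative group effects, not the baselines, are the calibrated quantities).
Defaults are realistic for a 15-minute intraperitoneal bolus in brain:
glycolytic 12–25 %, TCA turn 1 ≈ 5–6 %, turn 2 ≈ 1–1.5 %.

**Noise model.** Peak areas are back-computed from latent enrichments and
concentrations, then multiplied by (a) a shared per-sample × analyte
lognormal factor (CV 10 %) modeling ionization/matrix efficiency — this
cancels exactly in enrichment ratios, which is why isotope-ratio
measurements are far more precise than raw areas — and (b) independent
per-channel integration noise (CV 2 %). Splitting the 10 % area noise into a
shared factor plus small channel noise is the realistic reading of LC-MS
behavior; had the 10 % been applied independently per channel, enrichment
correlations above ≈ 0.85 would be unobservable at any biological coupling,
contradicting the correlation structure the generator must reproduce. With
both CVs zero, pipeline enrichment equals the latent truth exactly (a test
asserts this to 10⁻¹²).

**Concentrations** are drawn lognormally per group around the configured
means with SDs derived from the target SEMs at n = 8. **Enzyme traces** are
exact lines (slope from the latent activity via the Beer–Lambert inverse)
plus Gaussian absorbance noise (SD 8·10⁻⁴ AU); per-enzyme protein loads are
set so every enzyme produces a mid-scale slope (~0.05 AU/min). **OCR
profiles** share a per-animal scale factor (CV 15 %) plus per-stage noise
(CV 5 %) and have no group effect.

**What the generator does not emulate:** retention-time drift, batch
effects, peak-shape pathology, missing channels, natural-abundance
satellites, or any raw chromatogram structure. Passing the recovery tests
demonstrates that the pipeline is an unbiased estimator of the effects under
this noise model — it says nothing about robustness to integration errors or
matrix effects beyond the multiplicative model.

## Numerical conventions and problem sizes

Pool weights are validated to sum to 1 within 10⁻⁹; oracle comparisons use
10⁻¹²; ANOVA oracle agreement is asserted to 10⁻¹⁰. Degenerate cases are
explicit: constant ANOVA responses give zero SS and F (not NaN), constant
correlation inputs and zero pooled variances are flagged, a state 4o at or
below nonmitochondrial OCR leaves RCR undefined.

The calibration suites use 200 generator replicates for parameter-recovery
checks (recovered effects within ±3 percentage points, correlations within
±0.05), 5000 replicates for the LSD type-I calibration, and 100 replicates
for the null respirometry comparisons — sizes at which the Monte Carlo error
of each check is several times smaller than its tolerance. The acceptance
script (`scripts/acceptance.R`) re-runs the 200-replicate recovery from any
seed in about a minute.

## Known limitations

* Nominal-mass arithmetic only; no isotope fine structure, adducts, or
  natural-abundance correction in the defaults.
* The label model is a single-pass bookkeeping of two TCA turns, not a flux
  model: no exchange fluxes, no anaplerosis, no isotopic steady state.
* Absolute concentrations depend on per-analyte response factors that
  default to 1; treat them as relative unless calibrated.
* The LSD posttests are intentionally uncorrected — interpret families of
  comparisons accordingly.
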