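---
title: "Chromosomal-ratio aneuploidy screening with chip-based digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosomal-ratio aneuploidy screening with chip-based digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcrscreen)
```

## The measurement model

Chip-based digital PCR partitions a reaction into roughly 20,000 wells of
volume $V_p$. A well that received at least one target molecule amplifies
and is called positive. If molecules load independently, the number per
well is Poisson with mean occupancy $\lambda$, so the positive fraction is
$p = 1 - e^{-\lambda}$ and the concentration of the target in the
pre-partition reaction is

$$T = -\frac{D}{V_p}\,\ln\!\left(1 - \frac{P}{N}\right)
\quad\text{copies/}\mu\text{L},$$

with $P$ positive wells out of $N$ and dilution factor $D$.
`occupancy_from_counts()` and `poisson_concentration()` implement exactly
this inversion. Saturation ($P = N$) is a hard error rather than a clamp:
the assay is run at 200–2000 copies/µL precisely to stay in the
informative range, and a saturated chip carries no concentration
information.

Each chip is a duplex: two targets, one per dye (VIC and FAM), measured
in the same wells. The screening statistic is the **chromosomal ratio**,
the concentration of the interrogated chromosome's target divided by that
of a reference chromosome on the other dye. Dosage 2:2 gives a ratio near
1; a full trisomy gives 3:2 = 1.5. Because both channels share the chip,
$V_p$, $D$ and the loaded DNA mass cancel from the ratio — the assay needs
no external calibration.

The panel set (`default_panels()`) pairs chr13 (VIC, *MBNL2*) with chr21
(FAM, *PRDM15*), chr13 (VIC) with chr18 (FAM, *EHZF*), and a noncoding
chrX sequence (VIC) with the Y-linked *SRY* gene (FAM). chr13 is the
reference of both autosomal duplexes.

## Interval estimates

No interval formula is standard for chip dPCR, so the package makes two
explicit, testable choices:

* **Concentration CI** — a Wilson score interval on $p = P/N$, mapped
  through the monotone transform $p \mapsto -(D/V_p)\ln(1-p)$
  (`concentration_ci()`). Wilson is well behaved near $p = 0$ and
  $p = 1$, where the Wald interval degenerates; monotonicity guarantees
  the transformed endpoints bracket the point estimate. Simulated
  coverage at nominal 95% stays within 93–97% (checked in the test
  suite at $N = 20{,}000$).
* **Ratio CI** — the delta method on the log ratio,
  $\mathrm{Var}(\log \hat R) \approx \sum_{c}\,
  p_c / \big((1-p_c)\,N\,\lambda_c^2\big)$, treating the two channel
  occupancies as independent. Co-loading of the two targets into a well
  is independent under the Poisson model, so the approximation is good
  away from saturation.

## Classification bands

`classification_bands()` encodes the decision rule, all values
configurable:

| parameter | default | meaning |
|---|---|---|
| euploid band | 0.9–1.1 | ratios called euploid |
| aneuploid threshold | 1.15 | ratios at/above are called trisomy |
| per-chromosome cutoffs | 1.145 (13), 1.077 (18), 1.068 (21) | dilution/detection-limit analysis only |
| typical-trisomy floor | 1.35 | trisomy calls below it are flagged |
| X-dosage bands | 0.4–0.6 / 0.9–1.1 / ≥1.4 | one / two / three-plus X copies |
| SRY floor | ≥10 copies/µL and ≥20 positive wells | Y-presence limit of blank |

The gap (1.1, 1.15) is deliberately a third class, *inconclusive*: the
euploid band and the trisomy threshold do not meet, and in a clinical
screen the safe reading of the gap is "repeat or reflex to karyotype",
not a forced call. Trisomy calls in [1.15, 1.35) carry an
`intermediate_possible_mosaic_or_contamination` flag, and the implied
aneuploid fraction $\hat f = 2(\hat R - 1)$
(`estimate_aneuploid_fraction()`) is reported with them; 1.35 sits just
below the smallest ratio we would regard as a typical full trisomy
(observed full-trisomy ratios start around 1.38). Mixtures of a trisomic
and a euploid population — mosaicism, or maternal-cell contamination of
a fetal sample — move the expected ratio along $1 + f/2$, which is why an
intermediate ratio such as 1.19 reads as roughly 40% trisomic material
rather than as a distinct karyotype.

The per-chromosome cutoffs are used only for detection-limit analysis of
dilution series; clinical calling uses the global 1.15 threshold. The
cutoffs are kept as configurable defaults even though they sit oddly
against the euploid maxima of a typical cohort (the chr21 cutoff 1.068 is
*above* a typical euploid maximum near 1.01, the chr13 cutoff 1.145 right
at one); resolving that tension is a calibration question for real data,
not something the package should silently decide.

Sample-level calls average the QC-passing replicate ratios and classify
the mean; if any two replicates disagree at the euploid-versus-trisomy
level the sample is returned inconclusive with a `repeat_test` flag
(`aggregate_replicates()`). Chip QC (`qc_chip()`) fails inconsistent
counts and saturated channels, and warns (by default) when the reference
channel leaves the validated 200–2000 copies/µL window.

### The chr13 reconstruction

chr13 has no duplex of its own — it is the VIC reference in both
autosomal panels. Its ratio is therefore reconstructed as the mean of the
inverse ratios chr13:chr21 and chr13:chr18 across the two panels. This
has a known consequence: in a trisomy-21 sample the chr13:chr21 ratio is
2:3 ≈ 0.67 while chr13:chr18 is 1, so the reconstructed chr13 ratio
(~0.83) falls below the euploid band and is reported inconclusive with a
`below_euploid_range` flag. That is the honest output of a ratio-based
design whose reference can itself be aberrant: each trisomy is still
detected by its own ratio, and evaluation compares each trisomy's samples
only against euploids. Similarly, the X:autosome dosage used for sex
calling is normalised to the chr13 channel, so trisomy-13 samples get an
inconclusive sex call. Autosomal monosomy (ratio near 0.5–0.75) is never
called, only flagged low — no such karyotype is in scope.

Cross-chip X:autosome normalisation assumes equal DNA input per chip of a
sample (same extraction and adjustment feed all three duplexes). The
simulator deliberately stress-tests this with a per-chip lognormal
loading factor.

## What the simulator emulates

`simulate_chip()` is the generative counterpart of the quantification
model: per channel, occupancy $\lambda = C V_p / D$, each well positive
with probability $1 - e^{-\lambda}$, channels independent, and the four
joint counts drawn from the implied multinomial — so count conservation
holds by construction. Three noise sources are layered on
(`noise_params()`):

* per-chip lognormal loading factor, CV 2%, shared by both channels of a
  chip — replicate-to-replicate spread without distorting within-chip
  ratios; technical-replicate variability of this assay is low, and 2%
  is a realistic pipetting CV;
* false-positive well calls at 2×10⁻⁴ — sparse "rain" above threshold;
* false-negative calls at 10⁻³ — dropout of true positives.

`sample_profile()` carries the truth: per-chromosome copy numbers of the
(possibly aberrant) karyotype, the mosaic fraction $f$ of genomes
carrying it, a maternal-contamination fraction $m$ of euploid female
genomes, and the genome concentration. Channel concentrations follow the
blended copy number
$(1-m)\,[f\,\mathrm{cn} + (1-f)\,\mathrm{cn}_{\text{euploid}}] +
m\,\mathrm{cn}_{\text{maternal}}$, scaled so a disomic autosome channel
at the default `genome_conc = 500` measures 500 copies/µL — mid-range of
the validated window, where the Poisson estimator is most precise.
Setting $m = 1$ reproduces a euploid female signal regardless of the
fetal profile, the degenerate limit of complete maternal contamination.

The default cohort (`cohort_spec()`) matches the validation study's
composition: 133 samples — 17 trisomy 21, 9 trisomy 18, 3 trisomy 13, one
monosomy X, one XXXY, 102 euploid (split evenly by sex) — in triplicate
per panel. Dilution series (`mixture_spec()`) default to the seven-point
design 0, 5, 10, 30, 50, 70, 100% trisomic DNA in technical duplicates.

What the simulator does **not** emulate: spatially correlated well
failures, partial amplification ("rain" as an intensity continuum rather
than call flips), inter-locus amplification-efficiency differences,
droplet/chip loss, or a realistic distribution of fetal fraction in
contaminated samples. Passing tests therefore demonstrate that the
analysis correctly inverts its own generative assumptions at realistic
noise levels — not that those assumptions exhaust real chip behaviour.

## The evaluation layer

`cohort_summary()` compares each trisomy's samples against euploids with
a Mann–Whitney U test (exact enumeration when the smaller group has ≤8
observations and no ties, normal approximation with tie correction
otherwise), computes the AUROC by the pair-ordering estimator (ties count
½; algebraically $U/(n_1 n_2)$, an identity the tests assert), a
percentile-bootstrap 95% CI over samples (2000 resamples, seeded;
single-class resamples are redrawn), and sensitivity/specificity at the
calling threshold.

`dilution_fit()` is the model object of the mosaicism experiment: it
reduces a dilution series to per-chip observed ratios, regresses the
per-fraction mean on the theoretical ratio $1 + f/2$ by OLS, and locates
the detection limit — the smallest grid fraction whose mean ratio exceeds
the chromosome's cutoff *with every larger fraction also exceeding it*
(an onset-of-stable-exceedance rule, so an isolated noisy spike cannot
create a spurious limit). Per-fraction intervals use the $t$ distribution
over replicates; with duplicates these are very wide, so the default
detection-limit rule uses the mean only, with `use_ci_lower = TRUE`
available to require the interval too. Detection-limit grids default to
10% steps: the seven-point design cannot distinguish, say, 15% from 20%,
and a regular grid makes the reported limit a well-defined grid point.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on simulated data
at the study's own scale: 20,000-well chips, triplicate panels,
the 133-sample cohort, seven-point duplicate dilution series; Monte-Carlo
checks use 100 chips (bias), 1000 chips (interval coverage) and
20–200 replicates per dilution point (detection limits — the chr13
cutoff sits 0.005 below the 30%-point mean, so its limit is estimated
with 200 chips per point). All randomness is explicitly seeded;
`simulate_*()` functions restore the caller's RNG stream, and identical
spec + seed yields byte-identical datasets.

Degenerate inputs are handled explicitly rather than coerced: saturated
channels and malformed counts are errors at quantification and QC
failures at calling; an empty reference channel makes the ratio an error
(or `NA` in vectorised paths); ratios below 1 clamp the implied aneuploid
fraction to 0 with a warning; dilution fits with fewer than three
fractions report `NA` regression summaries.

## Known limitations

* Absolute copies/µL depend on $V_p$ (default 809 pL, the platform's
  nominal well volume) and $D$; neither affects any ratio-level output.
* The chr13-as-reference design confounds chr13 and sex calls in the
  ways described above; a production assay would add a second reference
  chromosome.
* The global threshold and the band edges are taken as configured
  constants; the package evaluates them but does not re-derive them from
  training data.
* p-values from exact rank tests at very small group sizes (three
  trisomy-13 samples) are granular; they are reported as computed and
  should not be over-interpreted.
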