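---
title: "Scoring compound perturbations of a bioreactor gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring compound perturbations of a bioreactor gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbrascreen)
library(dplyr)
```

## The experimental design this package analyses

A minibioreactor array (MBRA) maintains a human fecal microbiota ex vivo in
24 parallel continuous-flow anaerobic chambers (15 mL, 8-h retention time).
A screening experiment inoculates all chambers from one donor, lets the
community stabilize for 72 h, then feeds compound-supplemented medium to
triplicate treatment chambers from 72 h to 216 h while 3 chambers stay
untreated, and follows the washout until 274 h. Samples are drawn at 17
times (`mbra_schedule()`): 4 before treatment, 10 during, 3 after. Each
independent experiment carries its own controls; treatments are only ever
compared within their experiment.

Per sample the screen measures: total bacterial density (16S qPCR),
community composition (16S features: Jaccard, unweighted/weighted UniFrac),
alpha diversity (Pielou evenness, observed features), bioactive
lipopolysaccharide and flagellin (TLR4/TLR5 reporter cells against
purified-standard curves), and — at the single 120-h time point — a
transcript table of gene-family relative abundances.

## The trajectory statistic

The central quantity is a per-chamber, per-time *distance to control*: for
a treated chamber the mean distance to all control chambers, for a control
chamber the mean distance to the other controls. Scalar readouts (density,
alpha diversity, bioassay levels) enter directly as per-chamber values.
Two normalizations follow:

1. **Control normalization** (`normalize_to_control()`): every value at
   time $t$ is divided by the control-chamber mean at $t$, removing
   day-to-day drift common to all chambers. The control group then averages
   exactly 1 at every time point.
2. **Baseline normalization** (`normalize_to_baseline()`): every chamber's
   whole trajectory is divided by its *treatment group's* mean at the 24-h
   baseline, removing pre-existing group offsets. The division is by the
   group mean, not per chamber, so each group — not each chamber — averages
   1 at 24 h.

The unit of statistical analysis is the trapezoid area under the doubly
normalized trajectory over a phase window (`trapezoid_auc()`): treatment
phase 72–216 h, post-treatment phase 216–274 h, in value·hours. A flat
control trajectory gives 144 and 58 value·hours respectively. The 72-h and
216-h samples anchor both adjacent phases: they are drawn immediately
before the medium switch takes effect, which also makes AUCs additive
across the shared boundary. For readouts that can move in either direction
the deviation from baseline is split into area above and below 1
(`phase_auc_above_below()`), with piecewise-linear segments cut exactly at
baseline crossings so that `above - below` equals the signed AUC to
machine precision.

Group comparison (`compare_to_control()`) is a one-way ANOVA across all
groups of a readout × phase family followed by treatment-versus-control t
tests on the pooled within-group variance, each raw p multiplied by the
number of treatments (Bonferroni) and capped at 1 — the standard
many-to-one reading of "ANOVA with Bonferroni's multiple comparisons";
Dunnett's exact test is deliberately out of scope, and corrections never
cross readout families. A treatment × readout is classified
(`classify_reversibility()`) `none` / `reversible` / `non_reversible` from
its two phase flags; a late-emerging post-phase effect counts as
non-reversible because it outlives the exposure. `build_impact_summary()`
counts significant cells per treatment and ranks compounds from least to
most impactful.

The transcriptome readout is measured once (120 h), so it is tested as a
plain Bray-Curtis distance-to-control value in the treatment phase, with
no AUC and no post-phase flag. Gene families are additionally classified
on a volcano (`volcano()`): log2 fold change of group means with a
pseudocount of half the smallest positive abundance, Welch t tests, and
Benjamini–Hochberg q values; `up`/`down` requires at least a 16-fold
change (|log2FC| ≥ 4, inclusive) *and* q < 0.1 (strict).

## The synthetic experiment generator

`generate_experiment()` produces a complete in-silico experiment with a
known answer key, so the whole pipeline can be validated without access to
sequencing archives. It emulates, with one log-normal baseline community
per experiment (200 features, sdlog 1.5):

* **Stabilization.** A fixed 25% of inoculum features wash out of every
  chamber geometrically over the first 48 h (the initial alpha-diversity
  drop, stationary afterwards), and each chamber additionally lacks a
  chamber-specific 10% founder set from inoculation onwards. The founder
  sets give every chamber a persistent presence/absence identity that is
  already in place at the 24-h baseline — the property that makes baseline
  normalization informative rather than noise-injecting.
* **Persistent chamber effects.** Per-chamber log-normal offsets on
  feature abundances (sdlog 0.2), total load (0.15) and analyte levels
  (0.2), on top of per-time noise (0.2, 0.1 and 0.15). Parallel chemostat
  chambers genuinely differ more from each other than from themselves over
  time; the group-baseline + pooled-t procedure is only calibrated in that
  regime, because the within-group spread must carry the chamber-level
  variance that also drives group-mean differences.
* **Counts.** Dirichlet-multinomial per sample (precision 200, depth
  15 000), the standard overdispersed count model for 16S data.
* **Treatment effects** (`effect_spec()`), applied for 72 < t ≤ 216 only:
  a fold change of total load; a clade-coherent abundance shift (the
  responding clade is chosen with abundance share commensurate to its
  feature share — compositional responses in this system are
  phylogenetically coherent, and scattered random shift sets would cancel
  on deep branches); a clade-coherent dropout to near-zero abundance (the
  presence-level effect); an evenness compression implemented as a power
  transform whose exponent is solved numerically for the requested evenness
  reduction; fold changes of LPS/flagellin; and a transcript-family shift.
  Reversible effects relax after 216 h with an 8-h half-life — the chamber
  retention time, since washout of the compound and of accumulated analytes
  is what drives relaxation.
* **Assay layers.** Cq values from an exact qPCR standard curve
  (slope −3.32, efficiency 1) plus standards; plate readings from monotone
  piecewise-linear reporter curves over a 3-point dilution series;
  FASTQ reads with controlled per-read fractions of bases ≥ Q28.

The answer key (`derive_answer_key()`) maps each effect dial to the
readouts it moves — density fold to density, abundance shift to weighted
UniFrac, dropout to Jaccard/unweighted UniFrac/observed richness, evenness
to evenness and observed, analyte folds to their bioassays, transcript
shift to the transcriptome cell — with the post-phase flag set only for
persistent effects.

What the generator does **not** emulate: taxon interactions and dynamics
between samplings, chemostat washout ODEs, primer or extraction biases,
batch effects between experiments, and compositional covariation between
density and bioassay levels. Passing the validation suites therefore shows
the pipeline recovers planted effects of the modelled kinds at realistic
noise — not that it would detect any particular real compound.

## Numerical and design choices

* Phase boundaries: `pre` t ≤ 72, `treatment` 72 < t ≤ 216, `post`
  t > 216 — reproducing the 4/10/3 sample split; the boundary samples are
  AUC anchors for both adjacent phases.
* Presence means count > 0; no rarefaction by default (`rarefy_counts()`
  is available as an explicit pre-step). Natural log in Pielou evenness;
  single-feature samples have evenness 0 by convention.
* Weighted UniFrac defaults to the normalized variant so values are
  comparable across time points; both variants are exposed. Unrooted trees
  are midpoint-rooted, since UniFrac needs a root.
* The reporter curve is a monotone piecewise-linear interpolant on
  log-concentration — assumption-free, exact at the knots; a 4PL fit is
  deliberately not offered. Quantification takes the least-diluted reading
  inside the declared linear range (any in-range dilution agrees when
  noise-free) and distinguishes saturated-above from below-detection
  failures. Bioassay levels are *not* normalized per bacterial density.
* AUCs are reported in value·hours without dividing by phase duration;
  comparisons are always against controls within the same phase, so the
  duration cancels.
* Distance-to-control aggregation is the per-chamber mean over control
  chambers, giving N = 3 analysis units per treatment — the coarsest
  aggregation that still yields a replicate structure for ANOVA.

## Known limitations

Three properties of the method — not of the implementation — surface in
the validation suites and are worth knowing:

* **Distance readouts run hot at the cell level.** With only three shared
  controls, control self-distances are mutually correlated (each pair
  contributes to two chambers' values), so the pooled within-group variance
  understates the variance of a treatment-versus-control contrast, and the
  ratio to a noisy 3-chamber control mean is biased upward for treated
  chambers (a Jensen effect). Bonferroni correction across the 6–7
  treatments of a full panel absorbs this at the pipeline level — the
  overall null significance rate stays within the nominal α — but
  individual uncorrected distance cells (especially Jaccard) exceed their
  nominal rate.
* **The shared 216-h anchor drags reversible tails into the post phase.**
  The 216-h sample is drawn at full effect, so even an instantly reversible
  strong effect leaves a triangular excess in the post-phase AUC. Strong
  reversible effects are therefore sometimes classified non-reversible;
  this is the main source of disagreement with the generator's answer key.
* **Phylogenetic metrics are the power bottleneck.** Weighted UniFrac
  responds to a clade shift only through deep-branch mass differences,
  which compete with Dirichlet-multinomial noise in the 3-control divisor;
  its per-cell power at the standard panel's effect sizes is materially
  below that of Jaccard or the scalar readouts.

## Problem sizes used by the validation suites

The unit and property tests run on reduced communities (60–150 features,
depth 1 500–5 000) chosen to exercise every code path quickly. The two
Monte-Carlo acceptance suites — the 500-replicate null calibration and the
100-seed recovery/answer-key suite — run at the generator's full default
problem size (24 chambers, 200 features, depth 15 000, 17 time points).
`scripts/acceptance.R` recomputes and reports all headline quantities from
scratch at those sizes.
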