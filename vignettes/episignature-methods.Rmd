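---
title: "Methods: episignature discovery, epigenetic age, and probability-scored classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature discovery, epigenetic age, and probability-scored classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episigr)
```

episigr implements the complete loop used to establish blood DNA
methylation (DNAm) episignatures for rare disorders: probe quality
control, blood cell deconvolution, epigenetic age, covariate-adjusted
moderated differential methylation, dual-threshold signature selection,
enrichment, correlation pruning, and a calibrated SVM scorer. This
vignette explains the statistical model behind each stage, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The data model

All stages operate on a beta-value matrix: per CpG probe and sample, the
fraction methylated, in [0, 1]. Betas arrive after array preprocessing
(normalization, background subtraction); episigr deliberately starts
*after* that step, so IDAT-level processing and intensity-based sample
QC are out of scope. Sample metadata travel in a sample sheet whose
`role` column fixes cohort membership: only `discovery_*` samples ever
enter model fitting, `validation_*` and `test` samples are strictly
scored. Ages are stored in years as reals so that infants can be
represented (a 2-day-old is 2/365.25 years) and the clock transform
stays continuous.

## Probe quality control

`filter_probes()` applies six exclusion rules in a fixed order:
detection failures (p > 0.01 in at least one sample by default, both
configurable), SNP-proximal probes (manifest minor allele frequency
above 1%), known cross-reactive probes, probes with a raw beta of
exactly 0 or 1 in more than 0.25% of samples, non-CpG probes, and X/Y
probes. Three choices deserve note:

* The rule categories overlap on real manifests, so the report carries
  both `matched` (rule satisfied) and `removed` (incremental removal in
  application order); `n_input = n_remaining + sum(removed)` is an
  invariant, and the final probe set does not depend on rule order.
* "Raw beta of 0 or 1" is read literally: equality at the endpoints,
  with a configurable tolerance that defaults to 0. With 34 samples,
  0.25% of samples is 0.085, so a single endpoint value triggers
  removal.
* The detection-failure definition is not standardized across
  pipelines; the default here ("p > 0.01 anywhere") is the conservative
  small-cohort choice and both the threshold and the sample fraction are
  arguments.

## Cell-type deconvolution

Whole blood is a mixture; case/control differences in cell composition
masquerade as methylation differences. `estimate_cell_proportions()`
solves, per sample, the constrained least-squares problem

$$\min_{\pi}\;\lVert \beta_s - R\pi \rVert^2
  \quad\text{s.t.}\quad \pi \ge 0,\; \textstyle\sum_i \pi_i = 1,$$

with $R$ the reference panel of sorted-cell beta profiles. The simplex
constraints are imposed exactly via quadratic programming rather than by
projecting an unconstrained fit and truncating: both approaches satisfy
the same contract, but the QP form needs no post-hoc renormalization
logic and is deterministic. Estimates are renormalized to sum exactly
to 1 (solver tolerance only). `covariate_block()` then drops one cell
type — neutrophils by default, the dominant blood fraction — because the
proportions sum to one and a full block would be collinear with the
intercept.

The reference panel is an input file: sorted-cell reference data are
distributed under their own licenses, so the package ships none; the
generator builds a synthetic six-cell panel with one discriminating CpG
block per cell type, which is also what the tests use.

## Epigenetic age and acceleration

DNAm age uses a weighted-CpG clock: a linear predictor
$a_0 + \sum_i w_i \beta_i$ on the transformed-age scale, mapped back to
years by the inverse of

$$T(x)=\begin{cases}\log(x+1)-\log(A+1), & x \le A\\
(x-A)/(A+1), & x > A\end{cases}$$

with knot `adult_age` $A = 20$ by default. $T$ is continuous, strictly
increasing and exactly invertible, which the tests check on a grid to
1e-10. Clock coefficients are an input file (the package bundles no
published clock; tests and simulations use synthetic clocks), read by
`read_clock()`. Missing clock CpGs follow a 5% policy: at most 5% of
clock CpGs may be absent (imputed at the cohort mean with a warning);
more is an error, since the linear predictor would silently drift.

Age acceleration is the plain difference DNAm age − chronological age.
The model also uses the *residual* of DNAm age regressed on
chronological age as a covariate; the regression's fitting set defaults
to all modeled (discovery) samples, a choice left open by common
practice — fitting within controls only is available via
`fitting_roles`. Group comparisons use the paired Wilcoxon signed-rank
test (chronological vs DNAm age within a group) and the Mann–Whitney U
test (acceleration between groups); both are two-sided, exact for small
samples without ties (n ≤ 25 paired, smaller group ≤ 8 unpaired) and
normal approximations with continuity/tie corrections otherwise. The
exact branches are tested against full enumeration of sign patterns and
group assignments.

Why the residual covariate matters: cases carry a planted acceleration,
so clock-adjacent CpGs are *genuinely* differentially methylated between
groups. Without the residual covariate those CpGs can enter the
signature; with it they are absorbed, at the cost of some power because
the residual partially tracks case status. This is the central
confounding trade-off of the design, and it is why the generator plants
acceleration with realistic between-individual spread (SD 4 years in
cases, 3 years of clock deviation in controls): with perfectly uniform
acceleration the residual would be collinear with the case indicator and
the group effect would be unidentifiable.

## Differential methylation and signature selection

Per CpG, ordinary least squares on the beta scale with the design
intercept + case indicator + age + sex + five cell proportions + DNAm
age residual (any block can be disabled; the design must be full rank,
and rank failures name the collinear columns). Models are fit on betas,
not M-values, because the selection thresholds are defined on the beta
scale; an M-value analysis can be emulated by transforming the input,
but the shipped thresholds only make sense on betas.

Variance moderation is the standard empirical-Bayes construction:
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, moderated
$t = \hat b_g /(\tilde s_g u_g)$ on $d_0 + d_g$ df, with the prior
estimated by method of moments on the log variances (zero-variance
probes are excluded from prior estimation). `d0 = 0` reproduces the
ordinary t exactly and `d0 = Inf` the fully pooled normal reference;
both limits are tested, and the estimated-prior path is cross-checked
against an independent reference implementation of the same estimator.
On pure-noise data the resulting p-values are uniform
(Kolmogorov–Smirnov check at 5,000–10,000 probes) and BH keeps the
q < 0.05 rate at effectively zero.

Selection applies **strict** dual thresholds — q < 0.05 and
|Δβ| > 0.10 — where Δβ is the raw difference of group mean betas
(computed directly, not the adjusted coefficient, and skipping missing
values per group). A probe at exactly Δβ = 0.10 or q = 0.05 is *not*
selected. The effect-size threshold is what keeps the signature
biologically meaningful at small n: moderated tests alone would admit
tiny shifts at well-measured CpGs. Results are ordered by q, then
|Δβ| descending, with probe id as the final tie-break so output order is
deterministic.

## Enrichment

Island/shore enrichment is a one-sided upper-tail hypergeometric test of
Island ∪ Shore membership (a shore being within 2 kb of an island in the
annotation) in the signature versus the post-QC background probe set.
Gene-set enrichment first maps CpGs to genes whose annotated span lies
within 10 kb — *inclusive* at the boundary, a convention pinned by a
dedicated fixture with a span ending exactly 10,000 bp from its probe —
then tests each term hypergeometrically over genes, BH-adjusts across
terms, and reports terms with at least 3 foreground hits and q < 0.05.
Distance is measured to the nearest span edge (0 inside the span);
regulatory-domain extension rules of web enrichment tools are
deliberately not replicated.

## Pruning and classification

Signature CpGs are highly inter-correlated by construction. The pruner
removes features greedily: find the worst pair (largest |r|, ties broken
by probe id), drop the member with the larger mean absolute correlation
to everything else (lexicographically larger id on a tie), repeat until
no pair reaches the cutoff (0.90; a pair *at* the cutoff is pruned).
Pruning sees only training samples, to avoid leaking validation
structure into feature selection. The kept-set post-condition — no pair
with |r| ≥ cutoff — is asserted on every run, and the greedy path is
tested against an independently coded oracle.

The classifier is a linear SVM (cost 1) in probability mode: Platt
sigmoid calibration fitted by internal cross-validation under a caller
seed. Kernel, cost and calibration internals are not sacred — the design
goal is a reproducible probability scale, not a specific margin — so all
are recorded in the model and configurable (`kernel = "radial"` is
available). Features are standardized by training mean/SD; missing
feature values are imputed with training-control means (warning), and a
sample missing more than 20% of model features is flagged unscoreable
rather than silently imputed into a score. Scores above 0.5 are called
"high" (case-like), below "low"; exactly 0.5 is undefined by the
convention, so it is called "low" with a warning. The serialized JSON
model carries the collapsed linear weights, calibration coefficients and
standardization, so a model read back from disk scores byte-identically
with no dependence on the training session; training itself is
deterministic given the seed, which the tests check by comparing
serialized models byte for byte.

One behavior worth understanding: at the generator's default noise the
planted group effect dominates every signature CpG, so their pairwise
training correlations all exceed 0.9 and pruning collapses the signature
to a single representative CpG. That is the contract operating
correctly — redundant features carry no additional training information
— and classification performance is unaffected; on noisier data the
kept set grows accordingly.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the package targets:
8 discovery cases vs 26 discovery controls, 6 validation cases, 100
validation controls, and on demand extra cohorts (`case_like`,
`control_like`, `other_signature` — the last carrying a disjoint second
episignature, the analogue of scoring a different syndrome against this
model). Per-probe baselines are bimodal (methylation mass near 0 and 1);
per-sample values are `plogis(qlogis(baseline) + effects + noise)` with
Gaussian noise on the logit scale (SD 0.05 by default) — noise on the
logit scale keeps values in (0, 1) without distributional gymnastics at
the boundaries, at the cost of non-constant beta-scale variance, which
is itself realistic. The planted case effect at signature CpGs is a
logit offset calibrated in closed form so the realized mean Δβ equals
the configured target at the baseline; planted magnitudes default to
0.10–0.25 with mixed sign. Deconvolution CpGs are linear mixtures of the
synthetic reference under per-sample Dirichlet compositions centered on
a neutrophil-dominant blood profile; clock CpGs encode each sample's
(possibly accelerated) transformed age so DNAm age is exactly
recoverable at zero clock noise (default clock noise SD 0.005 on the
beta scale). Sixty decoy probes exercise every QC rule. Island/shore
annotation rates are 55% among signature probes vs 37% in the
background, mirroring the enrichment structure the analysis should
detect. Truth tables record every planted quantity, so recall, empirical
FDR, deconvolution error and acceleration recovery are all measurable.

What the generator does **not** emulate: probe-chemistry (type I/II)
differences, batch and chip effects, genuine biological covariance
between neighboring CpGs beyond the planted blocks, non-Gaussian
technical artifacts, and population structure among controls. Passing
tests therefore demonstrate that the pipeline's statistics behave as
specified under the assumed model — they do not certify performance on
any particular real cohort.

## Numerical choices and problem sizes

Tolerances follow the precision each quantity supports: exact identities
(BH vs its step-up definition, hypergeometric tails vs explicit
summation, rank-test p-values vs enumeration) are tested to 1e-12;
noise-free deconvolution to 1e-6 and the clock transform round trip to
1e-8; simulation-recovered quantities at their sampling precision. Test
and acceptance runs use 3,000–20,000 probes and the 8/26 + 6/100 cohort
design; the full acceptance computation takes a few seconds on one core.
Degenerate inputs are handled explicitly rather than by crashing:
constant probes are flagged out of moderation, empty signatures warn
and propagate as empty tibbles, all-zero paired differences return
p = 1 with a warning, single-sample cohorts report SD 0 with an
`sd_undefined` flag, and boundary scores of exactly 0.5 warn.

## Known limitations

* Betas are modeled with homoskedastic per-probe Gaussian errors; near
  the [0, 1] boundaries this is an approximation (heteroskedasticity is
  the price of staying on the interpretable beta scale).
* The DNAm-age-residual covariate trades power for protection against
  acceleration-driven false positives; cohorts with extreme, uniform
  acceleration will lose group-effect identifiability (by design).
* The pruner optimizes a redundancy criterion, not classification
  performance; with very clean signals it keeps few features.
* Calibration of SVM probabilities with 8 training cases is coarse;
  scores are decision aids near 0/1, not well-calibrated probabilities
  in the mid-range.
* Hypergeometric enrichment treats CpGs (and genes) as exchangeable;
  spatial correlation along the genome is not modeled.
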