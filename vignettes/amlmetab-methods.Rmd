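---
title: "Methods: integrated genomic-metabolomic AML analysis with amlmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated genomic-metabolomic AML analysis with amlmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amlmetab)
```

# Scope and model of the analysis

`amlmetab` implements a multi-layer characterization of acute myeloid
leukemia (AML): classification of patients against healthy controls from
serum and urine NMR spectra, unsupervised subtyping of the intracellular
metabolome and its association with genomic classes, and constraint-based
prediction of metabolic perturbations from transcriptional differences.
Because the patient-level data of such studies are not publicly
redistributable, every stage is exercised on seeded synthetic cohorts with
planted ground truth; the generator is first-class, tested code, and what
a green test does and does not establish is discussed at the end.

# Statistics core

**Exact Fisher test (2×2).** Two-sided p by the probability-mass rule: the
sum of hypergeometric probabilities of all tables sharing the observed
margins whose probability does not exceed the observed one, with a `1e-7`
relative slack on the comparison (the convention used by mainstream
implementations; ties at machine precision otherwise flip terms in and
out). The worked enrichment table with 6/10 versus 1/11 carriers gives
p = 8372/352716 ≈ 0.0237, printed as 0.024.

**Monte Carlo Fisher (r×c).** Margins are held fixed; tables are resampled
by Patefield's algorithm (`r2dtable`), with a hypergeometric shortcut for
2×2 tables (one free cell). The estimator is `(1 + #{P(T*) ≤ P(T)}) /
(B + 1)`, which cannot return zero; `B` defaults to 10⁶ (a printed value
of "1000,000" in the source literature is read as 10⁶ — it is an argument,
not a constant). Agreement with the exact test is enforced within three
Monte Carlo standard errors on a fixture set.

**Rank tests and Welch.** Mann–Whitney U and Kruskal–Wallis H use midranks
with the standard tie-corrected variance and asymptotic p-values (normal
with continuity correction; chi-square). Welch's t uses the Satterthwaite
degrees of freedom. All are validated against the base-R implementations.

**Multiplicity.** Bonferroni, Benjamini–Hochberg step-up (with monotone
enforcement), and Holm's step-down Šidák: sorted p_(i) mapped to
`1 − (1 − p_(i))^(m−i+1)` and monotonized by a cumulative maximum. All
corrections satisfy adjusted ≥ raw and sorted-order monotonicity by
property tests.

# NMR pipeline

**Preprocessing.** Spectra are binned into mean intensities over
left-closed windows of 0.04 ppm anchored at 0.5 ppm; water (4.50–5.00 ppm)
is excluded, and urine additionally drops the urea band (5.5–6.0 ppm).
These are field-standard defaults; the upstream study does not state its
values, so all are arguments. Negative bins are clipped to zero.
Normalization is `total_area` for serum and PQN for urine: PQN divides
each spectrum by the median ratio to the cohort median spectrum, the
standard correction for urine dilution; a spectrum that is an exact 2×
dilution twin of another is mapped back onto it (tested). `total_area` is
idempotent and PQN against oneself is the identity.

**Latent models.** PCA by SVD of the centered (optionally unit-variance
scaled) matrix; loadings are orthonormal and explained variance is
nonincreasing. PLS-DA uses NIPALS against a centered class-indicator
matrix; the stored loadings are the projection weights `W (PᵀW)⁻¹` so the
invariant `scores = scaled(data) %*% loadings` holds for every method.
Sparse PLS-DA zeroes all but the requested number of largest-magnitude
weights per component before deflation. Unit-variance scaling is the
default scaler, as some scaling is unavoidable for spectra in which a few
intense peaks otherwise dominate.

**Stochastic grid search.** The configuration space (method ×
n_components × scaler × classifier) is sampled uniformly without
replacement, capped at the grid size; each configuration is scored by
stratified k-fold CV accuracy with the latent model refit inside every
training fold (no information leak from test folds into the projection).
One fold assignment, fixed by the seed, is shared by all configurations so
the winner does not depend on draw order.

**Stratification.** Folds stratify on class × gender when every stratum
holds at least `k` members, otherwise on class only; age acts as a
secondary balancing key by ordering samples within strata before
round-robin dealing. This operationalizes "stratified for gender and age
when possible" without failing on small strata.

**Signature extraction.** Component loadings are smoothed by a centered
moving average (default 5 bins); the noise scale is the median absolute
deviation × 1.4826 of the smoothed vector; features pass at
|weight|/noise ≥ 3 by default. MAD is used because the loading vector is
mostly nulls plus a few signal bins — exactly the situation where an SD
estimate would be inflated by the signal itself.

**Classifiers.** AdaBoost (multiclass SAMME over depth-one stumps) and a
one-vs-rest linear SVM trained by deterministic subgradient descent are
implemented in the package (no suitable packages exist in the pinned
environment), as is the CART random forest used by the MS module. Ties
between classifiers are broken by lower accuracy SD, then in favor of
AdaBoost, so reports are deterministic.

**Blast classes.** Bone-marrow blast percentage is partitioned into
[20, 50), [50, 75), [75, ∞) and peripheral-blood into (−∞, 30), [30, 70),
[70, ∞); intervals are left-closed so 49% falls in the 20–49 class. Each
class is compared with the control score distribution by the two-sample
KS distance.

# MS pipeline

Intensities are area-under-curve values normalized to DNA content
(nonpositive content is an error naming the sample). Missing values are
imputed at half the observed per-metabolite minimum — the standard recipe
for left-censored (detection-limit) missingness. Differential calls use
Welch on log-transformed values (Kruskal–Wallis available), BH q-values
over the tested set, and the inclusive flag rule FC ≥ 2 & q ≤ 0.05 (down:
FC ≤ 1/2); inclusivity at the boundary is tested with an exact
fold-change-2 construction. Fold change is the ratio of group means of
normalized, imputed intensities. Pathway over-representation is a
hypergeometric upper tail of the flagged-set overlap within the measured
universe, with impact simplified to the hit fraction — topology-weighted
impact would require external pathway graphs and is out of scope. The
outlier rule flags values strictly beyond 5 control SDs from the control
mean, two-sided by default with a `direction` argument, since the
published use (high outliers of one metabolite) states only a threshold
distance.

# Integration

**Component selection.** Latent components from both biofluids are scored
by how well a classifier discriminates the three genomic classes
(NPM1-mut, chromatin/spliceosome-mut, TP53-mut/aneuploid). The default
score is the component's own stratified-CV accuracy above the
majority-class rate ("solo" mode). Joint-model permutation importance is
also provided, but it was deliberately not made the default: when several
components carry overlapping class signal — the normal situation for
spectra, and the exact situation of the provenance fixture in the test
suite — shuffling any single component leaves a joint model's accuracy
unchanged and every redundant component scores zero. A per-component
classifier score stays informative under redundancy and is closer to the
"classifier-derived scores" the original description suggests.

**Integration and clustering.** Serum and urine score matrices are
inner-joined on the patient key and standardized per column. Hierarchical
clustering defaults to Ward linkage on Euclidean distance (correlation
distance and average/complete linkage available); cluster ids are
relabeled by decreasing size so output is stable under sample
permutation. `k` is fixed by configuration (3 for the intracellular
metabolome, 4 for biofluid NMR profiles) because the original analysis
fixed cluster counts by inspection; a silhouette-based chooser would hide
that judgment rather than encode it.

**Cluster–genotype association.** The cluster × class contingency table is
tested by the Monte Carlo Fisher test (B configurable); per-cluster modal
classes and enrichment fractions are reported. Association p-values are
calibrated under label permutation (KS against uniform, tested).

**NPM1 subgroup split.** Within NPM1-mut patients the metabolic subgroup
split is recovered from the serum latent space: every candidate component
is cut by the exact optimal 1-D two-cluster partition (minimum
within-group sum of squares over all sorted split points, both groups at
least 15% of patients so single outliers cannot pose as subgroups), and
the most bimodal component — largest between-group SS fraction — defines
the split. PCA for this scan runs unscaled: the subgroup signal lives in
a few intense marker peaks, and unit-variance scaling drowns it in noise
bins. A full-space Ward 2-cut was evaluated first and recovered the
planted subgroup in under half of the replicates; the single-component
scan mirrors how such splits are actually visible in practice (on one
latent direction) and is deterministic. The resulting 2×2 subgroup ×
cohesin-flag table is tested by the exact Fisher test with per-subgroup
percentages.

# Constraint-based flux module

Models are stoichiometric matrices with reaction bounds and GPR boolean
rules, read and written as SBML Level 3 with the fbc package (bounds as
flux-bound parameters, GPRs as nested gene-product associations; files
load in COBRApy). Missing bounds default to (−1000, 1000) for reversible
and (0, 1000) for irreversible reactions.

**Expression → constraints.** Gene activity multipliers in (0, 1] are
derived as group-B/group-A mean expression ratios clamped to
[0.05, 1]. A reaction's activity is its GPR evaluated with AND = min
(a complex is as available as its scarcest subunit) and OR = max
(isoenzymes substitute); bounds then scale toward zero: `lb' = a·lb` when
lb < 0, `ub' = a·ub` when ub > 0. This multiplicative bound scaling is a
deliberate simplification of MILP-based expression integration: it is
LP-only, deterministic, and monotone — no feasible-region growth is
possible, which the tests verify as "no FVA interval widens" over random
constraint sets.

**FVA and capability.** Each reaction's flux is minimized and maximized
over the full region `S v = 0, lb ≤ v ≤ ub` — no objective fixation,
because the question is what the feasible space allows, not what a
growth-optimal slice allows. The LPs are solved by a built-in two-phase
tableau simplex with Bland's rule (tolerance 1e-9); an independent oracle
in the test suite re-solves every LP with `boot::simplex` after dead-end
reduction and must agree within 1e-6. Production/consumption capability
adds a temporary drain (`m →`) or feed (`→ m`) with bounds [0, 10⁶] and
maximizes its flux.

**Perturbation calls and network.** A reaction is called when its minimum
(or maximum) flux moves by more than `ε · max(1, baseline range)`,
ε = 0.01 by default; `calls(A) \ calls(B)` gives subgroup-specific calls.
The perturbation network is a directed bipartite graph (substrate →
reaction → product) over called reactions; node size equals outdegree and
colors follow the minimum-flux red / maximum-flux green / no-call light
blue convention ("no call" is the reading adopted for entities without
information; "both" is orange). GraphML is emitted via igraph.

**Toy models.** The `core` variant is a feasible ~18-reaction network
(glucose and glutamine uptake, a glycolysis-like chain, lactate excretion,
TCA-like oxidation, a biomass drain), with coarse C/N element tags chosen
so every internal reaction is exactly element-balanced (cofactor detail is
collapsed; the tags are bookkeeping, not chemistry). `nad_purine` adds
three flux-isolated arms — nicotinamide→NAD, inosine→IMP, and a lipid
modification path — each gated by analogues of the seven genes found
downregulated in the NPM1/cohesin-mut subgroup (ADCY9, DPYSL2, LPL,
CHST13, CYP1B1, SLC8A1, SLC1A3), plus a control subnetwork gated by
unrelated genes. Gated reactions carry capacity 10 against uptake limits
of 5, so any downregulation multiplier below 0.5 binds and propagates a
call to every reaction of the arm; flux isolation guarantees the
subgroup-specific call set covers the NAD/purine subsystem exactly and the
control subsystem not at all. `idh` adds the mutant
akg + NADPH → 2-HG + NADP reaction, disabled by default: with it disabled
the network cannot produce 2-hydroxyglutarate at all; enabled, production
is capped by NADPH supply (5), reproducing the validation logic of
modeling IDH mutations.

# The synthetic world

`cohort_config()` defaults are the stated study design where one exists:
119 AML / 145 control serum donors, AML bone-marrow blasts uniform on
[20, 100] so all three blast classes are populated, cohesin-flag rates
0.60 / 0.091 in the two NPM1 subgroups, and the packaged serum/urine
effect-direction table (glutamine and threonine down in serum; lactate,
3-hydroxybutyrate, glucose and others up; citrate, creatinine, hippurate,
glycine down in urine; phenylalanine up in both). Spectra are sums of
Lorentzian peaks (half-width 0.004 ppm, well under the 0.04 ppm bin so
jitter tests the binning), a flat 0.01 baseline, Gaussian point noise
(SD 0.02), per-sample global shift jitter (SD 0.002 ppm), and per-sample
log-normal concentration noise (SD 0.2); 25 seed-independent background
peaks per biofluid make total-area normalization non-trivial.

Where the literature gives no effect size the defaults were chosen once,
calibrated against the package's own recovery targets, and frozen: peak
fold-change magnitude 1.5 (consistent with the strong reported
significances at these cohort sizes); intracellular panel shift 3 log
units across the high/intermediate/low cluster grades on the 15-metabolite
panel (amino acids, purine/pyrimidine intermediates, lipids), with 30
secondary metabolites at 40% of that shift — real cluster differences
extend beyond a top-scoring panel, and without that mass the 30 pure-noise
metabolites flip borderline samples — and left-censored missingness
(lowest 10% of each metabolite below the detection limit), the mechanism
half-minimum imputation is built for. Null switches (`effect_scale = 0`,
`fold = 1`, `shift = 0`) make classes exchangeable, and the suite checks
chance-level accuracy and ARI ≈ 0 there.

What a green test establishes: that the pipeline recovers planted
structure of realistic shape and size, and that its statistics are
calibrated under the null. What it does not establish: performance on real
spectra (phase/baseline artifacts, peak overlap, annotation ambiguity are
not simulated), nor the cohort-level accuracies of the original study,
which depend on data that are not publicly packaged.

# Numerical choices

- Simplex tolerances 1e-9; FVA–oracle agreement asserted at 1e-6;
  Bland's rule for anti-cycling; iteration cap proportional to problem
  size.
- Fisher probability-mass comparisons use 1e-7 relative slack.
- Classifier tie-breaks: lower SD, then AdaBoost; cluster ids by
  decreasing size; 1-D subgroup partition is exact, not heuristic.
- All randomness flows from a single integer seed through per-purpose
  derived seeds (kept below 2³¹), so every generator and every fold split
  is bit-reproducible and independent sub-steps do not share streams.
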