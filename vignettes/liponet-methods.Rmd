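---
title: "Methods: integrated lipidomics-proteomics analysis with liponet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated lipidomics-proteomics analysis with liponet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analytical problem

Serum lipoprotein particles carry hundreds of lipid species (cholesteryl
esters, triacylglycerols, phospholipids, sphingolipids, free fatty acids)
together with a focused panel of apolipoproteins and remodeling enzymes.
In dyslipidemic states — hypercholesterolemia (HC), hypertriglyceridemia
(HT), combined hyperlipidemia (HL), hyperglycemia (HG) — both the absolute
concentrations and the within-class composition of these molecules shift
relative to normolipidemic (NL) donors. `liponet` implements the complete
downstream analysis of such a study: quantifiable-feature QC, fatty-acyl
saturation categorization, differential abundance versus the NL reference,
per-group lipid–protein correlation networks, local over-representation
analysis, and a data-driven neural-network classifier of the five metabolic
groups. Because the original serum dataset is not publicly deposited, the
package ships a synthetic cohort generator that emulates the cohort's
statistical structure, and every stage is tested against that generator's
ground truth.

# Quality control and imputation

Input is a wide samples × features concentration table (lipids in nmol/mL,
proteins in nmol/L) with per-feature metadata. Features are removed when
their missing fraction across all samples exceeds 30% or their QC-replicate
coefficient of variation (sd/mean) exceeds 30%. Both thresholds are strict
(`>`), so boundary features are retained; this follows the "more than 30%"
wording of the filtering rule. Missingness is computed across the whole
cohort, not per group, since no per-group rule is documented. Zero
concentrations count as observed values. Remaining missing cells are imputed
with one half of the per-feature minimum observed value; observed cells are
never altered, and filter→impute is idempotent. The quantifiability
guideline that species should show roughly 10–20% CVs is reported (the
generator targets 15%) but not enforced — only the 30% rule removes
features.

# Lipid annotation and saturation categories

Species names follow the grammar `CLASS '(' [P-|O-] C:D { '/' C:D }
[ '-FA' C:D ] ')'`. Multi-chain names (e.g. `PC(16:0/20:4)`) carry per-chain
carbon:double-bond annotations whose sums define the totals; Lipidyzer-style
TAG names (`TAG(52:2-FA16:0)`) carry class totals plus one identified fatty
acid. Categorization applies, in order:

1. **ODD** — odd total fatty-acyl carbon count, regardless of double bonds;
2. otherwise the *deciding* double-bond count `d` maps to **SFA/MUFA**
   (`d ≤ 1`), **DUFA** (`d = 2`; "double-unsaturated" fixes the cut at
   exactly two), or **PUFA** (`d ≥ 3`).

When chains are annotated, `d` is the maximum double-bond count over chains
(the "FA with the greater number of double bonds"). For TAG totals-plus-one-FA
names the per-chain maximum is not recoverable; the package's documented
convention is `d = total double bonds`, an upper bound on the true per-chain
maximum. This can only promote a species toward PUFA, never demote it, and
affects only even-carbon TAGs whose double bonds are spread across chains.
The sphingoid backbone of SM/CER species is implicit in their names and
ignored — `SM(14:0)` is categorized from the N-acyl chain alone. Ether
(plasmalogen) chains participate in the maximum like acyl chains.

Class totals are plain member sums per sample; %Abundance divides the
per-category sums by the class total, so the four categories sum to 100% in
every (sample, class) with nonzero total. Group summaries use t-based 95%
confidence intervals and report differences against the NL mean.

# Differential abundance

Per-species comparisons of each disease group against NL use the two-sided
Wilcoxon rank-sum test for independent samples (donors are unrelated, so the
signed-rank variant would be wrong). For combined `n ≤ 12` with untied data
the null distribution is enumerated exactly over all `C(n1+n2, n1)` rank
assignments; otherwise a normal approximation with tie correction and
continuity correction is used. Without the continuity correction the squared
rank-sum z equals the two-group Kruskal–Wallis statistic — a property the
test suite checks directly from the U statistic. Across-group tests are the
tie-corrected Kruskal–Wallis chi-square and, for the class/protein summary
tables, classic one-way ANOVA.

Benjamini–Hochberg q-values are computed by the package's own step-up
(`q_(i) = min_{j≥i} m·p_(j)/j`, capped at 1) and verified against both
`p.adjust` and a brute-force evaluation of the definition. The BH family
defaults to each (group comparison × omics layer); the original report did
not state its family, so this is configurable. Fold changes are log2 ratios
of arithmetic group means, matching the summary tables' use of arithmetic
means. Direction calls use `p ≤ 0.05` (the volcano-plot threshold); q-values
are reported alongside but do not gate the call.

Heatmap inputs are z-scores of group means against the grand mean of the
group means (so each feature's row is exactly centered), clustered with
Euclidean distance and Ward (`ward.D2`) linkage.

# Lipid–protein networks

Within each group, every (protein, lipid) pair's Pearson correlation is
computed on the imputed table (an option for pairwise-complete data exists
upstream by skipping imputation, but the default mirrors imputation-first
processing). Two-sided p-values come from the t transform
`t = r√(n−2)/√(1−r²)`; the paired thresholds `|r| > 0.5` and `p < 0.002` are
consistent at the cohort's group sizes (at n = 36, r = 0.5 gives p ≈ 0.0019).
q-values are BH within the group's full protein × lipid family.

The dual filter keeps an edge iff the correlation is strong (`|r| > 0.5`,
`p < 0.002`, both strict — `|r| = 0.5` exactly is excluded) *and* a
designated endpoint is dysregulated versus NL (`p < 0.05`). Which endpoint
must be dysregulated is not documented; the default is `either`, because the
published networks contain edges (e.g. a negative lipoprotein(a)–ceramide
correlation) whose protein endpoint is only marginally dysregulated, and
`both` would drop them. `lipid` and `both` are available. Edge signs are
retained and exported as distinct `corr_pos`/`corr_neg` interaction types in
SIF/GraphML, which Cytoscape reads directly. Hub proteins are ranked by
lipid degree with alphabetical tie-breaks.

Pathway enrichment replaces the original remote API calls with a local
upper-tail hypergeometric over-representation test over user-supplied GMT
collections: `p = P(X ≥ overlap)` with the supplied universe as population,
BH across sets. Results therefore depend only on files the user provides.

# Predictor screening and the greedy ANN search

The cohort (146 samples) is split 70/30. The split is stratified by default
— the published per-group training counts are near-stratified — using
largest-remainder rounding so the training total is exactly `round(0.7·n)`
(102/44 for this cohort); a simple-random mode reproduces the "randomly
split" wording. Remainder ties break by group level order.

Screening runs repeated cycles (default 100) of a bootstrap-forest
importance ranking: each cycle resamples the training set, fits an ensemble
of Gini-impurity CART trees (package-authored; defaults 25 trees, depth 4,
`mtry = ⌊√p⌋` — the original screening tool does not publish its internals,
so these are documented conventions), and records the top features by
impurity-decrease contribution share. The pool is the 20 most frequently
recorded features, entered into the search in contribution order.

The classifier is a fully connected MLP with one hidden layer of five
Gaussian-activation nodes, `g(z) = exp(−z²)` on the affine pre-activation —
the convention read off "Gaussian activation function nodes" — and
softmax-normalized outputs, fit by BFGS on the multinomial cross-entropy
with a small ridge penalty (default 1e-3) and best-of-restarts selection.
Initialization keeps pre-activations near ±0.7 because the Gaussian
activation has zero gradient exactly at z = 0 and saturates for large |z|.

The greedy search takes each pool member in turn as *leading predictor* and
adds, at each step, the unused pool feature whose addition maximizes the
selection metric, accepting only strict improvements; traces are therefore
acceptance-monotone by construction. The winner across leaders is chosen by
selection accuracy, then macro AUC, then smaller set, then pool order (the
original tie-break is unstated). Two selection modes exist: the default
`cv` scores candidates by stratified 5-fold cross-validated accuracy on the
training set, leaving the test set untouched until the final evaluation;
`paper` scores candidates on the held-out test set, replicating the original
procedure as written — including its information leakage — and is labeled
accordingly. Whether the original "improve the model accuracy" meant
training or test accuracy is unknowable from the text; both modes are
provided. Evaluation reports the confusion matrix, overall accuracy
(trace/total) and per-group one-vs-rest AUC via the rank formulation with
half-credit ties.

# The synthetic cohort generator

The generator's defaults *are* the study's stated conditions: group sizes
36/32/28/29/21 (HC/HT/HL/HG/NL, 146 total); the quantifiable-species census
(12 SM, 9 LPC, 4 LPE, 22 CE, 22 PC, 20 PE, 6 CER, 4 HCER, 23 FFA, 17 DAG,
435 TAG = 574 species); 20 proteins; baseline magnitudes equal to the
printed NL class/protein means so tables are unit-realistic; default group
effects equal to the printed group/NL mean ratios; 15% measurement CV; 5%
sporadic missingness.

Concentrations are lognormal around class-typical means: the CV target maps
to the log-scale sigma via `σ = √ln(1+CV²)`. Latent "particle number"
factors express that protein and lipid concentrations on the same
lipoprotein pool are both proportional to particle number: a factor with
relative spread σ_f contributes a share `w` of each loaded feature's mean,
entering additively on the natural scale before multiplicative noise. The
planted pair correlation is then approximately
`r = w_i w_j σ_f² / √((w_i²σ_f²+c²)(w_j²σ_f²+c²))` with measurement CV `c`;
`factor_sigma_for_r()` inverts this (full loading and c = 0.15 give σ_f =
0.3 for r = 0.8). Ground truth records exactly the planted effects: features
whose effective group/NL mean ratio differs from 1 (shifts and factor group
scales combined), and protein–lipid pairs whose predicted correlation
reaches 0.5.

Missingness is MCAR — the original study does not describe its missingness
mechanism, so nothing more structured is defensible. QC replicates are pure
technical noise around the baseline panel. Within-group covariance beyond
what the latent factors induce is not modeled (the study gives no estimate
of it); loadings are free parameters of the stated scenario, not estimates.
Odd-carbon species are down-weighted 10:1 when the generator samples species
names, since even-chain fatty acyls dominate serum.

What a green test establishes is therefore calibration and recovery under
lognormal, MCAR, factor-block data of realistic magnitude — not performance
under instrument drift, batch structure, informative missingness, or
non-lognormal tails, none of which the generator emulates.

# Numerical and design choices

* Exact rank-sum enumeration switches on at combined n ≤ 12 without ties;
  `C(12,6) = 924` assignments keep it cheap.
* Degenerate inputs are flagged rather than silently dropped: all-identical
  two-group data give p = 1 with a degeneracy flag; zero within-group
  variance makes ANOVA undefined; zero-variance features are excluded from
  correlation with a warning; zero class totals give undefined %Abundance.
* A single master seed fans out to per-stage sub-seeds by a stable integer
  derivation (`sub_seed`), so any stage can be re-run in isolation and the
  whole pipeline is byte-reproducible; the manifest records md5 hashes of
  every output.
* Test-suite simulations use scaled-down search budgets (40 screening cycles
  where the headline example keeps 100; 3-fold CV, 1–2 restarts, small
  forests) to stay within CI time budgets; the statistical conditions (group
  sizes, effect sizes, CV) stay at the stated values.
* The LCER class code appears in quantified species lists but not in the
  class census; it is accepted as valid and simply has no default census
  count.

# Worked example

```{r, eval = FALSE}
library(liponet)

cfg <- synthetic_config(seed = 1)       # the full 146-sample stated world
cohort <- generate_cohort(cfg)
qc <- generate_qc_replicates(cfg, n_reps = 10)

flt <- filter_features(cohort$table, compute_cv(qc))
tab <- impute_half_min(flt$table)

diff <- differential_analysis(tab, cohort$design)
edges <- pairwise_correlations(tab, cohort$design, "HL")
net <- dual_filter(edges, diff, table = tab)
hub_table(net)

stage <- run_classification_stage(tab, cohort$design, seed = 1)
stage$test_eval
```

# Known limitations

* The TAG categorization convention (totals as the deciding double-bond
  count when chains are unknown) can over-call PUFA for even-carbon TAGs;
  it is configurable only by pre-annotating chains.
* The greedy search is not guaranteed optimal; the test suite compares it
  against an exhaustive-subset oracle on small pools and asserts its
  contracts (monotone traces, at least median-of-subsets accuracy) rather
  than optimality.
* Headline results of the original study (counts of dysregulated species,
  published accuracies) are not reproducible without the request-only
  dataset; the package's acceptance targets are the in-paper arithmetic
  quantities and property-based suites on synthetic data.
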