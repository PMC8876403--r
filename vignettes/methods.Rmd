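---
title: "Hierarchical carrier-risk prediction: model, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical carrier-risk prediction: model, generator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`drabc` predicts, from a breast cancer patient's clinical phenotype, the
probability that she carries a germline pathogenic variant (GPV) in a
cancer predisposition gene (CPG). This vignette is the package's account of
the model and of every place where the design was genuinely open: what we
chose, why, and what a green test does and does not establish.

## 1. The hierarchical model

Carrier status is a five-group label (non-carrier, *BRCA1*, *BRCA2*, other
HRR gene, other CPG), but the clinically reported quantities are three
nested probabilities: any-CPG carrier ($P_a$), BRCA1/2 carrier ($P_b$), and
other-CPG carrier ($P_c$). The network has two sigmoid output neurons —
$P_1$, the probability of carrying any GPV, and $P_2$, the probability that
a carrier's GPV is in *BRCA1/2* — composed by the probability chain rule:

$$P_a = P_1, \qquad P_b = P_1 P_2, \qquad P_c = P_1 (1 - P_2),$$

so $P_b + P_c = P_a$ holds *identically*, not approximately; the test suite
asserts it to $10^{-12}$ on random inputs and $10^{-9}$ on every ensemble
prediction.

Architecture: 25 input neurons, hidden layers of 16 and 8 units with SELU
activations (self-normalizing networks keep hidden representations roughly
Gaussian on standardized tabular input, which is why we standardize age
rather than min–max scale it), inverted dropout with rate 0.25 on both
hidden layers during training only, LeCun-normal initialization (variance
$1/\mathrm{fan_{in}}$, the initialization SELU's fixed-point analysis
assumes), and two independent sigmoid outputs.

**Loss.** The training targets are described in the source material as a
"one-hot" encoding of $[P_a, P_b, P_c]$, which cannot be literal: a BRCA
carrier's truth vector is $(1, 1, 0)$. We implement the factorization the
chain rule implies — hierarchical binary cross-entropy

$$L = \mathrm{BCE}(P_1, y_{any}) + y_{any}\,\mathrm{BCE}(P_2, y_{brca}),$$

with the $P_2$ term masked for non-carriers, for whom "which gene" is
undefined. A finite-difference test confirms $\partial L/\partial P_2 = 0$
for non-carriers.

**Optimization.** Beyond cross-entropy-with-gradient-descent, the original
method description pins down no optimizer; we use Adam (lr $10^{-3}$), batch size 64, up to 200
epochs with early stopping once the epoch training loss improves by less
than $10^{-6}$ for 10 consecutive epochs. All exposed as arguments. The
trainer is compiled C++ (RcppArmadillo) with its own Mersenne-Twister
stream, so training is bit-reproducible given `(data, seed,
hyperparameters)` and leaves R's RNG untouched; the plain-R forward pass is
the reference implementation the tests cross-check it against (an `lr = 0`
run returns the initial weights, whose R-side loss must equal the C++
epoch-1 loss).

**Ensemble.** 101 members by default. The diversity mechanism is not
specified in the main source text (it lives in a supplement we treat as
unavailable), so we declare one: bagging — member $k$ trains on a bootstrap
resample with seed $s_0 + k - 1$ — with the ensemble score the arithmetic
mean of member $(P_1, P_2)$ before the chain rule. Median aggregation is a
config switch. Class imbalance is left unweighted, matching the source's
silence.

**Cutoffs.** For each scenario the decision threshold is selected on the
*training* cohort's ensemble scores: the largest candidate threshold (the
distinct scores) whose sensitivity is at least 0.90, falling back to the
maximum-sensitivity (smallest) candidate when 0.90 is unattainable. Calls
use `score >= tau`. Whether the original thresholds were fixed on discovery
data only is implied but unstated; fixing them on training data is the
choice here.

## 2. The 25-feature encoding

The literal input-feature table of the source is in an unavailable
supplement, so the package ships a documented reconstruction — every member
is a significant class discriminator in the published characteristics
table: standardized age; personal history any/breast/ovarian; family
history breast/ovarian/pancreas/male-breast/any; bilaterality; tumor size
\> 2 cm; grade II and III; IDC and DCIS histology; ER/PR/AR/EGFR/CK5-6
positivity; HER2 positive and HER2 *uncertain* (its own level, mirroring
the published table); Ki67 \> 30%; P53 gain-of-function; node positivity.

The upstream default list nominally also included an early-onset
($\le 40$) flag, but the enumerated members sum to 26 against a hard
requirement of 25 input neurons; we dropped the early-onset indicator as
the redundant member (it is a deterministic threshold of the standardized
age feature already present) and kept the other 25. `age_center` and
`age_scale` are refit from each training cohort and serialized with the
model, so validation encoding is reproducible. The all-reference patient
(age at center, no history, unilateral, small low-grade non-IDC/DCIS
marker-negative tumor) encodes to the zero vector — a convenient test
anchor.

Exclusions before training mirror the source cohort construction: patients
whose testing found only variants of uncertain significance are removed
first, then patients with incomplete clinical information or family cancer
history; a record qualifying under both is counted once, under VUS.

## 3. The synthetic cohort generator

The generator emulates the *published class-conditional structure* of the
study cohort: group prevalences $(2596, 131, 132, 43, 26)/2928$; per-group
age-at-diagnosis Normal(mean, SD) truncated at 18 (re-draw on violation);
and per-group marginal frequencies for every flag and categorical feature,
renormalized over known categories because the published table does not
print unknown counts (an interpretation, flagged as such).

One joint structure is preserved: the published per-group triple-negative
rates over-determine independent ER/PR/HER2 draws, so the generator samples
HER2 from its three-level marginal and (ER, PR) from a $2\times2$ joint
whose both-negative mass is $q_g = t_g / \Pr(\mathrm{HER2}^-\mid g)$ (with
$t_g$ the group TNBC rate), clipped to the Fréchet bounds with a warning if
infeasible — for the packaged table it is feasible in every group. This
matches all three marginals and the TNBC rate in expectation; a 200k-draw
check during development found no bias.

**What the generator does not emulate** — and therefore what green tests do
not establish: features are conditionally *independent* given the carrier
group (the published table provides marginals only), so synthetic class
separability exceeds a real cohort's, where pathology features are strongly
inter-correlated. End-to-end held-out AUCs on synthetic data (≈ 0.85–0.90)
certify that the pipeline learns and generalizes the encoded signal, not
that the model achieves any particular performance on real patients.
Missingness and VUS status are optional rates (default 0) used to exercise
the exclusion filter, not a model of real missingness mechanisms; family
history is a set of flags, not a pedigree.

## 4. Comparators

**Rule engine.** The default ruleset encodes the guideline indications
expressible over a flag-level phenotype record: diagnosis $\le 45$; 46–50
with a second primary, an affected close relative (breast, ovarian,
pancreatic, prostate), or unknown family history; TNBC $\le 60$; any age
with a relative with ovarian, pancreatic or male breast cancer; personal
ovarian cancer; bilateral disease with family history. The clause "two or
more relatives with breast cancer" is not expressible over a single flag
and is omitted. Rules are data: eligibility is the OR over rules, a rule
touching an unknown field stays silent for that record, and the fired-rule
matrix is attached for audit. The expansion variant ORs in diagnosis
$\le 65$ and is provably a superset (tested). Because the original
operationalization is not enumerated, this engine approximates — it cannot
reproduce — the published eligibility counts.

**Reconstructed baselines.** In-cohort analogues of the classical models,
not re-implementations of their pedigree likelihoods: logistic regressions
(Myriad-like: age class + family breast/ovarian history; PENN-II-like: +
bilaterality and personal ovarian history) and naive-Bayes classifiers
(BRCAPRO-like: family history + age bins $\le 40$/41–50/51–65/$>65$;
BOADICEA-like: + ER/PR/HER2/grade, since incorporating pathology is that
model's distinguishing trait). Variable subsets are config-overridable; the
published subset table is in an unavailable supplement, so these are
declared defaults. Logistic fits fall back to ridge (glmnet, $\alpha = 0$,
$\lambda = 10^{-3}$, flagged) under separation; naive Bayes uses add-one
smoothing by default.

## 5. Evaluation statistics

Midrank (Mann–Whitney) AUC, verified against exhaustive pair counting.
DeLong structural-components variance for CIs and the paired test (the
midrank formulation, i.e. the fast algorithm); perfect separation yields a
zero-variance degenerate CI, returned flagged rather than hidden. Youden
$J$ = sensitivity + specificity − 1. Odds ratios with Woolf log-scale CIs
and the Haldane–Anscombe $+0.5$ correction applied to all cells iff any
cell is zero (flagged). Association tests follow the source's stated
choices: equal-variance Student's *t* for age (not Welch; switch available
in code by calling `t.test` directly), Pearson $\chi^2$ without continuity
correction, switching to Fisher's exact test when any expected cell is
below 5 — the conventional reading, since the source lists both tests
without stating its rule. No multiple-testing correction, matching the
source. Percentages print to one decimal; unrounded values are retained.

## 6. Numerical and degenerate-input choices

- Probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside logs.
- Cutoff candidates are the distinct observed scores; ties in the Youden
  maximizer resolve to the first (largest-threshold) maximum.
- Stratified splitting allocates `floor(fraction * n)` records in total by
  the largest-remainder method over groups, so each group lands within one
  record of its share; fold assignment deals a seeded within-group
  permutation round-robin.
- Empty cohorts, single-class labels, scenarios without positives, and
  zero-variance comparisons all produce explicit errors or flagged `NA`s,
  never silent numbers.
- Serialized models use 17-significant-digit JSON so a reloaded model
  reproduces calls exactly at threshold boundaries; the frequency table and
  configs use the same container format (JSON throughout — the environment
  provides no YAML parser, and a diff-able text container was the goal, not
  a particular syntax).

## 7. The label-shuffle control

One subtlety worth recording: a model trained on permuted labels and then
scored against the *true* labels of an independent cohort does **not**
concentrate at AUC 0.5. The noise-fit model implements an essentially
random direction in feature space, and a random direction's AUC against a
real discriminant has a spread far wider than sampling noise (we measured
0.35 on the first attempt). The calibrated negative control — and the one
this package's acceptance suite uses — is the *cross-validated* AUC on the
label-shuffled cohort itself: held-out labels are then genuinely
signal-free, and the mean over folds concentrates tightly at 0.5.

## 8. Known limitations

- The 25-feature list, the ensemble diversity mechanism, and the baseline
  variable subsets are documented reconstructions of unavailable
  supplementary material, not transcriptions.
- The generator's conditional-independence assumption inflates synthetic
  separability; do not read synthetic AUCs as clinical performance.
- The rule engine operates on flags and cannot express relative-count or
  pedigree-level indications.
- Published headline AUCs (0.79 BRCA1/2, 0.74 any-CPG on the multi-center
  validation cohort) depend on the original patient-level data and trained
  weights and are not reproducible here; the acceptance suite therefore
  verifies worked examples computable from published numbers plus
  property-based checks of the machinery.
- Acceptance runtime scaling: the ablation-direction check uses 15-member
  ensembles (3 seeds × 2 conditions) rather than 101 to fit a desk-scale
  time budget; member count narrows ensemble variance but does not affect
  the tested direction.
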