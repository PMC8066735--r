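---
title: "plantloc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plantloc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant proteins are distributed over roughly a dozen subcellular
compartments, and the assignment is both *multiclass* (11 compartments
here: plastid, cytoplasm, extracellular, nucleus, mitochondrion, cell
membrane, Golgi, endoplasmic reticulum, vacuole, peroxisome, cell wall)
and *multilabel* (some proteins genuinely reside in two compartments;
the supported pairs are Mito–Plastid, Cyto–Nucleus and Cyto–Golgi).
Class sizes are strongly imbalanced: plastid and membrane proteins
dominate, while cell wall and peroxisome proteins are rare. `plantloc`
implements the full prediction workflow: a fixed 479-dimensional
sequence encoding, three feature-selection procedures, a heterogeneous
average-voting ensemble, and the evaluation machinery around it.

## The feature encoding

Every protein is mapped to the same ordered 479-feature schema
(`feature_schema()`), organized in blocks:

| block | size | content |
|---|---|---|
| AAC | 20 | amino acid composition |
| APAAC | 30 | amphiphilic pseudo amino acid composition, $\lambda=5$, $w=0.1$ |
| Blosum | 8 | BLOSUM62-derived residue scale projection |
| CTDC / CTDT / CTDD | 21 / 21 / 105 | composition–transition–distribution |
| Geary | 40 | Geary autocorrelation, 4 properties × lags 1..10 |
| PAAC | 30 | type-I pseudo amino acid composition, $\lambda=10$, $w=0.1$ |
| PsePC | 22 | type-I (parallel) PseAAC, $\lambda=2$, $w=0.05$ |
| PseSC | 26 | type-II (serial) PseAAC, 3 properties, $\lambda=2$, $w=0.05$ |
| scalar/scale block | 57 | physicochemical indices + 9 scale projections |
| QSO / SOCN | 60 / 20 | quasi-sequence-order, 2 distance matrices, lags 1..10 |
| external | 18 | sorting-signal/TM/NLS/ER/mitochondrial/aggregation scores |
| Homology | 1 | GO-homology categorical code |

Design notes on the encoding:

* **PseAAC.** Type-I correlation factors are
  $\theta_k = \frac{1}{L-k}\sum_i \Theta(R_i, R_{i+k})$ with $\Theta$
  the mean squared difference of three standardized residue properties
  (Eisenberg-consensus hydrophobicity, Hopp–Woods hydrophilicity,
  side-chain mass). Type-II ("serial"/amphiphilic) keeps one
  product-correlation factor per property and lag, in lag-major order.
  The per-block $\lambda$ values (2, 2, 10, 5) are pinned by the block
  dimensions of the schema (22, 26, 30, 30): for APAAC, $20+2\lambda=30$
  forces $\lambda=5$. The weight assignment (0.05 for the parallel and
  serial blocks, 0.1 for PAAC/APAAC) is the package's choice among the
  two published values.
* **CTD.** Residues map into 3 groups under 7 physicochemical
  properties (Dubchak-style partitions, shipped as a versioned table).
  The distribution block uses the ceiling percentile rule: the position
  of the $\lceil q \cdot n_g \rceil$-th group member for
  $q \in \{0^+, .25, .5, .75, 1\}$, as percent of sequence length,
  zeros when a group is absent. The transition block is normalized by
  the number of *cross-group* adjacencies, so it is a distribution over
  the three unordered group pairs whenever any transition exists (the
  classical definition divides by $L-1$ instead; the distributional
  form was chosen as the cleaner contract and is what the tests pin).
* **Geary.** $c(k) = \frac{(N-1)\sum_i (x_i - x_{i+k})^2}
  {2(N-k)\sum_i (x_i-\bar x)^2}$ on alphabet-standardized property
  values; the 40-feature block uses hydrophobicity, hydrophilicity,
  side-chain mass and polarity — the property count is forced by the
  printed block size, the specific four are the package's choice and
  configurable. Zero-variance input returns the no-autocorrelation
  fixpoint $c(k)=1$.
* **QSO/SOCN.** Coupling numbers
  $\tau_d = \sum_i d(R_i, R_{i+d})^2$ under two residue distance
  matrices. The Grantham chemical distance is *recomputed* from its
  published formula over the Grantham composition/polarity/volume
  indices (AAindex) and rescaled to mean 100; the reconstruction
  reproduces the published extremes (Leu–Ile 5, Cys–Trp 215). The
  second matrix is an in-package construction: Euclidean distance over
  standardized hydrophobicity, hydrophilicity and side-chain mass,
  scaled to max 1. It follows the design of the classical
  sequence-order distance table but its numeric values are this
  package's own derivation — a documented stand-in, not a transcription.
* **Property scales.** The nine multi-dimensional residue scales
  (Cruciani-style 3, FASGAI-style 6, MS-WHIM-style 3, protFP-style 8,
  st-scale-style 8, t-scale-style 5, VHSE-style 8, z-scales 5,
  BLOSUM-derived 8) are projected by the arithmetic mean over residues.
  With the exception of the z-scales (the published Sandberg table,
  transcribed), the scale values are derived at load time as principal
  components of thematically curated AAindex subsets (hydrophobic,
  steric, electronic, structural groups), mirroring how the published
  scale families were constructed; the BLOSUM scale is the PCA of the
  BLOSUM62 substitution matrix rows. Only the dimensions are
  contract-bound; the derivation is deterministic (fixed index lists,
  fixed sign convention).
* **Scalar indices.** Net charge and isoelectric point use a
  Henderson–Hasselbalch model with the EMBOSS pK set (pI by bisection
  on [0, 14] to 1e-4). The instability index uses the published
  Guruprasad dipeptide weights with the $10/L$ scaling. The aliphatic
  index is $100 f_A + 2.9\cdot 100 f_V + 3.9(100 f_I + 100 f_L)$. The
  Boman index is the mean of negated Radzicka–Wolfenden octanol→water
  transfer energies. Hydrophobic moments are maxima over 11-residue
  windows at 100° (helix) and 160° (sheet). Auto-/cross-covariance are
  lag-averaged products of standardized hydropathy and hydrophilicity
  profiles (the two cross terms are the two lag orderings).
* **Minimum length.** Sequences shorter than 11 residues are rejected
  at extraction: lag-10 descriptors are undefined below nlag+1.
* Ambiguous residue letters follow a configurable policy, default
  U→C, O→K, B→N, Z→Q, J→L with X dropped, because all descriptor
  formulas are defined over the 20 canonical letters only.

## External scores and the homology feature

The 18 external predictor scores (targeting probabilities cTP/mTP/SP/
other, transmembrane segment count, NLS, ER score, five mitochondrial
sub-location SVM scores, six aggregation/conformation scores) are
inputs, not re-implementations: they arrive via a TSV table or from a
deterministic mock provider whose per-class latent biases make them
learnable stand-ins in simulation. The GO-homology feature searches an
annotated reference by local alignment (BLOSUM62, gap 11/1, an
approximate Karlin–Altschul e-value, cutoff 1e-5 by default), maps the
best hit's first mapped cellular-component GO term through the shipped
27-term GO→compartment table (sub-locations map to their parent
compartment), and encodes the result as a categorical code 0..11 with 0
the no-evidence sentinel. The search backend is pluggable, so an
external aligner can replace the built-in one without touching the
feature contract.

## Feature selection

* **ReliefF** (multiclass, class-prior-weighted misses, Manhattan
  distance on [0,1]-scaled features, k = 10 neighbours, all instances
  sampled by default).
* **OneR** ranking: equal-frequency discretization (10 bins; distinct
  values when fewer), score = training accuracy of the per-bin majority
  rule.
* **CFS** merit $\frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\bar r_{ff}}}$
  with symmetric uncertainty on discretized variables, searched by a
  bitmask genetic algorithm (population 50, 100 generations, uniform
  crossover 0.6, per-bit mutation 0.02, tournament selection, elitism
  1 — so the best merit is non-decreasing). The GA parameters are
  package defaults; no published values exist for this workflow.

Subset sizes for the ranking methods are a user decision (`top_n`,
default 95): published subset sizes of comparable workflows are
empirical outcomes of their specific training data, not a rule. A
formula fixpoint worth knowing: two *exact* copies of a feature have
the same merit as the singleton ($k{=}2$, $\bar r_{ff}{=}1$ gives
exactly $r$); redundancy strictly lowers merit once the duplicate is
degraded relative to a strong original.

## The ensemble

Three base classifiers are trained on identical rows and features:
inverse-distance-weighted KNN with k = 12 (Euclidean distance on
features standardized by training mean/sd — KNN needs a scale decision,
and the standardization parameters are stored in the model), a
100-tree random forest, and XGBoost (50 rounds, depth 5, eta 0.1,
multiclass log-loss). The consensus is the unweighted mean of the three
class-probability vectors ("average voting"); it is permutation-
equivariant in the base models and remains a valid distribution if a
model is dropped and the rest re-averaged.

Dual-labeled training records are handled by the `duplicate` policy by
default (the record appears once per constituent class), matching a
base-learner setup with 11 classes; a `pair-class` alternative treats
each pair as its own training class and collapses pair probability
mass back onto the constituents at prediction. The label decision takes
the top consensus class always and adds the runner-up iff its
consensus probability reaches `theta` (default 0.30, chosen so a
near-tie like 0.45/0.40 yields two labels while a dominant top class
yields one; `theta = 1` forces single-label output). At most two labels
are ever emitted, since all supported multilabel classes are pairs.
XGBoost's float32 probability rows are renormalized so consensus rows
sum to 1 at double precision.

## Evaluation

Per-class one-vs-rest counts give ACC, Sn, Sp and MCC (MCC set to 0 on
a vanishing denominator factor); AUC is the midrank Mann–Whitney
statistic. A record is *correct* only when its predicted label set
equals the true set exactly — an all-or-nothing rule, which is the
stricter reading for dual-label records; per-location tables report
single-location rows, pair rows, and single/multi/combined subtotals.
Dual-labeled records count as positives of both their compartments in
one-vs-rest tallies. The single AUC summary is the macro average over
per-compartment AUCs. Cross-validation is stratified by label set;
feature selection and model fitting happen inside each training fold
only, and classes with fewer members than folds degrade stratification
gracefully with a warning.

## The synthetic generator

`generate_synthetic()` draws sequences from a shared background
composition perturbed along a per-class signature direction (3–4
boosted marker residues) scaled by `signal_strength`, adds simple
sorting-signal-like motifs (N-terminal Arg/Ser stretch for plastid,
internal Lys/Arg block for nucleus, hydrophobic N-terminus for
extracellular, hydrophobic internal block for membrane proteins), and
pairs each record with mock external scores biased toward its class.
Dual-label records mix the two parent signatures 50/50. Default class
counts mirror a redundancy-reduced plant training set's imbalance shape
at about 1/6.5 scale (546 records, max/min single-class ratio ≈ 14,
with 49 dual-label records across the three pairs); lengths are uniform
on 50–400.

What the generator does *not* emulate: real transit-peptide grammar,
homology structure between records, correlated noise between the
external tools, or realistic class overlap. Passing the recovery tests
therefore demonstrates that the pipeline's plumbing, encoding and
learners work end to end and that the evaluation is honest — not that
the same accuracy would be reached on curated plant proteomes.
Dual-label calls are markedly harder than single-label calls under
these conditions (the mixed-signature records sit between two classes
and the runner-up rarely clears `theta`), which mirrors the gap between
single- and multi-location accuracy that localization predictors report
on real data.

## Numerical and reproducibility choices

* Every stochastic step (generator, mock scores, ReliefF sampling, GA,
  RF/XGB fits, fold assignment) funnels through an explicit integer
  seed, and RNG state is restored afterwards; two runs with the same
  seed are identical.
* Feature TSVs serialize at 12 significant digits; descriptor oracles
  agree with an independently coded brute-force implementation within
  1e-8 relative tolerance on 200 random sequences (15–500 residues).
* Rank-2 label ties break by canonical compartment order; ranking-
  selection ties break by schema order.
* Problem sizes used by the shipped checks — 546-record strong-signal
  CV, 220-record null CV, 200-sequence oracle sweeps, 100 GA recovery
  runs — were chosen as the smallest sizes at which the statistical
  contracts are stable.

## Known limitations

* The external predictors are mocked or file-fed; the package makes no
  claim about their availability or calibration.
* The derived property scales and the second sequence-order distance
  matrix are in-package derivations with the published *structure* but
  not the published numbers; workflows requiring byte-compatibility
  with other descriptor software should supply their own tables.
* No probability calibration, stacking or resampling for class
  imbalance is performed; the ensemble is exactly the three base
  models under average voting.
* Benchmark figures from curated plant datasets are not reproducible
  here by design: they require the original sequence sets and live
  external tools. The package reproduces the *workflow* and its
  arithmetic, and verifies it on synthetic conditions.
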