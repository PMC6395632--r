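---
title: "Sequence encodings, feature selection and evaluation for S-nitrosylation site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence encodings, feature selection and evaluation for S-nitrosylation site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrosite)
```

## The problem

S-nitrosylation (SNO) is a reversible post-translational modification in
which nitric oxide covalently attaches to the thiol group of a cysteine
residue. Because experimental mapping of SNO sites (biotin-switch and
related chemistries) is slow and low-throughput, sequence-based
classifiers are used to triage candidate cysteines. The task is binary:
given the local sequence neighbourhood of a cysteine, predict whether it
is S-nitrosylated.

The unit of analysis is a *peptide window*
$P = R_{-t} \ldots R_{-1}\,(C)\,R_{+1} \ldots R_{+t}$: the cysteine plus
$t$ flanking residues on each side. The package default is $t = 10$,
giving 21-mers; flanks that run past a protein terminus are padded with
the dummy residue `X`, so the window alphabet has 21 letters (20 standard
amino acids + `X`). `extract_windows()` produces one window per cysteine
of a protein; `sno_dataset()` carries equal-length labeled windows.

## The nine sequence encoders

Each window is mapped to a numeric feature vector by up to nine encoders,
in two families.

**Composition encoders** depend only on the window itself:

* *Pseudo amino acid composition* (`pcpseaac`, 20 + λ features): the 20
  normalized residue frequencies $f_i$ plus λ sequence-order correlation
  factors $\Theta_j$, all divided by the common denominator
  $\sum f_i + w\sum_j \Theta_j$ so the vector sums to 1. The tier factor
  $\Theta_j$ is the mean, over residue pairs $j$ positions apart, of the
  mean squared difference of standardized physicochemical indices of the
  two residues. The classic three indices are used: Chou's
  hydrophobicity, Hopp–Woods hydrophilicity and side-chain mass. Each
  index is standardized over the 20 amino acids to zero mean and unit
  mean square (population divisor 20), so indices on different natural
  scales contribute comparably.
* *General pseudo amino acid composition* (`pcpseaacg`, 20 + λ): the same
  construction averaged over an arbitrary user-supplied index set
  (`sno_indices()`, `read_index_tsv()`); with the classic three indices
  it reproduces `pcpseaac` exactly, which is tested.
* *kmer* (`kmer1`, 20; `kmer2`, 400): occurrence frequencies of single
  residues and dipeptides over the 20-letter alphabet, normalized by the
  number of `X`-free k-mers.

Defaults are $\lambda = 5$ and $w = 0.5$, the values reported as optimal
for this task in the source datasets. `X` has neither physicochemical
values nor a slot in the 20-letter composition alphabet, so `X`
occurrences are excluded from frequencies and `X`-containing pairs are
skipped in $\Theta_j$ with the denominator reduced to the number of
evaluated pairs. Whether the original predictor computed the composition
on the padded or de-gapped window is not recorded anywhere we could
verify; exclusion is this package's choice and keeps every composition
vector a proper probability vector.

**Profile encoders** additionally require class-conditional positional
frequency tables fitted on training data
(`fit_positional_profiles()`):

* *Bi-profile Bayes* (`bpb`, $2 \cdot 2t$ = 40): the empirical
  probability of the observed residue at each non-center position, one
  block from the positive-class profile, one from the negative.
* *Adapted-normal BPB* (`anbpb`, 40): as BPB, but each positional
  frequency is z-scored against the 21 letter-frequencies at that
  position within the class and mapped through the standard normal CDF
  $\Phi$. The z-scoring population (the 21 letter frequencies at the
  position, population standard deviation) is this package's recorded
  convention; the original description delegates the formula to earlier
  work. A zero-spread position encodes $\Phi(0) = 0.5$.
* *Double BPB* (`dbpb`, $2(2t-1)$ = 38): adjacent residue *pairs* of the
  de-centered window, positive block then negative block.
* *IAAPair* (`iaapair`, $4t - 1$ = 39): over the **full** 21-residue
  window (the center cysteine is deliberately kept), the
  positive-minus-negative posterior probability of the observed adjacent
  pair (20 positions) and gap-1 pair (19 positions).
* *PSTAAP* (`pstaap`, $2t - 2$ = 18): positive-minus-negative posterior
  of the adjacent residue triplets of the de-centered window.

The center-inclusion conventions are fixed by the published feature
dimensions (40/38/40/39/18 at $t = 10$; 645 for all nine blocks with
$\lambda = 5$) and verified by test. Raw empirical frequencies are used;
a Laplace `smoothing` pseudocount is available but off by default.

Because profile encoders are supervised, they leak label information if
fitted on data that later serves as test material. Every evaluation
routine here refits profiles (and feature selection, scaling and the
classifier) on each training fold; `paper_mode = TRUE` fits profiles
once on the full dataset, which reproduces the convention some published
predictors appear to have used and is kept only to demonstrate the
inflation (a test shows pure-noise data scores above honest chance under
it).

## Feature ranking and selection

**Information gain** (`information_gain()`, `rank_features_ig()`):
features are reduced to binary presence (value > 0) and scored by
$IG = H(\text{class}) - H(\text{class} \mid \text{feature})$ in bits,
computed from the 2×2 contingency counts with $0 \log 0 := 0$. The
implementation is verified exhaustively against a brute-force plug-in
mutual-information oracle on every contingency pattern up to $n = 12$.
Residue-level (`rank_residue_ig()`), dipeptide-level
(`rank_dipeptide_ig()`) and position-level (`rank_position_ig()`)
rankings follow the same estimator.

**MRMD** (`mrmd_rank()`): each feature is scored as
$w_r \cdot |r_{\text{Pearson}}(\text{feature}, \text{label})| +
w_d \cdot \overline{D}_i$, where $\overline{D}_i$ is the feature's mean
distance to all other features under Euclidean distance, cosine
dissimilarity ($1 - \cos$), one minus the Tanimoto coefficient, or the
arithmetic mean of the three. Defaults are $w_r = w_d = 1$ and **raw**
(unscaled) distances: min-max scaling the distances
(`scale_distance = TRUE`) stretches chance-level distance differences
among near-exchangeable features across the whole unit interval and lets
them swamp the relevance term — measured on the synthetic generator it
makes the cosine and Tanimoto variants rank a noise residue above a
strongly planted one. The raw combination presumes features of
commensurate scale, which all encoder outputs here are (bounded
frequencies and probabilities); this scale sensitivity is a known
limitation for arbitrary user matrices.

**Incremental selection**: `incremental_selection()` walks down a
ranking, evaluating the top-$d$ subset for each candidate dimension and
keeping the $d$ with the best accuracy (ties toward the smaller
dimension). `incremental_cv()` is the cross-validated form used
end-to-end: per fold it fits profiles and the ranking on the training
part once, then scans the dimension grid refitting only the classifier,
pooling confusion counts across folds per dimension. The default grid
doubles from 1 to the full dimension — the accuracy-versus-dimension
curves this produces are coarse but locate the plateau at a fraction of
the cost of a step-1 scan, whose granularity the original study did not
record either.

A practical division of labour, visible in the package's own
experiments: presence-binarized IG is informative for sparse frequency
blocks (kmer2 above all — 400 mostly-zero dimensions) but is blind to
dense continuous profile features, whose presence is nearly always 1;
correlation-based MRMD handles those. The end-to-end demonstration
therefore ranks the mixed 645-feature matrix with MRMD, while IG is the
tool of choice for reducing kmer2 (400 → 180 in the source study,
leaving 425 of 645 features).

## Classifier and evaluation

The original study never discloses its classifier, so the classifier
here is pluggable (any list with `fit`/`predict`) and deliberately
excluded from scientific claims. The default is an RBF-kernel SVM with
per-training-fold feature standardization, fixed $C = 1$ and
$\gamma = 1/d$; `sno_classifier("svm", tune = TRUE)` enables a small
grid search ($C \in \{1, 10, 100\}$,
$\gamma \in \{1/d, 0.01, 0.001\}$, 5-fold internal accuracy) for final
models where the extra cost is justified. A logistic-regression
baseline is included.

Performance is reported as sensitivity, specificity, accuracy and the
Matthews correlation coefficient from pooled confusion counts
(`compute_metrics()`); any 0/0 ratio is defined as 0 with a warning, so
degenerate all-one-class predictions yield Sp = 0, MCC = 0 rather than
NaN. `cross_validate()` provides seeded stratified repeated k-fold and
the deterministic jackknife (leave-one-out); repeated CV reports both
the per-repeat mean and the best repeat, the two conventions used in
the source study's comparison tables.

## The synthetic generator

`simulate_dataset()` emulates the structure the profile encoders and IG
assume: windows with a center cysteine whose non-center positions are
drawn from a background distribution (default uniform over the 20
standard residues), with planted positional signals — residue $r$ at
offset $o$ overwriting the background draw with probability $p^+$ in
positives and $p^-$ in negatives. The default motif is a single lysine
immediately upstream of the cysteine ($o = -1$, $p^+ = 0.8$,
$p^- = 0.05$), an idealization of the acid-base motif enrichment that
positional SNO encoders exploit. Under it
$P(K_{-1} \mid +) = 0.81$ and $P(K_{-1} \mid -) = 0.0975$, so the Bayes
accuracy of the generating process is ≈ 0.856: the end-to-end
requirement of cross-validated accuracy above 0.85 is met only when the
pipeline isolates the informative positional features essentially
perfectly, which is what makes it a sharp acceptance property.

What the generator does **not** emulate: the amino-acid background of
the real SNO proteome (deliberately uniform), correlations between
positions, homology structure between windows (the real corpora were
redundancy-reduced at 40% identity upstream), and `X` padding patterns
of windows near protein termini. Passing the synthetic acceptance
checks therefore demonstrates correctness of the machinery, not
real-data performance. The published training corpus (731 positive /
810 negative 21-mers) and the two independent test sets can be loaded
with `load_dataset()` when available; reproducing the published
accuracy figures is explicitly out of scope because they depend on the
undisclosed classifier.

## Numerical conventions and problem sizes

* All arithmetic in double precision; composition-vector normalization
  tested at 1e−9, index standardization at 1e−12.
* Entropies in bits (base-2 logarithms); $0 \log 0 := 0$.
* Ranking ties broken by original column order (stable sort) for
  reproducibility.
* Every stochastic routine takes a single integer seed; identical seeds
  give bit-identical outputs, which is tested.
* Profile JSON serialization stores integer counts, not probabilities,
  so a round trip is exact.
* The test-suite and demonstration problem sizes are 500 + 500 windows
  at $t = 10$ for the end-to-end checks and the published corpus shape
  (731/810) for the ingestion check — large enough for the planted
  signal to dominate sampling noise, small enough that the whole suite
  runs in a couple of minutes on one CPU.
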