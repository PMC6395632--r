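# nitrosite

Sequence-based prediction of protein S-nitrosylation (SNO) sites in R.

S-nitrosylation — the covalent attachment of nitric oxide to a cysteine
thiol — regulates redox signalling, and mapping which cysteines carry it
experimentally is slow. `nitrosite` implements the sequence-window
machinery used by modern SNO-site predictors as a reusable toolkit for
bioinformaticians building or benchmarking such classifiers:

* **Windows**: extraction of cysteine-centered peptide windows
  $R_{-t}\ldots R_{-1}(C)R_{+1}\ldots R_{+t}$ (default $t = 10$,
  21-mers, `X`-padded at protein termini) from FASTA, plus labeled
  TSV/FASTA dataset I/O.
* **Nine encoders**: pseudo amino acid composition (classic and
  general-index form, $20+\lambda$ features each), kmer1/kmer2
  compositions (20/400), and five training-set-dependent positional
  encoders — bi-profile Bayes (40), adapted-normal BPB (40), double BPB
  (38), pairwise propensity IAAPair (39) and tri-amino-acid propensity
  PSTAAP (18); all nine concatenate to 645 features at $t = 10$,
  $\lambda = 5$.
* **Feature selection**: information gain
  $IG = H(\text{class}) - H(\text{class}\mid\text{feature})$ on
  presence-binarized features (verified against an exhaustive
  brute-force oracle), MRMD ranking (absolute Pearson relevance + mean
  Euclidean/cosine/Tanimoto distance), and incremental
  accuracy-versus-dimension selection under cross-validation.
* **Evaluation**: Sn/Sp/Acc/MCC from pooled confusion counts, seeded
  stratified repeated k-fold and jackknife CV, with supervised stages
  refit per training fold (no label leakage; a `paper_mode` switch
  demonstrates the inflation the leaky convention causes).
* **Synthetic data**: seeded generators of proteins and labeled window
  datasets with planted positional motifs, so everything is testable
  without downloads.

## Worked example

```r
library(nitrosite)

## a labeled window dataset with a planted K at position -1
d <- simulate_dataset(200, 200, t = 10, seed = 1)
d
#> sno_dataset: 400 windows of length 21 (t = 10)
#>   200 positive (SNO), 200 negative

## which residues carry label information?
print(rank_residue_ig(d), n = 3)
#> sno_ranking (ig): 20 features
#>   feature    score
#> 1       K 0.105800
#> 2       R 0.011860
#> 3       H 0.007245
#>   ...

## fit a predictor and cross-validate it honestly
m <- sno_fit(d, encoders = c("bpb", "anbpb"), seed = 1)
m
#> sno_model: S-nitrosylation site predictor
#>   trained on 400 windows (200 SNO / 200 non-SNO), t = 10
#>   encoders: bpb, anbpb
#>   features: 80 retained (no selection)
#>   classifier: svm

cross_validate(d, k = 5, config = sno_config(encoders = c("bpb", "anbpb"),
                                             seed = 1))
#> kfold cross-validation (k = 5, repeats = 1)
#> mean: Sn 0.6850  Sp 0.7550  Acc 0.7200  MCC 0.4411

## score every cysteine of a protein
prot <- paste0("MKLV", strrep("A", 8), "KCDE", strrep("G", 8), "CW")
predict(m, prot)
#>                 peptide      score label site_position
#> 1 VAAAAAAAAKCDEGGGGGGGG 0.14466603     1            14
#> 2 DEGGGGGGGGCWXXXXXXXXX 0.05490385     1            25
```

The IG ranking puts the planted lysine far above every other residue
(0.106 bits vs 0.012 for the runner-up). The CV accuracy of the
BPB+ANBPB model (0.72) sits below the generating process's Bayes
accuracy (≈ 0.86) because the 80 features include 76 pure-noise
positions; `incremental_cv()` with MRMD ranking recovers the informative
positional features and closes that gap (see the methods vignette).
Both cysteines of the example protein are scored; the decision score is
oriented so larger = more SNO-like.

A thin CLI over the same functions ships in `inst/exec/nitrosite`
(subcommands `extract`, `simulate`, `fit-profiles`, `encode`, `rank`,
`eval`, `run`).

## Scope

The package deliberately does not reimplement the previously published
predictors it is benchmarked against (GPS-SNO, iSNO-PseAAC, iSNO-ANBPB,
PSNO, iSNO-AAPair, SNOSite), does not model protein structure, and makes
no claim of reproducing published accuracy figures that depend on
undisclosed classifier choices — the classifier interface is pluggable
precisely so those numbers can be approached when the corresponding
datasets are supplied.
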