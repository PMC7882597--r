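# bowdti

Sequence-based prediction of GPCR–drug interactions with bag-of-words
wordbook features and gradient boosted trees.

G protein-coupled receptors (GPCRs) are the largest family of drug
targets, yet for most receptor–compound pairs no structure is available.
`bowdti` predicts whether a receptor and a drug interact using nothing
but the receptor's amino-acid sequence and the drug's path-based
molecular fingerprint, for computational chemists and bioinformaticians
screening candidate pairs before experimental follow-up.

## The method

**Receptor features.** A sequence is encoded residue-by-residue with the
Kyte–Doolittle hydropathy index and cut into fragments by four sliding
windows: single residues (wordbook *WB_A*), contiguous pairs (*WB_B*),
contiguous triples (*WB_C*) and pairs separated by one residue (*WB_D*),
all with stride 1. Fragments of each learned shape are pooled across
sequences and clustered with K-means; the cluster centers are the
"words". The number of words *K* is chosen by maximizing a weighted
silhouette coefficient

    wdist(d) = d / (1 + e^(-d)),
    WSC_i = (d̄_ex − d̄_in) / max(d̄_ex, d̄_in),   WSC = mean_i WSC_i,

where d̄_in is the mean logistic-weighted distance from sample *i* to
its own cluster and d̄_ex the smallest such mean to any other cluster.
With the default word counts (20, 16, 62, 16) a receptor becomes a 114-D
vector of word relative frequencies.

**Drug features.** An FP2-style fingerprint (256 hexadecimal characters)
is read as a 256-sample integer signal; a single-level Haar wavelet
transform keeps the 128 approximation coefficients
`W_i = (x_{2i−1} + x_{2i})/√2` (a DFT amplitude variant is available for
comparison).

**Pairs and classifier.** Receptor and drug blocks concatenate to a
242-D pair vector. Training folds are balanced with SMOTE, optionally
compressed 242→121 by the second hidden layer of a small LeakyReLU
network trained on the interaction label, and classified with gradient
boosted decision trees (random forest, RBF-SVM and logistic regression
comparators included). Performance is reported as Sn, Sp, Acc,
Str = (Sn+Sp)/2, MCC and ROC AUC, pooled over leave-one-out or
stratified k-fold cross-validation.

## Worked example

```r
library(bowdti)

# a synthetic benchmark with planted interaction structure:
# 60 receptors, 40 drugs, 390 labelled pairs at 1:2 imbalance
bench <- generateBenchmark(synthConfig())

wb <- buildWordbooks(bench$sequences, seed = 1)
wb
#> WordbookSet (Kyte-Doolittle hydropathy scale, seed 1)
#>   words: A=20, B=16, C=62, D=16  -> feature dimension 114

res <- runCV(bench$sequences, bench$fingerprints, bench$pairs,
             pipelineConfig(), cvScheme("kfold", 10))
res
#> CVResult (kfold, 10 folds, pooled)
#> MetricsReport: Sn 71.5%  Sp 83.8%  Acc 79.7%  Str 77.7%  MCC 0.55  AUC 0.832
#>   (TP 93, TN 218, FP 42, FN 37)
```

The pooled confusion counts come from scoring every pair exactly once
while it was held out; an AUC of 0.83 against this generator's planted
signal (label noise 0.1) sits close to the best achievable value for
the draw — the compatibility rule itself scores 0.89 here.

The same pipeline is scriptable from the shell via
`inst/scripts/bowdti` (`simulate`, `build-wordbooks`, `featurize`,
`train`, `evaluate`, `predict`), e.g.

```sh
bowdti simulate --out bench --seed 7
bowdti evaluate --fasta bench/gpcrs.fasta --fingerprints bench/fingerprints.tsv \
       --pairs bench/pairs.tsv --out results --folds 10 --seed 7
```

Real data plug in the same way: a FASTA of receptor sequences, a TSV of
`drug_id<TAB>hex256` fingerprints (e.g. OpenBabel FP2 output of KEGG MOL
files, `obabel drug.mol -ofpt -xfFP2`), and a labelled pair TSV.

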