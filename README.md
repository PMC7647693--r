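# lysucc

Sequence-based prediction of lysine succinylation sites.

Succinylation attaches a succinyl group (-CO-CH2-CH2-CO-) to lysine side
chains and regulates a broad range of cellular processes. Because
mass-spectrometry mapping of succinylated lysines is laborious, computational
predictors that score every lysine of a protein from its sequence context are
widely used to prioritize candidate sites. `lysucc` implements such a
predictor for R users: it classifies each lysine from the composition of its
flanking region, using a support vector machine over interpretable
composition features, and ships a synthetic succinylome generator so the
whole pipeline can be exercised and validated without any external dataset.

## Method at a glance

Every candidate site is a 31-mer window `x` centered on a lysine (flank width
n = 15, `-` padding past the termini). Three encoders map windows to numeric
vectors:

- **AAC** (20-dim): residue probabilities
  `P_x(k) = n_x(k) / sum_k n_x(k)`.
- **AAPC** (400-dim): adjacent dipeptide frequencies
  `p_k(x) = f_k(x) / sum_i f_i(x)`.
- **CKSAAP** (2000-dim): for each pair `(A_i, A_j)` and spacing `k = 1..5`,
  the count of occurrences `A_i x{k} A_j` divided by the number of available
  slots `(2n+1) - k - 1`.

Dataset-level statistics guide attribute screening: dipeptides are kept when
their class probability difference exceeds 0.02 with a two-proportion
p-value below 0.05; k-spaced pairs are scored by the class-contrast strength
`C = log(P+ / P-)` of their conditional probabilities and, for modeling,
ranked by **mRMR** (`score_j = I(f_j, c) - (1/m) sum_i I(f_i, f_j)`, with
plug-in mutual information) followed by **sequential forward selection** of
the prefix with the best 10-fold cross-validated Matthews correlation
coefficient (MCC), capped at 30 attributes — the informative subset
(**CIKSAAP**).

The classifier is an RBF-kernel SVM, `K(x, x') = exp(-gamma ||x - x'||^2)`,
with `(cost, gamma)` selected on the standard LIBSVM grid by cross-validated
MCC and probabilities calibrated by a Platt-style sigmoid. Performance is
reported as Sn, Sp, Acc and MCC from pooled cross-validation confusion
counts, with ROC/AUC for model comparison. Hybrid feature sets
(e.g. `AAC+CIKSAAP`) are first-class: the hybrid of composition and
informative pairs is the recommended configuration.

## Worked example

```r
library(lysucc)

# a synthetic succinylome: 40 positive + 80 negative lysines, planted motif
sim <- generate_succinylome(n_proteins = 40, mean_length = 200,
                            n_pos_sites = 40, n_neg_sites = 80, seed = 3)

cfg <- run_config(feature_set = "AAC+CIKSAAP", budget = 3, cv_folds = 3,
                  cost = 5, seed = 17)
res <- cmd_train(sim$proteins, sim$annotations, cfg)
res$report
#>   feature_set n_features TP FP TN FN  sn     sp       acc       mcc
#> 1 AAC+CIKSAAP         23 24 13 67 16 0.6 0.8375 0.7583333 0.4465943

res$selection$selected      # the informative k-spaced pairs chosen by SFS
#> [1] "K_5_K" "P_2_R" "K_2_K"

preds <- cmd_predict(sim$proteins[1:2, ], res$model)
head(preds, 3)
#>    protein_id position                          window     score  call
#> 1 synprot0001       33 FIFDHIWEIIMWIPSKVYLHSWIMWKSRVCK 0.3542792 FALSE
#> 2 synprot0001       43 MWIPSKVYLHSWIMWKSRVCKMPGCAGERSI 0.4448573 FALSE
#> 3 synprot0001       48 KVYLHSWIMWKSRVCKMPGCAGERSIVKPIS 0.6696729  TRUE
```

The report row gives the pooled 10-fold (here 3-fold) cross-validation
confusion counts and metrics for the trained feature set; `score` is the
calibrated probability that the lysine is succinylated, and `call` applies
the 0.5 threshold. Training writes `config.json`, `cv_report.tsv`,
`selected_attributes.tsv` and `model.rds` when given `out_dir`.

A thin command-line front end with `train` / `predict` / `evaluate` /
`features` / `logo` / `simulate` subcommands is installed at
`inst/cli/lysucc.R` (run `Rscript <path-to-pkg>/cli/lysucc.R train --fasta
proteins.fasta --annotations sites.tsv --out run1`).

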