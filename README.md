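# pbip — strain-level phage–bacterium interaction prediction

`pbip` predicts whether a phage infects a bacterial strain from the two
organisms' protein sequences alone.  It is aimed at phage-therapy and
microbiome researchers who have proteomes (e.g. from assembled and
annotated isolates) and a partially measured infection matrix, and want a
classifier for the unmeasured pairs together with an honest evaluation
protocol for heavily imbalanced interaction data.

## The method

For a phage–bacterium pair the pipeline computes:

1. **Deep protein embeddings.**  Each protein
   `S = (a_1, …, a_T)` over the 20-letter alphabet is one-hot encoded,
   projected through a token embedding (`X_emb = X_one W_emb`), and run
   through a multiplicative LSTM; hidden states are mean-pooled,
   `x = (1/T) Σ h_t`, and proteins are mean-pooled to an organism vector
   `x_p = (1/N_p) Σ x_pi`.  A pair is the concatenation `[x_p, x_b]`.
   Pretrained weights of the 1900-unit protein representation model can
   be loaded; seeded random weights are the desk-scale default.
2. **SMOTE augmentation.**  Positive pairs (typically ~7% of a strain
   matrix) are oversampled in embedding space,
   `[x_p, x_b]' = [x_p, x_b] + α([x_p, x_b]_n − [x_p, x_b])`,
   `α ∼ U[0,1]`, until classes balance — training splits only.
3. **CNN → Bi-GRU → attention classifier.**  Per-organism towers of 1-D
   convolutions with max-pooling, a bidirectional GRU, and additive
   attention pooling; the pooled phage and bacterium states feed one
   sigmoid unit, `ŷ = σ(W_f (h_p ⊕ h_b) + b_f)`.  Training minimizes
   binary cross-entropy with AMSGrad (forward and backward passes are
   implemented in base R and verified against finite differences).
4. **Evaluation.**  Accuracy, precision, sensitivity, specificity, F1,
   MCC, AUC (Mann–Whitney identity), AUPR (step-wise area), stratified
   10-fold CV, imbalance-ratio case studies (1:2 … 1:10), MinHash k-mer
   similarity auditing and leakage filtering.

A planted-motif simulator generates desk-scale datasets with a known
interaction rule so the whole pipeline can be exercised without any
external data.  See the methods vignette
(`vignettes/pbip-methods.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(pbip)

# a 40 x 40 strain-level screen with a planted receptor rule
sim <- generate_dataset(downscale_profile("desk", seed = 1))
print(sim)
#> <pbip_sim_data> 40 phages x 40 bacteria, 1600 records (3.0% positive), 4 motif classes

stats <- matrix_statistics(sim$table)
print(stats)
#> Interaction matrix: 40 phages x 40 bacteria = 1600 pairs
#>   positives: 48 (3.00%)
#>   mean positives per phage: 1.20; per bacterium: 1.20

# embed every proteome (seeded random mLSTM, d_h = 16)
ep <- random_embedder_params(d_e = 10, d_h = 16, seed = 101)
pairs <- pair_embedding_table(sim$table,
                              embed_organisms(sim$phages, ep),
                              embed_organisms(sim$bacteria, ep))

# hold out 20% of pairs, fit on the rest (SMOTE inside)
fold <- stratified_folds(pairs$y, 5, seed = 1)
fit <- pbip_fit(pairs[fold != 1], seed = 1)
print(fit)
#> <pbip_model> variant full, d_h = 16
#>   conv filters: 8/16 | GRU hidden: 8 | attention units: 8
#>   trained 30 epochs on 2482 pairs (1203 synthetic); final loss 0.1952

report <- evaluate_predictions(predict(fit, pairs[fold == 1]),
                               pairs$y[fold == 1])
print(report)
#> Prediction metrics:
#>    accuracy   precision sensitivity specificity          f1         mcc
#>      0.9097      0.2564      1.0000      0.9068      0.4082      0.4822
#>         auc        aupr
#>      0.9990      0.9698
```

The held-out AUC of 0.999 shows the classifier recovered the planted
receptor rule; precision is low at the 0.5 cut-off because positives are
3% of pairs — exactly the regime the MCC/AUPR-centred protocol is built
for.  The generator's positive rate targets 7.22% in expectation; the
realized rate varies with the sampled motif classes (3.0% for this
seed).

The same pipeline runs end to end with one call, writing all artifacts
(embeddings, loss history, metrics, ROC/PR points, config snapshot, log)
to a run directory:

```r
run <- run_pipeline(run_config(profile = "desk", seed = 1))
```

or from a shell via the thin CLI wrapper:

```sh
inst/cli/pbip simulate --profile desk --seed 1 --out simdir
inst/cli/pbip stats --interactions simdir/interactions.csv
```

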