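# Shared fixtures and independent oracles, all built in code.

# Complete 104-phage x 125-bacterium interaction table with 938 positives
# spread round-robin over the first 120 strains (so exactly 5 strains are
# fully resistant), matching the printed strain-level matrix counts.
make_strain_matrix <- function() {
  phages <- sprintf("P%03d", 1:104)
  bacts <- sprintf("B%03d", 1:125)
  lab <- matrix(0L, 104, 125)
  for (i in 0:937) {
    lab[i %/% 120 + 1L, i %% 120 + 1L] <- 1L
  }
  grid <- expand.grid(p = 1:104, b = 1:125)
  interaction_table(data.frame(phage_id = phages[grid$p],
                               bacterium_id = bacts[grid$b],
                               label = lab[cbind(grid$p, grid$b)]))
}

# Random pbip_pairs object with a given class mix.
make_random_pairs <- function(n_pos, n_neg, d_h = 3L, seed = 1L) {
  set.seed(seed)
  n <- n_pos + n_neg
  structure(list(x = matrix(rnorm(n * 2 * d_h), n),
                 y = c(rep(1L, n_pos), rep(0L, n_neg)),
                 phage_id = sprintf("P%03d", seq_len(n)),
                 bacterium_id = sprintf("B%03d", seq_len(n)),
                 synthetic = rep(FALSE, n), d_h = d_h),
            class = "pbip_pairs")
}

# Linearly separable toy pairs: positives shifted by +2 in every coordinate.
make_separable_pairs <- function(n_per_class = 20L, d_h = 16L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- matrix(rnorm(n * 2 * d_h, sd = 0.3), n)
  x[seq_len(n_per_class), ] <- x[seq_len(n_per_class), ] + 2
  structure(list(x = x, y = rep(c(1L, 0L), each = n_per_class),
                 phage_id = sprintf("P%03d", seq_len(n)),
                 bacterium_id = sprintf("B%03d", seq_len(n)),
                 synthetic = rep(FALSE, n), d_h = d_h),
            class = "pbip_pairs")
}

# O(n^2) Mann-Whitney AUC oracle, ties counted 1/2.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Per-threshold PR sweep oracle (step-wise area).
aupr_bruteforce <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  n1 <- sum(labels == 1L)
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    prec <- tp / sum(pred)
    rec <- tp / n1
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

# Direct plug-in metric formulas (independent of scalar_metrics).
metrics_bruteforce <- function(TP, TN, FP, FN) {
  tot <- TP + TN + FP + FN
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  rec <- if (TP + FN > 0) TP / (TP + FN) else 0
  spec <- if (TN + FP > 0) TN / (TN + FP) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den) else 0
  c(accuracy = (TP + TN) / tot, precision = prec, sensitivity = rec,
    specificity = spec, f1 = f1, mcc = mcc)
}

# Sliding-window "same"-padded 1-D convolution oracle (single channel).
conv_same_oracle <- function(x, kernel, bias = 0) {
  k <- length(kernel)
  half <- (k - 1) / 2
  xp <- c(rep(0, half), x, rep(0, half))
  vapply(seq_along(x), function(i) sum(xp[i:(i + k - 1)] * kernel) + bias,
         numeric(1))
}

# All k-mers of a string (for exact Jaccard oracles).
kmer_set <- function(s, k) {
  unique(substring(s, seq_len(nchar(s) - k + 1L), seq(k, nchar(s))))
}

# Embedded desk-scale dataset -> pbip_pairs, shared by pipeline-level tests.
make_embedded_desk <- function(seed, d_h = 16L) {
  sim <- generate_dataset(downscale_profile("desk", seed = seed))
  ep <- random_embedder_params(d_e = 10L, d_h = d_h, seed = seed + 100L)
  P <- embed_organisms(sim$phages, ep)
  B <- embed_organisms(sim$bacteria, ep)
  pair_embedding_table(sim$table, P, B)
}

reduced_train <- function(epochs = 30L) {
  train_config(epochs = epochs, learning_rate = 3e-3)
}
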