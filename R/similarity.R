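# Sketch-based sequence similarity (bottom-k MinHash over k-mers), the
# train/test similarity audit, and leakage filtering.

# Deterministic 2^31-scale polynomial hash of every k-mer in a sequence,
# vectorized over positions.  `hash_seed` perturbs the rolling base so
# different seeds give independent-looking hash orders.
kmer_hashes <- function(sequence, k, hash_seed = 1L) {
  n <- nchar(sequence)
  if (n < k) {
    stop_pbip(sprintf("sequence length %d shorter than k = %d", n, k))
  }
  codes <- utf8ToInt(sequence)
  p <- 2147483629                       # prime below 2^31
  base <- 131 + 2 * (hash_seed %% 1021)
  n_kmers <- n - k + 1L
  h <- numeric(n_kmers)
  for (j in seq_len(k)) {
    h <- (h * base + codes[j:(j + n_kmers - 1L)]) %% p
  }
  # final scramble decorrelates adjacent k-mers (multipliers keep every
  # intermediate product below 2^53, so arithmetic in doubles stays exact)
  h <- (h * 48271) %% p
  h <- (h * 69621) %% p
  unique(h)
}

#' MinHash k-mer similarity between two sequences
#'
#' Estimates the Jaccard similarity of the two k-mer sets with bottom-k
#' MinHash sketches: each sequence keeps its `sketch_size` smallest k-mer
#' hashes; the estimate is the fraction of the union sketch present in
#' both.  When both k-mer sets fit inside the sketch the value is the
#' exact Jaccard index.  Symmetric and deterministic for a fixed
#' `hash_seed`.  This is a documented sketching stand-in for external
#' genome-sketching tools with the same similarity semantics.
#'
#' @param seq_a,seq_b Sequences (nucleotide, or concatenated protein
#'   strings); each at least `k` long.
#' @param k k-mer length (default 21).
#' @param sketch_size Sketch size (default 1024).
#' @param hash_seed Seed of the hash function (not a sampling seed; fixed
#'   by default so results are reproducible).
#' @return Similarity in `[0, 1]`.
#' @export
sketch_similarity <- function(seq_a, seq_b, k = 21L, sketch_size = 1024L,
                              hash_seed = 1L) {
  ha <- kmer_hashes(seq_a, k, hash_seed)
  hb <- kmer_hashes(seq_b, k, hash_seed)
  if (length(ha) <= sketch_size && length(hb) <= sketch_size) {
    return(length(intersect(ha, hb)) / length(union(ha, hb)))
  }
  sa <- sort(ha)[seq_len(min(sketch_size, length(ha)))]
  sb <- sort(hb)[seq_len(min(sketch_size, length(hb)))]
  un <- sort(unique(c(sa, sb)))[seq_len(sketch_size)]
  sum(un %in% sa & un %in% sb) / sketch_size
}

# Concatenated-proteome sequence used for organism-level similarity.
proteome_sequence <- function(org) {
  paste(org$proteins, collapse = "")
}

max_similarity_to_set <- function(query_seq, reference_seqs, k, sketch_size,
                                  hash_seed) {
  max(vapply(reference_seqs, sketch_similarity, numeric(1),
             seq_a = query_seq, k = k, sketch_size = sketch_size,
             hash_seed = hash_seed))
}

#' Train/test similarity audit
#'
#' For each test phage, computes its maximum sketch similarity to any
#' training phage, bins the test phages into `bins` equal-width similarity
#' intervals over `[0, 1]`, and reports per-bin prediction accuracy.
#'
#' @param test_phages,train_phages Named character vectors of organism
#'   sequences (e.g. concatenated proteomes via [proteome()] objects and
#'   `paste`), or lists of [proteome()] objects.
#' @param predictions Data frame with columns `phage_id`, `label`,
#'   `predicted` (hard 0/1 calls) covering the test pairs.
#' @param bins Number of equal-width similarity intervals.
#' @param k,sketch_size,hash_seed Passed to [sketch_similarity()].
#' @return List of class `pbip_similarity_audit`: `per_phage` (data frame
#'   `phage_id`, `max_similarity`, `bin`), `per_bin` (data frame `bin`,
#'   `lower`, `upper`, `n_phages`, `n_pairs`, `accuracy`; accuracy is `NA`
#'   for empty bins).
#' @export
similarity_audit <- function(test_phages, train_phages, predictions,
                             bins = 5L, k = 21L, sketch_size = 1024L,
                             hash_seed = 1L) {
  as_seqs <- function(x) {
    if (is.list(x)) {
      out <- vapply(x, proteome_sequence, character(1))
      names(out) <- vapply(x, `[[`, character(1), "id")
      out
    } else x
  }
  test_seqs <- as_seqs(test_phages)
  train_seqs <- as_seqs(train_phages)
  sim <- vapply(test_seqs, max_similarity_to_set, numeric(1),
                reference_seqs = train_seqs, k = k,
                sketch_size = sketch_size, hash_seed = hash_seed)
  bin <- pmin(floor(sim * bins) + 1L, bins)   # similarity 1.0 -> top bin
  per_phage <- data.frame(phage_id = names(test_seqs),
                          max_similarity = unname(sim), bin = unname(bin))
  edges <- seq(0, 1, length.out = bins + 1L)
  rows <- lapply(seq_len(bins), function(b) {
    ph <- per_phage$phage_id[per_phage$bin == b]
    pr <- predictions[predictions$phage_id %in% ph, , drop = FALSE]
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
               n_phages = length(ph), n_pairs = nrow(pr),
               accuracy = if (nrow(pr) > 0L) {
                 mean(pr$predicted == pr$label)
               } else NA_real_)
  })
  structure(list(per_phage = per_phage, per_bin = do.call(rbind, rows)),
            class = "pbip_similarity_audit")
}

#' @export
print.pbip_similarity_audit <- function(x, ...) {
  cat("Similarity audit (max similarity of each test phage to training set):\n")
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}

#' Filter leaking training negatives
#'
#' Removes training negatives whose phage has maximum sketch similarity at
#' or above `similarity_threshold` to any test phage, to keep
#' near-duplicate phages from appearing on both sides of the split.
#'
#' @param training_negatives Data frame of negative training records with
#'   a `phage_id` column.
#' @param train_phage_seqs Named character vector of training phage
#'   sequences (names = phage ids).
#' @param test_phage_seqs Named character vector of test phage sequences.
#' @param similarity_threshold Removal cut-off (default 0.9).
#' @param k,sketch_size,hash_seed Passed to [sketch_similarity()].
#' @return The filtered data frame, with attribute `removal_log` (data
#'   frame `phage_id`, `max_similarity`, `n_records_removed`).
#' @export
leakage_filter <- function(training_negatives, train_phage_seqs,
                           test_phage_seqs, similarity_threshold = 0.9,
                           k = 21L, sketch_size = 1024L, hash_seed = 1L) {
  used <- intersect(unique(training_negatives$phage_id),
                    names(train_phage_seqs))
  sim <- vapply(train_phage_seqs[used], max_similarity_to_set, numeric(1),
                reference_seqs = test_phage_seqs, k = k,
                sketch_size = sketch_size, hash_seed = hash_seed)
  drop_ids <- used[sim >= similarity_threshold]
  keep <- !(training_negatives$phage_id %in% drop_ids)
  out <- training_negatives[keep, , drop = FALSE]
  rownames(out) <- NULL
  log <- data.frame(phage_id = drop_ids,
                    max_similarity = unname(sim[drop_ids]),
                    n_records_removed = vapply(drop_ids, function(id) {
                      sum(training_negatives$phage_id == id)
                    }, integer(1)))
  rownames(log) <- NULL
  attr(out, "removal_log") <- log
  out
}
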