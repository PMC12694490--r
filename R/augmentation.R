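# SMOTE oversampling of positive pair embeddings.

#' k nearest minority neighbors
#'
#' Euclidean nearest neighbors among the minority vectors themselves,
#' excluding each point from its own neighbor list.  Ties are broken by
#' index order for determinism.
#'
#' @param minority_vectors Matrix with one minority sample per row.
#' @param k Number of neighbors; must be smaller than the number of rows.
#' @return Integer matrix, n x k: row i holds the indices of the k nearest
#'   neighbors of row i.
#' @export
minority_neighbors <- function(minority_vectors, k) {
  n <- nrow(minority_vectors)
  if (k >= n) {
    stop_pbip(sprintf("k = %d neighbors requested but only %d minority samples; need k < n",
                      k, n))
  }
  d <- as.matrix(stats::dist(minority_vectors))
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))     # distance, then index (determinism)
    ord <- ord[ord != i]
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

#' Linear interpolation between two pair vectors
#'
#' `x + alpha * (x_n - x)`: the synthetic point lies on the segment from
#' `x` (`alpha = 0`) to its neighbor `x_n` (`alpha = 1`).
#'
#' @param x,x_n Numeric vectors of equal length.
#' @param alpha Interpolation coefficient in `[0, 1]`.
#' @return Numeric vector.
#' @export
interpolate <- function(x, x_n, alpha) {
  if (length(x) != length(x_n)) stop_pbip("interpolation endpoints differ in length")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop_pbip("alpha must lie in [0, 1]")
  }
  x + alpha * (x_n - x)
}

#' Balance a training set with SMOTE in embedding space
#'
#' Adds synthetic positive pair embeddings until the positive and negative
#' counts are equal.  Each synthetic sample interpolates between a randomly
#' chosen original positive and one of its `k_neighbors` nearest positive
#' neighbors with an independent `alpha ~ Uniform[0, 1]`; interpolation acts
#' on the whole concatenated pair vector.  Original samples are preserved
#' unmodified; synthetic rows are appended, flagged, and carry provenance
#' (`parent_a`, `parent_b`, `alpha`) for auditing.  Intended for training
#' splits only -- never augment a test set.
#'
#' @param pairs A `pbip_pairs` object (see [pair_embedding_table()]).
#' @param k_neighbors Nearest-neighbor count (default 5, the conventional
#'   SMOTE setting).
#' @param seed Integer seed for the sampling of parents, neighbors and
#'   alphas.
#' @return A `pbip_pairs` object with equal class counts and a
#'   `smote_provenance` attribute (data frame: `parent_a`, `parent_b`,
#'   `alpha`, row indices into the original positive set).  Returned
#'   unchanged when positives are not the minority.
#' @export
balance_with_smote <- function(pairs, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(pairs, "pbip_pairs"))
  y <- pairs$y
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_pbip("both classes must be present before balancing")
  }
  n_new <- n_neg - n_pos
  if (n_new <= 0L) return(pairs)
  if (n_pos <= k_neighbors) {
    stop_pbip(sprintf(
      "only %d positives but k_neighbors = %d; use a smaller k (< number of positives)",
      n_pos, k_neighbors))
  }
  pos_idx <- which(y == 1L)
  pos <- pairs$x[pos_idx, , drop = FALSE]
  nn <- minority_neighbors(pos, k_neighbors)
  with_seed(seed, {
    seed_pick <- sample.int(n_pos, n_new, replace = TRUE)
    nbr_pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    alphas <- stats::runif(n_new)
    synth <- matrix(0, n_new, ncol(pos))
    parent_b <- integer(n_new)
    for (j in seq_len(n_new)) {
      a <- seed_pick[j]
      b <- nn[a, nbr_pick[j]]
      parent_b[j] <- b
      synth[j, ] <- interpolate(pos[a, ], pos[b, ], alphas[j])
    }
    prov <- data.frame(parent_a = pos_idx[seed_pick],
                       parent_b = pos_idx[parent_b],
                       alpha = alphas)
    out <- structure(list(
      x = rbind(pairs$x, synth),
      y = c(y, rep(1L, n_new)),
      phage_id = c(pairs$phage_id, rep(NA_character_, n_new)),
      bacterium_id = c(pairs$bacterium_id, rep(NA_character_, n_new)),
      synthetic = c(pairs$synthetic, rep(TRUE, n_new)),
      d_h = pairs$d_h), class = "pbip_pairs")
    attr(out, "smote_provenance") <- prov
    out
  })
}
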