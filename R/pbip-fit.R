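# User-facing fitting surface: pbip_fit() returns a classed model object
# with the usual print/summary/predict/plot methods.

#' Fit a phage-bacterium interaction classifier
#'
#' Trains the CNN / bidirectional-GRU / attention pair classifier on a
#' paired-embedding table.  Unless disabled (ablation `"PBIP5"` or
#' `augment = FALSE`), the positive class is first rebalanced with SMOTE in
#' the embedding space; augmentation never touches data you later predict
#' on -- apply this function to training splits only.
#'
#' @param pairs A `pbip_pairs` object from [pair_embedding_table()] (or
#'   [balance_with_smote()], in which case set `augment = FALSE`).
#' @param config A [model_config()]; the default reduced architecture
#'   (filters 8/16, 8 GRU units) suits desk-scale embeddings
#'   (`d_h` 16-32).  Pass `model_config()` defaults for the full-size
#'   published architecture.
#' @param train A [train_config()].
#' @param k_neighbors SMOTE neighbor count.
#' @param augment Apply SMOTE balancing before training.
#' @param standardize Center and scale each pair-embedding column to zero
#'   mean and unit variance on the training set before augmentation and
#'   training (the scaling is stored in the model and re-applied at
#'   prediction time).  Keeps the network's input on a unit scale whatever
#'   the embedder's output magnitude.
#' @param seed Integer seed controlling augmentation, initialization,
#'   shuffling and dropout; a fixed seed reproduces the fit exactly.
#' @param verbose Print progress.
#' @return An object of class `pbip_model` with components `params`,
#'   `config`, `train`, `loss_history`, `n_train`, `n_synthetic`, `d_h`,
#'   `seed`.
#' @seealso [predict.pbip_model()], [evaluate_predictions()], [kfold_cv()]
#' @export
pbip_fit <- function(pairs,
                     config = model_config(filters = c(8L, 16L),
                                           gru_hidden = 8L,
                                           attention_units = 8L),
                     train = train_config(epochs = 30L, learning_rate = 3e-3),
                     k_neighbors = 5L, augment = TRUE, standardize = TRUE,
                     seed = 1L, verbose = FALSE) {
  stopifnot(inherits(pairs, "pbip_pairs"))
  scaling <- NULL
  if (standardize) {
    ctr <- colMeans(pairs$x)
    scl <- apply(pairs$x, 2L, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    scaling <- list(center = ctr, scale = scl)
    pairs$x <- sweep(sweep(pairs$x, 2L, ctr), 2L, scl, "/")
  }
  use_smote <- augment && config$variant != "PBIP5"
  train_pairs <- if (use_smote) {
    balance_with_smote(pairs, k_neighbors = k_neighbors,
                       seed = stage_seed(seed, "augment"))
  } else {
    pairs
  }
  fit <- train_model(train_pairs, config, train,
                     seed = stage_seed(seed, "network"), verbose = verbose)
  structure(list(params = fit$params,
                 config = config,
                 train = train,
                 loss_history = fit$loss_history,
                 n_train = nrow(train_pairs$x),
                 n_synthetic = sum(train_pairs$synthetic),
                 d_h = pairs$d_h,
                 scaling = scaling,
                 seed = seed),
            class = "pbip_model")
}

#' @export
print.pbip_model <- function(x, ...) {
  cat(sprintf("<pbip_model> variant %s, d_h = %d\n", x$config$variant, x$d_h))
  cat(sprintf("  conv filters: %s | GRU hidden: %d | attention units: %d\n",
              paste(x$config$filters, collapse = "/"),
              x$config$gru_hidden, x$config$attention_units))
  cat(sprintf("  trained %d epochs on %d pairs (%d synthetic); final loss %.4f\n",
              x$train$epochs, x$n_train, x$n_synthetic,
              if (length(x$loss_history)) utils::tail(x$loss_history, 1L) else NA))
  invisible(x)
}

#' @export
summary.pbip_model <- function(object, ...) {
  n_par <- sum(rapply(unclass(object$params), length, how = "unlist"))
  cat("Phage-bacterium interaction classifier\n")
  print(object)
  cat(sprintf("  parameters: %d | optimizer: %s | lr %g | batch %d\n",
              n_par, object$train$optimizer, object$train$learning_rate,
              object$train$batch_size))
  if (length(object$loss_history)) {
    cat(sprintf("  loss: first %.4f -> last %.4f\n",
                object$loss_history[1L], utils::tail(object$loss_history, 1L)))
  }
  invisible(object)
}

#' Predict interaction probabilities
#'
#' @param object A fitted `pbip_model`.
#' @param pairs A `pbip_pairs` object with the same embedding dimension.
#' @param type `"prob"` for probabilities, `"label"` for hard 0/1 calls at
#'   the configured classification threshold (>= threshold is positive).
#' @param ... Ignored.
#' @return Numeric vector of probabilities or integer labels.
#' @export
predict.pbip_model <- function(object, pairs, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(pairs, "pbip_pairs"))
  if (ncol(pairs$x) != 2L * object$d_h) {
    stop_pbip(sprintf("pair vectors have %d columns; model expects %d",
                      ncol(pairs$x), 2L * object$d_h))
  }
  x <- pairs$x
  if (!is.null(object$scaling)) {
    x <- sweep(sweep(x, 2L, object$scaling$center), 2L,
               object$scaling$scale, "/")
    pairs$x <- x
  }
  p <- predict_probs(object$params, object$config, pairs)
  if (type == "prob") p
  else as.integer(p >= object$config$classification_threshold)
}

#' Plot the training loss curve
#'
#' @param x A fitted `pbip_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pbip_model <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training BCE loss",
                 main = "pbip training loss", ...)
  invisible(x)
}
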