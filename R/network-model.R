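# Model configuration, parameter initialization, full forward/backward and
# AMSGrad training for the pair classifier.

#' Model architecture configuration
#'
#' Defaults follow the published architecture: four 1-D convolution stages
#' (kernel 3, max-pool 2, filters 32/64/128/256, dropout 0.5), a
#' bidirectional GRU with 64 hidden units (dropout 0.5), a 32-unit additive
#' attention layer, and a sigmoid head thresholded at 0.5.  Tests and
#' simulations use reduced settings (e.g. `filters = c(8, 16)`,
#' `gru_hidden = 8`).
#'
#' @param filters Integer vector of per-stage convolution filter counts;
#'   its length sets the number of conv stages.
#' @param kernel_size Convolution kernel width (odd).
#' @param pool_size Max-pool window.
#' @param cnn_dropout Dropout rate applied once after the conv tower.
#' @param gru_hidden Hidden units per GRU direction.
#' @param gru_dropout Dropout rate on the bidirectional GRU output.
#' @param attention_units Units in the attention scoring network.
#' @param tower_sharing `"separate"` (default) gives the phage and
#'   bacterium branches untied parameters; `"shared"` ties them.
#' @param classification_threshold Probability cut-off for hard labels.
#' @param variant `"full"`, or an ablation: `"PBIP3"` (no bidirectional
#'   GRU; attention pools the CNN features), `"PBIP4"` (no attention;
#'   GRU states are mean-pooled), `"PBIP5"` (no SMOTE augmentation).
#' @return An object of class `pbip_model_config`.
#' @export
model_config <- function(filters = c(32L, 64L, 128L, 256L),
                         kernel_size = 3L, pool_size = 2L,
                         cnn_dropout = 0.5, gru_hidden = 64L,
                         gru_dropout = 0.5, attention_units = 32L,
                         tower_sharing = c("separate", "shared"),
                         classification_threshold = 0.5,
                         variant = c("full", "PBIP3", "PBIP4", "PBIP5")) {
  tower_sharing <- match.arg(tower_sharing)
  variant <- match.arg(variant)
  stopifnot(length(filters) >= 1L, all(filters >= 1L),
            kernel_size %% 2L == 1L, pool_size >= 1L,
            cnn_dropout >= 0, cnn_dropout < 1,
            gru_dropout >= 0, gru_dropout < 1,
            gru_hidden >= 1L, attention_units >= 1L)
  structure(list(conv_layers = length(filters),
                 filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 cnn_dropout = cnn_dropout,
                 gru_hidden = as.integer(gru_hidden),
                 gru_dropout = gru_dropout,
                 attention_units = as.integer(attention_units),
                 tower_sharing = tower_sharing,
                 classification_threshold = classification_threshold,
                 variant = variant),
            class = "pbip_model_config")
}

#' Training configuration
#'
#' @param learning_rate AMSGrad step size (default 3e-4).
#' @param batch_size Mini-batch size (default 16; the last incomplete batch
#'   is kept).
#' @param epochs Training epochs (default 200).
#' @return An object of class `pbip_train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 16L,
                         epochs = 200L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 optimizer = "amsgrad"),
            class = "pbip_train_config")
}

#' Configure an ablation variant
#'
#' Returns a [model_config()] with the named component removed:
#' `"PBIP3"` drops the bidirectional GRU (attention pools the CNN feature
#' map directly), `"PBIP4"` drops attention (GRU states are mean-pooled),
#' and `"PBIP5"` keeps the full network but disables SMOTE augmentation.
#'
#' @param name `"PBIP3"`, `"PBIP4"` or `"PBIP5"`.
#' @param ... Passed to [model_config()].
#' @return A `pbip_model_config`.
#' @export
ablation_variant <- function(name, ...) {
  if (!name %in% c("PBIP3", "PBIP4", "PBIP5")) {
    stop_pbip(sprintf("unknown ablation variant '%s' (expected PBIP3, PBIP4 or PBIP5)",
                      name))
  }
  model_config(..., variant = name)
}

# Length of the signal after the conv tower; errors if pooling exhausts it.
conv_output_length <- function(d_h, config) {
  L <- d_h
  for (s in seq_len(config$conv_layers)) {
    if (L < config$pool_size) {
      min_dh <- config$pool_size^config$conv_layers
      stop_pbip(sprintf(
        "input length %d too short for %d conv/pool stages; need >= %d",
        d_h, config$conv_layers, min_dh))
    }
    L <- L %/% config$pool_size
  }
  L
}

tower_output_dim <- function(config) {
  switch(config$variant,
         PBIP3 = config$filters[config$conv_layers],
         2L * config$gru_hidden)
}

init_gru_dir <- function(C, H) {
  list(W_r = glorot(C, H), U_r = glorot(H, H), b_r = numeric(H),
       W_z = glorot(C, H), U_z = glorot(H, H), b_z = numeric(H),
       W_g = glorot(C, H), U_g = glorot(H, H), b_g = numeric(H))
}

init_tower <- function(d_h, config) {
  tw <- list(conv = vector("list", config$conv_layers))
  Cin <- 1L
  for (s in seq_len(config$conv_layers)) {
    Cout <- config$filters[s]
    Wl <- array(0, c(config$kernel_size, Cin, Cout))
    lim <- sqrt(6 / (config$kernel_size * Cin + Cout))
    Wl[] <- stats::runif(length(Wl), -lim, lim)
    tw$conv[[s]] <- list(W = Wl, b = numeric(Cout))
    Cin <- Cout
  }
  if (config$variant != "PBIP3") {
    H <- config$gru_hidden
    tw$gru_fwd <- init_gru_dir(Cin, H)
    tw$gru_bwd <- init_gru_dir(Cin, H)
  }
  if (config$variant != "PBIP4") {
    D <- tower_output_dim(config)
    A <- config$attention_units
    tw$attn <- list(W = glorot(D, A), b = numeric(A),
                    v = drop(glorot(A, 1L)))
  }
  tw
}

#' Initialize network parameters
#'
#' Seeded Glorot-uniform initialization for all weight matrices; biases
#' start at zero.
#'
#' @param d_h Organism embedding dimension (per-organism half of the pair
#'   vector).
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `pbip_net_params`.
#' @export
init_network_params <- function(d_h, config, seed = 1L) {
  conv_output_length(d_h, config)   # validates d_h
  with_seed(seed, {
    D <- tower_output_dim(config)
    params <- list(phage = init_tower(d_h, config))
    if (config$tower_sharing == "separate") {
      params$bacterium <- init_tower(d_h, config)
    }
    params$head <- list(w = drop(glorot(2L * D, 1L)), b = 0)
    attr(params, "d_h") <- as.integer(d_h)
    class(params) <- "pbip_net_params"
    params
  })
}

tower_forward <- function(X, tw, config, training = FALSE) {
  cache <- list(conv = vector("list", config$conv_layers))
  A <- X
  for (s in seq_len(config$conv_layers)) {
    cv <- conv1d_forward(A, tw$conv[[s]]$W, tw$conv[[s]]$b)
    rl <- relu_forward(cv$out)
    mp <- maxpool_forward(rl$out, config$pool_size)
    cache$conv[[s]] <- list(cv = cv$cache, relu = rl$cache, mp = mp$cache)
    A <- mp$out
  }
  dr <- dropout_forward(A, config$cnn_dropout, training)
  cache$cnn_drop <- dr$cache
  A <- dr$out
  if (config$variant == "PBIP3") {
    at <- attention_forward(A, tw$attn)
    cache$attn <- at$cache
    return(list(out = at$out, cache = cache, alpha = at$alpha))
  }
  bg <- bigru_seq_forward(A, tw$gru_fwd, tw$gru_bwd)
  cache$gru <- bg$cache
  dr2 <- dropout_forward(bg$out, config$gru_dropout, training)
  cache$gru_drop <- dr2$cache
  S <- dr2$out
  if (config$variant == "PBIP4") {
    mp <- meanpool_forward(S)
    cache$meanpool <- mp$cache
    list(out = mp$out, cache = cache, alpha = NULL)
  } else {
    at <- attention_forward(S, tw$attn)
    cache$attn <- at$cache
    list(out = at$out, cache = cache, alpha = at$alpha)
  }
}

tower_backward <- function(dout, cache, tw, config) {
  g_ <- list(conv = vector("list", config$conv_layers))
  if (config$variant == "PBIP3") {
    ab <- attention_backward(dout, cache$attn, tw$attn)
    g_$attn <- ab$grads
    dA <- ab$dS
  } else {
    if (config$variant == "PBIP4") {
      dS <- meanpool_backward(dout, cache$meanpool)
    } else {
      ab <- attention_backward(dout, cache$attn, tw$attn)
      g_$attn <- ab$grads
      dS <- ab$dS
    }
    dS <- dropout_backward(dS, cache$gru_drop)
    bb <- bigru_seq_backward(dS, cache$gru, tw$gru_fwd, tw$gru_bwd)
    g_$gru_fwd <- bb$grads_fwd
    g_$gru_bwd <- bb$grads_bwd
    dA <- bb$dX
  }
  dA <- dropout_backward(dA, cache$cnn_drop)
  for (s in rev(seq_len(config$conv_layers))) {
    st <- cache$conv[[s]]
    dA <- maxpool_backward(dA, st$mp)
    dA <- relu_backward(dA, st$relu)
    cb <- conv1d_backward(dA, st$cv)
    g_$conv[[s]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  g_
}

net_forward <- function(params, config, Xp, Xb, training = FALSE) {
  B <- nrow(Xp)
  d_h <- ncol(Xp)
  tw_p <- params$phage
  tw_b <- if (config$tower_sharing == "separate") params$bacterium else params$phage
  fp <- tower_forward(array(Xp, c(B, d_h, 1L)), tw_p, config, training)
  fb <- tower_forward(array(Xb, c(B, d_h, 1L)), tw_b, config, training)
  U <- cbind(fp$out, fb$out)
  z <- drop(U %*% params$head$w) + params$head$b
  prob <- sigmoid(z)
  list(prob = prob,
       cache = list(fp = fp$cache, fb = fb$cache, U = U, B = B))
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

net_backward <- function(params, config, cache, prob, y) {
  B <- cache$B
  dz <- (prob - y) / B
  D <- ncol(cache$U) %/% 2L
  g_head <- list(w = drop(crossprod(cache$U, dz)), b = sum(dz))
  dU <- outer(dz, params$head$w)
  tw_p <- params$phage
  tw_b <- if (config$tower_sharing == "separate") params$bacterium else params$phage
  gp <- tower_backward(dU[, seq_len(D), drop = FALSE], cache$fp, tw_p, config)
  gb <- tower_backward(dU[, D + seq_len(D), drop = FALSE], cache$fb, tw_b, config)
  grads <- if (config$tower_sharing == "separate") {
    list(phage = gp, bacterium = gb, head = g_head)
  } else {
    list(phage = tree_add(gp, gb), head = g_head)
  }
  grads
}

#' Mean binary cross-entropy loss
#'
#' Predictions are clipped to `[eps, 1 - eps]` before taking logs.
#'
#' @param predictions Vector of predicted probabilities.
#' @param labels Vector of 0/1 labels, same length.
#' @param eps Clipping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(predictions, labels, eps = 1e-7) {
  if (length(predictions) != length(labels)) {
    stop_pbip("predictions and labels differ in length")
  }
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# -- AMSGrad ----------------------------------------------------------------

tree_zero <- function(tree) {
  if (is.list(tree)) return(lapply(tree, tree_zero))
  if (is.null(dim(tree))) numeric(length(tree))
  else array(0, dim = dim(tree))
}

amsgrad_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v, vhat) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v; out_vh <- vhat
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], vhat[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m
        out_v[[nm]] <- r$v; out_vh[[nm]] <- r$vhat
      }
      return(list(p = out_p, m = out_m, v = out_v, vhat = out_vh))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    vh2 <- pmax(vhat, v2)
    p2 <- p - lr * m2 / (sqrt(vh2) + eps)
    list(p = p2, m = m2, v = v2, vhat = vh2)
  }
  a <- attributes(params)
  r <- walk(params, grads, state$m, state$v, state$vhat)
  attributes(r$p) <- a
  list(params = r$p, state = list(m = r$m, v = r$v, vhat = r$vhat))
}

#' Train the pair classifier
#'
#' Mini-batch AMSGrad on mean binary cross-entropy.  Batches are reshuffled
#' every epoch from the seeded generator; the last incomplete batch is
#' kept; dropout is active during training only.  Deterministic for a fixed
#' seed.
#'
#' @param pairs A `pbip_pairs` object (typically after
#'   [balance_with_smote()]).
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param params Optional pre-initialized `pbip_net_params` (e.g. to resume
#'   training); default initializes from `seed`.
#' @param verbose Print the loss every 10 epochs.
#' @return List with `params` (trained `pbip_net_params`) and
#'   `loss_history` (numeric, one mean training loss per epoch).
#' @export
train_model <- function(pairs, config, train = train_config(), seed = 1L,
                        params = NULL, verbose = FALSE) {
  stopifnot(inherits(pairs, "pbip_pairs"))
  n <- nrow(pairs$x)
  if (n == 0L) stop_pbip("empty training set")
  d_h <- ncol(pairs$x) %/% 2L
  if (is.null(params)) params <- init_network_params(d_h, config, seed)
  state <- list(m = tree_zero(params), v = tree_zero(params),
                vhat = tree_zero(params))
  loss_history <- numeric(train$epochs)
  Xp_all <- pairs$x[, seq_len(d_h), drop = FALSE]
  Xb_all <- pairs$x[, d_h + seq_len(d_h), drop = FALSE]
  y_all <- pairs$y
  with_seed(stage_seed(seed, "train_loop"), {
    for (ep in seq_len(train$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = train$batch_size)
      ep_loss <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + train$batch_size - 1L, n)]
        fw <- net_forward(params, config,
                          Xp_all[idx, , drop = FALSE],
                          Xb_all[idx, , drop = FALSE], training = TRUE)
        loss <- bce_loss(fw$prob, y_all[idx])
        if (!is.finite(loss)) {
          stop_pbip(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        }
        ep_loss <- ep_loss + loss * length(idx)
        grads <- net_backward(params, config, fw$cache, fw$prob, y_all[idx])
        upd <- amsgrad_step(params, grads, state, train$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      loss_history[ep] <- ep_loss / n
      if (verbose && ep %% 10L == 0L) {
        message(sprintf("epoch %3d  loss %.4f", ep, loss_history[ep]))
      }
    }
  })
  list(params = params, loss_history = loss_history)
}

predict_probs <- function(params, config, pairs) {
  d_h <- ncol(pairs$x) %/% 2L
  fw <- net_forward(params, config,
                    pairs$x[, seq_len(d_h), drop = FALSE],
                    pairs$x[, d_h + seq_len(d_h), drop = FALSE],
                    training = FALSE)
  fw$prob
}

# -- single-sample reference ops (spec-level surface) -----------------------

#' Conv tower forward pass for one organism embedding
#'
#' Runs the configured convolution/ReLU/max-pool stages (no dropout:
#' inference mode) on one length-`d_h` embedding vector.
#'
#' @param x_i Numeric embedding vector.
#' @param config A [model_config()].
#' @param tower Tower parameter list (e.g. `params$phage` from
#'   [init_network_params()]).
#' @return Feature map matrix, steps x final filter count.
#' @export
conv_tower_forward <- function(x_i, config, tower) {
  conv_output_length(length(x_i), config)
  A <- array(x_i, c(1L, length(x_i), 1L))
  for (s in seq_len(config$conv_layers)) {
    cv <- conv1d_forward(A, tower$conv[[s]]$W, tower$conv[[s]]$b)
    rl <- relu_forward(cv$out)
    A <- maxpool_forward(rl$out, config$pool_size)$out
  }
  matrix(A, dim(A)[2], dim(A)[3])
}

#' Non-overlapping 1-D max pooling
#'
#' @param map Numeric vector, or matrix (steps x channels).
#' @param pool_size Window width; trailing remainder positions are dropped.
#' @return Pooled vector or matrix of length `floor(n / pool_size)`.
#' @export
#' @examples
#' max_pool(c(1, 3, 2, 0))      # 3 2
#' max_pool(c(5, 1, 4))         # 5 (remainder dropped)
max_pool <- function(map, pool_size = 2L) {
  vec <- is.null(dim(map))
  M <- if (vec) matrix(map, ncol = 1L) else map
  if (nrow(M) < pool_size) stop_pbip("map shorter than pool window")
  A <- array(M, c(1L, nrow(M), ncol(M)))
  out <- maxpool_forward(aperm(A, c(1L, 2L, 3L)), pool_size)$out
  R <- matrix(out, dim(out)[2], dim(out)[3])
  if (vec) drop(R) else R
}

#' One GRU step
#'
#' Computes the reset gate `r`, update gate `z`, candidate `g` and new
#' hidden state `h = (1 - z) * h_prev + z * g`.
#'
#' @param x Input vector (feature channels at this step).
#' @param h_prev Previous hidden state vector.
#' @param dir_params One GRU direction's parameter list (`W_r`, `U_r`,
#'   `b_r`, ...; see [init_network_params()]).
#' @return List with `r`, `z`, `g`, `h`.
#' @export
gru_step <- function(x, h_prev, dir_params) {
  st <- gru_cell(matrix(x, 1L), matrix(h_prev, 1L), dir_params)
  lapply(st, drop)
}

#' Bidirectional GRU over a feature map
#'
#' @param feature_map Matrix, steps x channels (e.g. from
#'   [conv_tower_forward()]).
#' @param fwd_params,bwd_params GRU direction parameter lists.
#' @return Matrix, steps x 2 * hidden: forward states followed by backward
#'   states at each step.
#' @export
bigru_forward <- function(feature_map, fwd_params, bwd_params) {
  A <- array(feature_map, c(1L, nrow(feature_map), ncol(feature_map)))
  S <- bigru_seq_forward(A, fwd_params, bwd_params)$out
  matrix(S, dim(S)[2], dim(S)[3])
}

#' Attention pooling over hidden states
#'
#' Additive attention: `score_t = v' tanh(W h_t + b)`, softmax-normalized
#' weights, pooled vector = weighted sum of states.
#'
#' @param states Matrix, steps x state dimension.
#' @param attn_params List with `W`, `b`, `v`.
#' @return List with `weights` (non-negative, summing to 1) and `pooled`.
#' @export
attention_pool <- function(states, attn_params) {
  A <- array(states, c(1L, nrow(states), ncol(states)))
  at <- attention_forward(A, attn_params)
  list(weights = drop(at$alpha), pooled = drop(at$out))
}

#' Sigmoid interaction probability from pooled tower outputs
#'
#' @param h_p,h_b Pooled phage and bacterium vectors.
#' @param head List with weight vector `w` (length = combined input) and
#'   scalar bias `b`.
#' @return Probability in (0, 1).
#' @export
predict_pair <- function(h_p, h_b, head) {
  u <- c(h_p, h_b)
  if (length(u) != length(head$w)) stop_pbip("head weight length mismatch")
  sigmoid(sum(u * head$w) + head$b)
}
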