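zeroed <- function(params) {
  rapply(unclass(params), function(w) { w[] <- 0; w }, how = "replace")
}

test_that("conv tower passes positives through an identity kernel", {
  cfg <- model_config(filters = 1L, cnn_dropout = 0, gru_hidden = 2L,
                      attention_units = 2L)
  params <- init_network_params(8L, cfg, seed = 1L)
  tw <- params$phage
  tw$conv[[1]]$W[] <- c(0, 1, 0)     # kernel picks the center position
  tw$conv[[1]]$b[] <- 0
  x <- c(2, 5, 1, 7, 3, 8, 4, 6)
  out <- conv_tower_forward(x, cfg, tw)
  expect_equal(drop(out), c(5, 7, 8, 6))  # maxpool of the unchanged signal

  tw$conv[[1]]$b[] <- -100            # all pre-activations negative
  expect_equal(drop(conv_tower_forward(x, cfg, tw)), rep(0, 4))
})

test_that("convolution matches a sliding-window dot-product oracle", {
  cfg <- model_config(filters = 1L, pool_size = 1L, cnn_dropout = 0,
                      gru_hidden = 2L, attention_units = 2L)
  params <- init_network_params(8L, cfg, seed = 2L)
  tw <- params$phage
  kernel <- c(0.5, -1, 2)
  tw$conv[[1]]$W[] <- kernel
  tw$conv[[1]]$b[] <- 0.3
  x <- c(1, -2, 0.5, 4, -1, 2, 0, 3)
  expect_equal(drop(conv_tower_forward(x, cfg, tw)),
               pmax(conv_same_oracle(x, kernel, 0.3), 0))
})

test_that("max pooling keeps window maxima and drops the remainder", {
  expect_equal(max_pool(c(1, 3, 2, 0)), c(3, 2))
  expect_equal(max_pool(rep(4, 6)), rep(4, 3))
  expect_equal(max_pool(c(5, 1, 4)), 5)
  m <- cbind(c(1, 3, 2, 0), c(0, 1, 5, 2))
  expect_equal(max_pool(m), cbind(c(3, 2), c(1, 5)))
})

test_that("GRU step follows the gated recurrence in closed-form cases", {
  H <- 3L
  p <- list(W_r = matrix(0, 2, H), U_r = matrix(0, H, H), b_r = numeric(H),
            W_z = matrix(0, 2, H), U_z = matrix(0, H, H), b_z = numeric(H),
            W_g = matrix(0, 2, H), U_g = matrix(0, H, H), b_g = numeric(H))
  v <- c(0.4, -1, 2)
  st <- gru_step(c(1, 1), v, p)
  expect_equal(st$z, rep(0.5, H))
  expect_equal(st$g, rep(0, H))
  expect_equal(st$h, 0.5 * v)        # zero parameters halve the state

  p$b_z[] <- 50                      # update gate forced to ~1
  st <- gru_step(c(1, 1), v, p)
  expect_equal(st$h, st$g, tolerance = 1e-12)
})

test_that("GRU step matches a hand-computed scalar cell", {
  p <- list(W_r = matrix(0.3, 1, 1), U_r = matrix(-0.2, 1, 1), b_r = 0.1,
            W_z = matrix(-0.5, 1, 1), U_z = matrix(0.4, 1, 1), b_z = 0.2,
            W_g = matrix(1.2, 1, 1), U_g = matrix(0.6, 1, 1), b_g = -0.3)
  x <- 0.7; h0 <- -0.4
  sig <- function(v) 1 / (1 + exp(-v))
  r <- sig(0.3 * x - 0.2 * h0 + 0.1)
  z <- sig(-0.5 * x + 0.4 * h0 + 0.2)
  g <- tanh(1.2 * x + 0.6 * (r * h0) - 0.3)
  h <- (1 - z) * h0 + z * g
  st <- gru_step(x, h0, p)
  expect_equal(st$r, r, tolerance = 1e-12)
  expect_equal(st$z, z, tolerance = 1e-12)
  expect_equal(st$g, g, tolerance = 1e-12)
  expect_equal(st$h, h, tolerance = 1e-12)
})

test_that("bidirectional GRU concatenates direction states", {
  cfg <- model_config(filters = c(2L, 3L), gru_hidden = 4L,
                      attention_units = 2L, cnn_dropout = 0, gru_dropout = 0)
  params <- init_network_params(16L, cfg, seed = 3L)
  X <- matrix(rnorm(12), 4, 3)
  S <- bigru_forward(X, params$phage$gru_fwd, params$phage$gru_bwd)
  expect_equal(dim(S), c(4L, 8L))

  # single step: both directions see the same single input
  S1 <- bigru_forward(X[1, , drop = FALSE], params$phage$gru_fwd,
                      params$phage$gru_fwd)
  expect_equal(S1[1, 1:4], S1[1, 5:8])

  # default hidden size gives width 2H = 128
  expect_equal(2L * model_config()$gru_hidden, 128L)

  # reversing the input swaps the roles of the two passes (checked with
  # tied direction parameters, where the swap is an exact identity)
  Ssame <- bigru_forward(X, params$phage$gru_fwd, params$phage$gru_fwd)
  Ssame_rev <- bigru_forward(X[4:1, ], params$phage$gru_fwd,
                             params$phage$gru_fwd)
  expect_equal(Ssame_rev[4:1, 1:4], Ssame[, 5:8], tolerance = 1e-12)
})

test_that("attention weights are a softmax with an exact weighted sum", {
  ap <- list(W = matrix(rnorm(8), 4, 2), b = rnorm(2), v = rnorm(2))
  s1 <- matrix(rnorm(4), 1, 4)
  at <- attention_pool(s1, ap)
  expect_equal(at$weights, 1)
  expect_equal(at$pooled, drop(s1))

  same <- matrix(rep(rnorm(4), each = 3), 3, 4)
  at <- attention_pool(same, ap)
  expect_equal(at$weights, rep(1 / 3, 3))
  expect_equal(at$pooled, same[1, ])

  set.seed(5)
  states <- matrix(rnorm(12), 3, 4)
  at <- attention_pool(states, ap)
  scores <- apply(states, 1L,
                  function(h) sum(ap$v * tanh(drop(h %*% ap$W) + ap$b)))
  w <- exp(scores) / sum(exp(scores))
  expect_equal(at$weights, w, tolerance = 1e-12)
  expect_equal(at$pooled, drop(t(w) %*% states), tolerance = 1e-12)
  expect_equal(sum(at$weights), 1, tolerance = 1e-6)
  expect_true(all(at$weights >= 0))
})

test_that("the sigmoid head reproduces direct arithmetic", {
  head <- list(w = numeric(8), b = 0)
  expect_equal(predict_pair(rnorm(4), rnorm(4), head), 0.5)

  head$w <- rep(10, 8); head$b <- 5
  expect_gt(predict_pair(rep(1, 4), rep(1, 4), head), 1 - 1e-12)

  head <- list(w = c(0.5, -1, 2, 0.1), b = -0.2)
  hp <- c(1, 0.5); hb <- c(-1, 2)
  expect_equal(predict_pair(hp, hb, head),
               1 / (1 + exp(-(sum(c(hp, hb) * head$w) - 0.2))))
})

test_that("binary cross-entropy matches closed forms", {
  expect_equal(bce_loss(rep(0.5, 10), rbinom(10, 1, 0.5)), log(2))
  y <- c(1, 0, 1, 1, 0)
  expect_lt(bce_loss(y, y), 1e-6)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               -0.5 * (log(0.9) + log(0.8)))
  expect_error(bce_loss(c(0.5), c(1, 0)), "length")
  expect_gte(bce_loss(runif(20), rbinom(20, 1, 0.5)), 0)
})

test_that("an all-zero network outputs 0.5 for every pair", {
  for (variant in c("full", "PBIP3", "PBIP4")) {
    cfg <- model_config(filters = c(2L, 3L), gru_hidden = 3L,
                        attention_units = 2L, cnn_dropout = 0,
                        gru_dropout = 0, variant = variant)
    params <- zeroed(init_network_params(16L, cfg, seed = 1L))
    Xp <- matrix(rnorm(5 * 16), 5)
    Xb <- matrix(rnorm(5 * 16), 5)
    fw <- pbip:::net_forward(params, cfg, Xp, Xb)
    expect_equal(fw$prob, rep(0.5, 5))
  }
})

test_that("inference is deterministic and strictly inside (0, 1)", {
  cfg <- model_config(filters = c(2L, 4L), gru_hidden = 3L,
                      attention_units = 3L)
  params <- init_network_params(16L, cfg, seed = 7L)
  Xp <- matrix(rnorm(6 * 16), 6)
  Xb <- matrix(rnorm(6 * 16), 6)
  p1 <- pbip:::net_forward(params, cfg, Xp, Xb)$prob
  p2 <- pbip:::net_forward(params, cfg, Xp, Xb)$prob
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("analytic gradients agree with finite differences", {
  for (variant in c("full", "PBIP3", "PBIP4")) {
    set.seed(17)
    cfg <- model_config(filters = c(3L, 4L), gru_hidden = 3L,
                        attention_units = 3L, cnn_dropout = 0,
                        gru_dropout = 0, variant = variant)
    d_h <- 8L
    params <- init_network_params(d_h, cfg, seed = 17L)
    B <- 4L
    Xp <- matrix(rnorm(B * d_h), B)
    Xb <- matrix(rnorm(B * d_h), B)
    y <- rbinom(B, 1, 0.5)
    fw <- pbip:::net_forward(params, cfg, Xp, Xb)
    grads <- pbip:::net_backward(params, cfg, fw$cache, fw$prob, y)
    loss_at <- function(p) bce_loss(pbip:::net_forward(p, cfg, Xp, Xb)$prob, y)
    get_path <- function(x, path) { for (p in path) x <- x[[p]]; x }
    mod_path <- function(x, path, i, delta) {
      if (length(path) == 1L) {
        x[[path[[1]]]][i] <- x[[path[[1]]]][i] + delta
        x
      } else {
        x[[path[[1]]]] <- mod_path(x[[path[[1]]]], path[-1], i, delta)
        x
      }
    }
    eps <- 1e-6
    check <- function(path) {
      g <- get_path(grads, path)
      for (i in sample(length(g), min(3L, length(g)))) {
        num <- (loss_at(mod_path(params, path, i, eps)) -
                loss_at(mod_path(params, path, i, -eps))) / (2 * eps)
        expect_equal(g[i], num, tolerance = 1e-3)
      }
    }
    walk <- function(node, path) {
      if (is.list(node)) {
        keys <- names(node)
        if (is.null(keys)) keys <- seq_along(node)
        for (k in keys) walk(node[[k]], c(path, k))
      } else check(path)
    }
    walk(unclass(params), list())
  }
})

test_that("training reduces loss on separable data, deterministically", {
  pairs <- make_separable_pairs(20L, d_h = 16L, seed = 1L)
  cfg <- model_config(filters = c(2L, 4L), gru_hidden = 3L,
                      attention_units = 3L)
  fit <- train_model(pairs, cfg, train_config(epochs = 30L,
                                              learning_rate = 3e-3),
                     seed = 5L)
  expect_lt(utils::tail(fit$loss_history, 1L), fit$loss_history[1L])

  fit2 <- train_model(pairs, cfg, train_config(epochs = 30L,
                                               learning_rate = 3e-3),
                      seed = 5L)
  expect_identical(fit$loss_history, fit2$loss_history)

  # zero epochs leave the initialization untouched
  init <- init_network_params(16L, cfg, seed = 5L)
  fit0 <- train_model(pairs, cfg, train_config(epochs = 0L), seed = 5L,
                      params = init)
  expect_identical(fit0$params, init)
})

test_that("ablation variants change the architecture as named", {
  cfg3 <- ablation_variant("PBIP3", filters = c(2L, 3L), gru_hidden = 3L,
                           attention_units = 2L)
  p3 <- init_network_params(16L, cfg3, seed = 1L)
  expect_null(p3$phage$gru_fwd)
  expect_false(is.null(p3$phage$attn))

  cfg4 <- ablation_variant("PBIP4", filters = c(2L, 3L), gru_hidden = 3L,
                           attention_units = 2L)
  p4 <- init_network_params(16L, cfg4, seed = 1L)
  expect_null(p4$phage$attn)
  expect_false(is.null(p4$phage$gru_fwd))

  expect_error(ablation_variant("PBIP9"), "unknown")

  # PBIP5 keeps the network but skips augmentation
  pairs <- make_random_pairs(8L, 24L, d_h = 8L, seed = 3L)
  cfg5 <- ablation_variant("PBIP5", filters = c(2L, 2L), gru_hidden = 2L,
                           attention_units = 2L)
  fit <- pbip_fit(pairs, config = cfg5, train = train_config(epochs = 1L),
                  seed = 1L)
  expect_identical(fit$n_synthetic, 0L)
  expect_identical(fit$n_train, 32L)
})

test_that("inputs too short for the pooling pyramid are rejected", {
  cfg <- model_config()   # four pool-2 stages need d_h >= 16
  expect_error(init_network_params(8L, cfg, seed = 1L), ">= 16")
})
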