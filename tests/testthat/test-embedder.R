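test_that("one-hot encoding is an exact indicator over the fixed alphabet", {
  m <- one_hot("A")
  expect_equal(dim(m), c(1L, 20L))
  expect_equal(which(m[1, ] == 1L), c(A = 1L))

  m <- one_hot("AR")
  expect_equal(rowSums(m), c(1, 1))
  expect_equal(unname(apply(m, 1L, which.max)), c(1L, 2L))

  expect_equal(unname(one_hot(paste(AA_ALPHABET20, collapse = ""))),
               diag(20))

  # decoding the argmax recovers the sequence
  s <- "MKVLAWYH"
  expect_identical(paste(AA_ALPHABET20[apply(one_hot(s), 1, which.max)],
                         collapse = ""), s)

  expect_error(one_hot("AXB"), "non-canonical")
})

test_that("token projection selects embedding rows", {
  set.seed(3)
  W <- matrix(rnorm(200), 20, 10)
  X <- one_hot("RAV")
  P <- project_tokens(X, W)
  expect_equal(P, W[c(2L, 1L, 20L), ], ignore_attr = TRUE)

  expect_equal(project_tokens(X, matrix(0, 20, 10)),
               matrix(0, 3, 10), ignore_attr = TRUE)

  # random one-hot against a naive triple-loop multiply
  Xr <- one_hot("WHD")
  naive <- matrix(0, 3, 10)
  for (i in 1:3) for (j in 1:10) for (k in 1:20) {
    naive[i, j] <- naive[i, j] + Xr[i, k] * W[k, j]
  }
  expect_equal(unname(project_tokens(Xr, W)), naive)

  expect_error(project_tokens(X, matrix(0, 19, 10)), "mismatch")
})

test_that("mLSTM with all-zero parameters yields all-zero states", {
  p <- random_embedder_params(d_e = 4L, d_h = 6L, seed = 1L)
  for (nm in setdiff(names(p), c("d_e", "d_h"))) p[[nm]][] <- 0
  H <- mlstm_forward(matrix(rnorm(5 * 4), 5), p)
  expect_equal(H, matrix(0, 5, 6))
})

test_that("mLSTM matches a hand-computed scalar recurrence", {
  # d_e = 1, d_h = 1 with simple weights; two steps computed by hand
  p <- random_embedder_params(d_e = 1L, d_h = 1L, seed = 1L)
  p$W_mx[] <- 1; p$W_mh[] <- 0.5
  p$W_ix[] <- 0.2; p$W_im[] <- 0.3; p$b_i[] <- 0.1
  p$W_fx[] <- -0.4; p$W_fm[] <- 0.2; p$b_f[] <- 0.5
  p$W_ox[] <- 0.6; p$W_om[] <- -0.1; p$b_o[] <- 0
  p$W_cx[] <- 1.1; p$W_cm[] <- 0.7; p$b_c[] <- -0.2
  x <- c(0.8, -0.5)
  sig <- function(v) 1 / (1 + exp(-v))
  h <- 0; cc <- 0
  expected <- numeric(2)
  for (t in 1:2) {
    m <- (x[t] * 1) * (h * 0.5)
    i <- sig(0.2 * x[t] + 0.3 * m + 0.1)
    f <- sig(-0.4 * x[t] + 0.2 * m + 0.5)
    o <- sig(0.6 * x[t] - 0.1 * m + 0)
    g <- tanh(1.1 * x[t] + 0.7 * m - 0.2)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    expected[t] <- h
  }
  H <- mlstm_forward(matrix(x, 2, 1), p)
  expect_equal(drop(H), expected, tolerance = 1e-12)
})

test_that("mLSTM is order-sensitive, deterministic, and touches T steps", {
  p <- random_embedder_params(d_e = 3L, d_h = 5L, seed = 2L)
  X <- matrix(rnorm(12), 4, 3)
  H1 <- mlstm_forward(X, p)
  H2 <- mlstm_forward(X[4:1, ], p)
  expect_false(isTRUE(all.equal(H1[4, ], H2[4, ])))
  expect_identical(H1, mlstm_forward(X, p))   # bitwise determinism
  expect_identical(nrow(mlstm_forward(X[1:3, , drop = FALSE], p)), 3L)
})

test_that("protein embedding is the mean of hidden states", {
  p <- random_embedder_params(d_e = 10L, d_h = 4L, seed = 5L)
  s <- "ARNDAR"
  H <- mlstm_forward(project_tokens(one_hot(s), p$W_emb), p)
  manual <- apply(H, 2L, function(col) sum(col) / length(col))
  expect_equal(protein_embedding(s, p), manual, tolerance = 1e-12)

  # T = 1: embedding equals the single hidden state
  expect_equal(protein_embedding("A", p),
               drop(mlstm_forward(project_tokens(one_hot("A"), p$W_emb), p)))

  # truncation flag caps the recurrence length
  expect_equal(protein_embedding(s, p, max_length = 3L),
               protein_embedding("ARN", p))
})

test_that("organism embedding is a permutation-invariant mean", {
  v1 <- c(1, 0, 0); v2 <- c(0, 1, 0)
  expect_equal(organism_embedding(list(v1)), v1)
  expect_equal(organism_embedding(list(v1, v2)), c(0.5, 0.5, 0))
  vs <- lapply(1:6, function(i) rnorm(8))
  expect_equal(organism_embedding(vs), organism_embedding(rev(vs)))
  expect_equal(organism_embedding(rep(list(v1), 5L)), v1)
  expect_error(organism_embedding(list()), "no protein")
  expect_error(organism_embedding(list(v1, c(1, 2))), "mixed")
})

test_that("pair embedding concatenates the two organism embeddings", {
  p <- random_embedder_params(d_e = 10L, d_h = 4L, seed = 8L)
  set.seed(8)
  mk <- function(id, role, n) {
    prots <- vapply(seq_len(n), function(i) {
      paste(sample(AA_ALPHABET20, 12, replace = TRUE), collapse = "")
    }, character(1))
    names(prots) <- paste0(id, "|", seq_len(n))
    proteome(id, role, prots)
  }
  ph <- mk("ph1", "phage", 3L)
  ba <- mk("ba1", "bacterium", 2L)
  v <- embed_pair(ph, ba, p)
  expect_length(v, 8L)
  expect_equal(v[1:4], embed_proteome(ph, p))
  expect_equal(v[5:8], embed_proteome(ba, p))

  same <- embed_pair(ph, proteome("x", "bacterium", ph$proteins), p)
  expect_equal(same[1:4], same[5:8])
})

test_that("pretrained weight loading validates shapes and reads npy arrays", {
  d_e <- 3L; d_h <- 4L
  ref <- random_embedder_params(d_e, d_h, seed = 11L)
  dir <- withr::local_tempdir()

  write_npy <- function(mat, path) {
    dims <- if (is.null(dim(mat))) length(mat) else dim(mat)
    shape <- if (length(dims) == 1L) sprintf("(%d,)", dims)
             else sprintf("(%d, %d)", dims[1], dims[2])
    header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': %s, }",
                      shape)
    pad <- (64L - (10L + nchar(header) + 1L) %% 64L) %% 64L
    header <- paste0(header, strrep(" ", pad), "\n")
    con <- file(path, "wb")
    writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
    writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
    writeBin(charToRaw(header), con)
    writeBin(as.numeric(mat), con, size = 8L, endian = "little")
    close(con)
  }

  for (nm in setdiff(names(ref), c("d_e", "d_h"))) {
    write_npy(ref[[nm]], file.path(dir, paste0(nm, ".npy")))
  }
  loaded <- load_pretrained_weights(dir, d_e, d_h)
  for (nm in setdiff(names(ref), c("d_e", "d_h"))) {
    expect_equal(loaded[[nm]], ref[[nm]], tolerance = 1e-15,
                 ignore_attr = TRUE)
  }

  file.remove(file.path(dir, "W_emb.npy"))
  expect_error(load_pretrained_weights(dir, d_e, d_h), "W_emb")

  write_npy(matrix(0, 2, 2), file.path(dir, "W_emb.npy"))
  expect_error(load_pretrained_weights(dir, d_e, d_h), "shape")
})

test_that("seeded random parameters are reproducible", {
  a <- random_embedder_params(d_e = 5L, d_h = 8L, seed = 42L)
  b <- random_embedder_params(d_e = 5L, d_h = 8L, seed = 42L)
  expect_identical(a, b)
  expect_identical(b$d_h, 8L)
})
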