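# Protein sequence embedding: one-hot -> token embedding -> mLSTM -> mean
# pooling over residues and proteins.

#' One-hot encode a protein sequence
#'
#' Encodes a canonical residue string as a T x 20 indicator matrix over the
#' fixed alphabet [AA_ALPHABET20]; row t has a single 1 at the alphabet
#' index of residue t.
#'
#' @param residues Canonical residue string (see [parse_protein_fasta()]).
#' @return A T x 20 binary matrix with alphabet letters as column names.
#' @export
#' @examples
#' one_hot("AR")           # ones at columns A and R
one_hot <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop_pbip("cannot one-hot encode an empty sequence")
  idx <- match(chars, AA_ALPHABET20)
  if (anyNA(idx)) {
    stop_pbip(sprintf("non-canonical residue(s): %s",
                      paste(unique(chars[is.na(idx)]), collapse = ", ")))
  }
  m <- matrix(0L, nrow = length(idx), ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET20))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Project one-hot rows through the token embedding
#'
#' Each one-hot row selects the corresponding row of the 20 x d_e token
#' embedding matrix, giving the continuous T x d_e input to the mLSTM.
#'
#' @param X_one T x 20 one-hot matrix from [one_hot()].
#' @param W_emb 20 x d_e token embedding matrix.
#' @return T x d_e matrix.
#' @export
project_tokens <- function(X_one, W_emb) {
  if (ncol(X_one) != nrow(W_emb)) {
    stop_pbip(sprintf("shape mismatch: one-hot has %d columns, W_emb has %d rows",
                      ncol(X_one), nrow(W_emb)))
  }
  X_one %*% W_emb
}

#' Random embedder parameters
#'
#' Initializes the token embedding and all multiplicative-LSTM weight
#' matrices from a seeded generator.  Weights are Gaussian with standard
#' deviation `1/sqrt(fan_in)`; all biases are zero.  Used whenever the
#' released pretrained weights are not supplied (the default in tests and
#' simulations, where the embedder acts as a fixed random feature map).
#'
#' @param d_e Token embedding dimension (the pretrained model uses 10).
#' @param d_h mLSTM hidden dimension (the pretrained model uses 1900; tests
#'   run at 8-32).
#' @param seed Integer seed.
#' @return An object of class `pbip_embedder_params`.
#' @export
random_embedder_params <- function(d_e = 10L, d_h = 1900L, seed = 1L) {
  stopifnot(d_e >= 1L, d_h >= 1L)
  with_seed(seed, {
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
    p <- list(
      W_emb = g(20L, d_e),
      W_mx = g(d_e, d_h), W_mh = g(d_h, d_h),
      W_ix = g(d_e, d_h), W_im = g(d_h, d_h), b_i = numeric(d_h),
      W_fx = g(d_e, d_h), W_fm = g(d_h, d_h), b_f = numeric(d_h),
      W_ox = g(d_e, d_h), W_om = g(d_h, d_h), b_o = numeric(d_h),
      W_cx = g(d_e, d_h), W_cm = g(d_h, d_h), b_c = numeric(d_h),
      d_e = d_e, d_h = d_h)
    class(p) <- "pbip_embedder_params"
    p
  })
}

embedder_shapes <- function(d_e, d_h) {
  list(W_emb = c(20L, d_e),
       W_mx = c(d_e, d_h), W_mh = c(d_h, d_h),
       W_ix = c(d_e, d_h), W_im = c(d_h, d_h), b_i = d_h,
       W_fx = c(d_e, d_h), W_fm = c(d_h, d_h), b_f = d_h,
       W_ox = c(d_e, d_h), W_om = c(d_h, d_h), b_o = d_h,
       W_cx = c(d_e, d_h), W_cm = c(d_h, d_h), b_c = d_h)
}

#' Load pretrained embedder weights from a directory
#'
#' Reads one array file per parameter (`W_emb.npy`, `W_mx.npy`, ...; plain
#' whitespace-delimited `.txt` matrices are also accepted) and checks every
#' shape against the expected dimensions.  The released 1900-unit protein
#' representation model uses `d_e = 10`, `d_h = 1900`.
#'
#' @param directory Directory holding the weight arrays.
#' @param d_e,d_h Expected dimensions.
#' @return An object of class `pbip_embedder_params`.
#' @export
load_pretrained_weights <- function(directory, d_e = 10L, d_h = 1900L) {
  shapes <- embedder_shapes(d_e, d_h)
  p <- list()
  for (nm in names(shapes)) {
    npy <- file.path(directory, paste0(nm, ".npy"))
    txt <- file.path(directory, paste0(nm, ".txt"))
    if (file.exists(npy)) {
      arr <- read_npy_matrix(npy)
    } else if (file.exists(txt)) {
      arr <- as.matrix(utils::read.table(txt, header = FALSE))
      dimnames(arr) <- NULL
    } else {
      stop_pbip(sprintf("missing weight array '%s' (expected shape %s) in '%s'",
                        nm, paste(shapes[[nm]], collapse = "x"), directory))
    }
    want <- shapes[[nm]]
    if (length(want) == 1L) {
      arr <- as.numeric(arr)
      if (length(arr) != want) {
        stop_pbip(sprintf("weight '%s' has length %d, expected %d",
                          nm, length(arr), want))
      }
    } else if (!identical(dim(arr), as.integer(want))) {
      stop_pbip(sprintf("weight '%s' has shape %s, expected %s", nm,
                        paste(dim(arr), collapse = "x"),
                        paste(want, collapse = "x")))
    }
    p[[nm]] <- arr
  }
  p$d_e <- as.integer(d_e)
  p$d_h <- as.integer(d_h)
  class(p) <- "pbip_embedder_params"
  p
}

# Minimal reader for NumPy .npy v1/v2 files (C-order, little-endian float32
# or float64 matrices), the format the released weights ship in.  No
# installed R package reads .npy, so this is done by hand.
read_npy_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop_pbip(sprintf("'%s' is not an .npy file", path))
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexec("'descr':\\s*'([^']+)'", header))[[1]][2]
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- regmatches(header, regexec("'shape':\\s*\\(([^)]*)\\)", header))[[1]][2]
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  size <- switch(descr, "<f4" = 4L, "<f8" = 8L,
                 stop_pbip(sprintf("unsupported .npy dtype '%s' in '%s'",
                                   descr, path)))
  n <- prod(shape)
  vals <- readBin(con, "numeric", n, size = size, endian = "little")
  if (length(shape) == 1L) return(vals)
  if (length(shape) != 2L) stop_pbip("only 1-D/2-D .npy arrays are supported")
  if (fortran) matrix(vals, shape[1], shape[2])
  else t(matrix(vals, shape[2], shape[1]))
}

#' Multiplicative-LSTM forward pass
#'
#' Runs the mLSTM recurrence over the continuous token matrix.  At each
#' step an intermediate multiplicative state
#' `m_t = (X_t W_mx) * (h_{t-1} W_mh)` (elementwise product) replaces the
#' previous hidden state in the input, forget and output gates and the
#' candidate update of a standard LSTM; `h_t = o_t * tanh(c_t)`.  Initial
#' hidden and cell states are zero.
#'
#' @param X_emb T x d_e matrix from [project_tokens()].
#' @param params `pbip_embedder_params`.
#' @return T x d_h matrix of hidden states (row t = `h_t`).
#' @export
mlstm_forward <- function(X_emb, params) {
  T_ <- nrow(X_emb)
  if (is.null(T_) || T_ < 1L) stop_pbip("mlstm_forward needs T >= 1")
  d_h <- params$d_h
  H <- matrix(0, T_, d_h)
  h <- numeric(d_h)
  cc <- numeric(d_h)
  # hoisted input-side products: T x d_h each
  Xmx <- X_emb %*% params$W_mx
  Xix <- X_emb %*% params$W_ix
  Xfx <- X_emb %*% params$W_fx
  Xox <- X_emb %*% params$W_ox
  Xcx <- X_emb %*% params$W_cx
  for (t in seq_len(T_)) {
    m <- Xmx[t, ] * drop(h %*% params$W_mh)
    i <- sigmoid(Xix[t, ] + drop(m %*% params$W_im) + params$b_i)
    f <- sigmoid(Xfx[t, ] + drop(m %*% params$W_fm) + params$b_f)
    o <- sigmoid(Xox[t, ] + drop(m %*% params$W_om) + params$b_o)
    g <- tanh(Xcx[t, ] + drop(m %*% params$W_cm) + params$b_c)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    if (any(!is.finite(h))) {
      stop_pbip(sprintf("non-finite mLSTM state at time step %d", t))
    }
    H[t, ] <- h
  }
  H
}

#' Embed one protein sequence
#'
#' One-hot encodes the sequence, projects it through the token embedding,
#' runs the mLSTM and averages the hidden states over residues.
#'
#' @param residues Canonical residue string.
#' @param params `pbip_embedder_params`.
#' @param max_length Optional truncation length for very long proteins;
#'   `Inf` (default) processes the full sequence.
#' @return Numeric vector of length `params$d_h`.
#' @export
protein_embedding <- function(residues, params, max_length = Inf) {
  if (is.finite(max_length) && nchar(residues) > max_length) {
    residues <- substr(residues, 1L, max_length)
  }
  H <- mlstm_forward(project_tokens(one_hot(residues), params$W_emb), params)
  colMeans(H)
}

#' Mean-pool protein embeddings to an organism embedding
#'
#' @param embeddings A list of equal-length numeric vectors, or a matrix
#'   with one row per protein.
#' @return Componentwise mean vector.
#' @export
organism_embedding <- function(embeddings) {
  if (is.list(embeddings)) {
    if (length(embeddings) == 0L) stop_pbip("no protein embeddings to pool")
    lens <- lengths(embeddings)
    if (length(unique(lens)) != 1L) {
      stop_pbip("protein embeddings have mixed lengths")
    }
    embeddings <- do.call(rbind, embeddings)
  }
  if (is.null(dim(embeddings)) || nrow(embeddings) == 0L) {
    stop_pbip("no protein embeddings to pool")
  }
  colMeans(embeddings)
}

#' Embed an organism proteome
#'
#' @param org A [proteome()] object.
#' @param params `pbip_embedder_params`.
#' @param max_length Passed to [protein_embedding()].
#' @return Numeric vector of length `params$d_h`.
#' @export
embed_proteome <- function(org, params, max_length = Inf) {
  stopifnot(inherits(org, "pbip_proteome"))
  embs <- lapply(org$proteins, protein_embedding, params = params,
                 max_length = max_length)
  organism_embedding(embs)
}

#' Embed a phage-bacterium pair
#'
#' Concatenates the phage and bacterium organism embeddings into one
#' pair vector of length `2 * d_h` (phage half first).
#'
#' @param phage,bacterium [proteome()] objects.
#' @param params `pbip_embedder_params`.
#' @param max_length Passed to [protein_embedding()].
#' @return Numeric vector of length `2 * params$d_h`.
#' @export
embed_pair <- function(phage, bacterium, params, max_length = Inf) {
  c(embed_proteome(phage, params, max_length),
    embed_proteome(bacterium, params, max_length))
}

#' Embed many organisms into a matrix
#'
#' @param proteomes List of [proteome()] objects.
#' @param params `pbip_embedder_params`.
#' @param max_length Passed to [protein_embedding()].
#' @return Matrix with one row per organism (rownames = organism ids).
#' @export
embed_organisms <- function(proteomes, params, max_length = Inf) {
  M <- t(vapply(proteomes, embed_proteome, numeric(params$d_h),
                params = params, max_length = max_length))
  rownames(M) <- vapply(proteomes, `[[`, character(1), "id")
  M
}

#' Build the paired-embedding table for an interaction table
#'
#' Looks up the phage and bacterium organism embeddings for every record
#' and returns the concatenated pair matrix alongside ids and labels --
#' the input format of [balance_with_smote()] and [pbip_fit()].
#'
#' @param table A `pbip_interactions` table.
#' @param phage_embeddings,bacterium_embeddings Matrices from
#'   [embed_organisms()] with organism ids as rownames.
#' @return An object of class `pbip_pairs`: list with `x` (n x 2 d_h
#'   matrix), `y` (integer labels), `phage_id`, `bacterium_id`, `synthetic`
#'   (logical), `d_h`.
#' @export
pair_embedding_table <- function(table, phage_embeddings,
                                 bacterium_embeddings) {
  pi_ <- match(table$phage_id, rownames(phage_embeddings))
  bi <- match(table$bacterium_id, rownames(bacterium_embeddings))
  if (anyNA(pi_)) {
    stop_pbip(sprintf("no embedding for phage(s): %s",
                      paste(unique(table$phage_id[is.na(pi_)]), collapse = ", ")))
  }
  if (anyNA(bi)) {
    stop_pbip(sprintf("no embedding for bacterium(s): %s",
                      paste(unique(table$bacterium_id[is.na(bi)]), collapse = ", ")))
  }
  x <- cbind(phage_embeddings[pi_, , drop = FALSE],
             bacterium_embeddings[bi, , drop = FALSE])
  rownames(x) <- NULL
  structure(list(x = x, y = as.integer(table$label),
                 phage_id = table$phage_id, bacterium_id = table$bacterium_id,
                 synthetic = rep(FALSE, nrow(x)),
                 d_h = ncol(phage_embeddings)),
            class = "pbip_pairs")
}

#' @export
print.pbip_pairs <- function(x, ...) {
  cat(sprintf("<pbip_pairs> %d pairs (%d positive, %d synthetic), d_h = %d\n",
              nrow(x$x), sum(x$y == 1L), sum(x$synthetic), x$d_h))
  invisible(x)
}

#' Subset a paired-embedding table
#'
#' @param x A `pbip_pairs` object.
#' @param i Row indices.
#' @param ... Ignored.
#' @return A `pbip_pairs` object with the selected rows.
#' @export
`[.pbip_pairs` <- function(x, i, ...) {
  structure(list(x = x$x[i, , drop = FALSE], y = x$y[i],
                 phage_id = x$phage_id[i], bacterium_id = x$bacterium_id[i],
                 synthetic = x$synthetic[i], d_h = x$d_h),
            class = "pbip_pairs")
}
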