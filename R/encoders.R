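# Note text encoders and the hierarchical temporal module.
#
# The default encoder is a lightweight embedding bag: hashed token
# embeddings, mean-pooled, with seeded Xavier initialization, so note
# embeddings are bitwise reproducible without any pretrained weights. The
# adapter interface (name, dim, max_length, encode(tokens)) lets a
# long-context transformer be plugged in unchanged. The temporal module is
# a bidirectional LSTM (2 layers) followed by additive attention over the
# per-note states.

.encoder_registry <- new.env(parent = emptyenv())

#' Register a note encoder adapter
#'
#' @param name Adapter name.
#' @param encoder List with fields `name`, `dim`, `max_length`, and
#'   `encode` (`function(tokens) -> numeric(dim)`).
#' @export
register_encoder <- function(name, encoder) {
  stopifnot(is.function(encoder$encode), is.numeric(encoder$dim))
  assign(name, encoder, envir = .encoder_registry)
  invisible(encoder)
}

#' Fetch a registered encoder by name
#'
#' @param name Adapter name; unregistered names are fatal.
#' @export
get_encoder <- function(name) {
  if (!exists(name, envir = .encoder_registry, inherits = FALSE)) {
    stopf("no encoder adapter registered under '%s'", name)
  }
  get(name, envir = .encoder_registry, inherits = FALSE)
}

#' Create the embedding-bag note encoder
#'
#' Tokens are hashed into a fixed vocabulary of embedding rows; a note
#' embedding is the mean of its token embeddings. Deterministic given the
#' seed.
#'
#' @param dim Embedding dimension.
#' @param vocab_size Hashed vocabulary size.
#' @param max_length Truncation length (tokens beyond it are ignored and
#'   the truncation is recorded on the result).
#' @param seed Integer seed.
#' @return Encoder adapter list (also registered as `"embedding_bag"`).
#' @export
embedding_bag_encoder <- function(dim = 32L, vocab_size = 4096L,
                                  max_length = 4096L, seed = 1L) {
  emb <- withr::with_seed(seed, xavier_matrix(vocab_size, dim))
  enc <- list(
    name = "embedding_bag", dim = dim, max_length = max_length,
    encode = function(tokens) {
      truncated <- length(tokens) > max_length
      if (truncated) tokens <- tokens[seq_len(max_length)]
      if (length(tokens) == 0) return(structure(numeric(dim), truncated = FALSE))
      idx <- vapply(tokens, function(t) (hash31(t) %% vocab_size) + 1L, integer(1))
      structure(colMeans(emb[idx, , drop = FALSE]), truncated = truncated)
    })
  register_encoder("embedding_bag", enc)
  enc
}

#' Encode one note to its dense embedding
#'
#' @param note A [note()] object (tokens computed from text if absent).
#' @param encoder Adapter list or registered adapter name.
#' @return Numeric embedding of length `encoder$dim`.
#' @export
encode_note <- function(note, encoder = "embedding_bag") {
  if (is.character(encoder)) encoder <- get_encoder(encoder)
  tokens <- if (length(note$tokens)) note$tokens else tokenize_text(note$text)
  encoder$encode(tokens)
}

# ---------------------------------------------------------------------------
# Bidirectional LSTM + additive temporal attention

lstm_cell_params <- function(input_dim, hidden) {
  list(W = xavier_matrix(input_dim, 4L * hidden),   # input weights (i,f,g,o)
       U = xavier_matrix(hidden, 4L * hidden),
       b = numeric(4L * hidden),
       hidden = hidden)
}

#' Temporal encoder parameters
#'
#' A 2-layer bidirectional LSTM (each direction `hidden/2` units so the
#' concatenated state has size `hidden`) plus an additive attention head.
#'
#' @param input_dim Note-embedding dimension.
#' @param hidden Total recurrent state size per note (default 256).
#' @param n_layers Number of stacked layers (default 2).
#' @param seed Integer seed.
#' @return A `temporal_params` list.
#' @export
temporal_params <- function(input_dim, hidden = 256L, n_layers = 2L, seed = 1L) {
  stopifnot(hidden %% 2L == 0L)
  h2 <- hidden %/% 2L
  withr::with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) {
      d_in <- if (l == 1L) input_dim else hidden
      list(fwd = lstm_cell_params(d_in, h2), bwd = lstm_cell_params(d_in, h2))
    })
    attn <- list(Wa = xavier_matrix(hidden, hidden), ba = numeric(hidden),
                 ctx = as.numeric(xavier_matrix(hidden, 1L)))
    structure(list(layers = layers, attn = attn, hidden = hidden,
                   n_layers = n_layers),
              class = "temporal_params")
  })
}

# Single-direction LSTM pass over rows of X (T x d_in).
lstm_forward <- function(X, cell, reverse = FALSE) {
  T_ <- nrow(X); H <- cell$hidden
  idx <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  out <- matrix(0, T_, H)
  h <- numeric(H); cst <- numeric(H)
  XW <- X %*% cell$W
  for (t in idx) {
    z <- as.numeric(XW[t, ]) + as.numeric(h %*% cell$U) + cell$b
    i <- sigmoid(z[seq_len(H)])
    f <- sigmoid(z[H + seq_len(H)])
    g <- tanh(z[2L * H + seq_len(H)])
    o <- sigmoid(z[3L * H + seq_len(H)])
    cst <- f * cst + i * g
    h <- o * tanh(cst)
    out[t, ] <- h
  }
  out
}

#' Hierarchical temporal encoding of a note sequence
#'
#' Runs the stacked bidirectional LSTM over the time-ordered note
#' embeddings, then pools the per-note states with additive attention:
#' `e_t = ctx' tanh(Wa u_t + ba)`, `alpha = softmax(e)`,
#' `v = sum_t alpha_t u_t`.
#'
#' @param S Matrix of note embeddings, rows in ascending time order.
#' @param params [temporal_params()].
#' @return List with `u` (T x hidden states), `v` (patient vector), and
#'   `alpha` (attention weights summing to 1).
#' @export
temporal_encode <- function(S, params) {
  S <- as.matrix(S)
  if (nrow(S) == 0) stopf("temporal_encode: empty note sequence")
  X <- S
  for (l in seq_len(params$n_layers)) {
    lay <- params$layers[[l]]
    X <- cbind(lstm_forward(X, lay$fwd, reverse = FALSE),
               lstm_forward(X, lay$bwd, reverse = TRUE))
  }
  u <- X
  e <- as.numeric(tanh(sweep(u %*% params$attn$Wa, 2L, params$attn$ba, `+`)) %*%
                    params$attn$ctx)
  alpha <- softmax(e)
  v <- as.numeric(crossprod(u, alpha))
  list(u = u, v = v, alpha = alpha)
}
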