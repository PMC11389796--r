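# Multi-head self-attention encoder over token embeddings, written with
# explicit forward and reverse passes so that per-layer, per-head attention
# scores A and their gradients dPrediction/dA can be captured during a
# single forward/backward pair -- the quantities the relevance-propagation
# attribution consumes. Pre-normalization residual blocks:
#
#   x <- x + MHSA(LN1(x));  x <- x + FFN(LN2(x))
#
# All parameters live in a flat named list so a single AdamW implementation
# serves encoder, heads and the pretraining projection alike.

.LN_EPS <- 1e-5

#' Encoder configuration
#'
#' @param num_layers Number of transformer layers (L).
#' @param num_heads Number of attention heads per layer (H).
#' @param model_dim Embedding/latent dimensionality (d); must be divisible
#'   by `num_heads`.
#' @param feedforward_dim Hidden width of the position-wise feed-forward
#'   network.
#' @param max_tokens Maximum sequence length (including the readout token).
#' @param vocab_size Vocabulary size (number of embedding rows).
#' @param seed Seed for weight initialization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(num_layers, num_heads, model_dim, feedforward_dim,
                           max_tokens, vocab_size, seed = 0L) {
  stopifnot(num_layers >= 1, num_heads >= 1, model_dim >= 1,
            feedforward_dim >= 1, max_tokens >= 1, vocab_size >= 1)
  if (model_dim %% num_heads != 0L) {
    stopf("model_dim (%d) must be divisible by num_heads (%d)", model_dim, num_heads)
  }
  structure(list(num_layers = as.integer(num_layers),
                 num_heads = as.integer(num_heads),
                 model_dim = as.integer(model_dim),
                 feedforward_dim = as.integer(feedforward_dim),
                 max_tokens = as.integer(max_tokens),
                 vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Desk-scale encoder preset (L=2, H=4, d=64)
#'
#' A configuration small enough to train on one CPU in minutes while
#' preserving the architecture of full-scale chemical language models
#' (which use L=6, H=8, d=512 -- also representable via
#' [encoder_config()]).
#' @param vocab_size Vocabulary size.
#' @param seed Initialization seed.
#' @return An `encoder_config`.
#' @export
desk_config <- function(vocab_size, seed = 0L) {
  encoder_config(num_layers = 2L, num_heads = 4L, model_dim = 64L,
                 feedforward_dim = 128L, max_tokens = 64L,
                 vocab_size = vocab_size, seed = seed)
}

rnorm_mat <- function(n, m, sd) matrix(stats::rnorm(n * m, 0, sd), n, m)

#' Initialize encoder weights
#' @param config An `encoder_config`.
#' @return A `clm_encoder`: list with `config` and flat named `params`.
#' @export
init_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  d <- config$model_dim; ff <- config$feedforward_dim
  with_seed(config$seed, {
    p <- list(
      tok_emb = rnorm_mat(config$vocab_size, d, 0.02),
      pos_emb = rnorm_mat(config$max_tokens, d, 0.02)
    )
    sdw <- 1 / sqrt(d)
    for (l in seq_len(config$num_layers)) {
      pre <- sprintf("L%d.", l)
      p[[paste0(pre, "Wq")]] <- rnorm_mat(d, d, sdw)
      p[[paste0(pre, "Wk")]] <- rnorm_mat(d, d, sdw)
      p[[paste0(pre, "Wv")]] <- rnorm_mat(d, d, sdw)
      p[[paste0(pre, "Wo")]] <- rnorm_mat(d, d, sdw)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      p[[paste0(pre, "W1")]] <- rnorm_mat(d, ff, sdw)
      p[[paste0(pre, "b1")]] <- rep(0, ff)
      p[[paste0(pre, "W2")]] <- rnorm_mat(ff, d, 1 / sqrt(ff))
      p[[paste0(pre, "b2")]] <- rep(0, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    }
    structure(list(config = config, params = p), class = "clm_encoder")
  })
}

#' @export
print.clm_encoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<clm_encoder: L=%d H=%d d=%d ff=%d vocab=%d>\n",
              cfg$num_layers, cfg$num_heads, cfg$model_dim,
              cfg$feedforward_dim, cfg$vocab_size))
  invisible(x)
}

# row-broadcast a length-d vector over a T x d matrix
brow <- function(v, nr) matrix(v, nr, length(v), byrow = TRUE)

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd_ <- sqrt(rowMeans(xc * xc) + .LN_EPS)
  xhat <- xc / sd_
  list(Y = xhat * brow(g, nrow(X)) + brow(b, nrow(X)), xhat = xhat, sd = sd_)
}

ln_bwd <- function(dY, cache, g) {
  Tn <- nrow(dY)
  dxhat <- dY * brow(g, Tn)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) / cache$sd
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

softmax_rows <- function(S) {
  mx <- apply(S, 1, max)
  E <- exp(S - mx)
  E[is.nan(E)] <- 0  # rows that were entirely -Inf
  E / pmax(rowSums(E), .Machine$double.xmin)
}

#' Scaled dot-product attention scores
#'
#' Computes the row-stochastic attention matrix
#' `A = softmax(Q K^T / sqrt(d_k))`, excluding padded key positions from
#' the normalization.
#'
#' @param Q,K Matrices of shape T x d_k.
#' @param pad_mask Optional logical vector of length T; `TRUE` marks real
#'   (non-PAD) positions. `NULL` means no padding.
#' @return A T x T matrix whose non-PAD rows each sum to 1; PAD columns
#'   are exactly zero.
#' @examples
#' attention_scores(matrix(0, 3, 2), matrix(rnorm(6), 3, 2))
#' @export
attention_scores <- function(Q, K, pad_mask = NULL) {
  stopifnot(is.matrix(Q), is.matrix(K), all(dim(Q) == dim(K)), ncol(Q) >= 1)
  Tn <- nrow(Q)
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, Tn)
  stopifnot(length(pad_mask) == Tn)
  if (!any(pad_mask)) stopf("all positions are padded; attention undefined")
  S <- (Q %*% t(K)) / sqrt(ncol(Q))
  S[, !pad_mask] <- -Inf
  softmax_rows(S)
}

head_cols <- function(h, dk) ((h - 1L) * dk + 1L):(h * dk)

# Full forward pass over one sequence of 0-based token ids.
# Returns latent (T x d), attention scores per layer (H x T x T arrays)
# when trace is on, and the cache needed for the reverse pass.
encoder_forward <- function(enc, ids0, pad_mask = NULL, trace = FALSE,
                            keep_cache = FALSE) {
  cfg <- enc$config; p <- enc$params
  Tn <- length(ids0)
  if (Tn > cfg$max_tokens) {
    stopf("sequence length %d exceeds max_tokens %d", Tn, cfg$max_tokens)
  }
  if (any(ids0 < 0L | ids0 >= cfg$vocab_size)) stopf("token id outside vocabulary")
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, Tn)
  d <- cfg$model_dim; H <- cfg$num_heads; dk <- d %/% H
  count_forward()

  x <- p$tok_emb[ids0 + 1L, , drop = FALSE] + p$pos_emb[seq_len(Tn), , drop = FALSE]
  layers <- vector("list", cfg$num_layers)
  attn <- if (trace || keep_cache) vector("list", cfg$num_layers) else NULL

  for (l in seq_len(cfg$num_layers)) {
    pre <- sprintf("L%d.", l)
    x_in <- x
    ln1 <- ln_fwd(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    n1 <- ln1$Y
    Qf <- n1 %*% p[[paste0(pre, "Wq")]]
    Kf <- n1 %*% p[[paste0(pre, "Wk")]]
    Vf <- n1 %*% p[[paste0(pre, "Wv")]]
    O <- matrix(0, Tn, d)
    A_l <- array(0, c(H, Tn, Tn))
    for (h in seq_len(H)) {
      cols <- head_cols(h, dk)
      A <- attention_scores(Qf[, cols, drop = FALSE], Kf[, cols, drop = FALSE], pad_mask)
      A_l[h, , ] <- A
      O[, cols] <- A %*% Vf[, cols, drop = FALSE]
    }
    attn_out <- O %*% p[[paste0(pre, "Wo")]]
    x_mid <- x_in + attn_out
    ln2 <- ln_fwd(x_mid, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    n2 <- ln2$Y
    Hpre <- n2 %*% p[[paste0(pre, "W1")]] + brow(p[[paste0(pre, "b1")]], Tn)
    Hact <- pmax(Hpre, 0)
    x <- x_mid + Hact %*% p[[paste0(pre, "W2")]] + brow(p[[paste0(pre, "b2")]], Tn)

    if (!is.null(attn)) attn[[l]] <- A_l
    if (keep_cache) {
      layers[[l]] <- list(ln1 = ln1, n1 = n1, Qf = Qf, Kf = Kf, Vf = Vf,
                          A = A_l, O = O, ln2 = ln2, n2 = n2,
                          Hpre = Hpre, Hact = Hact)
    }
  }

  list(latent = x,
       attn = if (trace) attn else NULL,
       cache = if (keep_cache) list(ids0 = ids0, pad_mask = pad_mask,
                                    Tn = Tn, layers = layers) else NULL)
}

# Reverse pass from d_latent (T x d). Returns parameter gradients (same
# flat naming as enc$params) and the attention-score gradients
# dScalar/dA per layer as H x T x T arrays.
encoder_backward <- function(enc, cache, d_latent) {
  cfg <- enc$config; p <- enc$params
  Tn <- cache$Tn; d <- cfg$model_dim; H <- cfg$num_heads; dk <- d %/% H
  count_backward()
  g <- list()
  d_attn <- vector("list", cfg$num_layers)
  dx <- d_latent

  for (l in rev(seq_len(cfg$num_layers))) {
    pre <- sprintf("L%d.", l)
    lc <- cache$layers[[l]]
    # feed-forward block
    dHact <- dx %*% t(p[[paste0(pre, "W2")]])
    g[[paste0(pre, "W2")]] <- t(lc$Hact) %*% dx
    g[[paste0(pre, "b2")]] <- colSums(dx)
    dHpre <- dHact * (lc$Hpre > 0)
    g[[paste0(pre, "W1")]] <- t(lc$n2) %*% dHpre
    g[[paste0(pre, "b1")]] <- colSums(dHpre)
    dn2 <- dHpre %*% t(p[[paste0(pre, "W1")]])
    lb2 <- ln_bwd(dn2, lc$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dx_mid <- dx + lb2$dX
    # attention block
    dattn_out <- dx_mid
    g[[paste0(pre, "Wo")]] <- t(lc$O) %*% dattn_out
    dO <- dattn_out %*% t(p[[paste0(pre, "Wo")]])
    dQf <- matrix(0, Tn, d); dKf <- matrix(0, Tn, d); dVf <- matrix(0, Tn, d)
    dA_l <- array(0, c(H, Tn, Tn))
    for (h in seq_len(H)) {
      cols <- head_cols(h, dk)
      A <- lc$A[h, , , drop = TRUE]
      if (Tn == 1L) A <- matrix(A, 1, 1)
      dOh <- dO[, cols, drop = FALSE]
      dA <- dOh %*% t(lc$Vf[, cols, drop = FALSE])
      dA_l[h, , ] <- dA
      dVf[, cols] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQf[, cols] <- (dS %*% lc$Kf[, cols, drop = FALSE]) / sqrt(dk)
      dKf[, cols] <- (t(dS) %*% lc$Qf[, cols, drop = FALSE]) / sqrt(dk)
    }
    d_attn[[l]] <- dA_l
    g[[paste0(pre, "Wq")]] <- t(lc$n1) %*% dQf
    g[[paste0(pre, "Wk")]] <- t(lc$n1) %*% dKf
    g[[paste0(pre, "Wv")]] <- t(lc$n1) %*% dVf
    dn1 <- dQf %*% t(p[[paste0(pre, "Wq")]]) +
           dKf %*% t(p[[paste0(pre, "Wk")]]) +
           dVf %*% t(p[[paste0(pre, "Wv")]])
    lb1 <- ln_bwd(dn1, lc$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dx <- dx_mid + lb1$dX
  }

  # embedding gradients
  dtok <- matrix(0, cfg$vocab_size, d)
  rows <- cache$ids0 + 1L
  for (t in seq_len(Tn)) dtok[rows[t], ] <- dtok[rows[t], ] + dx[t, ]
  dpos <- matrix(0, cfg$max_tokens, d)
  dpos[seq_len(Tn), ] <- dx
  g$tok_emb <- dtok
  g$pos_emb <- dpos

  list(grads = g, d_attn = d_attn)
}

#' Encode a tokenized molecule into latent representations
#'
#' Runs the encoder forward pass, producing the T x d latent matrix. With
#' `trace = TRUE` the per-layer, per-head attention scores are captured;
#' the matching attention gradients are populated only after a subsequent
#' reverse pass from a scalar prediction (see [attribute_readout()]), so
#' `grads` is `NULL` here.
#'
#' @param encoder A `clm_encoder`.
#' @param tokenized A `tokenized_molecule` with `ids` filled in.
#' @param pad_mask Optional logical vector marking real positions.
#' @param trace Capture attention scores (default `FALSE`).
#' @return A `latent_representation`: list with `matrix` (T x d), `tokens`,
#'   `attn` (list of H x T x T arrays or `NULL`) and `grads` (`NULL` until a
#'   reverse pass fills it).
#' @export
encode <- function(encoder, tokenized, pad_mask = NULL, trace = FALSE) {
  stopifnot(inherits(encoder, "clm_encoder"), inherits(tokenized, "tokenized_molecule"))
  if (is.null(tokenized$ids)) stopf("tokenized molecule has no ids; tokenize with a vocabulary")
  fw <- encoder_forward(encoder, tokenized$ids, pad_mask = pad_mask, trace = trace)
  structure(list(matrix = fw$latent, tokens = tokenized$tokens,
                 attn = fw$attn, grads = NULL),
            class = "latent_representation")
}

#' Pool latent representations into a molecule-level vector
#'
#' @param latent A T x d matrix or a `latent_representation`.
#' @param strategy `"avg"` (token-wise mean over non-PAD rows) or
#'   `"readout"` (the row of the readout token, position 1).
#' @param pad_mask Optional logical vector; `TRUE` marks real tokens.
#' @param has_readout Whether position 1 holds the readout token (required
#'   for `strategy = "readout"`).
#' @return A numeric vector of length d.
#' @export
pool <- function(latent, strategy = c("avg", "readout"), pad_mask = NULL,
                 has_readout = TRUE) {
  strategy <- match.arg(strategy)
  X <- if (inherits(latent, "latent_representation")) latent$matrix else latent
  stopifnot(is.matrix(X))
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, nrow(X))
  if (strategy == "readout") {
    if (!has_readout) stopf("readout pooling requested but the sequence has no readout token")
    X[1, ]
  } else {
    if (!any(pad_mask)) stopf("all positions padded; nothing to pool")
    colMeans(X[pad_mask, , drop = FALSE])
  }
}

# gradient of pool() wrt the latent matrix
pool_bwd <- function(dvec, Tn, strategy, pad_mask = NULL) {
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, Tn)
  dX <- matrix(0, Tn, length(dvec))
  if (strategy == "readout") {
    dX[1, ] <- dvec
  } else {
    n <- sum(pad_mask)
    dX[pad_mask, ] <- matrix(dvec / n, n, length(dvec), byrow = TRUE)
  }
  dX
}
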