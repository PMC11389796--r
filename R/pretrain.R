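# Masked-reconstruction pretraining: random subsets of input tokens are
# replaced by <MASK> and the encoder, through a temporary linear projection
# to vocabulary logits, learns to reconstruct them. This is the desk-scale
# stand-in for a large pretrained chemical language model: "frozen"
# experiments use the weights it produces.

mask_positions <- function(n_tokens, mask_fraction, skip = integer(0)) {
  cand <- setdiff(seq_len(n_tokens), skip)
  k <- max(1L, round(mask_fraction * length(cand)))
  sample(cand, min(k, length(cand)))
}

softmax_vec_rows <- function(L) {
  mx <- apply(L, 1, max)
  E <- exp(L - mx)
  E / rowSums(E)
}

#' Pretrain an encoder by masked token reconstruction
#'
#' @param encoder A `clm_encoder`.
#' @param tokenized List of `tokenized_molecule`s with ids (typically
#'   without a readout token, but the readout position is simply never
#'   masked if present).
#' @param mask_fraction Fraction of tokens masked per sequence, in (0, 1)
#'   (default 0.15).
#' @param epochs Training epochs; `0` returns the encoder unchanged.
#' @param batch_size Sequences per gradient step.
#' @param learning_rate AdamW learning rate.
#' @param seed Seed for masking and shuffling; identical seeds give
#'   identical final weights.
#' @return List with the pretrained `encoder`, the per-epoch mean
#'   cross-entropy `loss_curve`, and `accuracy` — the reconstruction
#'   accuracy on masked positions in the final epoch.
#' @export
masked_reconstruction_pretrain <- function(encoder, tokenized,
                                           mask_fraction = 0.15, epochs = 10L,
                                           batch_size = 16L,
                                           learning_rate = 1e-3, seed = 0L) {
  stopifnot(inherits(encoder, "clm_encoder"),
            mask_fraction > 0, mask_fraction < 1, length(tokenized) > 0)
  if (epochs == 0L) {
    return(list(encoder = encoder, loss_curve = numeric(0), accuracy = NA_real_))
  }
  cfg <- encoder$config
  V <- cfg$vocab_size; d <- cfg$model_dim
  mask_id <- 1L  # <MASK> is the second special token (0-based id 1)
  n <- length(tokenized)

  with_seed(seed, {
    proj <- list(W_out = rnorm_mat(d, V, 1 / sqrt(d)), b_out = rep(0, V))
    opt_e <- adamw_init(encoder$params)
    opt_p <- adamw_init(proj)
    loss_curve <- numeric(epochs)
    acc_num <- 0; acc_den <- 0

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      if (ep == epochs) { acc_num <- 0; acc_den <- 0 }
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        acc_e <- NULL; acc_pW <- NULL; acc_pb <- NULL
        for (i in idx) {
          tk <- tokenized[[i]]
          ids <- tk$ids
          skip <- if (tk$has_readout) 1L else integer(0)
          mpos <- mask_positions(length(ids), mask_fraction, skip)
          corrupted <- ids
          corrupted[mpos] <- mask_id
          fw <- encoder_forward(encoder, corrupted, keep_cache = TRUE)
          logits <- fw$latent %*% proj$W_out + brow(proj$b_out, length(ids))
          P <- softmax_vec_rows(logits)
          tgt <- ids[mpos] + 1L
          pt <- P[cbind(mpos, tgt)]
          losses[i] <- -mean(log(pmax(pt, 1e-12)))
          if (ep == epochs) {
            acc_num <- acc_num + sum(max.col(P[mpos, , drop = FALSE]) == tgt)
            acc_den <- acc_den + length(mpos)
          }
          dlogits <- matrix(0, length(ids), V)
          dlogits[mpos, ] <- P[mpos, , drop = FALSE] / length(mpos)
          dlogits[cbind(mpos, tgt)] <- dlogits[cbind(mpos, tgt)] - 1 / length(mpos)
          d_latent <- dlogits %*% t(proj$W_out)
          acc_pW <- if (is.null(acc_pW)) t(fw$latent) %*% dlogits else
            acc_pW + t(fw$latent) %*% dlogits
          acc_pb <- if (is.null(acc_pb)) colSums(dlogits) else acc_pb + colSums(dlogits)
          eb <- encoder_backward(encoder, fw$cache, d_latent)
          acc_e <- grads_add(acc_e, eb$grads)
        }
        k <- length(idx)
        se <- adamw_step(encoder$params, grads_scale(acc_e, 1 / k), opt_e,
                         lr = learning_rate,
                         skip_decay = .no_decay(names(encoder$params)))
        encoder$params <- se$params; opt_e <- se$state
        sp <- adamw_step(proj, list(W_out = acc_pW / k, b_out = acc_pb / k),
                         opt_p, lr = learning_rate, skip_decay = "b_out")
        proj <- sp$params; opt_p <- sp$state
      }
      loss_curve[ep] <- mean(losses)
    }
    list(encoder = encoder, loss_curve = loss_curve,
         accuracy = if (acc_den > 0) acc_num / acc_den else NA_real_)
  })
}

#' Majority-token baseline for masked reconstruction
#'
#' The accuracy achieved by always predicting the most frequent token of
#' the corpus; the floor any pretrained encoder must beat.
#' @param tokenized List of `tokenized_molecule`s with ids.
#' @return Frequency of the modal token among all tokens.
#' @export
majority_token_baseline <- function(tokenized) {
  ids <- unlist(lapply(tokenized, function(tk) {
    if (tk$has_readout) tk$ids[-1] else tk$ids
  }))
  max(table(ids)) / length(ids)
}
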