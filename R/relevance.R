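# Gradient-weighted attention relevance propagation for readout-token
# models, plus latent-feature masking and the four-way sign decomposition.
#
# Per layer, attention scores are multiplied elementwise by their gradients
# (taken of the raw scalar prediction, not the loss), clipped to their
# positive part, and averaged over heads:
#
#   Abar^l = E_h( (A^l_h (*) grad A^l_h)^+ )
#
# Relevance starts from the identity and accumulates through the layers
# with a skip-connection term:
#
#   R^0 = I;   R^l = R^{l-1} + Abar^l . R^{l-1}
#
# The attribution of each input token is the readout row of R^L with the
# readout self-entry removed. No row normalization is applied between
# layers: the update rule is implemented exactly as stated.

#' Gradient-weighted, positive-clipped head average
#'
#' @param A Attention scores, an H x T x T array (or T x T matrix for a
#'   single head).
#' @param gradA Gradients of the scalar prediction with respect to `A`,
#'   same shape.
#' @return A T x T matrix `mean_h((A * gradA)^+)` with all entries >= 0.
#' @export
head_average <- function(A, gradA) {
  if (is.matrix(A)) A <- array(A, c(1, dim(A)))
  if (is.matrix(gradA)) gradA <- array(gradA, c(1, dim(gradA)))
  if (!all(dim(A) == dim(gradA))) stopf("attention scores and gradients differ in shape")
  H <- dim(A)[1]
  P <- pmax(A * gradA, 0)
  M <- apply(P, c(2, 3), sum) / H
  if (dim(A)[2] == 1L) M <- matrix(M, 1, 1)
  M
}

#' Propagate relevance through the layers
#'
#' Applies the identity-initialized, skip-connection-aware update
#' `R^l = R^{l-1} + Abar^l %*% R^{l-1}` across all layers.
#'
#' @param abar_list List of L non-negative T x T matrices (layer 1 first).
#' @param keep_layers Return all intermediate `R^l` (default `FALSE`).
#' @return The final T x T relevance matrix `R^L`; with
#'   `keep_layers = TRUE`, a list of L+1 matrices starting at `R^0 = I`.
#' @examples
#' propagate(list(matrix(0, 2, 2)))  # identity preserved
#' @export
propagate <- function(abar_list, keep_layers = FALSE) {
  stopifnot(length(abar_list) >= 1)
  Tn <- nrow(abar_list[[1]])
  R <- diag(Tn)
  out <- list(R)
  for (l in seq_along(abar_list)) {
    Ab <- abar_list[[l]]
    if (!is.matrix(Ab) || any(dim(Ab) != Tn)) stopf("layer %d matrix is not %d x %d", l, Tn, Tn)
    if (any(Ab < -1e-12)) {
      stopf("negative entry in aggregated attention at layer %d; positive-part clipping was not applied", l)
    }
    R <- R + Ab %*% R
    if (keep_layers) out[[l + 1L]] <- R
  }
  if (keep_layers) out else R
}

# One traced forward pass and one reverse pass from the scalar prediction;
# returns prediction, per-layer A and dPred/dA, pooled features and head
# weights. Shared by attribute_readout() and masked_feature_attribution().
.trace_prediction <- function(model, tokenized, feature_mask = NULL) {
  fw <- model_forward(model, tokenized, feature_mask = feature_mask,
                      keep_cache = TRUE, trace = TRUE)
  bw <- model_backward(model, fw, dpred = 1)
  A <- lapply(fw$enc_fw$cache$layers, function(lc) lc$A)
  list(pred = fw$pred, A = A, gradA = bw$d_attn, z = fw$z,
       head_cache = fw$head_cache)
}

.relevance_from_trace <- function(tr, tokenized, model, method) {
  abar <- Map(head_average, tr$A, tr$gradA)
  R <- propagate(abar)
  row <- R[1, ]
  token_relevance <- row[-1]          # drop the readout self-entry
  names(token_relevance) <- tokenized$tokens[-1]
  new_attribution(tokenized, token_relevance, method = method,
                  model_tag = model$tag, base_value = NULL)
}

# Common container for all attribution methods: per-token values plus the
# per-atom projection via the token-to-atom map.
new_attribution <- function(tokenized, token_values, method, model_tag,
                            base_value = NULL, extra = list()) {
  amap <- tokenized$atom_map
  body_map <- if (tokenized$has_readout) amap[-1] else amap
  n_atoms <- sum(!is.na(amap))
  atom_values <- numeric(n_atoms)
  for (k in seq_along(token_values)) {
    a <- body_map[k]
    if (!is.na(a)) atom_values[a] <- atom_values[a] + token_values[k]
  }
  structure(c(list(smiles = tokenized$smiles,
                   tokens = if (tokenized$has_readout) tokenized$tokens[-1] else tokenized$tokens,
                   token_relevance = unname(token_values),
                   atom_relevance = atom_values,
                   method = method, model_tag = model_tag,
                   base_value = base_value), extra),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution [%s] for '%s': %d tokens, %d atoms>\n",
              x$method, x$smiles, length(x$token_relevance),
              length(x$atom_relevance)))
  invisible(x)
}

#' Attribute a prediction to input tokens via the readout row
#'
#' Runs one forward pass (capturing attention scores) and one reverse pass
#' from the scalar prediction (capturing attention gradients), aggregates
#' per layer with [head_average()], propagates with [propagate()] and
#' returns the readout row of the final relevance matrix. Requires a
#' readout-pooling model: average pooling distributes the prediction
#' gradient uniformly across tokens and admits no token-resolved
#' backpropagated attribution — use the Shapley module for such models.
#'
#' @param model A `clm_model` with `pool = "readout"`.
#' @param tokenized A `tokenized_molecule` with the readout token at
#'   position 1.
#' @return An `attribution` with non-negative `token_relevance` (length
#'   T - 1) and its per-atom projection; also carries `prediction`.
#' @export
attribute_readout <- function(model, tokenized) {
  stopifnot(inherits(model, "clm_model"), inherits(tokenized, "tokenized_molecule"))
  if (model$pool != "readout") {
    stopf("relevance attribution requires readout pooling; for average-pooling models use sampled_shapley()/exact_shapley()")
  }
  if (!tokenized$has_readout) stopf("tokenized molecule lacks the readout token")
  tr <- .trace_prediction(model, tokenized)
  out <- .relevance_from_trace(tr, tokenized, model, method = "readout_relevance")
  out$prediction <- tr$pred
  out
}

#' Classify latent features by activation and weight sign
#'
#' Each feature's contribution to a bias-free linear head is the product of
#' its (post-normalization) activation and its regression weight. The sign
#' pair divides features into four classes: `(+,+)` and `(-,-)` contribute
#' positively, `(+,-)` and `(-,+)` negatively; zero contributions are
#' neutral. The positive-class and negative-class contributions partition
#' the prediction.
#'
#' @param activations Numeric vector z (post-normalization features).
#' @param weights Numeric vector w of head weights, same length.
#' @return A data.frame with `feature`, `activation_sign`, `weight_sign`,
#'   `class`, `contribution`.
#' @export
classify_features <- function(activations, weights) {
  stopifnot(length(activations) == length(weights))
  contribution <- activations * weights
  sgn <- function(x) ifelse(x > 0, "+", ifelse(x < 0, "-", "0"))
  cls <- ifelse(contribution > 0,
                paste0("(", sgn(activations), ",", sgn(weights), ")"),
                ifelse(contribution < 0,
                       paste0("(", sgn(activations), ",", sgn(weights), ")"),
                       "neutral"))
  data.frame(feature = seq_along(weights),
             activation_sign = sgn(activations),
             weight_sign = sgn(weights),
             class = cls, contribution = contribution,
             stringsAsFactors = FALSE)
}

# Post-normalization feature vector fed to a bias-free linear head, and the
# head weights, for a given molecule.
linear_head_features <- function(model, tokenized) {
  if (model$head$config$kind != "linear" || model$head$config$linear_bias) {
    stopf("sign decomposition requires the bias-free linear head")
  }
  fw <- model_forward(model, tokenized)
  list(z = fw$head_cache$feat, w = model$head$params$W, pred = fw$pred)
}

#' Attribution under latent-feature masking
#'
#' Masks latent features of the bias-free linear head (after the pre-head
#' normalization) in both the forward and reverse passes, so that the
#' masked prediction is exactly the summed contribution of the kept
#' features, and computes the readout-relevance attribution under that
#' mask. Selecting the negative-contribution class probes the empirical
#' phenomenon that such features yield (near-)zero attributed relevance in
#' isolation, because positive-part clipping removes the sign-flipped
#' attention-gradient products.
#'
#' @param model A `clm_model` with readout pooling and a bias-free linear
#'   head.
#' @param tokenized A `tokenized_molecule`.
#' @param selector Either a single feature index, or `"positive"` /
#'   `"negative"` to keep the full positive- or negative-contribution
#'   class, or a logical/integer mask vector of kept features.
#' @return List with `prediction` (the masked prediction), `attribution`
#'   (an `attribution` object), `kept` (logical vector of kept features)
#'   and `classes` (the [classify_features()] table).
#' @export
masked_feature_attribution <- function(model, tokenized, selector) {
  stopifnot(inherits(model, "clm_model"))
  if (model$pool != "readout") stopf("latent-feature masking uses the readout attribution path")
  lf <- linear_head_features(model, tokenized)
  cls <- classify_features(lf$z, lf$w)
  d <- length(lf$w)
  kept <- if (is.character(selector)) {
    selector <- match.arg(selector, c("positive", "negative", "all"))
    switch(selector,
           positive = cls$contribution > 0,
           negative = cls$contribution < 0,
           all = rep(TRUE, d))
  } else if (is.logical(selector)) {
    stopifnot(length(selector) == d); selector
  } else {
    k <- rep(FALSE, d); k[as.integer(selector)] <- TRUE; k
  }
  mask <- as.numeric(kept)
  tr <- .trace_prediction(model, tokenized, feature_mask = mask)
  attribution <- .relevance_from_trace(tr, tokenized, model,
                                       method = "readout_relevance_masked")
  attribution$prediction <- tr$pred
  list(prediction = tr$pred, attribution = attribution, kept = kept,
       classes = cls)
}
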