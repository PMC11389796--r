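# Model-agnostic Shapley-value token attribution. Tokens are "players";
# masking a token substitutes the <MASK> id (never deletion, which usually
# breaks the string and changes its length). Works for any pooling
# strategy because only model predictions are queried. Exact enumeration
# serves as the small-T oracle; permutation sampling (with antithetic
# pairs) scales to longer strings.

#' Mask a set of token positions
#'
#' Replaces the tokens at the given positions by `<MASK>`; token count and
#' all other positions are unchanged, and the original object is not
#' modified.
#'
#' @param tokenized A `tokenized_molecule` with ids.
#' @param drop Integer vector of positions (1-based) to mask; must not
#'   include the readout position.
#' @return A new `tokenized_molecule` with masked tokens/ids.
#' @export
mask_tokens <- function(tokenized, drop) {
  stopifnot(inherits(tokenized, "tokenized_molecule"))
  drop <- as.integer(drop)
  if (tokenized$has_readout && 1L %in% drop) {
    stopf("the readout token cannot be masked")
  }
  if (any(drop < 1L | drop > length(tokenized$tokens))) stopf("mask position out of range")
  out <- tokenized
  sp <- special_tokens()
  out$tokens[drop] <- sp[["MASK"]]
  if (!is.null(out$ids)) out$ids[drop] <- 1L  # <MASK> id
  out$atom_map[drop] <- NA_integer_
  out
}

# Memoized coalition value function: v(S) = model prediction with every
# maskable token NOT in S masked. Coalitions are keyed by bitmask string.
make_value_fn <- function(model, tokenized) {
  maskable <- maskable_positions(tokenized)
  cache <- new.env(parent = emptyenv())
  function(keep_flags) {  # logical vector over maskable positions
    key <- paste(as.integer(keep_flags), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    masked <- mask_tokens(tokenized, maskable[!keep_flags])
    v <- model_forward(model, masked)$pred
    cache[[key]] <- v
    v
  }
}

# Exact Shapley values of an m-player game by subset enumeration.
shapley_enumerate <- function(value_fn, m) {
  phi <- numeric(m)
  # precompute all 2^m coalition values
  n_sub <- 2^m
  vals <- numeric(n_sub)
  sizes <- integer(n_sub)
  for (s in 0:(n_sub - 1L)) {
    flags <- as.logical(bitwAnd(s, 2^(0:(m - 1L))))
    vals[s + 1L] <- value_fn(flags)
    sizes[s + 1L] <- sum(flags)
  }
  wts <- vapply(0:(m - 1L), function(k) {
    exp(lfactorial(k) + lfactorial(m - k - 1L) - lfactorial(m))
  }, numeric(1))
  for (t in seq_len(m)) {
    bit <- 2^(t - 1L)
    for (s in 0:(n_sub - 1L)) {
      if (bitwAnd(s, bit) == 0) {
        k <- sizes[s + 1L]
        phi[t] <- phi[t] + wts[k + 1L] * (vals[s + bit + 1L] - vals[s + 1L])
      }
    }
  }
  list(phi = phi, base = vals[1L], full = vals[n_sub])
}

#' Exact Shapley values of a constructed coalition game
#'
#' Enumeration oracle over all `2^m` coalitions with standard Shapley
#' weights; useful for testing axioms on hand-built games.
#'
#' @param value_fn Function taking a logical keep-vector of length
#'   `n_players` and returning the coalition value.
#' @param n_players Number of players (kept small; cost is `2^m`).
#' @return List with `phi`, `base` (= v(empty)) and `full` (= v(all)).
#' @examples
#' v <- function(k) c(0, 1, 2, 4)[1 + k[1] + 2 * k[2]]
#' shapley_from_game(v, 2)$phi  # 1.5, 2.5
#' @export
shapley_from_game <- function(value_fn, n_players) {
  stopifnot(n_players >= 1)
  shapley_enumerate(value_fn, as.integer(n_players))
}

.shapley_result <- function(tokenized, phi, base, full, mode, n_samples = NA,
                            seed = NA, se = NULL) {
  maskable <- maskable_positions(tokenized)
  token_values <- numeric(length(tokenized$tokens) - as.integer(tokenized$has_readout))
  body_idx <- if (tokenized$has_readout) maskable - 1L else maskable
  token_values[body_idx] <- phi
  att <- new_attribution(tokenized, token_values, method = "shapley",
                         model_tag = NULL, base_value = base,
                         extra = list(full_value = full, mode = mode,
                                      n_samples = n_samples, seed = seed,
                                      standard_error = se))
  att
}

#' Exact Shapley token attribution
#'
#' Enumerates all `2^m` coalitions of maskable tokens (m = token count
#' excluding the readout token). The efficiency axiom
#' `sum(phi) = v(full) - v(empty)` holds by construction.
#'
#' @param model A `clm_model` (any pooling strategy).
#' @param tokenized A `tokenized_molecule` with ids.
#' @param max_T Refuse enumeration beyond this many maskable tokens
#'   (default 10); use [sampled_shapley()] instead.
#' @return An `attribution` with signed `token_relevance` (the Shapley
#'   values), `base_value` = v(empty: all tokens masked) and `full_value`.
#' @export
exact_shapley <- function(model, tokenized, max_T = 10L) {
  stopifnot(inherits(model, "clm_model"), inherits(tokenized, "tokenized_molecule"))
  m <- length(maskable_positions(tokenized))
  if (m > max_T) {
    stopf("%d maskable tokens exceed max_T = %d; use sampled_shapley()", m, max_T)
  }
  vf <- make_value_fn(model, tokenized)
  res <- shapley_enumerate(vf, m)
  out <- .shapley_result(tokenized, res$phi, res$base, res$full, mode = "exact")
  out$model_tag <- model$tag
  out
}

#' Sampled Shapley token attribution (permutation estimator)
#'
#' Draws random permutations of the maskable tokens and accumulates
#' marginal contributions along each insertion order; each sampled
#' permutation is paired with its reverse (antithetic pairing) for variance
#' reduction. Coalition values are memoized, so repeated coalitions cost
#' nothing. Deterministic under a fixed seed.
#'
#' @param model A `clm_model`.
#' @param tokenized A `tokenized_molecule` with ids.
#' @param n_samples Number of permutations (>= 1); odd values are rounded
#'   up to the next even number so antithetic pairs stay complete.
#' @param seed RNG seed.
#' @return An `attribution` with signed Shapley estimates, per-token
#'   `standard_error`, `base_value` and `full_value`.
#' @export
sampled_shapley <- function(model, tokenized, n_samples = 200L, seed = 0L) {
  stopifnot(inherits(model, "clm_model"), inherits(tokenized, "tokenized_molecule"),
            n_samples >= 1)
  m <- length(maskable_positions(tokenized))
  vf <- make_value_fn(model, tokenized)
  n_perm <- as.integer(2 * ceiling(n_samples / 2))
  contrib <- matrix(0, n_perm, m)
  with_seed(seed, {
    for (p in seq_len(n_perm / 2L)) {
      perm <- sample.int(m)
      for (half in 1:2) {
        ord <- if (half == 1) perm else rev(perm)
        flags <- rep(FALSE, m)
        v_prev <- vf(flags)
        for (t in ord) {
          flags[t] <- TRUE
          v_new <- vf(flags)
          contrib[2L * (p - 1L) + half, t] <- v_new - v_prev
          v_prev <- v_new
        }
      }
    }
  })
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_perm)
  base <- vf(rep(FALSE, m)); full <- vf(rep(TRUE, m))
  out <- .shapley_result(tokenized, phi, base, full, mode = "sampled",
                         n_samples = n_perm, seed = seed, se = se)
  out$model_tag <- model$tag
  out
}
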