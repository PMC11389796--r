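# Regression heads, frozen vs fine-tuned training, evaluation metrics and
# fingerprint baseline regressors.
#
# The linear head is deliberately bias-free with a pre-head layer
# normalization whose gain is learnable but whose shift is fixed at zero:
# the prediction is then exactly a weighted sum of post-normalization
# features, which makes the latent-feature sign decomposition an identity
# rather than an approximation.

#' Regression head configuration
#'
#' @param kind `"linear"` (single d -> 1 projection, no bias) or
#'   `"hierarchical"` (three projections d -> hidden -> hidden -> 1 with
#'   interleaved ReLU).
#' @param input_dim Feature dimensionality d.
#' @param hidden_dim Hidden width of the hierarchical head (default 64).
#' @param pre_normalization Apply layer normalization before the first
#'   projection (default `TRUE`).
#' @param linear_bias Include a bias in the linear head (default `FALSE`).
#' @return A `head_config`.
#' @export
head_config <- function(kind = c("linear", "hierarchical"), input_dim,
                        hidden_dim = 64L, pre_normalization = TRUE,
                        linear_bias = FALSE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 pre_normalization = pre_normalization,
                 linear_bias = linear_bias),
            class = "head_config")
}

#' Initialize a regression head
#' @param config A `head_config`.
#' @param seed Initialization seed.
#' @return A `clm_head`: list with `config` and flat named `params`.
#' @export
init_head <- function(config, seed = 0L) {
  stopifnot(inherits(config, "head_config"))
  d <- config$input_dim; h <- config$hidden_dim
  with_seed(seed, {
    p <- list()
    if (config$pre_normalization) {
      p$ln_g <- rep(1, d)
      if (config$kind == "hierarchical") p$ln_b <- rep(0, d)
    }
    if (config$kind == "linear") {
      p$W <- stats::rnorm(d, 0, 1 / sqrt(d))
      if (config$linear_bias) p$b <- 0
    } else {
      p$W1 <- rnorm_mat(d, h, 1 / sqrt(d)); p$b1 <- rep(0, h)
      p$W2 <- rnorm_mat(h, h, 1 / sqrt(h)); p$b2 <- rep(0, h)
      p$W3 <- stats::rnorm(h, 0, 1 / sqrt(h)); p$b3 <- 0
    }
    structure(list(config = config, params = p), class = "clm_head")
  })
}

# vector layer normalization (population variance, eps as in the encoder);
# shift optional
vln_fwd <- function(z, g, b = NULL) {
  mu <- mean(z); zc <- z - mu
  sd_ <- sqrt(mean(zc * zc) + .LN_EPS)
  zhat <- zc / sd_
  y <- zhat * g
  if (!is.null(b)) y <- y + b
  list(y = y, zhat = zhat, sd = sd_)
}

vln_bwd <- function(dy, cache, g) {
  dzhat <- dy * g
  dz <- (dzhat - mean(dzhat) - cache$zhat * mean(dzhat * cache$zhat)) / cache$sd
  list(dz = dz, dg = dy * cache$zhat, db = dy)
}

head_forward <- function(head, z, feature_mask = NULL) {
  cfg <- head$config; p <- head$params
  if (length(z) != cfg$input_dim) {
    stopf("feature length %d does not match head input_dim %d", length(z), cfg$input_dim)
  }
  cache <- list(z = z, mask = feature_mask)
  if (cfg$pre_normalization) {
    ln <- vln_fwd(z, p$ln_g, if (cfg$kind == "hierarchical") p$ln_b else NULL)
    feat <- ln$y
    cache$ln <- ln
  } else {
    feat <- z
  }
  cache$feat <- feat
  if (cfg$kind == "linear") {
    fm <- if (is.null(feature_mask)) feat else feat * feature_mask
    cache$fm <- fm
    pred <- sum(p$W * fm) + if (cfg$linear_bias) p$b else 0
  } else {
    if (!is.null(feature_mask)) {
      stopf("latent-feature masking requires the linear head; the hierarchical head admits no exact decomposition")
    }
    h1p <- as.vector(feat %*% p$W1) + p$b1; h1 <- pmax(h1p, 0)
    h2p <- as.vector(h1 %*% p$W2) + p$b2; h2 <- pmax(h2p, 0)
    pred <- sum(p$W3 * h2) + p$b3
    cache$h1p <- h1p; cache$h1 <- h1; cache$h2p <- h2p; cache$h2 <- h2
  }
  list(pred = pred, cache = cache)
}

head_backward <- function(head, cache, dpred = 1) {
  cfg <- head$config; p <- head$params
  g <- list()
  if (cfg$kind == "linear") {
    g$W <- dpred * cache$fm
    if (cfg$linear_bias) g$b <- dpred
    dfm <- dpred * p$W
    dfeat <- if (is.null(cache$mask)) dfm else dfm * cache$mask
  } else {
    g$W3 <- dpred * cache$h2; g$b3 <- dpred
    dh2 <- (dpred * p$W3) * (cache$h2p > 0)
    g$W2 <- outer(cache$h1, dh2); g$b2 <- dh2
    dh1 <- as.vector(p$W2 %*% dh2) * (cache$h1p > 0)
    g$W1 <- outer(cache$feat, dh1); g$b1 <- dh1
    dfeat <- as.vector(p$W1 %*% dh1)
  }
  if (cfg$pre_normalization) {
    lb <- vln_bwd(dfeat, cache$ln, p$ln_g)
    g$ln_g <- lb$dg
    if (cfg$kind == "hierarchical") g$ln_b <- lb$db
    dz <- lb$dz
  } else {
    dz <- dfeat
  }
  list(grads = g, dz = dz)
}

#' Apply a regression head to a feature vector
#'
#' @param head A `clm_head`.
#' @param features Numeric vector of length `input_dim`.
#' @return The scalar prediction.
#' @examples
#' h <- init_head(head_config("linear", 2, pre_normalization = FALSE))
#' h$params$W <- c(0.5, -1)
#' head_predict(h, c(2, 3))  # -2
#' @export
head_predict <- function(head, features) {
  head_forward(head, features)$pred
}

#' Assemble an encoder, head and pooling strategy into a model
#'
#' @param encoder A `clm_encoder`.
#' @param head A `clm_head` whose `input_dim` equals the encoder's
#'   `model_dim`.
#' @param pool `"readout"` or `"avg"` pooling.
#' @param vocab The `clm_vocabulary` the encoder was built for.
#' @param tag Optional model label used in attribution outputs.
#' @return A `clm_model`.
#' @export
build_model <- function(encoder, head, pool = c("readout", "avg"), vocab,
                        tag = NULL) {
  pool <- match.arg(pool)
  stopifnot(inherits(encoder, "clm_encoder"), inherits(head, "clm_head"))
  if (head$config$input_dim != encoder$config$model_dim) {
    stopf("head input_dim (%d) != encoder model_dim (%d)",
          head$config$input_dim, encoder$config$model_dim)
  }
  structure(list(encoder = encoder, head = head, pool = pool, vocab = vocab,
                 tag = tag %||% paste0("clm-", pool, "-", head$config$kind)),
            class = "clm_model")
}

#' @export
print.clm_model <- function(x, ...) {
  cat(sprintf("<clm_model '%s': %s pooling, %s head>\n", x$tag, x$pool,
              x$head$config$kind))
  invisible(x)
}

model_forward <- function(model, tokenized, feature_mask = NULL,
                          keep_cache = FALSE, trace = FALSE) {
  fw <- encoder_forward(model$encoder, tokenized$ids, trace = trace,
                        keep_cache = keep_cache)
  z <- pool(fw$latent, model$pool, has_readout = tokenized$has_readout)
  hf <- head_forward(model$head, z, feature_mask = feature_mask)
  list(pred = hf$pred, enc_fw = fw, z = z, head_cache = hf$cache,
       Tn = length(tokenized$ids))
}

model_backward <- function(model, fw, dpred = 1) {
  hb <- head_backward(model$head, fw$head_cache, dpred)
  dL <- pool_bwd(hb$dz, fw$Tn, model$pool)
  eb <- encoder_backward(model$encoder, fw$enc_fw$cache, dL)
  list(enc_grads = eb$grads, d_attn = eb$d_attn, head_grads = hb$grads)
}

#' Predict property values for molecules
#'
#' @param object A `clm_model`.
#' @param newdata Character vector of SMILES or a list of
#'   `tokenized_molecule`s.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.clm_model <- function(object, newdata, ...) {
  toks <- if (is.character(newdata)) {
    lapply(newdata, tokenize, vocab = object$vocab,
           prepend_readout = object$pool == "readout")
  } else if (inherits(newdata, "tokenized_molecule")) {
    list(newdata)
  } else {
    newdata
  }
  vapply(toks, function(tk) model_forward(object, tk)$pred, numeric(1))
}

#' Training configuration
#'
#' @param mode `"frozen"` (only the head is trained; encoder weights remain
#'   bit-identical) or `"finetune"` (encoder and head are trained jointly).
#' @param epochs Number of passes over the training set (default 30).
#' @param batch_size Minibatch size for gradient averaging (default 48).
#' @param learning_rate AdamW learning rate (default 3e-4).
#' @param weight_decay Decoupled weight decay (default 0.01).
#' @param huber_delta Transition point of the Huber criterion (default 1).
#' @param seed Seed controlling shuffling (and nothing else).
#' @return A `train_config`.
#' @export
train_config <- function(mode = c("finetune", "frozen"), epochs = 30L,
                         batch_size = 48L, learning_rate = 3e-4,
                         weight_decay = 0.01, huber_delta = 1, seed = 0L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 huber_delta = huber_delta, seed = as.integer(seed)),
            class = "train_config")
}

.no_decay <- function(nms) nms[grepl("ln|^b$|\\.b[0-9]|^b[0-9]", nms)]

#' Train a model on tokenized molecules
#'
#' Frozen mode pools each molecule once through the fixed encoder and then
#' trains only the head on the cached features; fine-tuning backpropagates
#' the Huber loss through head and encoder jointly. Training is
#' deterministic given `cfg$seed`.
#'
#' @param model A `clm_model`.
#' @param tokenized List of `tokenized_molecule`s (with ids).
#' @param y Numeric targets aligned with `tokenized`.
#' @param cfg A `train_config`.
#' @return List with the trained `model` and `loss_curve` (mean training
#'   Huber loss per epoch; length 0 when `epochs = 0`).
#' @export
train_model <- function(model, tokenized, y, cfg = train_config()) {
  stopifnot(inherits(model, "clm_model"), inherits(cfg, "train_config"),
            length(tokenized) == length(y), length(y) > 0)
  if (cfg$epochs == 0L) return(list(model = model, loss_curve = numeric(0)))
  n <- length(y)
  with_seed(cfg$seed, {
    loss_curve <- numeric(cfg$epochs)
    if (cfg$mode == "frozen") {
      Z <- t(vapply(tokenized, function(tk) {
        fw <- encoder_forward(model$encoder, tk$ids)
        pool(fw$latent, model$pool, has_readout = tk$has_readout)
      }, numeric(model$encoder$config$model_dim)))
      opt <- adamw_init(model$head$params)
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        losses <- numeric(n)
        for (start in seq(1, n, by = cfg$batch_size)) {
          idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
          acc <- NULL
          for (i in idx) {
            hf <- head_forward(model$head, Z[i, ])
            losses[i] <- huber_loss(hf$pred, y[i], cfg$huber_delta)
            hb <- head_backward(model$head, hf$cache,
                                huber_grad(hf$pred, y[i], cfg$huber_delta))
            acc <- grads_add(acc, hb$grads)
          }
          st <- adamw_step(model$head$params, grads_scale(acc, 1 / length(idx)),
                          opt, lr = cfg$learning_rate,
                          weight_decay = cfg$weight_decay,
                          skip_decay = .no_decay(names(model$head$params)))
          model$head$params <- st$params; opt <- st$state
        }
        loss_curve[ep] <- mean(losses)
      }
    } else {
      opt_e <- adamw_init(model$encoder$params)
      opt_h <- adamw_init(model$head$params)
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        losses <- numeric(n)
        for (start in seq(1, n, by = cfg$batch_size)) {
          idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
          acc_e <- NULL; acc_h <- NULL
          for (i in idx) {
            fw <- model_forward(model, tokenized[[i]], keep_cache = TRUE)
            losses[i] <- huber_loss(fw$pred, y[i], cfg$huber_delta)
            bw <- model_backward(model, fw,
                                 huber_grad(fw$pred, y[i], cfg$huber_delta))
            acc_e <- grads_add(acc_e, bw$enc_grads)
            acc_h <- grads_add(acc_h, bw$head_grads)
          }
          se <- adamw_step(model$encoder$params, grads_scale(acc_e, 1 / length(idx)),
                           opt_e, lr = cfg$learning_rate,
                           weight_decay = cfg$weight_decay,
                           skip_decay = .no_decay(names(model$encoder$params)))
          model$encoder$params <- se$params; opt_e <- se$state
          sh <- adamw_step(model$head$params, grads_scale(acc_h, 1 / length(idx)),
                           opt_h, lr = cfg$learning_rate,
                           weight_decay = cfg$weight_decay,
                           skip_decay = .no_decay(names(model$head$params)))
          model$head$params <- sh$params; opt_h <- sh$state
        }
        loss_curve[ep] <- mean(losses)
        if (!is.finite(loss_curve[ep])) {
          stopf("non-finite training loss at epoch %d; aborting", ep)
        }
      }
    }
    list(model = model, loss_curve = loss_curve)
  })
}

#' Evaluation metrics from predictions and targets
#'
#' @param predictions,targets Aligned numeric vectors (non-empty).
#' @return An `eval_report`: list with `MAE`, `RMSE`, `predictions`,
#'   `residuals`. RMSE >= MAE always holds (power-mean inequality).
#' @examples
#' eval_report(c(1, 1), c(0, 2))  # MAE 1, RMSE 1
#' @export
eval_report <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets), length(targets) > 0)
  r <- predictions - targets
  structure(list(MAE = mean(abs(r)), RMSE = sqrt(mean(r * r)),
                 predictions = predictions, residuals = r),
            class = "eval_report")
}

#' Evaluate a model on a split
#' @param model A `clm_model`.
#' @param tokenized List of `tokenized_molecule`s.
#' @param y Numeric targets.
#' @return An [eval_report()].
#' @export
evaluate_model <- function(model, tokenized, y) {
  stopifnot(length(tokenized) == length(y), length(y) > 0)
  eval_report(predict(model, tokenized), y)
}

#' Fit baseline regressors on fingerprint vectors
#'
#' @param fingerprints Numeric matrix (molecules x bits).
#' @param targets Numeric vector aligned with rows.
#' @param model_kind One of `"linear_head"` (bias-free minimum-norm least
#'   squares; the weight vector used for bit-to-atom attribution),
#'   `"hierarchical_head"` (small MLP trained with AdamW/Huber), `"svr"`
#'   (radial-basis support vector regression) or `"rf"` (random forest).
#' @param seed Seed for the stochastic fitters.
#' @param epochs,learning_rate Training settings for `"hierarchical_head"`.
#' @param ntree Trees for `"rf"` (default 100).
#' @return An `fp_baseline` with a `predict` method; for `"linear_head"`
#'   the per-bit weights are in `$weights`.
#' @export
fit_fingerprint_baselines <- function(fingerprints, targets,
                                      model_kind = c("linear_head", "hierarchical_head", "svr", "rf"),
                                      seed = 0L, epochs = 200L,
                                      learning_rate = 1e-2, ntree = 100L) {
  model_kind <- match.arg(model_kind)
  X <- as.matrix(fingerprints)
  stopifnot(nrow(X) == length(targets))
  if (stats::var(targets) == 0) {
    warning("targets are constant; fit proceeds but is degenerate", call. = FALSE)
  }
  fit <- switch(model_kind,
    linear_head = {
      sv <- svd(X)
      pos <- sv$d > max(sv$d[1], 1) * 1e-10
      w <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% targets) / sv$d[pos])
      list(weights = as.vector(w))
    },
    hierarchical_head = {
      cfg <- head_config("hierarchical", ncol(X), hidden_dim = 32L,
                         pre_normalization = FALSE)
      head <- init_head(cfg, seed = seed)
      with_seed(seed, {
        opt <- adamw_init(head$params)
        for (ep in seq_len(epochs)) {
          acc <- NULL;
          for (i in seq_len(nrow(X))) {
            hf <- head_forward(head, X[i, ])
            hb <- head_backward(head, hf$cache, huber_grad(hf$pred, targets[i]))
            acc <- grads_add(acc, hb$grads)
          }
          st <- adamw_step(head$params, grads_scale(acc, 1 / nrow(X)), opt,
                           lr = learning_rate,
                           skip_decay = .no_decay(names(head$params)))
          head$params <- st$params; opt <- st$state
        }
      })
      list(head = head)
    },
    svr = list(svm = e1071::svm(X, targets, kernel = "radial")),
    rf = with_seed(seed,
      list(rf = randomForest::randomForest(X, targets, ntree = ntree)))
  )
  structure(c(fit, list(kind = model_kind)), class = "fp_baseline")
}

#' @export
predict.fp_baseline <- function(object, newx, ...) {
  X <- as.matrix(newx)
  switch(object$kind,
    linear_head = as.vector(X %*% object$weights),
    hierarchical_head = vapply(seq_len(nrow(X)), function(i) {
      head_forward(object$head, X[i, ])$pred
    }, numeric(1)),
    svr = as.vector(stats::predict(object$svm, X)),
    rf = as.vector(stats::predict(object$rf, X))
  )
}
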