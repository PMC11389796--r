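test_that("head_predict matches closed forms", {
  h <- init_head(head_config("linear", 2, pre_normalization = FALSE))
  h$params$W <- c(0.5, -1)
  expect_equal(head_predict(h, c(2, 3)), -2)          # 0.5*2 - 1*3

  # zero final weights silence the hierarchical head
  hh <- init_head(head_config("hierarchical", 4, hidden_dim = 8,
                              pre_normalization = FALSE), seed = 2)
  hh$params$W3 <- rep(0, 8); hh$params$b3 <- 0
  expect_equal(head_predict(hh, rnorm(4)), 0)

  # constant features normalize to ~0, hence bias-free linear pred ~0
  hl <- init_head(head_config("linear", 6), seed = 3)
  expect_equal(head_predict(hl, rep(2.5, 6)), 0, tolerance = 1e-9)

  expect_error(head_predict(h, c(1, 2, 3)), "input_dim")
})

test_that("eval_report computes MAE/RMSE and their ordering", {
  r <- eval_report(c(1, 1), c(0, 2))
  expect_equal(r$MAE, 1); expect_equal(r$RMSE, 1)
  r <- eval_report(c(1, -3), c(0, 0))     # residuals 1, -3
  expect_equal(r$MAE, 2)
  expect_equal(r$RMSE, sqrt(5))
  expect_equal(r$residuals, c(1, -3))
  # property: RMSE >= MAE on random residual vectors
  for (i in 1:25) {
    p <- rnorm(10); t0 <- rnorm(10)
    rr <- eval_report(p, t0)
    expect_gte(rr$RMSE, rr$MAE - 1e-12)
  }
  expect_error(eval_report(numeric(0), numeric(0)))
})

test_that("frozen training leaves the encoder bit-identical and learns", {
  recs <- generate_molecules(80, seed = 13)
  v <- build_vocabulary(recs$smiles)
  toks <- tokenize_set(recs$smiles, v, prepend_readout = TRUE)
  enc <- init_encoder(encoder_config(2, 2, 16, 32, 64, length(v), seed = 4))
  m <- build_model(enc, init_head(head_config("linear", 16), seed = 5),
                   pool = "readout", vocab = v)

  # epochs = 0 is the identity on the whole model
  out0 <- train_model(m, toks, recs$y, train_config("frozen", epochs = 0))
  expect_identical(serialize(out0$model, NULL), serialize(m, NULL))
  expect_length(out0$loss_curve, 0L)

  out <- train_model(m, toks, recs$y,
                     train_config("frozen", epochs = 8, seed = 1))
  expect_identical(serialize(out$model$encoder, NULL), serialize(m$encoder, NULL))
  expect_false(identical(out$model$head$params$W, m$head$params$W))
  expect_lt(tail(out$loss_curve, 1), out$loss_curve[1])
  # determinism under the training seed
  out2 <- train_model(m, toks, recs$y,
                      train_config("frozen", epochs = 8, seed = 1))
  expect_identical(out$model$head$params, out2$model$head$params)
})

test_that("fine-tuning moves encoder weights and reduces the loss", {
  recs <- generate_molecules(60, seed = 14)
  v <- build_vocabulary(recs$smiles)
  toks <- tokenize_set(recs$smiles, v, prepend_readout = TRUE)
  enc <- init_encoder(encoder_config(2, 2, 16, 32, 64, length(v), seed = 6))
  m <- build_model(enc, init_head(head_config("linear", 16), seed = 7),
                   pool = "readout", vocab = v)
  out <- train_model(m, toks, recs$y,
                     train_config("finetune", epochs = 6, seed = 2))
  expect_false(identical(out$model$encoder$params$tok_emb, enc$params$tok_emb))
  expect_lt(tail(out$loss_curve, 1), out$loss_curve[1])
  rep_ <- evaluate_model(out$model, toks, recs$y)
  expect_lt(rep_$MAE, evaluate_model(m, toks, recs$y)$MAE)
})

test_that("fingerprint baselines fit their respective families", {
  cfg <- fingerprint_config(n_bits = 128)
  recs <- generate_molecules(60, seed = 15)
  X <- fingerprint_matrix(recs$smiles, cfg)

  # linear_head recovers an exactly linear target in the bit space
  w_true <- rep(0, ncol(X)); w_true[c(3, 17, 40)] <- c(1, -2, 0.5)
  y_lin <- as.vector(X %*% w_true)
  fit <- fit_fingerprint_baselines(X, y_lin, "linear_head")
  expect_equal(predict(fit, X), y_lin, tolerance = 1e-8)

  # svr predictions stay near targets that sit inside the epsilon tube
  # constant (never-set) bits draw a scaling warning from the SVR backend
  fit_svr <- suppressWarnings(fit_fingerprint_baselines(X, recs$y, "svr"))
  expect_lt(mean(abs(predict(fit_svr, X) - recs$y)), stats::sd(recs$y))

  # rf reproduces a single training point exactly-ish and is seeded
  fit_rf <- fit_fingerprint_baselines(X, recs$y, "rf", seed = 9)
  fit_rf2 <- fit_fingerprint_baselines(X, recs$y, "rf", seed = 9)
  expect_identical(predict(fit_rf, X), predict(fit_rf2, X))

  fit_h <- fit_fingerprint_baselines(X, recs$y, "hierarchical_head",
                                     seed = 9, epochs = 50)
  expect_lt(mean(abs(predict(fit_h, X) - recs$y)),
            mean(abs(mean(recs$y) - recs$y)))

  expect_warning(fit_fingerprint_baselines(X, rep(1, nrow(X)), "linear_head"),
                 "constant")
})
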