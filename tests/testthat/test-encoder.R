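test_that("attention scores follow the scaled-softmax contract", {
  # equal raw scores -> uniform rows
  A <- attention_scores(matrix(0, 3, 2), matrix(rnorm(6), 3, 2))
  expect_equal(A, matrix(1 / 3, 3, 3))

  # closed-form check: raw score row (ln 2, 0) -> (2/3, 1/3)
  Q <- matrix(c(log(2), 0), 1, 2)          # d_k = 2, scale sqrt(2)
  K <- rbind(c(sqrt(2), 0), c(0, 0))       # Q K^T / sqrt(2) = (ln2, 0)
  A <- attention_scores(rbind(Q, c(0, 0)), K)
  expect_equal(A[1, ], c(2 / 3, 1 / 3), tolerance = 1e-12)

  # PAD column excluded before normalization
  A <- attention_scores(matrix(rnorm(6), 3, 2), matrix(rnorm(6), 3, 2),
                        pad_mask = c(TRUE, TRUE, FALSE))
  expect_equal(A[, 3], rep(0, 3))
  expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-9)
  expect_error(attention_scores(matrix(0, 2, 2), matrix(0, 2, 2),
                                pad_mask = c(FALSE, FALSE)), "padded")
})

test_that("encode returns finite T x d latents and traces attention", {
  s <- tiny_setup()
  tk <- tokenize("CCNO", vocab = s$vocab, prepend_readout = TRUE)
  lat <- encode(s$encoder, tk, trace = TRUE)
  expect_equal(dim(lat$matrix), c(5L, 16L))
  expect_true(all(is.finite(lat$matrix)))
  expect_null(lat$grads)                      # no reverse pass yet
  expect_length(lat$attn, 2L)
  expect_equal(dim(lat$attn[[1]]), c(2L, 5L, 5L))
  # determinism
  lat2 <- encode(s$encoder, tk, trace = TRUE)
  expect_identical(lat$matrix, lat2$matrix)
  # max_tokens guard
  long <- paste(rep("C", 60), collapse = "")
  expect_error(encode(s$encoder, tokenize(long, vocab = s$vocab)), "max_tokens")
})

test_that("captured attention rows are stochastic for random inputs", {
  s <- tiny_setup()
  recs <- generate_molecules(20, seed = 3)
  v <- build_vocabulary(recs$smiles)
  enc <- init_encoder(encoder_config(2, 2, 16, 32, 64, length(v), seed = 1))
  for (sm in recs$smiles) {
    tk <- tokenize(sm, vocab = v, prepend_readout = TRUE)
    lat <- encode(enc, tk, trace = TRUE)
    for (Al in lat$attn) {
      for (h in seq_len(dim(Al)[1])) {
        expect_equal(rowSums(Al[h, , ]), rep(1, dim(Al)[2]), tolerance = 1e-6)
        expect_true(all(Al[h, , ] >= 0))
      }
    }
  }
})

test_that("pooling strategies and PAD exclusion", {
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(pool(X, "avg"), c(2, 3))
  expect_equal(pool(X, "readout"), c(1, 2))
  expect_equal(pool(rbind(X, c(9, 9)), "avg",
                    pad_mask = c(TRUE, TRUE, FALSE)), c(2, 3))
  expect_error(pool(X, "readout", has_readout = FALSE), "readout")
})

test_that("gradients match central finite differences through the stack", {
  s <- tiny_setup(d = 8L, L = 2L, H = 2L, seed = 3)
  m <- tiny_model(d = 8L, setup = s)
  tk <- tokenize("CC(N)O", vocab = s$vocab, prepend_readout = TRUE)
  fw <- clmexplain:::model_forward(m, tk, keep_cache = TRUE)
  bw <- clmexplain:::model_backward(m, fw, dpred = 1)
  eps <- 1e-6
  set.seed(1)
  for (nm in c("tok_emb", "pos_emb", "L1.Wq", "L1.Wk", "L1.Wv", "L1.Wo",
               "L1.ln1_g", "L2.W1", "L2.W2", "L2.ln2_b")) {
    P <- m$encoder$params[[nm]]
    for (ii in sample(length(P), 3)) {
      m2 <- m
      m2$encoder$params[[nm]][ii] <- P[ii] + eps
      p1 <- clmexplain:::model_forward(m2, tk)$pred
      m2$encoder$params[[nm]][ii] <- P[ii] - eps
      p0 <- clmexplain:::model_forward(m2, tk)$pred
      expect_equal(bw$enc_grads[[nm]][ii], (p1 - p0) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("masked-reconstruction pretraining learns above the majority baseline", {
  recs <- generate_molecules(120, seed = 21)
  v <- build_vocabulary(recs$smiles)
  toks <- tokenize_set(recs$smiles, v, prepend_readout = FALSE)
  enc <- init_encoder(encoder_config(2, 2, 24, 48, 64, length(v), seed = 21))
  # epochs = 0 leaves weights untouched
  same <- masked_reconstruction_pretrain(enc, toks, epochs = 0)
  expect_identical(same$encoder$params, enc$params)
  pre <- masked_reconstruction_pretrain(enc, toks, mask_fraction = 0.15,
                                        epochs = 4, seed = 21)
  expect_gt(pre$accuracy, majority_token_baseline(toks))
  # same seed twice -> bit-identical weights
  pre2 <- masked_reconstruction_pretrain(enc, toks, mask_fraction = 0.15,
                                         epochs = 4, seed = 21)
  expect_identical(pre$encoder$params, pre2$encoder$params)
})
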