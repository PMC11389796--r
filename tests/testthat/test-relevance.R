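test_that("head_average applies the positive-clipped elementwise product", {
  A <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  G <- rbind(c(1, -1), c(2, 0))
  expect_equal(head_average(A, G), rbind(c(0.6, 0), c(1.0, 0)))

  # zero gradients give a zero matrix
  expect_equal(head_average(A, matrix(0, 2, 2)), matrix(0, 2, 2))

  # head 2 products negate head 1's non-negative products: only head 1
  # survives the clipping, so the average is head1 products / 2
  Gp <- abs(G)
  A2 <- array(0, c(2, 2, 2)); G2 <- array(0, c(2, 2, 2))
  A2[1, , ] <- A;  G2[1, , ] <- Gp
  A2[2, , ] <- A;  G2[2, , ] <- -Gp
  expect_equal(head_average(A2, G2), pmax(A * Gp, 0) / 2)
  # with mixed signs each entry keeps whichever head clips positive
  G2[1, , ] <- G; G2[2, , ] <- -G
  expect_equal(head_average(A2, G2), abs(A * G) / 2)

  expect_error(head_average(A, matrix(0, 3, 3)), "shape")
})

test_that("propagate matches closed forms and rejects negative input", {
  # all-zero layers preserve the identity
  expect_equal(propagate(list(matrix(0, 3, 3), matrix(0, 3, 3))), diag(3))
  # single layer: I + Abar
  Ab <- rbind(c(0.1, 0.2), c(0.3, 0.4))
  expect_equal(propagate(list(Ab)), diag(2) + Ab)
  # two layers, explicit oracle value
  Ab2 <- rbind(c(0, 0.5), c(0.5, 0))
  expect_equal(propagate(list(Ab, Ab2)),
               rbind(c(1.25, 0.9), c(0.85, 1.5)), tolerance = 1e-12)
  # keep_layers returns R^0 = I first
  ks <- propagate(list(Ab, Ab2), keep_layers = TRUE)
  expect_length(ks, 3L)
  expect_equal(ks[[1]], diag(2))
  expect_equal(ks[[3]], propagate(list(Ab, Ab2)))
  expect_error(propagate(list(rbind(c(-0.1, 0), c(0, 0)))), "negative")
})

test_that("propagation is monotone for non-negative layers", {
  set.seed(42)
  for (i in 1:20) {
    ab <- random_abar_list(Tn = sample(2:6, 1), L = sample(1:3, 1))
    ks <- propagate(ab, keep_layers = TRUE)
    for (l in seq_along(ab)) {
      expect_true(all(ks[[l + 1]] - ks[[l]] >= -1e-12))
    }
  }
})

test_that("attribute_readout is non-negative, aligned, and single-pass", {
  m <- tiny_model()
  s <- tokenize("CC(N)O", vocab = m$vocab, prepend_readout = TRUE)
  reset_call_counts()
  at <- attribute_readout(m, s)
  counts <- get_call_counts()
  expect_equal(counts[["forward"]], 1L)     # exactly one traced forward
  expect_equal(counts[["backward"]], 1L)    # and one reverse pass
  expect_s3_class(at, "attribution")
  expect_length(at$token_relevance, length(s$ids) - 1L)
  expect_true(all(at$token_relevance >= 0))
  expect_true(all(is.finite(at$token_relevance)))
  expect_length(at$atom_relevance, 4L)
  expect_equal(at$prediction, predict(m, list(s)))
  # atom projection sums token relevance of atom-mapped tokens only
  expect_equal(sum(at$atom_relevance),
               sum(at$token_relevance[!is.na(s$atom_map[-1])]))

  avg <- tiny_model(pool = "avg")
  tk2 <- tokenize("CCO", vocab = avg$vocab, prepend_readout = FALSE)
  expect_error(attribute_readout(avg, tk2), "shapley")
})

test_that("single-layer single-head attribution equals the direct formula", {
  s <- tiny_setup(L = 1L, H = 1L, d = 8L, seed = 9)
  m <- tiny_model(d = 8L, setup = s)
  tk <- tokenize("NCCO", vocab = s$vocab, prepend_readout = TRUE)
  tr <- clmexplain:::.trace_prediction(m, tk)
  Ab <- head_average(tr$A[[1]], tr$gradA[[1]])
  direct <- (diag(nrow(Ab)) + Ab)[1, -1]
  at <- attribute_readout(m, tk)
  expect_equal(unname(at$token_relevance), unname(direct), tolerance = 1e-12)
})

test_that("zero attention gradients imply zero attribution", {
  m <- tiny_model()
  # zero head weights make the prediction (and every gradient) zero
  m$head$params$W <- rep(0, length(m$head$params$W))
  tk <- tokenize("CCN", vocab = m$vocab, prepend_readout = TRUE)
  at <- attribute_readout(m, tk)
  expect_equal(unname(at$token_relevance), rep(0, 3))
})

test_that("classify_features implements the four-way sign arithmetic", {
  cl <- classify_features(c(1, -1, 2), c(0.5, 0.5, -1))
  expect_equal(cl$class, c("(+,+)", "(-,+)", "(+,-)"))
  expect_equal(cl$contribution, c(0.5, -0.5, -2))
  expect_equal(which(cl$contribution > 0), 1L)
  expect_equal(which(cl$contribution < 0), c(2L, 3L))

  cl0 <- classify_features(rep(0, 3), c(1, -1, 0))
  expect_true(all(cl0$class == "neutral"))

  # (-,-) contributes positively
  expect_equal(classify_features(-2, -3)$class, "(-,-)")
  expect_equal(classify_features(-2, -3)$contribution, 6)
})

test_that("positive- and negative-class masked predictions partition the full one", {
  m <- tiny_model()
  for (sm in c("CCO", "CC(N)O", "c1ccccc1Cl", "OCC(C)N")) {
    tk <- tokenize(sm, vocab = m$vocab, prepend_readout = TRUE)
    full <- predict(m, list(tk))
    pos <- masked_feature_attribution(m, tk, "positive")
    neg <- masked_feature_attribution(m, tk, "negative")
    expect_equal(pos$prediction + neg$prediction, full, tolerance = 1e-10)
    expect_false(any(pos$kept & neg$kept))
    # single-feature mask yields exactly that feature's contribution
    i <- which.max(abs(pos$classes$contribution))
    one <- masked_feature_attribution(m, tk, i)
    expect_equal(one$prediction, pos$classes$contribution[i], tolerance = 1e-10)
  }
})
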