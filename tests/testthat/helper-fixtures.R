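# Shared fixtures: tiny models built in code, and one memoized full
# desk-scale training run that the end-to-end checks share.

fixture_smiles <- c("CCO", "CCN", "NCCO", "CC(N)O", "OCC(C)N", "c1ccccc1Cl",
                    "C1CCNCC1", "O=C=O", "CC(Cl)CN")

# vocabulary + tiny encoder/model for fast structural tests
tiny_setup <- function(d = 16L, L = 2L, H = 2L, seed = 7L,
                       corpus = fixture_smiles) {
  vocab <- build_vocabulary(corpus)
  enc <- init_encoder(encoder_config(L, H, d, 2L * d, 48L,
                                     vocab_size = length(vocab), seed = seed))
  list(vocab = vocab, encoder = enc)
}

tiny_model <- function(pool = "readout", kind = "linear", d = 16L, seed = 7L,
                       setup = tiny_setup(d = d, seed = seed)) {
  head <- init_head(head_config(kind, d), seed = seed + 1L)
  build_model(setup$encoder, head, pool = pool, vocab = setup$vocab)
}

# One shared desk-scale planted-property run (the expensive fixture):
# computed on first use, reused by every later test in the session.
.fixture_env <- new.env(parent = emptyenv())
get_fixture_experiment <- function() {
  if (is.null(.fixture_env$ex)) {
    .fixture_env$ex <- planted_recovery_experiment(n = 500L, seed = 11L,
                                                   epochs = 30L)
  }
  .fixture_env$ex
}

# explicit-loop reference for relevance propagation (independent oracle)
propagate_loops <- function(abar_list) {
  Tn <- nrow(abar_list[[1]])
  R <- diag(Tn)
  for (Ab in abar_list) {
    M <- matrix(0, Tn, Tn)
    for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
      s <- 0
      for (k in seq_len(Tn)) s <- s + Ab[i, k] * R[k, j]
      M[i, j] <- s
    }
    R <- R + M
  }
  R
}

random_abar_list <- function(Tn, L) {
  lapply(seq_len(L), function(l) matrix(stats::runif(Tn * Tn), Tn, Tn))
}
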