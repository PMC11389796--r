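Package: clmexplain
Title: Attribution Methods for Chemical Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale toolkit for explaining property predictions of
    transformer chemical language models operating on SMILES strings.
    Provides a regex SMILES tokenizer with a prepended readout token and
    token-to-atom mapping, a multi-head self-attention encoder that records
    attention scores and their gradients during a single forward/backward
    pass, linear and hierarchical regression heads with frozen and
    fine-tuned training, gradient-weighted attention relevance propagation
    with positive-part clipping, Shapley-value token attribution via a
    mask-token masker (exact enumeration and permutation sampling),
    circular-fingerprint bit-to-atom weight attribution with conservation,
    latent-feature sign decomposition, quantitative comparison of
    attribution methods, and a synthetic molecule generator with a planted
    structure-derived property for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
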