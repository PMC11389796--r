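# Tokenizer module: regex SMILES tokenization with special tokens,
# vocabulary management and token-to-atom index mapping.

#' Special tokens
#'
#' The reserved tokens of every vocabulary: `<PAD>` (padding), `<MASK>`
#' (masked positions, used both by masked-reconstruction pretraining and by
#' the Shapley masker), `<R>` (the readout token prepended to sequences,
#' the regression analogue of a classification token) and `<UNK>` (unknown
#' token substitution).
#' @export
special_tokens <- function() c(PAD = "<PAD>", MASK = "<MASK>", READOUT = "<R>", UNK = "<UNK>")

#' Build a vocabulary from a SMILES corpus
#'
#' Ids are contiguous from 0, with the four special tokens first
#' (in the fixed order PAD, MASK, READOUT, UNK) followed by all corpus
#' tokens in lexicographic order, so a vocabulary is fully determined by
#' the set of tokens in the corpus.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @return An object of class `clm_vocabulary`: a named integer vector
#'   mapping token string to 0-based id, with a `specials` attribute.
#' @examples
#' v <- build_vocabulary(c("CCO", "CCN"))
#' v[["C"]]
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0L) stopf("cannot build a vocabulary from an empty corpus")
  toks <- unique(unlist(lapply(corpus, scan_smiles)))
  toks <- sort(toks, method = "radix")  # locale-independent ordering
  sp <- special_tokens()
  all_tokens <- c(unname(sp), setdiff(toks, sp))
  ids <- seq_along(all_tokens) - 1L
  names(ids) <- all_tokens
  structure(ids, specials = sp, class = "clm_vocabulary")
}

#' @export
print.clm_vocabulary <- function(x, ...) {
  cat(sprintf("<clm_vocabulary: %d tokens (4 special)>\n", length(x)))
  invisible(x)
}

#' Number of tokens in a vocabulary
#' @param vocab A `clm_vocabulary`.
#' @return Integer vocabulary size.
#' @export
vocab_size <- function(vocab) length(vocab)

vocab_id <- function(vocab, token) {
  i <- match(token, names(vocab))
  unname(vocab[i])
}

#' Serialize a vocabulary to JSON
#' @param vocab A `clm_vocabulary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_vocabulary <- function(vocab, path) {
  obj <- list(tokens = as.list(unclass(vocab)),
              specials = as.list(attr(vocab, "specials")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a vocabulary from JSON
#' @param path File written by [save_vocabulary()].
#' @return A `clm_vocabulary`; ids (including the readout token's) round-trip
#'   exactly.
#' @export
load_vocabulary <- function(path) {
  obj <- jsonlite::read_json(path)
  ids <- as.integer(unlist(obj$tokens))
  names(ids) <- names(obj$tokens)
  structure(ids, specials = unlist(obj$specials), class = "clm_vocabulary")
}

#' Tokenize a SMILES string
#'
#' Scans the string with the token grammar (bracket atoms, two-letter
#' halogens, organic-subset and aromatic single letters, bond symbols, ring
#' closures, branch parentheses), optionally prepends the readout token
#' `<R>`, and aligns atom-bearing tokens with atom indices of the parsed
#' molecule. The string is tokenized exactly as given (no canonicalization):
#' attributions must refer to the string the model saw.
#'
#' @param smiles A single SMILES string; must parse under [parse_smiles()].
#' @param vocab Optional `clm_vocabulary`; when supplied, `ids` are filled,
#'   with out-of-vocabulary tokens mapped to `<UNK>` under a warning.
#' @param prepend_readout Prepend the `<R>` readout token (default `TRUE`).
#' @return An object of class `tokenized_molecule`: list with `smiles`,
#'   `tokens`, `ids` (0-based, or `NULL` without a vocabulary),
#'   `has_readout`, and `atom_map` — an integer vector over token positions
#'   (1-based) with the 1-based atom index for atom tokens and `NA`
#'   elsewhere (readout, bonds, ring digits, parentheses).
#' @examples
#' tk <- tokenize("CCO", prepend_readout = TRUE)
#' tk$tokens
#' tk$atom_map
#' @export
tokenize <- function(smiles, vocab = NULL, prepend_readout = TRUE) {
  mol <- parse_smiles(smiles)  # validity gate; errors name the string
  raw <- scan_smiles(smiles)
  sp <- special_tokens()
  tokens <- if (prepend_readout) c(sp[["READOUT"]], raw) else raw
  offset <- if (prepend_readout) 1L else 0L

  atom_map <- rep(NA_integer_, length(tokens))
  atom_positions <- offset + which(is_atom_token(raw))
  atom_map[atom_positions] <- seq_along(atom_positions)
  if (length(atom_positions) != mol$n_atoms) {
    stopf("internal consistency error: token scan found %d atoms but parser found %d in '%s'",
          length(atom_positions), mol$n_atoms, smiles)
  }

  ids <- NULL
  if (!is.null(vocab)) {
    idx <- match(tokens, names(vocab))
    if (anyNA(idx)) {
      missing <- unique(tokens[is.na(idx)])
      warning(sprintf("token(s) outside vocabulary substituted by <UNK>: %s",
                      paste(missing, collapse = " ")), call. = FALSE)
      idx[is.na(idx)] <- match(sp[["UNK"]], names(vocab))
    }
    ids <- unname(vocab[idx])
  }

  structure(list(smiles = smiles, tokens = tokens, ids = ids,
                 has_readout = prepend_readout, atom_map = atom_map),
            class = "tokenized_molecule")
}

#' @export
print.tokenized_molecule <- function(x, ...) {
  cat(sprintf("<tokenized_molecule: '%s', %d tokens%s>\n", x$smiles,
              length(x$tokens), if (x$has_readout) " (readout)" else ""))
  invisible(x)
}

#' Map token positions to atom indices
#'
#' Recomputes the token-position-to-atom mapping of a tokenized molecule and
#' cross-checks it against the parsed molecule's atom count. Every heavy
#' atom is claimed by exactly one token position, following left-to-right
#' appearance order; bond symbols, ring closures, branches and the readout
#' token map to no atom.
#'
#' @param tokenized A `tokenized_molecule`.
#' @return Integer vector over token positions; `NA` for non-atom tokens.
#' @export
map_tokens_to_atoms <- function(tokenized) {
  stopifnot(inherits(tokenized, "tokenized_molecule"))
  mol <- parse_smiles(tokenized$smiles)
  body <- tokenized$tokens
  if (tokenized$has_readout) body <- body[-1]
  n_claimed <- sum(is_atom_token(body))
  if (n_claimed != mol$n_atoms) {
    stopf("atom count mismatch: %d atom tokens vs %d parsed atoms for '%s'",
          n_claimed, mol$n_atoms, tokenized$smiles)
  }
  tokenized$atom_map
}

# Positions eligible for masking: every real token except the readout.
maskable_positions <- function(tokenized) {
  pos <- seq_along(tokenized$tokens)
  if (tokenized$has_readout) pos[-1] else pos
}
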