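# Minimal SMILES machinery: token scanning, molecular-graph parsing,
# ring perception and Bemis-Murcko scaffold keys.
#
# The toolkit needs a parser that (a) defines which strings are valid input,
# (b) exposes atoms in left-to-right string appearance order so token
# positions align with atom indices, and (c) yields the graph needed for
# circular fingerprints and scaffold splits. Atom indices are 1-based.

.token_pattern <- "\\[[^]]+\\]|%[0-9]{2}|Cl|Br|[BCNOPSFI]|[bcnosp]|[0-9]|[=#$:/\\\\-]|[().]"

.bond_order <- c("-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5, "/" = 1, "\\" = 1)

.max_valence <- c(B = 3, C = 4, N = 5, O = 3, P = 5, S = 6, F = 1,
                  Cl = 1, Br = 1, I = 1)

# Scan a SMILES string into its lexical tokens. Errors when any character
# is not covered by the token grammar (gap in the match coverage).
scan_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stopf("expected a single non-empty SMILES string")
  }
  m <- gregexpr(.token_pattern, smiles, perl = TRUE)[[1]]
  if (m[1] == -1L) stopf("no tokens recognised in SMILES '%s'", smiles)
  toks <- regmatches(smiles, gregexpr(.token_pattern, smiles, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    stopf("SMILES '%s' contains characters outside the token grammar", smiles)
  }
  toks
}

is_atom_token <- function(tok) {
  startsWith(tok, "[") |
    tok %in% c("Cl", "Br") |
    tok %in% c("B", "C", "N", "O", "P", "S", "F", "I") |
    tok %in% c("b", "c", "n", "o", "s", "p")
}

.parse_bracket_atom <- function(tok, smiles) {
  inner <- sub("^\\[(.*)\\]$", "\\1", tok)
  m <- regexec("^([0-9]*)([A-Z][a-z]?|[a-z]|\\*)(@{1,2})?(H[0-9]*)?(\\+{1,3}|-{1,3}|[+-][0-9]+)?(:[0-9]+)?$",
               inner)
  parts <- regmatches(inner, m)[[1]]
  if (length(parts) == 0L) {
    stopf("invalid bracket atom '%s' in SMILES '%s'", tok, smiles)
  }
  sym <- parts[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  chg <- parts[6]
  charge <- if (!nzchar(chg)) {
    0L
  } else if (grepl("^[+-][0-9]+$", chg)) {
    as.integer(chg)
  } else {
    nchar(chg) * if (startsWith(chg, "+")) 1L else -1L
  }
  hc <- parts[5]
  hcount <- if (!nzchar(hc)) 0L else if (hc == "H") 1L else as.integer(substring(hc, 2))
  list(symbol = if (aromatic) paste0(toupper(substring(sym, 1, 1)), substring(sym, 2)) else sym,
       aromatic = aromatic, charge = charge, hcount = hcount)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic
#' lowercase atoms, bracket atoms with isotope/stereo/H-count/charge, bond
#' symbols, branches, ring closures (digits and `%nn`) and dot-separated
#' components. Atoms are numbered 1..n in the order they appear in the
#' string, which is the ordering all attribution vectors in this package
#' refer to.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `clm_molecule`: a list with `atoms`
#'   (data.frame: `symbol`, `aromatic`, `charge`, `bracket`), `bonds`
#'   (data.frame: `from`, `to`, `order`), `n_atoms` and `smiles`.
#' @examples
#' mol <- parse_smiles("c1ccccc1Cl")
#' mol$n_atoms
#' @export
parse_smiles <- function(smiles) {
  toks <- scan_smiles(smiles)
  sym <- character(0); arom <- logical(0); charge <- integer(0); bracket <- logical(0)
  b_from <- integer(0); b_to <- integer(0); b_ord <- numeric(0)
  prev <- NA_integer_
  pending <- NA_real_
  stack <- integer(0)
  rings <- list()  # label -> list(atom, order)

  add_bond <- function(i, j, ord) {
    if (i == j) stopf("ring closure bonds atom to itself in '%s'", smiles)
    if (any((b_from == i & b_to == j) | (b_from == j & b_to == i))) {
      stopf("duplicate bond between atoms %d and %d in '%s'", i, j, smiles)
    }
    b_from <<- c(b_from, i); b_to <<- c(b_to, j); b_ord <<- c(b_ord, ord)
  }

  for (tok in toks) {
    if (is_atom_token(tok)) {
      if (startsWith(tok, "[")) {
        at <- .parse_bracket_atom(tok, smiles)
        sym <- c(sym, at$symbol); arom <- c(arom, at$aromatic)
        charge <- c(charge, at$charge); bracket <- c(bracket, TRUE)
      } else {
        is_ar <- tok %in% c("b", "c", "n", "o", "s", "p")
        sym <- c(sym, if (is_ar) toupper(tok) else tok)
        arom <- c(arom, is_ar); charge <- c(charge, 0L); bracket <- c(bracket, FALSE)
      }
      idx <- length(sym)
      if (!is.na(prev)) {
        ord <- if (!is.na(pending)) pending else if (arom[prev] && arom[idx]) 1.5 else 1
        add_bond(prev, idx, ord)
      }
      prev <- idx
      pending <- NA_real_
    } else if (tok %in% names(.bond_order)) {
      if (is.na(prev)) stopf("bond symbol '%s' with no preceding atom in '%s'", tok, smiles)
      if (!is.na(pending)) stopf("consecutive bond symbols in '%s'", smiles)
      pending <- .bond_order[[tok]]
    } else if (grepl("^[0-9]$|^%[0-9]{2}$", tok)) {
      if (is.na(prev)) stopf("ring closure '%s' with no preceding atom in '%s'", tok, smiles)
      lbl <- sub("^%", "", tok)
      if (!is.null(rings[[lbl]])) {
        open <- rings[[lbl]]
        ord <- if (!is.na(pending)) pending
          else if (!is.na(open$order)) open$order
          else if (arom[open$atom] && arom[prev]) 1.5 else 1
        add_bond(open$atom, prev, ord)
        rings[[lbl]] <- NULL
      } else {
        rings[[lbl]] <- list(atom = prev, order = pending)
      }
      pending <- NA_real_
    } else if (tok == "(") {
      if (is.na(prev)) stopf("branch opened before any atom in '%s'", smiles)
      if (!is.na(pending)) stopf("bond symbol before '(' in '%s'", smiles)
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stopf("unmatched ')' in '%s'", smiles)
      if (!is.na(pending)) stopf("dangling bond before ')' in '%s'", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      if (!is.na(pending)) stopf("bond symbol before '.' in '%s'", smiles)
      prev <- NA_integer_
    } else {
      stopf("unhandled token '%s' in '%s'", tok, smiles)
    }
  }
  if (length(stack) > 0L) stopf("unclosed branch in '%s'", smiles)
  if (!is.na(pending)) stopf("dangling bond at end of '%s'", smiles)
  if (length(rings) > 0L) stopf("unmatched ring closure(s) %s in '%s'",
                                paste(names(rings), collapse = ","), smiles)
  if (length(sym) == 0L) stopf("SMILES '%s' contains no atoms", smiles)

  # light valence screen on non-bracket atoms (bracket atoms carry explicit
  # H counts/charges and are taken at face value)
  for (i in seq_along(sym)) {
    if (bracket[i]) next
    tot <- sum(b_ord[b_from == i | b_to == i])
    maxv <- .max_valence[[sym[i]]]
    if (!is.null(maxv) && tot > maxv + 1e-9) {
      stopf("valence of atom %d (%s, total bond order %.1f) exceeds %d in '%s'",
            i, sym[i], tot, maxv, smiles)
    }
  }

  structure(list(
    atoms = data.frame(symbol = sym, aromatic = arom, charge = charge,
                       bracket = bracket, stringsAsFactors = FALSE),
    bonds = data.frame(from = b_from, to = b_to, order = b_ord),
    n_atoms = length(sym),
    smiles = smiles
  ), class = "clm_molecule")
}

#' Check whether a SMILES string parses
#' @param smiles A single SMILES string.
#' @return `TRUE` if [parse_smiles()] succeeds, else `FALSE`.
#' @export
is_valid_smiles <- function(smiles) {
  !inherits(try(parse_smiles(smiles), silent = TRUE), "try-error")
}

# Adjacency list of a parsed molecule.
mol_adjacency <- function(mol) {
  adj <- vector("list", mol$n_atoms)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Atom indices surviving iterative removal of degree-1 atoms: the
# Bemis-Murcko scaffold (ring systems plus linkers). Empty for acyclic
# molecules.
murcko_scaffold_atoms <- function(mol) {
  keep <- rep(TRUE, mol$n_atoms)
  repeat {
    deg <- integer(mol$n_atoms)
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
      if (keep[i] && keep[j]) {
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
    leaves <- keep & deg <= 1L
    if (!any(leaves)) break
    keep[leaves] <- FALSE
  }
  which(keep)
}

#' Bemis-Murcko scaffold key of a molecule
#'
#' Computes a deterministic, order-independent key for the ring-and-linker
#' framework obtained by iteratively pruning terminal atoms. Molecules whose
#' frameworks are isomorphic (same atoms, bonds and connectivity under
#' iterative neighbourhood refinement) receive the same key; acyclic
#' molecules have an empty framework and each gets a unique key of the form
#' `"acyclic:<smiles>"` so that a scaffold split treats them as singleton
#' groups.
#'
#' @param smiles A single SMILES string.
#' @return A character scaffold key.
#' @export
scaffold_key <- function(smiles) {
  mol <- parse_smiles(smiles)
  core <- murcko_scaffold_atoms(mol)
  if (length(core) == 0L) return(paste0("acyclic:", smiles))
  idx <- match(seq_len(mol$n_atoms), core)  # old -> new (NA outside core)
  sub_bonds <- mol$bonds[mol$bonds$from %in% core & mol$bonds$to %in% core, , drop = FALSE]
  n <- length(core)
  # initial invariants: element, aromaticity, charge, degree within core
  deg <- integer(n)
  nb <- vector("list", n)
  for (k in seq_len(nrow(sub_bonds))) {
    i <- idx[sub_bonds$from[k]]; j <- idx[sub_bonds$to[k]]
    o <- as.integer(round(sub_bonds$order[k] * 2))
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    nb[[i]] <- rbind(nb[[i]], c(j, o)); nb[[j]] <- rbind(nb[[j]], c(i, o))
  }
  inv <- vapply(seq_len(n), function(i) {
    a <- mol$atoms[core[i], ]
    hash_ints(c(match(a$symbol, names(.max_valence), nomatch = 99L),
                as.integer(a$aromatic), a$charge, deg[i]))
  }, integer(1))
  for (round_ in seq_len(n)) {
    inv <- vapply(seq_len(n), function(i) {
      pairs <- nb[[i]]
      if (is.null(pairs)) return(hash_ints(inv[i]))
      nbr <- sort(as.numeric(inv[pairs[, 1]]) * 7 + pairs[, 2])
      hash_ints(c(inv[i], nbr))
    }, integer(1))
  }
  paste0("ring:", hash_ints(c(n, nrow(sub_bonds), sort(inv))))
}

#' Count atoms of given element symbols
#' @param smiles A single SMILES string.
#' @param symbols Character vector of element symbols to count.
#' @return Named integer vector of counts.
#' @export
count_atoms <- function(smiles, symbols = c("C", "N", "O")) {
  mol <- parse_smiles(smiles)
  vapply(symbols, function(s) sum(mol$atoms$symbol == s), integer(1))
}
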