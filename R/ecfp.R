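# Circular (Morgan-style) fingerprints with per-bit environment recovery,
# linear-weight attribution to atoms, and robust target scaling.
#
# Each atom's neighbourhood of radius 0..r is hashed to an identifier;
# identifiers are folded into n_bits by modulo, so distinct environments
# can collide on one bit (the classic bit-collision phenomenon). Every
# environment that sets a bit is recorded (center atom, radius, constituent
# atom set), which is what makes bit weights attributable to atoms.

#' Fingerprint configuration
#' @param n_bits Number of bits (512 or 2048 are the conventional sizes).
#' @param radius Maximum environment radius (default 2, i.e. ECFP4-like).
#' @param binary Only binary fingerprints are produced.
#' @return A `fingerprint_config`.
#' @export
fingerprint_config <- function(n_bits = 512L, radius = 2L, binary = TRUE) {
  stopifnot(n_bits > 0, radius >= 0, isTRUE(binary))
  structure(list(n_bits = as.integer(n_bits), radius = as.integer(radius),
                 binary = TRUE), class = "fingerprint_config")
}

#' Circular fingerprint with bit environments
#'
#' @param smiles A single SMILES string (must parse).
#' @param cfg A [fingerprint_config()].
#' @return List with `bits` (0/1 integer vector of length `n_bits`),
#'   `on_bits` (1-based bit indices that are set) and `environments` — a
#'   list with one entry per environment: `bit` (1-based), `center` atom
#'   index, `radius`, and `atoms` (sorted constituent atom indices).
#'   Duplicate environments covering the same bond set are recorded once.
#' @export
fingerprint <- function(smiles, cfg = fingerprint_config()) {
  stopifnot(inherits(cfg, "fingerprint_config"))
  mol <- parse_smiles(smiles)
  n <- mol$n_atoms
  nb <- vector("list", n)  # each: matrix cols (nbr, order2x, bond_idx)
  nbonds <- nrow(mol$bonds)
  for (k in seq_len(nbonds)) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    o <- as.integer(round(mol$bonds$order[k] * 2))
    nb[[i]] <- rbind(nb[[i]], c(j, o, k))
    nb[[j]] <- rbind(nb[[j]], c(i, o, k))
  }
  deg <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  ids <- vapply(seq_len(n), function(i) {
    a <- mol$atoms[i, ]
    hash_ints(c(match(a$symbol, names(.max_valence), nomatch = 99L),
                deg[i], a$charge, as.integer(a$aromatic)))
  }, integer(1))

  # BFS distances from each atom (bounded by radius)
  dists <- lapply(seq_len(n), function(i) {
    d <- rep(NA_integer_, n); d[i] <- 0L
    frontier <- i
    for (r in seq_len(cfg$radius)) {
      nxt <- integer(0)
      for (a in frontier) {
        if (is.null(nb[[a]])) next
        for (b in nb[[a]][, 1]) if (is.na(d[b])) { d[b] <- r; nxt <- c(nxt, b) }
      }
      frontier <- nxt
      if (length(frontier) == 0L) break
    }
    d
  })

  envs <- list()
  seen <- character(0)
  cur <- ids
  for (r in 0:cfg$radius) {
    if (r > 0) {
      cur <- vapply(seq_len(n), function(i) {
        if (is.null(nb[[i]])) return(hash_ints(c(r, cur[i])))
        pairs <- nb[[i]]
        o <- order(pairs[, 2], cur[pairs[, 1]])
        flat <- as.vector(t(cbind(pairs[o, 2], cur[pairs[o, 1]])))
        hash_ints(c(r, cur[i], flat))
      }, integer(1))
    }
    for (i in seq_len(n)) {
      d <- dists[[i]]
      atoms <- which(!is.na(d) & d <= r)
      bond_set <- which(vapply(seq_len(nbonds), function(k) {
        a <- mol$bonds$from[k]; b <- mol$bonds$to[k]
        fa <- d[a]; fb <- d[b]
        !is.na(fa) && !is.na(fb) && min(fa, fb) <= r - 1L && max(fa, fb) <= r
      }, logical(1)))
      key <- if (r == 0L) paste0("a", i) else paste(bond_set, collapse = ",")
      if (key %in% seen) next
      if (r > 0L && length(bond_set) == 0L) next  # isolated atom: radius-0 only
      seen <- c(seen, key)
      bit <- (cur[i] %% cfg$n_bits) + 1L
      envs[[length(envs) + 1L]] <- list(bit = bit, center = i, radius = r,
                                        atoms = sort(atoms))
    }
  }

  bits <- integer(cfg$n_bits)
  for (e in envs) bits[e$bit] <- 1L
  list(bits = bits, on_bits = sort(unique(vapply(envs, `[[`, integer(1), "bit"))),
       environments = envs, n_atoms = n)
}

#' Fingerprint a set of molecules into a bit matrix
#' @param smiles Character vector of SMILES.
#' @param cfg A [fingerprint_config()].
#' @return Integer matrix (molecules x bits).
#' @export
fingerprint_matrix <- function(smiles, cfg = fingerprint_config()) {
  t(vapply(smiles, function(s) fingerprint(s, cfg)$bits, integer(cfg$n_bits)))
}

#' Attribute per-bit regression weights to atoms
#'
#' Each on bit's weight is split equally across the environments that set
#' it (collisions within a molecule included), then equally across each
#' environment's constituent atoms, and per-atom shares are summed. The
#' total attributed relevance equals the summed weight of the on bits, so
#' overall relevance to the prediction is conserved.
#'
#' @param weights Numeric vector of per-bit weights (length `n_bits`).
#' @param fp A fingerprint as returned by [fingerprint()] (its
#'   `environments` and `n_atoms` are used).
#' @return List with `atom_attribution` (per-atom values), `total`
#'   (their sum) and `conservation_residual`
#'   (`total - sum(weights[on_bits])`, ~0 up to rounding).
#' @export
attribute_weights_to_atoms <- function(weights, fp) {
  envs <- fp$environments
  n_atoms <- fp$n_atoms
  for (e in envs) {
    if (any(e$atoms < 1L | e$atoms > n_atoms)) {
      stopf("environment of bit %d references a nonexistent atom", e$bit)
    }
  }
  atom_attribution <- numeric(n_atoms)
  bit_of <- vapply(envs, `[[`, integer(1), "bit")
  for (bit in unique(bit_of)) {
    idx <- which(bit_of == bit)
    share <- weights[bit] / length(idx)
    for (k in idx) {
      a <- envs[[k]]$atoms
      atom_attribution[a] <- atom_attribution[a] + share / length(a)
    }
  }
  total <- sum(atom_attribution)
  list(atom_attribution = atom_attribution, total = total,
       conservation_residual = total - sum(weights[unique(bit_of)]))
}

#' Robust target scaling
#'
#' Centers by the median and scales by the spread between the 10th and
#' 90th percentiles (linear-interpolation quantiles), which is insensitive
#' to outliers in long-tailed property distributions.
#'
#' @param targets Numeric vector with at least 2 distinct values.
#' @return A `robust_scaler`: list with `scaled`, `center` (median) and
#'   `scale` (p90 - p10).
#' @examples
#' s <- robust_scale(0:10)
#' s$scaled[10]  # (9 - 5) / (9 - 1) = 0.5
#' @export
robust_scale <- function(targets) {
  if (length(unique(targets)) < 2) stopf("targets need at least 2 distinct values")
  ctr <- stats::median(targets)
  q <- stats::quantile(targets, c(0.1, 0.9), names = FALSE, type = 7)
  scl <- q[2] - q[1]
  if (scl == 0) stopf("10th and 90th percentiles coincide; robust scale undefined")
  structure(list(scaled = (targets - ctr) / scl, center = ctr, scale = scl),
            class = "robust_scaler")
}

#' Invert robust scaling
#' @param scaled Numeric vector on the scaled scale.
#' @param scaler A `robust_scaler`.
#' @return Values on the original scale.
#' @export
robust_unscale <- function(scaled, scaler) {
  stopifnot(inherits(scaler, "robust_scaler"))
  scaled * scaler$scale + scaler$center
}
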