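# Synthetic molecule generation with a planted structure-derived property,
# the three train/validation/test split strategies, and the CSV reader for
# externally supplied solubility tables.
#
# The generator builds a random molecular graph first (tree plus an
# optional 5- or 6-ring) under valence constraints and writes the SMILES
# itself, so every emitted string is valid by construction; the parser is
# still run on each as a final gate. The planted property
#
#   y* = 1.0 * (#N + #O) - 0.3 * (#C)
#
# gives attributions a known ground truth: electronegative atoms should
# receive positive importance and carbon skeletons negative, the pattern a
# sound attribution method must recover.

.gen_valence <- c(C = 4L, N = 3L, O = 2L, Cl = 1L)

# write a SMILES string for a generated graph (atoms: symbols; bonds: all
# single), via DFS from atom 1 with ring-closure digits for back edges
write_smiles <- function(symbols, edges) {
  n <- length(symbols)
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  visited <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  order_ <- integer(0)
  children <- vector("list", n)
  back_edges <- list()
  # iterative DFS, preserving neighbour order
  stack <- list(c(1L, NA_integer_))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1]; p <- top[2]
    if (visited[v]) next
    visited[v] <- TRUE
    parent[v] <- p
    if (!is.na(p)) children[[p]] <- c(children[[p]], v)
    order_ <- c(order_, v)
    nbrs <- adj[[v]]
    for (u in rev(setdiff(nbrs, p))) {
      if (visited[u]) {
        key <- paste(sort(c(v, u)), collapse = "-")
        back_edges[[key]] <- c(v, u)
      } else {
        stack[[length(stack) + 1L]] <- c(u, v)
      }
    }
  }
  digits <- vector("list", n)
  if (length(back_edges) > 0) {
    for (k in seq_along(back_edges)) {
      e <- back_edges[[k]]
      digits[[e[1]]] <- c(digits[[e[1]]], k)
      digits[[e[2]]] <- c(digits[[e[2]]], k)
    }
  }
  emit <- function(v) {
    s <- paste0(symbols[v], paste(digits[[v]], collapse = ""))
    ch <- children[[v]]
    if (length(ch) > 0) {
      for (c_ in ch[-length(ch)]) s <- paste0(s, "(", emit(c_), ")")
      s <- paste0(s, emit(ch[length(ch)]))
    }
    s
  }
  emit(1L)
}

gen_one_graph <- function(size_range, p_ring) {
  n <- sample(size_range[1]:size_range[2], 1)
  symbols <- character(n)
  symbols[1] <- sample(c("C", "N", "O"), 1, prob = c(0.7, 0.15, 0.15))
  edges <- matrix(integer(0), ncol = 2)
  used <- integer(n)  # bonds used per atom
  for (i in seq_len(n)[-1]) {
    symbols[i] <- sample(names(.gen_valence), 1, prob = c(0.60, 0.15, 0.15, 0.10))
    open <- which(used[seq_len(i - 1)] < .gen_valence[symbols[seq_len(i - 1)]])
    if (length(open) == 0) { symbols <- symbols[seq_len(i - 1)]; break }
    p <- if (length(open) == 1) open else sample(open, 1)
    edges <- rbind(edges, c(p, i))
    used[p] <- used[p] + 1L; used[i] <- used[i] + 1L
  }
  n <- length(symbols)
  # optionally close one 5- or 6-ring between atoms at tree distance 4 or 5
  if (n >= 5 && stats::runif(1) < p_ring) {
    adj <- vector("list", n)
    for (k in seq_len(nrow(edges))) {
      adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
      adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
    }
    dist1 <- function(s) {  # BFS distances from s
      d <- rep(NA_integer_, n); d[s] <- 0L; fr <- s
      while (length(fr) > 0) {
        nx <- integer(0)
        for (a in fr) for (b in adj[[a]]) if (is.na(d[b])) { d[b] <- d[a] + 1L; nx <- c(nx, b) }
        fr <- nx
      }
      d
    }
    cand <- matrix(integer(0), ncol = 2)
    for (a in seq_len(n)) {
      if (used[a] >= .gen_valence[symbols[a]]) next
      d <- dist1(a)
      for (b in seq_len(n)) {
        if (b <= a) next
        if (used[b] >= .gen_valence[symbols[b]]) next
        if (!is.na(d[b]) && d[b] %in% c(4L, 5L)) cand <- rbind(cand, c(a, b))
      }
    }
    if (nrow(cand) > 0) {
      pick <- cand[sample.int(nrow(cand), 1), ]
      edges <- rbind(edges, pick)
      used[pick[1]] <- used[pick[1]] + 1L; used[pick[2]] <- used[pick[2]] + 1L
    }
  }
  list(symbols = symbols, edges = edges)
}

#' Planted property of a molecule
#'
#' The ground-truth value the synthetic generator assigns:
#' `(#N + #O) - 0.3 * #C`.
#' @param smiles A single SMILES string.
#' @return Numeric planted property value.
#' @examples
#' planted_property("CCO")  # 1 - 0.3 * 2 = 0.4
#' @export
planted_property <- function(smiles) {
  cts <- count_atoms(smiles, c("C", "N", "O"))
  unname(1.0 * (cts["N"] + cts["O"]) - 0.3 * cts["C"])
}

#' Generate synthetic molecules with a planted property
#'
#' Molecules are random valence-respecting graphs over C, N, O and Cl with
#' branches and an optional 5- or 6-membered ring, written to SMILES by
#' construction and re-validated by the parser. Each molecule receives
#' replicate noisy measurements of its planted property; a configured
#' fraction gets 2-4 replicates so that the "accurate" split filter has
#' material to act on.
#'
#' @param n Number of molecules (>= 1).
#' @param seed RNG seed; identical seeds give identical records.
#' @param noise_sd Gaussian noise s.d. per replicate (default 0.15).
#' @param frac_replicated Fraction of molecules with >= 2 replicates
#'   (default 0.5).
#' @param size_range Heavy-atom count range (default 5-16).
#' @param p_ring Probability of attempting one ring closure (default 0.6).
#' @return A data.frame with columns `smiles`, `y_true` (planted value),
#'   `y` (mean of replicates), `n_measurements`, `y_std` (sample s.d.,
#'   `NA` for single measurements) and a list column `replicates`.
#' @export
generate_molecules <- function(n, seed = 0L, noise_sd = 0.15,
                               frac_replicated = 0.5,
                               size_range = c(5L, 16L), p_ring = 0.6) {
  stopifnot(n >= 1)
  with_seed(seed, {
    smiles <- character(n); y_true <- numeric(n)
    reps <- vector("list", n)
    i <- 1L
    while (i <= n) {
      g <- gen_one_graph(size_range, p_ring)
      s <- write_smiles(g$symbols, g$edges)
      if (!is_valid_smiles(s)) next  # reject and resample (not expected)
      smiles[i] <- s
      y_true[i] <- planted_property(s)
      k <- if (stats::runif(1) < frac_replicated) sample(2:4, 1) else 1L
      reps[[i]] <- y_true[i] + stats::rnorm(k, 0, noise_sd)
      i <- i + 1L
    }
    data.frame(smiles = smiles, y_true = y_true,
               y = vapply(reps, mean, numeric(1)),
               n_measurements = vapply(reps, length, integer(1)),
               y_std = vapply(reps, function(r) if (length(r) > 1) stats::sd(r) else NA_real_,
                              numeric(1)),
               replicates = I(reps), stringsAsFactors = FALSE)
  })
}

.make_folds <- function(pool, n_folds, val_fraction = 0.1) {
  lapply(seq_len(n_folds), function(f) {
    val <- sort(sample(pool, max(1L, ceiling(val_fraction * length(pool)))))
    list(train = setdiff(pool, val), validation = val)
  })
}

#' Split records into train/validation/test sets
#'
#' Three strategies:
#' * `"random"`: a test set of `ceiling(test_fraction * n)` molecules from
#'   a fixed seed; the remainder is resampled into 90/10
#'   train/validation folds (3 by default).
#' * `"accurate"`: the test set is every molecule with more than one
#'   measurement whose replicate standard deviation does not exceed 0.2
#'   (low experimental uncertainty); the remainder is cross-validated
#'   (5 folds by default). The filter is independent of record order and
#'   of the seed.
#' * `"scaffold"`: molecules are grouped by Bemis-Murcko framework
#'   ([scaffold_key()]; acyclic molecules are singleton groups) and whole
#'   groups are assigned to the test set until it reaches at least
#'   `test_fraction`, so no scaffold straddles train and test.
#'
#' @param records Data.frame from [generate_molecules()] or
#'   [read_dataset()].
#' @param strategy Split strategy.
#' @param test_fraction Target test fraction (random/scaffold; default 0.1).
#' @param n_folds Cross-validation folds (default 3; 5 for `"accurate"`).
#' @param seed RNG seed; identical seeds reproduce the manifest exactly.
#' @param sd_threshold Uncertainty cutoff of the accurate filter
#'   (default 0.2).
#' @return A `split_manifest`: list with `strategy`, `test_idx`, `folds`
#'   (each with `train` and `validation` indices), `seed`.
#' @export
split_dataset <- function(records, strategy = c("random", "accurate", "scaffold"),
                          test_fraction = 0.1, n_folds = NULL, seed = 0L,
                          sd_threshold = 0.2) {
  strategy <- match.arg(strategy)
  n <- nrow(records)
  stopifnot(n >= 2)
  n_folds <- n_folds %||% if (strategy == "accurate") 5L else 3L
  with_seed(seed, {
    if (strategy == "random") {
      test_idx <- sort(sample.int(n, ceiling(test_fraction * n)))
    } else if (strategy == "accurate") {
      pass <- records$n_measurements > 1 &
        !is.na(records$y_std) & records$y_std <= sd_threshold
      if (!any(pass)) {
        stopf("accurate filter matched no records (%d with >1 measurement, %d below sd threshold)",
              sum(records$n_measurements > 1),
              sum(!is.na(records$y_std) & records$y_std <= sd_threshold))
      }
      test_idx <- which(pass)
    } else {
      keys <- vapply(records$smiles, scaffold_key, character(1))
      groups <- split(seq_len(n), keys)
      ord <- sample.int(length(groups))
      target <- ceiling(test_fraction * n)
      test_idx <- integer(0)
      for (gi in ord) {
        if (length(test_idx) >= target) break
        test_idx <- c(test_idx, groups[[gi]])
      }
      test_idx <- sort(test_idx)
    }
    pool <- setdiff(seq_len(n), test_idx)
    folds <- .make_folds(pool, n_folds)
    structure(list(strategy = strategy, test_idx = test_idx, folds = folds,
                   seed = seed, test_fraction = test_fraction),
              class = "split_manifest")
  })
}

#' Read a solubility dataset from CSV
#'
#' Accepts any CSV holding one molecule per row with a SMILES column and a
#' scalar target column; replicate count and replicate standard deviation
#' columns are optional (defaulting to single measurements), matching the
#' layout of public aqueous-solubility tables.
#'
#' @param path CSV file path.
#' @param smiles_col,target_col,count_col,sd_col Column names (the latter
#'   two optional in the file).
#' @return A data.frame with columns `smiles`, `y`, `n_measurements`,
#'   `y_std`, carrying a `report` attribute with `n_rows`,
#'   `n_molecules` and `total_measurements`.
#' @export
read_dataset <- function(path, smiles_col = "smiles", target_col = "y",
                         count_col = "n_measurements", sd_col = "y_std") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(smiles_col, target_col)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("dataset %s lacks required column(s): %s (expected SMILES column '%s' and target column '%s')",
          path, paste(missing, collapse = ", "), smiles_col, target_col)
  }
  out <- data.frame(smiles = df[[smiles_col]], y = as.numeric(df[[target_col]]),
                    stringsAsFactors = FALSE)
  out$n_measurements <- if (count_col %in% names(df)) as.integer(df[[count_col]]) else 1L
  out$y_std <- if (sd_col %in% names(df)) as.numeric(df[[sd_col]]) else NA_real_
  attr(out, "report") <- list(n_rows = nrow(out),
                              n_molecules = length(unique(out$smiles)),
                              total_measurements = sum(out$n_measurements))
  out
}
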