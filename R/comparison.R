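# Quantitative comparison of attribution methods: cosine similarity of
# per-atom attribution vectors averaged over a molecule set, a uniform
# baseline, PCA projection of latent space, and k-means exemplar selection.

#' Cosine similarity of two attribution vectors
#'
#' @param a,b Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return Cosine similarity in [-1, 1].
#' @export
cosine <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stopf("cosine undefined for an all-zero vector")
  sum(a * b) / (na * nb)
}

#' Mean pairwise cosine similarity of attribution sets
#'
#' Entry (i, j) is the mean, over molecules, of the cosine similarity
#' between method i's and method j's per-atom attribution of that
#' molecule. Molecules where either vector of a pair is all-zero are
#' excluded from that pair's mean (cosine undefined); the number of
#' exclusions per pair is reported.
#'
#' @param attribution_sets Named list; each element is a list of per-atom
#'   numeric vectors, one per molecule, in the same molecule order and
#'   atom ordering across methods.
#' @return A `similarity_matrix`: list with `mean` (symmetric matrix, unit
#'   diagonal), `excluded` (matrix of per-pair exclusion counts) and
#'   `per_molecule` (list of per-pair cosine vectors).
#' @export
mean_similarity_matrix <- function(attribution_sets) {
  k <- length(attribution_sets)
  stopifnot(k >= 1, !is.null(names(attribution_sets)))
  n_mol <- unique(vapply(attribution_sets, length, integer(1)))
  if (length(n_mol) != 1L) stopf("attribution sets cover different numbers of molecules")
  for (m in seq_len(n_mol)) {
    lens <- vapply(attribution_sets, function(s) length(s[[m]]), integer(1))
    if (length(unique(lens)) != 1L) {
      stopf("molecule %d has inconsistent atom counts across methods", m)
    }
  }
  labels <- names(attribution_sets)
  M <- matrix(1, k, k, dimnames = list(labels, labels))
  EX <- matrix(0L, k, k, dimnames = list(labels, labels))
  per <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) next
    sims <- numeric(0); excl <- 0L
    for (m in seq_len(n_mol)) {
      a <- attribution_sets[[i]][[m]]; b <- attribution_sets[[j]][[m]]
      if (all(a == 0) || all(b == 0)) { excl <- excl + 1L; next }
      sims <- c(sims, cosine(a, b))
    }
    val <- if (length(sims) > 0) mean(sims) else NA_real_
    M[i, j] <- val; M[j, i] <- val
    EX[i, j] <- excl; EX[j, i] <- excl
    per[[paste(labels[i], labels[j], sep = "|")]] <- sims
  }
  diag(M) <- ifelse(is.na(diag(M)), NA_real_, 1)
  structure(list(mean = M, excluded = EX, per_molecule = per),
            class = "similarity_matrix")
}

#' Uniform-relevance baseline
#'
#' The attribution in which every atom carries the same importance,
#' normalized to unit L2 norm; the reference row of similarity
#' comparisons.
#' @param n_atoms Number of atoms (>= 1).
#' @return Constant vector of length `n_atoms` with unit norm.
#' @export
uniform_baseline <- function(n_atoms) {
  stopifnot(n_atoms >= 1)
  rep(1 / sqrt(n_atoms), n_atoms)
}

#' Project latent vectors onto principal components of a fitting set
#'
#' The orthonormal basis (and centering) is estimated on the fitting set
#' only; all rows are then projected with that fixed basis, so evaluation
#' sets share the fitted coordinate frame.
#'
#' @param latents Numeric matrix (molecules x d) of pooled latent vectors.
#' @param fit_idx Row indices of the fitting (e.g. validation) set;
#'   at least 2.
#' @param n_components Number of components to keep (default 2).
#' @return A `latent_projection`: list with `coords` (all rows projected),
#'   `basis`, `center` and `explained_variance` shares.
#' @export
project_latents <- function(latents, fit_idx, n_components = 2L) {
  X <- as.matrix(latents)
  stopifnot(length(fit_idx) >= 2)
  pc <- stats::prcomp(X[fit_idx, , drop = FALSE], center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$rotation))
  basis <- pc$rotation[, seq_len(nc), drop = FALSE]
  coords <- sweep(X, 2, pc$center) %*% basis
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = coords, basis = basis, center = pc$center,
                 explained_variance = ev[seq_len(nc)], fit_idx = fit_idx),
            class = "latent_projection")
}

#' Select exemplar molecules by k-means in projection space
#'
#' Clusters projected coordinates with k-means (fixed seed, 10 restarts)
#' and returns, per cluster, the molecules nearest its centroid — the
#' selection scheme used to pick representative compounds for attribution
#' visualisation (defaults: 4 clusters, 12 compounds each).
#'
#' @param points Numeric matrix of projected coordinates.
#' @param k Number of clusters (default 4).
#' @param n_per_cluster Exemplars per cluster (default 12); clusters
#'   smaller than this return all members with a warning.
#' @param seed Seed for the k-means restarts.
#' @return List of integer index vectors, one per cluster, ordered by
#'   distance to the centroid.
#' @export
select_exemplars <- function(points, k = 4L, n_per_cluster = 12L, seed = 0L) {
  X <- as.matrix(points)
  stopifnot(k >= 1, nrow(X) >= k)
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 10))
  lapply(seq_len(k), function(cl) {
    members <- which(km$cluster == cl)
    d2 <- rowSums((X[members, , drop = FALSE] -
                     matrix(km$centers[cl, ], length(members), ncol(X), byrow = TRUE))^2)
    ord <- members[order(d2)]
    if (length(ord) < n_per_cluster) {
      warning(sprintf("cluster %d has only %d members (< %d requested)",
                      cl, length(ord), n_per_cluster), call. = FALSE)
      ord
    } else {
      ord[seq_len(n_per_cluster)]
    }
  })
}
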