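#' Principal component analysis of a functional profile
#'
#' Column-centers the relative abundance matrix and projects samples onto the
#' top eigenvectors of the sample covariance.
#'
#' @param p A `functional_profile` in relative units.
#' @param n_components Number of components to return; at most
#'   `min(n_samples - 1, n_functions)`.
#' @return List of class `pca_result`: `scores` (sample x component),
#'   `explained_fraction` (per-component fraction of total variance, over all
#'   non-null components), `rotation`.
#' @export
fp_pca <- function(p, n_components = 2) {
  stopifnot(inherits(p, "functional_profile"))
  if (p$unit != "relative") stop("`p` must be in relative units")
  X <- p$values
  if (nrow(X) < 2) stop("need at least 2 samples")
  maxc <- min(nrow(X) - 1, ncol(X))
  if (n_components > maxc)
    stop(sprintf("n_components (%d) exceeds min(n_samples-1, n_functions) = %d",
                 n_components, maxc))
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  frac <- ev / sum(ev)
  structure(list(scores = pr$x[, seq_len(n_components), drop = FALSE],
                 explained_fraction = frac[seq_len(n_components)],
                 all_explained = frac,
                 rotation = pr$rotation[, seq_len(n_components), drop = FALSE]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$explained_fraction)))
  invisible(x)
}

# internal: total dissimilarity of each point to its nearest medoid
pam_objective <- function(d, medoids) sum(apply(d[, medoids, drop = FALSE], 1, min))

#' Partitioning around medoids (k-medoids) clustering
#'
#' Deterministic PAM: greedy BUILD seeding followed by SWAP local search that
#' repeatedly applies the best medoid/non-medoid exchange lowering the total
#' within-cluster dissimilarity, until no exchange improves. Ties between
#' equal-objective swaps are broken by the lexicographically smallest
#' (medoid index, candidate index) pair, so the result depends only on the
#' dissimilarity matrix and `k`.
#'
#' @param d Symmetric non-negative dissimilarity matrix with zero diagonal
#'   (a `dist` object is accepted).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Accepted for interface stability; the algorithm is
#'   deterministic and does not consume randomness.
#' @return List of class `cluster_assignment`: `labels` (cluster index in
#'   1..k per sample, clusters numbered by ascending medoid index),
#'   `medoids` (sample indices), `objective`.
#' @export
pam_cluster <- function(d, k, seed = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be a square matrix")
  if (any(abs(d - t(d)) > 1e-8)) stop("`d` must be symmetric")
  if (any(diag(d) != 0)) stop("`d` must have a zero diagonal")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  n <- nrow(d)
  if (k < 1 || k > n) stop("`k` must lie in 1..n")

  # BUILD: first medoid minimizes total distance; then greedily add the point
  # giving the largest objective decrease (smallest index on ties)
  medoids <- unname(which.min(colSums(d)))
  while (length(medoids) < k) {
    nearest <- apply(d[, medoids, drop = FALSE], 1, min)
    cand <- setdiff(seq_len(n), medoids)
    gain <- vapply(cand, function(h) sum(pmax(nearest - d[, h], 0)), numeric(1))
    medoids <- c(medoids, cand[which.max(gain)])
  }

  # SWAP: best-improvement exchanges, lexicographic tie-break
  obj <- pam_objective(d, medoids)
  repeat {
    best <- NULL
    best_obj <- obj
    for (m in sort(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        trial <- c(setdiff(medoids, m), h)
        o <- pam_objective(d, trial)
        if (o < best_obj - 1e-12) {
          best_obj <- o
          best <- c(m, h)
        }
      }
    }
    if (is.null(best)) break
    medoids <- c(setdiff(medoids, best[1]), best[2])
    obj <- best_obj
  }

  medoids <- sort(unname(medoids))
  labels <- apply(d[, medoids, drop = FALSE], 1, which.min)
  labels[medoids] <- seq_along(medoids)  # each medoid belongs to its own cluster
  structure(list(labels = as.integer(labels), medoids = medoids,
                 objective = pam_objective(d, medoids)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k=%d, n=%d, objective=%.4g\n",
              length(x$medoids), length(x$labels), x$objective))
  invisible(x)
}

#' Cross-tabulate cluster assignment against study groups
#'
#' @param c A `cluster_assignment` (or an integer label vector).
#' @param groups Per-sample group labels, same length.
#' @return Cluster x group contingency table of counts.
#' @export
cluster_group_crosstab <- function(c, groups) {
  labels <- if (inherits(c, "cluster_assignment")) c$labels else c
  if (length(labels) != length(groups)) stop("label/group length mismatch")
  table(cluster = labels, group = groups)
}

#' Cluster samples by functional composition (PCA then PAM)
#'
#' Convenience wrapper for the standard route: PCA of the relative-abundance
#' profile, Euclidean distance on the components retained to reach at least
#' `var_target` explained variance (or on raw profiles / correlation
#' dissimilarity), then PAM.
#'
#' @param p A `functional_profile`.
#' @param k Number of clusters (default 3).
#' @param space `"pca"` (default), `"raw"`, or `"correlation"`
#'   (1 - Spearman correlation between samples).
#' @param var_target Explained-variance target for PCA component retention.
#' @param seed Passed to [pam_cluster()].
#' @return List with `assignment` ([pam_cluster()] result), `pca` (when used),
#'   `crosstab` (cluster x group table), `n_components`.
#' @export
cluster_profiles <- function(p, k = 3, space = c("pca", "raw", "correlation"),
                             var_target = 0.95, seed = NULL) {
  stopifnot(inherits(p, "functional_profile"))
  space <- match.arg(space)
  rel <- functional_profile(rel_values(p), p$group, unit = "relative")
  pca <- NULL; ncomp <- NA_integer_
  if (space == "pca") {
    maxc <- min(nrow(rel$values) - 1, ncol(rel$values))
    full <- fp_pca(rel, n_components = maxc)
    ncomp <- which(cumsum(full$all_explained) >= var_target)[1]
    if (is.na(ncomp)) ncomp <- maxc
    d <- stats::dist(full$scores[, seq_len(ncomp), drop = FALSE])
    pca <- full
  } else if (space == "raw") {
    d <- stats::dist(rel$values)
  } else {
    d <- stats::as.dist(1 - stats::cor(t(rel$values), method = "spearman"))
  }
  a <- pam_cluster(as.matrix(d), k = k, seed = seed)
  list(assignment = a, pca = pca,
       crosstab = cluster_group_crosstab(a, as.character(p$group)),
       n_components = ncomp)
}

#' Silhouette-guided scan over the number of clusters
#'
#' @param d Dissimilarity matrix.
#' @param ks Candidate cluster counts (default 2..8).
#' @return Data frame with `k`, `objective` and mean silhouette width per k.
#' @export
pam_scan_k <- function(d, ks = 2:8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  res <- lapply(ks, function(k) {
    a <- pam_cluster(d, k)
    data.frame(k = k, objective = a$objective,
               mean_silhouette = mean_silhouette(d, a$labels))
  })
  do.call(rbind, res)
}

# internal: mean silhouette width for a labeling
mean_silhouette <- function(d, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    other <- setdiff(unique(labels), labels[i])
    if (!length(other)) { s[i] <- 0; next }
    b <- min(vapply(other, function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
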