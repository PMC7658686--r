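# shared fixtures and independent oracles

make_profile <- function(values, group, unit = "counts") {
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("COG%04d", seq_len(ncol(values)))
  functional_profile(values, group = group, unit = unit)
}

random_counts <- function(n, j, seed = 1, lambda = 50) {
  set.seed(seed)
  matrix(rpois(n * j, lambda) + 1, nrow = n,
         dimnames = list(paste0("s", seq_len(n)), sprintf("COG%04d", seq_len(j))))
}

# exhaustive k-medoids: minimum objective over all medoid subsets
brute_force_pam_objective <- function(d, k) {
  n <- nrow(d)
  combos <- utils::combn(n, k)
  best <- Inf
  for (i in seq_len(ncol(combos))) {
    o <- sum(apply(d[, combos[, i], drop = FALSE], 1, min))
    if (o < best) best <- o
  }
  best
}

# bundled small clustering instances (n <= 8): separated 1-D runs and 2-D
# blobs, the regime k-medoids is meant for
bundled_pam_instances <- function() {
  inst <- list(
    list(d = as.matrix(dist(c(0, 0.1, 0.2, 10, 10.1, 20, 20.2))), k = 3),
    list(d = as.matrix(dist(c(0, 1, 2, 10, 11, 12, 13))), k = 2),
    list(d = as.matrix(dist(c(0, 0.5, 5, 5.5, 11, 11.5))), k = 3))
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  for (seed in 1:5) {
    set.seed(seed)
    X <- do.call(rbind, lapply(1:3, function(i)
      sweep(matrix(rnorm(4, sd = 0.8), 2), 2, centers[i, ], "+")))
    inst[[length(inst) + 1]] <- list(d = as.matrix(dist(X)), k = 3)
    inst[[length(inst) + 1]] <- list(d = as.matrix(dist(X)), k = 2)
  }
  inst
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# exact two-sided Spearman p-value by full permutation enumeration (n <= 7)
exact_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- gtools_permutations(n)
  rx <- rank(x)
  robs <- abs(cor(rx, rank(y)))
  rhos <- apply(perms, 1, function(pm) abs(cor(rx, rank(y)[pm])))
  mean(rhos >= robs - 1e-12)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}
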