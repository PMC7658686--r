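# One-way ANOVA F statistics for every column of X under a given labeling.
# Vectorized across functions: group means via rowsum(), between/within
# decomposition in matrix form. Returns NaN for zero-variance columns.
anova_f_vec <- function(X, lab, gsizes) {
  n <- nrow(X); G <- length(gsizes)
  M <- rowsum(X, lab) / gsizes            # G x J group means
  mbar <- colMeans(X)
  ssb <- colSums(gsizes * (M - rep(mbar, each = G))^2)
  sst <- colSums(X^2) - n * mbar^2
  ssw <- pmax(sst - ssb, 0)
  (ssb / (G - 1)) / (ssw / (n - G))
}

# Enumerate all distinct assignments of a multiset of group labels and apply
# FUN to each label vector. Used by exhaustive-mode permutation tests.
for_each_label_assignment <- function(gsizes, FUN) {
  n <- sum(gsizes)
  recurse <- function(free, gi, lab) {
    if (gi == length(gsizes)) {
      lab[free] <- gi
      FUN(lab)
      return(invisible(NULL))
    }
    picks <- utils::combn(length(free), gsizes[gi])
    for (j in seq_len(ncol(picks))) {
      lab2 <- lab
      lab2[free[picks[, j]]] <- gi
      recurse(free[-picks[, j]], gi + 1L, lab2)
    }
  }
  recurse(seq_len(n), 1L, integer(n))
}

n_label_assignments <- function(gsizes) {
  exp(lgamma(sum(gsizes) + 1) - sum(lgamma(gsizes + 1)))
}

#' Permutational one-way ANOVA across functions
#'
#' For every function, computes the classical one-way ANOVA F statistic on
#' the observed group labels and calibrates it against the permutation null:
#' group labels are shuffled and each shuffled labeling is applied
#' identically to all functions (one label vector per randomization, so the
#' cross-function dependence of the null draws mirrors that of the data). In
#' sampled mode the p-value is `(b + 1) / (B + 1)` with `b` the number of
#' null F values at or above the observed one; exhaustive mode enumerates all
#' distinct label assignments (allowed when their number is at most 1e5) and
#' reports the exact proportion.
#'
#' Zero-variance (constant) functions have an undefined F; they are skipped
#' with a warning and reported with `F = NA`, `p_perm = 1`, `q = 1` and
#' `constant = TRUE`.
#'
#' @param p A `functional_profile`; counts are converted to relative
#'   abundances internally.
#' @param n_perm Number of random label permutations (sampled mode).
#' @param seed Integer seed; identical seeds give identical p-value vectors.
#' @param mode `"sampled"` or `"exhaustive"`.
#' @return A data frame of class `diff_test` with columns `function_id`, `F`,
#'   `p_perm`, `q` (Benjamini-Hochberg across non-constant functions),
#'   `constant`, and one `mean_<group>` column of group-mean relative
#'   abundances per group. Attributes record `n_perm` and `mode`.
#' @export
permutation_anova <- function(p, n_perm = 1000, seed = 1L,
                              mode = c("sampled", "exhaustive")) {
  stopifnot(inherits(p, "functional_profile"))
  mode <- match.arg(mode)
  X <- rel_values(p)
  g <- droplevels(p$group)
  gsizes <- as.integer(table(g))
  if (length(gsizes) < 2) stop("need at least 2 groups")
  if (any(gsizes < 2)) stop("every group needs at least 2 samples")
  if (mode == "sampled" && n_perm < 99)
    warning("n_perm < 99 gives a very coarse p-value grid")

  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    warning(sprintf("%d constant function(s) excluded from testing", sum(const)))
  Xt <- X[, !const, drop = FALSE]
  lab <- as.integer(g)

  M <- rowsum(X, lab) / gsizes
  rownames(M) <- levels(g)

  Fobs_all <- rep(NA_real_, ncol(X))
  p_all <- rep(1, ncol(X))
  q_all <- rep(1, ncol(X))

  if (ncol(Xt) > 0) {
    Fobs <- anova_f_vec(Xt, lab, gsizes)
    eps <- 1e-8 * pmax(1, Fobs)
    b <- numeric(ncol(Xt))
    if (mode == "exhaustive") {
      B <- n_label_assignments(gsizes)
      if (B > 1e5)
        stop(sprintf("exhaustive enumeration infeasible: %.3g distinct assignments", B))
      for_each_label_assignment(gsizes, function(lb) {
        Fp <- anova_f_vec(Xt, lb, gsizes)
        b <<- b + (Fp >= Fobs - eps)
      })
      pv <- b / B
    } else {
      set.seed(seed)
      for (it in seq_len(n_perm)) {
        lb <- sample(lab)
        Fp <- anova_f_vec(Xt, lb, gsizes)
        b <- b + (Fp >= Fobs - eps)
      }
      pv <- (b + 1) / (n_perm + 1)
    }
    Fobs_all[!const] <- Fobs
    p_all[!const] <- pv
    q_all[!const] <- bh_fdr(pv)
  }

  out <- data.frame(function_id = colnames(X), F = Fobs_all, p_perm = p_all,
                    q = q_all, constant = const, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (lev in levels(g)) out[[paste0("mean_", lev)]] <- M[lev, ]
  attr(out, "n_perm") <- if (mode == "sampled") n_perm else NA_integer_
  attr(out, "mode") <- mode
  attr(out, "groups") <- levels(g)
  class(out) <- c("diff_test", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values via the standard min-cummin construction.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values of the same length, each in (0, 1].
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pairwise Wilcoxon rank-sum contrasts between two groups
#'
#' Two-sided rank-sum test per function between the two named groups, with
#' exact null enumeration when the combined sample size is at most
#' `exact_threshold` and the data are untied, and the tie-corrected normal
#' approximation otherwise. Fully tied data carry no ordering information and
#' are reported with p = 1.
#'
#' @param p A `functional_profile`.
#' @param pair Character vector of two group labels.
#' @param exact_threshold Combined-n ceiling for the exact null.
#' @return Data frame of class `pairwise_test`: `function_id`, `W`, `p`, `q`
#'   (BH across functions), plus the two group means.
#' @export
pairwise_ranksum <- function(p, pair, exact_threshold = 50) {
  stopifnot(inherits(p, "functional_profile"), length(pair) == 2)
  g <- as.character(p$group)
  if (!all(pair %in% g)) stop("unknown group label: ",
                              paste(setdiff(pair, g), collapse = ", "))
  X <- rel_values(p)
  xi <- g == pair[1]; yi <- g == pair[2]
  if (sum(xi) < 2 || sum(yi) < 2) stop("both groups need at least 2 samples")
  res <- t(apply(X, 2, function(v) {
    x <- v[xi]; y <- v[yi]
    pooled <- c(x, y)
    if (max(pooled) == min(pooled))
      return(c(W = length(x) * length(y) / 2, p = 1))
    use_exact <- (length(pooled) <= exact_threshold) && !anyDuplicated(pooled)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact))
    c(W = unname(wt$statistic), p = wt$p.value)
  }))
  out <- data.frame(function_id = colnames(X), W = res[, "W"], p = res[, "p"],
                    q = bh_fdr(res[, "p"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[[paste0("mean_", pair[1])]] <- colMeans(X[xi, , drop = FALSE])
  out[[paste0("mean_", pair[2])]] <- colMeans(X[yi, , drop = FALSE])
  attr(out, "pair") <- pair
  class(out) <- c("pairwise_test", "data.frame")
  out
}

#' Functions significant and maximally abundant in a given group
#'
#' Filters a [permutation_anova()] result to the functions with `q <
#' alpha_q` whose group-mean relative abundance is highest in `group`.
#'
#' @param results A `diff_test` data frame.
#' @param group Group label.
#' @param alpha_q FDR threshold (default 0.05).
#' @return The filtered `diff_test` rows (with the per-group means).
#' @export
enriched_in <- function(results, group, alpha_q = 0.05) {
  stopifnot(inherits(results, "diff_test"))
  groups <- attr(results, "groups")
  if (!group %in% groups) stop("unknown group: ", group)
  mcols <- paste0("mean_", groups)
  M <- as.matrix(results[, mcols])
  ismax <- max.col(M, ties.method = "first") == match(group, groups)
  results[!results$constant & results$q < alpha_q & ismax, , drop = FALSE]
}

#' @export
print.diff_test <- function(x, ...) {
  cat(sprintf("<diff_test> %d functions (%s mode), %d with q < 0.05\n",
              nrow(x), attr(x, "mode"), sum(x$q < 0.05, na.rm = TRUE)))
  NextMethod()
}
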