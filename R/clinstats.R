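#' Pearson chi-square test of independence
#'
#' Classical chi-square on a contingency table, without continuity
#' correction by default (matching cohort sex-by-group comparisons).
#'
#' @param counts Matrix (or table) of non-negative integer counts, at least
#'   2 x 2, with no zero row or column margin.
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Classical one-way ANOVA
#'
#' Equal-variance between/within decomposition: `F = MSB / MSW` with degrees
#' of freedom `(g - 1, n - g)`.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length; at least 2 groups with at least
#'   2 observations each.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = ft$p.value)
}

#' Per-group mean and standard error summaries
#'
#' The cohort-table convention: mean plus SEM, with SEM the sample standard
#' deviation (n - 1 denominator) over the square root of n. Groups of size 1
#' report `NA` SEM.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return Data frame with `group`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (!length(values)) stop("empty input")
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    v <- values[g == lev & !is.na(values)]
    data.frame(group = lev, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Cohort summary table (group statistics per clinical index)
#'
#' For every clinical index: per-group n / mean / SEM and the one-way ANOVA
#' F and p across groups.
#'
#' @param clinical A [clinical_table()].
#' @return Data frame, one row per (index, group), with the index-level F and
#'   p repeated on each row.
#' @export
cohort_table <- function(clinical) {
  stopifnot(inherits(clinical, "clinical_table"))
  out <- lapply(colnames(clinical$indices), function(ix) {
    v <- clinical$indices[[ix]]
    s <- group_summary(v, clinical$group)
    ok <- !is.na(v)
    a <- tryCatch(one_way_anova(v[ok], clinical$group[ok]),
                  error = function(e) list(F = NA_real_, p = NA_real_))
    s$index <- ix; s$F <- a$F; s$p <- a$p
    s
  })
  do.call(rbind, out)[, c("index", "group", "n", "mean", "sem", "F", "p")]
}

#' Feature-by-clinical-index Spearman correlation screen
#'
#' Computes Spearman r and two-sided p for every (feature, index) pair over
#' the chosen sample subset, handling missing clinical values
#' pairwise-complete. Pairs with fewer than 4 complete observations are
#' reported as not assessable (`NA`). The significance mask marks `p <
#' alpha`.
#'
#' @param features A `functional_profile` or a numeric sample x feature
#'   matrix (e.g. a metabolite table) with row names matching the clinical
#'   table.
#' @param clinical A [clinical_table()].
#' @param subset A group label, or `"all"` (default) for every sample.
#' @param alpha Significance level for the mask (default 0.05).
#' @return Object of class `correlation_screen`: matrices `r`, `p`,
#'   `mask` (features x indices), `n` (complete observations), `alpha`.
#' @export
correlate_with_clinical <- function(features, clinical, subset = "all",
                                    alpha = 0.05) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (inherits(features, "functional_profile")) {
    check_aligned(features, clinical)
    X <- rel_values(features)
  } else {
    X <- as.matrix(features)
    if (!identical(rownames(X), clinical$sample_ids))
      stop("feature rows and clinical table sample IDs do not align")
  }
  keep <- if (identical(subset, "all")) rep(TRUE, length(clinical$sample_ids))
          else as.character(clinical$group) == subset
  if (!any(keep)) stop("empty sample subset: ", subset)
  X <- X[keep, , drop = FALSE]
  idx <- clinical$indices[keep, , drop = FALSE]

  J <- ncol(X); K <- ncol(idx)
  r <- p <- nmat <- matrix(NA_real_, J, K,
                           dimnames = list(colnames(X), colnames(idx)))
  for (j in seq_len(J)) for (k in seq_len(K)) {
    st <- spearman_test(X[, j], idx[[k]])
    r[j, k] <- st$r; p[j, k] <- st$p; nmat[j, k] <- st$n
  }
  mask <- !is.na(p) & p < alpha
  structure(list(r = r, p = p, mask = mask, n = nmat, alpha = alpha),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> %d features x %d indices, %d significant at p < %g\n",
              nrow(x$r), ncol(x$r), sum(x$mask), x$alpha))
  invisible(x)
}
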