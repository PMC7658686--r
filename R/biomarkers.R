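# Spearman association between two vectors with pairwise-complete handling.
# Exact p below n = 8 (untied), t-approximation otherwise; NA below n = 4.
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4) return(list(r = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (max(x) == min(x) || max(y) == min(y))
    return(list(r = NA_real_, p = NA_real_, n = n))
  tied <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = (n < 8 && !tied)))
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Select functional biomarkers for one study group
#'
#' Applies the three-filter conjunction in order: (1) differential abundance
#' across groups (permutational ANOVA `p_perm < alpha_anova`); (2) clinical
#' relevance — within the target group's samples, Spearman correlation with
#' at least one clinical index at `p < alpha_corr` after the configured
#' multiplicity correction (Bonferroni over the indices tested per function,
#' by default); (3) highest group-mean relative abundance in the target
#' group.
#'
#' @param diff A [permutation_anova()] result over the same profile.
#' @param profile The `functional_profile` (all samples).
#' @param clinical A [clinical_table()] aligned with the profile.
#' @param group Target group label.
#' @param alpha_anova ANOVA p threshold (default 0.01).
#' @param alpha_corr Clinical-correlation p threshold (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"` for the per-function
#'   multiplicity correction over clinical indices.
#' @param indices Clinical index names to use (default: all columns).
#' @return Object of class `biomarker_panel`: `group`, `function_ids`,
#'   `evidence` (per-member p_perm, best index, its r and p, raw and
#'   corrected), thresholds.
#' @export
select_biomarkers <- function(diff, profile, clinical, group,
                              alpha_anova = 0.01, alpha_corr = 0.05,
                              correction = c("bonferroni", "none"),
                              indices = NULL) {
  stopifnot(inherits(diff, "diff_test"), inherits(profile, "functional_profile"),
            inherits(clinical, "clinical_table"))
  correction <- match.arg(correction)
  check_aligned(profile, clinical)
  if (!group %in% levels(profile$group)) stop("unknown group: ", group)
  if (is.null(indices)) indices <- colnames(clinical$indices)
  if (!length(indices)) stop("no clinical indices configured for group ", group)

  groups <- attr(diff, "groups")
  mcols <- paste0("mean_", groups)
  cand <- diff[!diff$constant & diff$p_perm < alpha_anova, , drop = FALSE]

  empty <- structure(list(group = group, function_ids = character(0),
                          evidence = NULL, alpha_anova = alpha_anova,
                          alpha_corr = alpha_corr, correction = correction),
                     class = "biomarker_panel")
  if (!nrow(cand)) return(empty)

  # the conjunction is order-independent; documented order kept for the
  # reported evidence: clinical screen on ANOVA survivors, then group-max
  insel <- profile$group == group
  X <- rel_values(profile)[insel, , drop = FALSE]
  idx <- clinical$indices[insel, indices, drop = FALSE]
  m <- length(indices)

  ev <- lapply(cand$function_id, function(f) {
    tests <- lapply(indices, function(ix) spearman_test(X[, f], idx[[ix]]))
    praw <- vapply(tests, function(t) ifelse(is.na(t$p), Inf, t$p), numeric(1))
    pcor <- if (correction == "bonferroni") pmin(praw * m, 1) else praw
    best <- which.min(pcor)
    data.frame(function_id = f, best_index = indices[best],
               r = tests[[best]]$r, p_raw = praw[best],
               p_corrected = min(pcor[best], 1),
               passes = pcor[best] < alpha_corr, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  cand <- cbind(cand, ev[, -1])
  cand <- cand[cand$passes, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  M <- as.matrix(cand[, mcols])
  ismax <- max.col(M, ties.method = "first") == match(group, groups)
  cand <- cand[ismax, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  structure(list(group = group, function_ids = cand$function_id,
                 evidence = cand[, c("function_id", "p_perm", "q",
                                     "best_index", "r", "p_raw", "p_corrected",
                                     mcols)],
                 alpha_anova = alpha_anova, alpha_corr = alpha_corr,
                 correction = correction),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> group %s: %d function(s)\n",
              x$group, length(x$function_ids)))
  if (length(x$function_ids)) print(utils::head(x$evidence, 10))
  invisible(x)
}

# Mann-Whitney AUC of scores for a logical positive-class indicator
auc_rank <- function(positive, scores) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# TPR at a grid of FPR values for one score vector (step-function ROC)
roc_tpr_at <- function(positive, scores, fpr_grid) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  vapply(fpr_grid, function(f) {
    i <- which(fpr <= f)
    if (!length(i)) 0 else max(tpr[i])
  }, numeric(1))
}

# stratified fold assignment: within each class, shuffle and deal into folds
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  fold
}

#' One-vs-rest random-forest discrimination with repeated five-fold CV
#'
#' Labels samples as the target group versus all others, runs stratified
#' k-fold cross-validation with a random forest fit on each training fold
#' only, scores the held-out samples, and repeats with re-randomized folds.
#' AUC is the Mann-Whitney statistic of held-out class probabilities; the
#' reported mean is the average over all fold-repeats. A ROC band (min/max
#' held-out TPR per FPR grid point across repeats) summarizes variability.
#'
#' @param profile A `functional_profile`.
#' @param group Target group label.
#' @param features Function IDs to use (or a `biomarker_panel`); default all.
#' @param n_folds Folds (default 5).
#' @param n_trees Trees per forest (default 500).
#' @param n_repeats Cross-validation repeats (default 100).
#' @param seed Integer seed; fixes fold assignments and forests.
#' @return Object of class `model_evaluation`: `fold_aucs` (repeats x folds),
#'   `mean_auc`, `roc_band` (data frame fpr / tpr_mean / tpr_min / tpr_max),
#'   `n_folds`, `n_repeats`, `seed`.
#' @export
train_discriminator <- function(profile, group, features = NULL, n_folds = 5,
                                n_trees = 500, n_repeats = 100, seed = 1L) {
  stopifnot(inherits(profile, "functional_profile"))
  if (inherits(features, "biomarker_panel")) features <- features$function_ids
  if (!group %in% levels(profile$group)) stop("unknown group: ", group)
  X <- rel_values(profile)
  if (!is.null(features)) {
    if (!length(features)) stop("empty feature panel")
    X <- X[, features, drop = FALSE]
  }
  y <- factor(ifelse(profile$group == group, "case", "rest"),
              levels = c("rest", "case"))
  if (min(table(y)) < n_folds)
    stop("a class has fewer members than folds; reduce n_folds")

  set.seed(seed)
  fpr_grid <- seq(0, 1, by = 0.02)
  fold_aucs <- matrix(NA_real_, n_repeats, n_folds)
  tpr_rep <- matrix(NA_real_, n_repeats, length(fpr_grid))
  for (rep_i in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds)
    scores <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                       ntree = n_trees)
      pr <- stats::predict(rf, X[!tr, , drop = FALSE], type = "prob")[, "case"]
      scores[!tr] <- pr
      fold_aucs[rep_i, f] <- auc_rank(y[!tr] == "case", pr)
    }
    tpr_rep[rep_i, ] <- roc_tpr_at(y == "case", scores, fpr_grid)
  }
  roc_band <- data.frame(fpr = fpr_grid,
                         tpr_mean = colMeans(tpr_rep),
                         tpr_min = apply(tpr_rep, 2, min),
                         tpr_max = apply(tpr_rep, 2, max))
  structure(list(group = group, fold_aucs = fold_aucs,
                 mean_auc = mean(fold_aucs), roc_band = roc_band,
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> group %s: mean AUC %.3f over %d x %d-fold CV\n",
              x$group, x$mean_auc, x$n_repeats, x$n_folds))
  invisible(x)
}

#' Leakage-audited discrimination: select biomarkers inside each training fold
#'
#' The default pipeline selects biomarkers on the full cohort and then
#' cross-validates only the classifier, which leaks selection information
#' into the evaluation. This audit re-runs the full selection (permutational
#' ANOVA and clinical-correlation screen restricted to the training samples)
#' inside every training fold and evaluates on the untouched test fold. A
#' fold whose training selection is empty scores its test samples with a
#' constant, i.e. AUC 0.5.
#'
#' @param profile,clinical,group As in [select_biomarkers()].
#' @param alpha_anova,alpha_corr,correction Selection thresholds.
#' @param n_perm ANOVA permutations inside each fold.
#' @param n_folds,n_trees,n_repeats,seed As in [train_discriminator()].
#' @return A `model_evaluation` with an extra `panel_sizes` matrix (selected
#'   panel size per repeat x fold).
#' @export
audit_discriminator <- function(profile, clinical, group,
                                alpha_anova = 0.01, alpha_corr = 0.05,
                                correction = "bonferroni", n_perm = 199,
                                n_folds = 5, n_trees = 500, n_repeats = 5,
                                seed = 1L) {
  stopifnot(inherits(profile, "functional_profile"))
  check_aligned(profile, clinical)
  X <- rel_values(profile)
  y <- factor(ifelse(profile$group == group, "case", "rest"),
              levels = c("rest", "case"))
  if (min(table(y)) < n_folds)
    stop("a class has fewer members than folds; reduce n_folds")

  set.seed(seed)
  fold_seeds <- sample.int(2^31 - 1, n_repeats * n_folds)
  fold_aucs <- matrix(NA_real_, n_repeats, n_folds)
  panel_sizes <- matrix(0L, n_repeats, n_folds)
  si <- 0
  for (rep_i in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds)
    for (f in seq_len(n_folds)) {
      si <- si + 1
      tr <- fold != f
      sub <- subset_profile(profile, samples = tr)
      subcl <- clinical_table(clinical$sample_ids[tr], clinical$group[tr],
                              clinical$indices[tr, , drop = FALSE])
      dt <- suppressWarnings(
        permutation_anova(sub, n_perm = n_perm, seed = fold_seeds[si]))
      panel <- select_biomarkers(dt, sub, subcl, group,
                                 alpha_anova = alpha_anova,
                                 alpha_corr = alpha_corr,
                                 correction = correction)
      panel_sizes[rep_i, f] <- length(panel$function_ids)
      if (!length(panel$function_ids)) {
        fold_aucs[rep_i, f] <- 0.5
        next
      }
      rf <- randomForest::randomForest(X[tr, panel$function_ids, drop = FALSE],
                                       y[tr], ntree = n_trees)
      pr <- stats::predict(rf, X[!tr, panel$function_ids, drop = FALSE],
                           type = "prob")[, "case"]
      fold_aucs[rep_i, f] <- auc_rank(y[!tr] == "case", pr)
    }
  }
  structure(list(group = group, fold_aucs = fold_aucs,
                 mean_auc = mean(fold_aucs), roc_band = NULL,
                 panel_sizes = panel_sizes,
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed),
            class = "model_evaluation")
}
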