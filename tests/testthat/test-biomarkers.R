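# small planted scenario reused across selection tests: one function enriched
# in IBS-D and linked to a clinical index, one enriched only
planted_dataset <- function(seed, link_strength = 0.8) {
  generate_dataset(simulation_config(
    n_functions = 60, depth = 1e4, seed = seed,
    enrichments = data.frame(function_id = c("COG0001", "COG0002"),
                             group = c("IBS-D", "IBS-D"), fold = c(5, 5)),
    clinical_links = data.frame(index = "IBS_SSS", function_id = "COG0001",
                                sign = 1, strength = link_strength),
    clinical_indices = c("IBS_SSS", "SDS")))
}

test_that("selection applies the ANOVA, clinical and group-max filters in turn", {
  ds <- planted_dataset(31)
  rel <- normalize_relative(ds$profile)
  dt <- permutation_anova(rel, n_perm = 999, seed = 1)
  panel <- select_biomarkers(dt, rel, ds$clinical, "IBS-D")
  expect_s3_class(panel, "biomarker_panel")
  expect_true("COG0001" %in% panel$function_ids)
  expect_false("COG0002" %in% panel$function_ids)
  expect_true(all(panel$evidence$p_perm < 0.01))

  # nothing passes an impossible ANOVA threshold
  none <- select_biomarkers(dt, rel, ds$clinical, "IBS-D", alpha_anova = 1e-9)
  expect_length(none$function_ids, 0)

  # the linked function is NOT selected for a group where it is not maximal
  other <- select_biomarkers(dt, rel, ds$clinical, "HC")
  expect_false("COG0001" %in% other$function_ids)
})

test_that("panel membership is monotone in both alpha thresholds", {
  ds <- planted_dataset(32)
  rel <- normalize_relative(ds$profile)
  dt <- permutation_anova(rel, n_perm = 499, seed = 2)
  tight <- select_biomarkers(dt, rel, ds$clinical, "IBS-D",
                             alpha_anova = 0.01, alpha_corr = 0.01)
  loose <- select_biomarkers(dt, rel, ds$clinical, "IBS-D",
                             alpha_anova = 0.05, alpha_corr = 0.2)
  expect_true(all(tight$function_ids %in% loose$function_ids))
})

test_that("Bonferroni correction is stricter than no correction", {
  ds <- planted_dataset(33, link_strength = 0.5)
  rel <- normalize_relative(ds$profile)
  dt <- permutation_anova(rel, n_perm = 499, seed = 3)
  bon <- select_biomarkers(dt, rel, ds$clinical, "IBS-D", correction = "bonferroni")
  raw <- select_biomarkers(dt, rel, ds$clinical, "IBS-D", correction = "none")
  expect_true(all(bon$function_ids %in% raw$function_ids))
})

test_that("the rank AUC matches hand-computed values", {
  pos <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(cogmwas:::auc_rank(pos, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(cogmwas:::auc_rank(pos, c(0.9, 0.8, 0.2, 0.1)), 0)
  expect_equal(cogmwas:::auc_rank(pos, c(0.5, 0.5, 0.5, 0.5)), 0.5)
  # 3 of 4 positive/negative pairs correctly ordered
  expect_equal(cogmwas:::auc_rank(c(TRUE, FALSE, TRUE, FALSE),
                                  c(0.9, 0.8, 0.2, 0.1)), 0.75)
})

test_that("a perfectly separating feature yields mean AUC 1", {
  n <- 40
  x <- c(runif(20, 0.6, 0.9), runif(20, 0.1, 0.4))
  X <- cbind(f1 = x, f2 = 1 - x)
  rownames(X) <- paste0("s", 1:n)
  p <- functional_profile(X / rowSums(X), group = rep(c("case", "rest"), each = 20),
                          unit = "relative")
  ev <- train_discriminator(p, "case", n_trees = 100, n_repeats = 3, seed = 1)
  expect_equal(ev$mean_auc, 1)
  expect_equal(ev$mean_auc, mean(ev$fold_aucs), tolerance = 1e-12)
  expect_true(all(ev$fold_aucs >= 0 & ev$fold_aucs <= 1))
})

test_that("pure-noise features give chance-level AUC", {
  set.seed(44)
  X <- matrix(rexp(200 * 5), 200)
  rownames(X) <- paste0("s", 1:200)
  colnames(X) <- paste0("f", 1:5)
  p <- functional_profile(X / rowSums(X), group = rep(c("a", "b"), 100),
                          unit = "relative")
  ev <- train_discriminator(p, "a", n_trees = 100, n_repeats = 5, seed = 2)
  expect_gt(ev$mean_auc, 0.4)
  expect_lt(ev$mean_auc, 0.6)
})

test_that("evaluation is seed-deterministic and validates class sizes", {
  ds <- planted_dataset(35)
  rel <- normalize_relative(ds$profile)
  feats <- c("COG0001", "COG0002", "COG0003")
  e1 <- train_discriminator(rel, "IBS-D", feats, n_trees = 50, n_repeats = 2, seed = 9)
  e2 <- train_discriminator(rel, "IBS-D", feats, n_trees = 50, n_repeats = 2, seed = 9)
  expect_identical(e1$fold_aucs, e2$fold_aucs)
  expect_error(train_discriminator(rel, "IBS-D", feats, n_folds = 30),
               "fewer members")
  expect_error(train_discriminator(rel, "nope"), "unknown group")
})

test_that("the ROC band brackets the mean curve and is monotone", {
  ds <- planted_dataset(36)
  rel <- normalize_relative(ds$profile)
  ev <- train_discriminator(rel, "IBS-D", c("COG0001", "COG0002"),
                            n_trees = 100, n_repeats = 4, seed = 3)
  b <- ev$roc_band
  expect_true(all(b$tpr_min <= b$tpr_mean + 1e-12))
  expect_true(all(b$tpr_mean <= b$tpr_max + 1e-12))
  expect_true(all(diff(b$tpr_mean) >= -1e-12))
  expect_equal(b$tpr_mean[b$fpr == 1], 1)
})

test_that("leakage-audited evaluation runs selection inside the folds", {
  ds <- planted_dataset(37)
  ev <- audit_discriminator(normalize_relative(ds$profile), ds$clinical,
                            "IBS-D", n_perm = 99, n_trees = 50,
                            n_repeats = 2, seed = 5)
  expect_s3_class(ev, "model_evaluation")
  expect_equal(dim(ev$panel_sizes), c(2, 5))
  expect_true(all(ev$fold_aucs >= 0 & ev$fold_aucs <= 1))
})
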