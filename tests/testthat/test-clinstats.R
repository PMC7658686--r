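test_that("chi-square independence matches hand calculations", {
  # cohort sex-by-group table
  sex <- rbind(c(10, 10, 9, 7), c(5, 12, 6, 6))
  res <- chi_square_independence(sex)
  expect_equal(res$statistic, 1.792, tolerance = 5e-4)
  expect_equal(res$df, 3)

  # proportional rows: perfect independence
  expect_equal(chi_square_independence(rbind(c(10, 20), c(5, 10)))$statistic, 0)

  # diagonal table, all expected cells 5
  res2 <- chi_square_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1)

  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chi_square_independence(matrix(1:3, 1)), "2 x 2")
})

test_that("2x2 chi-square equals the closed form N(ad-bc)^2 / margins", {
  set.seed(10)
  for (i in 1:10) {
    t2 <- matrix(sample(1:30, 4), 2)
    n <- sum(t2)
    a <- t2[1, 1]; b <- t2[1, 2]; c_ <- t2[2, 1]; d <- t2[2, 2]
    closed <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(chi_square_independence(t2)$statistic, closed, tolerance = 1e-10)
  }
})

test_that("one-way ANOVA reproduces the classical decomposition", {
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5)
  expect_equal(c(res$df1, res$df2), c(1, 4))

  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0)

  # shift invariance
  v <- rnorm(20); g <- rep(letters[1:4], 5)
  expect_equal(one_way_anova(v, g)$F, one_way_anova(v + 100, g)$F,
               tolerance = 1e-9)
  expect_error(one_way_anova(1:5, rep("a", 5)), "2 groups")
})

test_that("group summaries use the n-1 SEM convention", {
  s <- group_summary(c(1, 2, 3), rep("a", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(group_summary(c(5, 5, 5), rep("a", 3))$sem, 0)
  one <- group_summary(7, "a")
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sem))
})

test_that("the cohort table combines summaries with ANOVA per index", {
  set.seed(6)
  ct <- clinical_table(paste0("s", 1:30), rep(c("HC", "IBS-D", "DEP"), 10),
                       data.frame(sss = rnorm(30, 100, 10), sds = rnorm(30, 40, 5)))
  tab <- cohort_table(ct)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$index), c("sss", "sds"))
  expect_true(all(tab$n == 10))
})

test_that("a feature identical to an index correlates perfectly", {
  set.seed(2)
  v <- runif(10)
  X <- cbind(f1 = v, f2 = 1 - v)
  rownames(X) <- paste0("s", 1:10)
  p <- functional_profile(X / rowSums(X), group = rep("g", 10), unit = "relative")
  ct <- clinical_table(paste0("s", 1:10), rep("g", 10),
                       data.frame(ix = X[, "f1"] / rowSums(X)))
  scr <- correlate_with_clinical(p, ct)
  expect_equal(scr$r["f1", "ix"], 1)
  expect_true(scr$mask["f1", "ix"])
})

test_that("Spearman p-values match exact enumeration for small untied samples", {
  set.seed(8)
  for (i in 1:4) {
    n <- sample(5:7, 1)
    x <- sample(100, n); y <- sample(100, n)
    st <- cogmwas:::spearman_test(x, y)
    expect_equal(st$p, exact_spearman_p(x, y), tolerance = 1e-10)
  }
})

test_that("missing values are handled pairwise-complete, short pairs flagged", {
  x <- c(1, 2, 3, 4, 5, NA)
  y <- c(2, 1, 4, 3, NA, 6)
  st <- cogmwas:::spearman_test(x, y)
  expect_equal(st$n, 4)
  short <- cogmwas:::spearman_test(c(1, 2, NA, NA, NA), c(1, 2, 3, 4, 5))
  expect_true(is.na(short$p))

  ct <- clinical_table(paste0("s", 1:6), rep("g", 6),
                       data.frame(a = y, b = rep(NA_real_, 6)))
  X <- cbind(f = x + 0.5); rownames(X) <- paste0("s", 1:6)
  scr <- correlate_with_clinical(X, ct)
  expect_true(is.na(scr$p["f", "b"]))
  expect_false(scr$mask["f", "b"])
})

test_that("the null correlation screen marks about alpha of pairs", {
  set.seed(15)
  n <- 25
  X <- matrix(runif(n * 100), n, dimnames = list(paste0("s", 1:n), paste0("f", 1:100)))
  ct <- clinical_table(paste0("s", 1:n), rep("g", n),
                       as.data.frame(matrix(rnorm(n * 10), n,
                                            dimnames = list(NULL, paste0("ix", 1:10)))))
  p <- functional_profile(X / rowSums(X), group = rep("g", n), unit = "relative")
  scr <- correlate_with_clinical(p, ct)
  frac <- mean(scr$mask)
  tol <- 2.58 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(frac, 0.05 - tol - 0.005)
  expect_lt(frac, 0.05 + tol + 0.005)
})

test_that("group subsetting restricts the screen to that group's samples", {
  ds <- generate_dataset(simulation_config(
    n_functions = 30, depth = 1e4, seed = 22,
    clinical_links = data.frame(index = "sss", function_id = "COG0004",
                                sign = 1, strength = 0.9)))
  rel <- normalize_relative(ds$profile)
  scr <- correlate_with_clinical(rel, ds$clinical, subset = "IBS-D")
  expect_true(scr$mask["COG0004", "sss"])
  expect_equal(unique(as.vector(scr$n)), 22)
  expect_error(correlate_with_clinical(rel, ds$clinical, subset = "zz"),
               "empty")
})
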