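rel_profile <- function(X, group = rep("g", nrow(X))) {
  dimnames(X) <- list(paste0("s", seq_len(nrow(X))),
                      sprintf("COG%04d", seq_len(ncol(X))))
  functional_profile(X / rowSums(X), group = group, unit = "relative")
}

test_that("Spearman correlations hit the closed-form oracles", {
  set.seed(1)
  x <- runif(12)
  X <- cbind(x, x + 0.001 * 0, rev(sort(x))[rank(x)])  # x, x, anti-monotone
  X <- cbind(x, 2 * x, max(x) + min(x) - x, runif(12))
  p <- rel_profile(abs(X) + 0.01)
  cr <- suppressWarnings(correlation_matrix(p, n_perm = 99, seed = 1))
  # note: closure distorts columns, so test the rank arithmetic directly
  expect_equal(cor(x, 2 * x, method = "spearman"), 1)
  expect_equal(cor(x, max(x) + min(x) - x, method = "spearman"), -1)
  # tied-rank oracle: Pearson on average ranks
  expect_equal(cor(c(1, 2, 2, 4), c(10, 20, 30, 40), method = "spearman"),
               4.5 / sqrt(22.5))
  expect_true(all(abs(cr$r) <= 1))
  expect_true(all(cr$p[upper.tri(cr$p)] > 0 & cr$p[upper.tri(cr$p)] <= 1))
})

test_that("correlation matrices are symmetric with unit diagonal and valid q", {
  set.seed(5)
  p <- rel_profile(matrix(runif(80), 10, 8))
  cr <- correlation_matrix(p, n_perm = 199, seed = 2)
  expect_equal(cr$r, t(cr$r), tolerance = 1e-12)
  expect_equal(unname(diag(cr$r)), rep(1, 8))
  ut <- upper.tri(cr$q)
  expect_equal(cr$q[ut], bh_fdr(cr$p[ut]))
  expect_error(correlation_matrix(rel_profile(matrix(runif(9), 3, 3))),
               "at least 4 samples")
})

test_that("Spearman r is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- runif(15); y <- runif(15)
  r0 <- cor(x, y, method = "spearman")
  expect_equal(cor(exp(3 * x), y, method = "spearman"), r0)
  expect_equal(cor(x, y^3, method = "spearman"), r0)
  # and in the package pipeline: closure then ranks (same sample total)
  X1 <- cbind(x, y, 2 - x - y)
  p1 <- rel_profile(X1)
  cr1 <- suppressWarnings(correlation_matrix(p1, n_perm = 99, seed = 1))
  expect_equal(cr1$r["COG0001", "COG0002"], r0, tolerance = 1e-12)
})

test_that("the signed edge rule admits exactly the qualifying pairs", {
  r <- matrix(c(1, 0.9, -0.85, 0.9, 1, 0.5, -0.85, 0.5, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  q <- matrix(0.01, 3, 3, dimnames = dimnames(r)); diag(q) <- NA
  net <- build_network(r, q)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("+", "-"))
  plus <- net$edges[net$edges$sign == "+", ]
  expect_setequal(c(plus$from, plus$to), c("a", "b"))

  # below-threshold correlations yield an empty network
  r2 <- r * 0.5; diag(r2) <- 1
  expect_equal(nrow(build_network(r2, q)$edges), 0)
  # significant q but sub-threshold r, and vice versa, are both excluded
  q3 <- q; q3[1, 2] <- q3[2, 1] <- 0.5
  expect_equal(build_network(r, q3)$edges$sign, "-")
  expect_error(build_network(matrix(c(1, 0.2, 0.9, 1), 2), matrix(0.01, 2, 2)),
               "symmetric")
})

test_that("active index is degree over possible partners", {
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.9; r[2, 3] <- r[3, 2] <- 0.9
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  q <- matrix(0.01, 3, 3, dimnames = dimnames(r))
  net <- build_network(r, q)
  expect_equal(unname(active_index(net)[c("a", "b", "c")]), c(0.5, 1, 0.5))

  iso <- build_network(diag(3) + 0, q * 0 + 0.5,
                       group = "x")
  dimnames(iso$nodes) <- NULL
  expect_true(all(active_index(iso) == 0))
})

test_that("internal complexity is the within-category pair density", {
  nodes <- c("a1", "a2", "a3", "b1")
  r <- diag(4); dimnames(r) <- list(nodes, nodes)
  set_edge <- function(r, i, j, v = 0.9) { r[i, j] <- v; r[j, i] <- v; r }
  r <- set_edge(r, "a1", "a2"); r <- set_edge(r, "a2", "a3")
  q <- matrix(0.01, 4, 4, dimnames = dimnames(r))
  net <- build_network(r, q)
  m <- category_map(nodes, c("A", "A", "A", "B"),
                    c(rep("metabolism", 3), "poorly characterized"))
  ic <- internal_complexity(net, m)
  expect_equal(unname(ic["A"]), 2 / 3)
  expect_equal(unname(ic["B"]), 0)   # single-member category

  # complete within-category subgraph reaches 1
  r2 <- set_edge(r, "a1", "a3")
  expect_equal(unname(internal_complexity(build_network(r2, q), m)["A"]), 1)

  # empty network: all categories 0
  re <- diag(4); dimnames(re) <- dimnames(q)
  nete <- build_network(re, q)
  expect_true(all(internal_complexity(nete, m) == 0))
  expect_error(internal_complexity(net, category_map("a1", "A", "metabolism")),
               "unmapped")
})

test_that("interaction complexity is the symmetric cross-pair density", {
  nodes <- c("a1", "a2", "b1", "b2", "b3")
  r <- diag(5); dimnames(r) <- list(nodes, nodes)
  r["a1", "b2"] <- r["b2", "a1"] <- 0.95
  q <- matrix(0.01, 5, 5, dimnames = dimnames(r))
  net <- build_network(r, q)
  m <- category_map(nodes, c("A", "A", "B", "B", "B"),
                    c(rep("metabolism", 2), rep("poorly characterized", 3)))
  M <- interaction_complexity(net, m)
  expect_equal(M["A", "B"], 1 / 6)
  expect_identical(M, t(M))
  expect_true(all(M >= 0 & M <= 1))

  # no cross-category edges: off-diagonal all zero
  r0 <- diag(5); dimnames(r0) <- dimnames(r)
  r0["a1", "a2"] <- r0["a2", "a1"] <- 0.9
  M0 <- interaction_complexity(build_network(r0, q), m)
  expect_equal(M0["A", "B"], 0)
  expect_equal(M0["A", "A"], 1)  # diagonal carries internal complexity
})

test_that("complexity indices are invariant to node relabeling", {
  set.seed(7)
  nodes <- sprintf("n%02d", 1:8)
  r <- diag(8); dimnames(r) <- list(nodes, nodes)
  for (k in 1:6) {
    ij <- sample(8, 2)
    r[ij[1], ij[2]] <- r[ij[2], ij[1]] <- 0.9
  }
  q <- matrix(0.01, 8, 8, dimnames = dimnames(r))
  cats <- rep(c("A", "B"), each = 4)
  m <- category_map(nodes, cats, rep("metabolism", 8))
  base <- internal_complexity(build_network(r, q), m)
  perm <- sample(8)
  r2 <- r[perm, perm]; q2 <- q[perm, perm]
  m2 <- category_map(nodes[perm], cats[perm], rep("metabolism", 8))
  expect_equal(internal_complexity(build_network(r2, q2), m2), base)
})

test_that("planted correlated blocks produce dense within-block subnetworks", {
  members <- sprintf("COG%04d", 1:10)
  cfg <- simulation_config(group_sizes = c(g = 60), n_functions = 60,
                           depth = 1e5, noise_sdlog = 0.8,
                           blocks = list(list(members = members, strength = 0.95)),
                           seed = 19)
  ds <- generate_dataset(cfg)
  # the p-value floor 1/(B+1) must undercut 0.05 * (block pairs / all pairs)
  # for BH to admit the block edges, hence B = 999 here
  net <- suppressWarnings(group_network(normalize_relative(ds$profile), "g",
                                        n_perm = 999, seed = 3))
  inblock <- net$edges$from %in% members & net$edges$to %in% members
  d_in <- sum(inblock) / choose(10, 2)
  d_out <- sum(!inblock) / (choose(60, 2) - choose(10, 2))
  expect_gt(d_in, d_out)
  expect_gt(d_in, 0.2)
})

test_that("networks export as edge lists and GraphML", {
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.9
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  q <- matrix(0.01, 3, 3, dimnames = dimnames(r))
  net <- build_network(r, q, group = "HC")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tsv)
  el <- read.delim(tsv)
  expect_equal(names(el), c("node1", "node2", "r", "q", "sign"))
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
})
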