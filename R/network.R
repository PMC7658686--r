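#' Spearman correlation matrix with permutation p-values
#'
#' Computes pairwise Spearman correlations (average ranks for ties) between
#' functions, a permutation p-value per pair, and Benjamini-Hochberg q-values
#' over the strict upper triangle. The null is generated by re-ordering the
#' samples of one side of every pair with a single shared permutation per
#' randomization: Spearman r equals the Pearson correlation of column ranks,
#' so each null draw is one cross-correlation of the permuted and unpermuted
#' rank matrices. p = (b + 1) / (B + 1) with b the number of null |r| at or
#' above the observed |r|.
#'
#' @param p A `functional_profile` (one group's samples, typically);
#'   constant functions are excluded with a warning.
#' @param method Only `"spearman"`.
#' @param n_perm Number of permutations (warning below 99).
#' @param seed Integer seed.
#' @return List of class `correlation_result`: `r`, `p`, `q` square matrices
#'   over the retained functions (diagonal: r = 1, p and q = NA).
#' @export
correlation_matrix <- function(p, method = "spearman", n_perm = 999, seed = 1L) {
  stopifnot(inherits(p, "functional_profile"))
  method <- match.arg(method, "spearman")
  X <- rel_values(p)
  if (nrow(X) < 4) stop("need at least 4 samples for correlation screening")
  if (n_perm < 99) warning("n_perm < 99 gives a very coarse p-value grid")
  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    warning(sprintf("%d constant function(s) excluded from correlation", sum(const)))
  X <- X[, !const, drop = FALSE]
  J <- ncol(X); n <- nrow(X)
  if (J < 2) stop("need at least 2 non-constant functions")

  R <- apply(X, 2, rank)                      # average ranks for ties
  Rs <- scale(R)                              # standardized ranks
  robs <- crossprod(Rs) / (n - 1)
  robs[robs > 1] <- 1; robs[robs < -1] <- -1

  set.seed(seed)
  b <- matrix(0, J, J)
  aobs <- abs(robs) - 1e-12
  for (it in seq_len(n_perm)) {
    perm <- sample.int(n)
    rnull <- crossprod(Rs[perm, , drop = FALSE], Rs) / (n - 1)
    b <- b + (abs(rnull) >= aobs)
  }
  b <- (b + t(b)) / 2                          # symmetrize pair counts
  P <- (b + 1) / (n_perm + 1)
  diag(P) <- NA_real_
  diag(robs) <- 1

  Q <- matrix(NA_real_, J, J)
  ut <- upper.tri(P)
  Q[ut] <- bh_fdr(P[ut])
  Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
  dimnames(robs) <- dimnames(P) <- dimnames(Q) <- list(colnames(X), colnames(X))
  structure(list(r = robs, p = P, q = Q, n_perm = n_perm),
            class = "correlation_result")
}

#' Build a signed co-occurrence network from correlation matrices
#'
#' An edge joins two functions when the correlation magnitude and FDR both
#' pass their thresholds: positive edges need `r >= r_threshold` and `q <
#' q_threshold`, negative edges `r <= -r_threshold` and `q < q_threshold`.
#'
#' @param r Symmetric correlation matrix (or a `correlation_result`, in
#'   which case `q` is taken from it).
#' @param q Symmetric FDR matrix aligned with `r`.
#' @param r_threshold Correlation magnitude threshold (default 0.8).
#' @param q_threshold FDR threshold (default 0.05).
#' @param group Optional group label carried on the network.
#' @return Object of class `cooccurrence_network`: `nodes`, `edges` (data
#'   frame `from`, `to`, `r`, `q`, `sign`), thresholds, `group`.
#' @export
build_network <- function(r, q = NULL, r_threshold = 0.8, q_threshold = 0.05,
                          group = NA_character_) {
  if (inherits(r, "correlation_result")) { q <- r$q; r <- r$r }
  if (is.null(q)) stop("`q` matrix required")
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("`r` must be square")
  if (!identical(dim(r), dim(q))) stop("`r` and `q` must be aligned")
  if (any(abs(r - t(r)) > 1e-8, na.rm = TRUE)) stop("`r` must be symmetric")
  if (any(abs(q - t(q)) > 1e-8, na.rm = TRUE) || any(is.na(q) != t(is.na(q))))
    stop("`q` must be symmetric")
  qt <- q; qt[is.na(qt)] <- Inf
  nodes <- colnames(r)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(ncol(r)))
  idx <- which(upper.tri(r) & abs(r) >= r_threshold & qt < q_threshold,
               arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      r = r[idx], q = q[idx],
                      sign = ifelse(r[idx] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  structure(list(group = group, nodes = nodes, edges = edges,
                 r_threshold = r_threshold, q_threshold = q_threshold),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network>%s %d nodes, %d edges (%d positive, %d negative)\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

#' @export
summary.cooccurrence_network <- function(object, ...) {
  data.frame(group = object$group, nodes = length(object$nodes),
             edges = nrow(object$edges),
             positive = sum(object$edges$sign == "+"),
             negative = sum(object$edges$sign == "-"))
}

# internal: per-node degree in a network
node_degree <- function(net) {
  deg <- setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$from); t2 <- table(net$edges$to)
    deg[names(t1)] <- deg[names(t1)] + t1
    deg[names(t2)] <- deg[names(t2)] + t2
  }
  deg
}

#' Active index of each network node
#'
#' Degree normalized by the number of possible partners: degree / (|nodes| -
#' 1), in \[0, 1\]. A single-node network has all-zero indices.
#'
#' @param net A `cooccurrence_network`.
#' @return Named numeric vector, one value per node.
#' @export
active_index <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nn <- length(net$nodes)
  if (nn < 2) return(setNames(numeric(nn), net$nodes))
  node_degree(net) / (nn - 1)
}

#' Internal complexity of each functional category
#'
#' Within-category edge density: for category c with `n_c` member nodes, the
#' number of network edges with both endpoints in c divided by the number of
#' possible within-category pairs `n_c (n_c - 1) / 2`; zero when `n_c < 2`.
#'
#' @param net A `cooccurrence_network`.
#' @param m A [category_map()] covering all nodes.
#' @return Named numeric vector, one value in \[0, 1\] per category present.
#' @export
internal_complexity <- function(net, m) {
  stopifnot(inherits(net, "cooccurrence_network"))
  lk <- map_lookup(m, net$nodes)
  cat_of <- setNames(lk$category, lk$function_id)
  cats <- sort(unique(lk$category))
  nsz <- table(lk$category)
  out <- setNames(numeric(length(cats)), cats)
  if (nrow(net$edges)) {
    ec1 <- cat_of[net$edges$from]; ec2 <- cat_of[net$edges$to]
    within <- table(factor(ec1[ec1 == ec2], levels = cats))
    pairs <- as.numeric(nsz[cats]) * (as.numeric(nsz[cats]) - 1) / 2
    out[pairs > 0] <- as.numeric(within)[pairs > 0] / pairs[pairs > 0]
  }
  out
}

#' Interaction complexity between functional categories
#'
#' Cross-category edge density: for distinct categories c1, c2 the number of
#' edges with one endpoint in each divided by `n_c1 * n_c2`. The matrix is
#' symmetric; diagonal entries report the internal complexity.
#'
#' @param net A `cooccurrence_network`.
#' @param m A [category_map()] covering all nodes.
#' @return Symmetric category x category matrix of values in \[0, 1\].
#' @export
interaction_complexity <- function(net, m) {
  stopifnot(inherits(net, "cooccurrence_network"))
  lk <- map_lookup(m, net$nodes)
  cat_of <- setNames(lk$category, lk$function_id)
  cats <- sort(unique(lk$category))
  nsz <- as.numeric(table(lk$category)[cats]); names(nsz) <- cats
  M <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  if (nrow(net$edges)) {
    ec1 <- cat_of[net$edges$from]; ec2 <- cat_of[net$edges$to]
    cross <- ec1 != ec2
    if (any(cross)) {
      a <- pmin(ec1[cross], ec2[cross]); b <- pmax(ec1[cross], ec2[cross])
      cnt <- table(a, b)
      for (i in rownames(cnt)) for (j in colnames(cnt)) {
        if (cnt[i, j] > 0) {
          v <- cnt[i, j] / (nsz[i] * nsz[j])
          M[i, j] <- v; M[j, i] <- v
        }
      }
    }
  }
  diag(M) <- internal_complexity(net, m)[cats]
  M
}

#' Build the per-group co-occurrence network for one study group
#'
#' Subsets the profile to the group's samples, screens pairwise Spearman
#' correlations with permutation p-values, and applies the signed edge rule.
#' Nodes with no passing edge are kept unless `prune = TRUE`.
#'
#' @param p A `functional_profile` over all samples.
#' @param group Group label.
#' @param r_threshold,q_threshold Edge thresholds (defaults 0.8 and 0.05).
#' @param n_perm,seed Passed to [correlation_matrix()].
#' @param prune Drop isolated nodes from the node list.
#' @return A `cooccurrence_network`.
#' @export
group_network <- function(p, group, r_threshold = 0.8, q_threshold = 0.05,
                          n_perm = 999, seed = 1L, prune = FALSE) {
  stopifnot(inherits(p, "functional_profile"))
  if (!group %in% levels(p$group)) stop("unknown group: ", group)
  sub <- subset_profile(p, samples = p$group == group)
  cr <- correlation_matrix(sub, n_perm = n_perm, seed = seed)
  net <- build_network(cr, r_threshold = r_threshold,
                       q_threshold = q_threshold, group = group)
  if (prune) {
    used <- union(net$edges$from, net$edges$to)
    net$nodes <- net$nodes[net$nodes %in% used]
  }
  net
}

#' Export a network as an edge-list TSV
#' @param net A `cooccurrence_network`.
#' @param path Output path. Columns: node1, node2, r, q, sign.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  names(e) <- c("node1", "node2", "r", "q", "sign")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a co-occurrence network to an igraph object
#' @param net A `cooccurrence_network`.
#' @return An undirected `igraph` graph with `r`, `q`, `sign` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Export a network as GraphML
#' @param net A `cooccurrence_network`.
#' @param path Output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
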