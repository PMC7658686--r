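#' Configure a synthetic functional-abundance simulation
#'
#' Defines the generative model used throughout the test suite: a
#' compositional count model in which each sample draws a latent log-scale
#' abundance vector (log-normal base abundances plus block-correlated
#' Gaussian noise), group-specific multiplicative enrichments are applied,
#' the vector is closed to proportions, and counts are drawn multinomially at
#' a fixed sequencing depth. Clinical indices are linear in the within-group
#' rank-transformed relative abundance of a designated function plus
#' independent Gaussian noise, so a link of strength `s` targets a Spearman
#' correlation close to `s` inside each study group — the scale on which
#' per-group correlation screens operate.
#'
#' Defaults mirror a four-group gut-microbiome cohort: groups HC, IBS-D, DEP
#' and COMO of sizes 15, 22, 15 and 13.
#'
#' @param group_sizes Named integer vector of per-group sample counts
#'   (each >= 2). Names are the group labels.
#' @param n_functions Number of functional units.
#' @param depth Expected total counts per sample (multinomial size).
#' @param base_abundance Optional positive concentration vector of length
#'   `n_functions`; if `NULL` one is drawn log-normally (meanlog 0, sdlog
#'   `base_sdlog`).
#' @param base_sdlog Log-scale spread of drawn base abundances.
#' @param noise_sdlog Per-sample latent log-noise standard deviation.
#' @param enrichments Data frame with columns `function_id`, `group`, `fold`
#'   (fold > 0): multiplicative group enrichments.
#' @param blocks List of `list(members = <function IDs>, strength = rho)` with
#'   rho in (0,1): latent within-block correlation, creating co-occurrence
#'   edges.
#' @param clinical_links Data frame with columns `index`, `function_id`,
#'   `sign` (+1/-1), `strength` in (0,1): planted monotone clinical links.
#' @param clinical_indices Character vector of clinical index names; indices
#'   not named in `clinical_links` are pure noise. Defaults to the linked
#'   indices (plus `"IBS_SSS"` and `"SDS"` when no links are given).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(group_sizes = c("HC" = 15, "IBS-D" = 22,
                                              "DEP" = 15, "COMO" = 13),
                              n_functions = 500,
                              depth = 1e5,
                              base_abundance = NULL,
                              base_sdlog = 1.5,
                              noise_sdlog = 0.5,
                              enrichments = NULL,
                              blocks = list(),
                              clinical_links = NULL,
                              clinical_indices = NULL,
                              seed = 1L) {
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  if (any(group_sizes < 2)) stop("every group needs at least 2 samples")
  if (n_functions < 2) stop("need at least 2 functions")
  if (!is.null(base_abundance)) {
    if (length(base_abundance) != n_functions || any(base_abundance <= 0))
      stop("`base_abundance` must be a positive vector of length n_functions")
  }
  if (!is.null(enrichments)) {
    enrichments <- as.data.frame(enrichments)
    stopifnot(all(c("function_id", "group", "fold") %in% names(enrichments)))
    if (any(enrichments$fold <= 0)) stop("fold factors must be > 0")
  }
  for (b in blocks) {
    if (!is.list(b) || is.null(b$members) || is.null(b$strength))
      stop("each block needs `members` and `strength`")
    if (b$strength <= 0 || b$strength >= 1) stop("block strength must lie in (0,1)")
  }
  if (!is.null(clinical_links)) {
    clinical_links <- as.data.frame(clinical_links)
    stopifnot(all(c("index", "function_id", "sign", "strength") %in% names(clinical_links)))
    if (any(clinical_links$strength <= 0 | clinical_links$strength >= 1))
      stop("link strengths must lie in (0,1)")
    if (!all(clinical_links$sign %in% c(-1, 1))) stop("link signs must be +1 or -1")
  }
  if (is.null(clinical_indices)) {
    clinical_indices <- if (!is.null(clinical_links)) unique(clinical_links$index)
                        else c("IBS_SSS", "SDS")
  }
  structure(list(group_sizes = group_sizes, n_functions = n_functions,
                 depth = depth, base_abundance = base_abundance,
                 base_sdlog = base_sdlog, noise_sdlog = noise_sdlog,
                 enrichments = enrichments, blocks = blocks,
                 clinical_links = clinical_links,
                 clinical_indices = clinical_indices,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic dataset with planted structure
#'
#' Draws a counts profile, clinical table and category map from a
#' [simulation_config()]. The returned `truth` element records the config and
#' the per-group expected relative abundances, sufficient to recompute the
#' expected group-mean abundance ratio of every planted enrichment: since the
#' latent log-noise has the same variance for every function, the expected
#' relative abundance of function j in group g is the closure of
#' `base_j * fold_gj` over functions.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `synthetic_dataset` with elements `profile`
#'   ([functional_profile()], counts), `clinical` ([clinical_table()]), `map`
#'   ([category_map()]), and `truth` (config plus `expected_rel`, a group x
#'   function matrix of expected relative abundances).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  J <- cfg$n_functions
  fun_ids <- sprintf("COG%04d", seq_len(J))
  labels <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n <- length(labels)
  samp_ids <- sprintf("S%03d", seq_len(n))

  base <- cfg$base_abundance
  if (is.null(base)) base <- stats::rlnorm(J, meanlog = 0, sdlog = cfg$base_sdlog)
  names(base) <- fun_ids

  # per-group log fold matrix
  logfold <- matrix(0, nrow = length(cfg$group_sizes), ncol = J,
                    dimnames = list(names(cfg$group_sizes), fun_ids))
  if (!is.null(cfg$enrichments)) {
    for (i in seq_len(nrow(cfg$enrichments))) {
      e <- cfg$enrichments[i, ]
      if (!e$function_id %in% fun_ids)
        stop("enrichment references unknown function: ", e$function_id)
      if (!e$group %in% names(cfg$group_sizes))
        stop("enrichment references unknown group: ", e$group)
      logfold[e$group, e$function_id] <-
        logfold[e$group, e$function_id] + log(e$fold)
    }
  }

  # latent noise: block members share a common factor to induce correlation
  block_of <- rep(NA_integer_, J); names(block_of) <- fun_ids
  for (bi in seq_along(cfg$blocks)) {
    mem <- cfg$blocks[[bi]]$members
    bad <- setdiff(mem, fun_ids)
    if (length(bad)) stop("block references unknown function(s): ", paste(bad, collapse = ", "))
    block_of[mem] <- bi
  }
  sd0 <- cfg$noise_sdlog
  eps <- matrix(stats::rnorm(n * J, sd = sd0), nrow = n)
  for (bi in seq_along(cfg$blocks)) {
    rho <- cfg$blocks[[bi]]$strength
    mem <- which(block_of == bi)
    shared <- stats::rnorm(n, sd = sd0)
    eps[, mem] <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(stats::rnorm(n * length(mem), sd = sd0), nrow = n)
  }

  z <- matrix(rep(log(base), each = n), nrow = n) + logfold[labels, ] + eps
  prop <- exp(z); prop <- prop / rowSums(prop)
  counts <- t(apply(prop, 1, function(p) stats::rmultinom(1, size = cfg$depth, prob = p)[, 1]))
  dimnames(counts) <- list(samp_ids, fun_ids)
  profile <- functional_profile(counts, group = labels, unit = "counts")

  # clinical indices
  relab <- counts / rowSums(counts)
  idx_names <- cfg$clinical_indices
  indices <- as.data.frame(matrix(stats::rnorm(n * length(idx_names)),
                                  nrow = n, dimnames = list(samp_ids, idx_names)))
  if (!is.null(cfg$clinical_links)) {
    for (i in seq_len(nrow(cfg$clinical_links))) {
      l <- cfg$clinical_links[i, ]
      if (!l$function_id %in% fun_ids)
        stop("clinical link references unknown function: ", l$function_id)
      # rank within each study group: group enrichments compress a function's
      # within-group rank range on the cohort-wide scale, so a cohort-level
      # rank link would attenuate exactly where per-group correlation screens
      # measure it
      r <- numeric(n)
      for (gl in names(cfg$group_sizes)) {
        gi <- labels == gl
        r[gi] <- as.numeric(scale(rank(relab[gi, l$function_id])))
      }
      indices[[l$index]] <- l$sign * l$strength * r +
        sqrt(1 - l$strength^2) * stats::rnorm(n)
    }
  }
  clinical <- clinical_table(samp_ids, labels, indices)

  map <- default_category_map(fun_ids)

  w <- exp(logfold + matrix(rep(log(base), each = nrow(logfold)), nrow = nrow(logfold)))
  expected_rel <- w / rowSums(w)

  structure(list(profile = profile, clinical = clinical, map = map,
                 truth = list(config = cfg, expected_rel = expected_rel)),
            class = "synthetic_dataset")
}

#' Default round-robin category map
#'
#' Assigns function IDs round-robin to the 26 one-letter COG categories,
#' which carry their standard membership in the four functional classes.
#' Intended for simulation: it exercises aggregation and network-complexity
#' code paths, not biology.
#'
#' @param function_ids Character vector of function IDs.
#' @return A [category_map()].
#' @export
default_category_map <- function(function_ids) {
  cats <- names(cog_category_classes())
  cat_i <- cats[((seq_along(function_ids) - 1) %% length(cats)) + 1]
  category_map(function_ids, cat_i, unname(cog_category_classes()[cat_i]))
}

#' Expected group-vs-group mean abundance ratio for a planted enrichment
#'
#' @param ds A `synthetic_dataset`.
#' @param function_id Function of interest.
#' @param group,ref Group labels to compare.
#' @return Expected ratio of mean relative abundance, `group` over `ref`,
#'   recomputed from the recorded truth.
#' @export
expected_enrichment_ratio <- function(ds, function_id, group, ref) {
  er <- ds$truth$expected_rel
  er[group, function_id] / er[ref, function_id]
}

#' Persist a synthetic dataset as TSVs plus a YAML truth file
#'
#' Writes `profile.tsv`, `clinical.tsv`, `category_map.tsv` and `truth.yaml`
#' (the generating configuration and expected relative abundances). Because
#' generation is seed-deterministic, regenerating from the recorded seed and
#' re-writing yields byte-identical files.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("directory not writable: ", dir)
  write_abundance_table(ds$profile, file.path(dir, "profile.tsv"))
  write_clinical_table(ds$clinical, file.path(dir, "clinical.tsv"))
  write_category_map(ds$map, file.path(dir, "category_map.tsv"))
  cfg <- ds$truth$config
  truth <- list(
    config = list(group_sizes = as.list(cfg$group_sizes),
                  n_functions = cfg$n_functions, depth = cfg$depth,
                  base_sdlog = cfg$base_sdlog, noise_sdlog = cfg$noise_sdlog,
                  enrichments = if (is.null(cfg$enrichments)) list() else
                    lapply(seq_len(nrow(cfg$enrichments)), function(i) as.list(cfg$enrichments[i, ])),
                  blocks = cfg$blocks,
                  clinical_links = if (is.null(cfg$clinical_links)) list() else
                    lapply(seq_len(nrow(cfg$clinical_links)), function(i) as.list(cfg$clinical_links[i, ])),
                  seed = cfg$seed),
    expected_rel = apply(ds$truth$expected_rel, 1, as.list, simplify = FALSE))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
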