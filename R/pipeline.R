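#' Default end-to-end run configuration
#'
#' @param profile,clinical,map Input file paths (`clinical` and `map` may be
#'   `NULL`; stages needing them are then skipped with a warning).
#' @param out Output directory.
#' @param k Number of PAM clusters.
#' @param n_perm Permutations for ANOVA and correlation screening.
#' @param r_threshold,q_threshold Network edge thresholds.
#' @param alpha_anova,alpha_corr Biomarker selection thresholds.
#' @param n_trees,n_repeats Random-forest size and CV repeats.
#' @param seed Master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(profile, clinical = NULL, map = NULL, out = "mwas_run",
                       k = 3, n_perm = 999, r_threshold = 0.8,
                       q_threshold = 0.05, alpha_anova = 0.01,
                       alpha_corr = 0.05, n_trees = 500, n_repeats = 10,
                       seed = 17L) {
  structure(list(profile = profile, clinical = clinical, map = map, out = out,
                 k = k, n_perm = n_perm, r_threshold = r_threshold,
                 q_threshold = q_threshold, alpha_anova = alpha_anova,
                 alpha_corr = alpha_corr, n_trees = n_trees,
                 n_repeats = n_repeats, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full downstream analysis pipeline
#'
#' Executes normalize -> cluster -> difftest -> per-group networks ->
#' per-group biomarkers -> clinical correlation screen, writing one TSV per
#' stage output plus a YAML manifest recording every parameter, per-stage
#' seed and row count. Re-running with the same configuration reproduces all
#' outputs byte-identically. Stages whose inputs are missing (no clinical
#' table, no category map) are skipped with a warning; any stage error
#' aborts with the stage name.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("cogmwas")),
                   parameters = cfg[setdiff(names(cfg), "out")],
                   stages = list())
  set.seed(cfg$seed)
  stage_seeds <- as.list(sample.int(2^31 - 1, 6))
  names(stage_seeds) <- c("cluster", "difftest", "network", "biomarkers",
                          "correlate", "spare")

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  profile <- run_stage("read", read_abundance_table(cfg$profile))
  rel <- run_stage("normalize", normalize_relative(profile))
  write_abundance_table(rel, file.path(cfg$out, "relative_abundance.tsv"))
  manifest$stages$normalize <- list(rows = nrow(rel$values))

  clus <- run_stage("cluster",
                    cluster_profiles(rel, k = cfg$k, seed = stage_seeds$cluster))
  utils::write.table(data.frame(sample = rownames(rel$values),
                                cluster = clus$assignment$labels),
                     file.path(cfg$out, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame.matrix(clus$crosstab),
                     file.path(cfg$out, "cluster_crosstab.tsv"),
                     sep = "\t", quote = FALSE)
  manifest$stages$cluster <- list(seed = stage_seeds$cluster, k = cfg$k,
                                  n_components = clus$n_components,
                                  objective = clus$assignment$objective)

  dt <- run_stage("difftest", suppressWarnings(
    permutation_anova(rel, n_perm = cfg$n_perm, seed = stage_seeds$difftest)))
  utils::write.table(as.data.frame(dt), file.path(cfg$out, "difftest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$difftest <- list(seed = stage_seeds$difftest,
                                   n_perm = cfg$n_perm, rows = nrow(dt))

  nets <- list()
  for (grp in levels(rel$group)) {
    net <- run_stage("network", suppressWarnings(
      group_network(rel, grp, r_threshold = cfg$r_threshold,
                    q_threshold = cfg$q_threshold, n_perm = cfg$n_perm,
                    seed = stage_seeds$network)))
    nets[[grp]] <- net
    safe <- gsub("[^A-Za-z0-9]", "_", grp)
    write_edge_list(net, file.path(cfg$out, paste0("network_", safe, ".tsv")))
    write_graphml(net, file.path(cfg$out, paste0("network_", safe, ".graphml")))
  }
  manifest$stages$network <- list(seed = stage_seeds$network,
                                  summary = lapply(nets, function(n)
                                    as.list(summary(n)[, -1])))
  if (!is.null(cfg$map)) {
    m <- read_category_map(cfg$map)
    for (grp in names(nets)) {
      safe <- gsub("[^A-Za-z0-9]", "_", grp)
      ic <- internal_complexity(nets[[grp]], m)
      utils::write.table(data.frame(category = names(ic), internal = ic),
                         file.path(cfg$out, paste0("complexity_", safe, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    warning("no category map supplied; complexity stage skipped")
  }

  panels <- NULL; screens <- NULL
  if (!is.null(cfg$clinical)) {
    clinical <- run_stage("clinical", read_clinical_table(cfg$clinical))
    panels <- list()
    for (grp in levels(rel$group)) {
      panel <- run_stage("biomarkers",
                         select_biomarkers(dt, rel, clinical, grp,
                                           alpha_anova = cfg$alpha_anova,
                                           alpha_corr = cfg$alpha_corr))
      panels[[grp]] <- panel
      if (length(panel$function_ids)) {
        safe <- gsub("[^A-Za-z0-9]", "_", grp)
        utils::write.table(panel$evidence,
                           file.path(cfg$out, paste0("biomarkers_", safe, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    manifest$stages$biomarkers <- list(seed = stage_seeds$biomarkers,
                                       panel_sizes = lapply(panels, function(p)
                                         length(p$function_ids)))
    screen <- run_stage("correlate",
                        correlate_with_clinical(rel, clinical))
    utils::write.table(as.data.frame(screen$r),
                       file.path(cfg$out, "clinical_correlation_r.tsv"),
                       sep = "\t", quote = FALSE)
    manifest$stages$correlate <- list(significant = sum(screen$mask))
    screens <- screen
  } else {
    warning("no clinical table supplied; biomarker and correlation stages skipped")
    manifest$stages$biomarkers <- list(skipped = TRUE)
    manifest$stages$correlate <- list(skipped = TRUE)
  }

  yaml::write_yaml(manifest, file.path(cfg$out, "manifest.yaml"))
  invisible(list(profile = rel, clusters = clus, difftest = dt,
                 networks = nets, panels = panels, screen = screens,
                 manifest = manifest))
}

#' Generate and persist a synthetic fixture dataset
#'
#' Convenience wrapper: build a [simulation_config()] (from a YAML file or an
#' in-memory config), generate the dataset, and write the TSVs plus truth
#' file with [write_fixture()].
#'
#' @param cfg A `simulation_config`, or the path to a YAML file whose keys
#'   are [simulation_config()] arguments.
#' @param out Output directory.
#' @param seed Optional seed overriding the configured one.
#' @return The generated `synthetic_dataset`, invisibly.
#' @export
simulate_fixture <- function(cfg = simulation_config(), out, seed = NULL) {
  if (is.character(cfg)) {
    y <- yaml::read_yaml(cfg)
    if (!is.null(y$group_sizes)) y$group_sizes <- unlist(y$group_sizes)
    if (!is.null(y$enrichments)) y$enrichments <- do.call(rbind, lapply(y$enrichments, as.data.frame))
    if (!is.null(y$clinical_links)) y$clinical_links <- do.call(rbind, lapply(y$clinical_links, as.data.frame))
    cfg <- do.call(simulation_config, y)
  }
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  ds <- generate_dataset(cfg)
  write_fixture(ds, out)
  invisible(ds)
}
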