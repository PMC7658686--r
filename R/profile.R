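#' Construct a functional abundance profile
#'
#' A `functional_profile` holds a sample x function abundance matrix together
#' with a per-sample group label and the abundance unit. Rows are samples,
#' columns are functional units (COG-style identifiers such as `"COG0738"`).
#'
#' @param values Numeric matrix of non-negative abundances with unique row
#'   names (sample IDs) and unique column names (function IDs).
#' @param group Character or factor vector of per-sample group labels, one per
#'   row of `values`.
#' @param unit Either `"counts"` (raw or coverage-scaled counts) or
#'   `"relative"` (each row sums to 1).
#' @return An object of class `functional_profile` with fields `values`,
#'   `group` (factor) and `unit`.
#' @examples
#' m <- matrix(c(2, 2, 4, 1, 3, 6), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("COG0001", "COG0002", "COG0003")))
#' fp <- functional_profile(m, group = c("HC", "IBS-D"))
#' @export
functional_profile <- function(values, group, unit = c("counts", "relative")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (samples) and column names (functions)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicated function ID(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values)) stop("`values` must not contain missing entries")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', function '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (length(group) != nrow(values))
    stop("`group` must have one label per sample row")
  if (unit == "relative") {
    bad <- which(abs(rowSums(values) - 1) > 1e-9)
    if (length(bad))
      stop("relative-unit rows must sum to 1; offending sample(s): ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  storage.mode(values) <- "double"
  structure(list(values = values, group = factor(group), unit = unit),
            class = "functional_profile")
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("<functional_profile> %d samples x %d functions (unit: %s)\n",
              nrow(x$values), ncol(x$values), x$unit))
  tab <- table(x$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.functional_profile <- function(x) dim(x$values)

sample_ids <- function(p) rownames(p$values)
function_ids <- function(p) colnames(p$values)

#' Subset a functional profile
#'
#' @param x A `functional_profile`.
#' @param samples,functions Index vectors (logical, integer, or names) over
#'   samples and functions; `NULL` keeps everything.
#' @return A `functional_profile`. Relative profiles keep their unit only if
#'   all functions are retained; otherwise rows no longer sum to 1, so the
#'   subset is returned with unit `"counts"` semantics removed — callers
#'   dropping functions from a relative profile should renormalize.
#' @export
subset_profile <- function(x, samples = NULL, functions = NULL) {
  stopifnot(inherits(x, "functional_profile"))
  v <- x$values
  g <- x$group
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
    g <- g[if (is.character(samples)) match(samples, sample_ids(x)) else samples]
  }
  keep_all_fun <- is.null(functions)
  if (!keep_all_fun) v <- v[, functions, drop = FALSE]
  unit <- if (x$unit == "relative" && keep_all_fun) "relative" else "counts"
  structure(list(values = v, group = droplevels(factor(g)), unit = unit),
            class = "functional_profile")
}

#' Read a sample x function abundance table
#'
#' Reads a delimited text table with a header row. Samples are in rows by
#' default (first column = sample ID); a reserved column named `group` carries
#' the study-group label. With `transpose = TRUE` the file is function x
#' sample and group labels must be supplied via `group`.
#'
#' @param path Path to the table.
#' @param sep Field delimiter (default tab).
#' @param transpose Logical; set `TRUE` when functions are in rows.
#' @param group Optional character vector of group labels overriding (or, for
#'   transposed input, replacing) the `group` column.
#' @return A validated [functional_profile()]. The unit is `"relative"` when
#'   every row already sums to 1 (within 1e-6), else `"counts"`.
#' @export
read_abundance_table <- function(path, sep = "\t", transpose = FALSE, group = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated ID(s) in first column: ", paste(unique(dup), collapse = ", "))
  df2 <- df[, -1, drop = FALSE]
  if (transpose) {
    m <- t(as.matrix(df2))
    colnames(m) <- ids
    if (is.null(group)) stop("transposed input carries no group column; supply `group`")
  } else {
    if (is.null(group)) {
      if (!"group" %in% names(df2))
        stop("no `group` column found and no `group` argument supplied")
      group <- as.character(df2[["group"]])
      df2 <- df2[, setdiff(names(df2), "group"), drop = FALSE]
    } else if ("group" %in% names(df2)) {
      df2 <- df2[, setdiff(names(df2), "group"), drop = FALSE]
    }
    m <- as.matrix(df2)
    rownames(m) <- ids
  }
  if (!is.numeric(m)) stop("abundance columns must all be numeric")
  unit <- if (all(abs(rowSums(m) - 1) < 1e-6)) "relative" else "counts"
  functional_profile(m, group = group, unit = unit)
}

#' Write a functional profile as a TSV
#'
#' Inverse of [read_abundance_table()]: samples in rows, first column
#' `sample`, then a `group` column, then one column per function. Values are
#' written at full precision (round-trips integer counts bit-exactly).
#'
#' @param p A `functional_profile`.
#' @param path Output path.
#' @export
write_abundance_table <- function(p, path) {
  stopifnot(inherits(p, "functional_profile"))
  df <- data.frame(sample = sample_ids(p), group = as.character(p$group),
                   p$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to 1.
#'
#' @param p A `functional_profile` with unit `"counts"`.
#' @return A `functional_profile` with unit `"relative"`.
#' @export
normalize_relative <- function(p) {
  stopifnot(inherits(p, "functional_profile"))
  if (p$unit == "relative") return(p)
  tot <- rowSums(p$values)
  if (any(tot == 0))
    stop("all-zero sample row(s): ",
         paste(sample_ids(p)[tot == 0], collapse = ", "))
  functional_profile(p$values / tot, group = p$group, unit = "relative")
}

# internal: relative-abundance matrix regardless of stored unit
rel_values <- function(p) {
  if (p$unit == "relative") return(p$values)
  tot <- rowSums(p$values)
  if (any(tot == 0))
    stop("all-zero sample row(s): ", paste(sample_ids(p)[tot == 0], collapse = ", "))
  p$values / tot
}

#' Construct a function -> category -> class map
#'
#' Maps each functional unit to a one-letter COG category and each category to
#' one of the four broad functional classes. A category must map to exactly
#' one class.
#'
#' @param function_id Character vector of function IDs.
#' @param category One-letter category code per function.
#' @param class Functional class per function; one of
#'   `"information storage and processing"`, `"cellular processes and
#'   signaling"`, `"metabolism"`, `"poorly characterized"`.
#' @return An object of class `category_map` (a validated data frame).
#' @export
category_map <- function(function_id, category, class) {
  function_id <- as.character(function_id)
  category <- as.character(category)
  class <- as.character(class)
  stopifnot(length(function_id) == length(category),
            length(function_id) == length(class))
  dup <- function_id[duplicated(function_id)]
  if (length(dup)) stop("duplicated function ID(s) in map: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(class, cog_classes())
  if (length(bad)) stop("unknown functional class(es): ", paste(bad, collapse = ", "))
  # each category must belong to exactly one class
  cc <- unique(data.frame(category = category, class = class, stringsAsFactors = FALSE))
  multi <- cc$category[duplicated(cc$category)]
  if (length(multi))
    stop("category mapped to more than one class: ", paste(unique(multi), collapse = ", "))
  structure(data.frame(function_id = function_id, category = category,
                       class = class, stringsAsFactors = FALSE),
            class = c("category_map", "data.frame"))
}

#' The four broad COG functional classes
#' @return Character vector of the four class names.
#' @export
cog_classes <- function() {
  c("information storage and processing",
    "cellular processes and signaling",
    "metabolism",
    "poorly characterized")
}

#' Standard class membership of the 26 one-letter COG categories
#' @return Named character vector: category letter -> functional class.
#' @export
cog_category_classes <- function() {
  cl <- cog_classes()
  c(J = cl[1], A = cl[1], K = cl[1], L = cl[1], B = cl[1],
    D = cl[2], Y = cl[2], V = cl[2], T = cl[2], M = cl[2], N = cl[2],
    Z = cl[2], W = cl[2], U = cl[2], O = cl[2], X = cl[2],
    C = cl[3], G = cl[3], E = cl[3], F = cl[3], H = cl[3], I = cl[3],
    P = cl[3], Q = cl[3],
    R = cl[4], S = cl[4])
}

# internal: look up categories/classes for a set of function IDs
map_lookup <- function(m, ids, allow_unmapped = FALSE) {
  stopifnot(inherits(m, "category_map"))
  idx <- match(ids, m$function_id)
  if (anyNA(idx)) {
    missing_ids <- ids[is.na(idx)]
    if (!allow_unmapped)
      stop("unmapped function ID(s): ", paste(missing_ids, collapse = ", "))
  }
  data.frame(function_id = ids,
             category = ifelse(is.na(idx), "unmapped", m$category[idx]),
             class = ifelse(is.na(idx), "unmapped", m$class[idx]),
             stringsAsFactors = FALSE)
}

#' Read a category map from a TSV
#'
#' Expects columns `function_id`, `category`, `class` (header required).
#' @param path Path to the table.
#' @param sep Field delimiter.
#' @return A [category_map()].
#' @export
read_category_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("function_id", "category", "class")
  if (!all(need %in% names(df)))
    stop("category map must have columns: ", paste(need, collapse = ", "))
  category_map(df$function_id, df$category, df$class)
}

#' @export
write_category_map <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate a profile by COG category or functional class
#'
#' Sums abundance columns within each category (or class). Per-sample totals
#' are conserved exactly.
#'
#' @param p A `functional_profile`.
#' @param m A [category_map()] covering the profile's functions.
#' @param level `"category"` or `"class"`.
#' @param allow_unmapped If `TRUE`, unmapped functions are collected under an
#'   `"unmapped"` column instead of raising an error.
#' @return A `functional_profile` whose columns are categories or classes.
#' @export
aggregate_by_category <- function(p, m, level = c("category", "class"),
                                  allow_unmapped = FALSE) {
  stopifnot(inherits(p, "functional_profile"))
  level <- match.arg(level)
  lk <- map_lookup(m, function_ids(p), allow_unmapped = allow_unmapped)
  key <- lk[[level]]
  groups <- sort(unique(key))
  agg <- sapply(groups, function(g)
    rowSums(p$values[, key == g, drop = FALSE]))
  if (nrow(p$values) == 1) agg <- matrix(agg, nrow = 1, dimnames = list(sample_ids(p), groups))
  functional_profile(agg, group = p$group, unit = p$unit)
}

#' Per-sample and cohort-mean fractions of the four functional classes
#'
#' @param p A `functional_profile` in relative units.
#' @param m A [category_map()].
#' @param allow_unmapped Passed to [aggregate_by_category()].
#' @return List with `per_sample` (sample x class fraction matrix, rows sum to
#'   1) and `cohort_mean` (unweighted mean fraction per class across samples).
#' @export
class_fractions <- function(p, m, allow_unmapped = FALSE) {
  stopifnot(inherits(p, "functional_profile"))
  if (p$unit != "relative") stop("`p` must be in relative units; see normalize_relative()")
  agg <- aggregate_by_category(p, m, level = "class", allow_unmapped = allow_unmapped)
  per_sample <- agg$values
  list(per_sample = per_sample, cohort_mean = colMeans(per_sample))
}

#' Construct a clinical-index table
#'
#' @param sample_ids Character vector of sample IDs (unique).
#' @param group Per-sample group labels.
#' @param indices Data frame (or matrix) of numeric clinical indices; missing
#'   values (`NA`) are permitted.
#' @return An object of class `clinical_table`.
#' @export
clinical_table <- function(sample_ids, group, indices) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample IDs in clinical table")
  indices <- as.data.frame(indices)
  if (nrow(indices) != length(sample_ids)) stop("indices rows must match sample IDs")
  if (!all(vapply(indices, is.numeric, logical(1))))
    stop("all clinical indices must be numeric")
  rownames(indices) <- sample_ids
  structure(list(sample_ids = sample_ids, group = factor(group), indices = indices),
            class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("<clinical_table> %d samples, %d indices (%d missing values)\n",
              length(x$sample_ids), ncol(x$indices), sum(is.na(x$indices))))
  invisible(x)
}

#' Read a clinical table (sample, group, numeric indices) from TSV
#' @param path Path to the table; first column sample IDs, a `group` column,
#'   remaining columns numeric indices.
#' @param sep Field delimiter.
#' @return A [clinical_table()].
#' @export
read_clinical_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) stop("clinical table requires a `group` column")
  ids <- as.character(df[[1]])
  idx <- df[, setdiff(names(df)[-1], "group"), drop = FALSE]
  clinical_table(ids, df$group, idx)
}

#' @export
write_clinical_table <- function(ct, path) {
  df <- data.frame(sample = ct$sample_ids, group = as.character(ct$group),
                   ct$indices, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: check that a profile and clinical table describe the same samples,
# in the same order, with the same group labels
check_aligned <- function(p, ct) {
  if (!identical(sample_ids(p), ct$sample_ids))
    stop("profile and clinical table sample IDs do not align")
  if (!identical(as.character(p$group), as.character(ct$group)))
    stop("profile and clinical table group labels disagree")
  invisible(TRUE)
}
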