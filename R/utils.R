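# Internal helpers shared across modules.

# Coerce a count/abundance table to a taxa x samples numeric matrix.
#
# Accepted inputs: a tibble/data.frame whose first column is `taxon_id`
# (character), with an optional `lineage` character column, and one numeric
# column per sample; or a numeric matrix with taxa as rownames and samples as
# colnames. Returns list(mat, lineage) where lineage is a named character
# vector (possibly NULL).
as_taxa_matrix <- function(x, require_counts = FALSE, arg = "counts") {
  if (is.matrix(x)) {
    mat <- x
    lineage <- attr(x, "lineage", exact = TRUE)
  } else if (is.data.frame(x)) {
    if (!"taxon_id" %in% names(x)) {
      abort(sprintf("`%s` must have a `taxon_id` column.", arg),
            class = "mg_format_error")
    }
    ids <- as.character(x[["taxon_id"]])
    lineage <- if ("lineage" %in% names(x)) {
      setNames(as.character(x[["lineage"]]), ids)
    } else {
      NULL
    }
    value_cols <- setdiff(names(x), c("taxon_id", "lineage"))
    if (length(value_cols) == 0L) {
      abort(sprintf("`%s` has no sample columns.", arg),
            class = "mg_format_error")
    }
    mat <- as.matrix(x[, value_cols, drop = FALSE])
    if (!is.numeric(mat)) {
      abort(sprintf("`%s` has non-numeric sample cells.", arg),
            class = "mg_format_error")
    }
    rownames(mat) <- ids
  } else {
    abort(sprintf("`%s` must be a data frame or matrix.", arg),
          class = "mg_format_error")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort(sprintf("`%s` must carry taxon and sample identifiers.", arg),
          class = "mg_format_error")
  }
  if (anyDuplicated(rownames(mat))) {
    abort(sprintf("duplicate taxon identifiers in `%s`.", arg),
          class = "mg_format_error")
  }
  if (anyDuplicated(colnames(mat))) {
    abort(sprintf("duplicate sample identifiers in `%s`.", arg),
          class = "mg_format_error")
  }
  if (anyNA(mat)) {
    abort(sprintf("`%s` contains missing values.", arg),
          class = "mg_format_error")
  }
  if (any(mat < 0)) {
    abort(sprintf("`%s` contains negative values.", arg),
          class = "mg_format_error")
  }
  if (require_counts && any(mat != round(mat))) {
    abort(sprintf("`%s` must contain integer counts.", arg),
          class = "mg_format_error")
  }
  list(mat = mat, lineage = lineage)
}

# Back from matrix to the tibble representation.
taxa_matrix_to_tibble <- function(mat, lineage = NULL) {
  out <- tibble(taxon_id = rownames(mat))
  if (!is.null(lineage)) {
    out$lineage <- unname(lineage[rownames(mat)])
  }
  dplyr::bind_cols(out, as_tibble(mat, .name_repair = "minimal"))
}

# Validate a symmetric matrix of declared kind ("correlation" or "distance").
check_symmetric <- function(m, kind = c("correlation", "distance"),
                            tol = 1e-8, arg = "m") {
  kind <- match.arg(kind)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("`%s` must be symmetric.", arg))
  }
  if (kind == "correlation") {
    if (max(abs(diag(m) - 1)) > tol || max(abs(m)) > 1 + tol) {
      abort(sprintf("`%s` is not a valid correlation matrix.", arg))
    }
  } else {
    if (max(abs(diag(m))) > tol || min(m) < -tol) {
      abort(sprintf("`%s` is not a valid distance matrix.", arg))
    }
  }
  invisible(m)
}

# Deterministic per-stage seed derived from a global seed. Stage offsets are
# fixed small integers so every derived seed stays far below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 11L, sparcc = 23L, guilds = 37L, networks = 47L,
    signatures = 59L, bootstrap = 67L, diversity = 79L, permanova = 89L,
    anosim = 97L
  )
  off <- offsets[[stage]]
  if (is.null(off)) off <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.integer(seed) %% 2000000L) * 1000L + off)
}

#' Adjusted Rand index between two partitions
#'
#' The chance-corrected agreement between two labelings of the same items,
#' used as the recovery metric when comparing detected guilds against a
#' planted partition. 1 means identical partitions (up to label names), 0 is
#' the expected value for independent partitions.
#'
#' @param a,b Vectors of cluster labels of equal length (any atomic type).
#' @return A single number in [-1, 1].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Named group factor aligned to sample ids; errors on missing metadata rows.
group_lookup <- function(metadata, sample_ids, arg = "metadata") {
  md <- as_tibble(metadata)
  if (!all(c("sample_id", "group") %in% names(md))) {
    abort(sprintf("`%s` must have `sample_id` and `group` columns.", arg))
  }
  idx <- match(sample_ids, md$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples without metadata: ",
                 paste(head(sample_ids[is.na(idx)], 5), collapse = ", ")),
          class = "mg_metadata_error")
  }
  setNames(as.character(md$group[idx]), sample_ids)
}
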