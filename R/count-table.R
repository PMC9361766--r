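# data model & I/O: count tables, metadata, taxonomy aggregation.

#' Read a taxa-by-sample count table from TSV
#'
#' Reads a tab-separated count table (UTF-8, header row, first column holds
#' identifiers, `#` comment lines ignored) into the package's tidy count-table
#' form: a tibble with a `taxon_id` column, an optional `lineage` column and
#' one integer column per sample. A `lineage` column in the file (semicolon
#' separated, rank-prefixed, e.g. `k__Bacteria;p__Firmicutes;...`) is carried
#' through.
#'
#' @param path Path to a TSV file.
#' @param orientation `"taxa_rows"` (default) if rows are taxa, or
#'   `"samples_rows"` if rows are samples; the result is always taxa x samples.
#' @return A tibble: `taxon_id`, optional `lineage`, then sample columns.
#' @seealso [write_count_table()], [to_relative()], [aggregate_rank()]
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort("empty count table.", class = "mg_format_error")
  }
  names(df)[1] <- "taxon_id"
  df$taxon_id <- as.character(df$taxon_id)
  has_lineage <- "lineage" %in% names(df)[-1]
  if (orientation == "samples_rows") {
    if (has_lineage) {
      abort("a `lineage` column is only meaningful with taxa_rows orientation.",
            class = "mg_format_error")
    }
    ids <- df$taxon_id # actually sample ids in this orientation
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) {
      abort("non-numeric count cells.", class = "mg_format_error")
    }
    rownames(mat) <- ids
    mat <- t(mat)
    df <- dplyr::bind_cols(tibble(taxon_id = rownames(mat)),
                           as_tibble(mat, .name_repair = "minimal"))
  }
  parsed <- as_taxa_matrix(df, require_counts = TRUE, arg = "count table")
  taxa_matrix_to_tibble(parsed$mat, parsed$lineage)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; round-trips exactly.
#'
#' @param counts A count-table tibble or taxa x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  parsed <- as_taxa_matrix(counts, require_counts = TRUE)
  out <- taxa_matrix_to_tibble(parsed$mat, parsed$lineage)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write a sample metadata table
#'
#' Metadata TSV columns: `sample_id`, `group` (G1 = centenarian, G2 = elderly,
#' G3 = young), optional `family_id` and `generation`, then any number of
#' numeric host-variable columns (cytokines, amyloid-beta, BDNF, ...). Missing
#' host values are `NA`, never silently 0.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(md))) {
    abort("metadata must have `sample_id` and `group` columns.",
          class = "mg_format_error")
  }
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) {
    abort("duplicate sample identifiers in metadata.",
          class = "mg_format_error")
  }
  bad <- setdiff(unique(md$group), c("G1", "G2", "G3"))
  if (length(bad)) {
    abort(paste0("unknown group labels: ", paste(bad, collapse = ", ")),
          class = "mg_format_error")
  }
  as_tibble(md)
}

#' @rdname read_sample_metadata
#' @param metadata A metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(as_tibble(metadata), path, progress = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its total so each column sums to 1. Samples
#' with zero total are rejected by name rather than silently producing NaN.
#'
#' @param counts A count-table tibble or taxa x samples matrix.
#' @return A tibble of the same shape with values in [0, 1].
#' @export
to_relative <- function(counts) {
  parsed <- as_taxa_matrix(counts)
  tot <- colSums(parsed$mat)
  if (any(tot == 0)) {
    abort(paste0("all-zero sample column(s): ",
                 paste(colnames(parsed$mat)[tot == 0], collapse = ", ")),
          class = "mg_degenerate_sample")
  }
  rel <- sweep(parsed$mat, 2, tot, "/")
  taxa_matrix_to_tibble(rel, parsed$lineage)
}

# Split a "k__Bacteria;p__Firmicutes;..." lineage string at a rank.
# Returns "Unclassified" when the rank is absent or empty.
lineage_rank_name <- function(lineage, rank) {
  prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__",
                species = "s__")
  pre <- prefixes[[rank]]
  if (is.null(pre)) {
    abort(sprintf("unknown taxonomy rank `%s`.", rank),
          class = "mg_config_error")
  }
  vapply(strsplit(ifelse(is.na(lineage), "", lineage), ";", fixed = TRUE),
         function(parts) {
           parts <- trimws(parts)
           hit <- parts[startsWith(parts, pre)]
           name <- if (length(hit)) sub(pre, "", hit[1], fixed = TRUE) else ""
           if (nzchar(name)) name else "Unclassified"
         }, character(1))
}

#' Aggregate a count table at a taxonomy rank
#'
#' Sums member taxa into one row per distinct name at the requested rank
#' (e.g. phylum-level composition barplots). Taxa whose lineage does not
#' define the rank are pooled into `"Unclassified"`. Column totals are
#' preserved exactly (integer arithmetic).
#'
#' @param counts A count-table tibble with a `lineage` column.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return A count-table tibble with one row per name at `rank`.
#' @export
aggregate_rank <- function(counts, rank) {
  parsed <- as_taxa_matrix(counts)
  if (is.null(parsed$lineage)) {
    abort("`counts` must carry a `lineage` column to aggregate by rank.",
          class = "mg_config_error")
  }
  names_at_rank <- lineage_rank_name(parsed$lineage[rownames(parsed$mat)], rank)
  agg <- rowsum(parsed$mat, group = names_at_rank, reorder = TRUE)
  taxa_matrix_to_tibble(agg, NULL)
}

#' Firmicutes/Bacteroidetes ratio per group
#'
#' The F/B ratio of the group-mean composition, a conventional coarse index
#' of gut community structure. Computed from phylum-aggregated relative
#' abundances; a group with zero Bacteroidetes is flagged undefined rather
#' than erroring.
#'
#' @param counts A count-table tibble with `lineage`.
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @return A tibble: `group`, `firmicutes`, `bacteroidetes`, `ratio`,
#'   `undefined`.
#' @export
firmicutes_bacteroidetes_ratio <- function(counts, metadata) {
  phyla <- aggregate_rank(counts, "phylum")
  rel <- to_relative(phyla)
  parsed <- as_taxa_matrix(rel)
  groups <- group_lookup(metadata, colnames(parsed$mat))
  pick <- function(name) {
    if (name %in% rownames(parsed$mat)) parsed$mat[name, ] else
      setNames(rep(0, ncol(parsed$mat)), colnames(parsed$mat))
  }
  f <- pick("Firmicutes")
  b <- pick("Bacteroidetes")
  purrr::map_dfr(sort(unique(groups)), function(g) {
    sel <- groups == g
    fm <- mean(f[sel])
    bm <- mean(b[sel])
    tibble(group = g, firmicutes = fm, bacteroidetes = bm,
           ratio = if (bm > 0) fm / bm else NA_real_,
           undefined = bm == 0)
  })
}

#' Validate a cohort (count table + metadata) before analysis
#'
#' Reports, without stopping, every violation that would break downstream
#' stages: samples missing metadata or counts, bad group labels, families
#' contributing more than one sample to a group, all-zero samples or taxa.
#'
#' @param counts A count-table tibble or matrix.
#' @param metadata A metadata tibble.
#' @return A tibble of violations (`check`, `item`, `detail`); zero rows when
#'   clean.
#' @export
validate_cohort <- function(counts, metadata) {
  parsed <- as_taxa_matrix(counts)
  md <- as_tibble(metadata)
  v <- list()
  add <- function(check, item, detail) {
    v[[length(v) + 1L]] <<- tibble(check = check, item = item, detail = detail)
  }
  miss_md <- setdiff(colnames(parsed$mat), md$sample_id)
  for (s in miss_md) add("missing_metadata", s, "sample has counts but no metadata row")
  miss_ct <- setdiff(md$sample_id, colnames(parsed$mat))
  for (s in miss_ct) add("missing_counts", s, "metadata row without count column")
  bad_grp <- md$sample_id[!md$group %in% c("G1", "G2", "G3")]
  for (s in bad_grp) add("bad_group", s, "group label outside {G1,G2,G3}")
  if ("family_id" %in% names(md)) {
    fam <- md %>%
      filter(!is.na(.data$family_id)) %>%
      dplyr::count(.data$family_id, .data$group) %>%
      filter(.data$n > 1)
    for (i in seq_len(nrow(fam))) {
      add("family_group_duplicate", fam$family_id[i],
          sprintf("family has %d samples in group %s", fam$n[i], fam$group[i]))
    }
  }
  zero_s <- colnames(parsed$mat)[colSums(parsed$mat) == 0]
  for (s in zero_s) add("zero_sample", s, "sample column sums to zero")
  zero_t <- rownames(parsed$mat)[rowSums(parsed$mat) == 0]
  for (t in zero_t) add("zero_taxon", t, "taxon row sums to zero")
  if (length(v)) bind_rows(v) else
    tibble(check = character(), item = character(), detail = character())
}
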