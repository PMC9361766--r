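# Co-abundance guild detection: prevalence filter -> SparCC rho -> Ward tree
# on the 1-rho distance -> PERMANOVA-guided top-down tree division.

#' Filter taxa by prevalence and relative abundance
#'
#' Retains taxa whose relative abundance is at least `min_rel_abundance` in at
#' least `ceiling(min_prevalence * n_samples)` samples. With
#' `min_rel_abundance = 0` the criterion is plain presence (count > 0) — the
#' "shared by at least 20% of the samples" rule; with 0.001 it is the
#' "at least 0.1% relative abundance in at least 20% of samples" variant.
#'
#' @param counts Count-table tibble or taxa x samples matrix.
#' @param min_prevalence Fraction of samples required, in (0, 1].
#' @param min_rel_abundance Relative-abundance floor (0 = presence).
#' @return The filtered count table (same representation as the input tibble);
#'   zero-row result carries attribute `empty = TRUE`.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.2,
                              min_rel_abundance = 0) {
  stopifnot(min_prevalence > 0, min_prevalence <= 1, min_rel_abundance >= 0)
  parsed <- as_taxa_matrix(counts)
  need <- ceiling(min_prevalence * ncol(parsed$mat))
  hits <- if (min_rel_abundance == 0) {
    rowSums(parsed$mat > 0)
  } else {
    rel <- sweep(parsed$mat, 2, colSums(parsed$mat), "/")
    rowSums(rel >= min_rel_abundance)
  }
  keep <- hits >= need
  out <- taxa_matrix_to_tibble(parsed$mat[keep, , drop = FALSE],
                               parsed$lineage)
  if (!any(keep)) attr(out, "empty") <- TRUE
  out
}

#' Ward dendrogram of taxa from a correlation matrix
#'
#' Converts correlations to the correlation distance \eqn{d = 1 - \rho}
#' (range [0, 2]) and applies Ward minimum-variance agglomeration. Taxa are
#' ordered lexicographically first so the result is invariant to input order.
#'
#' @param rho Symmetric correlation matrix with taxon dimnames.
#' @return An [stats::hclust] tree.
#' @export
ward_tree <- function(rho) {
  check_symmetric(rho, "correlation", arg = "rho")
  if (nrow(rho) < 2) abort("need at least 2 taxa to cluster.")
  ord <- order(rownames(rho))
  d <- stats::as.dist(1 - rho[ord, ord])
  hclust(d, method = "ward.D2")
}

#' Divide a Ward tree into guilds with PERMANOVA
#'
#' Top-down recursion from the root: at each internal node a PERMANOVA is run
#' on the 1-rho distance submatrix of the node's taxa, with the two child
#' memberships as the grouping. If the split is supported (p <= `alpha`) and
#' both children have at least 2 taxa, the recursion descends into both
#' children; otherwise the node's taxa become one guild. Every tested node is
#' recorded in `division_log`.
#'
#' @param tree An [stats::hclust] tree over the taxa of `rho`.
#' @param rho Symmetric correlation matrix (same taxa as `tree`).
#' @param n_perm Permutations per node test (>= 999; the cohort default is
#'   9999).
#' @param alpha Per-node significance level (default 0.001).
#' @param seed Integer seed; node tests draw deterministic sub-seeds.
#' @return An object of class `guild_partition`: `assignment` (tibble
#'   `taxon_id`, `guild`), `tree`, `division_log` (tibble of tested nodes),
#'   `n_guilds`, `alpha`, `n_perm`.
#' @export
divide_tree <- function(tree, rho, n_perm = 9999, alpha = 0.001, seed = 1) {
  stopifnot(inherits(tree, "hclust"))
  check_symmetric(rho, "correlation", arg = "rho")
  if (n_perm < 999) abort("n_perm must be at least 999.")
  stopifnot(alpha > 0, alpha < 1)
  ids <- tree$labels
  if (!setequal(ids, rownames(rho))) {
    abort("tree and rho must cover the same taxa.")
  }
  dmat <- 1 - rho[ids, ids]
  diag(dmat) <- 0
  # members below each merge node of the hclust tree
  n_leaf <- length(ids)
  members <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    get_side <- function(j) if (j < 0) ids[-j] else members[[j]]
    members[[i]] <- c(get_side(tree$merge[i, 1]), get_side(tree$merge[i, 2]))
  }
  child_sets <- function(node) {
    lapply(tree$merge[node, ], function(j) {
      if (j < 0) ids[-j] else members[[j]]
    })
  }
  guilds <- list()
  log_rows <- list()
  node_counter <- 0L
  recurse <- function(node) {
    # node: positive index into merge rows
    kids <- child_sets(node)
    left <- kids[[1]]; right <- kids[[2]]
    all_taxa <- c(left, right)
    if (length(left) >= 2 && length(right) >= 2) {
      node_counter <<- node_counter + 1L
      labels <- c(rep("L", length(left)), rep("R", length(right)))
      sub <- dmat[all_taxa, all_taxa]
      res <- permanova_test(sub, labels, n_perm = n_perm,
                            seed = stage_seed(seed, "permanova") + node_counter)
      log_rows[[length(log_rows) + 1L]] <<- tibble(
        node = node, n_taxa = length(all_taxa),
        n_left = length(left), n_right = length(right),
        pseudo_f = res$statistic, p_value = res$p_value,
        split_accepted = res$p_value <= alpha
      )
      if (res$p_value <= alpha) {
        descend <- function(side_taxa, side_node) {
          if (length(side_taxa) >= 2 && side_node > 0) {
            recurse(side_node)
          } else {
            guilds[[length(guilds) + 1L]] <<- side_taxa
          }
        }
        descend(left, tree$merge[node, 1])
        descend(right, tree$merge[node, 2])
        return(invisible(NULL))
      }
    }
    guilds[[length(guilds) + 1L]] <<- all_taxa
    invisible(NULL)
  }
  recurse(nrow(tree$merge))
  assignment <- bind_rows(purrr::imap(guilds, function(tx, g) {
    tibble(taxon_id = tx, guild = as.integer(g))
  })) %>% arrange(.data$guild, .data$taxon_id)
  structure(list(
    assignment = assignment,
    tree = tree,
    division_log = if (length(log_rows)) bind_rows(log_rows) else
      tibble(node = integer(), n_taxa = integer(), n_left = integer(),
             n_right = integer(), pseudo_f = double(), p_value = double(),
             split_accepted = logical()),
    n_guilds = length(guilds), alpha = alpha, n_perm = as.integer(n_perm)
  ), class = "guild_partition")
}

#' @export
print.guild_partition <- function(x, ...) {
  cat(sprintf("guild partition: %d taxa in %d guild(s) (alpha = %g, %d perms)\n",
              nrow(x$assignment), x$n_guilds, x$alpha, x$n_perm))
  invisible(x)
}

#' Per-sample guild abundances
#'
#' Sums the relative abundances of each guild's member taxa per sample.
#' Relative abundance is computed on the full (unfiltered) table so guild
#' abundances are comparable across samples; their per-sample sum equals the
#' summed relative abundance of the guild taxa (at most 1).
#'
#' @param partition A `guild_partition` from [divide_tree()].
#' @param counts The count table the partition's taxa came from.
#' @return A tibble: `guild`, then one column per sample.
#' @export
guild_abundance <- function(partition, counts) {
  stopifnot(inherits(partition, "guild_partition"))
  rel <- as_taxa_matrix(to_relative(counts))$mat
  missing <- setdiff(partition$assignment$taxon_id, rownames(rel))
  if (length(missing)) {
    abort(paste0("taxa in partition but not in counts: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  sub <- rel[partition$assignment$taxon_id, , drop = FALSE]
  agg <- rowsum(sub, group = partition$assignment$guild)
  dplyr::bind_cols(tibble(guild = as.integer(rownames(agg))),
                   as_tibble(agg, .name_repair = "minimal"))
}

#' Compare guild abundances across age groups
#'
#' Per guild: Kruskal-Wallis across G1/G2/G3, pairwise Wilcoxon rank-sum
#' tests, BH adjustment within each test family (across guilds), and group
#' medians.
#'
#' @param gab A guild-abundance tibble from [guild_abundance()].
#' @param metadata Sample metadata.
#' @return A tibble with one row per guild: `kw_p`, `kw_q`, per-pair
#'   `p_*`/`q_*` columns and `median_*` columns.
#' @export
guild_group_comparison <- function(gab, metadata) {
  stopifnot("guild" %in% names(gab))
  samples <- setdiff(names(gab), "guild")
  groups <- group_lookup(metadata, samples)
  lev <- sort(unique(groups))
  if (length(lev) < 2) abort("need at least 2 groups.", class = "mg_config_error")
  pair_names <- if (length(lev) >= 3) {
    utils::combn(lev, 2, FUN = function(z) paste(z, collapse = "v"))
  } else paste(lev, collapse = "v")
  rows <- purrr::map_dfr(seq_len(nrow(gab)), function(i) {
    y <- as.numeric(gab[i, samples])
    row <- tibble(guild = gab$guild[i])
    row$kw_p <- if (sd(y) == 0) 1 else
      suppressWarnings(kruskal.test(y, factor(groups))$p.value)
    for (lv in lev) {
      row[[paste0("median_", lv)]] <- median(y[groups == lv])
    }
    prs <- utils::combn(lev, 2, simplify = FALSE)
    for (pr in prs) {
      nm <- paste(pr, collapse = "v")
      ya <- y[groups == pr[1]]; yb <- y[groups == pr[2]]
      row[[paste0("p_", nm)]] <- if (sd(c(ya, yb)) == 0) 1 else
        suppressWarnings(wilcox.test(ya, yb)$p.value)
    }
    row
  })
  rows$kw_q <- bh_adjust(rows$kw_p)
  for (nm in paste0("p_", pair_names)) {
    rows[[sub("^p_", "q_", nm)]] <- bh_adjust(rows[[nm]])
  }
  rows
}

#' Guild interaction network above a correlation threshold
#'
#' Nodes are taxa annotated with guild id and mean relative abundance; edges
#' connect pairs with \eqn{|\rho|} above `edge_threshold` (the display rule
#' "absolute correlation greater than 0.70"). Isolated nodes are omitted from
#' the network but remain in the partition.
#'
#' @param rho Symmetric correlation matrix over the partition's taxa.
#' @param partition A `guild_partition`.
#' @param counts Count table for node mean relative abundances.
#' @param edge_threshold Absolute-correlation cutoff in (0, 1), default 0.70.
#' @return An `mg_network` (see [mg_network()]).
#' @export
guild_network <- function(rho, partition, counts, edge_threshold = 0.70) {
  stopifnot(edge_threshold > 0, edge_threshold < 1)
  check_symmetric(rho, "correlation", arg = "rho")
  rel <- as_taxa_matrix(to_relative(counts))$mat
  ids <- intersect(rownames(rho), partition$assignment$taxon_id)
  r <- rho[ids, ids]
  sel <- which(abs(r) > edge_threshold & upper.tri(r), arr.ind = TRUE)
  edges <- tibble(
    source = ids[sel[, 1]], target = ids[sel[, 2]],
    weight = r[sel], sign = ifelse(r[sel] >= 0, "+", "-")
  )
  connected <- union(edges$source, edges$target)
  nodes <- tibble(
    node = connected,
    mean_abundance = rowMeans(rel[connected, , drop = FALSE]),
    guild = partition$assignment$guild[
      match(connected, partition$assignment$taxon_id)]
  )
  mg_network(nodes, edges, rho_threshold = edge_threshold)
}
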