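# broom-style tidiers for the package's fitted objects.

#' Tidy a permutation test
#'
#' @param x An `mg_perm_test`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `statistic`, `p_value`,
#'   `n_permutations`, `exact`.
#' @export
tidy.mg_perm_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n_permutations = x$n_permutations, exact = x$exact)
}

#' Tidy a SparCC fit into an edge list
#'
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return Tibble of taxon pairs: `taxon_a`, `taxon_b`, `rho`.
#' @export
tidy.sparcc_fit <- function(x, ...) {
  r <- x$rho
  idx <- which(upper.tri(r), arr.ind = TRUE)
  tibble(taxon_a = rownames(r)[idx[, 1]], taxon_b = colnames(r)[idx[, 2]],
         rho = r[idx]) %>%
    arrange(dplyr::desc(abs(.data$rho)))
}

#' @rdname tidy.sparcc_fit
#' @export
glance.sparcc_fit <- function(x, ...) {
  tibble(n_taxa = nrow(x$rho), n_excluded_pairs = nrow(x$excluded_pairs),
         n_iterations = x$n_iterations, n_clipped = x$n_clipped,
         converged = x$converged, pseudocount = x$pseudocount)
}

#' Tidy a guild partition
#'
#' @param x A `guild_partition`.
#' @param ... Unused.
#' @return The taxon-to-guild assignment tibble.
#' @export
tidy.guild_partition <- function(x, ...) x$assignment

#' @rdname tidy.guild_partition
#' @export
glance.guild_partition <- function(x, ...) {
  sizes <- table(x$assignment$guild)
  tibble(n_taxa = nrow(x$assignment), n_guilds = x$n_guilds,
         largest_guild = max(sizes), smallest_guild = min(sizes),
         n_singletons = sum(sizes == 1), alpha = x$alpha, n_perm = x$n_perm)
}

#' Tidy a network into its edge list
#'
#' @param x An `mg_network`.
#' @param ... Unused.
#' @return The edge tibble (`source`, `target`, `weight`, `sign`).
#' @export
tidy.mg_network <- function(x, ...) x$edges

#' @rdname tidy.mg_network
#' @export
glance.mg_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_positive = sum(x$edges$sign == "+"),
         n_negative = sum(x$edges$sign == "-"),
         rho_threshold = x$rho_threshold)
}

#' Tidy a PCoA ordination
#'
#' @param x An `mg_pcoa`.
#' @param ... Unused.
#' @return The sample coordinate tibble.
#' @export
tidy.mg_pcoa <- function(x, ...) x$points

#' @rdname tidy.mg_pcoa
#' @export
glance.mg_pcoa <- function(x, ...) {
  tibble(k_returned = x$k_returned, truncated = x$truncated,
         rel_eigen_1 = x$rel_eigen[1],
         rel_eigen_2 = if (length(x$rel_eigen) > 1) x$rel_eigen[2]
         else NA_real_,
         n_negative_eigen = sum(x$eigenvalues < 0))
}
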