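# Co-occurrence networks per age group and their discrepancy analysis.

#' Construct a microbial network object
#'
#' Lightweight undirected-network container: a node tibble (`node`,
#' `mean_abundance`, optional extras) and an edge tibble (`source`, `target`,
#' `weight`, `sign`). No self-loops or duplicate edges; every stored edge
#' satisfies the correlation threshold it was built with.
#'
#' @param nodes Tibble with a `node` column (plus attributes).
#' @param edges Tibble with `source`, `target`, `weight`, `sign` columns.
#' @param rho_threshold The threshold the edges were filtered at (metadata).
#' @return An object of class `mg_network`.
#' @export
mg_network <- function(nodes, edges, rho_threshold = NA_real_) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot("node" %in% names(nodes),
            all(c("source", "target", "weight", "sign") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) abort("self-loop edge.")
    key <- edge_key(edges$source, edges$target)
    if (anyDuplicated(key)) abort("duplicate edge.")
    if (!all(c(edges$source, edges$target) %in% nodes$node)) {
      abort("edge endpoint missing from node table.")
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 rho_threshold = rho_threshold),
            class = "mg_network")
}

# Canonical unordered-pair key (sign-blind edge identity).
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @export
print.mg_network <- function(x, ...) {
  cat(sprintf("mg_network: %d node(s), %d edge(s)", nrow(x$nodes),
              nrow(x$edges)))
  if (!is.na(x$rho_threshold)) cat(sprintf(" (|rho| >= %g)", x$rho_threshold))
  cat("\n")
  invisible(x)
}

#' Write / read a network
#'
#' `edge_tsv` writes the edge list (`source`, `target`, `weight`, `sign`) plus
#' a companion `<path>.nodes.tsv` node table so the round trip is lossless
#' even for isolated nodes; `graphml` writes a single GraphML file via igraph
#' with the same attributes.
#'
#' @param net An `mg_network`.
#' @param path Output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly (writer); an `mg_network` (reader).
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "mg_network"))
  if (format == "edge_tsv") {
    readr::write_tsv(net$edges, path, progress = FALSE)
    readr::write_tsv(net$nodes, paste0(path, ".nodes.tsv"), progress = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(edges) == 0) {
      edges <- tibble(source = character(), target = character(),
                      weight = double(), sign = character())
    }
    nodes_path <- paste0(path, ".nodes.tsv")
    nodes <- if (file.exists(nodes_path)) {
      readr::read_tsv(nodes_path, show_col_types = FALSE, progress = FALSE)
    } else {
      tibble(node = union(edges$source, edges$target))
    }
    mg_network(nodes, edges)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    nodes <- as_tibble(va) %>% rename(node = "name")
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble(source = ed$from, target = ed$to,
                    weight = if ("weight" %in% names(ed)) ed$weight else
                      rep(NA_real_, nrow(ed)),
                    sign = if ("sign" %in% names(ed)) ed$sign else
                      ifelse(ed$weight >= 0, "+", "-"))
    mg_network(nodes, edges)
  }
}

# mg_network -> igraph (unsigned simple graph with attributes).
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(net$edges[, c("source", "target", "weight", "sign")]),
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
  g
}

#' Per-group Spearman co-occurrence network
#'
#' Within one age group: taxa are filtered by prevalence/abundance inside the
#' group, all-vs-all mid-rank Spearman correlations are computed on relative
#' abundances, and edges are kept when \eqn{|\rho| \ge} `rho_threshold` AND
#' BH q < `q_threshold` (the "rho >= 0.7, FDR < 0.05" rule). Node attribute
#' `mean_abundance` is the group-mean relative abundance; isolated nodes are
#' kept in the node table.
#'
#' @param counts Count-table tibble or matrix (all samples).
#' @param metadata Sample metadata.
#' @param group Which group to build the network for (`"G1"`, `"G2"`, `"G3"`).
#' @param min_prevalence,min_rel_abundance Within-group taxon filter; the
#'   defaults follow the display rule (0.1% relative abundance in >= 20% of
#'   the group's samples).
#' @param rho_threshold Absolute Spearman threshold (default 0.7).
#' @param q_threshold BH q cutoff (default 0.05).
#' @return An `mg_network`; the full correlation table is attached as
#'   attribute `"tests"`.
#' @export
cooccurrence_network <- function(counts, metadata, group,
                                 min_prevalence = 0.2,
                                 min_rel_abundance = 0.001,
                                 rho_threshold = 0.7, q_threshold = 0.05) {
  parsed <- as_taxa_matrix(counts)
  groups <- group_lookup(metadata, colnames(parsed$mat))
  sel <- names(groups)[groups == group]
  if (length(sel) < 5) {
    abort(sprintf("group %s has %d samples; need at least 5.", group,
                  length(sel)), class = "mg_precondition_error")
  }
  sub <- parsed$mat[, sel, drop = FALSE]
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]
  filt <- as_taxa_matrix(
    prevalence_filter(sub, min_prevalence, min_rel_abundance))$mat
  if (nrow(filt) < 2) {
    return(mg_network(tibble(node = rownames(filt),
                             mean_abundance = double(nrow(filt))),
                      tibble(source = character(), target = character(),
                             weight = double(), sign = character()),
                      rho_threshold))
  }
  rel <- sweep(filt, 2, colSums(sub)[colnames(filt)], "/")
  tests <- spearman_assoc(rel)
  keep <- !is.na(tests$rho) & abs(tests$rho) >= rho_threshold &
    !is.na(tests$q) & tests$q < q_threshold
  edges <- tests[keep, ] %>%
    mutate(weight = .data$rho, sign = ifelse(.data$rho >= 0, "+", "-")) %>%
    select(source = "id_a", target = "id_b", "weight", "sign")
  nodes <- tibble(node = rownames(rel), mean_abundance = rowMeans(rel))
  out <- mg_network(nodes, edges, rho_threshold)
  attr(out, "tests") <- tests
  out
}

# Wasserman-Faust closeness for possibly disconnected graphs:
#   C(v) = ((r_v - 1) / (n - 1)) * ((r_v - 1) / sum of distances to reachable)
# with r_v the size of v's reachable set (component). Isolated vertices get 0.
closeness_wf <- function(g) {
  n <- igraph::vcount(g)
  dm <- igraph::distances(g, weights = NA) # hop counts, not correlations
  vapply(seq_len(n), function(v) {
    dv <- dm[v, -v]
    reach <- is.finite(dv)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(dv[reach]))
  }, numeric(1))
}

# Eigenvector centrality of the unsigned adjacency by power iteration,
# deterministic uniform start, normalised to max 1.
eigen_centrality_power <- function(g, tol = 1e-10, max_iter = 10000) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- abs(adj)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    x_new <- adj %*% x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) return(rep(0, n))
    x_new <- as.numeric(x_new / nrm)
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x <- abs(x)
  if (max(x) > 0) x <- x / max(x)
  x
}

#' Compare co-occurrence networks across groups
#'
#' Edge identity is the unordered node pair, sign-blind; sign flips between
#' groups are reported as discordant. `shared_edges` appear in every group,
#' `specific_edges` in exactly one; edges in more than one but not all groups
#' are counted in `partial_edges`. Closeness (Wasserman-Faust, component
#' scaled) and eigenvector centralities (power iteration on the unsigned
#' adjacency, max-normalised) are reported, with within-group ranks, for
#' nodes present in every network.
#'
#' @param nets Named list of `mg_network` objects (>= 2), e.g.
#'   `list(G1 = ..., G2 = ..., G3 = ...)`.
#' @return An object of class `network_comparison`: `edge_counts` (tibble per
#'   group), `shared_edges`, `specific_edges`, `partial_edges`,
#'   `discordant_edges`, `centrality` (tibble), `shared_nodes`.
#' @export
compare_networks <- function(nets) {
  stopifnot(length(nets) >= 2, all(vapply(nets, inherits, TRUE, "mg_network")))
  if (is.null(names(nets)) || any(!nzchar(names(nets)))) {
    abort("`nets` must be a named list.")
  }
  edge_tbl <- purrr::imap_dfr(nets, function(nt, g) {
    if (nrow(nt$edges) == 0) {
      return(tibble(group = character(), key = character(),
                    source = character(), target = character(),
                    weight = double(), sign = character()))
    }
    mutate(nt$edges, group = g, key = edge_key(.data$source, .data$target),
           .before = 1)
  })
  n_groups <- length(nets)
  by_key <- edge_tbl %>% group_by(.data$key) %>%
    summarise(n_groups_present = dplyr::n_distinct(.data$group),
              n_signs = dplyr::n_distinct(.data$sign),
              source = .data$source[1], target = .data$target[1],
              groups = paste(sort(unique(.data$group)), collapse = ","))
  shared <- filter(by_key, .data$n_groups_present == n_groups)
  specific <- filter(by_key, .data$n_groups_present == 1)
  partial <- filter(by_key, .data$n_groups_present > 1,
                    .data$n_groups_present < n_groups)
  discordant <- filter(by_key, .data$n_signs > 1)
  shared_nodes <- purrr::reduce(purrr::map(nets, ~ .x$nodes$node), intersect)
  centrality <- purrr::imap_dfr(nets, function(nt, g) {
    if (nrow(nt$nodes) == 0) return(tibble())
    ig <- as_igraph(nt)
    tibble(group = g, node = igraph::V(ig)$name,
           closeness = closeness_wf(ig),
           eigenvector = eigen_centrality_power(ig))
  }) %>%
    filter(.data$node %in% shared_nodes) %>%
    group_by(.data$group) %>%
    mutate(closeness_rank = rank(-.data$closeness, ties.method = "average"),
           eigenvector_rank = rank(-.data$eigenvector,
                                   ties.method = "average")) %>%
    ungroup()
  structure(list(
    edge_counts = purrr::imap_dfr(nets, function(nt, g) {
      tibble(group = g, n_nodes = nrow(nt$nodes), n_edges = nrow(nt$edges),
             n_specific = sum(specific$groups == g))
    }),
    shared_edges = select(shared, "source", "target", "groups"),
    specific_edges = select(specific, "source", "target", "groups"),
    partial_edges = select(partial, "source", "target", "groups"),
    discordant_edges = select(discordant, "source", "target", "groups"),
    centrality = centrality,
    shared_nodes = shared_nodes
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("network comparison:\n")
  print(x$edge_counts)
  cat(sprintf("shared edges: %d; partial: %d; discordant sign: %d\n",
              nrow(x$shared_edges), nrow(x$partial_edges),
              nrow(x$discordant_edges)))
  invisible(x)
}

#' Associate taxa with continuous host variables
#'
#' Spearman rho/p for every (taxon, host variable) pair on relative
#' abundances, BH adjustment over the full pair family, significance flags at
#' `q_threshold`. Host variables that are entirely missing or constant are
#' excluded with a warning. Used for the taxa-vs-cytokine/amyloid/BDNF panel.
#'
#' @param counts Count-table tibble or matrix.
#' @param metadata Metadata tibble whose extra numeric columns are the host
#'   variables.
#' @param taxa Optional subset of taxa (default all).
#' @param vars Optional subset of host-variable names (default every numeric
#'   metadata column besides `generation`).
#' @param q_threshold Significance cutoff (default 0.05).
#' @return A tibble: `taxon_id`, `variable`, `n`, `rho`, `p`, `q`,
#'   `significant`.
#' @export
host_association <- function(counts, metadata, taxa = NULL, vars = NULL,
                             q_threshold = 0.05) {
  rel <- as_taxa_matrix(to_relative(counts))$mat
  md <- as_tibble(metadata)
  if (is.null(vars)) {
    reserved <- c("sample_id", "group", "family_id", "generation")
    vars <- names(md)[!names(md) %in% reserved &
                        vapply(md, is.numeric, TRUE)]
  }
  if (length(vars) == 0) abort("no host variables found.")
  if (!is.null(taxa)) rel <- rel[intersect(taxa, rownames(rel)), , drop = FALSE]
  idx <- match(colnames(rel), md$sample_id)
  if (anyNA(idx)) abort("samples without metadata.", class = "mg_metadata_error")
  hv <- t(as.matrix(md[idx, vars, drop = FALSE]))
  colnames(hv) <- colnames(rel)
  usable <- apply(hv, 1, function(z) sum(!is.na(z)) >= 5 &&
                    sd(z, na.rm = TRUE) > 0)
  if (any(!usable)) {
    warn(paste0("host variable(s) excluded (all-missing or constant): ",
                paste(rownames(hv)[!usable], collapse = ", ")))
    hv <- hv[usable, , drop = FALSE]
  }
  if (nrow(hv) == 0) abort("no usable host variables.")
  res <- spearman_assoc(rel, hv)
  res %>%
    rename(taxon_id = "id_a", variable = "id_b") %>%
    mutate(significant = !is.na(.data$q) & .data$q < q_threshold)
}
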