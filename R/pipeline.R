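# End-to-end orchestration: validate -> diversity -> sparcc/guilds ->
# networks -> signatures -> stable species, with a reproducibility manifest.

#' Run the full cohort analysis pipeline
#'
#' Chains every stage on a count table + metadata, collecting results and a
#' manifest (stage, output hash, wall time, seed). Re-running with the same
#' inputs, parameters and seed reproduces identical hashes.
#'
#' @param counts Count-table tibble or matrix.
#' @param metadata Sample metadata tibble.
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV (and networks additionally as GraphML) under fixed names,
#'   together with `manifest.tsv` and the effective `config.json`.
#' @param min_prevalence,min_rel_abundance Guild-stage prevalence filter
#'   (defaults: presence in >= 20% of samples).
#' @param pseudocount,exclusion_threshold SparCC parameters.
#' @param n_perm Permutations for tree division and ANOSIM (cohort default
#'   9999; reduce for quick runs).
#' @param alpha Tree-division significance level.
#' @param edge_threshold Guild-network display threshold.
#' @param net_min_prevalence,net_min_rel_abundance,rho_threshold,q_threshold
#'   Per-group co-occurrence network parameters (display-rule defaults).
#' @param n_boot,subsample_size,ci_level Bootstrap-confirmation parameters.
#' @param seed Global seed; each stage derives its own sub-seed.
#' @param stages Character vector of stages to run (dependencies are not
#'   auto-resolved; `guilds` requires nothing else, `networks` and
#'   `signatures` are independent).
#' @return A list of class `mg_pipeline_run`: `results` (named list),
#'   `manifest` (tibble), `params`.
#' @export
run_cohort_pipeline <- function(counts, metadata, out_dir = NULL,
                                min_prevalence = 0.2, min_rel_abundance = 0,
                                pseudocount = 0.5, exclusion_threshold = 0.8,
                                n_perm = 9999, alpha = 0.001,
                                edge_threshold = 0.70,
                                net_min_prevalence = 0.2,
                                net_min_rel_abundance = 0.001,
                                rho_threshold = 0.7, q_threshold = 0.05,
                                n_boot = 1000, subsample_size = 10,
                                ci_level = 0.90, seed = 1,
                                stages = c("diversity", "guilds", "networks",
                                           "signatures", "stable")) {
  parsed <- as_taxa_matrix(counts)
  md <- as_tibble(metadata)
  params <- list(
    min_prevalence = min_prevalence, min_rel_abundance = min_rel_abundance,
    pseudocount = pseudocount, exclusion_threshold = exclusion_threshold,
    n_perm = n_perm, alpha = alpha, edge_threshold = edge_threshold,
    net_min_prevalence = net_min_prevalence,
    net_min_rel_abundance = net_min_rel_abundance,
    rho_threshold = rho_threshold, q_threshold = q_threshold,
    n_boot = n_boot, subsample_size = subsample_size, ci_level = ci_level,
    seed = seed, stages = stages
  )
  violations <- validate_cohort(parsed$mat, md)
  fatal <- violations$check %in%
    c("missing_metadata", "bad_group", "zero_sample")
  if (any(fatal)) {
    abort(paste0("input validation failed: ",
                 paste(sprintf("%s (%s)", violations$check[fatal],
                               violations$item[fatal]), collapse = "; ")),
          class = "mg_validation_error")
  }
  results <- list(validation = violations)
  manifest <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- fn()
    elapsed <- proc.time()[["elapsed"]] - t0
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = name, hash = rlang::hash(out),
      elapsed_s = round(elapsed, 3), seed = as.integer(seed)
    )
    out
  }
  if ("diversity" %in% stages) {
    results$diversity <- run_stage("diversity", function() {
      rel <- to_relative(parsed$mat)
      d <- bray_curtis(rel)
      groups <- group_lookup(md, colnames(parsed$mat))
      list(alpha = alpha_diversity(parsed$mat, md),
           bray_curtis = d,
           pcoa = pcoa(d, k = 2),
           anosim = anosim_test(d, groups, n_perm = min(n_perm, 9999),
                                seed = stage_seed(seed, "anosim")),
           fb_ratio = if (!is.null(parsed$lineage))
             firmicutes_bacteroidetes_ratio(counts, md) else NULL)
    })
  }
  if ("guilds" %in% stages) {
    results$guilds <- run_stage("guilds", function() {
      filt <- prevalence_filter(parsed$mat, min_prevalence, min_rel_abundance)
      fit <- sparcc(filt, pseudocount = pseudocount,
                    exclusion_threshold = exclusion_threshold,
                    seed = stage_seed(seed, "sparcc"))
      tree <- ward_tree(fit$rho)
      partition <- divide_tree(tree, fit$rho, n_perm = n_perm, alpha = alpha,
                               seed = stage_seed(seed, "guilds"))
      gab <- guild_abundance(partition, parsed$mat)
      list(filtered = filt, sparcc = fit, partition = partition,
           abundance = gab,
           comparison = guild_group_comparison(gab, md),
           network = guild_network(fit$rho, partition, parsed$mat,
                                   edge_threshold))
    })
  }
  if ("networks" %in% stages) {
    results$networks <- run_stage("networks", function() {
      grs <- sort(unique(md$group))
      nets <- setNames(purrr::map(grs, function(g) {
        cooccurrence_network(parsed$mat, md, g,
                             min_prevalence = net_min_prevalence,
                             min_rel_abundance = net_min_rel_abundance,
                             rho_threshold = rho_threshold,
                             q_threshold = q_threshold)
      }), grs)
      list(networks = nets, comparison = compare_networks(nets))
    })
  }
  if ("signatures" %in% stages) {
    results$signatures <- run_stage("signatures", function() {
      diff <- differential_abundance(parsed$mat, md,
                                     q_threshold = q_threshold)
      cls <- classify_signatures(diff)
      boots <- purrr::map_dfr(names(sig_pairs), function(nm) {
        sig_taxa <- diff$taxon_id[diff[[paste0("q_", nm)]] < q_threshold]
        if (length(sig_taxa) == 0) return(tibble())
        bootstrap_confirm(parsed$mat, md, taxa = sig_taxa,
                          pair = sig_pairs[[nm]], n_boot = n_boot,
                          subsample_size = subsample_size,
                          ci_level = ci_level,
                          seed = stage_seed(seed, "signatures"))
      })
      list(differential = diff, classes = cls, bootstrap = boots)
    })
  }
  if ("stable" %in% stages &&
      "family_id" %in% names(md) && any(!is.na(md$family_id))) {
    results$stable <- run_stage("stable", function() {
      stable_species(parsed$mat, md)
    })
  }
  manifest <- bind_rows(manifest)
  run <- structure(list(results = results, manifest = manifest,
                        params = params), class = "mg_pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, counts, out_dir)
  run
}

#' @export
print.mg_pipeline_run <- function(x, ...) {
  cat("cohort pipeline run:\n")
  print(x$manifest)
  invisible(x)
}

# Fixed-name TSV/GraphML outputs + manifest + effective config.
write_pipeline_outputs <- function(run, counts, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(out_dir, name), progress = FALSE)
  }
  res <- run$results
  w(res$validation, "validation.tsv")
  if (!is.null(res$diversity)) {
    w(res$diversity$alpha, "alpha_diversity.tsv")
    w(res$diversity$pcoa$points, "pcoa_coordinates.tsv")
    bc <- res$diversity$bray_curtis
    w(dplyr::bind_cols(tibble(sample_id = rownames(bc)),
                       as_tibble(bc, .name_repair = "minimal")),
      "bray_curtis.tsv")
    w(tidy(res$diversity$anosim), "anosim.tsv")
    if (!is.null(res$diversity$fb_ratio)) w(res$diversity$fb_ratio,
                                            "fb_ratio.tsv")
  }
  if (!is.null(res$guilds)) {
    w(res$guilds$partition$assignment, "guild_assignment.tsv")
    w(res$guilds$partition$division_log, "division_log.tsv")
    w(res$guilds$abundance, "guild_abundance.tsv")
    w(res$guilds$comparison, "guild_tests.tsv")
    write_network(res$guilds$network, file.path(out_dir, "guild_network.tsv"),
                  "edge_tsv")
    write_network(res$guilds$network,
                  file.path(out_dir, "guild_network.graphml"), "graphml")
    rho <- res$guilds$sparcc$rho
    w(dplyr::bind_cols(tibble(taxon_id = rownames(rho)),
                       as_tibble(rho, .name_repair = "minimal")),
      "sparcc_rho.tsv")
  }
  if (!is.null(res$networks)) {
    for (g in names(res$networks$networks)) {
      write_network(res$networks$networks[[g]],
                    file.path(out_dir, sprintf("network_%s.tsv", g)),
                    "edge_tsv")
    }
    cmp <- res$networks$comparison
    w(cmp$edge_counts, "network_edge_counts.tsv")
    w(cmp$centrality, "network_centrality.tsv")
    w(cmp$shared_edges, "network_shared_edges.tsv")
    w(cmp$specific_edges, "network_specific_edges.tsv")
  }
  if (!is.null(res$signatures)) {
    w(res$signatures$differential, "diff_abundance.tsv")
    w(res$signatures$classes, "signatures.tsv")
    if (nrow(res$signatures$bootstrap)) w(res$signatures$bootstrap,
                                          "bootstrap.tsv")
  }
  if (!is.null(res$stable)) w(res$stable, "stable_species.tsv")
  w(run$manifest, "manifest.tsv")
  jsonlite::write_json(run$params, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
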