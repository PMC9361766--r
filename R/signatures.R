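# Aging-trajectory signatures: pairwise differential abundance, bootstrap
# confirmation, rejuvenation/centenarian classification, stable species.
#
# Age order is G3 (young) < G2 (elderly) < G1 (centenarian). The three
# canonical pairs are G3vG2, G2vG1 and G3vG1; `dir_*` is the sign of
# (median of the older group - median of the younger group).

sig_pairs <- list(G3vG2 = c("G3", "G2"), G2vG1 = c("G2", "G1"),
                  G3vG1 = c("G3", "G1"))

#' Pairwise differential abundance across age groups
#'
#' Per taxon, Wilcoxon rank-sum tests for G3 vs G2, G2 vs G1 and G3 vs G1 on
#' relative abundances, BH adjustment within each pairwise family (across
#' taxa), and the direction of the median change toward the older group.
#' Constant taxa get p = 1 and direction 0.
#'
#' @param counts Count-table tibble or matrix (all three groups present, each
#'   with >= 3 samples).
#' @param metadata Sample metadata.
#' @param q_threshold Stored on the result for downstream classification
#'   (default 0.05).
#' @return A tibble with one row per taxon: `median_G*`, `mean_G*`, and per
#'   pair `p_*`, `q_*`, `dir_*` (+1/-1/0).
#' @export
differential_abundance <- function(counts, metadata, q_threshold = 0.05) {
  rel <- as_taxa_matrix(to_relative(counts))$mat
  groups <- group_lookup(metadata, colnames(rel))
  sizes <- table(factor(groups, levels = c("G1", "G2", "G3")))
  if (any(sizes < 3)) {
    abort("all three groups must be present with at least 3 samples each.",
          class = "mg_precondition_error")
  }
  out <- tibble(taxon_id = rownames(rel))
  for (g in c("G3", "G2", "G1")) {
    out[[paste0("median_", g)]] <-
      unname(apply(rel[, groups == g, drop = FALSE], 1, median))
    out[[paste0("mean_", g)]] <-
      unname(rowMeans(rel[, groups == g, drop = FALSE]))
  }
  for (nm in names(sig_pairs)) {
    young <- sig_pairs[[nm]][1]
    old <- sig_pairs[[nm]][2]
    ya <- rel[, groups == young, drop = FALSE]
    yb <- rel[, groups == old, drop = FALSE]
    p <- vapply(seq_len(nrow(rel)), function(i) {
      if (sd(c(ya[i, ], yb[i, ])) == 0) return(1)
      suppressWarnings(wilcox.test(ya[i, ], yb[i, ])$p.value)
    }, numeric(1))
    out[[paste0("p_", nm)]] <- p
    out[[paste0("q_", nm)]] <- bh_adjust(p)
    out[[paste0("dir_", nm)]] <-
      sign(out[[paste0("median_", old)]] - out[[paste0("median_", young)]])
  }
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Bootstrap confirmation of a group difference
#'
#' Per taxon and group pair: `n_boot` times, `subsample_size` samples are
#' drawn with replacement from each group, the difference of mean relative
#' abundance (older minus younger) is recorded, and the empirical central
#' `ci_level` percentile interval is formed. The difference is confirmed when
#' the interval excludes 0. Defaults (1000 replicates, subsample 10, 90%
#' interval) follow the cohort protocol.
#'
#' @param counts Count-table tibble or matrix.
#' @param metadata Sample metadata.
#' @param taxa Taxa to confirm (default all).
#' @param pair Length-2 group pair, younger first (default `c("G3","G1")`).
#' @param n_boot Bootstrap replicates.
#' @param subsample_size Draws per group per replicate (with replacement).
#' @param ci_level Central interval mass (default 0.90).
#' @param seed Integer seed.
#' @return A tibble: `taxon_id`, `pair`, `mean_diff` (observed), `ci_low`,
#'   `ci_high`, `confirmed`, `n_boot`, `subsample_size`, `seed`.
#' @export
bootstrap_confirm <- function(counts, metadata, taxa = NULL,
                              pair = c("G3", "G1"), n_boot = 1000,
                              subsample_size = 10, ci_level = 0.90,
                              seed = 1) {
  stopifnot(length(pair) == 2, ci_level > 0, ci_level < 1)
  rel <- as_taxa_matrix(to_relative(counts))$mat
  if (!is.null(taxa)) rel <- rel[intersect(taxa, rownames(rel)), , drop = FALSE]
  groups <- group_lookup(metadata, colnames(rel))
  sa <- which(groups == pair[1])
  sb <- which(groups == pair[2])
  if (length(sa) == 0 || length(sb) == 0) {
    abort(sprintf("pair group(s) absent from metadata: %s",
                  paste(pair, collapse = ", ")))
  }
  if (length(sa) < 3 || length(sb) < 3) {
    warn("a pair group has fewer than 3 samples; intervals will be fragile.")
  }
  old_rng <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_rng))
  set.seed(stage_seed(seed, "bootstrap"))
  # Shared draw matrices across taxa: column r of S holds the multiplicity of
  # each group sample in replicate r, so taxon means are one matrix product.
  draw_matrix <- function(idx) {
    s <- matrix(0, length(idx), n_boot)
    for (r in seq_len(n_boot)) {
      picks <- sample.int(length(idx), subsample_size, replace = TRUE)
      s[, r] <- tabulate(picks, nbins = length(idx))
    }
    s / subsample_size
  }
  s_a <- draw_matrix(sa)
  s_b <- draw_matrix(sb)
  means_a <- rel[, sa, drop = FALSE] %*% s_a
  means_b <- rel[, sb, drop = FALSE] %*% s_b
  diffs <- means_b - means_a # older minus younger
  alpha <- 1 - ci_level
  lo <- apply(diffs, 1, quantile, probs = alpha / 2, names = FALSE)
  hi <- apply(diffs, 1, quantile, probs = 1 - alpha / 2, names = FALSE)
  tibble(
    taxon_id = rownames(rel),
    pair = paste(pair, collapse = "v"),
    mean_diff = rowMeans(rel[, sb, drop = FALSE]) -
      rowMeans(rel[, sa, drop = FALSE]),
    ci_low = lo, ci_high = hi,
    confirmed = lo > 0 | hi < 0,
    n_boot = as.integer(n_boot),
    subsample_size = as.integer(subsample_size),
    seed = as.integer(seed)
  )
}

#' Classify aging-trajectory signatures
#'
#' Pure function of the pairwise significance pattern (q < `q_threshold`) and
#' median directions, applied in priority order:
#' \describe{
#'   \item{rejuvenation}{young and centenarian similar (G3vG1 not
#'     significant) but both distinct from the elderly.}
#'   \item{centenarian}{young and elderly similar (G3vG2 not significant) but
#'     both distinct from centenarians.}
#'   \item{monotone_increase / monotone_decrease}{both adjacent steps
#'     significant in the same direction toward older age, or only the
#'     G3-vs-G1 extreme significant.}
#'   \item{stable}{no pairwise test significant.}
#'   \item{other}{any remaining pattern.}
#' }
#'
#' @param diff Output of [differential_abundance()].
#' @param q_threshold Significance cutoff; defaults to the one stored on
#'   `diff`.
#' @return A tibble: `taxon_id`, `class`, plus the significance pattern
#'   columns `sig_G3vG2`, `sig_G2vG1`, `sig_G3vG1`.
#' @export
classify_signatures <- function(diff, q_threshold = NULL) {
  if (is.null(q_threshold)) {
    q_threshold <- attr(diff, "q_threshold") %||% 0.05
  }
  need <- c(paste0("q_", names(sig_pairs)), paste0("dir_", names(sig_pairs)))
  if (!all(need %in% names(diff))) {
    abort("`diff` must come from differential_abundance().")
  }
  s32 <- diff$q_G3vG2 < q_threshold
  s21 <- diff$q_G2vG1 < q_threshold
  s31 <- diff$q_G3vG1 < q_threshold
  d32 <- diff$dir_G3vG2
  d21 <- diff$dir_G2vG1
  d31 <- diff$dir_G3vG1
  cls <- dplyr::case_when(
    !s31 & s21 & s32 ~ "rejuvenation",
    !s32 & s21 & s31 ~ "centenarian",
    s32 & s21 & d32 > 0 & d21 > 0 ~ "monotone_increase",
    s32 & s21 & d32 < 0 & d21 < 0 ~ "monotone_decrease",
    s31 & !s32 & !s21 & d31 > 0 ~ "monotone_increase",
    s31 & !s32 & !s21 & d31 < 0 ~ "monotone_decrease",
    !s32 & !s21 & !s31 ~ "stable",
    TRUE ~ "other"
  )
  tibble(taxon_id = diff$taxon_id, class = cls,
         sig_G3vG2 = s32, sig_G2vG1 = s21, sig_G3vG1 = s31)
}

#' Identify family-stable species
#'
#' A taxon is a stable (heritable) species when it is present (relative
#' abundance > 0 in at least one member) in at least `min_family_fraction` of
#' the eligible families — families sampled in at least two distinct age
#' groups — AND shows no significant abundance difference across the three
#' groups (Kruskal-Wallis p >= `p_threshold`, unadjusted by default: an
#' absence-of-evidence criterion).
#'
#' @param counts Count-table tibble or matrix.
#' @param metadata Metadata with `family_id`.
#' @param min_family_fraction Minimum fraction of eligible families (default
#'   0.5).
#' @param p_threshold Kruskal-Wallis floor (default 0.05).
#' @param adjust Use BH-adjusted Kruskal-Wallis q instead of raw p.
#' @return A tibble: `taxon_id`, `n_families_present`, `n_eligible_families`,
#'   `family_fraction`, `kw_p` (and `kw_q` when `adjust`), `stable`.
#' @export
stable_species <- function(counts, metadata, min_family_fraction = 0.5,
                           p_threshold = 0.05, adjust = FALSE) {
  rel <- as_taxa_matrix(to_relative(counts))$mat
  md <- as_tibble(metadata)
  if (!"family_id" %in% names(md)) {
    abort("metadata must have `family_id`.", class = "mg_precondition_error")
  }
  groups <- group_lookup(md, colnames(rel))
  fam <- setNames(as.character(md$family_id[match(colnames(rel),
                                                  md$sample_id)]),
                  colnames(rel))
  eligible <- md %>%
    filter(!is.na(.data$family_id), .data$sample_id %in% colnames(rel)) %>%
    group_by(.data$family_id) %>%
    summarise(n_groups = dplyr::n_distinct(.data$group)) %>%
    filter(.data$n_groups >= 2) %>%
    pull(.data$family_id)
  if (length(eligible) < 2) {
    abort("need at least 2 families sampled in 2 or more groups.",
          class = "mg_precondition_error")
  }
  present_in_family <- vapply(eligible, function(f) {
    rowSums(rel[, !is.na(fam) & fam == f, drop = FALSE] > 0) > 0
  }, logical(nrow(rel)))
  n_present <- unname(rowSums(present_in_family))
  kw_p <- vapply(seq_len(nrow(rel)), function(i) {
    if (sd(rel[i, ]) == 0) return(1)
    suppressWarnings(kruskal.test(rel[i, ], factor(groups))$p.value)
  }, numeric(1))
  out <- tibble(
    taxon_id = rownames(rel),
    n_families_present = as.integer(n_present),
    n_eligible_families = length(eligible),
    family_fraction = n_present / length(eligible),
    kw_p = kw_p
  )
  crit_p <- if (adjust) {
    out$kw_q <- bh_adjust(kw_p)
    out$kw_q
  } else kw_p
  out$stable <- out$family_fraction >= min_family_fraction &
    crit_p >= p_threshold
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
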