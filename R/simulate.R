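# Synthetic three-generation cohort with planted ground truth.
#
# Generative model, per sample k and taxon i:
#   y_ik = mu_i + lambda_i * f_{g(i),k} + beta_i(group_k) * delta
#          + gamma_{i,fam(k)} + eps_ik,      eps ~ N(0, sigma^2)
# with guild factors f ~ N(0, tau^2), loadings lambda in a configured range,
# fixed trajectory patterns beta over (G3, G2, G1), and family effects gamma
# drawn once per (taxon, family) for stable-class taxa. The composition is
# the softmax of y over taxa; counts are multinomial at a lognormal depth.

beta_patterns <- list(
  monotone_up = c(G3 = 0, G2 = 0.5, G1 = 1),
  monotone_down = c(G3 = 1, G2 = 0.5, G1 = 0),
  rejuvenation = c(G3 = 0, G2 = 1, G1 = 0),
  centenarian = c(G3 = 0, G2 = 0, G1 = 1),
  stable = c(G3 = 0, G2 = 0, G1 = 0)
)

#' Default synthetic cohort configuration
#'
#' The documented stated world: 150 taxa, 8 planted guilds (sizes 5-15, 78
#' taxa; the rest are free/independent), group sizes G3 = 11, G2 = 30,
#' G1 = 32 (73 samples), 32 families each contributing at most one sample per
#' group, trajectory effect delta = 1.5 (in log-abundance SD units), guild
#' factor SD tau = 1, residual SD sigma = 0.5, family effect SD 1, sequencing
#' depth ~ LogNormal(ln 20000, 0.3). Ten taxa each are planted with
#' monotone-up, monotone-down, rejuvenation and centenarian trajectories
#' (drawn from the free taxa); all other taxa are stable. Two host variables
#' emulate an inflammatory cytokine rising with the monotone-up taxa and a
#' neurotrophin tracking the monotone-down taxa.
#'
#' @param ... Overrides for any config field (see [simulate_cohort()]).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_taxa = 150L,
    guild_sizes = c(5L, 7L, 8L, 9L, 10L, 11L, 13L, 15L),
    group_sizes = c(G3 = 11L, G2 = 30L, G1 = 32L),
    n_families = 32L,
    depth_log_mean = log(20000),
    depth_log_sd = 0.3,
    guild_factor_sd = 1,
    loading_range = c(0.8, 1.2),
    n_signature = c(monotone_up = 10L, monotone_down = 10L,
                    rejuvenation = 10L, centenarian = 10L),
    signature_assignment = NULL, # derived below unless supplied
    effect_size = 1.5,
    family_effect_sd = 1,
    noise_sd = 0.5,
    base_log_sd = 1.5,
    overdispersion = 0,
    host_var_spec = NULL, # derived below unless supplied
    seed = 0L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "mg_config_error")
  }
  cfg[names(over)] <- over
  taxa <- sprintf("ASV%03d", seq_len(cfg$n_taxa))
  if (is.null(cfg$signature_assignment)) {
    n_guild_taxa <- sum(cfg$guild_sizes)
    free <- taxa[setdiff(seq_len(cfg$n_taxa), seq_len(n_guild_taxa))]
    if (sum(cfg$n_signature) > length(free)) {
      abort("not enough free taxa for the requested signature counts.",
            class = "mg_config_error")
    }
    assign <- setNames(rep("stable", cfg$n_taxa), taxa)
    pos <- 0L
    for (cl in names(cfg$n_signature)) {
      k <- cfg$n_signature[[cl]]
      if (k > 0) assign[free[(pos + 1L):(pos + k)]] <- cl
      pos <- pos + k
    }
    cfg$signature_assignment <- assign
  }
  if (is.null(cfg$host_var_spec)) {
    up <- names(cfg$signature_assignment)[
      cfg$signature_assignment == "monotone_up"]
    down <- names(cfg$signature_assignment)[
      cfg$signature_assignment == "monotone_down"]
    cfg$host_var_spec <- list()
    if (length(up)) {
      cfg$host_var_spec$IL6 <- list(taxa = head(up, 5), coef = 1)
    }
    if (length(down)) {
      cfg$host_var_spec$BDNF <- list(taxa = head(down, 5), coef = 1)
    }
  }
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (sum(guild_sizes) > n_taxa) {
      abort("guild sizes exceed n_taxa.", class = "mg_config_error")
    }
    if (any(guild_sizes < 2)) {
      abort("every guild needs at least 2 taxa.", class = "mg_config_error")
    }
    if (any(group_sizes < 3)) {
      abort("every group needs at least 3 samples.", class = "mg_config_error")
    }
    if (effect_size < 0 || guild_factor_sd < 0 || noise_sd <= 0) {
      abort("need delta >= 0, tau >= 0, sigma > 0.", class = "mg_config_error")
    }
    if (n_families < max(group_sizes)) {
      abort(sprintf(
        "n_families (%d) below the largest group (%d): families cannot hold at most one sample per group.",
        n_families, max(group_sizes)), class = "mg_config_error")
    }
    bad <- setdiff(unique(signature_assignment), names(beta_patterns))
    if (length(bad)) {
      abort(paste0("unknown signature class(es): ",
                   paste(bad, collapse = ", ")), class = "mg_config_error")
    }
  })
  invisible(cfg)
}

#' Simulate a three-generation cohort with planted structure
#'
#' Draws a compositional count table, sample metadata (group, family,
#' generation, host variables) and a ground-truth record from a
#' `cohort_config`. Bit-for-bit reproducible from (config, seed): the
#' config's seed drives every random draw.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort_sim`: `counts` (count-table tibble),
#'   `metadata` (tibble), `truth` (list: `guild_of`, `signature_of`,
#'   `latent_log_abundance`, `true_basis_correlation`, `host_var_links`,
#'   `depths`), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  old_rng <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_rng))
  set.seed(stage_seed(config$seed, "simulate"))
  taxa <- names(config$signature_assignment)
  n_taxa <- config$n_taxa
  # samples, groups, families (round-robin: family j holds sample j of each
  # group, so no family repeats a group)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  sample_ids <- unlist(purrr::imap(config$group_sizes, function(n, g) {
    sprintf("%s_S%02d", g, seq_len(n))
  }), use.names = FALSE)
  family_of <- unlist(purrr::map(config$group_sizes, seq_len),
                      use.names = FALSE)
  family_ids <- sprintf("F%02d", family_of)
  generation <- c(G1 = 1L, G2 = 2L, G3 = 3L)[groups]
  n_samples <- length(sample_ids)
  # planted guilds: contiguous taxon blocks; remaining taxa are free
  guild_of <- rep(NA_integer_, n_taxa)
  pos <- 0L
  for (g in seq_along(config$guild_sizes)) {
    guild_of[(pos + 1L):(pos + config$guild_sizes[g])] <- g
    pos <- pos + config$guild_sizes[g]
  }
  names(guild_of) <- taxa
  mu <- rnorm(n_taxa, 0, config$base_log_sd)
  lambda <- runif(n_taxa, config$loading_range[1], config$loading_range[2])
  lambda[is.na(guild_of)] <- 0
  # guild factors per (guild, sample)
  n_guilds <- length(config$guild_sizes)
  f_gk <- matrix(rnorm(n_guilds * n_samples, 0, config$guild_factor_sd),
                 n_guilds, n_samples)
  beta <- t(vapply(config$signature_assignment,
                   function(cl) beta_patterns[[cl]], numeric(3)))
  colnames(beta) <- c("G3", "G2", "G1")
  # family effects for stable-class taxa
  stable_taxa <- config$signature_assignment == "stable"
  gamma <- matrix(0, n_taxa, config$n_families)
  if (any(stable_taxa) && config$family_effect_sd > 0) {
    gamma[stable_taxa, ] <- rnorm(sum(stable_taxa) * config$n_families, 0,
                                  config$family_effect_sd)
  }
  eps <- matrix(rnorm(n_taxa * n_samples, 0, config$noise_sd),
                n_taxa, n_samples)
  y <- matrix(mu, n_taxa, n_samples) +
    beta[, groups, drop = FALSE] * config$effect_size +
    gamma[, family_of, drop = FALSE] +
    eps
  guilded <- !is.na(guild_of)
  y[guilded, ] <- y[guilded, ] +
    lambda[guilded] * f_gk[guild_of[guilded], , drop = FALSE]
  dimnames(y) <- list(taxa, sample_ids)
  # composition and counts
  p <- apply(y, 2, function(col) {
    e <- exp(col - max(col))
    e / sum(e)
  })
  if (config$overdispersion > 0) {
    p <- apply(p, 2, function(col) {
      g <- stats::rgamma(length(col), shape = col / config$overdispersion)
      g / sum(g)
    })
  }
  depths <- pmax(1, round(rlnorm(n_samples, config$depth_log_mean,
                                 config$depth_log_sd)))
  counts <- vapply(seq_len(n_samples),
                   function(k) rmultinom(1, depths[k], p[, k])[, 1],
                   integer(n_taxa))
  dimnames(counts) <- list(taxa, sample_ids)
  # host variables: coef * mean latent log-abundance of linked taxa + noise
  md <- tibble(sample_id = sample_ids, group = groups,
               family_id = family_ids, generation = generation)
  for (nm in names(config$host_var_spec)) {
    spec <- config$host_var_spec[[nm]]
    link_mean <- colMeans(y[spec$taxa, , drop = FALSE])
    md[[nm]] <- spec$coef * link_mean + rnorm(n_samples)
  }
  # true basis correlation: guild-factor covariance over residual variance,
  # conditional on group/family (what SparCC should recover at delta = 0)
  var_i <- lambda^2 * config$guild_factor_sd^2 + config$noise_sd^2
  rho_true <- diag(n_taxa)
  for (g in seq_len(n_guilds)) {
    idx <- which(!is.na(guild_of) & guild_of == g)
    for (i in idx) for (j in idx) {
      if (i != j) {
        rho_true[i, j] <- lambda[i] * lambda[j] * config$guild_factor_sd^2 /
          sqrt(var_i[i] * var_i[j])
      }
    }
  }
  dimnames(rho_true) <- list(taxa, taxa)
  structure(list(
    counts = taxa_matrix_to_tibble(counts),
    metadata = md,
    truth = list(
      guild_of = guild_of,
      signature_of = config$signature_assignment,
      latent_log_abundance = y,
      true_basis_correlation = rho_true,
      host_var_links = config$host_var_spec,
      depths = setNames(depths, sample_ids)
    ),
    config = config
  ), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "simulated cohort: %d taxa x %d samples (%s), %d guild(s)\n",
    x$config$n_taxa, nrow(x$metadata),
    paste(sprintf("%s=%d", names(x$config$group_sizes),
                  x$config$group_sizes), collapse = ", "),
    length(x$config$guild_sizes)))
  invisible(x)
}
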