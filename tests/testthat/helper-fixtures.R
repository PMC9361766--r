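# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# Tiny deterministic count tibble with lineage (3 taxa x 4 samples).
tiny_counts <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    lineage = c("k__Bacteria;p__Firmicutes;g__Blautia",
                "k__Bacteria;p__Firmicutes;g__Roseburia",
                "k__Bacteria;p__Bacteroidetes;g__Bacteroides"),
    s1 = c(2L, 2L, 4L), s2 = c(7L, 0L, 0L),
    s3 = c(1L, 1L, 1L), s4 = c(0L, 5L, 5L)
  )
}

tiny_metadata <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:4),
    group = c("G1", "G1", "G2", "G2"),
    family_id = c("F1", "F2", "F1", "F2"),
    generation = c(1L, 1L, 2L, 2L)
  )
}

# Random integer count matrix (taxa x samples) under a fixed seed.
random_counts <- function(n_taxa = 20, n_samples = 10, seed = 1,
                          lambda = 30) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples)
    dimnames(m) <- list(sprintf("T%03d", seq_len(n_taxa)),
                        sprintf("S%03d", seq_len(n_samples)))
    m
  })
}

# Compositional null table: iid gamma then closed per sample, so taxa are
# exchangeable across any group split.
compositional_null <- function(n_taxa, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n_taxa * n_samples, shape = 2), n_taxa, n_samples)
    m <- sweep(m, 2, colSums(m), "/")
    dimnames(m) <- list(sprintf("T%03d", seq_len(n_taxa)),
                        sprintf("S%03d", seq_len(n_samples)))
    m
  })
}

# Block correlation matrix: `blocks` groups of `size` taxa at rho_in within,
# rho_out between.
block_rho <- function(blocks = 3, size = 5, rho_in = 0.9, rho_out = 0) {
  n <- blocks * size
  r <- matrix(rho_out, n, n)
  for (b in seq_len(blocks)) {
    idx <- ((b - 1) * size + 1):(b * size)
    r[idx, idx] <- rho_in
  }
  diag(r) <- 1
  ids <- sprintf("T%03d", seq_len(n))
  dimnames(r) <- list(ids, ids)
  r
}

# Lognormal "absolute abundance" world with one planted correlated pair,
# closed to compositions and multinomially sampled: a direct SparCC test bed
# independent of the cohort simulator.
planted_pair_counts <- function(n_taxa = 20, n_samples = 300, rho = 0.9,
                                depth = 20000, seed = 1) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n_taxa * n_samples), n_taxa, n_samples)
    z[2, ] <- rho * z[1, ] + sqrt(1 - rho^2) * z[2, ]
    y <- z + rnorm(n_taxa, 0, 1) # per-taxon base abundance
    counts <- vapply(seq_len(n_samples), function(k) {
      p <- exp(y[, k]); p <- p / sum(p)
      rmultinom(1, depth, p)[, 1]
    }, integer(n_taxa))
    dimnames(counts) <- list(sprintf("T%03d", seq_len(n_taxa)),
                             sprintf("S%03d", seq_len(n_samples)))
    counts
  })
}

# Independent closed-form 3-component SparCC basis solution:
#   w1 = (t12 + t13 - t23) / 2 (and cyclic), rho from the defining identity.
closed_form_3 <- function(t_mat) {
  t12 <- t_mat[1, 2]; t13 <- t_mat[1, 3]; t23 <- t_mat[2, 3]
  w <- c((t12 + t13 - t23) / 2, (t12 + t23 - t13) / 2, (t13 + t23 - t12) / 2)
  rho <- diag(3)
  for (i in 1:2) for (j in (i + 1):3) {
    rho[i, j] <- rho[j, i] <- (w[i] + w[j] - t_mat[i, j]) /
      (2 * sqrt(w[i] * w[j]))
  }
  list(w = w, rho = rho)
}

# Small valid network.
triangle_network <- function() {
  mg_network(
    nodes = tibble::tibble(node = c("a", "b", "c"),
                           mean_abundance = c(0.2, 0.3, 0.5)),
    edges = tibble::tibble(source = c("a", "a", "b"),
                           target = c("b", "c", "c"),
                           weight = c(0.8, -0.75, 0.9),
                           sign = c("+", "-", "+")),
    rho_threshold = 0.7
  )
}
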