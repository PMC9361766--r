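# stats core: self-implemented diversity, ordination and permutation tests.

#' Shannon diversity of one composition
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over positive entries, natural log.
#'
#' @param p Numeric vector of relative abundances summing to 1.
#' @return A single non-negative number.
#' @export
shannon_index <- function(p) {
  if (any(p < 0)) abort("negative relative abundance.", class = "mg_domain_error")
  if (abs(sum(p) - 1) > 1e-6) {
    abort("relative abundances must sum to 1.", class = "mg_domain_error")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Observed richness of one sample
#'
#' Number of taxa with non-zero count. Used as the richness estimate; the
#' package deliberately implements no extrapolated estimator.
#'
#' @param x Non-negative count vector.
#' @return Integer count of present taxa.
#' @export
observed_richness <- function(x) {
  if (any(x < 0)) abort("negative count.", class = "mg_domain_error")
  sum(x > 0)
}

#' Per-sample alpha diversity table
#'
#' @param counts A count-table tibble or taxa x samples matrix.
#' @param metadata Optional metadata; when given, a `group` column is joined.
#' @return A tibble: `sample_id`, `richness`, `shannon` (and `group`).
#' @export
alpha_diversity <- function(counts, metadata = NULL) {
  parsed <- as_taxa_matrix(counts)
  rel <- sweep(parsed$mat, 2, colSums(parsed$mat), "/")
  out <- tibble(
    sample_id = colnames(parsed$mat),
    richness = apply(parsed$mat, 2, observed_richness),
    shannon = apply(rel, 2, shannon_index)
  )
  if (!is.null(metadata)) {
    out$group <- unname(group_lookup(metadata, out$sample_id))
  }
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}, the standard
#' abundance-based beta diversity used for the cohort's PCoA and ANOSIM.
#'
#' @param rel A relative-abundance tibble or taxa x samples matrix.
#' @return A samples x samples symmetric distance matrix (base matrix with
#'   dimnames), entries in [0, 1] for normalised input.
#' @export
bray_curtis <- function(rel) {
  parsed <- as_taxa_matrix(rel)
  m <- parsed$mat
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(m[, i] - m[, j]))
      den <- sum(m[, i] + m[, j])
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared distance matrix (Gower) and eigendecomposes it.
#' Axes with negative eigenvalues are reported but never returned as
#' coordinates.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param k Number of axes requested (default 2).
#' @return An object of class `mg_pcoa`: `points` (tibble `sample_id`,
#'   `Axis1`..), `eigenvalues`, `rel_eigen` (relative to the positive total),
#'   `k_returned`, `truncated` (TRUE when fewer than `k` positive axes exist).
#' @export
pcoa <- function(d, k = 2) {
  check_symmetric(d, "distance", arg = "d")
  stopifnot(k >= 1)
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- j %*% a %*% j
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-10
  n_pos <- sum(pos)
  k_ret <- min(k, n_pos)
  truncated <- k_ret < k
  if (truncated) {
    warn(sprintf("only %d positive eigenvalue axes available (%d requested).",
                 n_pos, k))
  }
  coords <- e$vectors[, seq_len(k_ret), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k_ret)]), k_ret)
  colnames(coords) <- paste0("Axis", seq_len(k_ret))
  pts <- dplyr::bind_cols(tibble(sample_id = rownames(d)),
                          as_tibble(coords, .name_repair = "minimal"))
  structure(list(points = pts, eigenvalues = e$values,
                 rel_eigen = e$values / sum(e$values[e$values > 0]),
                 k_returned = k_ret, truncated = truncated),
            class = "mg_pcoa")
}

# ---- permutation machinery ----------------------------------------------

# All distinct arrangements of a label multiset as an integer matrix
# (columns = arrangements of group indices). Guarded against explosion.
all_label_arrangements <- function(groups, max_n = 1e5) {
  lev <- unique(groups)
  g <- match(groups, lev)
  n <- length(g)
  counts <- tabulate(g, nbins = length(lev))
  total <- round(exp(lgamma(n + 1) - sum(lgamma(counts + 1))))
  if (total > max_n) {
    abort(sprintf("exhaustive enumeration needs %d arrangements (> %d).",
                  total, max_n))
  }
  rec <- function(remaining) {
    n_r <- sum(remaining)
    if (n_r == 0L) return(matrix(integer(0), 0, 1))
    blocks <- list()
    for (i in seq_along(remaining)) {
      if (remaining[i] == 0L) next
      rem <- remaining
      rem[i] <- rem[i] - 1L
      sub <- rec(rem)
      blocks[[length(blocks) + 1L]] <- rbind(
        matrix(i, 1, ncol(sub)), sub
      )
    }
    do.call(cbind, blocks)
  }
  arr <- rec(counts)
  attr(arr, "levels") <- lev
  arr
}

# Sum over groups of (within-group pair sums of `m`) / n_g, for a matrix of
# label columns `labmat` (n x B integer matrix of group indices). Returns a
# length-B vector. `m` is an n x n symmetric matrix with zero diagonal.
within_group_pair_sums <- function(m, labmat, n_groups, scale_by_size) {
  res <- numeric(ncol(labmat))
  for (g in seq_len(n_groups)) {
    v <- labmat == g
    storage.mode(v) <- "double"
    s <- colSums(v * (m %*% v)) / 2
    if (scale_by_size) {
      res <- res + s / colSums(v)
    } else {
      res <- res + s
    }
  }
  res
}

perm_label_matrix <- function(groups_int, n_perm) {
  n <- length(groups_int)
  vapply(seq_len(n_perm), function(b) groups_int[sample.int(n)],
         integer(n))
}

new_perm_test <- function(method, statistic, p_value, n_perm, seed, exact,
                          extra = list()) {
  structure(c(list(method = method, statistic = statistic, p_value = p_value,
                   n_permutations = n_perm, seed = seed, exact = exact),
              extra),
            class = "mg_perm_test")
}

#' @export
print.mg_perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, %d permutations)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "exhaustive" else "Monte Carlo",
              x$n_permutations))
  invisible(x)
}

#' PERMANOVA (permutational multivariate ANOVA) on a distance matrix
#'
#' Anderson's pseudo-F from squared distances:
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n},
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' \eqn{F = (SS_{between}/(a-1)) / (SS_{within}/(n-a))}. The null comes from
#' unrestricted label permutation; Monte Carlo p-values use the add-one
#' estimator \eqn{(1+b)/(1+B)} so p is never 0. With `exact = TRUE` every
#' distinct label arrangement is enumerated and
#' \eqn{p = \#\{F_{perm} \ge F_{obs}\}/N} (the identity arrangement included).
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param groups Group label per row of `d` (at least 2 groups, each with at
#'   least 2 members).
#' @param n_perm Number of Monte Carlo permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @param exact Enumerate all distinct label arrangements instead of sampling.
#' @return An `mg_perm_test` with the pseudo-F `statistic` and `p_value`.
#' @export
permanova_test <- function(d, groups, n_perm = 999, seed = 1, exact = FALSE) {
  check_symmetric(d, "distance", arg = "d")
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups.")
  if (any(sizes < 2)) abort("every group needs at least 2 members.")
  if (!exact && n_perm < 99) abort("n_perm must be at least 99.")
  n <- nrow(d)
  a <- length(sizes)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  lev <- names(sizes)
  g_int <- match(groups, lev)
  f_stat <- function(labmat) {
    ss_w <- within_group_pair_sums(d2, labmat, a, scale_by_size = TRUE)
    ss_b <- ss_total - ss_w
    ifelse(ss_w <= 1e-12 & abs(ss_b) <= 1e-12, 0,
           (ss_b / (a - 1)) / (ss_w / (n - a)))
  }
  obs <- f_stat(matrix(g_int, ncol = 1))
  if (ss_total <= 1e-12) {
    return(new_perm_test("PERMANOVA", 0, 1, 0L, seed, exact))
  }
  if (exact) {
    arr <- all_label_arrangements(groups)
    f_all <- f_stat(arr)
    p <- mean(f_all >= obs - 1e-12)
    new_perm_test("PERMANOVA", obs, p, ncol(arr), seed, TRUE)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    labmat <- perm_label_matrix(g_int, n_perm)
    f_perm <- f_stat(labmat)
    p <- (1 + sum(f_perm >= obs - 1e-12)) / (1 + n_perm)
    new_perm_test("PERMANOVA", obs, p, as.integer(n_perm), seed, FALSE)
  }
}

#' ANOSIM on a distance matrix
#'
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} where the mean ranks are taken over
#' between- and within-group pairwise distances, ranks (mid-ranks on ties)
#' over all \eqn{M = n(n-1)/2} pairs. R is in [-1, 1]; values near 0 mean no
#' group separation. p-values as in [permanova_test()].
#'
#' @inheritParams permanova_test
#' @return An `mg_perm_test` with the ANOSIM R `statistic`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1, exact = FALSE) {
  check_symmetric(d, "distance", arg = "d")
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups.")
  if (any(sizes < 2)) abort("every group needs at least 2 members.")
  n <- nrow(d)
  m_pairs <- n * (n - 1) / 2
  rk <- matrix(0, n, n)
  ut <- upper.tri(d)
  rk[ut] <- rank(d[ut])
  rk <- rk + t(rk)
  total_rank <- m_pairs * (m_pairs + 1) / 2
  lev <- names(sizes)
  g_int <- match(groups, lev)
  n_within <- sum(sizes * (sizes - 1) / 2)
  n_between <- m_pairs - n_within
  r_stat <- function(labmat) {
    sw <- within_group_pair_sums(rk, labmat, length(lev),
                                 scale_by_size = FALSE)
    rw <- sw / n_within
    rb <- (total_rank - sw) / n_between
    (rb - rw) / (m_pairs / 2)
  }
  obs <- r_stat(matrix(g_int, ncol = 1))
  if (exact) {
    arr <- all_label_arrangements(groups)
    r_all <- r_stat(arr)
    p <- mean(r_all >= obs - 1e-12)
    new_perm_test("ANOSIM", obs, p, ncol(arr), seed, TRUE)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    labmat <- perm_label_matrix(g_int, n_perm)
    r_perm <- r_stat(labmat)
    p <- (1 + sum(r_perm >= obs - 1e-12)) / (1 + n_perm)
    new_perm_test("ANOSIM", obs, p, as.integer(n_perm), seed, FALSE)
  }
}

# Save/restore the global RNG state so seeded tests do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- Spearman -------------------------------------------------------------

perm_cache <- new.env(parent = emptyenv())

# Exact null distribution of the Spearman D = sum of squared rank differences
# for sample size n (no ties). Cached per n.
spearman_exact_null_d <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  all_perms <- function(k) {
    if (k == 1L) return(matrix(1L, 1, 1))
    p <- all_perms(k - 1L)
    np <- ncol(p)
    out <- matrix(0L, k, k * np)
    for (i in seq_len(k)) {
      out[, ((i - 1L) * np + 1L):(i * np)] <- rbind(i, p + (p >= i))
    }
    out
  }
  perms <- all_perms(n)
  d_null <- colSums((perms - seq_len(n))^2)
  perm_cache[[key]] <- d_null
  d_null
}

spearman_p <- function(rho, n, x_ranks = NULL, y_ranks = NULL) {
  if (is.na(rho)) return(NA_real_)
  no_ties <- !is.null(x_ranks) && !is.null(y_ranks) &&
    !anyDuplicated(x_ranks) && !anyDuplicated(y_ranks)
  if (n <= 9 && no_ties) {
    d_obs <- sum((x_ranks - y_ranks)^2)
    d_null <- spearman_exact_null_d(n)
    rho_null <- 1 - 6 * d_null / (n * (n^2 - 1))
    return(mean(abs(rho_null) >= abs(rho) - 1e-12))
  }
  if (n <= 2 || abs(rho) >= 1) {
    return(if (abs(rho) >= 1 && n > 2) 0 else 1)
  }
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

mid_rank_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Spearman correlations with BH false-discovery control
#'
#' Mid-rank Spearman rho for every pair, two-sided p-values (exact permutation
#' null when n <= 9 without ties, t-approximation otherwise), and
#' Benjamini-Hochberg q-values over exactly the tested pair family. Pairs with
#' a constant member get `rho = NA` and are excluded from the BH family.
#' Missing values are dropped pairwise.
#'
#' @param x Variables x observations numeric matrix (e.g. taxa x samples).
#' @param y Optional second matrix over the same observations; when `NULL`
#'   all within-`x` pairs are tested, otherwise all `x`-by-`y` pairs.
#' @param min_n Minimum paired observations for a pair to be tested.
#' @return A tibble: `id_a`, `id_b`, `n`, `rho`, `p`, `q`.
#' @export
spearman_assoc <- function(x, y = NULL, min_n = 5) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  pairs <- if (is.null(y)) {
    if (nrow(x) < 2) abort("need at least two variables.")
    t(combn(rownames(x), 2))
  } else {
    stopifnot(is.matrix(y), !is.null(rownames(y)), ncol(y) == ncol(x))
    as.matrix(expand.grid(id_a = rownames(x), id_b = rownames(y),
                          stringsAsFactors = FALSE))
  }
  # fast path: all-vs-all on complete data with n > 9 (t-approximation
  # throughout) — one rank pass and one correlation matrix
  if (is.null(y) && !anyNA(x) && ncol(x) > 9 && ncol(x) >= min_n) {
    n <- ncol(x)
    rk <- t(apply(x, 1, rank))
    keep_sd <- apply(rk, 1, sd) > 0
    rho_mat <- matrix(NA_real_, nrow(x), nrow(x),
                      dimnames = list(rownames(x), rownames(x)))
    if (sum(keep_sd) >= 2) {
      rho_mat[keep_sd, keep_sd] <- cor(t(rk[keep_sd, , drop = FALSE]))
    }
    rho <- rho_mat[pairs]
    p <- ifelse(is.na(rho), NA_real_,
                ifelse(abs(rho) >= 1, 0,
                       2 * pt(-abs(rho * sqrt((n - 2) /
                                                pmax(1 - rho^2, 1e-300))),
                              df = n - 2)))
    res <- tibble(id_a = pairs[, 1], id_b = pairs[, 2], n = n,
                  rho = rho, p = p)
    res$q <- NA_real_
    testable <- !is.na(res$p)
    res$q[testable] <- bh_adjust(res$p[testable])
    return(res)
  }
  get_b <- function(id) if (is.null(y)) x[id, ] else y[id, ]
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    va <- x[pairs[k, 1], ]
    vb <- get_b(pairs[k, 2])
    ok <- !is.na(va) & !is.na(vb)
    n <- sum(ok)
    if (n < min_n) {
      return(tibble(id_a = pairs[k, 1], id_b = pairs[k, 2], n = n,
                    rho = NA_real_, p = NA_real_))
    }
    va <- va[ok]; vb <- vb[ok]
    rho <- mid_rank_rho(va, vb)
    p <- if (is.na(rho)) NA_real_ else
      spearman_p(rho, n, rank(va), rank(vb))
    tibble(id_a = pairs[k, 1], id_b = pairs[k, 2], n = n, rho = rho, p = p)
  })
  res$q <- NA_real_
  testable <- !is.na(res$p)
  res$q[testable] <- bh_adjust(res$p[testable])
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} ( p_{(j)} m / j )}, capped at 1 and mapped
#' back to the input order. Never decreases a p-value and is invariant to the
#' ordering of the input.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no NA.", class = "mg_domain_error")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q_sorted <- pmin(1, cummin(m / (m:1) * p[o]))
  q_sorted[ro]
}
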