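# SparCC: basis correlations of absolute abundances inferred from
# compositional counts via log-ratio variances.
#
# The estimator rests on the identity
#   t_ij = var(log(x_i/x_j)) = w_i + w_j - 2 rho_ij sqrt(w_i w_j)
# where w_i is the basis (log absolute abundance) variance. Under the
# sparsity assumption sum_j rho_ij ~ 0 the row sums of t give a linear
# system for w, after which rho follows in closed form. Strongly correlated
# pairs violate the assumption, so the pair with the largest |rho| above a
# threshold is iteratively excluded from the system and the basis re-solved.

#' Variance of log-ratios between all taxon pairs
#'
#' First step of SparCC: adds a pseudocount, closes each sample to fractions,
#' and computes \eqn{t_{ij} = var_k \log(x_{ik}/x_{jk})} (sample variance over
#' samples).
#'
#' @param counts Count-table tibble or taxa x samples matrix (>= 4 samples).
#' @param pseudocount Positive value added to every count before closure
#'   (default 0.5).
#' @return A taxa x taxa symmetric matrix with zero diagonal.
#' @export
log_ratio_variances <- function(counts, pseudocount = 0.5) {
  parsed <- as_taxa_matrix(counts)
  if (ncol(parsed$mat) < 4) abort("need at least 4 samples.")
  if (pseudocount <= 0) abort("pseudocount must be positive.")
  x <- parsed$mat + pseudocount
  x <- sweep(x, 2, colSums(x), "/")
  lx <- log(x)
  # var(l_i - l_j) = var(l_i) + var(l_j) - 2 cov(l_i, l_j), over samples
  cv <- cov_rows(lx)
  v <- diag(cv)
  t_mat <- outer(v, v, "+") - 2 * cv
  t_mat[t_mat < 0] <- 0 # numeric floor
  diag(t_mat) <- 0
  dimnames(t_mat) <- list(rownames(parsed$mat), rownames(parsed$mat))
  t_mat
}

# Row-wise covariance (rows are variables, columns observations).
cov_rows <- function(m) {
  n <- ncol(m)
  mc <- m - rowMeans(m)
  tcrossprod(mc) / (n - 1)
}

#' Solve the SparCC basis system from a log-ratio variance matrix
#'
#' Solves \eqn{\Lambda w = T 1} with \eqn{\Lambda = (D-2)I + 1 1^T} (D = number
#' of taxa) for the basis variances, then
#' \eqn{\rho_{ij} = (w_i + w_j - t_{ij}) / (2\sqrt{w_i w_j})}. Pairs whose
#' \eqn{|\rho|} exceeds `exclusion_threshold` are removed one at a time
#' (largest first), the system is adjusted and re-solved, up to
#' `max_exclusion_rounds` rounds or until no pair exceeds the threshold.
#' Estimates outside [-1, 1] are clipped and counted.
#'
#' @param t_mat Symmetric log-ratio variance matrix from
#'   [log_ratio_variances()].
#' @param exclusion_threshold Absolute correlation above which the strongest
#'   pair is excluded from the basis system (default 0.8).
#' @param max_exclusion_rounds Maximum exclusion iterations (default 10).
#' @return An object of class `sparcc_fit`: `rho` (correlation matrix),
#'   `basis_variance`, `excluded_pairs` (tibble), `n_iterations`,
#'   `n_clipped`, `converged`.
#' @export
solve_basis <- function(t_mat, exclusion_threshold = 0.8,
                        max_exclusion_rounds = 10) {
  check_symmetric(t_mat, "distance", arg = "t_mat") # symmetric, >=0, 0 diag
  ids <- rownames(t_mat)
  d_taxa <- nrow(t_mat)
  if (d_taxa < 2) abort("need at least 2 taxa.")
  excl <- matrix(FALSE, d_taxa, d_taxa)
  excluded <- list()
  converged <- TRUE
  solve_once <- function() {
    # Row i of the system: sum over non-excluded j != i of t_ij =
    #   deg_i * w_i + sum over those j of w_j  (deg_i = # partners), i.e.
    #   Lambda = (D-2) I + 1 1^T on the full pair graph.
    lam <- matrix(0, d_taxa, d_taxa)
    lam[!excl] <- 1
    diag(lam) <- 0
    deg <- rowSums(lam)
    diag(lam) <- pmax(deg, 1e-10)
    tt <- t_mat
    tt[excl] <- 0
    w <- solve(lam, rowSums(tt))
    w <- pmax(w, 1e-12)
    rho <- (outer(w, w, "+") - t_mat) / (2 * sqrt(outer(w, w)))
    diag(rho) <- 1
    list(w = w, rho = rho)
  }
  sol <- solve_once()
  iter <- 0L
  if (d_taxa >= 4) {
    while (iter < max_exclusion_rounds) {
      cand <- abs(sol$rho)
      diag(cand) <- 0
      cand[excl] <- 0
      top <- which(cand == max(cand), arr.ind = TRUE)[1, ]
      if (cand[top[1], top[2]] <= exclusion_threshold) break
      # stop rather than hollow out the system: each taxon must keep >= 3
      # partners for its basis equation to stay meaningful
      partners <- rowSums(!excl) - 1L
      if (partners[top[1]] <= 3 || partners[top[2]] <= 3) {
        converged <- FALSE
        break
      }
      excl[top[1], top[2]] <- excl[top[2], top[1]] <- TRUE
      excluded[[length(excluded) + 1L]] <-
        tibble(taxon_a = ids[min(top)], taxon_b = ids[max(top)],
               rho_at_exclusion = sol$rho[top[1], top[2]])
      iter <- iter + 1L
      sol <- solve_once()
    }
    if (iter == max_exclusion_rounds) {
      cand <- abs(sol$rho)
      diag(cand) <- 0
      cand[excl] <- 0
      if (max(cand) > exclusion_threshold) converged <- FALSE
    }
  }
  rho <- sol$rho
  n_clipped <- sum(abs(rho) > 1) / 2
  rho <- pmin(pmax(rho, -1), 1)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(ids, ids)
  if (n_clipped > 0) {
    warn(sprintf("%d correlation estimate(s) clipped to [-1, 1].",
                 ceiling(n_clipped)))
  }
  structure(list(rho = rho, basis_variance = setNames(sol$w, ids),
                 excluded_pairs = if (length(excluded)) bind_rows(excluded)
                 else tibble(taxon_a = character(), taxon_b = character(),
                             rho_at_exclusion = double()),
                 n_iterations = iter, n_clipped = ceiling(n_clipped),
                 converged = converged,
                 pseudocount = NA_real_),
            class = "sparcc_fit")
}

#' SparCC basis correlations from a count table
#'
#' Orchestrates [log_ratio_variances()] and [solve_basis()]. With
#' `n_restarts > 1` the estimate is averaged over Dirichlet-resampled
#' fractions (posterior draws of each sample's composition), seeded and
#' deterministic; the default is the single deterministic pass.
#'
#' @inheritParams log_ratio_variances
#' @inheritParams solve_basis
#' @param n_restarts Number of Dirichlet resamples to average over (default 1
#'   = deterministic, no resampling).
#' @param seed Integer seed used when `n_restarts > 1`.
#' @return A `sparcc_fit` (see [solve_basis()]); `rho` is the averaged matrix
#'   when resampling.
#' @export
sparcc <- function(counts, pseudocount = 0.5, exclusion_threshold = 0.8,
                   max_exclusion_rounds = 10, n_restarts = 1, seed = 1) {
  parsed <- as_taxa_matrix(counts)
  if (n_restarts <= 1) {
    t_mat <- log_ratio_variances(parsed$mat, pseudocount)
    fit <- solve_basis(t_mat, exclusion_threshold, max_exclusion_rounds)
    fit$pseudocount <- pseudocount
    return(fit)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  acc <- NULL
  fit <- NULL
  for (r in seq_len(n_restarts)) {
    frac <- apply(parsed$mat + pseudocount, 2, function(col) {
      g <- stats::rgamma(length(col), shape = col)
      g / sum(g)
    })
    rownames(frac) <- rownames(parsed$mat)
    colnames(frac) <- colnames(parsed$mat)
    lx <- log(frac)
    cv <- cov_rows(lx)
    v <- diag(cv)
    t_mat <- outer(v, v, "+") - 2 * cv
    t_mat[t_mat < 0] <- 0
    diag(t_mat) <- 0
    dimnames(t_mat) <- dimnames(cv)
    fit <- solve_basis(t_mat, exclusion_threshold, max_exclusion_rounds)
    acc <- if (is.null(acc)) fit$rho else acc + fit$rho
  }
  fit$rho <- acc / n_restarts
  fit$pseudocount <- pseudocount
  fit
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat(sprintf(
    "SparCC fit: %d taxa, %d exclusion round(s), %d pair(s) excluded%s\n",
    nrow(x$rho), x$n_iterations, nrow(x$excluded_pairs),
    if (x$converged) "" else " [exclusion loop stopped early]"))
  invisible(x)
}
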