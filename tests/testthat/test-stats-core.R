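# diversity, ordination, permutation tests, Spearman, BH

test_that("shannon and richness match hand computation", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannon_index(p), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon_index(c(-0.1, 1.1)), class = "mg_domain_error")
  expect_equal(observed_richness(c(5, 0, 2, 0)), 2)
  expect_equal(observed_richness(rep(0, 4)), 0)
  x <- withr::with_seed(1, rbinom(50, 5, 0.3))
  expect_equal(observed_richness(x), sum(x != 0))
})

test_that("bray_curtis matches the formula and its bounds", {
  # hand computation: (0.6,0.4) vs (0.2,0.8) -> 0.4
  m <- cbind(a = c(0.6, 0.4), b = c(0.2, 0.8), c = c(0.6, 0.4))
  rownames(m) <- c("t1", "t2")
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.4)
  expect_equal(d["a", "c"], 0) # identical columns
  disj <- cbind(a = c(1, 0), b = c(0, 1))
  rownames(disj) <- c("t1", "t2")
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  # cross-check against vegan on a random composition
  rel <- compositional_null(15, 8, seed = 4)
  ours <- bray_curtis(rel)
  ref <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-12)
})

test_that("pcoa reconstructs Euclidean configurations", {
  # points on a line: axis-1 distances reproduce the input
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  expect_warning(ord <- pcoa(d, k = 3), "positive eigenvalue")
  expect_true(ord$truncated) # a line embeds in one axis
  ax1 <- ord$points$Axis1
  expect_equal(as.matrix(dist(ax1)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  rownames(d3) <- colnames(d3) <- paste0("s", 1:3)
  ord3 <- pcoa(d3, k = 2)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-12]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-12)
  # agreement with cmdscale on a random Euclidean distance
  y <- matrix(withr::with_seed(7, rnorm(24)), 8, 3)
  dy <- as.matrix(dist(y))
  rownames(dy) <- colnames(dy) <- paste0("s", 1:8)
  ours <- pcoa(dy, k = 3)
  ref <- stats::cmdscale(dy, k = 3)
  # axes match up to sign
  for (j in 1:3) {
    expect_equal(abs(ours$points[[paste0("Axis", j)]]), abs(ref[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # full Euclidean reconstruction through all positive axes
  ordf <- suppressWarnings(pcoa(dy, k = 8))
  coords <- as.matrix(ordf$points[, -1])
  expect_equal(as.matrix(dist(coords)), dy, tolerance = 1e-6,
               ignore_attr = TRUE)
  # id permutation permutes rows identically
  perm <- c(3, 1, 2, 4, 8, 7, 5, 6)
  ordp <- pcoa(dy[perm, perm], k = 2)
  expect_equal(ordp$points$sample_id, rownames(dy)[perm])
  expect_equal(abs(ordp$points$Axis1),
               abs(ours$points$Axis1[perm]), tolerance = 1e-8)
})

test_that("permanova matches vegan's F and exhaustive enumeration", {
  for (s in 1:3) {
    x <- matrix(withr::with_seed(s, runif(18)), 6, 3)
    d <- as.matrix(dist(x))
    rownames(d) <- colnames(d) <- paste0("s", 1:6)
    groups <- rep(c("A", "B"), each = 3)
    res <- permanova_test(d, groups, exact = TRUE)
    expect_equal(res$n_permutations, 20)
    # independent oracle: vegan F over every one of the 20 label splits
    f_all <- apply(combn(6, 3), 2, function(idx) {
      g <- rep("B", 6)
      g[idx] <- "A"
      suppressMessages(as.numeric(
        vegan::adonis2(stats::as.dist(d) ~ g, permutations = 2)$F[1]))
    })
    f_obs <- suppressMessages(as.numeric(
      vegan::adonis2(stats::as.dist(d) ~ groups, permutations = 2)$F[1]))
    expect_equal(res$statistic, f_obs, tolerance = 1e-10)
    expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
  }
  # duplicated groups: no between-group structure
  m <- compositional_null(10, 4, seed = 1)
  mm <- cbind(m, m)
  colnames(mm) <- paste0("s", 1:8)
  d <- bray_curtis(mm)
  res <- permanova_test(d, rep(c("A", "B"), each = 4), n_perm = 999, seed = 1)
  expect_gt(res$p_value, 0.5)
  # degenerate all-equal distances
  d0 <- matrix(0, 4, 4)
  rownames(d0) <- colnames(d0) <- paste0("s", 1:4)
  res0 <- permanova_test(d0, c("A", "A", "B", "B"), n_perm = 99)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("permutation p-values follow the add-one rule and are reproducible", {
  d <- bray_curtis(compositional_null(12, 10, seed = 3))
  g <- rep(c("A", "B"), each = 5)
  r1 <- permanova_test(d, g, n_perm = 199, seed = 5)
  r2 <- permanova_test(d, g, n_perm = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(r1$p_value >= 1 / 200 && r1$p_value <= 1)
  # p is a multiple of 1/(B+1)
  expect_equal(r1$p_value * 200, round(r1$p_value * 200), tolerance = 1e-9)
  a1 <- anosim_test(d, g, n_perm = 199, seed = 5)
  a2 <- anosim_test(d, g, n_perm = 199, seed = 5)
  expect_identical(a1$p_value, a2$p_value)
  expect_true(a1$statistic >= -1 && a1$statistic <= 1)
})

test_that("anosim matches vegan and hits its bounds", {
  # fully separated: all between > all within -> R = 1
  d <- matrix(1, 8, 8)
  d[1:4, 1:4] <- 0.1
  d[5:8, 5:8] <- 0.1
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  expect_equal(anosim_test(d, rep(c("A", "B"), each = 4),
                           n_perm = 99)$statistic, 1)
  # statistic equals vegan's on random fixtures (mid-ranks included)
  for (s in 1:3) {
    rel <- compositional_null(12, 10, seed = s)
    dd <- bray_curtis(rel)
    g <- rep(c("A", "B"), each = 5)
    ours <- anosim_test(dd, g, n_perm = 99)$statistic
    ref <- as.numeric(vegan::anosim(stats::as.dist(dd), g,
                                    permutations = 2)$statistic)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("spearman_assoc matches rank formula, exact small-n p, and flags constants", {
  x <- rbind(inc = 1:10, also_inc = (1:10)^2, dec = 10:1)
  colnames(x) <- paste0("s", 1:10)
  res <- spearman_assoc(x)
  expect_equal(res$rho[res$id_a == "inc" & res$id_b == "also_inc"], 1)
  expect_equal(res$rho[res$id_a == "inc" & res$id_b == "dec"], -1)
  # 8-point fixture with a tie: mid-rank formula oracle
  a <- c(1, 2, 2, 3, 4, 5, 6, 7)
  b <- c(2, 1, 4, 3, 6, 5, 8, 7)
  m <- rbind(a = a, b = b)
  colnames(m) <- paste0("s", 1:8)
  got <- spearman_assoc(m)$rho
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, suppressWarnings(
    cor.test(a, b, method = "spearman")$estimate[[1]]), tolerance = 1e-12)
  # exact p at n <= 9 (no ties) equals cor.test's exact p
  a2 <- c(3, 1, 4, 1.5, 5, 9, 2.6)
  b2 <- c(2, 7, 1, 8, 2.8, 1.7, 9)
  m2 <- rbind(a = a2, b = b2)
  colnames(m2) <- paste0("s", 1:7)
  res2 <- spearman_assoc(m2)
  ref2 <- cor.test(a2, b2, method = "spearman", exact = TRUE)
  expect_equal(res2$p, ref2$p.value, tolerance = 1e-12)
  expect_equal(res2$rho, ref2$estimate[[1]], tolerance = 1e-12)
  # constant vector -> NA rho, excluded from BH
  m3 <- rbind(a = 1:10, flat = rep(2, 10), b = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  colnames(m3) <- paste0("s", 1:10)
  res3 <- spearman_assoc(m3)
  flat_rows <- res3$id_a == "flat" | res3$id_b == "flat"
  expect_true(all(is.na(res3$rho[flat_rows])))
  expect_true(all(is.na(res3$q[flat_rows])))
  expect_false(anyNA(res3$q[!flat_rows]))
  # fast path (complete, n > 9) agrees with the per-pair path via NA injection
  big <- compositional_null(6, 12, seed = 8)
  fast <- spearman_assoc(big)
  # adding a row with an NA forces the per-pair path for the whole table
  slow <- spearman_assoc(rbind(big, dummy = c(NA, rep(1, 11))))
  merged <- merge(fast, slow, by = c("id_a", "id_b"))
  expect_equal(merged$rho.x, merged$rho.y, tolerance = 1e-12)
  expect_equal(merged$p.x, merged$p.y, tolerance = 1e-12)
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- withr::with_seed(2, runif(50))
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  # invariant to input ordering
  o <- sample(50)
  expect_equal(bh_adjust(p[o]), q[o], tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mg_domain_error")
})
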