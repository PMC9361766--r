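# differential abundance, bootstrap confirmation, trajectory classes,
# stable species

test_that("differential_abundance flags planted shifts and constants", {
  sim <- simulate_cohort(cohort_config(effect_size = 2, seed = 4))
  diff <- differential_abundance(sim$counts, sim$metadata)
  up <- names(sim$truth$signature_of)[
    sim$truth$signature_of == "monotone_up"]
  rows <- diff[diff$taxon_id %in% up, ]
  # the extreme contrast is significant for every planted monotone taxon
  expect_true(all(rows$q_G3vG1 < 0.05))
  expect_true(all(rows$dir_G3vG1 > 0))
  expect_true(all(diff$q_G3vG1 >= diff$p_G3vG1 - 1e-12))
  # taxon with constant relative abundance -> p = 1, direction 0
  m <- compositional_null(4, 12, seed = 1)
  m["T001", ] <- 0.25
  m[-1, ] <- sweep(m[-1, ], 2, colSums(m[-1, ]), "/") * 0.75
  md <- tibble::tibble(sample_id = colnames(m),
                       group = rep(c("G3", "G2", "G1"), each = 4))
  d2 <- differential_abundance(m, md)
  expect_equal(d2$p_G3vG1[d2$taxon_id == "T001"], 1)
  expect_equal(d2$dir_G3vG1[d2$taxon_id == "T001"], 0)
  expect_error(differential_abundance(m[, 1:7], md[1:7, ]),
               class = "mg_precondition_error")
})

test_that("null data yields few discoveries and mostly stable labels", {
  sim <- simulate_cohort(cohort_config(effect_size = 0, seed = 12,
                                       family_effect_sd = 0))
  diff <- differential_abundance(sim$counts, sim$metadata)
  any_sig <- diff$q_G3vG2 < 0.05 | diff$q_G2vG1 < 0.05 | diff$q_G3vG1 < 0.05
  expect_lte(mean(any_sig), 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(diff)))
  cls <- classify_signatures(diff)
  expect_gte(mean(cls$class == "stable"), 0.9)
})

test_that("classify_signatures implements the full decision table", {
  # exhaustively enumerate significance patterns x directions
  grid <- expand.grid(s32 = c(FALSE, TRUE), s21 = c(FALSE, TRUE),
                      s31 = c(FALSE, TRUE), d = c(-1, 1))
  diff <- tibble::tibble(
    taxon_id = sprintf("t%02d", seq_len(nrow(grid))),
    q_G3vG2 = ifelse(grid$s32, 0.01, 0.5),
    q_G2vG1 = ifelse(grid$s21, 0.01, 0.5),
    q_G3vG1 = ifelse(grid$s31, 0.01, 0.5),
    dir_G3vG2 = grid$d, dir_G2vG1 = grid$d, dir_G3vG1 = grid$d
  )
  cls <- classify_signatures(diff, q_threshold = 0.05)
  expected <- function(s32, s21, s31, d) {
    if (!s31 && s21 && s32) return("rejuvenation")
    if (!s32 && s21 && s31) return("centenarian")
    if (s32 && s21) return(if (d > 0) "monotone_increase"
                           else "monotone_decrease")
    if (s31 && !s32 && !s21) return(if (d > 0) "monotone_increase"
                                    else "monotone_decrease")
    if (!s32 && !s21 && !s31) return("stable")
    "other"
  }
  want <- mapply(expected, grid$s32, grid$s21, grid$s31, grid$d)
  expect_equal(cls$class, unname(want))
  # classes are exhaustive and single-valued by construction
  expect_true(all(cls$class %in% c("rejuvenation", "centenarian",
                                   "monotone_increase",
                                   "monotone_decrease", "stable", "other")))
  # the two named patterns from the trajectory definitions
  expect_equal(cls$class[!grid$s31 & grid$s21 & grid$s32][1], "rejuvenation")
  expect_equal(cls$class[!grid$s32 & grid$s21 & grid$s31][1], "centenarian")
})

test_that("planted trajectory classes are recovered at the default effect", {
  sim <- simulate_cohort(cohort_config(seed = 2))
  cls <- classify_signatures(differential_abundance(sim$counts,
                                                    sim$metadata))
  truth <- sim$truth$signature_of[cls$taxon_id]
  expect_gte(mean(cls$class[truth == "rejuvenation"] == "rejuvenation"), 0.9)
  expect_gte(mean(cls$class[truth == "centenarian"] == "centenarian"), 0.9)
})

test_that("bootstrap_confirm is deterministic, calibrated, and detects shifts", {
  rel <- compositional_null(50, 30, seed = 6)
  md <- tibble::tibble(sample_id = colnames(rel),
                       group = rep(c("G3", "G1"), each = 15))
  b1 <- bootstrap_confirm(rel, md, n_boot = 300, seed = 11)
  b2 <- bootstrap_confirm(rel, md, n_boot = 300, seed = 11)
  expect_identical(b1, b2)
  expect_true(all(b1$ci_low <= b1$ci_high))
  expect_equal(b1$confirmed, b1$ci_low > 0 | b1$ci_high < 0)
  # interval width shrinks as the subsample grows (10 -> 30)
  w10 <- bootstrap_confirm(rel, md, n_boot = 500, subsample_size = 10,
                           seed = 3)
  w30 <- bootstrap_confirm(rel, md, n_boot = 500, subsample_size = 30,
                           seed = 3)
  expect_lt(median(w30$ci_high - w30$ci_low),
            median(w10$ci_high - w10$ci_low))
  # planted 3-SD shift in a taxon subset is confirmed
  m <- compositional_null(50, 30, seed = 7) * 1e5
  sds <- apply(sweep(m, 2, colSums(m), "/")[1:10, 1:15], 1, sd)
  m[1:10, 16:30] <- m[1:10, 16:30] +
    outer(3 * sds, colSums(m)[16:30])
  bs <- bootstrap_confirm(m, md, taxa = rownames(m)[1:10], n_boot = 500,
                          seed = 5)
  expect_true(all(bs$confirmed))
  expect_true(all(bs$mean_diff > 0))
})

test_that("stable_species applies the family and stability rules", {
  # constructed fixture: 4 eligible families, known presence patterns
  m <- matrix(5L, 6, 8,
              dimnames = list(sprintf("T%d", 1:6), sprintf("S%d", 1:8)))
  md <- tibble::tibble(
    sample_id = colnames(m),
    group = rep(c("G1", "G2"), 4),
    family_id = rep(c("F1", "F2", "F3", "F4"), each = 2)
  )
  # T1 present in families F1, F2 only (2 of 4 = half)
  m["T1", ] <- 0L
  m["T1", c("S1", "S3")] <- 4L
  # T2 present in F1 only
  m["T2", ] <- 0L
  m["T2", "S1"] <- 4L
  res <- stable_species(m, md, min_family_fraction = 0.5)
  expect_equal(res$n_eligible_families[1], 4)
  expect_true(res$stable[res$taxon_id == "T1"])
  expect_false(res$stable[res$taxon_id == "T2"])
  expect_equal(res$family_fraction[res$taxon_id == "T2"], 0.25)
  # simulator: stable-heritable taxa recalled, monotone taxa excluded
  sim <- simulate_cohort(cohort_config(seed = 5))
  ss <- stable_species(sim$counts, sim$metadata)
  truth <- sim$truth$signature_of[ss$taxon_id]
  expect_gte(mean(ss$stable[truth == "stable"]), 0.9)
  expect_true(all(!ss$stable[truth %in% c("monotone_up",
                                          "monotone_down")]))
  expect_error(stable_species(m, md[, c("sample_id", "group")]),
               class = "mg_precondition_error")
})
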