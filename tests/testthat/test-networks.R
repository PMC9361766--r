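# mg_network container, I/O, co-occurrence construction, comparison,
# host-variable association

test_that("mg_network validates its invariants", {
  net <- triangle_network()
  expect_s3_class(net, "mg_network")
  expect_error(mg_network(net$nodes,
                          dplyr::mutate(net$edges,
                                        target = .data$source)),
               "self-loop")
  dup <- dplyr::bind_rows(net$edges, net$edges[1, ])
  expect_error(mg_network(net$nodes, dup), "duplicate")
  expect_error(mg_network(net$nodes[1:2, ], net$edges), "missing")
})

test_that("network writers round-trip in both formats", {
  net <- triangle_network()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, p1, "edge_tsv")
  expect_equal(nrow(readr::read_tsv(p1, show_col_types = FALSE)), 3)
  back <- read_network(p1, "edge_tsv")
  expect_equal(as.data.frame(back$edges), as.data.frame(net$edges))
  expect_equal(as.data.frame(back$nodes), as.data.frame(net$nodes))
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, p2, "graphml")
  back2 <- read_network(p2, "graphml")
  key <- function(e) paste(pmin(e$source, e$target),
                           pmax(e$source, e$target))
  expect_setequal(key(back2$edges), key(net$edges))
  expect_equal(back2$edges$weight[order(key(back2$edges))],
               net$edges$weight[order(key(net$edges))])
  # empty network -> header-only TSV
  empty <- mg_network(tibble::tibble(node = character(),
                                     mean_abundance = double()),
                      tibble::tibble(source = character(),
                                     target = character(),
                                     weight = double(), sign = character()))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_network(empty, p3)
  expect_equal(readLines(p3), "source\ttarget\tweight\tsign")
})

test_that("cooccurrence_network applies rho and q thresholds", {
  # two taxa tracking each other perfectly + independents
  m <- compositional_null(10, 20, seed = 2)
  m["T002", ] <- m["T001", ] * 2
  counts <- round(sweep(m, 2, 1e5, "*"))
  md <- tibble::tibble(sample_id = colnames(m), group = "G1")
  net <- cooccurrence_network(counts, md, "G1", min_rel_abundance = 0)
  pair <- net$edges[net$edges$source %in% c("T001", "T002") &
                      net$edges$target %in% c("T001", "T002"), ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$weight, 1)
  expect_equal(pair$sign, "+")
  # threshold contract: no stored edge below rho_threshold, even at rho 0.69
  tests <- attr(net, "tests")
  sub <- tests[!is.na(tests$rho) & abs(tests$rho) < 0.7, ]
  key <- paste(net$edges$source, net$edges$target)
  expect_false(any(paste(sub$id_a, sub$id_b) %in% key))
  expect_true(all(abs(net$edges$weight) >= 0.7))
  # too few samples
  expect_error(cooccurrence_network(counts[, 1:4],
                                    md[1:4, ], "G1"),
               class = "mg_precondition_error")
})

test_that("compare_networks partitions edges and ranks centralities", {
  net <- triangle_network()
  cmp_same <- compare_networks(list(A = net, B = net))
  expect_equal(nrow(cmp_same$shared_edges), 3)
  expect_equal(nrow(cmp_same$specific_edges), 0)
  # K4: all eigenvector centralities 1 after max-normalisation
  k4_edges <- tibble::tibble(
    source = c("a", "a", "a", "b", "b", "c"),
    target = c("b", "c", "d", "c", "d", "d"),
    weight = 0.9, sign = "+")
  k4 <- mg_network(tibble::tibble(node = letters[1:4],
                                  mean_abundance = 0.25), k4_edges)
  cmp_k4 <- compare_networks(list(A = k4, B = k4))
  expect_equal(cmp_k4$centrality$eigenvector, rep(1, 8))
  # path a-b-c: closeness(b) > closeness(a) = closeness(c)
  path <- mg_network(tibble::tibble(node = c("a", "b", "c"),
                                    mean_abundance = 1 / 3),
                     tibble::tibble(source = c("a", "b"),
                                    target = c("b", "c"),
                                    weight = 0.9, sign = "+"))
  cmp_p <- compare_networks(list(A = path, B = path))
  cc <- cmp_p$centrality[cmp_p$centrality$group == "A", ]
  expect_gt(cc$closeness[cc$node == "b"], cc$closeness[cc$node == "a"])
  expect_equal(cc$closeness[cc$node == "a"], cc$closeness[cc$node == "c"])
  # shared/specific/partial are disjoint and cover all distinct edges
  other <- mg_network(
    tibble::tibble(node = c("a", "b", "c", "d"), mean_abundance = 0.25),
    tibble::tibble(source = c("a", "c"), target = c("b", "d"),
                   weight = c(0.8, -0.8), sign = c("+", "-")))
  cmp3 <- compare_networks(list(A = net, B = net, C = other))
  n_all <- nrow(cmp3$shared_edges) + nrow(cmp3$specific_edges) +
    nrow(cmp3$partial_edges)
  expect_equal(n_all, 4) # ab, ac, bc, cd
  expect_equal(nrow(cmp3$shared_edges), 1) # ab is in all three
  expect_setequal(paste(cmp3$partial_edges$source,
                        cmp3$partial_edges$target), c("a c", "b c"))
  expect_setequal(paste(cmp3$specific_edges$source,
                        cmp3$specific_edges$target), "c d")
  # sign flip across groups is discordant
  flip <- mg_network(net$nodes,
                     dplyr::mutate(net$edges,
                                   weight = -.data$weight,
                                   sign = ifelse(.data$sign == "+", "-",
                                                 "+")))
  cmpf <- compare_networks(list(A = net, B = flip))
  expect_equal(nrow(cmpf$discordant_edges), 3)
  expect_equal(nrow(cmpf$shared_edges), 3) # identity is sign-blind
})

test_that("eigenvector centrality is reproducible and matches igraph", {
  net <- triangle_network()
  g <- igraph::graph_from_data_frame(as.data.frame(net$edges[, 1:2]),
                                     directed = FALSE)
  ours <- microguilds:::eigen_centrality_power(g)
  ref <- igraph::eigen_centrality(g)$vector
  ref <- ref / max(ref)
  expect_equal(ours, unname(ref[igraph::V(g)$name]), tolerance = 1e-6)
  expect_identical(ours, microguilds:::eigen_centrality_power(g))
})

test_that("host_association recovers planted links and skips constants", {
  sim <- simulate_cohort(cohort_config(seed = 1))
  ha <- host_association(sim$counts, sim$metadata)
  linked_up <- sim$truth$host_var_links$IL6$taxa
  hit <- ha[ha$variable == "IL6" & ha$taxon_id %in% linked_up, ]
  expect_true(all(hit$significant))
  expect_true(all(hit$rho > 0))
  # null rate: unlinked x unrelated variable pairs rarely significant
  md2 <- sim$metadata
  md2$noise_var <- withr::with_seed(3, rnorm(nrow(md2)))
  ha2 <- host_association(sim$counts, md2, vars = "noise_var")
  expect_lte(mean(ha2$significant), 0.05)
  # constant host variable excluded with a warning, no crash
  md3 <- sim$metadata
  md3$flat <- 5
  expect_warning(ha3 <- host_association(sim$counts, md3,
                                         vars = c("IL6", "flat")),
                 "flat")
  expect_false("flat" %in% ha3$variable)
})
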