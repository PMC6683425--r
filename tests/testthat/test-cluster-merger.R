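two_cluster_fixture <- function() {
  clustering <- tibble::tibble(
    vertex = c("m1", "g1", "m2", "g2"),
    vertex_type = c("miRNA", "mRNA", "miRNA", "mRNA"),
    cluster_id = c("A", "A", "B", "B"),
    round_label = "hungarian"
  )
  edges <- tibble::tibble(mrna = c("g1", "g2", "g2"),
                          mirna = c("m1", "m1", "m2"),
                          weight = c(0.5, 0.4, 0.3))
  list(clustering = clustering, edges = edges)
}

test_that("cross weight averages connecting weight by combined vertex count", {
  a <- list(mirnas = "m1", mrnas = "g1")
  b <- list(mirnas = "m2", mrnas = "g2")
  edges <- tibble::tibble(mrna = "g2", mirna = "m1", weight = 0.4)
  expect_equal(cross_weight(a, b, edges), 0.1) # 0.4 / 4
  expect_equal(cross_weight(b, a, edges), 0.1) # symmetric
  expect_equal(cross_weight(a, b, edges[0, ]), 0)
  expect_error(cross_weight(a, list(mirnas = "m1", mrnas = "g9"), edges),
               class = "mwmm_partition_error")
})

test_that("cross weight counts both directions of connection", {
  a <- list(mirnas = "m1", mrnas = c("g1", "g2"))
  b <- list(mirnas = "m2", mrnas = "g3")
  edges <- tibble::tibble(
    mrna = c("g3", "g1", "g2"), mirna = c("m1", "m2", "m2"),
    weight = c(0.6, 0.2, 0.1)
  ) # a->b: 0.6; b->a: 0.3
  expect_equal(cross_weight(a, b, edges), 0.9 / 5)
})

test_that("the auxiliary graph matches hand-computed pairwise cross weights", {
  fx <- two_cluster_fixture()
  aux <- build_auxiliary_graph(fx$clustering, fx$edges)
  expect_equal(nrow(aux), 1)
  expect_equal(aux$cross_weight, 0.4 / 4)

  # against the singular definition on a larger random clustering
  ds <- generate_planted_table(n_blocks = 4, mirnas_per_block = 2,
                               mrnas_per_block = 4, cross_edge_prob = 0.3,
                               seed = 21)
  ed <- build_weighted_edges(ds$table, "arithmetic_mean")
  st <- build_stars(ed)
  aux <- build_auxiliary_graph(st$clustering, ed)
  cl <- mwmm:::clustering_to_list(st$clustering)
  for (i in seq_len(nrow(aux))) {
    expect_equal(aux$cross_weight[i],
                 cross_weight(cl[[aux$cluster_a[i]]], cl[[aux$cluster_b[i]]], ed),
                 tolerance = 1e-12)
  }
  # zero-cross pairs are absent
  pairs <- utils::combn(names(cl), 2)
  listed <- paste(aux$cluster_a, aux$cluster_b)
  for (p in seq_len(ncol(pairs))) {
    cw <- cross_weight(cl[[pairs[1, p]]], cl[[pairs[2, p]]], ed)
    key <- paste(sort(pairs[, p])[1], sort(pairs[, p])[2])
    expect_equal(key %in% listed, cw > 0)
  }
})

test_that("disconnected clusters produce an empty auxiliary graph", {
  clustering <- tibble::tibble(
    vertex = c("m1", "g1", "m2", "g2", "m3", "g3"),
    vertex_type = rep(c("miRNA", "mRNA"), 3),
    cluster_id = rep(c("A", "B", "C"), each = 2),
    round_label = "hungarian"
  )
  edges <- tibble::tibble(mrna = c("g1", "g2", "g3"),
                          mirna = c("m1", "m2", "m3"), weight = rep(0.5, 3))
  expect_equal(nrow(build_auxiliary_graph(clustering, edges)), 0)
})

test_that("a merge round fuses matched pairs and carries the rest over", {
  fx <- two_cluster_fixture()
  out <- merge_round(fx$clustering, fx$edges)
  expect_equal(dplyr::n_distinct(out$cluster_id), 1)
  expect_equal(unique(out$round_label), "blossom_01")
  expect_setequal(out$vertex, fx$clustering$vertex)
  mg <- attr(out, "merges")
  expect_equal(nrow(mg), 1)
  expect_equal(mg$child, "A+B")

  # path a-b-c with equal weights: one pair merges, one cluster carries over
  clustering <- tibble::tibble(
    vertex = c("m1", "g1", "m2", "g2", "m3", "g3"),
    vertex_type = rep(c("miRNA", "mRNA"), 3),
    cluster_id = rep(c("a", "b", "c"), each = 2),
    round_label = "hungarian"
  )
  edges <- tibble::tibble(mrna = c("g1", "g2", "g2", "g3"),
                          mirna = c("m1", "m1", "m2", "m2"),
                          weight = c(0.5, 0.4, 0.5, 0.4))
  out <- merge_round(clustering, edges)
  expect_equal(dplyr::n_distinct(out$cluster_id), 2)

  # no auxiliary edges: fixed point, membership unchanged
  iso <- clustering
  iso_edges <- tibble::tibble(mrna = c("g1", "g2", "g3"),
                              mirna = c("m1", "m2", "m3"), weight = rep(0.5, 3))
  out2 <- merge_round(iso, iso_edges)
  expect_equal(out2$cluster_id, iso$cluster_id)
  expect_equal(nrow(attr(out2, "merges")), 0)
})

test_that("the full pipeline emits a coarsening history that terminates", {
  ds <- generate_planted_table(n_blocks = 3, mirnas_per_block = 2,
                               mrnas_per_block = 6, cross_edge_prob = 0.15,
                               seed = 42)
  h <- run_mwmm(ds$table, formula = "geometric_mean")
  expect_s3_class(h, "mwmm_history")
  expect_equal(names(h$rounds)[1], "hungarian")
  counts <- vapply(h$rounds, function(cl) dplyr::n_distinct(cl$cluster_id),
                   integer(1))
  expect_true(all(diff(counts) < 0)) # strictly decreasing while merging
  universe <- sort(h$rounds[[1]]$vertex)
  for (r in seq_along(h$rounds)) {
    expect_equal(sort(h$rounds[[r]]$vertex), universe)
    if (r > 1) expect_true(is_coarsening(h$rounds[[r - 1]], h$rounds[[r]]))
  }
  gl <- glance(h)
  expect_true(gl$converged)
  expect_lte(gl$n_merge_rounds, gl$n_clusters_initial - 1)
  td <- tidy(h)
  expect_equal(nrow(td), sum(vapply(h$rounds, nrow, integer(1))))
})

test_that("disconnected stars are an immediate fixed point", {
  tbl <- tibble::tibble(
    mrna = paste0("g", 1:3), mirna = paste0("m", 1:3),
    t_cc = c(-0.5, -0.6, -0.7), n_cc = c(0.5, 0.6, 0.7)
  )
  h <- run_mwmm(tbl, formula = "arithmetic_mean")
  expect_equal(length(h$rounds), 1)
  expect_equal(dplyr::n_distinct(h$rounds$hungarian$cluster_id), 3)
  expect_false(glance(h)$converged && FALSE) # glance runs without error
})

test_that("round-by-round counts match an oracle-driven replay", {
  ds <- generate_planted_table(n_blocks = 6, mirnas_per_block = 1,
                               mrnas_per_block = 3, cross_edge_prob = 0.25,
                               cross_weight_range = c(0.05, 0.2),
                               within_weight_range = c(0.5, 0.9), seed = 77)
  ed <- build_weighted_edges(ds$table, "maximum_absolute")
  h <- run_mwmm(ds$table, formula = "maximum_absolute")
  current <- build_stars(ed)$clustering
  for (r in seq_along(h$rounds)[-1]) {
    aux <- build_auxiliary_graph(current, ed)
    opt <- brute_matching_weight(aux$cluster_a, aux$cluster_b, aux$cross_weight)
    mg <- h$merges[h$merges$round_label == names(h$rounds)[r], ]
    expect_equal(sum(mg$cross_weight), opt, tolerance = 1e-9)
    current <- h$rounds[[r]]
  }
})

test_that("max_rounds caps the number of merge rounds", {
  ds <- generate_planted_table(seed = 4)
  h <- run_mwmm(ds$table, formula = "arithmetic_mean", max_rounds = 2)
  expect_lte(length(h$rounds), 3)
})
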