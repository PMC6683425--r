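metrics_fixture <- function() {
  clustering <- tibble::tibble(
    vertex = c("m1", "g1", "m2", "g2"),
    vertex_type = c("miRNA", "mRNA", "miRNA", "mRNA"),
    cluster_id = c("A", "A", "B", "B"),
    round_label = "hungarian"
  )
  edges <- tibble::tibble(mrna = c("g1", "g2", "g2"),
                          mirna = c("m1", "m1", "m2"),
                          weight = c(0.5, 0.2, 0.4))
  list(clustering = clustering, edges = edges)
}

test_that("inner and outer weights follow their definitions on a hand example", {
  fx <- metrics_fixture()
  m <- compute_cluster_metrics(fx$clustering, fx$edges)
  a <- m[m$cluster_id == "A", ]; b <- m[m$cluster_id == "B", ]
  expect_equal(a$iw, 0.5); expect_equal(a$e2mrow, 0.2); expect_equal(a$r2meow, 0)
  expect_equal(b$iw, 0.4); expect_equal(b$e2mrow, 0); expect_equal(b$r2meow, 0.2)
  expect_true(all(m$cond1)); expect_true(all(m$cond2))

  s <- summarize_clustering(fx$clustering, fx$edges)
  expect_equal(s$mean_iw, 0.45)
  expect_equal(s$mean_e2mrow, 0.1)
  expect_equal(s$mean_r2meow, 0.1)
  expect_equal(s$pct_cond1, 100)
  expect_equal(s$pct_cond2, 100)
})

test_that("a single all-inclusive cluster has zero outer weights", {
  clustering <- tibble::tibble(
    vertex = c("m1", "m2", "g1", "g2"),
    vertex_type = c("miRNA", "miRNA", "mRNA", "mRNA"),
    cluster_id = "all", round_label = "blossom_01"
  )
  edges <- metrics_fixture()$edges
  m <- compute_cluster_metrics(clustering, edges)
  expect_equal(m$e2mrow, 0)
  expect_equal(m$r2meow, 0)
  expect_true(m$cond1 && m$cond2)
  s <- summarize_clustering(clustering, edges)
  expect_equal(s$pct_cond1, 100)
  expect_equal(s$pct_cond2, 100)
})

test_that("zero inner weight with positive outer weight fails both conditions", {
  clustering <- tibble::tibble(
    vertex = c("m1", "g1", "g2", "m2"),
    vertex_type = c("miRNA", "mRNA", "mRNA", "miRNA"),
    cluster_id = c("A", "B", "B", "B"),
    round_label = "x"
  )
  edges <- tibble::tibble(mrna = "g1", mirna = "m1", weight = 0.4)
  m <- compute_cluster_metrics(clustering, edges)
  a <- m[m$cluster_id == "A", ]
  expect_equal(a$iw, 0)
  expect_false(a$cond1); expect_false(a$cond2)
  # non-strict flips the all-zero degenerate case
  b <- compute_cluster_metrics(clustering, edges, non_strict = TRUE)
  bb <- b[b$cluster_id == "B", ]
  expect_equal(bb$iw, 0); expect_equal(bb$e2mrow, 0)
  expect_false(bb$cond2) # r2meow = 0.4 still beats doubled zero inner weight
  expect_error(compute_cluster_metrics(clustering, edges, cluster_id = "nope"),
               class = "mwmm_partition_error")
})

test_that("weight accounting is conserved across random clusterings", {
  withr::local_seed(99)
  for (rep in 1:10) {
    ds <- generate_planted_table(n_blocks = 3, mirnas_per_block = 2,
                                 mrnas_per_block = 5, cross_edge_prob = 0.2,
                                 seed = rep)
    ed <- build_weighted_edges(ds$table, "arithmetic_mean")
    st <- build_stars(ed)
    m <- compute_cluster_metrics(st$clustering, ed)
    expect_equal(sum(m$iw) + sum(m$e2mrow), sum(ed$weight), tolerance = 1e-9)
    expect_equal(sum(m$iw) + sum(m$r2meow), sum(ed$weight), tolerance = 1e-9)
    expect_equal(sum(m$e2mrow), sum(m$r2meow), tolerance = 1e-9)
  }
})

test_that("condition percentages count clusters exactly", {
  clustering <- tibble::tibble(
    vertex = c("m1", "g1", "m2", "g2", "m3", "g3", "m4", "g4"),
    vertex_type = rep(c("miRNA", "mRNA"), 4),
    cluster_id = rep(c("a", "b", "c", "d"), each = 2),
    round_label = "x"
  )
  # one strong internal cluster; three clusters dominated by outward edges
  edges <- tibble::tibble(
    mrna = c("g1", "g2", "g3", "g4", "g1", "g1"),
    mirna = c("m1", "m2", "m3", "m4", "m2", "m3"),
    weight = c(0.9, 0.1, 0.1, 0.3, 1.0, 1.0)
  )
  s <- summarize_clustering(clustering, edges)
  m <- compute_cluster_metrics(clustering, edges)
  expect_equal(s$pct_cond2, round(100 * mean(m$cond2), 2))
  expect_equal(s$n_clusters, 4)
  expect_equal(s$pct_cond2, 25) # only the m4/g4 cluster passes condition two
})

test_that("ARI is exact on the textbook cases", {
  p <- setNames(c("a", "a", "b", "b"), paste0("v", 1:4))
  expect_equal(adjusted_rand_index(p, p), 1)
  singletons <- setNames(paste0("s", 1:4), paste0("v", 1:4))
  one_block <- setNames(rep("x", 4), paste0("v", 1:4))
  expect_equal(adjusted_rand_index(singletons, one_block), 0)
  expect_equal(adjusted_rand_index(one_block, one_block), 1)
  expect_equal(adjusted_rand_index(singletons, singletons), 1)
  expect_error(adjusted_rand_index(p, setNames("a", "w9")),
               class = "mwmm_data_error")
})

test_that("ARI agrees with an independent reference implementation", {
  withr::local_seed(314)
  for (rep in 1:100) {
    n <- sample(10:30, 1)
    p <- setNames(sample(letters[1:sample(2:6, 1)], n, replace = TRUE),
                  paste0("v", 1:n))
    q <- setNames(sample(letters[1:sample(2:6, 1)], n, replace = TRUE),
                  paste0("v", 1:n))
    ref <- mclust::adjustedRandIndex(p, q)
    expect_equal(adjusted_rand_index(p, q), ref, tolerance = 1e-12)
    expect_equal(adjusted_rand_index(q, p), adjusted_rand_index(p, q))
  }
})

test_that("ARI restricts to the common vertex set", {
  p <- setNames(c("a", "a", "b"), c("v1", "v2", "v3"))
  q <- setNames(c("x", "x", "z"), c("v1", "v2", "v9"))
  # common = v1, v2: both put them together
  expect_equal(adjusted_rand_index(p, q), 1)
})
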