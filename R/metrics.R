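# Cluster validity: inner weight (IW), the two directed outer weights
# (E2MROW: a cluster's miRNAs to outside mRNAs; R2MEOW: its mRNAs to outside
# miRNAs) and the two density conditions, plus the adjusted Rand index for
# comparing whole clusterings.

#' Per-cluster inner and outer weights and validity conditions
#'
#' For each cluster C: `iw` sums edges internal to C; `e2mrow` sums edges
#' from C's miRNAs to mRNAs outside C; `r2meow` sums edges from C's mRNAs to
#' miRNAs outside C. Condition one is `iw > e2mrow`; condition two is
#' `2 * iw > e2mrow + r2meow` (the inner weight is doubled because the
#' right-hand side counts both directions of outward connection). The strict
#' inequalities follow the conditions' definitions; `non_strict = TRUE`
#' switches to `>=`.
#'
#' @param clustering A membership tibble; must cover the edge endpoints that
#'   belong to any cluster (unclustered endpoints count as "outside").
#' @param edges The raw weighted edge list.
#' @param cluster_id Optional single cluster id to report; must belong to the
#'   clustering.
#' @param non_strict Use `>=` in the conditions (default `FALSE`).
#' @return A tibble with one row per cluster: `cluster_id`, `n_mirnas`,
#'   `n_mrnas`, `iw`, `e2mrow`, `r2meow`, `cond1`, `cond2`.
#' @export
compute_cluster_metrics <- function(clustering, edges, cluster_id = NULL,
                                    non_strict = FALSE) {
  validate_clustering(clustering)
  if (nrow(clustering) == 0) abort("empty clustering", class = "mwmm_data_error")
  ids <- unique(clustering$cluster_id)
  if (!is.null(cluster_id)) {
    if (!all(cluster_id %in% ids)) {
      abort("cluster_id not present in the clustering", class = "mwmm_partition_error")
    }
  }
  cl_of <- setNames(clustering$cluster_id, clustering$vertex)
  cm <- unname(cl_of[edges$mirna])
  cg <- unname(cl_of[edges$mrna])
  w <- edges$weight
  sum_by <- function(keys, keep) {
    v <- tapply(w[keep], keys[keep], sum)
    out <- setNames(rep(0, length(ids)), ids)
    out[names(v)] <- v
    out
  }
  internal <- !is.na(cm) & !is.na(cg) & cm == cg
  iw <- sum_by(cm, internal)
  out_m <- !is.na(cm) & (is.na(cg) | cg != cm)
  e2mrow <- sum_by(cm, out_m)
  out_g <- !is.na(cg) & (is.na(cm) | cm != cg)
  r2meow <- sum_by(cg, out_g)
  counts <- clustering |>
    dplyr::count(.data$cluster_id, .data$vertex_type) |>
    tidyr::pivot_wider(names_from = "vertex_type", values_from = "n",
                       values_fill = 0L)
  if (!"miRNA" %in% names(counts)) counts$miRNA <- 0L
  if (!"mRNA" %in% names(counts)) counts$mRNA <- 0L
  cmp <- if (non_strict) `>=` else `>`
  res <- tibble(
    cluster_id = ids,
    n_mirnas = counts$miRNA[match(ids, counts$cluster_id)],
    n_mrnas = counts$mRNA[match(ids, counts$cluster_id)],
    iw = unname(iw[ids]),
    e2mrow = unname(e2mrow[ids]),
    r2meow = unname(r2meow[ids])
  ) |>
    dplyr::mutate(cond1 = cmp(.data$iw, .data$e2mrow),
                  cond2 = cmp(2 * .data$iw, .data$e2mrow + .data$r2meow))
  if (!is.null(cluster_id)) res <- res[res$cluster_id %in% cluster_id, ]
  res
}

#' Summarise a clustering's validity metrics
#'
#' Arithmetic means of the three weights over clusters and the percentage of
#' clusters satisfying each condition (0-100 scale, two decimals).
#'
#' @inheritParams compute_cluster_metrics
#' @return A one-row tibble: `round_label`, `n_clusters`, `mean_iw`,
#'   `mean_e2mrow`, `mean_r2meow`, `pct_cond1`, `pct_cond2`.
#' @export
summarize_clustering <- function(clustering, edges, non_strict = FALSE) {
  if (nrow(clustering) == 0) abort("empty clustering", class = "mwmm_data_error")
  m <- compute_cluster_metrics(clustering, edges, non_strict = non_strict)
  tibble(
    round_label = clustering$round_label[1],
    n_clusters = nrow(m),
    mean_iw = mean(m$iw),
    mean_e2mrow = mean(m$e2mrow),
    mean_r2meow = mean(m$r2meow),
    pct_cond1 = round(100 * mean(m$cond1), 2),
    pct_cond2 = round(100 * mean(m$cond2), 2)
  )
}

#' Per-round metrics trajectory of a merge history
#'
#' Applies [summarize_clustering()] to every retained round.
#'
#' @param history An `mwmm_history` from [run_mwmm()].
#' @param non_strict Use `>=` in the validity conditions.
#' @return A tibble with one row per round, in round order.
#' @export
summarize_rounds <- function(history, non_strict = FALSE) {
  stopifnot(inherits(history, "mwmm_history"))
  dplyr::bind_rows(lapply(history$rounds, summarize_clustering,
                          edges = history$edges, non_strict = non_strict))
}

as_membership_vector <- function(x) {
  if (is.data.frame(x)) {
    validate_clustering(x)
    return(setNames(x$cluster_id, x$vertex))
  }
  if (is.null(names(x))) {
    abort("clustering must be a membership tibble or a named vector",
          class = "mwmm_format_error")
  }
  setNames(as.character(x), names(x))
}

#' Adjusted Rand index between two clusterings
#'
#' Standard pair-counting ARI, computed over the intersection of the two
#' vertex sets: 1 for identical partitions, about 0 for random labellings,
#' negative for systematic disagreement. When the chance-corrected
#' denominator is zero (both partitions trivial in the same way) the
#' partitions are identical on the common vertices and 1 is returned.
#'
#' @param p,q Membership tibbles (columns `vertex`, `cluster_id`) or named
#'   character vectors mapping vertex to cluster label.
#' @return A scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(p, q) {
  pv <- as_membership_vector(p)
  qv <- as_membership_vector(q)
  common <- intersect(names(pv), names(qv))
  if (length(common) == 0) {
    abort("the two clusterings share no vertices", class = "mwmm_data_error")
  }
  a <- pv[common]
  b <- qv[common]
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(length(common), 2)
  if (n_pairs == 0) return(1) # a single common vertex: trivially identical
  expected <- sum_a * sum_b / n_pairs
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
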