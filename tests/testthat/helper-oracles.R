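# Shared fixtures and independent brute-force oracles for the test suite.

# Ten example rows of a BRCA-style tumor/normal correlation table.
example_correlation_rows <- function() {
  tibble::tribble(
    ~mrna, ~mirna, ~t_cc, ~n_cc,
    "OBFC1", "hsa-mir-383", -0.092, 0.271,
    "SHROOM2", "hsa-mir-130a", -0.098, 0.442,
    "GABBR2", "hsa-mir-452", 0.142, -0.376,
    "ZNF90", "hsa-mir-452", 0.139, -0.365,
    "GIGYF1", "hsa-mir-3653", -0.192, 0.281,
    "MICALL1", "hsa-mir-375", -0.269, 0.305,
    "ZNF552", "hsa-mir-30e", -0.142, 0.279,
    "MT2A", "hsa-mir-744", -0.089, 0.341,
    "ISG20", "hsa-mir-215", 0.110, -0.373,
    "PJA1", "hsa-mir-204", 0.205, -0.283
  )
}

# Ten example weighted edges (integrated mean value weights).
example_edge_rows <- function() {
  tibble::tribble(
    ~mrna, ~mirna, ~weight,
    "ASB8", "hsa-mir-378", 0.802,
    "FYCO1", "hsa-mir-378", 0.773,
    "CYB5R1", "hsa-mir-378", 0.772,
    "TMEM143", "hsa-mir-378", 0.763,
    "PHKA1", "hsa-mir-944", 0.759,
    "MYOM3", "hsa-mir-95", 0.755,
    "PDLIM3", "hsa-mir-95", 0.751,
    "DCAF6", "hsa-mir-944", 0.749,
    "ASB14", "hsa-mir-378", 0.747,
    "PHTF2", "hsa-mir-944", 0.744
  )
}

# Exhaustive maximum-weight matching value: recursion over vertices (lowest
# unprocessed vertex is left unmatched or matched to each free neighbour),
# so the search tree enumerates exactly the partial matchings. Works for
# general graphs (and hence bipartite ones); keep instances small.
brute_matching_weight <- function(from, to, weight) {
  verts <- sort(unique(c(from, to)))
  n <- length(verts)
  fi <- match(from, verts)
  ti <- match(to, verts)
  adj <- vector("list", n)
  for (k in seq_along(weight)) {
    adj[[fi[k]]] <- rbind(adj[[fi[k]]], c(ti[k], weight[k]))
    adj[[ti[k]]] <- rbind(adj[[ti[k]]], c(fi[k], weight[k]))
  }
  best <- 0
  used <- rep(FALSE, n)
  rec <- function(v, tot) {
    while (v <= n && used[v]) v <- v + 1L
    if (v > n) {
      best <<- max(best, tot)
      return(invisible(NULL))
    }
    used[v] <<- TRUE
    rec(v + 1L, tot) # leave v unmatched
    a <- adj[[v]]
    if (!is.null(a)) {
      for (r in seq_len(nrow(a))) {
        u <- a[r, 1]
        if (!used[u]) {
          used[u] <<- TRUE
          rec(v + 1L, tot + a[r, 2])
          used[u] <<- FALSE
        }
      }
    }
    used[v] <<- FALSE
  }
  rec(1L, 0)
  best
}

# Brute-force optimum of the rectangular assignment on a weight matrix:
# equals the maximum-weight matching over its positive entries.
brute_assignment_weight <- function(mat) {
  pos <- which(mat > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) return(0)
  brute_matching_weight(paste0("r", pos[, 1]), paste0("c", pos[, 2]), mat[pos])
}

# Random general graph as an auxiliary-style edge tibble.
random_aux_graph <- function(n, p = 0.5, weights = NULL) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(tibble::tibble(cluster_a = character(), cluster_b = character(),
                          cross_weight = double()))
  }
  w <- if (is.null(weights)) stats::runif(nrow(pairs)) else weights
  tibble::tibble(cluster_a = sprintf("c%02d", pairs[, 1]),
                 cluster_b = sprintf("c%02d", pairs[, 2]),
                 cross_weight = w)
}

# TRUE iff partition `nxt` is a coarsening of `prev`: every cluster of prev
# maps into exactly one cluster of nxt.
is_coarsening <- function(prev, nxt) {
  nxt_of <- stats::setNames(nxt$cluster_id, nxt$vertex)
  all(vapply(split(prev$vertex, prev$cluster_id), function(vs) {
    length(unique(nxt_of[vs])) == 1
  }, logical(1)))
}
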