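# Top-n edge accretion ("traditional hierarchical clustering"): repeatedly
# add the largest-weight remaining edge to an empty graph and count disjoint
# connected clusters. Used to compare the six weight formulas - a formula
# whose top edges fall into fewer disjoint clusters groups the strongest
# interactions more coherently.

#' Top-n largest-weight subgraph
#'
#' Selects the `n` largest-weight edges (ties broken by miRNA then mRNA name,
#' ascending) and computes the connected components of the resulting bipartite
#' graph. Vertices never touched by a selected edge do not appear.
#'
#' @param edges A weighted edge list (`mrna`, `mirna`, `weight`).
#' @param n Number of edges to keep (positive integer). If `n` exceeds the
#'   number of available edges, all edges are used with a warning.
#' @return An object of class `mwmm_topn`: a list with `edges` (the selected
#'   rows, in selection order) and `membership` (tibble `vertex`,
#'   `vertex_type`, `component`).
#' @export
hierarchical_topn <- function(edges, n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  ordered <- order_edges(edges)
  if (n > nrow(ordered)) {
    warn(sprintf("n = %d exceeds the %d available edges; using all", n, nrow(ordered)))
    n <- nrow(ordered)
  }
  sel <- ordered[seq_len(n), , drop = FALSE]
  membership <- component_membership(sel)
  structure(list(edges = sel, membership = membership), class = "mwmm_topn")
}

# Connected components over the vertices incident to the given edges.
# miRNA and mRNA name spaces are kept distinct by prefixing.
component_membership <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble(vertex = character(), vertex_type = character(),
                  component = integer()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("mi:", edges$mirna), to = paste0("g:", edges$mrna)),
    directed = FALSE
  )
  comp <- igraph::components(g)
  nm <- names(comp$membership)
  tibble(
    vertex = sub("^(mi|g):", "", nm),
    vertex_type = ifelse(startsWith(nm, "mi:"), "miRNA", "mRNA"),
    component = as.integer(comp$membership)
  )
}

#' Number of disjoint clusters in a top-n subgraph
#'
#' @param graph An `mwmm_topn` object from [hierarchical_topn()].
#' @return The number of connected components (positive integer).
#' @export
count_components <- function(graph) {
  stopifnot(inherits(graph, "mwmm_topn"))
  if (nrow(graph$membership) == 0) return(0L)
  max(graph$membership$component)
}

#' Compare the six weight formulas by top-n cluster counts
#'
#' For each formula, builds its edge list from the table and records the
#' number of disjoint clusters among the top-n edges at every step of the
#' grid. The formula(s) attaining the minimum count at each step are flagged;
#' a formula whose strongest edges coalesce into fewer clusters is preferred.
#'
#' @param table A strict-filtered correlation table.
#' @param steps Integer vector of n values (the grid), or a single maximum n
#'   (expanded to `1:steps`).
#' @return A tibble of class `mwmm_curve` with columns `n`, `formula`,
#'   `n_components`, `is_min` (logical: formula attains the per-step minimum).
#' @export
formula_evaluation_curve <- function(table, steps) {
  stopifnot(length(steps) >= 1)
  if (length(steps) == 1 && steps > 1) steps <- seq_len(steps)
  steps <- sort(unique(as.integer(steps)))
  edge_lists <- lapply(setNames(nm = weight_formulas()), function(f) {
    order_edges(build_weighted_edges(table, f))
  })
  rows <- purrr::imap(edge_lists, function(ed, f) {
    counts <- vapply(steps, function(n) {
      nn <- min(n, nrow(ed))
      if (nn == 0) return(0L)
      count_components(structure(
        list(edges = ed[seq_len(nn), ], membership = component_membership(ed[seq_len(nn), ])),
        class = "mwmm_topn"))
    }, integer(1))
    tibble(n = steps, formula = f, n_components = counts)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$n) |>
    dplyr::mutate(is_min = .data$n_components == min(.data$n_components)) |>
    dplyr::ungroup()
  class(out) <- c("mwmm_curve", class(out))
  out
}

#' Plot a formula evaluation curve
#'
#' Disjoint-cluster counts against the number of top edges added, one line
#' per weight formula.
#'
#' @param object An `mwmm_curve` from [formula_evaluation_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mwmm_curve
#' @export
autoplot.mwmm_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$n_components,
                                       colour = .data$formula)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "top-n edges added", y = "disjoint clusters",
                  colour = "weight formula") +
    ggplot2::theme_minimal()
}
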