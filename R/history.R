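# The merge-history object: the clustering emitted at every stage of the
# pipeline, with broom-style accessors and a trajectory plot.

#' @export
print.mwmm_history <- function(x, ...) {
  n0 <- dplyr::n_distinct(x$rounds[[1]]$cluster_id)
  nf <- dplyr::n_distinct(x$rounds[[length(x$rounds)]]$cluster_id)
  cat(sprintf(
    "MWMM merge history (%s weight)\n  %d matching rounds -> %d stars\n  %d merge round(s): %d -> %d clusters\n",
    x$formula, x$n_hungarian_rounds, n0, length(x$rounds) - 1L, n0, nf))
  if (!is.null(x$lambdas)) {
    cat(sprintf("  lambda1 = %.4f, lambda2 = %.4f\n",
                x$lambdas$lambda1, x$lambdas$lambda2))
  }
  invisible(x)
}

#' Tidy a merge history into one long membership table
#'
#' @param x An `mwmm_history` from [run_mwmm()].
#' @param ... Unused.
#' @return A tibble with columns `vertex`, `vertex_type`, `cluster_id`,
#'   `round_label`, stacking every retained round.
#' @method tidy mwmm_history
#' @export
tidy.mwmm_history <- function(x, ...) {
  dplyr::bind_rows(x$rounds)
}

#' One-row overview of a merge history
#'
#' @param x An `mwmm_history` from [run_mwmm()].
#' @param ... Unused.
#' @return A one-row tibble: `formula`, `n_edges`, `n_hungarian_rounds`,
#'   `n_merge_rounds`, `n_clusters_initial`, `n_clusters_final`, `converged`
#'   (TRUE when no positive cross weight remained or one cluster was left).
#' @method glance mwmm_history
#' @export
glance.mwmm_history <- function(x, ...) {
  final <- x$rounds[[length(x$rounds)]]
  nf <- dplyr::n_distinct(final$cluster_id)
  aux_left <- build_auxiliary_graph(final, x$edges)
  tibble(
    formula = x$formula,
    n_edges = nrow(x$edges),
    n_hungarian_rounds = x$n_hungarian_rounds,
    n_merge_rounds = length(x$rounds) - 1L,
    n_clusters_initial = dplyr::n_distinct(x$rounds[[1]]$cluster_id),
    n_clusters_final = nf,
    converged = nf == 1L || nrow(aux_left) == 0L
  )
}

#' Plot the merge trajectory
#'
#' Cluster count and the percentage of clusters meeting each validity
#' condition, by round: the cluster count falls as merging proceeds while
#' condition satisfaction climbs toward 100%.
#'
#' @param object An `mwmm_history` from [run_mwmm()].
#' @param non_strict Use `>=` in the validity conditions.
#' @param ... Unused.
#' @return A ggplot object (two facets sharing the round axis).
#' @method autoplot mwmm_history
#' @export
autoplot.mwmm_history <- function(object, non_strict = FALSE, ...) {
  traj <- summarize_rounds(object, non_strict = non_strict)
  traj$round <- factor(traj$round_label, levels = traj$round_label)
  long <- dplyr::bind_rows(
    tibble(round = traj$round, panel = "clusters",
           series = "n_clusters", value = as.numeric(traj$n_clusters)),
    tibble(round = traj$round, panel = "% clusters meeting condition",
           series = "condition 1", value = traj$pct_cond1),
    tibble(round = traj$round, panel = "% clusters meeting condition",
           series = "condition 2", value = traj$pct_cond2)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$round, y = .data$value,
                                     colour = .data$series,
                                     group = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
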