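# Planted-cluster generator. Emulates the statistical structure the merger
# method assumes: every pair inverts correlation sign between normal and
# tumor, within-block miRNA-mRNA edges are dense and strong, cross-block
# edges sparse and weak. Records are symmetric (t_cc = -w, n_cc = +w or the
# mirror), so all six weight formulas recover the planted weight w exactly
# and pipeline tests are independent of the formula choice; the asymmetric
# variant breaks that tie to exercise formula-comparison code.

#' Generate a correlation table with planted cluster structure
#'
#' Each of `n_blocks` blocks owns `mirnas_per_block` miRNAs and
#' `mrnas_per_block` mRNAs. Within-block (miRNA, mRNA) pairs receive an edge
#' with probability `within_edge_prob` and a weight uniform in
#' `within_weight_range`; cross-block pairs with probability
#' `cross_edge_prob` and weight in `cross_weight_range`. The ranges must be
#' separated (`max(cross) < min(within)`). Each sampled edge of target
#' weight `w` becomes a sign-inverting record, `(t_cc, n_cc) = (-w, +w)`
#' with probability `direction_prob` or `(+w, -w)` otherwise. A block that
#' drew no within-block edge is given one (its first miRNA-mRNA pair) so
#' every block is recoverable in principle.
#'
#' @param n_blocks,mirnas_per_block,mrnas_per_block Positive integers.
#' @param within_weight_range,cross_weight_range Length-2 numeric intervals
#'   within (0, 1\].
#' @param within_edge_prob,cross_edge_prob,direction_prob Probabilities.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration and this seed.
#' @return An object of class `mwmm_planted`: a list with `table` (a
#'   correlation tibble `mrna`, `mirna`, `t_cc`, `n_cc`), `truth` (tibble
#'   `vertex`, `vertex_type`, `block`) and `config`.
#' @export
generate_planted_table <- function(n_blocks = 6, mirnas_per_block = 2,
                                   mrnas_per_block = 10,
                                   within_weight_range = c(0.5, 0.9),
                                   within_edge_prob = 0.9,
                                   cross_edge_prob = 0.02,
                                   cross_weight_range = c(0.01, 0.1),
                                   direction_prob = 0.5,
                                   seed = 1L) {
  stopifnot(n_blocks >= 1, mirnas_per_block >= 1, mrnas_per_block >= 1)
  probs <- c(within_edge_prob, cross_edge_prob, direction_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "mwmm_config_error")
  }
  if (max(cross_weight_range) >= min(within_weight_range)) {
    abort("cross_weight_range must lie strictly below within_weight_range",
          class = "mwmm_config_error")
  }
  if (min(cross_weight_range) <= 0 || max(within_weight_range) > 1) {
    abort("weight ranges must lie within (0, 1]", class = "mwmm_config_error")
  }
  mirna_block <- rep(seq_len(n_blocks), each = mirnas_per_block)
  mrna_block <- rep(seq_len(n_blocks), each = mrnas_per_block)
  mirnas <- sprintf("mir-b%02d-%02d", mirna_block,
                    sequence(rep(mirnas_per_block, n_blocks)))
  mrnas <- sprintf("gene-b%02d-%02d", mrna_block,
                   sequence(rep(mrnas_per_block, n_blocks)))
  grid <- tidyr::expand_grid(mi = seq_along(mirnas), g = seq_along(mrnas))
  grid$within <- mirna_block[grid$mi] == mrna_block[grid$g]
  tab <- withr::with_seed(seed, {
    p <- ifelse(grid$within, within_edge_prob, cross_edge_prob)
    grid$keep <- runif(nrow(grid)) < p
    # guarantee each block at least one within edge
    for (b in seq_len(n_blocks)) {
      in_b <- grid$within & mirna_block[grid$mi] == b
      if (!any(grid$keep & in_b)) grid$keep[which(in_b)[1]] <- TRUE
    }
    sel <- grid[grid$keep, , drop = FALSE]
    lo <- ifelse(sel$within, within_weight_range[1], cross_weight_range[1])
    hi <- ifelse(sel$within, within_weight_range[2], cross_weight_range[2])
    w <- lo + (hi - lo) * runif(nrow(sel))
    flip <- runif(nrow(sel)) < direction_prob
    tibble(
      mrna = mrnas[sel$g],
      mirna = mirnas[sel$mi],
      t_cc = ifelse(flip, -w, w),
      n_cc = ifelse(flip, w, -w)
    )
  })
  truth <- tibble(
    vertex = c(mirnas, mrnas),
    vertex_type = c(rep("miRNA", length(mirnas)), rep("mRNA", length(mrnas))),
    block = c(mirna_block, mrna_block)
  )
  structure(
    list(table = tab, truth = truth,
         config = list(n_blocks = n_blocks, mirnas_per_block = mirnas_per_block,
                       mrnas_per_block = mrnas_per_block,
                       within_weight_range = within_weight_range,
                       within_edge_prob = within_edge_prob,
                       cross_edge_prob = cross_edge_prob,
                       cross_weight_range = cross_weight_range,
                       direction_prob = direction_prob, seed = seed)),
    class = "mwmm_planted"
  )
}

#' Break the symmetry of a planted dataset
#'
#' Perturbs each record to `(t_cc * (1 - skew * u), n_cc * (1 + skew * u'))`
#' with independent `u, u' ~ U(0, 1)`, re-clipped to \[-1, 1\] with signs
#' preserved. Afterwards `|t_cc| != |n_cc|` in general, so the six weight
#' formulas disagree - the regime in which formula comparison is meaningful.
#'
#' @param dataset An `mwmm_planted` object.
#' @param skew Scalar in (0, 1); `0` returns the dataset unchanged.
#' @param seed Integer seed for the perturbation.
#' @return An `mwmm_planted` object with the perturbed table.
#' @export
asymmetric_variant <- function(dataset, skew, seed = 1L) {
  stopifnot(inherits(dataset, "mwmm_planted"), skew >= 0, skew < 1)
  if (skew == 0) return(dataset)
  tab <- dataset$table
  out <- withr::with_seed(seed, {
    u <- runif(nrow(tab))
    u2 <- runif(nrow(tab))
    clip <- function(x) sign(x) * pmin(abs(x), 1)
    dplyr::mutate(tab,
                  t_cc = clip(.data$t_cc * (1 - skew * u)),
                  n_cc = clip(.data$n_cc * (1 + skew * u2)))
  })
  dataset$table <- out
  dataset$config$skew <- skew
  dataset
}

#' Score how well a merge history recovers the planted blocks
#'
#' Computes the adjusted Rand index of every retained round against the
#' planted block labels (over the vertices that were clustered) and reports
#' the best round.
#'
#' @param dataset An `mwmm_planted` object.
#' @param history An `mwmm_history` computed on `dataset$table`.
#' @return A list with `best_round` (round label), `best_ari` and
#'   `by_round` (tibble `round_label`, `ari`).
#' @export
recovery_score <- function(dataset, history) {
  stopifnot(inherits(dataset, "mwmm_planted"), inherits(history, "mwmm_history"))
  truth <- setNames(as.character(dataset$truth$block), dataset$truth$vertex)
  by_round <- tibble(
    round_label = names(history$rounds),
    ari = unname(vapply(history$rounds,
                        function(cl) adjusted_rand_index(cl, truth),
                        double(1)))
  )
  best <- which.max(by_round$ari)
  list(best_round = by_round$round_label[best],
       best_ari = unname(by_round$ari[best]),
       by_round = by_round)
}
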