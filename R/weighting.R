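# The six edge-weight formulas that fold the tumor (T_CC) and normal (N_CC)
# correlation coefficients of a sign-inverting miRNA-mRNA pair into a single
# non-negative edge weight, plus the dataset-level sign-partitioned means and
# lambda coefficients used by the integrated mean value weight.

#' The six edge-weight formula identifiers
#'
#' @return Character vector of the admissible formula ids, in canonical
#'   order: `integrated_mean`, `all_negative`, `all_positive`,
#'   `arithmetic_mean`, `geometric_mean`, `maximum_absolute`.
#' @export
weight_formulas <- function() {
  c("integrated_mean", "all_negative", "all_positive",
    "arithmetic_mean", "geometric_mean", "maximum_absolute")
}

#' Sign-partitioned means of the correlation coefficients
#'
#' Splits each of T_CC and N_CC into its positive and negative subsets and
#' averages the absolute values within each subset. These four means are the
#' data-level statistics behind the lambda coefficients of the integrated
#' mean value weight. A mean over an empty subset is `NA` (undefined), never
#' silently zero.
#'
#' @param table A correlation table (`mrna`, `mirna`, `t_cc`, `n_cc`).
#' @return A one-row tibble with columns `m_t_plus`, `m_t_minus`,
#'   `m_n_plus`, `m_n_minus`, each in \[0, 1\] or `NA`.
#' @export
compute_sign_means <- function(table) {
  if (nrow(table) == 0) abort("empty correlation table", class = "mwmm_data_error")
  subset_mean <- function(v, pos) {
    s <- if (pos) v[v > 0] else abs(v[v < 0])
    if (length(s) == 0) NA_real_ else mean(s)
  }
  tibble(
    m_t_plus = subset_mean(table$t_cc, TRUE),
    m_t_minus = subset_mean(table$t_cc, FALSE),
    m_n_plus = subset_mean(table$n_cc, TRUE),
    m_n_minus = subset_mean(table$n_cc, FALSE)
  )
}

#' Lambda coefficients of the integrated mean value weight
#'
#' `lambda1 = m_t_plus / (m_t_plus + m_n_minus)` weighs pairs whose
#' correlation moves from negative in normal to positive in tumor;
#' `lambda2 = m_t_minus / (m_t_minus + m_n_plus)` weighs the opposite
#' direction. Both lie in \[0, 1\].
#'
#' @param means A one-row tibble from [compute_sign_means()].
#' @return A one-row tibble with columns `lambda1`, `lambda2`.
#' @export
compute_lambdas <- function(means) {
  m <- as.list(means)
  if (anyNA(unlist(m))) {
    abort("a sign-partitioned mean is undefined (empty subset); lambdas cannot be computed",
          class = "mwmm_config_error")
  }
  d1 <- m$m_t_plus + m$m_n_minus
  d2 <- m$m_t_minus + m$m_n_plus
  if (d1 <= 0 || d2 <= 0) {
    abort("degenerate data: zero denominator in lambda computation",
          class = "mwmm_data_error")
  }
  tibble(lambda1 = m$m_t_plus / d1, lambda2 = m$m_t_minus / d2)
}

#' Edge weight of a miRNA-mRNA pair under one formula
#'
#' Vectorised over `t_cc` and `n_cc`. The piecewise formulas
#' (`integrated_mean`, `all_negative`, `all_positive`) branch on the sign of
#' `t_cc` and are defined only for sign-inverting pairs
#' (`t_cc * n_cc < 0`); they refuse zero or same-sign inputs. The
#' absolute-value formulas (`arithmetic_mean`, `geometric_mean`,
#' `maximum_absolute`) accept any correlations.
#'
#' @param t_cc,n_cc Numeric vectors of tumor / normal correlations in
#'   \[-1, 1\].
#' @param formula One of [weight_formulas()].
#' @param lambdas A one-row tibble or list with `lambda1`, `lambda2`;
#'   required iff `formula = "integrated_mean"`.
#' @return Numeric vector of non-negative weights.
#' @export
edge_weight <- function(t_cc, n_cc, formula, lambdas = NULL) {
  formula <- match.arg(formula, weight_formulas())
  piecewise <- formula %in% c("integrated_mean", "all_negative", "all_positive")
  if (piecewise) {
    if (any(t_cc == 0)) {
      abort(sprintf("'%s' is undefined at T_CC = 0", formula),
            class = "mwmm_config_error")
    }
    if (any(t_cc * n_cc > 0)) {
      abort(sprintf("'%s' requires sign-inverting pairs (T_CC * N_CC < 0)", formula),
            class = "mwmm_config_error")
    }
  }
  switch(formula,
    integrated_mean = {
      if (is.null(lambdas)) {
        abort("integrated_mean requires lambdas (see compute_lambdas)",
              class = "mwmm_config_error")
      }
      l1 <- lambdas$lambda1
      l2 <- lambdas$lambda2
      ifelse(t_cc > 0,
             l1 * t_cc + (1 - l1) * abs(n_cc),
             l2 * abs(t_cc) + (1 - l2) * n_cc)
    },
    all_negative = ifelse(t_cc > 0, abs(n_cc), abs(t_cc)),
    all_positive = ifelse(t_cc > 0, t_cc, n_cc),
    arithmetic_mean = (abs(t_cc) + abs(n_cc)) / 2,
    geometric_mean = sqrt(abs(t_cc) * abs(n_cc)),
    maximum_absolute = pmax(abs(t_cc), abs(n_cc))
  )
}

#' Build a weighted edge list from a correlation table
#'
#' Applies one weight formula to every row. For `integrated_mean` the lambda
#' coefficients are computed once from the whole table (they are dataset-level
#' statistics) and then applied per record, unless supplied.
#'
#' @param table A strict-filtered correlation table
#'   (see [filter_sign_inversion()]).
#' @param formula One of [weight_formulas()].
#' @param lambdas Optional precomputed lambdas for `integrated_mean`.
#' @return A tibble with columns `mrna`, `mirna`, `weight`, in the input row
#'   order. For `integrated_mean`, the lambdas and sign means used are
#'   attached as attributes `lambdas` and `sign_means`.
#' @export
build_weighted_edges <- function(table, formula, lambdas = NULL) {
  formula <- match.arg(formula, weight_formulas())
  if (nrow(table) == 0) {
    return(tibble(mrna = character(), mirna = character(), weight = double()))
  }
  means <- NULL
  if (formula == "integrated_mean" && is.null(lambdas)) {
    means <- compute_sign_means(table)
    lambdas <- compute_lambdas(means)
  }
  out <- tibble(
    mrna = table$mrna,
    mirna = table$mirna,
    weight = edge_weight(table$t_cc, table$n_cc, formula, lambdas)
  )
  if (formula == "integrated_mean") {
    attr(out, "lambdas") <- lambdas
    attr(out, "sign_means") <- means
  }
  out
}
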