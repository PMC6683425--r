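# Merge stage: clusters become vertices of an auxiliary graph whose edge
# weights are cross weights (total connecting weight normalised by the two
# clusters' combined vertex count, so big clusters are not merged merely for
# being big). Each round runs a maximum-weight matching on the auxiliary
# graph and fuses every matched pair; unmatched clusters carry over and
# re-enter the next round's auxiliary graph.

#' Cross weight between two clusters
#'
#' Sum of the weights of all edges connecting the two clusters - miRNAs of
#' one to mRNAs of the other, in both directions - divided by the total
#' number of vertices in the two clusters. Symmetric in its arguments.
#'
#' @param a,b Clusters: lists with character fields `mirnas` and `mrnas`.
#' @param edges The raw weighted edge list (`mrna`, `mirna`, `weight`).
#' @return A non-negative scalar.
#' @export
cross_weight <- function(a, b, edges) {
  va <- c(a$mirnas, a$mrnas)
  vb <- c(b$mirnas, b$mrnas)
  if (length(intersect(va, vb)) > 0) {
    abort("clusters overlap; cross weight is defined for disjoint clusters",
          class = "mwmm_partition_error")
  }
  ab <- edges$mirna %in% a$mirnas & edges$mrna %in% b$mrnas
  ba <- edges$mirna %in% b$mirnas & edges$mrna %in% a$mrnas
  sum(edges$weight[ab | ba]) / (length(va) + length(vb))
}

#' Auxiliary graph of cross weights over a clustering
#'
#' All unordered pairs of clusters with positive cross weight; pairs with no
#' connecting edges are omitted.
#'
#' @param clustering A membership tibble (`vertex`, `vertex_type`,
#'   `cluster_id`, `round_label`).
#' @param edges The raw weighted edge list.
#' @return A tibble with columns `cluster_a`, `cluster_b`, `cross_weight`
#'   (`cluster_a < cluster_b` lexicographically), sorted by pair.
#' @export
build_auxiliary_graph <- function(clustering, edges) {
  validate_clustering(clustering)
  empty <- tibble(cluster_a = character(), cluster_b = character(),
                  cross_weight = double())
  if (nrow(clustering) == 0 || nrow(edges) == 0) return(empty)
  cl_of <- setNames(clustering$cluster_id, clustering$vertex)
  sizes <- clustering |> dplyr::count(.data$cluster_id, name = "size")
  size_of <- setNames(sizes$size, sizes$cluster_id)
  cm <- unname(cl_of[edges$mirna])
  cg <- unname(cl_of[edges$mrna])
  keep <- !is.na(cm) & !is.na(cg) & cm != cg & edges$weight > 0
  if (!any(keep)) return(empty)
  pa <- pmin(cm[keep], cg[keep])
  pb <- pmax(cm[keep], cg[keep])
  tibble(cluster_a = pa, cluster_b = pb, w = edges$weight[keep]) |>
    dplyr::summarise(s = sum(.data$w), .by = c("cluster_a", "cluster_b")) |>
    dplyr::mutate(cross_weight = .data$s /
                    (unname(size_of[.data$cluster_a]) + unname(size_of[.data$cluster_b]))) |>
    dplyr::select("cluster_a", "cluster_b", "cross_weight") |>
    dplyr::filter(.data$cross_weight > 0) |>
    dplyr::arrange(.data$cluster_a, .data$cluster_b)
}

#' Maximum-weight matching on the auxiliary graph
#'
#' Thin wrapper over [blossom_matching()]: finds the set of disjoint cluster
#' pairs with maximum total cross weight.
#'
#' @param aux An auxiliary edge tibble from [build_auxiliary_graph()].
#' @return A tibble with columns `cluster_a`, `cluster_b`, `cross_weight`,
#'   one row per matched pair.
#' @export
max_weight_general_matching <- function(aux) {
  if (nrow(aux) == 0) {
    return(tibble(cluster_a = character(), cluster_b = character(),
                  cross_weight = double()))
  }
  m <- blossom_matching(tibble(from = aux$cluster_a, to = aux$cluster_b,
                               weight = aux$cross_weight))
  tibble(cluster_a = pmin(m$from, m$to), cluster_b = pmax(m$from, m$to),
         cross_weight = m$weight) |>
    dplyr::arrange(.data$cluster_a)
}

# "hungarian" -> "blossom_01"; "blossom_03" -> "blossom_04"; else "merged_01"
next_round_label <- function(label) {
  label <- unique(label)[1]
  if (identical(label, "hungarian")) return("blossom_01")
  m <- regmatches(label, regexec("^blossom_(\\d+)$", label))[[1]]
  if (length(m) == 2) return(sprintf("blossom_%02d", as.integer(m[2]) + 1L))
  "merged_01"
}

#' One merge round
#'
#' Builds the auxiliary graph, matches clusters by maximum total cross
#' weight, and fuses each matched pair into one cluster whose id joins the
#' two parent ids with `"+"` (an auditable merge tree). Unmatched clusters
#' carry over unchanged; the vertex universe is preserved.
#'
#' @param clustering A membership tibble.
#' @param edges The raw weighted edge list.
#' @param round_label Label for the produced clustering; default increments
#'   the input's label (`hungarian` to `blossom_01`, `blossom_01` to
#'   `blossom_02`, ...).
#' @return The new membership tibble. The merge records (tibble `parent_a`,
#'   `parent_b`, `child`, `cross_weight`) are attached as attribute
#'   `"merges"`; an empty record set signals a fixed point.
#' @export
merge_round <- function(clustering, edges, round_label = NULL) {
  validate_clustering(clustering)
  if (is.null(round_label)) round_label <- next_round_label(clustering$round_label)
  aux <- build_auxiliary_graph(clustering, edges)
  matched <- max_weight_general_matching(aux)
  out <- clustering
  out$round_label <- round_label
  if (nrow(matched) > 0) {
    child <- purrr::map2_chr(matched$cluster_a, matched$cluster_b,
                             function(a, b) paste(sort(c(a, b)), collapse = "+"))
    remap <- setNames(rep(child, 2), c(matched$cluster_a, matched$cluster_b))
    hit <- out$cluster_id %in% names(remap)
    out$cluster_id[hit] <- unname(remap[out$cluster_id[hit]])
  }
  merges <- tibble(parent_a = matched$cluster_a, parent_b = matched$cluster_b,
                   child = if (nrow(matched) > 0) {
                     purrr::map2_chr(matched$cluster_a, matched$cluster_b,
                                     function(a, b) paste(sort(c(a, b)), collapse = "+"))
                   } else character(),
                   cross_weight = matched$cross_weight)
  attr(out, "merges") <- merges
  out
}

#' Run the full maximum weighted merger pipeline
#'
#' Filters the correlation table to sign-inverting pairs, computes edge
#' weights under the chosen formula, grows one star per miRNA by iterated
#' bipartite matching, then repeats cross-weight merge rounds until no
#' positive cross weight remains, a single cluster is left, or `max_rounds`
#' merge rounds have run. Every round's clustering is retained so any
#' intermediate partition can be selected afterwards (the trade-off between
#' cluster size and cluster number is the user's to make).
#'
#' @param table A correlation table (`mrna`, `mirna`, `t_cc`, `n_cc`).
#' @param formula One of [weight_formulas()] (default `integrated_mean`).
#' @param max_rounds Cap on the number of merge rounds (default unlimited).
#' @param strict_filter Apply [filter_sign_inversion()] first (default TRUE).
#' @param lambdas Optional precomputed lambdas for `integrated_mean`.
#' @return An object of class `mwmm_history`: a list with `rounds` (named
#'   list of membership tibbles: `hungarian`, `blossom_01`, ...), `merges`
#'   (tibble `round_label`, `parent_a`, `parent_b`, `child`,
#'   `cross_weight`), `edges`, `stars`, `formula`, `lambdas` (or NULL) and
#'   `n_hungarian_rounds`.
#' @export
run_mwmm <- function(table, formula = "integrated_mean", max_rounds = Inf,
                     strict_filter = TRUE, lambdas = NULL) {
  formula <- match.arg(formula, weight_formulas())
  tbl <- if (strict_filter) filter_sign_inversion(table, "strict") else table
  if (nrow(tbl) == 0) abort("no sign-inverting records", class = "mwmm_data_error")
  edges <- build_weighted_edges(tbl, formula, lambdas)
  st <- build_stars(edges)
  rounds <- list(hungarian = st$clustering)
  merges <- list()
  current <- st$clustering
  r <- 0L
  while (r < max_rounds && dplyr::n_distinct(current$cluster_id) > 1) {
    nxt <- merge_round(current, edges)
    mg <- attr(nxt, "merges")
    if (nrow(mg) == 0) break # fixed point: no positive cross weight remains
    r <- r + 1L
    label <- nxt$round_label[1]
    rounds[[label]] <- nxt
    merges[[label]] <- dplyr::mutate(mg, round_label = label, .before = 1)
    current <- nxt
  }
  structure(
    list(
      rounds = rounds,
      merges = if (length(merges) > 0) dplyr::bind_rows(merges) else
        tibble(round_label = character(), parent_a = character(),
               parent_b = character(), child = character(),
               cross_weight = double()),
      edges = edges,
      stars = st$stars,
      formula = formula,
      lambdas = attr(edges, "lambdas"),
      n_hungarian_rounds = st$n_rounds
    ),
    class = "mwmm_history"
  )
}
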