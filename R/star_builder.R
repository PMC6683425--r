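# Star construction stage: iterated maximum-weight bipartite matching on the
# miRNA x mRNA weight matrix. Each round matches every miRNA to at most one
# new mRNA; matched mRNA columns leave the matrix, so over the rounds each
# miRNA accretes a star K_1,k (the miRNA is the internal node, its matched
# mRNAs the leaves). Zero-weight matches are bookkeeping artifacts of
# rectangular assignment and are discarded without removing their vertices.

#' Bipartite weight matrix from an edge list
#'
#' One row per distinct miRNA, one column per distinct mRNA (both sorted for
#' determinism); absent pairs get weight 0.
#'
#' @param edges A weighted edge list (`mrna`, `mirna`, `weight`).
#' @return A numeric matrix with miRNA row names and mRNA column names.
#' @export
matrix_from_edges <- function(edges) {
  if (nrow(edges) == 0) {
    return(matrix(numeric(0), 0, 0))
  }
  key <- paste(edges$mirna, edges$mrna, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (miRNA, mRNA) pair in edge list", class = "mwmm_duplicate_error")
  }
  mirnas <- sort(unique(edges$mirna))
  mrnas <- sort(unique(edges$mrna))
  mat <- matrix(0, length(mirnas), length(mrnas),
                dimnames = list(mirnas, mrnas))
  mat[cbind(match(edges$mirna, mirnas), match(edges$mrna, mrnas))] <- edges$weight
  mat
}

#' Maximum-weight bipartite matching of a weight matrix
#'
#' Solves the rectangular assignment problem on the matrix: a matching of
#' maximum total weight in which every vertex on the smaller side is matched
#' (vertices left over by the weighted optimum are paired to remaining
#' partners at weight 0, the implicit zero padding). Zero entries mean "no
#' interaction".
#'
#' @param matrix A non-negative matrix with miRNA row names and mRNA column
#'   names (see [matrix_from_edges()]).
#' @return A tibble with columns `mirna`, `mrna`, `weight`, one row per
#'   matched pair, sorted by `mirna`.
#' @export
max_weight_bipartite_matching <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) == 0 || ncol(matrix) == 0) {
    return(tibble(mirna = character(), mrna = character(), weight = double()))
  }
  if (any(matrix < 0)) abort("weights must be non-negative", class = "mwmm_data_error")
  mirnas <- rownames(matrix)
  mrnas <- colnames(matrix)
  pos <- which(matrix > 0, arr.ind = TRUE)
  matched <- tibble(mirna = character(), mrna = character(), weight = double())
  if (nrow(pos) > 0) {
    # vertex order: rows then columns, canonical (matrix dimnames are sorted
    # by construction upstream; igraph is deterministic given this order)
    g <- igraph::make_empty_graph(n = length(mirnas) + length(mrnas),
                                  directed = FALSE)
    igraph::V(g)$type <- c(rep(FALSE, length(mirnas)), rep(TRUE, length(mrnas)))
    ends <- rbind(pos[, 1], length(mirnas) + pos[, 2])
    g <- igraph::add_edges(g, as.vector(ends))
    res <- igraph::max_bipartite_match(g, weights = matrix[pos])
    mt <- res$matching[seq_along(mirnas)]
    hit <- which(!is.na(mt))
    if (length(hit) > 0) {
      ci <- mt[hit] - length(mirnas)
      matched <- tibble(mirna = mirnas[hit], mrna = mrnas[ci],
                        weight = matrix[cbind(hit, ci)])
    }
  }
  # zero padding: every vertex on the smaller side must be matched
  small_is_rows <- length(mirnas) <= length(mrnas)
  if (small_is_rows) {
    left <- setdiff(mirnas, matched$mirna)
    avail <- setdiff(mrnas, matched$mrna)
  } else {
    left <- setdiff(mrnas, matched$mrna)
    avail <- setdiff(mirnas, matched$mirna)
  }
  k <- min(length(left), length(avail))
  if (k > 0) {
    pad <- if (small_is_rows) {
      tibble(mirna = sort(left)[seq_len(k)], mrna = sort(avail)[seq_len(k)],
             weight = 0)
    } else {
      tibble(mirna = sort(avail)[seq_len(k)], mrna = sort(left)[seq_len(k)],
             weight = 0)
    }
    # padded pairs must be genuine zero entries (they are: neither end was
    # touched by the positive-weight optimum)
    matched <- dplyr::bind_rows(matched, pad)
  }
  dplyr::arrange(matched, .data$mirna)
}

#' One round of the star-construction bookkeeping
#'
#' Runs a maximum-weight matching on the current matrix, then: discards
#' matched pairs of weight 0 (their vertices stay in the matrix for later
#' rounds); removes the columns of mRNAs matched at positive weight; removes
#' any miRNA row whose remaining entries are all zero.
#'
#' @param state The current bipartite weight matrix.
#' @return A list with `matches` (tibble `mirna`, `mrna`, `weight`, positive
#'   weights only) and `matrix` (the reduced matrix).
#' @export
hungarian_round <- function(state) {
  stopifnot(is.matrix(state))
  matches <- max_weight_bipartite_matching(state)
  matches <- matches[matches$weight > 0, , drop = FALSE]
  mat <- state
  if (nrow(matches) > 0) {
    mat <- mat[, !(colnames(mat) %in% matches$mrna), drop = FALSE]
  }
  if (nrow(mat) > 0) {
    keep <- if (ncol(mat) > 0) rowSums(mat > 0) > 0 else rep(FALSE, nrow(mat))
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(matches) == 0 && identical(dim(mat), dim(state))) {
    # degenerate: nothing matched and nothing removable; clear to terminate
    mat <- mat[integer(0), integer(0), drop = FALSE]
  }
  list(matches = matches, matrix = mat)
}

#' Build the star-graph clustering by iterated bipartite matching
#'
#' Repeats [hungarian_round()] until the matrix is exhausted. Each round's
#' positive-weight matches append one leaf mRNA to the matching miRNA's star.
#' Every mRNA with at least one positive entry ends up as a leaf of exactly
#' one star; the number of stars equals the number of miRNAs with at least
#' one positive entry.
#'
#' @param x A bipartite weight matrix or a weighted edge list
#'   (`mrna`, `mirna`, `weight`).
#' @return An object of class `mwmm_stars`: a list with `stars` (tibble
#'   `center`, `mrna`, `weight`, `round`), `clustering` (membership tibble,
#'   `round_label = "hungarian"`, one cluster per star named after its center
#'   miRNA, sorted by center) and `n_rounds`.
#' @export
build_stars <- function(x) {
  mat <- if (is.matrix(x)) x else matrix_from_edges(x)
  all_rounds <- list()
  n_rounds <- 0L
  while (nrow(mat) > 0 && ncol(mat) > 0) {
    res <- hungarian_round(mat)
    n_rounds <- n_rounds + 1L
    if (nrow(res$matches) > 0) {
      all_rounds[[n_rounds]] <- dplyr::mutate(res$matches, round = n_rounds)
    }
    mat <- res$matrix
  }
  if (n_rounds == 0L) n_rounds <- 1L # empty input still counts as one pass
  stars <- if (length(all_rounds) > 0) {
    dplyr::bind_rows(all_rounds) |>
      dplyr::rename(center = "mirna") |>
      dplyr::arrange(.data$center, .data$round)
  } else {
    tibble(center = character(), mrna = character(), weight = double(),
           round = integer())
  }
  clustering <- if (nrow(stars) > 0) {
    tibble(
      vertex = c(unique(stars$center), stars$mrna),
      vertex_type = c(rep("miRNA", dplyr::n_distinct(stars$center)),
                      rep("mRNA", nrow(stars))),
      cluster_id = c(unique(stars$center), stars$center),
      round_label = "hungarian"
    ) |>
      dplyr::arrange(.data$cluster_id, dplyr::desc(.data$vertex_type), .data$vertex)
  } else {
    tibble(vertex = character(), vertex_type = character(),
           cluster_id = character(), round_label = character())
  }
  validate_clustering(clustering)
  structure(list(stars = stars, clustering = clustering, n_rounds = n_rounds),
            class = "mwmm_stars")
}

#' @export
print.mwmm_stars <- function(x, ...) {
  cat(sprintf("Star-graph clustering: %d stars, %d leaf mRNAs, %d matching rounds\n",
              dplyr::n_distinct(x$stars$center), nrow(x$stars), x$n_rounds))
  invisible(x)
}
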