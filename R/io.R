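# Reading, validating and writing the tabular formats the pipeline speaks:
# correlation tables (mRNA, microRNA, T_CC, N_CC), weighted edge lists
# (mRNA, microRNA, weight) and clustering membership tables.

# Case-insensitive header resolution, tolerant of the common spelling
# variants ("microRNA" vs "miRNA"). Returns the actual column name or errors.
resolve_column <- function(nms, aliases, label) {
  hit <- which(tolower(nms) %in% tolower(aliases))
  if (length(hit) == 0) {
    abort(sprintf("required column '%s' not found (accepted names: %s)",
                  label, paste(aliases, collapse = ", ")),
          class = "mwmm_format_error")
  }
  nms[hit[1]]
}

sniff_separator <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) return("\t")
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Read a tumor/normal correlation table
#'
#' Reads a delimited table with one row per miRNA-mRNA pair and columns
#' `mRNA`, `microRNA`, `T_CC` (correlation across tumor samples) and `N_CC`
#' (correlation across normal samples). Column matching is case-insensitive
#' and accepts `miRNA` for `microRNA`. The separator is auto-detected from
#' the header (tab preferred, then comma) unless given.
#'
#' @param path Path to a TSV or CSV file.
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @return A tibble with columns `mrna`, `mirna`, `t_cc`, `n_cc`, preserving
#'   the file's row order.
#' @export
read_correlation_table <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "mwmm_io_error")
  }
  if (is.null(sep)) sep <- sniff_separator(path)
  raw <- readr::read_delim(path, delim = sep, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  nms <- names(raw)
  col_mrna <- resolve_column(nms, c("mrna", "gene", "mRNA"), "mRNA")
  col_mirna <- resolve_column(nms, c("microrna", "mirna"), "microRNA")
  col_t <- resolve_column(nms, c("t_cc", "tcc"), "T_CC")
  col_n <- resolve_column(nms, c("n_cc", "ncc"), "N_CC")
  out <- tibble(
    mrna = as.character(raw[[col_mrna]]),
    mirna = as.character(raw[[col_mirna]]),
    t_cc = parse_correlation(raw[[col_t]], "T_CC"),
    n_cc = parse_correlation(raw[[col_n]], "N_CC")
  )
  validate_correlation_table(out)
  out
}

# Minus signs come in unicode variants in exported tables.
parse_correlation <- function(x, label) {
  x <- gsub("−|–", "-", x)
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(val))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric %s value '%s' at row %d", label, x[bad[1]], bad[1]),
          class = "mwmm_row_error")
  }
  val
}

validate_correlation_table <- function(tbl) {
  stopifnot(all(c("mrna", "mirna", "t_cc", "n_cc") %in% names(tbl)))
  if (nrow(tbl) == 0) return(invisible(tbl))
  if (any(!nzchar(tbl$mrna)) || any(!nzchar(tbl$mirna)) ||
      anyNA(tbl$mrna) || anyNA(tbl$mirna)) {
    abort("mRNA and miRNA names must be non-empty", class = "mwmm_row_error")
  }
  for (col in c("t_cc", "n_cc")) {
    v <- tbl[[col]]
    bad <- which(is.na(v) | v < -1 | v > 1)
    if (length(bad) > 0) {
      abort(sprintf("%s out of [-1, 1] (or missing) at row %d", toupper(col), bad[1]),
            class = "mwmm_row_error")
    }
  }
  dup <- duplicated(paste(tbl$mirna, tbl$mrna, sep = "\r"))
  if (any(dup)) {
    d <- which(dup)[1]
    abort(sprintf("duplicate (miRNA, mRNA) pair at row %d: (%s, %s)",
                  d, tbl$mirna[d], tbl$mrna[d]),
          class = "mwmm_duplicate_error")
  }
  invisible(tbl)
}

#' Keep only sign-inverting miRNA-mRNA pairs
#'
#' A pair is retained when its correlation flips sign between normal and
#' tumor, i.e. `t_cc * n_cc < 0`. Pairs with a zero coefficient do not invert
#' and are dropped in strict mode (the piecewise weight formulas are undefined
#' at `T_CC = 0`).
#'
#' @param table A correlation table (see [read_correlation_table()]).
#' @param mode `"strict"` (default) removes non-inverting rows; `"keep-all"`
#'   returns the table unchanged and reports the non-inverting count.
#' @return A tibble with the same columns, in the original row order.
#' @export
filter_sign_inversion <- function(table, mode = c("strict", "keep-all")) {
  mode <- match.arg(mode)
  inv <- table$t_cc * table$n_cc < 0
  if (mode == "keep-all") {
    inform(sprintf("%d of %d records do not invert sign", sum(!inv), nrow(table)))
    return(as_tibble(table))
  }
  as_tibble(table[inv, , drop = FALSE])
}

#' Write / read a weighted edge list
#'
#' Tab-separated with header `mRNA`, `microRNA`, `weight`; weights are
#' rendered with 10 decimal places so files round-trip through
#' [read_edge_list()] at the printed precision.
#'
#' @param edges A data frame with columns `mrna`, `mirna`, `weight`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  out <- tibble(
    mRNA = edges$mrna,
    microRNA = edges$mirna,
    weight = sprintf("%.10f", edges$weight)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @return For `read_edge_list()`: a tibble with columns `mrna`, `mirna`,
#'   `weight`.
#' @export
read_edge_list <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "mwmm_io_error")
  }
  if (is.null(sep)) sep <- sniff_separator(path)
  raw <- readr::read_delim(path, delim = sep, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  nms <- names(raw)
  col_mrna <- resolve_column(nms, c("mrna", "gene"), "mRNA")
  col_mirna <- resolve_column(nms, c("microrna", "mirna"), "microRNA")
  col_w <- resolve_column(nms, c("weight", "w"), "weight")
  w <- suppressWarnings(as.numeric(gsub("−", "-", raw[[col_w]])))
  bad <- which(is.na(w) | w < 0)
  if (length(bad) > 0) {
    abort(sprintf("invalid weight at row %d", bad[1]), class = "mwmm_row_error")
  }
  tibble(mrna = as.character(raw[[col_mrna]]),
         mirna = as.character(raw[[col_mirna]]),
         weight = w)
}

#' Write / read a clustering membership table
#'
#' One row per clustered vertex with columns `vertex`,
#' `vertex_type` (`miRNA` or `mRNA`), `cluster_id` and `round_label`.
#' On write, cluster ids are relabelled to contiguous integers in order of
#' first appearance; the partition structure is unchanged.
#'
#' @param clustering A membership tibble as produced by the pipeline
#'   (columns `vertex`, `vertex_type`, `cluster_id`, `round_label`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, path) {
  validate_clustering(clustering)
  out <- tibble(
    vertex = clustering$vertex,
    vertex_type = clustering$vertex_type,
    cluster_id = match(clustering$cluster_id, unique(clustering$cluster_id)),
    round_label = clustering$round_label
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_clustering
#' @return For `read_clustering()`: the membership tibble.
#' @export
read_clustering <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "mwmm_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("vertex", "vertex_type", "cluster_id", "round_label")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
          class = "mwmm_format_error")
  }
  out <- as_tibble(raw[need])
  validate_clustering(out)
  out
}

validate_clustering <- function(clustering) {
  need <- c("vertex", "vertex_type", "cluster_id", "round_label")
  stopifnot(all(need %in% names(clustering)))
  if (nrow(clustering) == 0) return(invisible(clustering))
  if (anyDuplicated(clustering$vertex)) {
    abort("a vertex appears in more than one cluster", class = "mwmm_partition_error")
  }
  if (!all(clustering$vertex_type %in% c("miRNA", "mRNA"))) {
    abort("vertex_type must be 'miRNA' or 'mRNA'", class = "mwmm_format_error")
  }
  invisible(clustering)
}

# Construct a membership tibble from a named list of clusters
# (each list(mirnas = chr, mrnas = chr)).
clustering_from_list <- function(clusters, round_label) {
  if (length(clusters) == 0) {
    return(tibble(vertex = character(), vertex_type = character(),
                  cluster_id = character(), round_label = character()))
  }
  rows <- purrr::imap(clusters, function(cl, id) {
    tibble(
      vertex = c(cl$mirnas, cl$mrnas),
      vertex_type = c(rep("miRNA", length(cl$mirnas)), rep("mRNA", length(cl$mrnas))),
      cluster_id = id,
      round_label = round_label
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_clustering(out)
  out
}

# Inverse of clustering_from_list().
clustering_to_list <- function(clustering) {
  validate_clustering(clustering)
  ids <- unique(clustering$cluster_id)
  setNames(lapply(ids, function(id) {
    sub <- clustering[clustering$cluster_id == id, ]
    list(mirnas = sub$vertex[sub$vertex_type == "miRNA"],
         mrnas = sub$vertex[sub$vertex_type == "mRNA"])
  }), ids)
}
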