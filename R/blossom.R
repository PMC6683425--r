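# Maximum-weight matching in a general graph: primal-dual blossom algorithm,
# O(n^3) stage structure (Galil 1986). Vertices are 1..n; blossom slots occupy
# n+1..2n. Edge k has endpoint slots 2k-1 (toward its first vertex) and 2k
# (toward its second); opp() flips a slot to the other end of the same edge.
# Duals are kept in doubled units so slacks stay exact for terminating decimals.

#' Maximum-weight matching in a general graph
#'
#' Finds a matching (a set of edges no two of which share a vertex) whose total
#' weight is maximum. This is the matching step used to pair clusters in each
#' merge round; it is exposed directly so the solver can be exercised and
#' checked on arbitrary graphs.
#'
#' @param edges A data frame with columns `from`, `to` (vertex identifiers,
#'   coercible to character) and `weight` (non-negative numeric).
#' @return A tibble with columns `from`, `to`, `weight`: one row per matched
#'   edge, ordered by `from`. Vertices are returned under their original
#'   labels; internally labels are sorted so the result is deterministic
#'   whenever the optimum is unique (ties may resolve to any optimal matching).
#' @examples
#' tri <- tibble::tibble(from = c("a", "b", "a"), to = c("b", "c", "c"),
#'                       weight = c(3, 2, 2))
#' blossom_matching(tri) # matches a-b, total 3
#' @export
blossom_matching <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = double()))
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- as.numeric(edges$weight)
  if (any(from == to)) stop("self-loops are not allowed in a matching problem")
  if (anyNA(w) || any(w < 0)) stop("edge weights must be non-negative numbers")
  verts <- sort(unique(c(from, to)))
  i <- match(from, verts)
  j <- match(to, verts)
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) stop("duplicate edges between the same vertex pair")
  mate <- max_weight_matching_impl(i, j, w, length(verts))
  sel <- which(mate > seq_along(mate)) # each matched pair once, smaller index first
  out <- tibble::tibble(from = verts[sel], to = verts[mate[sel]])
  ekey <- paste(pmin(sel, mate[sel]), pmax(sel, mate[sel]))
  out$weight <- w[match(ekey, key)]
  dplyr::arrange(out, .data$from)
}

# Returns mate[v] (vertex index of partner, or 0 if unmatched) for the
# maximum-weight matching of the graph with edges (ei[k], ej[k], wt[k]).
max_weight_matching_impl <- function(ei, ej, wt, nvertex) {
  nedge <- length(wt)
  mate_v <- integer(nvertex) # 0 = unmatched; else partner's endpoint SLOT
  if (nedge == 0L || nvertex == 0L) return(integer(nvertex))
  maxweight <- max(wt)

  opp <- function(p) p + 1L - 2L * ((p - 1L) %% 2L) # flip endpoint slot
  edge_of <- function(p) (p + 1L) %/% 2L
  # endpoint[p]: vertex that slot p points AT (slot 2k-1 -> ei[k], 2k -> ej[k])
  endpoint <- integer(2L * nedge)
  endpoint[2L * seq_len(nedge) - 1L] <- ei
  endpoint[2L * seq_len(nedge)] <- ej
  # neighbend[[v]]: slots p with endpoint[opp(p)] == v, i.e. slots leaving v
  neighbend <- vector("list", nvertex)
  for (k in seq_len(nedge)) {
    neighbend[[ej[k]]] <- c(neighbend[[ej[k]]], 2L * k - 1L)
    neighbend[[ei[k]]] <- c(neighbend[[ei[k]]], 2L * k)
  }

  two_n <- 2L * nvertex
  mate <- integer(nvertex); mate[] <- -1L # -1 unmatched, else endpoint slot
  label <- integer(two_n)
  labelend <- integer(two_n); labelend[] <- -1L
  inblossom <- seq_len(nvertex)
  blossomparent <- integer(two_n); blossomparent[] <- -1L
  blossomchilds <- vector("list", two_n)
  blossombase <- c(seq_len(nvertex), rep(-1L, nvertex))
  blossomendps <- vector("list", two_n)
  bestedge <- integer(two_n); bestedge[] <- -1L
  blossombestedges <- vector("list", two_n)
  unusedblossoms <- as.list((nvertex + 1L):two_n)
  dualvar <- c(rep(maxweight, nvertex), rep(0, nvertex))
  allowedge <- rep(FALSE, nedge)
  queue <- integer(0)
  scanned <- rep(FALSE, two_n) # scanBlossom visitation marks

  slack <- function(k) dualvar[ei[k]] + dualvar[ej[k]] - 2 * wt[k]

  blossom_leaves <- function(b) {
    if (b <= nvertex) return(b)
    unlist(lapply(blossomchilds[[b]], blossom_leaves))
  }

  assign_label <- function(wv, t, p) {
    b <- inblossom[wv]
    label[wv] <<- t; label[b] <<- t
    labelend[wv] <<- p; labelend[b] <<- p
    bestedge[wv] <<- -1L; bestedge[b] <<- -1L
    if (t == 1L) {
      queue <<- c(queue, blossom_leaves(b))
    } else if (t == 2L) {
      base <- blossombase[b]
      assign_label(endpoint[mate[base]], 1L, opp(mate[base]))
    }
  }

  # Trace back from v and w toward roots; return common ancestor base vertex
  # (a new blossom forms) or -1 (augmenting path found).
  scan_blossom <- function(v, wv) {
    path <- integer(0)
    base <- -1L
    while (v != -1L || wv != -1L) {
      b <- inblossom[v]
      if (scanned[b]) { base <- blossombase[b]; break }
      path <- c(path, b)
      scanned[b] <<- TRUE
      if (mate[blossombase[b]] == -1L) {
        v <- -1L
      } else {
        v <- endpoint[mate[blossombase[b]]]
        b <- inblossom[v]
        v <- endpoint[labelend[b]]
      }
      if (wv != -1L) { tmp <- v; v <- wv; wv <- tmp }
    }
    scanned[path] <<- FALSE
    base
  }

  # 0-based, possibly negative, cyclic list access helpers
  cyc <- function(lst, jj) lst[[(jj %% length(lst)) + 1L]]

  add_blossom <- function(base, k) {
    v <- ei[k]; wv <- ej[k]
    bb <- inblossom[base]; bv <- inblossom[v]; bw <- inblossom[wv]
    b <- unusedblossoms[[length(unusedblossoms)]]
    unusedblossoms[[length(unusedblossoms)]] <<- NULL
    blossombase[b] <<- base
    blossomparent[b] <<- -1L
    blossomparent[bb] <<- b
    path <- integer(0); endps <- integer(0)
    while (bv != bb) {
      blossomparent[bv] <<- b
      path <- c(path, bv)
      endps <- c(endps, labelend[bv])
      v <- endpoint[labelend[bv]]
      bv <- inblossom[v]
    }
    path <- rev(c(path, bb))
    endps <- c(rev(endps), 2L * k - 1L)
    while (bw != bb) {
      blossomparent[bw] <<- b
      path <- c(path, bw)
      endps <- c(endps, opp(labelend[bw]))
      wv <- endpoint[labelend[bw]]
      bw <- inblossom[wv]
    }
    blossomchilds[[b]] <<- path
    blossomendps[[b]] <<- endps
    label[b] <<- 1L
    labelend[b] <<- labelend[bb]
    dualvar[b] <<- 0
    for (leaf in blossom_leaves(b)) {
      if (label[inblossom[leaf]] == 2L) queue <<- c(queue, leaf)
      inblossom[leaf] <<- b
    }
    bestedgeto <- integer(two_n); bestedgeto[] <- -1L
    for (bv2 in path) {
      if (is.null(blossombestedges[[bv2]])) {
        nblist <- unique(edge_of(unlist(lapply(blossom_leaves(bv2),
                                               function(x) neighbend[[x]]))))
      } else {
        nblist <- blossombestedges[[bv2]]
      }
      for (k2 in nblist) {
        i2 <- ei[k2]; j2 <- ej[k2]
        if (inblossom[j2] == b) { tmp <- i2; i2 <- j2; j2 <- tmp }
        bj <- inblossom[j2]
        if (bj != b && label[bj] == 1L &&
            (bestedgeto[bj] == -1L || slack(k2) < slack(bestedgeto[bj]))) {
          bestedgeto[bj] <- k2
        }
      }
      blossombestedges[bv2] <<- list(NULL)
      bestedge[bv2] <<- -1L
    }
    keep <- bestedgeto[bestedgeto != -1L]
    blossombestedges[[b]] <<- keep
    bestedge[b] <<- -1L
    for (k2 in keep) {
      if (bestedge[b] == -1L || slack(k2) < slack(bestedge[b])) {
        bestedge[b] <<- k2
      }
    }
  }

  expand_blossom <- function(b, endstage) {
    for (s in blossomchilds[[b]]) {
      blossomparent[s] <<- -1L
      if (s <= nvertex) {
        inblossom[s] <<- s
      } else if (endstage && dualvar[s] == 0) {
        expand_blossom(s, endstage)
      } else {
        for (v in blossom_leaves(s)) inblossom[v] <<- s
      }
    }
    if (!endstage && label[b] == 2L) {
      entrychild <- inblossom[endpoint[opp(labelend[b])]]
      jj <- which(blossomchilds[[b]] == entrychild) - 1L # 0-based
      len <- length(blossomchilds[[b]])
      if (jj %% 2L == 1L) {
        jj <- jj - len; jstep <- 1L; endptrick <- 0L
      } else {
        jstep <- -1L; endptrick <- 1L
      }
      p <- labelend[b]
      while (jj != 0L) {
        label[endpoint[opp(p)]] <<- 0L
        q <- cyc(as.list(blossomendps[[b]]), jj - endptrick)
        if (endptrick == 1L) q <- opp(q)
        label[endpoint[opp(q)]] <<- 0L
        assign_label(endpoint[opp(p)], 2L, p)
        allowedge[edge_of(q)] <<- TRUE
        jj <- jj + jstep
        p <- cyc(as.list(blossomendps[[b]]), jj - endptrick)
        if (endptrick == 1L) p <- opp(p)
        allowedge[edge_of(p)] <<- TRUE
        jj <- jj + jstep
      }
      bv <- cyc(as.list(blossomchilds[[b]]), jj)
      label[endpoint[opp(p)]] <<- 2L
      label[bv] <<- 2L
      labelend[endpoint[opp(p)]] <<- p
      labelend[bv] <<- p
      bestedge[bv] <<- -1L
      jj <- jj + jstep
      while (cyc(as.list(blossomchilds[[b]]), jj) != entrychild) {
        bv <- cyc(as.list(blossomchilds[[b]]), jj)
        if (label[bv] == 1L) { jj <- jj + jstep; next }
        v <- 0L
        for (lv in blossom_leaves(bv)) { v <- lv; if (label[lv] != 0L) break }
        if (label[v] != 0L) {
          label[v] <<- 0L
          label[endpoint[mate[blossombase[bv]]]] <<- 0L
          assign_label(v, 2L, labelend[v])
        }
        jj <- jj + jstep
      }
    }
    label[b] <<- -1L; labelend[b] <<- -1L
    blossomchilds[b] <<- list(NULL)
    blossomendps[b] <<- list(NULL)
    blossombase[b] <<- -1L
    blossombestedges[b] <<- list(NULL)
    bestedge[b] <<- -1L
    unusedblossoms[[length(unusedblossoms) + 1L]] <<- b
  }

  augment_blossom <- function(b, v) {
    t <- v
    while (blossomparent[t] != b) t <- blossomparent[t]
    if (t > nvertex) augment_blossom(t, v)
    i0 <- which(blossomchilds[[b]] == t) - 1L # 0-based entry index
    jj <- i0
    len <- length(blossomchilds[[b]])
    if (i0 %% 2L == 1L) {
      jj <- jj - len; jstep <- 1L; endptrick <- 0L
    } else {
      jstep <- -1L; endptrick <- 1L
    }
    while (jj != 0L) {
      jj <- jj + jstep
      t <- cyc(as.list(blossomchilds[[b]]), jj)
      p <- cyc(as.list(blossomendps[[b]]), jj - endptrick)
      if (endptrick == 1L) p <- opp(p)
      if (t > nvertex) augment_blossom(t, endpoint[p])
      jj <- jj + jstep
      t <- cyc(as.list(blossomchilds[[b]]), jj)
      if (t > nvertex) augment_blossom(t, endpoint[opp(p)])
      mate[endpoint[p]] <<- opp(p)
      mate[endpoint[opp(p)]] <<- p
    }
    ch <- blossomchilds[[b]]; ep <- blossomendps[[b]]
    if (i0 > 0L) {
      idx <- c((i0 + 1L):len, seq_len(i0))
      blossomchilds[[b]] <<- ch[idx]
      blossomendps[[b]] <<- ep[idx]
    }
    blossombase[b] <<- blossombase[blossomchilds[[b]][1L]]
  }

  augment_matching <- function(k) {
    starts <- list(c(ei[k], 2L * k), c(ej[k], 2L * k - 1L))
    for (sp in starts) {
      s <- sp[1L]; p <- sp[2L]
      repeat {
        bs <- inblossom[s]
        if (bs > nvertex) augment_blossom(bs, s)
        mate[s] <<- p
        if (labelend[bs] == -1L) break
        t <- endpoint[labelend[bs]]
        bt <- inblossom[t]
        s <- endpoint[labelend[bt]]
        jv <- endpoint[opp(labelend[bt])]
        if (bt > nvertex) augment_blossom(bt, jv)
        mate[jv] <<- labelend[bt]
        p <- opp(labelend[bt])
      }
    }
  }

  for (stage in seq_len(nvertex)) {
    label[] <- 0L
    bestedge[] <- -1L
    for (b in (nvertex + 1L):two_n) blossombestedges[b] <- list(NULL)
    allowedge[] <- FALSE
    queue <- integer(0)
    for (v in seq_len(nvertex)) {
      if (mate[v] == -1L && label[inblossom[v]] == 0L) assign_label(v, 1L, -1L)
    }
    augmented <- FALSE
    repeat {
      while (length(queue) > 0L && !augmented) {
        v <- queue[length(queue)]
        queue <- queue[-length(queue)]
        for (p in neighbend[[v]]) {
          k <- edge_of(p)
          wv <- endpoint[p]
          if (inblossom[v] == inblossom[wv]) next
          kslack <- NA_real_
          if (!allowedge[k]) {
            kslack <- slack(k)
            if (kslack <= 0) allowedge[k] <- TRUE
          }
          if (allowedge[k]) {
            if (label[inblossom[wv]] == 0L) {
              assign_label(wv, 2L, opp(p))
            } else if (label[inblossom[wv]] == 1L) {
              base <- scan_blossom(v, wv)
              if (base >= 0L) {
                add_blossom(base, k)
              } else {
                augment_matching(k)
                augmented <- TRUE
                break
              }
            } else if (label[wv] == 0L) {
              label[wv] <- 2L
              labelend[wv] <- opp(p)
            }
          } else if (label[inblossom[wv]] == 1L) {
            b <- inblossom[v]
            if (bestedge[b] == -1L || kslack < slack(bestedge[b])) {
              bestedge[b] <- k
            }
          } else if (label[wv] == 0L) {
            if (bestedge[wv] == -1L || kslack < slack(bestedge[wv])) {
              bestedge[wv] <- k
            }
          }
        }
      }
      if (augmented) break
      # dual adjustment
      deltatype <- -1L
      delta <- NA_real_; deltaedge <- -1L; deltablossom <- -1L
      deltatype <- 1L
      delta <- min(dualvar[seq_len(nvertex)])
      for (v in seq_len(nvertex)) {
        if (label[inblossom[v]] == 0L && bestedge[v] != -1L) {
          d <- slack(bestedge[v])
          if (deltatype == -1L || d < delta) {
            delta <- d; deltatype <- 2L; deltaedge <- bestedge[v]
          }
        }
      }
      for (b in seq_len(two_n)) {
        if (blossomparent[b] == -1L && label[b] == 1L && bestedge[b] != -1L) {
          d <- slack(bestedge[b]) / 2
          if (deltatype == -1L || d < delta) {
            delta <- d; deltatype <- 3L; deltaedge <- bestedge[b]
          }
        }
      }
      for (b in (nvertex + 1L):two_n) {
        if (blossombase[b] >= 0L && blossomparent[b] == -1L &&
            label[b] == 2L && (deltatype == -1L || dualvar[b] < delta)) {
          delta <- dualvar[b]; deltatype <- 4L; deltablossom <- b
        }
      }
      if (deltatype == -1L) {
        deltatype <- 1L
        delta <- max(0, min(dualvar[seq_len(nvertex)]))
      }
      for (v in seq_len(nvertex)) {
        lb <- label[inblossom[v]]
        if (lb == 1L) dualvar[v] <- dualvar[v] - delta
        else if (lb == 2L) dualvar[v] <- dualvar[v] + delta
      }
      for (b in (nvertex + 1L):two_n) {
        if (blossombase[b] >= 0L && blossomparent[b] == -1L) {
          if (label[b] == 1L) dualvar[b] <- dualvar[b] + delta
          else if (label[b] == 2L) dualvar[b] <- dualvar[b] - delta
        }
      }
      if (deltatype == 1L) {
        break
      } else if (deltatype == 2L) {
        allowedge[deltaedge] <- TRUE
        i2 <- ei[deltaedge]; j2 <- ej[deltaedge]
        if (label[inblossom[i2]] == 0L) i2 <- j2
        queue <- c(queue, i2)
      } else if (deltatype == 3L) {
        allowedge[deltaedge] <- TRUE
        queue <- c(queue, ei[deltaedge])
      } else if (deltatype == 4L) {
        expand_blossom(deltablossom, FALSE)
      }
    }
    if (!augmented) break
    for (b in (nvertex + 1L):two_n) {
      if (blossomparent[b] == -1L && blossombase[b] >= 0L &&
          label[b] == 1L && dualvar[b] == 0) {
        expand_blossom(b, TRUE)
      }
    }
  }

  out <- integer(nvertex)
  matched <- mate != -1L
  out[matched] <- endpoint[mate[matched]]
  out
}
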