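#' Planarity test
#'
#' Decides whether a graph can be drawn in the plane without edge
#' crossings, using the left-right (LR) planarity criterion: a DFS
#' orientation is computed with low-point data per edge, and back edges are
#' partitioned into two interleaving-free classes by a conflict-pair stack.
#' The test is verdict-only (no embedding or Kuratowski certificate is
#' produced). Trivial shortcuts: graphs with fewer than 5 vertices or
#' fewer than 9 edges are planar; graphs with q > 3p - 6 (p >= 3) are not.
#'
#' @param x a `molecular_graph`, or a square 0/1 adjacency matrix
#' @return `TRUE` if planar, `FALSE` otherwise
#' @examples
#' is_planar(make_fixture("complete", r = 4))  # TRUE
#' is_planar(make_fixture("complete", r = 5))  # FALSE (K5)
#' @export
is_planar <- function(x) {
  if (is.matrix(x)) {
    idx <- which(upper.tri(x) & x != 0, arr.ind = TRUE)
    p <- nrow(x)
    edges <- idx
  } else {
    stopifnot(inherits(x, "molecular_graph"))
    p <- graph_order(x)
    edges <- x$edge_idx
  }
  q <- nrow(edges)
  if (p < 5L || q < 9L) return(TRUE)
  if (q > 3L * p - 6L) return(FALSE)
  lr_planarity(p, edges)
}

# Left-right planarity test (Brandes' formulation), verdict only.
# Darts: undirected edge r gives darts 2r-1 (u->v) and 2r (v->u).
lr_planarity <- function(p, edges) {
  q <- nrow(edges)
  n_darts <- 2L * q
  dart_src <- integer(n_darts); dart_dst <- integer(n_darts)
  dart_src[seq(1L, n_darts, 2L)] <- edges[, 1L]
  dart_dst[seq(1L, n_darts, 2L)] <- edges[, 2L]
  dart_src[seq(2L, n_darts, 2L)] <- edges[, 2L]
  dart_dst[seq(2L, n_darts, 2L)] <- edges[, 1L]
  dart_undir <- rep(seq_len(q), each = 2L)
  out_darts <- rep(list(integer(0)), p)
  for (d in seq_len(n_darts)) {
    out_darts[[dart_src[d]]] <- c(out_darts[[dart_src[d]]], d)
  }

  env <- new.env(parent = emptyenv())
  env$height <- rep(NA_integer_, p)
  env$parent_edge <- rep(NA_integer_, p)       # dart id
  env$edge_oriented <- logical(q)
  env$oriented <- logical(n_darts)             # dart chosen in orientation
  env$lowpt <- rep(NA_integer_, n_darts)
  env$lowpt2 <- rep(NA_integer_, n_darts)
  env$nesting_depth <- rep(NA_integer_, n_darts)
  env$ref <- integer(n_darts)                  # 0 = none
  env$lowpt_edge <- integer(n_darts)
  env$stack_bottom <- integer(n_darts)
  env$S <- list()                              # conflict pairs c(Ll,Lh,Rl,Rh)

  # --- phase 1: DFS orientation with lowpoints -------------------------
  dfs1 <- function(v) {
    e <- env$parent_edge[v]
    for (d in out_darts[[v]]) {
      u <- dart_undir[d]
      if (env$edge_oriented[u]) next
      env$edge_oriented[u] <- TRUE
      env$oriented[d] <- TRUE
      w <- dart_dst[d]
      env$lowpt[d] <- env$height[v]
      env$lowpt2[d] <- env$height[v]
      if (is.na(env$height[w])) {              # tree edge
        env$parent_edge[w] <- d
        env$height[w] <- env$height[v] + 1L
        dfs1(w)
      } else {                                 # back edge
        env$lowpt[d] <- env$height[w]
      }
      env$nesting_depth[d] <- 2L * env$lowpt[d] +
        as.integer(env$lowpt2[d] < env$height[v])
      if (!is.na(e)) {
        if (env$lowpt[d] < env$lowpt[e]) {
          env$lowpt2[e] <- min(env$lowpt[e], env$lowpt2[d])
          env$lowpt[e] <- env$lowpt[d]
        } else if (env$lowpt[d] > env$lowpt[e]) {
          env$lowpt2[e] <- min(env$lowpt2[e], env$lowpt[d])
        } else {
          env$lowpt2[e] <- min(env$lowpt2[e], env$lowpt2[d])
        }
      }
    }
  }

  roots <- integer(0)
  for (v in seq_len(p)) {
    if (is.na(env$height[v])) {
      env$height[v] <- 0L
      roots <- c(roots, v)
      dfs1(v)
    }
  }

  # ordered adjacency by nesting depth
  ordered_out <- rep(list(integer(0)), p)
  for (v in seq_len(p)) {
    d <- out_darts[[v]][env$oriented[out_darts[[v]]]]
    ordered_out[[v]] <- d[order(env$nesting_depth[d])]
  }

  # --- conflict-pair helpers -------------------------------------------
  int_empty <- function(iv) iv[1L] == 0L && iv[2L] == 0L
  pair_empty <- function(P) all(P == 0L)
  conflicting <- function(iv, b) !int_empty(iv) && env$lowpt[iv[2L]] > env$lowpt[b]
  lowest <- function(P) {
    if (int_empty(P[1:2])) return(env$lowpt[P[3L]])
    if (int_empty(P[3:4])) return(env$lowpt[P[1L]])
    min(env$lowpt[P[1L]], env$lowpt[P[3L]])
  }
  top <- function() env$S[[length(env$S)]]
  pop <- function() {
    P <- env$S[[length(env$S)]]
    env$S[[length(env$S)]] <- NULL
    P
  }
  push <- function(P) env$S[[length(env$S) + 1L]] <- P
  swap_pair <- function(P) P[c(3L, 4L, 1L, 2L)]

  add_constraints <- function(ei, e) {
    P <- c(0L, 0L, 0L, 0L)
    # merge return edges of ei into P's right interval
    repeat {
      Q <- pop()
      if (!int_empty(Q[1:2])) Q <- swap_pair(Q)
      if (!int_empty(Q[1:2])) return(FALSE)    # not planar
      if (env$lowpt[Q[3L]] > env$lowpt[e]) {   # merge intervals
        if (int_empty(P[3:4])) P[4L] <- Q[4L] else env$ref[P[3L]] <- Q[4L]
        P[3L] <- Q[3L]
      } else {                                 # align
        env$ref[Q[3L]] <- env$lowpt_edge[e]
      }
      if (length(env$S) == env$stack_bottom[ei]) break
    }
    # merge conflicting return edges of earlier siblings into P's left side
    while (length(env$S) > 0L &&
           (conflicting(top()[1:2], ei) || conflicting(top()[3:4], ei))) {
      Q <- pop()
      if (conflicting(Q[3:4], ei)) Q <- swap_pair(Q)
      if (conflicting(Q[3:4], ei)) return(FALSE)  # not planar
      if (P[3L] != 0L) env$ref[P[3L]] <- Q[4L]
      if (Q[3L] != 0L) P[3L] <- Q[3L]
      if (int_empty(P[1:2])) P[2L] <- Q[2L] else env$ref[P[1L]] <- Q[2L]
      P[1L] <- Q[1L]
    }
    if (!pair_empty(P)) push(P)
    TRUE
  }

  trim_back_edges <- function(u) {
    # drop entire conflict pairs whose lowest return point is u
    while (length(env$S) > 0L && lowest(top()) == env$height[u]) {
      pop()
    }
    if (length(env$S) > 0L) {
      P <- pop()
      # trim left interval
      while (P[2L] != 0L && dart_dst[P[2L]] == u) P[2L] <- env$ref[P[2L]]
      if (P[2L] == 0L && P[1L] != 0L) {
        env$ref[P[1L]] <- P[3L]
        P[1L] <- 0L
      }
      # trim right interval
      while (P[4L] != 0L && dart_dst[P[4L]] == u) P[4L] <- env$ref[P[4L]]
      if (P[4L] == 0L && P[3L] != 0L) {
        env$ref[P[3L]] <- P[1L]
        P[3L] <- 0L
      }
      push(P)
    }
  }

  # --- phase 2: testing DFS --------------------------------------------
  dfs2 <- function(v) {
    e <- env$parent_edge[v]
    ord <- ordered_out[[v]]
    for (k in seq_along(ord)) {
      ei <- ord[[k]]
      env$stack_bottom[ei] <- length(env$S)
      w <- dart_dst[ei]
      if (!is.na(env$parent_edge[w]) && ei == env$parent_edge[w]) {  # tree edge
        if (!dfs2(w)) return(FALSE)
      } else {                                                       # back edge
        env$lowpt_edge[ei] <- ei
        push(c(0L, 0L, ei, ei))
      }
      if (env$lowpt[ei] < env$height[v]) {     # ei has a return edge
        if (k == 1L) {
          if (!is.na(e)) env$lowpt_edge[e] <- env$lowpt_edge[ord[[1L]]]
        } else {
          if (!add_constraints(ei, e)) return(FALSE)
        }
      }
    }
    if (!is.na(e)) {
      u <- dart_src[e]
      trim_back_edges(u)
      if (env$lowpt[e] < env$height[u]) {      # e has a return edge itself
        P <- top()
        hl <- P[2L]; hr <- P[4L]
        if (hl != 0L && (hr == 0L || env$lowpt[hl] > env$lowpt[hr])) {
          env$ref[e] <- hl
        } else {
          env$ref[e] <- hr
        }
      }
    }
    TRUE
  }

  for (v in roots) {
    if (!dfs2(v)) return(FALSE)
  }
  TRUE
}
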