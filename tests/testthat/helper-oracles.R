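# Independent brute-force oracles. These deliberately share no code with
# the implementation paths they check.

# Planarity by exhaustive search over rotation systems: a connected graph
# is planar iff some cyclic ordering of darts around each vertex yields an
# embedding with V - E + F = 2, faces counted by orbit tracing of
# phi(d) = successor of reverse(d) in the rotation at its head. Only
# viable for tiny graphs: prod (deg - 1)! rotation systems are enumerated.
oracle_planar_rotation <- function(g, cap = 5e4) {
  p <- graph_order(g)
  edges <- g$edge_idx
  q <- nrow(edges)
  if (q == 0L || p <= 2L) return(TRUE)
  stopifnot(validate_graph(g)$connected)
  dart_src <- c(edges[, 1L], edges[, 2L])
  rev_dart <- c(seq_len(q) + q, seq_len(q))
  out <- lapply(seq_len(p), function(v) which(dart_src == v))
  n_rot <- prod(vapply(out, function(d) factorial(max(length(d) - 1L, 0L)),
                       numeric(1)))
  if (n_rot > cap) stop("rotation oracle: too many rotation systems (", n_rot, ")")
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (tail in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], tail)
    }
    out
  }
  # fix the first dart at each vertex; permute the rest (cyclic orders)
  rot_choices <- lapply(out, function(d) {
    if (length(d) <= 1L) return(list(d))
    lapply(perms(d[-1L]), function(rest) c(d[1L], rest))
  })
  n_choice <- lengths(rot_choices)
  counter <- rep(1L, p)
  repeat {
    succ <- integer(2L * q)
    for (v in seq_len(p)) {
      ord <- rot_choices[[v]][[counter[v]]]
      if (length(ord)) succ[ord] <- ord[c(seq_along(ord)[-1L], 1L)]
    }
    phi <- succ[rev_dart]
    seen <- logical(2L * q)
    faces <- 0L
    for (d in seq_len(2L * q)) {
      if (seen[d]) next
      faces <- faces + 1L
      cur <- d
      while (!seen[cur]) {
        seen[cur] <- TRUE
        cur <- phi[cur]
      }
    }
    if (p - q + faces == 2L) return(TRUE)
    # advance mixed-radix counter
    v <- 1L
    while (v <= p) {
      counter[v] <- counter[v] + 1L
      if (counter[v] <= n_choice[v]) break
      counter[v] <- 1L
      v <- v + 1L
    }
    if (v > p) return(FALSE)
  }
}

# walks of length m from i to j by explicit recursive enumeration
oracle_walk_count <- function(g, i, j, m) {
  adj <- lapply(seq_len(graph_order(g)), function(v) {
    match(g$neighbors[[v]], g$vertices)
  })
  count <- function(at, left) {
    if (left == 0L) return(as.integer(at == j))
    sum(vapply(adj[[at]], count, integer(1), left = left - 1L))
  }
  count(i, m)
}

# 3-edge (4-vertex) simple paths by brute force over vertex permutations
oracle_path4_count <- function(g) {
  p <- graph_order(g)
  A <- graph_matrices(g)$adjacency
  n <- 0L
  for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p)) for (l in seq_len(p)) {
    if (length(unique(c(i, j, k, l))) == 4L &&
        A[i, j] == 1L && A[j, k] == 1L && A[k, l] == 1L) {
      n <- n + 1L
    }
  }
  n %/% 2L  # each unordered path counted in both directions
}

iso_check <- function(g1, g2) {
  igraph::isomorphic(as_igraph(g1), as_igraph(g2))
}
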