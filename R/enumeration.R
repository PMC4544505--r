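#' Count n-body interactions via the line-graph route
#'
#' The number of n-body bonded interactions equals the vertex count of
#' L^(n-1)(G): atoms for n = 1, bonds for n = 2, bends for n = 3, 4-body
#' terms (proper torsions plus the tripled rotational variants of
#' impropers and 3-cycles) for n = 4, and so on for any n. For n >= 2 the
#' count is also half the trace of A^2 of L^(n-2)(G) (its edge count); both
#' routes are computed and must agree.
#'
#' @param g a connected `molecular_graph`
#' @param n interaction order (>= 1)
#' @param vertex_budget passed to [iterate_line_graphs()]
#' @return integer count N_n(G)
#' @examples
#' toy <- read_graph(text = c("1 2", "2 3", "2 4", "3 4"))
#' count_via_line_graphs(toy, 3)  # 5 bends
#' count_via_line_graphs(toy, 4)  # 8 four-body terms
#' @export
count_via_line_graphs <- function(g, n, vertex_budget = 1e5) {
  ensure_valid(g)
  stopifnot(n >= 1L)
  if (n == 1L) return(graph_order(g))
  it <- iterate_line_graphs(g, n_max = n - 1L, vertex_budget = vertex_budget)
  if (length(it$levels) < n) {
    if (it$status == "budget_exceeded") {
      stop("vertex budget exhausted before level ", n - 1L)
    }
    # path exhausted below level n-1: no interactions of this order
    return(0L)
  }
  n_vertices <- graph_order(it$levels[[n]]$graph)
  prev <- it$levels[[n - 1L]]$graph
  # half Tr(A^2) = sum of degrees / 2 = edge count of L^(n-2)(G)
  half_tr_a2 <- sum(degrees(prev)) %/% 2L
  if (half_tr_a2 != n_vertices) {
    stop("internal error: |V(L^", n - 1L, ")| = ", n_vertices,
         " but (1/2)Tr(A^2(L^", n - 2L, ")) = ", half_tr_a2)
  }
  n_vertices
}

count_summary <- function(n1, n2, n3, n4, n_prop, n_impr, n_3cyc,
                          checksum_pass, method) {
  counts <- c(n1 = n1, n2 = n2, n3 = n3, n4 = n4,
              n_prop = n_prop, n_impr = n_impr, n_3cyc = n_3cyc)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("internal error: interaction counts must be non-negative integers, got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), n3 = as.integer(n3),
                 n4 = as.integer(n4), n_prop = as.integer(n_prop),
                 n_impr = as.integer(n_impr), n_3cyc = as.integer(n_3cyc),
                 checksum_pass = checksum_pass, method = method),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("interaction counts (%s):\n", x$method))
  cat(sprintf("  N1 (atoms)            %6d\n", x$n1))
  cat(sprintf("  N2 (bonds)            %6d\n", x$n2))
  cat(sprintf("  N3 (bends)            %6d\n", x$n3))
  cat(sprintf("  N_prop (proper)       %6d\n", x$n_prop))
  cat(sprintf("  N_impr (improper)     %6d\n", x$n_impr))
  cat(sprintf("  N_3cyc (triangles)    %6d\n", x$n_3cyc))
  cat(sprintf("  N4 (all 4-body terms) %6d  = N_prop + 3 N_impr + 3 N_3cyc\n", x$n4))
  cat("  checksums:", paste(names(x$checksum_pass),
                            ifelse(x$checksum_pass, "ok", "FAIL"),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form interaction counts from the molecular graph alone
#'
#' Evaluates the degree-based closed forms: N2 = (1/2)Tr(D);
#' N3 = (1/2)u'D^2u - N2; N_impr = (1/6)u'D^3u - N3 - (1/3)N2;
#' N_prop + 3 N_3cyc = (1/2)u'DADu - 2 N3 - N2; N_3cyc = (1/6)Tr(A^3); and
#' N4 = N_prop + 3 N_impr + 3 N_3cyc. The independent checksum
#' N4 = (1/2)u'DQDu - 5 N3 - 2 N2 (Q = A + D the signless Laplacian) is
#' verified, along with the handshake N2 = q and the binomial identities
#' N3 = sum choose(deg, 2), N_impr = sum choose(deg, 3). All arithmetic is
#' exact: fractional coefficients are applied as exact rational steps and
#' any non-integer intermediate raises an error.
#'
#' @param g a connected `molecular_graph`
#' @return a `count_summary`
#' @examples
#' tauro <- read_graph(system.file("extdata", "taurocholate.edges",
#'                                 package = "intramol"))
#' closed_form_counts(tauro)  # 12 bonds, 16 bends, 22 proper, 4 improper
#' @export
closed_form_counts <- function(g) {
  ensure_valid(g)
  m <- graph_matrices(g)
  d <- as.numeric(diag(m$degree))
  A <- m$adjacency
  exact_div <- function(num, den, what) {
    if (num %% den != 0) {
      stop("internal error: ", what, " is not an integer (", num, "/", den,
           "); formula misuse")
    }
    num %/% den
  }
  n1 <- graph_order(g)
  n2 <- exact_div(sum(d), 2, "N2 = (1/2)u'Du")
  n3 <- exact_div(sum(d^2) - 2 * n2, 2, "N3 = (1/2)u'D^2u - N2")
  # (1/6)u'D^3u - N3 - (1/3)N2, over the common denominator 6
  n_impr <- exact_div(sum(d^3) - 6 * n3 - 2 * n2, 6, "N_impr")
  uDADu <- as.numeric(t(d) %*% A %*% d)
  prop3cyc <- exact_div(uDADu - 4 * n3 - 2 * n2, 2, "N_prop + 3 N_3cyc")
  n_3cyc <- exact_div(sum(diag(A %*% A %*% A)), 6, "N_3cyc = (1/6)Tr(A^3)")
  n_prop <- prop3cyc - 3 * n_3cyc
  n4 <- n_prop + 3 * n_impr + 3 * n_3cyc
  # independent checksum via the signless Laplacian
  Q <- m$signless_laplacian
  uDQDu <- as.numeric(t(d) %*% Q %*% d)
  n4_checksum <- exact_div(uDQDu - 10 * n3 - 4 * n2, 2,
                           "N4 = (1/2)u'DQDu - 5 N3 - 2 N2")
  checks <- c(
    n1_is_p = n1 == graph_order(g),
    handshake_n2_is_q = n2 == graph_size(g),
    n3_binomial = n3 == sum(choose(d, 2)),
    n_impr_binomial = n_impr == sum(choose(d, 3)),
    n4_signless_laplacian = n4 == n4_checksum
  )
  if (!all(checks)) {
    stop("closed-form count checksum failure: ",
         paste(names(checks)[!checks], collapse = ", "),
         "; this signals a bug, not bad input")
  }
  count_summary(n1, n2, n3, n4, n_prop, n_impr, n_3cyc, checks, "closed_form")
}

#' Brute-force interaction counts by direct subgraph enumeration
#'
#' Independent oracle for the closed forms, counting each pattern by
#' explicit enumeration: bends as unordered pairs of edges at a common
#' vertex, proper torsions as unordered simple 4-vertex paths, impropers
#' as 3-subsets of edges at a common vertex, triangles as 3-cliques. N4 is
#' assembled from the ledger identity N4 = N_prop + 3 N_impr + 3 N_3cyc.
#'
#' @param g a connected `molecular_graph` with p <= 64 (oracle scale)
#' @return a `count_summary`
#' @export
brute_force_counts <- function(g) {
  ensure_valid(g)
  p <- graph_order(g)
  if (p > 64L) stop("brute-force oracle limited to p <= 64 (got p = ", p, ")")
  adj <- neighbor_index_list(g)
  inc <- incident_edge_list(g)
  n1 <- p
  n2 <- graph_size(g)
  # bends: unordered pairs of incident edges at each vertex
  n3 <- 0L
  for (v in seq_len(p)) {
    k <- length(inc[[v]])
    if (k >= 2L) n3 <- n3 + ncol(utils::combn(k, 2L))
  }
  # impropers: 3-subsets of incident edges at each vertex
  n_impr <- 0L
  for (v in seq_len(p)) {
    k <- length(inc[[v]])
    if (k >= 3L) n_impr <- n_impr + ncol(utils::combn(k, 3L))
  }
  # proper torsions: unordered simple paths i-j-k-l, identified by their
  # middle bond {j,k}; i attaches to j and l to k, so each path is
  # enumerated exactly once
  n_prop <- 0L
  for (r in seq_len(n2)) {
    jj <- g$edge_idx[r, 1L]; kk <- g$edge_idx[r, 2L]
    for (i in setdiff(adj[[jj]], kk)) {
      for (l in setdiff(adj[[kk]], jj)) {
        if (i != l) n_prop <- n_prop + 1L
      }
    }
  }
  # triangles: 3-cliques
  n_3cyc <- 0L
  A <- graph_matrices(g)$adjacency
  if (p >= 3L) {
    trip <- utils::combn(p, 3L)
    for (c_ in seq_len(ncol(trip))) {
      i <- trip[1L, c_]; j <- trip[2L, c_]; k <- trip[3L, c_]
      if (A[i, j] == 1L && A[i, k] == 1L && A[j, k] == 1L) n_3cyc <- n_3cyc + 1L
    }
  }
  n4 <- n_prop + 3L * n_impr + 3L * n_3cyc
  count_summary(n1, n2, n3, n4, n_prop, n_impr, n_3cyc,
                c(ledger_identity = TRUE), "brute_force")
}
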