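#' Line graph of a molecular graph
#'
#' The line graph L(G) has one vertex per edge of G, two vertices being
#' adjacent exactly when the corresponding edges of G share an endpoint.
#' Iterating L encodes the hierarchy of bonded interactions: vertices of
#' L(G) are the bonds seen as 2-body terms, edges of L(G) are the bends,
#' edges of L^2(G) the 4-body terms, and so on. The construction here is
#' combinatorial (pairs of incident edges at each vertex); the equivalent
#' algebraic route A(L(G)) = Z'Z - 2I via the incidence matrix is available
#' as [line_graph_adjacency_incidence()] and the two are compared in the
#' package tests.
#'
#' Vertex labels of L(G) are the canonical edge identifiers "(a,b)" (a
#' before b in vertex order) of G, so labels nest across levels.
#'
#' @param x a `molecular_graph`, or a `line_graph_level` (in which case the
#'   level counter advances from its level)
#' @return a `line_graph_level`: list with `level` (n, counting the input
#'   graph as level n-1), `graph` (the `molecular_graph` for L of the
#'   input), and `parent_edge_map` (q x 2 character matrix mapping each new
#'   vertex, in canonical order, to the endpoint labels of its parent edge)
#' @examples
#' toy <- read_graph(text = c("1 2", "2 3", "2 4", "3 4"))
#' lg <- line_graph(toy)
#' graph_order(lg$graph)  # = graph_size(toy)
#' @export
line_graph <- function(x) {
  if (inherits(x, "line_graph_level")) {
    parent <- x$graph
    lvl <- x$level + 1L
  } else {
    parent <- x
    lvl <- 1L
  }
  stopifnot(inherits(parent, "molecular_graph"))
  q <- graph_size(parent)
  if (q == 0L) stop("line graph is undefined for a graph with no edges")
  labs <- edge_labels(parent)
  inc <- incident_edge_list(parent)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (v in seq_len(graph_order(parent))) {
    e <- inc[[v]]
    d <- length(e)
    if (d >= 2L) {
      cmb <- utils::combn(e, 2L)
      pairs_a <- c(pairs_a, cmb[1L, ])
      pairs_b <- c(pairs_b, cmb[2L, ])
    }
  }
  edges <- cbind(labs[pairs_a], labs[pairs_b])
  gL <- molecular_graph(edges, vertices = labs)
  # the natural order of nested labels must reproduce the parent edge order;
  # this keeps adjacency comparable entrywise with Z'Z - 2I
  if (!identical(gL$vertices, labs)) {
    stop("internal error: canonical vertex order of L(G) does not match the parent edge order")
  }
  pem <- parent$edges
  rownames(pem) <- labs
  structure(list(level = lvl, graph = gL, parent_edge_map = pem),
            class = "line_graph_level")
}

#' @export
print.line_graph_level <- function(x, ...) {
  cat(sprintf("line_graph_level n = %d: ", x$level))
  print(x$graph)
  invisible(x)
}

#' Line-graph adjacency via the incidence matrix
#'
#' Computes A(L(G)) = Z'(G) Z(G) - 2 I_q directly from the incidence matrix
#' of G. This is the algebraic counterpart of the combinatorial
#' construction in [line_graph()]; both routes must agree entrywise.
#'
#' @param g a `molecular_graph` with at least one edge
#' @return q x q integer matrix, rows/columns in canonical edge order of g
#' @export
line_graph_adjacency_incidence <- function(g) {
  stopifnot(inherits(g, "molecular_graph"), graph_size(g) >= 1L)
  Z <- graph_matrices(g)$incidence
  M <- t(Z) %*% Z - 2L * diag(ncol(Z))
  storage.mode(M) <- "integer"
  dimnames(M) <- list(edge_labels(g), edge_labels(g))
  M
}

#' Iterate the line-graph transformation
#'
#' Returns levels L^0(G) = G up to L^n_max(G). Iteration stops early with
#' an explicit status when a level would exceed `vertex_budget` vertices
#' (prolific graphs grow without bound) or when a path graph exhausts to
#' the null graph.
#'
#' @param g a connected `molecular_graph`
#' @param n_max highest level to compute (>= 0)
#' @param vertex_budget cap on the vertex count of any computed level
#' @return list of class `line_graph_iteration` with `levels` (list of
#'   `line_graph_level`; level 0 wraps `g` with a `NULL` parent map) and
#'   `status` (`"complete"`, `"budget_exceeded"` or `"exhausted"`)
#' @export
iterate_line_graphs <- function(g, n_max, vertex_budget = 1e5) {
  ensure_valid(g)
  stopifnot(n_max >= 0L, vertex_budget >= graph_order(g))
  levels <- list(structure(list(level = 0L, graph = g, parent_edge_map = NULL),
                           class = "line_graph_level"))
  status <- "complete"
  n <- 0L
  while (n < n_max) {
    cur <- levels[[length(levels)]]
    q <- graph_size(cur$graph)
    if (q == 0L) {
      # one more application yields the null graph; stop there
      levels[[length(levels) + 1L]] <- structure(
        list(level = n + 1L, graph = null_graph(),
             parent_edge_map = matrix(character(0), ncol = 2L)),
        class = "line_graph_level")
      status <- "exhausted"
      break
    }
    if (q > vertex_budget) {
      status <- "budget_exceeded"
      break
    }
    levels[[length(levels) + 1L]] <- line_graph(cur)
    n <- n + 1L
  }
  structure(list(levels = levels, status = status, n_max = n_max,
                 vertex_budget = vertex_budget),
            class = "line_graph_iteration")
}

#' Asymptotic class of the iterated line-graph sequence
#'
#' Under iteration of L, a connected graph has exactly four possible fates:
#' cycles reproduce themselves (`cycle`), the claw K_{1,3} collapses to the
#' triangle (`claw`), paths shrink to the null graph (`path`, with order r
#' reported), and every other graph is `prolific` -- its iterated line
#' graphs grow without bound.
#'
#' @param g a connected `molecular_graph`
#' @return list of class `limit_class` with `class` and, for paths, `r`
#' @export
classify_limit <- function(g) {
  ensure_valid(g)
  d <- degrees(g)
  p <- graph_order(g)
  out <- if (p <= 2L || (sum(d == 1L) == 2L && all(d %in% c(1L, 2L)))) {
    list(class = "path", r = p)
  } else if (all(d == 2L)) {
    list(class = "cycle", r = p)
  } else if (p == 4L && identical(sort(unname(d)), c(1L, 1L, 1L, 3L))) {
    list(class = "claw", r = NULL)
  } else {
    list(class = "prolific", r = NULL)
  }
  structure(out, class = "limit_class")
}

#' @export
print.limit_class <- function(x, ...) {
  cat("limit class:", x$class,
      if (!is.null(x$r)) sprintf("(order r = %d)", x$r) else "", "\n")
  invisible(x)
}

#' Line index of a molecular graph
#'
#' The line index xi(G) is the smallest non-negative integer m such that
#' L^m(G) is nonplanar. Non-prolific graphs (paths, cycles, the claw) stay
#' planar forever and get xi = Inf without iteration. For prolific graphs
#' 0 <= xi <= 4, so failing to find a nonplanar level within `max_levels`
#' iterations signals an implementation bug and raises an error.
#'
#' @param g a connected `molecular_graph`
#' @param max_levels iteration cap for prolific graphs (default 6)
#' @return list of class `line_index_result` with `xi` (integer or `Inf`)
#'   and `planar` (named logical vector of per-level verdicts, empty when
#'   no iteration was needed)
#' @examples
#' toy <- read_graph(text = c("1 2", "2 3", "2 4", "3 4"))
#' line_index(toy)$xi  # 3
#' @export
line_index <- function(g, max_levels = 6L) {
  ensure_valid(g)
  lc <- classify_limit(g)
  if (lc$class != "prolific") {
    return(structure(list(xi = Inf, planar = logical(0), limit_class = lc$class),
                     class = "line_index_result"))
  }
  planar <- logical(0)
  cur <- structure(list(level = 0L, graph = g, parent_edge_map = NULL),
                   class = "line_graph_level")
  for (m in 0:max_levels) {
    verdict <- is_planar(cur$graph)
    planar <- c(planar, setNames(verdict, paste0("L^", m)))
    if (!verdict) {
      return(structure(list(xi = m, planar = planar, limit_class = "prolific"),
                       class = "line_index_result"))
    }
    if (m < max_levels) cur <- line_graph(cur)
  }
  stop("no nonplanar level found within ", max_levels,
       " iterations on a prolific graph; this contradicts the bound xi <= 4 ",
       "and indicates a bug")
}

#' @export
print.line_index_result <- function(x, ...) {
  if (is.infinite(x$xi)) {
    cat(sprintf("line index xi = infinite (%s graph, planar at every level)\n",
                x$limit_class))
  } else {
    cat(sprintf("line index xi = %d (first nonplanar level)\n", x$xi))
  }
  invisible(x)
}
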