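#' @importFrom stats setNames
NULL

# Natural sort key: digit runs compare numerically, everything else in C
# locale. Zero-padding digit runs to a fixed width reduces natural order to
# plain C-locale string order, which sort(method = "radix") provides.
natural_key <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    digits <- grepl("^[0-9]", parts)
    parts[digits] <- sprintf("%020d", as.numeric(parts[digits]))
    paste(parts, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

natural_order <- function(x) order(natural_key(x), method = "radix")

#' Construct a molecular graph
#'
#' A molecular graph is a simple, loopless, undirected graph whose vertices
#' are atoms (or coarse-grained beads) and whose edges are covalent bonds.
#' Vertex labels are opaque strings preserved from input; the canonical
#' vertex order is a natural sort of the labels (numeric labels sort by
#' value), and edges are stored in canonical lexicographic order by their
#' (min, max) endpoint positions.
#'
#' @param edges a two-column matrix or data frame of endpoint labels, one
#'   row per bond, or a character vector of length 2 for a single bond.
#' @param vertices optional character vector of vertex labels; defaults to
#'   the labels appearing in `edges`. Extra labels introduce isolated
#'   vertices, which [validate_graph()] will flag.
#' @return an object of class `molecular_graph` with elements `vertices`
#'   (character), `edges` (q x 2 character matrix, canonical order),
#'   `edge_idx` (q x 2 integer matrix of endpoint positions) and
#'   `neighbors` (named list of adjacent-label character vectors).
#' @examples
#' g <- molecular_graph(rbind(c("1", "2"), c("2", "3"), c("2", "4"), c("3", "4")))
#' graph_order(g)  # 4 atoms
#' graph_size(g)   # 4 bonds
#' @export
molecular_graph <- function(edges, vertices = NULL) {
  if (is.null(edges) || (is.character(edges) && length(edges) == 0L)) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.character(edges) && is.null(dim(edges))) {
    if (length(edges) != 2L) stop("a single edge needs exactly two labels")
    edges <- matrix(edges, ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  storage.mode(edges) <- "character"
  labels <- unique(c(as.vector(t(edges)), as.character(vertices)))
  if (length(labels) == 0L) stop("a molecular graph needs at least one vertex")
  if (anyNA(labels) || any(!nzchar(labels))) stop("vertex labels must be non-empty")
  verts <- labels[natural_order(labels)]
  i <- match(edges[, 1L], verts)
  j <- match(edges[, 2L], verts)
  loops <- which(i == j)
  if (length(loops)) {
    stop(sprintf("self-loop on vertex '%s' is not a valid bond", edges[loops[1L], 1L]))
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * length(verts) + hi
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate bond {%s, %s}: multi-edges are not allowed",
                 verts[lo[dup[1L]]], verts[hi[dup[1L]]]))
  }
  ord <- order(lo, hi)
  edge_idx <- cbind(lo, hi)[ord, , drop = FALSE]
  edge_lab <- cbind(verts[edge_idx[, 1L]], verts[edge_idx[, 2L]])
  dimnames(edge_idx) <- NULL
  nbr <- rep(list(character(0)), length(verts))
  names(nbr) <- verts
  for (r in seq_len(nrow(edge_idx))) {
    a <- edge_idx[r, 1L]; b <- edge_idx[r, 2L]
    nbr[[a]] <- c(nbr[[a]], verts[b])
    nbr[[b]] <- c(nbr[[b]], verts[a])
  }
  structure(
    list(vertices = verts, edges = edge_lab, edge_idx = edge_idx, neighbors = nbr),
    class = "molecular_graph"
  )
}

# zero-vertex graph: the terminal object of path exhaustion under iteration.
# Not constructible through molecular_graph(); internal use only.
null_graph <- function() {
  structure(
    list(vertices = character(0),
         edges = matrix(character(0), ncol = 2L),
         edge_idx = matrix(integer(0), ncol = 2L),
         neighbors = list()),
    class = "molecular_graph"
  )
}

#' Number of vertices (atoms) of a molecular graph
#' @param g a `molecular_graph`
#' @return integer vertex count p
#' @export
graph_order <- function(g) length(g$vertices)

#' Number of edges (bonds) of a molecular graph
#' @param g a `molecular_graph`
#' @return integer edge count q
#' @export
graph_size <- function(g) nrow(g$edges)

#' Vertex degrees in canonical vertex order
#' @param g a `molecular_graph`
#' @return named integer vector of degrees
#' @export
degrees <- function(g) {
  d <- integer(graph_order(g))
  names(d) <- g$vertices
  if (graph_size(g) > 0L) {
    tab <- tabulate(as.vector(g$edge_idx), nbins = graph_order(g))
    d[] <- tab
  }
  d
}

# canonical "(a,b)" label for edge row r; nested labels accumulate across
# line-graph levels
edge_labels <- function(g) {
  if (graph_size(g) == 0L) return(character(0))
  paste0("(", g$edges[, 1L], ",", g$edges[, 2L], ")")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("molecular_graph: p = %d vertices, q = %d edges\n",
              graph_order(x), graph_size(x)))
  if (graph_size(x) > 0L) {
    show <- utils::head(seq_len(graph_size(x)), 10L)
    cat(paste0("  {", x$edges[show, 1L], ", ", x$edges[show, 2L], "}",
               collapse = "\n"), "\n")
    if (graph_size(x) > 10L) cat(sprintf("  ... (%d more)\n", graph_size(x) - 10L))
  }
  invisible(x)
}

#' Convert a molecular graph to an igraph object
#'
#' Useful for isomorphism testing and plotting; vertex order and labels are
#' preserved.
#'
#' @param g a `molecular_graph`
#' @return an undirected `igraph` graph with a `name` vertex attribute
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  igraph::graph_from_data_frame(
    d = data.frame(from = g$edges[, 1L], to = g$edges[, 2L],
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$vertices, stringsAsFactors = FALSE)
  )
}

# traversal-based connectivity (route b of the validation contract)
is_connected_traversal <- function(g) {
  p <- graph_order(g)
  if (p <= 1L) return(TRUE)
  adj <- neighbor_index_list(g)
  seen <- logical(p)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nxt <- adj[[v]][!seen[adj[[v]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

neighbor_index_list <- function(g) {
  p <- graph_order(g)
  adj <- rep(list(integer(0)), p)
  for (r in seq_len(graph_size(g))) {
    a <- g$edge_idx[r, 1L]; b <- g$edge_idx[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# incident edge rows per vertex, in canonical edge order
incident_edge_list <- function(g) {
  p <- graph_order(g)
  inc <- rep(list(integer(0)), p)
  for (r in seq_len(graph_size(g))) {
    inc[[g$edge_idx[r, 1L]]] <- c(inc[[g$edge_idx[r, 1L]]], r)
    inc[[g$edge_idx[r, 2L]]] <- c(inc[[g$edge_idx[r, 2L]]], r)
  }
  inc
}

# hard gate used by enumeration / hierarchy / line-graph entry points
ensure_valid <- function(g, require_connected = TRUE) {
  stopifnot(inherits(g, "molecular_graph"))
  rep_ <- validate_graph(g)
  if (!rep_$covering) {
    stop("graph has isolated vertices: every atom must take part in a bond")
  }
  if (require_connected && !rep_$connected) {
    stop("graph is disconnected: one molecule per graph is required ",
         "(rank(K) = ", rep_$kirchhoff_rank, ", expected p - 1 = ",
         graph_order(g) - 1L, ")")
  }
  invisible(g)
}
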