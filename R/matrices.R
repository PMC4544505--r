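#' Standard matrix representations of a molecular graph
#'
#' Computes the five matrices that encode connectivity: the binary vertex
#' adjacency matrix A, the vertex-edge incidence matrix Z, the diagonal
#' degree matrix D, the Kirchhoff (Laplacian) matrix K = D - A, and the
#' signless Laplacian Q = A + D = Z Z'. Rows and columns follow the
#' canonical vertex and edge orders of `g`.
#'
#' @param g a `molecular_graph`
#' @return a list of class `graph_matrices` with integer matrices
#'   `adjacency`, `incidence`, `degree`, `kirchhoff`, `signless_laplacian`
#' @examples
#' m <- graph_matrices(read_graph(text = c("1 2", "2 3", "2 4", "3 4")))
#' m$adjacency
#' all(m$signless_laplacian == m$incidence %*% t(m$incidence))
#' @export
graph_matrices <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  p <- graph_order(g); q <- graph_size(g)
  A <- matrix(0L, p, p, dimnames = list(g$vertices, g$vertices))
  Z <- matrix(0L, p, q, dimnames = list(g$vertices, edge_labels(g)))
  for (r in seq_len(q)) {
    i <- g$edge_idx[r, 1L]; j <- g$edge_idx[r, 2L]
    A[i, j] <- A[j, i] <- 1L
    Z[i, r] <- Z[j, r] <- 1L
  }
  D <- diag(rowSums(A), p)
  storage.mode(D) <- "integer"
  dimnames(D) <- dimnames(A)
  structure(
    list(adjacency = A, incidence = Z, degree = D,
         kirchhoff = D - A, signless_laplacian = A + D),
    class = "graph_matrices"
  )
}

# Exact rank by Bareiss fraction-free elimination; intermediates are exact
# minors so a |value| > 2^53 guard triggers the SVD fallback. Numeric route
# uses singular values > 1e-9 * max.
matrix_rank_exact <- function(M) {
  M <- unname(M * 1.0)
  n <- nrow(M); m <- ncol(M)
  if (n == 0L || m == 0L) return(0L)
  if (max(n, m) > 64L) return(matrix_rank_numeric(M))
  prev <- 1.0
  rank <- 0L
  row <- 1L
  for (col in seq_len(m)) {
    piv <- which(abs(M[row:n, col]) > 0)
    if (!length(piv)) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(piv, row), ] <- M[c(row, piv), ]
    for (r in seq_len(n)[-seq_len(row)]) {
      M[r, ] <- (M[r, ] * M[row, col] - M[row, ] * M[r, col]) / prev
    }
    if (any(abs(M) > 2^53)) return(matrix_rank_numeric(M))
    prev <- M[row, col]
    rank <- rank + 1L
    row <- row + 1L
    if (row > n) break
  }
  rank
}

matrix_rank_numeric <- function(M) {
  sv <- svd(M, nu = 0L, nv = 0L)$d
  if (!length(sv) || max(sv) == 0) return(0L)
  sum(sv > 1e-9 * max(sv))
}

#' Validate a molecular graph
#'
#' Checks the structural invariants (simple, loopless, every vertex covered
#' by a bond) and determines connectivity two independent ways: the rank of
#' the Kirchhoff matrix K = D - A must equal p - 1 (the zero eigenvalue of K
#' has multiplicity equal to the number of components), and a breadth-first
#' traversal must reach every vertex. The two verdicts are required to
#' agree.
#'
#' @param g a `molecular_graph`
#' @return a list of class `validation_report` with logical flags `simple`,
#'   `loopless`, `covering`, `connected_rank`, `connected_traversal`,
#'   `connected`, and integers `p`, `q`, `kirchhoff_rank`
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  p <- graph_order(g)
  # loops and multi-edges are rejected at construction; re-derive anyway
  loopless <- p == 0L || all(g$edge_idx[, 1L] != g$edge_idx[, 2L])
  key <- (g$edge_idx[, 1L] - 1) * p + g$edge_idx[, 2L]
  simple <- !anyDuplicated(key)
  covering <- p <= 1L || all(degrees(g) >= 1L)
  rk <- if (p == 0L) 0L else matrix_rank_exact(graph_matrices(g)$kirchhoff)
  connected_rank <- rk == max(p - 1L, 0L)
  connected_traversal <- is_connected_traversal(g)
  if (connected_rank != connected_traversal) {
    stop("internal error: Kirchhoff-rank and traversal connectivity disagree")
  }
  structure(
    list(simple = simple, loopless = loopless, covering = covering,
         p = p, q = graph_size(g), kirchhoff_rank = rk,
         connected_rank = connected_rank,
         connected_traversal = connected_traversal,
         connected = connected_rank && connected_traversal),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: p = %d, q = %d\n", x$p, x$q))
  cat(sprintf("  simple: %s, loopless: %s, covering: %s\n",
              x$simple, x$loopless, x$covering))
  cat(sprintf("  rank(K) = %d (connected: %s; traversal agrees: %s)\n",
              x$kirchhoff_rank, x$connected_rank,
              x$connected_traversal == x$connected_rank))
  invisible(x)
}
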