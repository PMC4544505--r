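#' Generate fixture graphs
#'
#' Standard families used throughout the tests and examples: the path P_r,
#' the cycle C_r, the claw K_{1,3}, the complete graph K_r, and random
#' connected graphs built as a uniform random spanning tree (drawn by a
#' uniform Pruefer sequence) plus `k` distinct non-tree edges sampled
#' uniformly, so q = (p - 1) + k by construction. Identical seed and
#' parameters give identical graphs; the seed controls all randomness and
#' the caller's RNG state is left untouched.
#'
#' @param family one of `"path"`, `"cycle"`, `"claw"`, `"complete"`,
#'   `"random_connected"`
#' @param r order for path/cycle/complete (>= 1; cycle needs r >= 3)
#' @param p order for random_connected (>= 2)
#' @param k number of extra non-tree edges for random_connected
#' @param seed integer seed for random_connected
#' @return a `molecular_graph` with vertices named `1..p`
#' @examples
#' make_fixture("claw")                     # K_{1,3}
#' make_fixture("random_connected", p = 8, k = 3, seed = 42)  # q = 10
#' @export
make_fixture <- function(family = c("path", "cycle", "claw", "complete",
                                    "random_connected"),
                         r = NULL, p = NULL, k = 0L, seed = NULL) {
  family <- match.arg(family)
  if (family == "path") {
    stopifnot(r >= 1L)
    if (r == 1L) {
      return(structure(list(vertices = "1",
                            edges = matrix(character(0), ncol = 2L),
                            edge_idx = matrix(integer(0), ncol = 2L),
                            neighbors = list(`1` = character(0))),
                       class = "molecular_graph"))
    }
    v <- as.character(seq_len(r))
    return(molecular_graph(cbind(v[-r], v[-1L])))
  }
  if (family == "cycle") {
    stopifnot(r >= 3L)
    v <- as.character(seq_len(r))
    return(molecular_graph(cbind(v, c(v[-1L], v[1L]))))
  }
  if (family == "claw") {
    return(molecular_graph(cbind("1", c("2", "3", "4"))))
  }
  if (family == "complete") {
    stopifnot(r >= 2L)
    cmb <- utils::combn(r, 2L)
    return(molecular_graph(cbind(as.character(cmb[1L, ]),
                                 as.character(cmb[2L, ]))))
  }
  # random_connected
  stopifnot(!is.null(p), p >= 2L, k >= 0L)
  max_extra <- choose(p, 2) - (p - 1L)
  if (k > max_extra) {
    stop("unsatisfiable fixture: at most ", max_extra,
         " extra edges exist for p = ", p)
  }
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, globalenv())
      }
    })
    set.seed(seed)
  }
  tree <- if (p == 2L) {
    cbind(1L, 2L)
  } else {
    prufer_decode(sample.int(p, p - 2L, replace = TRUE))
  }
  key_of <- function(i, j) (pmin(i, j) - 1) * p + pmax(i, j)
  used <- key_of(tree[, 1L], tree[, 2L])
  extra <- matrix(integer(0), ncol = 2L)
  while (nrow(extra) < k) {
    i <- sample.int(p, 1L); j <- sample.int(p, 1L)
    if (i == j) next
    ky <- key_of(i, j)
    if (ky %in% used) next
    used <- c(used, ky)
    extra <- rbind(extra, c(i, j))
  }
  edges <- rbind(tree, extra)
  molecular_graph(cbind(as.character(edges[, 1L]), as.character(edges[, 2L])))
}

# decode a Pruefer sequence over 1..p into the p-1 edges of the labelled
# tree it encodes; a uniform sequence gives a uniform spanning tree of K_p
prufer_decode <- function(code) {
  p <- length(code) + 2L
  deg <- rep(1L, p)
  for (x in code) deg[x] <- deg[x] + 1L
  edges <- matrix(0L, nrow = p - 1L, ncol = 2L)
  for (i in seq_along(code)) {
    leaf <- which(deg == 1L)[1L]
    edges[i, ] <- c(leaf, code[i])
    deg[leaf] <- 0L
    deg[code[i]] <- deg[code[i]] - 1L
  }
  edges[p - 1L, ] <- which(deg == 1L)
  edges
}
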