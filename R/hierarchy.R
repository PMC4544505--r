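#' Build the interaction hierarchy DAG
#'
#' The hierarchy H_nu(G) is a nu-partite directed acyclic graph whose
#' level-n vertices are the n-body interactions, V_n(G) = V(L^(n-1)(G)),
#' and whose arcs record the two-parent composition of each interaction:
#' vertex j at level n+1 arose from an edge of L^(n-1)(G), and receives an
#' arc from each of that edge's two endpoints at level n. Sources are the
#' atoms, sinks the level-nu interactions, every non-source vertex has
#' indegree exactly 2, and the outdegree of a level-n vertex (n < nu)
#' equals its degree in L^(n-1)(G). The full adjacency matrix is block
#' tridiagonal with off-diagonal blocks the incidence matrices
#' Z(L^(n-1)(G)).
#'
#' @param g a connected `molecular_graph`
#' @param nu maximum interaction order (default 4; bonds, bends, dihedrals)
#' @param vertex_budget passed to [iterate_line_graphs()]
#' @return a list of class `interaction_hierarchy` with `nu`, `levels`
#'   (list of `line_graph_level`, level n holding L^(n-1)(G)), and `arcs`
#'   (data frame: `from_level`, `from`, `to_level`, `to`)
#' @examples
#' toy <- read_graph(text = c("1 2", "2 3", "2 4", "3 4"))
#' h <- build_hierarchy(toy, nu = 4)
#' vapply(h$levels, function(l) graph_order(l$graph), integer(1))  # 4 4 5 8
#' @export
build_hierarchy <- function(g, nu = 4L, vertex_budget = 1e5) {
  ensure_valid(g)
  stopifnot(nu >= 1L)
  it <- iterate_line_graphs(g, n_max = nu - 1L, vertex_budget = vertex_budget)
  if (it$status == "budget_exceeded") {
    stop("vertex budget exhausted while building H_", nu, "(G)")
  }
  levels <- it$levels[seq_len(min(nu, length(it$levels)))]
  arcs <- list()
  for (n in seq_along(levels)[-1L]) {
    pem <- levels[[n]]$parent_edge_map
    if (is.null(pem) || nrow(pem) == 0L) next
    child <- levels[[n]]$graph$vertices
    arcs[[length(arcs) + 1L]] <- data.frame(
      from_level = n - 1L,
      from = c(pem[, 1L], pem[, 2L]),
      to_level = n,
      to = c(child, child),
      stringsAsFactors = FALSE
    )
  }
  arcs <- if (length(arcs)) do.call(rbind, arcs) else
    data.frame(from_level = integer(0), from = character(0),
               to_level = integer(0), to = character(0))
  structure(list(nu = as.integer(nu), levels = levels, arcs = arcs,
                 graph = g),
            class = "interaction_hierarchy")
}

#' @export
print.interaction_hierarchy <- function(x, ...) {
  sizes <- vapply(x$levels, function(l) graph_order(l$graph), integer(1))
  cat(sprintf("interaction_hierarchy H_%d(G): level sizes %s; %d arcs\n",
              x$nu, paste(sizes, collapse = ", "), nrow(x$arcs)))
  invisible(x)
}

# sequences for every vertex of every level, computed bottom-up; level n
# vertex -> character vector of 2^(n-1) atom labels
all_sequences <- function(h) {
  seqs <- vector("list", length(h$levels))
  lvl1 <- h$levels[[1L]]$graph$vertices
  seqs[[1L]] <- setNames(as.list(lvl1), lvl1)
  for (n in seq_along(h$levels)[-1L]) {
    pem <- h$levels[[n]]$parent_edge_map
    prev <- seqs[[n - 1L]]
    labs <- h$levels[[n]]$graph$vertices
    # left half from the parent with the smaller canonical label: pem rows
    # are already ordered (a, b) with a < b in the parent vertex order
    seqs[[n]] <- setNames(
      lapply(seq_along(labs), function(r) c(prev[[pem[r, 1L]]], prev[[pem[r, 2L]]])),
      labs)
  }
  seqs
}

#' Backtrack a hierarchy vertex to its atomic index sequence
#'
#' Each vertex at level n of the hierarchy DAG determines a unique sequence
#' of 2^(n-1) atomic indexes: the base case is the single atom label at
#' level 1, and a level-n vertex concatenates its two parents' sequences
#' (the parent with the smaller canonical label contributes the left
#' half). The multiset structure of the sequence characterizes the
#' interaction: a bend shows one repeated hinge index, and the three 4-body
#' patterns are distinguished by [classify_sequence()].
#'
#' @param h an `interaction_hierarchy`
#' @param level level n of the vertex (1..nu)
#' @param vertex vertex label at that level (e.g. `"((1,2),(2,3))"`)
#' @return character vector of 2^(n-1) atom labels
#' @examples
#' toy <- read_graph(text = c("1 2", "2 3", "2 4", "3 4"))
#' h <- build_hierarchy(toy)
#' backtrack_sequence(h, 3, "((1,2),(2,3))")  # "1" "2" "2" "3"
#' @export
backtrack_sequence <- function(h, level, vertex) {
  stopifnot(inherits(h, "interaction_hierarchy"),
            level >= 1L, level <= length(h$levels))
  if (level == 1L) {
    if (!vertex %in% h$levels[[1L]]$graph$vertices) {
      stop("no vertex '", vertex, "' at level 1")
    }
    return(vertex)
  }
  pem <- h$levels[[level]]$parent_edge_map
  if (!vertex %in% rownames(pem)) {
    stop("no vertex '", vertex, "' at level ", level)
  }
  unname(c(backtrack_sequence(h, level - 1L, pem[[vertex, 1L]]),
           backtrack_sequence(h, level - 1L, pem[[vertex, 2L]])))
}

#' Classify a length-8 atomic index sequence
#'
#' A 4-body interaction is typed by the sorted multiplicity signature of
#' its backtracked sequence: two triply repeated hinge indexes plus two
#' distinct singletons (3,3,1,1) make a proper torsion; a fourfold hinge
#' with one doubled and two single indexes (4,2,1,1) an improper dihedral;
#' and three indexes in pattern (3,3,2) a degenerate 3-cycle. Any other
#' signature is impossible for a simple-graph hierarchy and raises an
#' error.
#'
#' @param seq character vector of 8 atom labels from level-4 backtracking
#' @return one of `"proper"`, `"improper"`, `"three_cycle"`
#' @export
classify_sequence <- function(seq) {
  if (length(seq) != 8L) {
    stop("a 4-body index sequence has length 8, got ", length(seq))
  }
  sig <- sort(as.integer(table(seq)), decreasing = TRUE)
  if (identical(sig, c(3L, 3L, 1L, 1L))) return("proper")
  if (identical(sig, c(4L, 2L, 1L, 1L))) return("improper")
  if (identical(sig, c(3L, 3L, 2L))) return("three_cycle")
  stop("impossible multiplicity signature (", paste(sig, collapse = ","),
       ") for a 4-body sequence; this signals a bug")
}

# canonical participants per type; returns list(participants=chr, type=chr)
canonical_participants <- function(seq, n, key) {
  tab <- table(seq)
  if (n == 1L) return(list(type = "atom", participants = seq))
  if (n == 2L) return(list(type = "bond", participants = seq[natural_order(seq)]))
  if (n == 3L) {
    sig <- sort(as.integer(tab), decreasing = TRUE)
    if (!identical(sig, c(2L, 1L, 1L))) {
      stop("impossible bend signature (", paste(sig, collapse = ","), ")")
    }
    hinge <- names(tab)[tab == 2L]
    ends <- names(tab)[tab == 1L]
    ends <- ends[natural_order(ends)]
    return(list(type = "bend", participants = c(ends[1L], hinge, ends[2L])))
  }
  if (n == 4L) {
    type <- classify_sequence(seq)
    if (type == "proper") {
      hinges <- names(tab)[tab == 3L]
      # left bend occupies seq[1:4]: its hinge is the doubled label there,
      # its outer atom the label absent from the right half's singles
      left <- seq[1:4]; right <- seq[5:8]
      jh <- names(which(table(left) == 2L))
      kh <- setdiff(hinges, jh)
      i <- setdiff(unique(left), c(jh, kh))
      l <- setdiff(unique(right), c(jh, kh))
      fwd <- c(i, jh, kh, l); rev_ <- rev(fwd)
      part <- if (paste(natural_key(fwd), collapse = "\r") <=
                  paste(natural_key(rev_), collapse = "\r")) fwd else rev_
      return(list(type = type, participants = part))
    }
    if (type == "improper") {
      hinge <- names(tab)[tab == 4L]
      periph <- setdiff(names(tab), hinge)
      return(list(type = type,
                  participants = c(hinge, periph[natural_order(periph)])))
    }
    trio <- names(tab)
    return(list(type = type, participants = trio[natural_order(trio)]))
  }
  list(type = "unclassified", participants = unique(seq)[natural_order(unique(seq))])
}

#' Enumerate and classify all interactions of a molecular graph
#'
#' Walks the hierarchy DAG, backtracks every vertex at every level up to
#' `nu` to its atomic index sequence, classifies it, and assigns canonical
#' participant tuples: bends as (i, hinge, k) with i < k; propers as
#' (i, j, k, l) with hinge bond {j, k}, oriented to the lexicographically
#' smaller of the two traversal directions; impropers as (hinge; periphery
#' sorted); 3-cycles as the sorted triple. With `dedupe = TRUE` the three
#' rotational variants of each improper and each 3-cycle (one per choice of
#' shared bond) collapse to a single physical record carrying a shared
#' `variant_group`.
#'
#' @param g a connected `molecular_graph`
#' @param nu maximum order (default 4)
#' @param dedupe collapse rotational variants of impropers/3-cycles?
#' @param vertex_budget passed to [build_hierarchy()]
#' @return data frame with columns `order`, `type`, `participants`
#'   (hyphen-joined atom labels), `variant_group`, `sequence`
#'   (comma-joined raw index sequence), sorted by (order, participants)
#' @examples
#' toy <- read_graph(text = c("1 2", "2 3", "2 4", "3 4"))
#' tab <- interaction_table(toy)
#' table(tab$type)  # 4 atoms, 4 bonds, 5 bends, 2 proper, 1 improper, 1 3-cycle
#' @export
interaction_table <- function(g, nu = 4L, dedupe = TRUE, vertex_budget = 1e5) {
  h <- build_hierarchy(g, nu = nu, vertex_budget = vertex_budget)
  seqs <- all_sequences(h)
  rows <- list()
  for (n in seq_along(seqs)) {
    for (v in names(seqs[[n]])) {
      s <- seqs[[n]][[v]]
      cp <- canonical_participants(s, n, v)
      rows[[length(rows) + 1L]] <- data.frame(
        order = n,
        type = cp$type,
        participants = paste(cp$participants, collapse = "-"),
        vertex = v,
        sequence = paste(s, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab$variant_group <- ifelse(tab$type %in% c("improper", "three_cycle"),
                              paste0(tab$type, ":", tab$participants), NA_character_)
  if (dedupe) {
    grouped <- !is.na(tab$variant_group)
    gsz <- table(tab$variant_group[grouped])
    if (length(gsz) && any(gsz != 3L)) {
      stop("internal error: each improper/3-cycle must have exactly 3 ",
           "rotational variants; got sizes ",
           paste(unique(gsz), collapse = ","))
    }
    keep <- !grouped | !duplicated(tab$variant_group, incomparables = NA)
    tab <- tab[keep, , drop = FALSE]
  }
  tab <- tab[order(tab$order, natural_key(tab$participants),
                   natural_key(tab$vertex)), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("order", "type", "participants", "variant_group", "sequence", "vertex")]
}

#' Convert an interaction hierarchy to a directed igraph
#'
#' Vertices are named `"n:label"` to keep levels disjoint, with `level` and
#' `label` attributes; arcs run from level n to level n+1.
#'
#' @param h an `interaction_hierarchy`
#' @return a directed `igraph` graph
#' @export
hierarchy_as_igraph <- function(h) {
  stopifnot(inherits(h, "interaction_hierarchy"))
  verts <- do.call(rbind, lapply(seq_along(h$levels), function(n) {
    data.frame(name = paste0(n, ":", h$levels[[n]]$graph$vertices),
               level = n, label = h$levels[[n]]$graph$vertices,
               stringsAsFactors = FALSE)
  }))
  arcs <- data.frame(
    from = paste0(h$arcs$from_level, ":", h$arcs$from),
    to = paste0(h$arcs$to_level, ":", h$arcs$to),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(arcs, directed = TRUE, vertices = verts)
}

#' Export the hierarchy DAG as text
#'
#' `dot` and `graphml` outputs are produced through igraph's writers on the
#' directed DAG (vertices annotated with their level and nested label).
#' `tsv` emits the block rows of the block-tridiagonal adjacency: one line
#' per non-sink vertex listing its level, its label, and the labels of its
#' children at the next level (the unit entries of its Z(L^(n-1)) row),
#' preceded by one `vertex` line per DAG vertex.
#'
#' @param h an `interaction_hierarchy`
#' @param format `"dot"`, `"graphml"` or `"tsv"`
#' @param file optional output path; when `NULL`, text is returned
#' @return character vector of output lines, invisibly when written to file
#' @export
export_dag <- function(h, format = c("dot", "graphml", "tsv"), file = NULL) {
  stopifnot(inherits(h, "interaction_hierarchy"))
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- character(0)
    for (n in seq_along(h$levels)) {
      for (v in h$levels[[n]]$graph$vertices) {
        lines <- c(lines, paste("vertex", n, v, sep = "\t"))
      }
    }
    a <- h$arcs
    if (nrow(a)) {
      for (n in sort(unique(a$from_level))) {
        an <- a[a$from_level == n, , drop = FALSE]
        for (v in h$levels[[n]]$graph$vertices) {
          kids <- an$to[an$from == v]
          lines <- c(lines, paste(c("block", n, v, kids), collapse = "\t"))
        }
      }
    }
  } else {
    ig <- hierarchy_as_igraph(h)
    tmp <- tempfile(fileext = paste0(".", format))
    on.exit(unlink(tmp), add = TRUE)
    igraph::write_graph(ig, tmp, format = format)
    lines <- readLines(tmp)
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
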