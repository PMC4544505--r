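test_that("hierarchy structure matches the worked examples", {
  h <- build_hierarchy(toy_graph(), nu = 4)
  sizes <- vapply(h$levels, function(l) graph_order(l$graph), integer(1))
  expect_equal(sizes, c(4L, 4L, 5L, 8L))
  # sinks are exactly the level-4 vertices
  sinks <- setdiff(paste0(4L, ":", h$levels[[4]]$graph$vertices), h$arcs$from)
  expect_length(sinks, 8L)

  h2 <- build_hierarchy(make_fixture("path", r = 2), nu = 2)
  expect_equal(vapply(h2$levels, function(l) graph_order(l$graph), integer(1)),
               c(2L, 1L))
  expect_equal(nrow(h2$arcs), 2L)

  ht <- build_hierarchy(tauro_graph(), nu = 4)
  expect_equal(vapply(ht$levels, function(l) graph_order(l$graph), integer(1)),
               c(12L, 12L, 16L, 34L))
})

test_that("DAG invariants hold: indegree 2, outdegree = degree, consecutive levels", {
  for (g in list(toy_graph(), tauro_graph(),
                 make_fixture("random_connected", p = 7, k = 2, seed = 5))) {
    h <- build_hierarchy(g, nu = 4)
    a <- h$arcs
    expect_true(all(a$to_level == a$from_level + 1L))
    # every non-source vertex has indegree exactly 2
    for (n in 2:4) {
      indeg <- table(a$to[a$to_level == n])
      expect_true(all(indeg == 2L))
      expect_setequal(names(indeg), h$levels[[n]]$graph$vertices)
    }
    # outdegree of a level-n vertex equals its degree in L^(n-1)(G)
    for (n in 1:3) {
      an <- a[a$from_level == n, , drop = FALSE]
      outdeg <- table(factor(an$from, levels = h$levels[[n]]$graph$vertices))
      expect_equal(as.integer(outdeg), unname(degrees(h$levels[[n]]$graph)))
    }
    # arc count = sum over non-source levels of 2 |V_{n+1}|
    expect_equal(nrow(a), sum(2L * vapply(h$levels[-1],
                                          function(l) graph_order(l$graph),
                                          integer(1))))
  }
})

test_that("the assembled DAG adjacency is block tridiagonal with incidence blocks", {
  g <- toy_graph()
  h <- build_hierarchy(g, nu = 3)
  sizes <- vapply(h$levels, function(l) graph_order(l$graph), integer(1))
  offs <- cumsum(c(0L, sizes))
  n_tot <- sum(sizes)
  M <- matrix(0L, n_tot, n_tot)
  all_names <- unlist(lapply(seq_along(h$levels),
                             function(n) paste0(n, ":", h$levels[[n]]$graph$vertices)))
  for (r in seq_len(nrow(h$arcs))) {
    i <- match(paste0(h$arcs$from_level[r], ":", h$arcs$from[r]), all_names)
    j <- match(paste0(h$arcs$to_level[r], ":", h$arcs$to[r]), all_names)
    M[i, j] <- 1L
  }
  for (n in 1:2) {
    Z <- graph_matrices(h$levels[[n]]$graph)$incidence
    block <- M[(offs[n] + 1):offs[n + 1], (offs[n + 1] + 1):offs[n + 2]]
    expect_equal(unname(block), unname(Z))
  }
  # everything off the superdiagonal blocks is zero
  expect_equal(sum(M), sum(vapply(1:2, function(n)
    sum(graph_matrices(h$levels[[n]]$graph)$incidence), integer(1))))
})

test_that("backtracking yields the 2^(n-1) atomic index sequences", {
  h <- build_hierarchy(toy_graph(), nu = 4)
  expect_equal(backtrack_sequence(h, 1, "3"), "3")
  # bends carry a single repeated hinge index
  expect_equal(backtrack_sequence(h, 3, "((1,2),(2,3))"), c("1", "2", "2", "3"))
  for (n in 1:4) {
    for (v in h$levels[[n]]$graph$vertices) {
      expect_length(backtrack_sequence(h, n, v), 2^(n - 1))
    }
  }
  expect_error(backtrack_sequence(h, 2, "(9,9)"), "no vertex")
})

test_that("4-body sequences classify by multiplicity signature", {
  expect_equal(classify_sequence(c("i", "j", "j", "j", "k", "k", "k", "n")), "proper")
  expect_equal(classify_sequence(c("i", "j", "j", "j", "j", "k", "k", "n")), "improper")
  expect_equal(classify_sequence(c("i", "i", "j", "j", "j", "k", "k", "k")), "three_cycle")
  expect_error(classify_sequence(c("i", "j", "k")), "length 8")
  expect_error(classify_sequence(rep("i", 8)), "impossible")
})

test_that("the bile salt 4-body classification matches the published table", {
  tab <- interaction_table(tauro_graph(), nu = 4, dedupe = FALSE)
  o4 <- tab[tab$order == 4, ]
  expect_equal(nrow(o4), 34L)
  expect_setequal(o4$vertex, names(tauro_order4_types))
  expect_identical(setNames(o4$type, o4$vertex)[names(tauro_order4_types)],
                   tauro_order4_types)
  # dedupe collapses the 12 improper variants to 4 physical records
  dd <- interaction_table(tauro_graph(), nu = 4, dedupe = TRUE)
  expect_equal(sum(dd$order == 4 & dd$type == "proper"), 22L)
  expect_equal(sum(dd$order == 4 & dd$type == "improper"), 4L)
  expect_equal(sum(dd$order == 4 & dd$type == "three_cycle"), 0L)
})

test_that("interaction records carry hinge-consistent canonical participants", {
  for (g in list(toy_graph(), tauro_graph(),
                 make_fixture("random_connected", p = 8, k = 3, seed = 17))) {
    A <- graph_matrices(g)$adjacency
    idx <- function(v) match(v, g$vertices)
    tab <- interaction_table(g, nu = 4, dedupe = FALSE)
    # order-3: hinge adjacent to both ends
    for (r in which(tab$order == 3)) {
      pr <- strsplit(tab$participants[r], "-", fixed = TRUE)[[1]]
      expect_equal(A[idx(pr[2]), idx(pr[1])], 1L)
      expect_equal(A[idx(pr[2]), idx(pr[3])], 1L)
      expect_true(idx(pr[1]) < idx(pr[3]))
    }
    for (r in which(tab$order == 4)) {
      pr <- strsplit(tab$participants[r], "-", fixed = TRUE)[[1]]
      if (tab$type[r] == "proper") {
        # the two hinges form a bond; each outer atom bonds its hinge
        expect_equal(A[idx(pr[2]), idx(pr[3])], 1L)
        expect_equal(A[idx(pr[1]), idx(pr[2])], 1L)
        expect_equal(A[idx(pr[3]), idx(pr[4])], 1L)
      } else if (tab$type[r] == "improper") {
        # quadruple hinge adjacent to all three peripheral atoms
        for (s in 2:4) expect_equal(A[idx(pr[1]), idx(pr[s])], 1L)
      } else {
        for (pair in list(1:2, 2:3, c(1, 3))) {
          expect_equal(A[idx(pr[pair[1]]), idx(pr[pair[2]])], 1L)
        }
      }
    }
  }
})

test_that("the order-4 census reproduces the closed-form counts", {
  for (seed in 1:12) {
    g <- make_fixture("random_connected", p = 5 + (seed %% 6), k = seed %% 3,
                      seed = 500 + seed)
    cf <- closed_form_counts(g)
    raw <- interaction_table(g, nu = 4, dedupe = FALSE)
    o4 <- raw[raw$order == 4, ]
    expect_equal(sum(o4$type == "proper"), cf$n_prop)
    expect_equal(sum(o4$type == "improper"), 3L * cf$n_impr)
    expect_equal(sum(o4$type == "three_cycle"), 3L * cf$n_3cyc)
    expect_equal(nrow(o4), cf$n4)
    # per-order raw record counts are the line-graph vertex counts
    expect_equal(as.integer(table(raw$order)),
                 vapply(1:4, function(n) count_via_line_graphs(g, n), integer(1)))
  }
})

test_that("orders beyond 4 are emitted unclassified", {
  tab <- interaction_table(toy_graph(), nu = 5, dedupe = FALSE)
  o5 <- tab[tab$order == 5, ]
  expect_true(all(o5$type == "unclassified"))
  expect_equal(nrow(o5), count_via_line_graphs(toy_graph(), 5))
  expect_true(all(lengths(strsplit(o5$sequence, ",")) == 16L))
})

test_that("DAG export produces the three formats", {
  h3 <- build_hierarchy(make_fixture("path", r = 3), nu = 3)
  expect_equal(vapply(h3$levels, function(l) graph_order(l$graph), integer(1)),
               c(3L, 2L, 1L))
  # indegree 2 everywhere above the sources: 2|V_2| + 2|V_3| = 4 + 2
  expect_equal(nrow(h3$arcs), 6L)

  h <- build_hierarchy(toy_graph(), nu = 4)
  dot <- export_dag(h, "dot")
  expect_true(any(grepl("digraph", dot)))
  gml <- export_dag(h, "graphml")
  expect_true(any(grepl("graphml", gml)))
  # graphml round-trips through igraph with the right vertex/arc counts
  tmp <- tempfile(fileext = ".graphml")
  writeLines(gml, tmp)
  ig <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::vcount(ig), 4L + 4L + 5L + 8L)
  expect_equal(igraph::ecount(ig), nrow(h$arcs))
  unlink(tmp)

  tsv <- export_dag(h, "tsv")
  expect_equal(sum(startsWith(tsv, "vertex")), 21L)
  blocks <- strsplit(tsv[startsWith(tsv, "block")], "\t", fixed = TRUE)
  kids <- sum(vapply(blocks, function(b) length(b) - 3L, integer(1)))
  expect_equal(kids, nrow(h$arcs))
})
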