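test_that("edge-list parsing builds the expected graphs", {
  g <- read_graph(text = c("1 2", "2 3", "2 4", "3 4"))
  expect_equal(graph_order(g), 4L)
  expect_equal(graph_size(g), 4L)
  expect_equal(g$vertices, c("1", "2", "3", "4"))

  tauro <- tauro_graph()
  expect_equal(graph_order(tauro), 12L)
  expect_equal(graph_size(tauro), 12L)

  single <- read_graph(text = "a b")
  expect_equal(graph_order(single), 2L)
  expect_equal(graph_size(single), 1L)

  # comments and blank lines are ignored; labels kept verbatim
  g2 <- read_graph(text = c("# molecule", "", "C1 C2  # bond", "C2 C3"))
  expect_equal(g2$vertices, c("C1", "C2", "C3"))
})

test_that("malformed input is rejected with a useful diagnostic", {
  expect_error(read_graph(text = c("1 2", "3 4 5")), "line 2")
  expect_error(read_graph(text = c("1 2", "2 2")), "self-loop")
  expect_error(read_graph(text = c("1 2", "2 1")), "duplicate bond")
  expect_error(read_graph(text = c("0,1", "0,0"), format = "adjacency_csv"),
               "symmetric")
  expect_error(read_graph(text = c("0,2", "2,0"), format = "adjacency_csv"),
               "binary")
  expect_error(read_graph(text = c("1,1", "1,0"), format = "adjacency_csv"),
               "diagonal")
})

test_that("adjacency CSV input matches the edge-list route", {
  path <- system.file("extdata", "methylcyclopropane_adjacency.csv",
                      package = "intramol")
  g_adj <- read_graph(path, format = "adjacency_csv")
  expect_identical(g_adj$edges, toy_graph()$edges)
  # headerless input gets vertices 1..p
  g_nohdr <- read_graph(text = c("0,1", "1,0"), format = "adjacency_csv")
  expect_equal(g_nohdr$vertices, c("1", "2"))
})

test_that("canonical edge order is lexicographic and numeric-label aware", {
  g <- molecular_graph(rbind(c("10", "1"), c("2", "1"), c("9", "2")))
  expect_equal(g$vertices, c("1", "2", "9", "10"))
  expect_equal(unname(g$edges),
               unname(rbind(c("1", "2"), c("1", "10"), c("2", "9"))))
})

test_that("write_graph round-trips bit-identically through read_graph", {
  for (g in list(toy_graph(), tauro_graph(),
                 make_fixture("path", r = 3),
                 random_connected_raw(7, 9, seed = 11))) {
    lines <- write_graph(g, "edge_list")
    g2 <- read_graph(text = lines)
    expect_identical(write_graph(g2, "edge_list"), lines)
    expect_identical(g2$edges, g$edges)
  }
  expect_identical(write_graph(make_fixture("path", r = 3), "edge_list"),
                   c("1 2", "2 3"))
})

test_that("validation computes connectivity two independent ways", {
  rep_toy <- validate_graph(toy_graph())
  expect_true(rep_toy$connected)
  expect_equal(rep_toy$kirchhoff_rank, 3L)  # p - 1

  # two disjoint edges: rank K = 2 != p - 1 = 3; both routes agree
  disc <- molecular_graph(rbind(c("1", "2"), c("3", "4")))
  rep_disc <- validate_graph(disc)
  expect_false(rep_disc$connected)
  expect_equal(rep_disc$kirchhoff_rank, 2L)
  expect_identical(rep_disc$connected_rank, rep_disc$connected_traversal)

  expect_true(validate_graph(tauro_graph())$connected)

  # downstream operations refuse disconnected input
  expect_error(closed_form_counts(disc), "disconnected")
  expect_error(build_hierarchy(disc), "disconnected")
  expect_error(line_index(disc), "disconnected")

  # isolated vertices are flagged and refused
  iso <- molecular_graph(rbind(c("1", "2")), vertices = c("1", "2", "3"))
  expect_false(validate_graph(iso)$covering)
  expect_error(closed_form_counts(iso), "isolated")
})

test_that("matrix representations match the worked example and each other", {
  m <- graph_matrices(toy_graph())
  expect_equal(unname(m$adjacency), toy_A)
  expect_equal(unname(diag(m$degree)), c(1, 3, 2, 2))
  expect_true(all(colSums(m$incidence) == 2L))
  expect_equal(rowSums(m$adjacency), diag(m$degree), ignore_attr = TRUE)

  p2 <- graph_matrices(make_fixture("path", r = 2))
  expect_equal(unname(p2$kirchhoff), rbind(c(1, -1), c(-1, 1)))

  for (g in list(toy_graph(), tauro_graph(), make_fixture("complete", r = 4),
                 random_connected_raw(8, 12, seed = 3))) {
    mm <- graph_matrices(g)
    Z <- mm$incidence
    expect_equal(unname(mm$signless_laplacian), unname(Z %*% t(Z)))
    expect_equal(unname(Z %*% t(Z) - 2 * mm$degree), unname(-mm$kirchhoff))
    # handshaking: (1/2) u'Du = q
    expect_equal(sum(diag(mm$degree)) / 2, graph_size(g))
    # Kirchhoff is PSD with zero row sums
    expect_true(all(rowSums(mm$kirchhoff) == 0))
    expect_true(min(eigen(mm$kirchhoff, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-9)
  }
})

test_that("powers of A count walks (against explicit walk enumeration)", {
  for (seed in c(2, 5)) {
    g <- random_connected_raw(6, 8, seed = seed)
    A <- graph_matrices(g)$adjacency
    for (m in 1:3) {
      Am <- A
      if (m > 1) for (s in seq_len(m - 1)) Am <- Am %*% A
      for (i in 1:3) for (j in c(1, 4, 6)) {
        expect_equal(Am[i, j], oracle_walk_count(g, i, j, m))
      }
    }
  }
})

test_that("exact Kirchhoff rank agrees with numeric rank on fixtures", {
  graphs <- list(toy_graph(), tauro_graph(), make_fixture("cycle", r = 6),
                 make_fixture("complete", r = 6),
                 molecular_graph(rbind(c("1", "2"), c("3", "4"), c("4", "5"))))
  for (g in graphs) {
    K <- graph_matrices(g)$kirchhoff
    expect_equal(intramol:::matrix_rank_exact(K),
                 intramol:::matrix_rank_numeric(K * 1.0))
  }
})
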