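# shared fixture graphs, built in code

toy_graph <- function() {
  molecular_graph(rbind(c("1", "2"), c("2", "3"), c("2", "4"), c("3", "4")))
}

tauro_graph <- function() {
  read_graph(system.file("extdata", "taurocholate.edges", package = "intramol"))
}

# printed adjacency matrices of the worked 4-vertex example, in canonical
# vertex/edge order (frozen expected values)
toy_A <- rbind(c(0, 1, 0, 0),
               c(1, 0, 1, 1),
               c(0, 1, 0, 1),
               c(0, 1, 1, 0))

toy_A_L <- rbind(c(0, 1, 1, 0),
                 c(1, 0, 1, 1),
                 c(1, 1, 0, 1),
                 c(0, 1, 1, 0))

toy_A_L2 <- rbind(c(0, 1, 1, 1, 0),
                  c(1, 0, 1, 0, 1),
                  c(1, 1, 0, 1, 1),
                  c(1, 0, 1, 0, 1),
                  c(0, 1, 1, 1, 0))

# random connected graph for property tests; distinct from make_fixture so
# fixture bugs cannot mask themselves (plain G(p, q) rejection sampling)
random_connected_raw <- function(p, q, seed) {
  stopifnot(q >= p - 1L, q <= choose(p, 2))
  set.seed(seed)
  cmb <- t(utils::combn(p, 2L))
  repeat {
    pick <- cmb[sample(nrow(cmb), q), , drop = FALSE]
    g <- try(molecular_graph(cbind(as.character(pick[, 1L]),
                                   as.character(pick[, 2L])),
                             vertices = as.character(seq_len(p))),
             silent = TRUE)
    if (!inherits(g, "try-error") && validate_graph(g)$connected) return(g)
  }
}

# published 4-body classification of the bile salt model, keyed by nested
# vertex label (order-insensitive): 22 proper, 12 improper variants
tauro_order4_types <- c(
  "(((1,2),(2,3)),((1,2),(2,4)))" = "improper",
  "(((1,2),(2,3)),((2,3),(2,4)))" = "improper",
  "(((1,2),(2,4)),((2,3),(2,4)))" = "improper",
  "(((1,2),(2,3)),((2,3),(3,5)))" = "proper",
  "(((2,3),(2,4)),((2,3),(3,5)))" = "proper",
  "(((1,2),(2,4)),((2,4),(4,5)))" = "proper",
  "(((2,3),(2,4)),((2,4),(4,5)))" = "proper",
  "(((2,3),(3,5)),((3,5),(4,5)))" = "proper",
  "(((2,4),(4,5)),((3,5),(4,5)))" = "proper",
  "(((2,3),(3,5)),((3,5),(5,6)))" = "proper",
  "(((3,5),(4,5)),((3,5),(5,6)))" = "improper",
  "(((2,4),(4,5)),((4,5),(5,6)))" = "proper",
  "(((3,5),(4,5)),((4,5),(5,6)))" = "improper",
  "(((3,5),(5,6)),((4,5),(5,6)))" = "improper",
  "(((3,5),(5,6)),((5,6),(6,7)))" = "proper",
  "(((4,5),(5,6)),((5,6),(6,7)))" = "proper",
  "(((5,6),(6,7)),((6,7),(7,8)))" = "proper",
  "(((6,7),(7,8)),((7,8),(8,9)))" = "proper",
  "(((1,2),(1,10)),((1,2),(2,3)))" = "proper",
  "(((1,2),(1,10)),((1,2),(2,4)))" = "proper",
  "(((1,2),(2,3)),((2,3),(3,11)))" = "proper",
  "(((2,3),(2,4)),((2,3),(3,11)))" = "proper",
  "(((2,3),(3,5)),((2,3),(3,11)))" = "improper",
  "(((2,3),(3,5)),((3,5),(3,11)))" = "improper",
  "(((3,5),(3,11)),((3,5),(4,5)))" = "proper",
  "(((3,5),(3,11)),((3,5),(5,6)))" = "proper",
  "(((2,3),(3,11)),((3,5),(3,11)))" = "improper",
  "(((1,2),(2,4)),((2,4),(4,12)))" = "proper",
  "(((2,3),(2,4)),((2,4),(4,12)))" = "proper",
  "(((2,4),(4,5)),((2,4),(4,12)))" = "improper",
  "(((2,4),(4,5)),((4,5),(4,12)))" = "improper",
  "(((3,5),(4,5)),((4,5),(4,12)))" = "proper",
  "(((4,5),(4,12)),((4,5),(5,6)))" = "proper",
  "(((2,4),(4,12)),((4,5),(4,12)))" = "improper"
)
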