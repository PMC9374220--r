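test_that("path_length handles adjacency, disconnection and weighted oracles", {
  fx <- fixture_toy_graphs()
  expect_equal(path_length(fx$star4, "k", "u1"), 1)
  expect_equal(path_length(fx$tri_iso, "a", "z"), Inf)
  expect_equal(path_length(fx$star4, "k", "k"), 0)
  expect_error(path_length(fx$star4, "k", "nope"), "unknown node")
  for (s in 1:50) {
    g <- random_weighted_graph(sample(4:8, 1), density = 0.4, seed = 200 + s)
    ids <- igraph::V(g)$name
    uv <- sample(ids, 2)
    expect_equal(path_length(g, uv[1], uv[2], mode = "weighted"),
                 brute_shortest(g, uv[1], uv[2], mode = "weighted"),
                 tolerance = 1e-9)
    expect_equal(path_length(g, uv[1], uv[2], mode = "hops"),
                 brute_shortest(g, uv[1], uv[2], mode = "hops"))
  }
})

test_that("constrained path length is the min over required nodes", {
  tri <- fixture_toy_graphs()$tri_iso
  expect_equal(constrained_path_length(tri, "a", "b", K = "c"), 2)
  expect_equal(constrained_path_length(tri, "a", "b", K = character(0)), Inf)
  expect_equal(constrained_path_length(tri, "a", "b", K = "z"), Inf)
  expect_error(constrained_path_length(tri, "a", "b", K = c("a", "c")),
               "must not contain")
  for (s in 1:50) {
    g <- random_weighted_graph(sample(5:8, 1), density = 0.45, seed = 800 + s)
    ids <- igraph::V(g)$name
    picks <- sample(ids, 4)
    K <- picks[3:4]
    for (mode in c("hops", "weighted"))
      expect_equal(constrained_path_length(g, picks[1], picks[2], K, mode),
                   brute_constrained(g, picks[1], picks[2], K, mode),
                   tolerance = 1e-9)
  }
})

test_that("classification reproduces the six path types on constructions", {
  fx <- fixture_toy_graphs()
  expect_equal(classify_pairs(attr(fx$star4, "subgraph"), fx$star4)$counts,
               c(B = 3, R = 0, I = 0, D = 0, E = 0, S = 0))
  expect_equal(classify_pairs(attr(fx$tri_iso, "subgraph"), fx$tri_iso)$counts,
               c(B = 0, R = 3, I = 0, D = 0, E = 0, S = 0))

  # triangle as full graph, subgraph {a, b}: direct edge vs forced 2-hop
  tri <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c")), directed = FALSE)
  igraph::E(tri)$weight <- 1
  bv <- classify_pairs(c("a", "b"), tri)
  expect_equal(bv$counts[["D"]], 1)
  expect_equal(bv$pairs$d_sub, 1)
  expect_equal(bv$pairs$d_constrained, 2)

  # shortcut: subgraph route u-a-b-v (3 hops), full graph offers u-k-v (2)
  sc <- igraph::graph_from_edgelist(
    rbind(c("u", "a"), c("a", "b"), c("b", "v"), c("u", "k"), c("k", "v")),
    directed = FALSE)
  igraph::E(sc)$weight <- 1
  bv2 <- classify_pairs(c("u", "a", "b", "v"), sc)
  row_uv <- bv2$pairs[bv2$pairs$u == "u" & bv2$pairs$v == "v", ]
  expect_equal(row_uv$type, "S")
  expect_equal(row_uv$d_sub, 3)
  expect_equal(row_uv$d_constrained, 2)

  # impasse: two isolated subgraph nodes no candidate can reach
  iso <- igraph::graph_from_edgelist(rbind(c("k", "x")), directed = FALSE)
  iso <- iso + igraph::vertices(c("p", "q"))
  igraph::E(iso)$weight <- 1
  expect_equal(classify_pairs(c("p", "q"), iso)$counts[["I"]], 1)
})

test_that("count conservation and the K-empty degenerate case", {
  set.seed(1234)
  for (rep in 1:200) {
    g <- random_weighted_graph(sample(4:10, 1), density = runif(1, 0.2, 0.8),
                               seed = sample.int(1e6, 1))
    ids <- igraph::V(g)$name
    sub <- sample(ids, sample(2:length(ids), 1))
    bv <- classify_pairs(sub, g)
    expect_equal(sum(bv$counts), choose(length(sub), 2))
    expect_true(all(bv$counts >= 0))
  }
  # subgraph = all nodes: every pair R (connected) or I (not); B=D=E=S=0
  g <- random_weighted_graph(8, density = 0.3, seed = 99)
  bv <- classify_pairs(igraph::V(g)$name, g)
  expect_equal(unname(bv$counts[c("B", "D", "E", "S")]), rep(0, 4))
  expect_equal(sum(bv$counts[c("R", "I")]), choose(8, 2))
})

test_that("repairing the subgraph never creates breakthroughs", {
  # with the full graph (hence the constrained lengths) held fixed, adding
  # an edge inside X_n can only connect pairs, so the breakthrough count is
  # non-increasing
  count_B <- function(sub_g, d_const) {
    d <- igraph::distances(sub_g, weights = NA)
    nm <- igraph::V(sub_g)$name
    sum(vapply(seq_len(nrow(d_const)), function(r)
      is.infinite(d[d_const$u[r], d_const$v[r]]) && is.finite(d_const$dc[r]),
      logical(1)))
  }
  set.seed(55)
  for (rep in 1:30) {
    g <- random_weighted_graph(8, density = 0.3, seed = 4000 + rep)
    ids <- igraph::V(g)$name
    sub <- sample(ids, 5)
    K <- setdiff(ids, sub)
    prs <- utils::combn(sub, 2)
    d_const <- data.frame(u = prs[1, ], v = prs[2, ],
                          dc = apply(prs, 2, function(p)
                            constrained_path_length(g, p[1], p[2], K)))
    sub_g <- igraph::induced_subgraph(g, sub)
    b0 <- count_B(sub_g, d_const)
    notadj <- !igraph::are_adjacent(sub_g, sub[1], sub[2])
    if (notadj) {
      sub_g2 <- igraph::add_edges(sub_g, c(sub[1], sub[2]))
      expect_lte(count_B(sub_g2, d_const), b0)
    }
  }
})

test_that("weight-model parsing, notation and scoring", {
  expect_equal(unclass(parse_weight_model("S1")),
               c(B = 0, R = 0, I = 0, D = 0, E = 0, S = 1))
  expect_equal(unclass(parse_weight_model("B1R-1D-1S1")),
               c(B = 1, R = -1, I = 0, D = -1, E = 0, S = 1))
  expect_equal(unclass(parse_weight_model("B3D1E2S3")),
               c(B = 3, R = 0, I = 0, D = 1, E = 2, S = 3))
  expect_equal(unclass(parse_weight_model(c(1, 0, 0, 0, 1, 1))),
               c(B = 1, R = 0, I = 0, D = 0, E = 1, S = 1))
  expect_error(parse_weight_model("B1X2"), "cannot parse")
  expect_error(parse_weight_model("B1B2"), "repeated")
  expect_error(weight_model(), "nonzero")
  expect_equal(format_weight_model("B1R-1D-1S1"), "B^1^R_1_D_1_S^1^")

  expect_equal(brides_score(c(3, 0, 0, 0, 0, 0), "B3S1"), 9)
  expect_equal(brides_score(c(5, 2, 1, 4, 9, 0), "S1"), 0)
  expect_equal(brides_score(c(1, 1, 0, 1, 0, 1), "B1R-1D-1S1"), 0)
})

test_that("model complexity counts nonzero weights", {
  expect_equal(model_complexity("S1"), 1L)
  expect_equal(model_complexity("B1R-1D-1S1"), 4L)
  expect_equal(model_complexity("B3D1E2S3"), 4L)
  expect_equal(sapply(standard_models(), model_complexity),
               c(`S1` = 1L, `B3S1` = 2L, `B1S3` = 2L,
                 `B1R-1D-1S1` = 4L, `B3D1E2S3` = 4L))
})

test_that("weighted-mode equality uses a relative tolerance", {
  # two routes of identical length up to representation noise -> E, not D/S
  g <- igraph::graph_from_edgelist(
    rbind(c("u", "v"), c("u", "k"), c("k", "v")), directed = FALSE)
  igraph::E(g)$weight <- c(0.3, 0.1, 0.2)
  bv <- classify_pairs(c("u", "v"), g, mode = "weighted")
  expect_equal(bv$pairs$type, "E")
})
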