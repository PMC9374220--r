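test_that("scenario thresholds carve the published attribute table correctly", {
  att <- wood_turtle_attributes()
  sc <- standard_scenarios()
  expect_setequal(build_scenario_subgraph(att, sc$C_P),
                  c("GA3", "GA5", "SM1", "DC1", "MA2", "MA3", "MI1", "SF1",
                    "GA4", "LO1", "MD1", "BE1", "MI3"))
  expect_setequal(build_scenario_subgraph(att, sc$C_R),
                  c("GA2", "LA1", "MA1", "MI2", "SF4", "SF3"))
  # boundary populations are excluded from both sides
  expect_false("GA2" %in% build_scenario_subgraph(att, sc$B_P))  # PSize = 75
  expect_false("GA2" %in% build_scenario_subgraph(att, sc$B_R))
  expect_false("GA3" %in% build_scenario_subgraph(att, sc$A_P))  # HE = 0.72
  expect_false("GA3" %in% build_scenario_subgraph(att, sc$A_R))
  sizes <- vapply(sc, function(s)
    length(build_scenario_subgraph(att, s)), integer(1))
  expect_equal(unname(sizes), c(9L, 9L, 8L, 10L, 13L, 6L))
})

test_that("scenario construction validates attributes", {
  att <- wood_turtle_attributes()
  g <- random_weighted_graph(3, seed = 1)
  expect_error(build_scenario_subgraph(att, standard_scenarios()$A_P, graph = g),
               "no attributes for node")
  expect_error(build_scenario_subgraph(att[, c("Id", "N")],
                                       standard_scenarios()$A_P),
               "lacks column HE")
  expect_error(scenario("heterozygosity", threshold = c(1, 2)), "single number")
})

test_that("normalized score is 1 with all candidates and 0 with none possible", {
  fx <- fixture_toy_graphs()
  g <- fx$bridge11
  sub <- attr(g, "subgraph")
  cand <- setdiff(igraph::V(g)$name, sub)
  expect_equal(as.numeric(normalized_score(sub, cand, g, "B1E1S1")), 1)
  # no shortcuts achievable for the star under S1: raw 0, flagged unnormalized
  st <- fx$star4
  ns <- normalized_score(attr(st, "subgraph"), character(0), st, "S1")
  expect_equal(as.numeric(ns), 0)
  expect_false(attr(ns, "normalized"))
})

test_that("the bridging candidate is uniquely optimal on the 11-node example", {
  g <- fixture_toy_graphs()$bridge11
  sub <- attr(g, "subgraph")
  scores <- vapply(c("c1", "c2", "c3"), function(cn)
    as.numeric(normalized_score(sub, cn, g, "B1E1S1")), numeric(1))
  expect_equal(unname(scores["c1"]), 1)
  expect_true(all(scores[c("c2", "c3")] < 1))
  sel <- stepwise_select(sub, g, "B1E1S1")
  expect_equal(sel$n_added, 1L)
  expect_equal(sel$solutions, list("c1"))
})

test_that("symmetric candidates are both reported as co-optimal solutions", {
  # two components {a,b}, {c,d}; k1 and k2 are mirror-image bridges
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("c", "d"),
          c("b", "k1"), c("k1", "c"), c("b", "k2"), c("k2", "c")),
    directed = FALSE)
  igraph::E(g)$weight <- 1
  sel <- stepwise_select(c("a", "b", "c", "d"), g, "B1S1")
  expect_equal(sel$n_added, 1L)
  expect_equal(sel$n_solutions, 2L)
  expect_setequal(unlist(sel$solutions), c("k1", "k2"))
})

test_that("runs where no candidate can score are flagged as no solution", {
  st <- fixture_toy_graphs()$star4
  sel <- stepwise_select(attr(st, "subgraph"), st, "S1")
  expect_true(sel$no_solution)
  expect_equal(sel$n_solutions, 0L)
  expect_true(is.na(sel$n_added))
})

test_that("every reported solution reaches score 1; greedy vs exhaustive", {
  set.seed(77)
  n_runs <- 0L; n_agree <- 0L
  for (rep in 1:50) {
    g <- random_weighted_graph(sample(7:9, 1), density = runif(1, 0.25, 0.6),
                               seed = 5000 + rep)
    ids <- igraph::V(g)$name
    sub <- sample(ids, sample(4:6, 1))
    cand_n <- length(ids) - length(sub)
    if (cand_n < 1 || cand_n > 4) next
    model <- sample(list("B1S1", "B1E1S1", "B3D1E2S3", "S1"), 1)[[1]]
    sel <- stepwise_select(sub, g, model)
    exact <- exhaustive_min_solution(sub, g, parse_weight_model(model))
    if (sel$no_solution) {
      expect_true(is.na(exact) || exact == 0L)
      next
    }
    n_runs <- n_runs + 1L
    for (sol in sel$solutions)
      expect_equal(as.numeric(normalized_score(sub, sol, g, model)), 1,
                   tolerance = 1e-9)
    # greedy can never beat the exhaustive optimum
    expect_gte(sel$n_added, exact)
    if (sel$n_added == exact) n_agree <- n_agree + 1L
  }
  expect_gt(n_runs, 10L)
  # the greedy frontier found the true minimum in the large majority of runs
  expect_gte(n_agree / n_runs, 0.8)
})

test_that("normalized greedy scores are monotone for non-negative models", {
  set.seed(31)
  for (rep in 1:100) {
    g <- random_weighted_graph(8, density = runif(1, 0.25, 0.6),
                               seed = 6000 + rep)
    sub <- sample(igraph::V(g)$name, 5)
    sel <- stepwise_select(sub, g, "B3D1E2S3")
    if (sel$no_solution || length(sel$steps) < 2) next
    sc <- vapply(sel$steps, `[[`, numeric(1), "score")
    expect_true(all(diff(sc) >= -1e-9))
  }
})

test_that("selection output is invariant to node relabeling", {
  g <- fixture_toy_graphs()$bridge11
  sub <- attr(g, "subgraph")
  sel <- stepwise_select(sub, g, "B3D1E2S3")
  set.seed(8)
  for (rep in 1:3) {
    perm <- sample(igraph::gorder(g))
    # shuffle internal vertex order and relabel with fresh ids
    g3 <- igraph::permute(g, perm)
    igraph::V(g3)$name[perm] <- paste0("y", seq_len(igraph::gorder(g)))
    sel3 <- stepwise_select(paste0("y", match(sub, igraph::V(g)$name)), g3,
                            "B3D1E2S3")
    expect_equal(sel3$n_added, sel$n_added)
    expect_equal(sel3$n_solutions, sel$n_solutions)
    sols <- lapply(sel3$solutions, function(s)
      sort(igraph::V(g)$name[match(s, paste0("y", seq_len(igraph::gorder(g))))]))
    expect_setequal(sols, lapply(sel$solutions, sort))
  }
})

test_that("selection frequency counts candidacy and optimal membership", {
  g <- fixture_toy_graphs()$bridge11
  att <- data.frame(Id = igraph::V(g)$name,
                    N = 10,
                    HE = c(rep(0.8, 4), rep(0.6, 4), 0.5, 0.9, 0.72),
                    PSize = c(rep(100, 4), rep(10, 4), 50, 200, 75),
                    EO = "B", stringsAsFactors = FALSE)
  att$EO <- factor(att$EO, levels = eo_levels(), ordered = TRUE)
  scs <- list(hp = scenario("heterozygosity", "proactive"),
              hr = scenario("heterozygosity", "reactive"))
  mods <- list(A = parse_weight_model("B1E1S1"),
               B = parse_weight_model("B1S1"))
  fr <- selection_frequency(g, att, scenarios = scs, models = mods)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 1, na.rm = TRUE))
  expect_true(all(fr$n_selected <= fr$n_candidate))
  runs <- attr(fr, "runs")
  expect_length(runs, 4L)
  # cross-check one node by hand against the stored runs
  cnt <- table(unlist(lapply(runs, function(r)
    unique(unlist(r$selection$solutions)))))
  for (id in names(cnt))
    expect_equal(fr$n_selected[fr$Id == id], as.integer(cnt[[id]]))
})

test_that("nodes never outside the subgraph get NA frequency", {
  g <- fixture_toy_graphs()$star4
  att <- data.frame(Id = igraph::V(g)$name, N = 5,
                    HE = c(0.5, 0.9, 0.9, 0.9), PSize = 10, EO = "B")
  fr <- selection_frequency(g, att,
                            scenarios = list(scenario("heterozygosity",
                                                      "proactive")),
                            models = list(parse_weight_model("B1S1")))
  expect_true(is.na(fr$frequency[fr$Id == "u1"]))   # always in the subgraph
  expect_equal(fr$frequency[fr$Id == "k"], 1)       # selected when candidate
})

test_that("Kendall tau-b handles ties, concordance and degenerate input", {
  expect_equal(complexity_node_correlation(1:5, 1:5)$tau, 1)
  expect_equal(complexity_node_correlation(c(1, 2, 3), c(1, 2, 1))$tau, 0)
  expect_error(complexity_node_correlation(c(1, 1, 1), c(1, 2, 3)),
               "all values tied")
  # NA = no-solution cells are excluded
  r <- complexity_node_correlation(c(1, 2, 3, 4), c(1, 2, 3, NA))
  expect_equal(r$tau, 1)
})
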