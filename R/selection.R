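#' Define a conservation scenario
#'
#' A scenario picks the nodes of the starting subgraph `X_n` by one
#' population attribute. Proactive scenarios keep the populations with the
#' *better* attribute values (high heterozygosity, large size, good EO
#' viability) as a low-vulnerability reservoir; reactive scenarios keep
#' the *worse* side, the populations in need of immediate action.
#' Comparisons are strict, so populations exactly at the threshold are
#' excluded from both sides and remain candidates.
#'
#' @param criterion `"heterozygosity"` (HE), `"pop_size"` (PSize) or
#'   `"eo_rank"` (EO).
#' @param direction `"proactive"` or `"reactive"`.
#' @param threshold numeric threshold for the first two criteria (defaults
#'   0.72 and 75); for `eo_rank` a pair of EO tokens
#'   `c(proactive, reactive)` — proactive keeps ranks strictly better than
#'   the first (default `"BC"`), reactive strictly worse than the second
#'   (default `"B"`).
#' @return an object of class `scenario`.
#' @export
scenario <- function(criterion = c("heterozygosity", "pop_size", "eo_rank"),
                     direction = c("proactive", "reactive"),
                     threshold = NULL) {
  criterion <- match.arg(criterion)
  direction <- match.arg(direction)
  if (is.null(threshold))
    threshold <- switch(criterion,
                        heterozygosity = 0.72,
                        pop_size = 75,
                        eo_rank = c("BC", "B"))
  if (criterion == "eo_rank") {
    threshold <- toupper(as.character(threshold))
    if (length(threshold) == 1L) threshold <- rep(threshold, 2L)
    validate_eo(threshold)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      stop("'threshold' must be a single number for criterion ", criterion)
  }
  structure(list(criterion = criterion, direction = direction,
                 threshold = threshold),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  thr <- paste(x$threshold, collapse = "/")
  cat(sprintf("scenario: %s, %s, threshold %s\n",
              x$criterion, x$direction, thr))
  invisible(x)
}

#' The six standard conservation scenarios
#'
#' Proactive and reactive variants for each of heterozygosity (threshold
#' 0.72), estimated population size (threshold 75) and EO rank (strictly
#' better than BC / strictly worse than B).
#'
#' @return named list of six [scenario()] objects.
#' @export
standard_scenarios <- function() {
  list(
    A_P = scenario("heterozygosity", "proactive"),
    A_R = scenario("heterozygosity", "reactive"),
    B_P = scenario("pop_size", "proactive"),
    B_R = scenario("pop_size", "reactive"),
    C_P = scenario("eo_rank", "proactive"),
    C_R = scenario("eo_rank", "reactive"))
}

#' Build the node set of a scenario subgraph
#'
#' Applies the scenario's strict threshold to the attribute table.
#' EO ranks are ordered A > AB > B > BC > C > CD > D (better viability
#' first): proactive keeps ranks strictly better than the proactive
#' threshold token, reactive strictly worse than the reactive one.
#'
#' @param attributes data.frame with columns `Id` and the needed attribute
#'   (`HE`, `PSize` or `EO`), as from [read_population_attributes()].
#' @param scen a [scenario()].
#' @param graph optional igraph; when given, the attribute table must
#'   cover every graph node and the result is restricted to graph nodes.
#' @return character vector of node ids.
#' @export
build_scenario_subgraph <- function(attributes, scen, graph = NULL) {
  stopifnot(inherits(scen, "scenario"))
  if (!is.null(graph)) {
    missing_ids <- setdiff(vertex_ids(graph), attributes$Id)
    if (length(missing_ids))
      stop("no attributes for node(s): ", paste(missing_ids, collapse = ", "))
    attributes <- attributes[attributes$Id %in% vertex_ids(graph), ]
  }
  col <- switch(scen$criterion, heterozygosity = "HE", pop_size = "PSize",
                eo_rank = "EO")
  if (!col %in% names(attributes))
    stop("attribute table lacks column ", col)
  if (anyNA(attributes[[col]]))
    stop("missing ", col, " for node(s): ",
         paste(attributes$Id[is.na(attributes[[col]])], collapse = ", "))
  if (scen$criterion == "eo_rank") {
    v <- eo_score(attributes$EO)
    keep <- if (scen$direction == "proactive")
      v > eo_score(scen$threshold[1]) else v < eo_score(scen$threshold[2])
  } else {
    v <- attributes[[col]]
    keep <- if (scen$direction == "proactive")
      v > scen$threshold else v < scen$threshold
  }
  attributes$Id[keep]
}

#' Normalized BRIDES selection score of an added node set
#'
#' Scores the subgraph `X_n` extended with `added` against the complete
#' graph, normalized by the maximal score obtained when every candidate
#' node is added (which by construction scores 1). When the maximal score
#' is not positive, normalization is undefined and the raw score is
#' returned with attribute `normalized = FALSE`.
#'
#' @param subgraph_nodes nodes of `X_n`.
#' @param added candidate nodes to add (subset of the full graph's nodes
#'   minus `subgraph_nodes`).
#' @param full_graph the complete graph.
#' @param model a weight model (see [parse_weight_model()]).
#' @inheritParams path_length
#' @return a number; attribute `raw` carries the unscaled score,
#'   attribute `normalized` says whether scaling was applied.
#' @export
normalized_score <- function(subgraph_nodes, added, full_graph, model,
                             mode = c("hops", "weighted")) {
  mode <- match.arg(mode)
  model <- parse_weight_model(model)
  cand <- setdiff(vertex_ids(full_graph), subgraph_nodes)
  if (!all(added %in% cand))
    stop("'added' must be candidate nodes (outside the subgraph)")
  raw <- raw_score(subgraph_nodes, added, full_graph, model, mode)
  mx <- raw_score(subgraph_nodes, cand, full_graph, model, mode)
  if (mx > 0) structure(raw / mx, raw = raw, max = mx, normalized = TRUE)
  else structure(raw, raw = raw, max = mx, normalized = FALSE)
}

raw_score <- function(subgraph_nodes, added, full_graph, model, mode) {
  g <- igraph::induced_subgraph(full_graph, c(subgraph_nodes, added))
  brides_score(classify_pairs(subgraph_nodes, g, mode = mode), model)
}

#' Stepwise BRIDES node selection
#'
#' Breadth-first greedy selection with tie branching: starting from the
#' empty added set, every frontier set is extended by each remaining
#' candidate, all extensions achieving the step's maximum normalized
#' score are kept, and branches reaching score 1 terminate. The first
#' depth at which any branch terminates is the minimal number of added
#' nodes; all distinct terminated sets of that size are reported as
#' co-optimal solutions. When no candidate can ever produce a positive
#' score the run is flagged `no_solution` (no node is worth adding).
#'
#' @inheritParams normalized_score
#' @param subgraph_nodes nodes of the starting subgraph `X_n`.
#' @param tol tolerance for "reached score 1".
#' @param max_steps safety cap on depth (default: number of candidates).
#' @return an object of class `brides_selection`: list with `solutions`
#'   (list of character vectors), `n_added`, `n_solutions`, `max_raw`
#'   (score with all candidates added), `steps` (per-depth trace:
#'   best normalized score and surviving sets), `no_solution`, plus the
#'   inputs (`model`, `mode`).
#' @export
stepwise_select <- function(subgraph_nodes, full_graph, model,
                            mode = c("hops", "weighted"), tol = 1e-9,
                            max_steps = NULL) {
  mode <- match.arg(mode)
  model <- parse_weight_model(model)
  subgraph_nodes <- as.character(subgraph_nodes)
  check_nodes(full_graph, subgraph_nodes)
  cand <- setdiff(vertex_ids(full_graph), subgraph_nodes)
  if (length(cand) == 0L) stop("no candidate nodes: subgraph is the full graph")
  if (is.null(max_steps)) max_steps <- length(cand)
  mx <- raw_score(subgraph_nodes, cand, full_graph, model, mode)

  result <- list(model = model, mode = mode, max_raw = mx,
                 subgraph_nodes = subgraph_nodes, candidates = cand)
  if (mx <= 0) {
    # normalization undefined; nothing can reach a positive maximal score
    result$no_solution <- TRUE
    result$solutions <- list()
    result$n_added <- NA_integer_
    result$n_solutions <- 0L
    result$steps <- list()
    class(result) <- "brides_selection"
    return(result)
  }

  frontier <- list(character(0))
  steps <- list()
  solutions <- list()
  for (depth in seq_len(max_steps)) {
    sets <- list()
    for (A in frontier) for (cnd in setdiff(cand, A))
      sets[[length(sets) + 1L]] <- sort(c(A, cnd))
    sets <- unique(sets)
    scores <- vapply(sets, function(A)
      raw_score(subgraph_nodes, A, full_graph, model, mode) / mx, numeric(1))
    best <- max(scores)
    keep <- which(scores >= best - tol * max(1, abs(best)))
    frontier <- sets[keep]
    steps[[depth]] <- list(depth = depth, score = best, sets = frontier)
    if (best >= 1 - tol) {
      solutions <- frontier
      break
    }
  }
  result$no_solution <- length(solutions) == 0L
  result$solutions <- solutions
  result$n_added <- if (length(solutions)) length(solutions[[1]]) else NA_integer_
  result$n_solutions <- length(solutions)
  result$steps <- steps
  class(result) <- "brides_selection"
  result
}

#' @export
print.brides_selection <- function(x, ...) {
  cat(sprintf("BRIDES selection (%s, %s mode)\n",
              format_weight_model(x$model), x$mode))
  if (x$no_solution) {
    cat("no solution: no candidate node improves the score\n")
  } else {
    cat(sprintf("minimal added nodes: %d; co-optimal solutions: %d\n",
                x$n_added, x$n_solutions))
    for (s in x$solutions)
      cat("  {", paste(s, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Selection frequency of each node over scenarios and models
#'
#' Runs [stepwise_select()] for every scenario x model combination and,
#' for each node, reports the fraction of runs in which it appeared in at
#' least one co-optimal solution, out of the runs in which it was a
#' candidate (i.e. outside the scenario subgraph). Runs with no solution
#' count in the denominator. Nodes that are never candidates get `NA`.
#'
#' @param full_graph the complete population graph.
#' @param attributes population attribute table.
#' @param scenarios list of [scenario()]s (default [standard_scenarios()]).
#' @param models list of weight models (default the five standard ones:
#'   S1, B3S1, B1S3, B1R-1D-1S1, B3D1E2S3).
#' @inheritParams path_length
#' @return data.frame with columns `Id`, `n_candidate`, `n_selected`,
#'   `frequency`, plus a `runs` attribute with the per-run results.
#' @export
selection_frequency <- function(full_graph, attributes,
                                scenarios = standard_scenarios(),
                                models = standard_models(),
                                mode = c("hops", "weighted")) {
  mode <- match.arg(mode)
  if (length(scenarios) == 0L || length(models) == 0L)
    stop("need at least one scenario and one model")
  ids <- vertex_ids(full_graph)
  n_cand <- n_sel <- stats::setNames(integer(length(ids)), ids)
  runs <- list()
  for (si in seq_along(scenarios)) {
    sub <- build_scenario_subgraph(attributes, scenarios[[si]],
                                   graph = full_graph)
    cand <- setdiff(ids, sub)
    if (length(cand) == 0L) next
    for (mi in seq_along(models)) {
      sel <- stepwise_select(sub, full_graph, models[[mi]], mode = mode)
      n_cand[cand] <- n_cand[cand] + 1L
      chosen <- unique(unlist(sel$solutions))
      n_sel[chosen] <- n_sel[chosen] + 1L
      runs[[length(runs) + 1L]] <-
        list(scenario = names(scenarios)[si] %||% si,
             model = names(models)[mi] %||% format_weight_model(models[[mi]]),
             selection = sel)
    }
  }
  out <- data.frame(Id = ids, n_candidate = as.integer(n_cand),
                    n_selected = as.integer(n_sel),
                    frequency = ifelse(n_cand > 0, n_sel / n_cand, NA_real_),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "runs") <- runs
  out
}

#' The five standard weight models
#'
#' `S1` (shortcuts only), `B3S1` and `B1S3` (breakthroughs and shortcuts,
#' contrasting weights), `B1R-1D-1S1` (penalizing roadblocks and detours)
#' and `B3D1E2S3` (all connectivity-increasing path types).
#'
#' @return named list of five [weight_model()]s.
#' @export
standard_models <- function() {
  list(`S1` = parse_weight_model("S1"),
       `B3S1` = parse_weight_model("B3S1"),
       `B1S3` = parse_weight_model("B1S3"),
       `B1R-1D-1S1` = parse_weight_model("B1R-1D-1S1"),
       `B3D1E2S3` = parse_weight_model("B3D1E2S3"))
}

#' Kendall correlation between model complexity and selection effort
#'
#' Tau-b (with tie corrections) between the complexity of the weight model
#' and the minimal number of nodes each run needed, with a normal-
#' approximation p-value. Runs with no solution are excluded.
#'
#' @param complexity integer vector of model complexities.
#' @param n_nodes integer vector of minimal node counts (`NA` = no
#'   solution, dropped).
#' @return list with `tau` and `p_value`.
#' @export
complexity_node_correlation <- function(complexity, n_nodes) {
  keep <- !is.na(n_nodes) & !is.na(complexity)
  x <- complexity[keep]; y <- n_nodes[keep]
  if (length(x) < 2L) stop("need at least 2 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("Kendall tau undefined: all values tied in one variable")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
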