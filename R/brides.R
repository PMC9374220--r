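#' Shortest-path length between two nodes
#'
#' @param graph an igraph object.
#' @param u,v node names (or indices for unnamed graphs).
#' @param mode `"hops"` (unweighted, default) or `"weighted"` (sum of
#'   `weight` attributes).
#' @return the shortest-path length; `Inf` if no path; 0 iff `u == v`.
#' @export
path_length <- function(graph, u, v, mode = c("hops", "weighted")) {
  mode <- match.arg(mode)
  check_nodes(graph, c(u, v))
  w <- if (mode == "weighted") igraph::E(graph)$weight else NA
  as.numeric(igraph::distances(graph, v = u, to = v, weights = w))
}

#' Shortest path length constrained through a required node set
#'
#' Length of the shortest route from `u` to `v` that visits at least one
#' node of `K`, computed as `min_k d(u,k) + d(k,v)`. With non-negative
#' weights this is the canonical constrained length; the realized route is
#' a walk and may revisit nodes. `Inf` when `K` is empty or no member of
#' `K` is reachable from both endpoints.
#'
#' @param graph an igraph object.
#' @param u,v node names; must not belong to `K`.
#' @param K required node set (candidate nodes).
#' @inheritParams path_length
#' @return the constrained length, or `Inf`.
#' @export
constrained_path_length <- function(graph, u, v, K,
                                    mode = c("hops", "weighted")) {
  mode <- match.arg(mode)
  check_nodes(graph, c(u, v, K))
  if (length(K) == 0L) return(Inf)
  if (any(c(u, v) %in% K)) stop("'K' must not contain 'u' or 'v'")
  w <- if (mode == "weighted") igraph::E(graph)$weight else NA
  d <- igraph::distances(graph, v = c(u, v), to = K, weights = w)
  min(d[1, ] + d[2, ])
}

#' Classify subgraph node pairs into the six BRIDES path types
#'
#' For every unordered pair of `subgraph_nodes`, compares the shortest
#' path inside the induced subgraph `X_n` with the shortest path in the
#' full graph `X_all` constrained to pass through at least one candidate
#' node (a node of `X_all` absent from `X_n`):
#' \describe{
#'   \item{B (breakthrough)}{impossible in `X_n`, possible in `X_all`}
#'   \item{R (roadblock)}{possible in `X_n`, impossible in `X_all`}
#'   \item{I (impasse)}{impossible in both}
#'   \item{D (detour)}{shorter in `X_n` than in `X_all`}
#'   \item{E (equal)}{same length in both}
#'   \item{S (shortcut)}{longer in `X_n` than in `X_all`}
#' }
#' In weighted mode, lengths within relative tolerance `tol` are treated
#' as equal to avoid spurious detours/shortcuts from floating-point noise.
#'
#' @param subgraph_nodes node names forming `X_n` (subset of the full
#'   graph's nodes).
#' @param full_graph the complete graph `X_all` (igraph).
#' @inheritParams path_length
#' @param tol relative tolerance for length equality in weighted mode.
#' @return an object of class `brides`: list with `counts` (named numeric
#'   B, R, I, D, E, S), `pairs` (per-pair detail: `u`, `v`, `d_sub`,
#'   `d_constrained`, `type`), `mode`.
#' @export
classify_pairs <- function(subgraph_nodes, full_graph,
                           mode = c("hops", "weighted"), tol = 1e-9) {
  mode <- match.arg(mode)
  ids <- vertex_ids(full_graph)
  subgraph_nodes <- as.character(subgraph_nodes)
  if (!all(subgraph_nodes %in% ids))
    stop("subgraph nodes not in full graph: ",
         paste(setdiff(subgraph_nodes, ids), collapse = ", "))
  subgraph_nodes <- unique(subgraph_nodes)
  n <- length(subgraph_nodes)
  K <- setdiff(ids, subgraph_nodes)
  w_full <- if (mode == "weighted") igraph::E(full_graph)$weight else NA
  sub <- igraph::induced_subgraph(full_graph, subgraph_nodes)
  w_sub <- if (mode == "weighted") igraph::E(sub)$weight else NA

  d_sub_m <- igraph::distances(sub, v = subgraph_nodes, to = subgraph_nodes,
                               weights = w_sub)
  if (length(K)) {
    d_uk <- igraph::distances(full_graph, v = subgraph_nodes, to = K,
                              weights = w_full)
  }
  counts <- stats::setNames(numeric(6), c("B", "R", "I", "D", "E", "S"))
  rows <- list()
  if (n >= 2L) {
    idx <- utils::combn(n, 2)
    for (c_i in seq_len(ncol(idx))) {
      i <- idx[1, c_i]; j <- idx[2, c_i]
      d_n <- d_sub_m[i, j]
      d_c <- if (length(K)) min(d_uk[i, ] + d_uk[j, ]) else Inf
      type <- classify_one(d_n, d_c, tol)
      counts[type] <- counts[type] + 1
      rows[[c_i]] <- data.frame(u = subgraph_nodes[i], v = subgraph_nodes[j],
                                d_sub = d_n, d_constrained = d_c,
                                type = type, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(u = character(), v = character(), d_sub = numeric(),
               d_constrained = numeric(), type = character(),
               stringsAsFactors = FALSE)
  structure(list(counts = counts, pairs = pairs, mode = mode,
                 n_subgraph = n, n_candidates = length(K)),
            class = "brides")
}

classify_one <- function(d_n, d_c, tol) {
  if (is.infinite(d_n) && is.infinite(d_c)) return("I")
  if (is.infinite(d_n)) return("B")
  if (is.infinite(d_c)) return("R")
  if (abs(d_n - d_c) <= tol * max(d_n, d_c)) return("E")
  if (d_n < d_c) "D" else "S"
}

#' @export
print.brides <- function(x, ...) {
  cat("BRIDES vector [B, R, I, D, E, S]: [",
      paste(x$counts, collapse = ", "), "]\n", sep = "")
  cat(sprintf("subgraph: %d nodes, %d candidate nodes, %s mode\n",
              x$n_subgraph, x$n_candidates, x$mode))
  invisible(x)
}

#' Score a BRIDES vector under a weight model
#'
#' The selection score is the weighted sum of the six path-type counts:
#' `w_B*B + w_R*R + w_I*I + w_D*D + w_E*E + w_S*S`.
#'
#' @param vector a `brides` object from [classify_pairs()], or a named (or
#'   B,R,I,D,E,S-ordered) numeric vector of six counts.
#' @param model a [weight_model()], or anything [parse_weight_model()]
#'   accepts.
#' @return a single number.
#' @export
brides_score <- function(vector, model) {
  counts <- if (inherits(vector, "brides")) vector$counts else {
    v <- as.numeric(vector)
    if (length(v) != 6L) stop("a BRIDES vector has exactly 6 counts")
    stats::setNames(v, c("B", "R", "I", "D", "E", "S"))
  }
  model <- parse_weight_model(model)
  sum(unclass(model) * counts)
}

#' Weight models for BRIDES scoring
#'
#' A weight model assigns a signed real weight to each of the six path
#' types; positive weights mark preferred path types, negative weights
#' penalized ones, and zeros are ignored. The display notation writes
#' positive weights as superscripts and negative ones as subscripts, e.g.
#' `B^3^S^1^` for `(3, 0, 0, 0, 0, 1)`.
#'
#' @param B,R,I,D,E,S the six weights.
#' @return an object of class `weight_model` (named numeric of length 6).
#' @export
weight_model <- function(B = 0, R = 0, I = 0, D = 0, E = 0, S = 0) {
  w <- c(B = as.numeric(B)[1], R = as.numeric(R)[1], I = as.numeric(I)[1],
         D = as.numeric(D)[1], E = as.numeric(E)[1], S = as.numeric(S)[1])
  if (!is.numeric(w) || length(w) != 6L || anyNA(w))
    stop("weights must be six non-missing numbers")
  if (all(w == 0)) stop("at least one weight must be nonzero")
  structure(w, class = "weight_model")
}

#' Parse a weight-model string
#'
#' Accepts compact letter+integer notation (`"B3D1E2S3"`, `"B1R-1D-1S1"`;
#' unlisted letters get weight 0), a numeric 6-vector, or an existing
#' `weight_model`.
#'
#' @param text model specification.
#' @return a [weight_model()].
#' @export
parse_weight_model <- function(text) {
  if (inherits(text, "weight_model")) return(text)
  if (is.numeric(text)) {
    if (length(text) != 6L) stop("numeric weight model must have length 6")
    return(weight_model(text[1], text[2], text[3], text[4], text[5], text[6]))
  }
  s <- gsub("[[:space:]]", "", as.character(text))
  m <- gregexpr("[BRIDES]-?[0-9]+", s)[[1]]
  toks <- regmatches(s, gregexpr("[BRIDES]-?[0-9]+", s))[[1]]
  if (length(toks) == 0L || sum(nchar(toks)) != nchar(s))
    stop("cannot parse weight model: ", text)
  letters_ <- substr(toks, 1, 1)
  if (anyDuplicated(letters_))
    stop("repeated path-type letter in weight model: ", text)
  w <- stats::setNames(numeric(6), c("B", "R", "I", "D", "E", "S"))
  w[letters_] <- as.numeric(substring(toks, 2))
  weight_model(w["B"], w["R"], w["I"], w["D"], w["E"], w["S"])
}

#' @export
print.weight_model <- function(x, ...) {
  cat("weight model:", format_weight_model(x), "(",
      paste(unclass(x), collapse = ", "), ")\n")
  invisible(x)
}

#' Display notation for a weight model
#' @param model a [weight_model()].
#' @return character scalar like `"B^3^S^1^"` (subscripts written `B_1_`).
#' @export
format_weight_model <- function(model) {
  model <- parse_weight_model(model)
  parts <- character(0)
  for (l in names(unclass(model))) {
    w <- unclass(model)[[l]]
    if (w > 0) parts <- c(parts, paste0(l, "^", w, "^"))
    else if (w < 0) parts <- c(parts, paste0(l, "_", abs(w), "_"))
  }
  paste(parts, collapse = "")
}

#' Model complexity
#'
#' The number of nonzero weights in a model; more complex models admit
#' more path types into the score.
#'
#' @param model a [weight_model()] or parseable specification.
#' @return integer in 1..6.
#' @export
model_complexity <- function(model) {
  model <- parse_weight_model(model)
  sum(unclass(model) != 0)
}

check_nodes <- function(graph, nodes) {
  ids <- vertex_ids(graph)
  bad <- setdiff(as.character(nodes), ids)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
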