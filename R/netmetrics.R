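#' Node centralities on the unweighted topology
#'
#' Degree (DC), unnormalized betweenness with fractional counting over
#' multiple shortest paths (BC), eigenvector centrality scaled so the
#' maximum entry is 1 (EC), and the local clustering coefficient (CC).
#' All four are computed on the unweighted topology: edge weights on a
#' population graph are distances, and hop-count centralities are the
#' convention for these conservation summaries; weighted shortest-path
#' variants of BC are available via `weighted = TRUE`.
#'
#' @param graph an igraph object.
#' @param weighted use edge weights as distances for BC (default `FALSE`).
#' @param cc_undefined value reported for the clustering coefficient of
#'   nodes with degree < 2: `"zero"` (default) or `"na"`.
#' @return data.frame with columns `Id`, `DC`, `BC`, `EC`, `CC`.
#' @export
node_centralities <- function(graph, weighted = FALSE,
                              cc_undefined = c("zero", "na")) {
  cc_undefined <- match.arg(cc_undefined)
  if (igraph::gorder(graph) == 0L) stop("graph is empty")
  if (!igraph::is_connected(graph))
    warning("graph is disconnected; betweenness computed per component")
  bw <- if (weighted) igraph::E(graph)$weight else NA
  dc <- igraph::degree(graph)
  bc <- igraph::betweenness(graph, directed = FALSE, weights = bw,
                            normalized = FALSE)
  ec <- igraph::eigen_centrality(graph, weights = NA)$vector
  cc <- igraph::transitivity(graph, type = "local", isolates = "NaN")
  if (cc_undefined == "zero") cc[!is.finite(cc)] <- 0
  else cc[!is.finite(cc)] <- NA_real_
  data.frame(Id = vertex_ids(graph), DC = as.integer(dc), BC = bc,
             EC = ec, CC = cc, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-node strength and average inverse edge weight
#'
#' Strength is the sum of incident edge weights; AIEW is the mean of the
#' inverse incident weights, a proxy for the number of migrants to and
#' from the node. Isolated nodes get strength 0 and `NA` AIEW.
#'
#' @param graph an igraph object with positive `weight`s.
#' @return data.frame with columns `Id`, `strength`, `AIEW`.
#' @export
edge_weight_stats <- function(graph) {
  w <- igraph::E(graph)$weight
  if (is.null(w)) stop("graph has no 'weight' edge attribute")
  if (any(w <= 0)) stop("edge weights must be strictly positive")
  ids <- vertex_ids(graph)
  strength <- igraph::strength(graph, weights = w)
  aiew <- vapply(seq_len(igraph::gorder(graph)), function(v) {
    inc <- igraph::incident(graph, v)
    if (length(inc) == 0L) return(NA_real_)
    mean(1 / w[as.integer(inc)])
  }, numeric(1))
  data.frame(Id = ids, strength = as.numeric(strength), AIEW = aiew,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average path length (unweighted)
#'
#' Mean shortest-path hop count over unordered node pairs. For a
#' disconnected graph the default is the mean over reachable pairs (with a
#' warning), which is what post-removal graphs need; `disconnected = "inf"`
#' returns `Inf` instead. `NA` when no pair is reachable.
#'
#' @param graph an igraph object.
#' @param disconnected `"reachable"` (default) or `"inf"`.
#' @return a single number.
#' @export
average_path_length <- function(graph, disconnected = c("reachable", "inf")) {
  disconnected <- match.arg(disconnected)
  n <- igraph::gorder(graph)
  if (n < 2L) return(NA_real_)
  if (!igraph::is_connected(graph)) {
    if (disconnected == "inf") return(Inf)
    warning("graph is disconnected; averaging over reachable pairs")
  }
  d <- igraph::distances(graph, weights = NA)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (length(d) == 0L) return(NA_real_)
  mean(d)
}

#' Node-removal impact on average path length
#'
#' Simulates local extirpation: each node is deleted in turn (with its
#' incident edges) and the average path length of the remainder is
#' recomputed. Larger increases mark nodes more important for network
#' connectivity; removals that disconnect the remainder are flagged.
#'
#' @param graph an igraph object with at least 3 nodes.
#' @return data.frame with columns `Id`, `APL` (after removing that node),
#'   `delta_APL` (APL minus the full-graph APL), `disconnects`.
#' @export
node_removal_impact <- function(graph) {
  n <- igraph::gorder(graph)
  if (n < 3L) stop("need at least 3 nodes")
  base <- suppressWarnings(average_path_length(graph))
  ids <- vertex_ids(graph)
  res <- lapply(seq_len(n), function(v) {
    g2 <- igraph::delete_vertices(graph, v)
    apl <- suppressWarnings(average_path_length(g2))
    data.frame(Id = ids[v], APL = apl, delta_APL = apl - base,
               disconnects = !igraph::is_connected(g2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cut nodes (articulation points)
#'
#' Nodes whose deletion, together with their incident edges, disconnects
#' the graph (increases the number of components).
#'
#' @param graph an igraph object.
#' @return character (or integer, for unnamed graphs) vector of node ids.
#' @export
articulation_nodes <- function(graph) {
  ap <- igraph::articulation_points(graph)
  vertex_ids(graph)[as.integer(ap)]
}

#' Full node-metric table
#'
#' One row per node with degree, betweenness, eigenvector centrality,
#' clustering coefficient, strength, average inverse edge weight, the
#' average path length after removing the node, and whether it is a cut
#' node — the standard per-population connectivity summary.
#'
#' @inheritParams node_centralities
#' @return data.frame with columns `Id`, `BC`, `DC`, `EC`, `strength`,
#'   `AIEW`, `CC`, `APL`, `cut_node`.
#' @export
node_metrics <- function(graph, weighted = FALSE) {
  cent <- node_centralities(graph, weighted = weighted)
  ws <- edge_weight_stats(graph)
  rem <- node_removal_impact(graph)
  cut <- vertex_ids(graph) %in% articulation_nodes(graph)
  data.frame(Id = cent$Id, BC = cent$BC, DC = cent$DC, EC = cent$EC,
             strength = ws$strength, AIEW = ws$AIEW, CC = cent$CC,
             APL = rem$APL, cut_node = cut,
             row.names = NULL, stringsAsFactors = FALSE)
}

vertex_ids <- function(graph) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) as.character(seq_len(igraph::gorder(graph))) else nm
}
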