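# Brute-force oracles built on exhaustive simple-path enumeration.
# Deliberately independent of the shortest-path/betweenness code paths the
# package uses: only feasible for tiny graphs.

path_weight <- function(g, p) {
  ids <- as.integer(p)
  if (length(ids) < 2) return(0)
  ep <- c(rbind(ids[-length(ids)], ids[-1]))
  sum(igraph::E(g)$weight[igraph::get_edge_ids(g, ep)])
}

brute_shortest <- function(g, u, v, mode = "hops") {
  iu <- match(u, igraph::V(g)$name)
  iv <- match(v, igraph::V(g)$name)
  if (is.na(iu)) iu <- as.integer(u)
  if (is.na(iv)) iv <- as.integer(v)
  if (iu == iv) return(0)
  ps <- suppressWarnings(igraph::all_simple_paths(g, from = iu, to = iv))
  if (!length(ps)) return(Inf)
  lens <- vapply(ps, function(p) {
    if (mode == "hops") length(p) - 1 else path_weight(g, p)
  }, numeric(1))
  min(lens)
}

brute_constrained <- function(g, u, v, K, mode = "hops") {
  if (!length(K)) return(Inf)
  min(vapply(K, function(k)
    brute_shortest(g, u, k, mode) + brute_shortest(g, k, v, mode),
    numeric(1)))
}

# Fractional-counting betweenness from enumerated shortest paths (hops).
brute_betweenness <- function(g) {
  n <- igraph::gorder(g)
  bc <- numeric(n)
  if (n < 3) return(bc)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- suppressWarnings(igraph::all_simple_paths(g, from = s, to = t))
    if (!length(ps)) next
    lens <- lengths(ps) - 1
    sp <- ps[lens == min(lens)]
    inner <- lapply(sp, function(p) setdiff(as.integer(p), c(s, t)))
    tab <- table(unlist(inner))
    if (length(tab)) {
      idx <- as.integer(names(tab))
      bc[idx] <- bc[idx] + as.numeric(tab) / length(sp)
    }
  }
  bc
}

brute_articulation <- function(g) {
  base <- igraph::count_components(g)
  ids <- seq_len(igraph::gorder(g))
  hit <- vapply(ids, function(v)
    igraph::count_components(igraph::delete_vertices(g, v)) > base,
    logical(1))
  nm <- igraph::V(g)$name
  if (is.null(nm)) as.character(ids[hit]) else nm[hit]
}

brute_apl <- function(g) {
  n <- igraph::gorder(g)
  if (n < 2) return(NA_real_)
  d <- c()
  for (s in 1:(n - 1)) for (t in (s + 1):n)
    d <- c(d, brute_shortest(g, s, t, "hops"))
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

# Smallest added-node subset reaching normalized score 1, by full subset
# enumeration over the candidate set.
exhaustive_min_solution <- function(sub, g, model, mode = "hops", tol = 1e-9) {
  cand <- setdiff(igraph::V(g)$name, sub)
  mx <- brides_score(classify_pairs(sub, g, mode = mode), model)
  if (mx <= 0) return(NA_integer_)
  for (k in 0:length(cand)) {
    for (A in if (k == 0) list(character(0)) else
         asplit(utils::combn(cand, k), 2)) {
      gi <- igraph::induced_subgraph(g, c(sub, as.character(A)))
      sc <- brides_score(classify_pairs(sub, gi, mode = mode), model)
      if (sc / mx >= 1 - tol) return(k)
    }
  }
  NA_integer_
}

rand_connected <- function(n, seed, density = 0.45) {
  random_weighted_graph(n, density = density, seed = seed, connected = TRUE,
                        weight_range = c(0.5, 5))
}
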