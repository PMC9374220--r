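#' Simulate multiallelic diploid genotypes under Dirichlet drift
#'
#' Generates the kind of data the pipeline consumes: diploid multilocus
#' genotypes for several populations. Per locus, ancestral allele
#' frequencies are drawn from a symmetric Dirichlet(1); each population's
#' frequencies drift from them via a Dirichlet with concentration
#' `ancestral * (1 - F) / F`, so larger `F` means more drift (more
#' among-population divergence). Migration then mixes population
#' frequencies linearly:
#' \describe{
#'   \item{island}{`p = (1 - 2m) p_pop + 2m p_ancestral`, `m` in
#'     `[0, 0.5]`; `m = 0.5` (every gene copy equally likely a migrant)
#'     gives exact panmixia.}
#'   \item{two_clusters}{populations are split into two equal clusters
#'     whose mean frequencies drift independently; each population mixes
#'     toward its cluster mean with weight `2*m_within` and toward the
#'     ancestral pool with weight `2*m_between`. Small `m_between` yields
#'     two weakly connected shores.}
#' }
#' Genotypes are two independent allele draws per individual and locus.
#'
#' @param n_pops number of populations (even for `two_clusters`).
#' @param n_ind individuals per population.
#' @param n_loci number of loci.
#' @param n_alleles alleles per locus.
#' @param F drift parameter in (0, 1); default 0.2 — moderate
#'   microsatellite-scale differentiation.
#' @param migration `"island"` or `"two_clusters"`.
#' @param m island migration rate in `[0, 0.5]`.
#' @param m_within,m_between two-cluster migration rates in `[0, 0.5]`.
#' @param missing_rate fraction of genotypes set missing at random.
#' @param seed integer seed; the output is fully reproducible from it.
#' @return a [genotype_table()] with populations `P1..Pk`; the cluster
#'   assignment (for `two_clusters`) is attached as attribute `clusters`.
#' @export
simulate_genotypes <- function(n_pops = 6, n_ind = 25, n_loci = 9,
                               n_alleles = 8, F = 0.2,
                               migration = c("island", "two_clusters"),
                               m = 0.01, m_within = 0.05, m_between = 0.005,
                               missing_rate = 0, seed = 1) {
  migration <- match.arg(migration)
  stopifnot(n_pops >= 2, n_ind >= 1, n_loci >= 1, n_alleles >= 2,
            F > 0, F < 1, missing_rate >= 0, missing_rate < 1)
  check_rate <- function(x, nm) if (x < 0 || x > 0.5)
    stop("'", nm, "' must lie in [0, 0.5]")
  check_rate(m, "m"); check_rate(m_within, "m_within")
  check_rate(m_between, "m_between")
  if (migration == "two_clusters" && n_pops %% 2 != 0)
    stop("'two_clusters' needs an even number of populations")
  set.seed(seed)

  pops <- paste0("P", seq_len(n_pops))
  clusters <- if (migration == "two_clusters")
    rep(1:2, each = n_pops %/% 2) else rep(1L, n_pops)
  n_total <- n_pops * n_ind
  a1 <- a2 <- matrix(NA_integer_, n_total, n_loci)
  pop_of <- rep(pops, each = n_ind)
  conc <- (1 - F) / F

  for (j in seq_len(n_loci)) {
    anc <- rdirichlet(1, rep(1, n_alleles))[1, ]
    if (migration == "island") {
      pf <- rdirichlet(n_pops, anc * conc)
      pf <- (1 - 2 * m) * pf +
        2 * m * matrix(anc, n_pops, n_alleles, byrow = TRUE)
    } else {
      cf <- rdirichlet(2, anc * conc)             # cluster-level drift
      pf <- matrix(0, n_pops, n_alleles)
      for (p in seq_len(n_pops))
        pf[p, ] <- rdirichlet(1, cf[clusters[p], ] * conc)[1, ]
      w0 <- 1 - 2 * m_within - 2 * m_between
      if (w0 < 0) stop("m_within + m_between must not exceed 0.5")
      pf <- w0 * pf + 2 * m_within * cf[clusters, , drop = FALSE] +
        2 * m_between * matrix(anc, n_pops, n_alleles, byrow = TRUE)
    }
    for (p in seq_len(n_pops)) {
      rows <- which(pop_of == pops[p])
      a1[rows, j] <- sample.int(n_alleles, n_ind, replace = TRUE, prob = pf[p, ])
      a2[rows, j] <- sample.int(n_alleles, n_ind, replace = TRUE, prob = pf[p, ])
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n_total * n_loci) < missing_rate,
                   n_total, n_loci)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  tbl <- genotype_table(sprintf("ind%03d", seq_len(n_total)), pop_of,
                        sprintf("loc%d", seq_len(n_loci)), a1, a2)
  attr(tbl, "clusters") <- stats::setNames(clusters, pops)
  tbl
}

# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sw <- rowSums(x)
  sw[sw == 0] <- 1   # guard against all-zero draws at tiny concentrations
  x / sw
}

#' Random weighted undirected graph
#'
#' Erdős–Rényi G(n, M)-style sampling with the edge count set by
#' `density`, uniform edge weights, and optional rejection sampling until
#' the graph is connected.
#'
#' @param n number of nodes.
#' @param density fraction of the `n(n-1)/2` possible edges, in (0, 1].
#' @param weight_range length-2 positive range for uniform edge weights.
#' @param seed integer seed.
#' @param connected rejection-sample until connected (up to `retries`).
#' @param retries attempts before giving up when `connected = TRUE`.
#' @return an igraph with nodes `n1..nN` and a `weight` edge attribute.
#' @export
random_weighted_graph <- function(n, density = 0.4, weight_range = c(1, 10),
                                  seed = 1, connected = FALSE,
                                  retries = 200) {
  stopifnot(n >= 2, density > 0, density <= 1,
            length(weight_range) == 2, all(weight_range > 0))
  set.seed(seed)
  m_edges <- max(1L, round(density * n * (n - 1) / 2))
  for (i in seq_len(retries)) {
    g <- igraph::sample_gnm(n, m_edges, directed = FALSE)
    if (!connected || igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("n", seq_len(n))
      igraph::E(g)$weight <- stats::runif(m_edges, weight_range[1],
                                          weight_range[2])
      return(g)
    }
  }
  stop("could not sample a connected graph in ", retries, " attempts")
}

#' Deterministic toy graphs with known BRIDES behaviour
#'
#' Small named fixtures used throughout the tests and examples:
#' \describe{
#'   \item{star4}{a star with center `k` and leaves `u1..u3`; with the
#'     leaves as subgraph all three pairs are breakthroughs:
#'     vector (3,0,0,0,0,0).}
#'   \item{tri_iso}{a triangle `a,b,c` plus an isolated node `z`; with the
#'     triangle as subgraph all three pairs are roadblocks:
#'     (0,3,0,0,0,0).}
#'   \item{two_cluster}{two triangles joined by a single bridge node
#'     `br`, which is the unique articulation point.}
#'   \item{bridge11}{an 11-node selection example: the subgraph
#'     `u1..u8` falls into two components, and of the three candidate
#'     nodes only `c1` bridges them, so `c1` alone reaches normalized
#'     score 1 under breakthrough-rewarding models.}
#' }
#' Each element carries attributes `subgraph` (the conventional `X_n`
#' node set) and, where meaningful, `expected_counts`.
#'
#' @return named list of igraph objects, all edge weights 1.
#' @export
fixture_toy_graphs <- function() {
  mk <- function(edges, nodes = NULL) {
    g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                     directed = FALSE)
    if (!is.null(nodes))
      g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
    igraph::E(g)$weight <- 1
    g
  }
  star4 <- mk(c("k", "u1", "k", "u2", "k", "u3"))
  attr(star4, "subgraph") <- c("u1", "u2", "u3")
  attr(star4, "expected_counts") <- c(B = 3, R = 0, I = 0, D = 0, E = 0, S = 0)

  tri_iso <- mk(c("a", "b", "b", "c", "a", "c"), nodes = "z")
  attr(tri_iso, "subgraph") <- c("a", "b", "c")
  attr(tri_iso, "expected_counts") <- c(B = 0, R = 3, I = 0, D = 0, E = 0, S = 0)

  two_cluster <- mk(c("a1", "a2", "a2", "a3", "a1", "a3",
                      "b1", "b2", "b2", "b3", "b1", "b3",
                      "a1", "br", "br", "b1"))
  attr(two_cluster, "subgraph") <- c("a1", "a2", "a3", "b1", "b2", "b3")

  # Two chains u1-u2-u3-u4 and u5-u6-u7-u8; c1 bridges u4 and u5,
  # c2 and c3 are pendants attached inside one chain each.
  bridge11 <- mk(c("u1", "u2", "u2", "u3", "u3", "u4",
                   "u5", "u6", "u6", "u7", "u7", "u8",
                   "u4", "c1", "c1", "u5",
                   "u2", "c2", "u7", "c3"))
  attr(bridge11, "subgraph") <- paste0("u", 1:8)

  list(star4 = star4, tri_iso = tri_iso, two_cluster = two_cluster,
       bridge11 = bridge11)
}
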