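#' Encode genotypes as an individual x allele-count matrix
#'
#' Each observed (locus, allele) pair becomes one column; the entry is the
#' number of copies (0, 1, 2) of that allele in the individual's genotype.
#' Missing genotypes are either mean-imputed (the grand mean allele count
#' over typed individuals, keeping every individual usable) or the whole
#' individual is dropped.
#'
#' @param table a [genotype_table()].
#' @param missing `"mean_impute"` (default) or `"drop_individual"`.
#' @return numeric matrix with rownames = individuals and an attribute
#'   `populations` giving the (possibly reduced) population labels.
#' @export
encode_genotypes <- function(table,
                             missing = c("mean_impute", "drop_individual")) {
  stopifnot(inherits(table, "genotype_table"))
  missing <- match.arg(missing)
  n <- length(table$individuals)
  keep <- rep(TRUE, n)
  if (missing == "drop_individual")
    keep <- rowSums(is.na(table$allele1)) == 0L
  cols <- list()
  for (j in seq_along(table$loci)) {
    a1 <- table$allele1[keep, j]; a2 <- table$allele2[keep, j]
    alleles <- sort(unique(c(a1, a2)))
    alleles <- alleles[!is.na(alleles)]
    for (al in alleles) {
      cnt <- (a1 == al) + (a2 == al)
      if (anyNA(cnt)) cnt[is.na(cnt)] <- mean(cnt, na.rm = TRUE)
      cols[[paste0(table$loci[j], ".", al)]] <- cnt
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- table$individuals[keep]
  attr(m, "populations") <- table$populations[keep]
  m
}

#' Among-population genetic covariance summary
#'
#' Centers the allele-count matrix to zero column means over all
#' individuals, averages rows within populations to get population
#' centroids, and forms the among-population covariance
#' `G = C C' / n_columns` from the centroid matrix `C`. The partial
#' correlations and edge-exclusion deviances derived from `G` drive graph
#' pruning, and the centroid cross-products give squared genetic distances
#' `g_ii + g_jj - 2 g_ij`.
#'
#' @param encoded matrix from [encode_genotypes()] (with its `populations`
#'   attribute), or any numeric individual x feature matrix.
#' @param populations population label per row; defaults to the matrix's
#'   `populations` attribute.
#' @return an object of class `covariance_summary`: list with `G` (k x k
#'   covariance), `pcor` (partial correlations), `eed` (edge-exclusion
#'   deviances), `n_total` (total individuals), `pops`.
#' @export
population_covariance <- function(encoded, populations = NULL) {
  if (is.null(populations)) populations <- attr(encoded, "populations")
  if (is.null(populations) || length(populations) != nrow(encoded))
    stop("need one population label per row of 'encoded'")
  pops <- unique(populations)
  k <- length(pops)
  if (k < 3L) stop("need at least 3 populations for partial correlations")
  if (any(table(populations) == 0L)) stop("population with 0 individuals")
  x <- scale(encoded, center = TRUE, scale = FALSE)
  centroids <- t(vapply(pops, function(p)
    colMeans(x[populations == p, , drop = FALSE]), numeric(ncol(x))))
  G <- tcrossprod(centroids) / ncol(x)
  dimnames(G) <- list(pops, pops)
  N <- nrow(encoded)
  pc <- partial_correlations(G)
  eed <- -N * log(pmax(1 - pc^2, .Machine$double.xmin))
  diag(eed) <- 0
  structure(list(G = G, pcor = pc, eed = eed, n_total = N, pops = pops),
            class = "covariance_summary")
}

#' @export
print.covariance_summary <- function(x, ...) {
  cat(sprintf("covariance_summary: %d populations, N = %d individuals\n",
              length(x$pops), x$n_total))
  invisible(x)
}

# Partial correlations from a covariance matrix via the precision matrix:
# r_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj). Centroid covariances of
# column-centered data are exactly rank-deficient (centroids are linearly
# dependent), so the precision is taken on the informative subspace with a
# Moore-Penrose pseudo-inverse; a plain inverse is used when the
# correlation matrix is well conditioned.
partial_correlations <- function(G) {
  R <- stats::cov2cor(G)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  Omega <- if (min(ev) > max(ev) * 1e-8) solve(R) else MASS::ginv(R)
  d <- sqrt(pmax(diag(Omega), .Machine$double.xmin))
  pc <- -Omega / outer(d, d)
  diag(pc) <- 1
  pc <- pmin(pmax(pc, -1), 1)
  dimnames(pc) <- dimnames(G)
  pc
}

#' Prune a population graph by edge-exclusion deviance
#'
#' Converts the among-population covariance to partial correlations, tests
#' each potential edge with the edge-exclusion deviance
#' `EED_ij = -N * ln(1 - r_ij^2)` against the chi-square critical value
#' with 1 degree of freedom at level `alpha`, and keeps the edges whose
#' conditional association is significant. Retained edges are weighted by
#' the genetic distance `sqrt(g_ii + g_jj - 2 g_ij)` (or its square with
#' `sqrt_weights = FALSE`).
#'
#' Rank deficiency of the centroid covariance (inherent to centering) is
#' handled by computing the precision matrix on the informative subspace
#' with a pseudo-inverse.
#'
#' @param cov a `covariance_summary` from [population_covariance()].
#' @param alpha significance level in (0, 1); default 0.05.
#' @param sqrt_weights use the square-root distance transform (default).
#' @param attributes optional data.frame (as from
#'   [read_population_attributes()]) whose rows are attached as vertex
#'   attributes by `Id`.
#' @return an igraph population graph: undirected, edge attribute `weight`
#'   (conditional genetic distance scale), graph attributes `alpha` and
#'   `n_total`.
#' @export
prune_popgraph <- function(cov, alpha = 0.05, sqrt_weights = TRUE,
                           attributes = NULL) {
  stopifnot(inherits(cov, "covariance_summary"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)")
  crit <- stats::qchisq(1 - alpha, df = 1)
  G <- cov$G
  k <- nrow(G)
  d2 <- outer(diag(G), diag(G), "+") - 2 * G     # squared distances
  d2[d2 < 0] <- 0                                 # numerical guard
  w <- if (sqrt_weights) sqrt(d2) else d2
  keep <- cov$eed > crit & upper.tri(G) & w > 0
  idx <- which(keep, arr.ind = TRUE)
  el <- cbind(cov$pops[idx[, 1]], cov$pops[idx[, 2]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- g + igraph::vertices(setdiff(cov$pops, igraph::V(g)$name))
  igraph::E(g)$weight <- w[idx]
  g <- igraph::permute(g, match(igraph::V(g)$name, cov$pops))
  g$alpha <- alpha
  g$n_total <- cov$n_total
  if (!is.null(attributes)) g <- attach_attributes(g, attributes)
  g
}

#' Build a population graph straight from genotypes
#'
#' Convenience pipeline: [encode_genotypes()] then [population_covariance()]
#' then [prune_popgraph()].
#'
#' @inheritParams encode_genotypes
#' @inheritParams prune_popgraph
#' @return an igraph population graph.
#' @export
build_popgraph <- function(table, alpha = 0.05, missing = "mean_impute",
                           sqrt_weights = TRUE, attributes = NULL) {
  enc <- encode_genotypes(table, missing = missing)
  cov <- population_covariance(enc)
  prune_popgraph(cov, alpha = alpha, sqrt_weights = sqrt_weights,
                 attributes = attributes)
}

#' Attach population attributes to graph vertices
#'
#' @param graph an igraph object whose vertex names are population ids.
#' @param attributes data.frame with an `Id` column.
#' @return the graph with one vertex attribute per attribute column.
#' @export
attach_attributes <- function(graph, attributes) {
  pos <- match(igraph::V(graph)$name, attributes$Id)
  if (anyNA(pos))
    stop("attributes missing for node(s): ",
         paste(igraph::V(graph)$name[is.na(pos)], collapse = ", "))
  for (col in setdiff(names(attributes), "Id")) {
    v <- attributes[[col]][pos]
    if (is.factor(v)) v <- as.character(v)
    graph <- igraph::set_vertex_attr(graph, col, value = v)
  }
  graph
}

#' Conditional genetic distances (all-pairs shortest paths)
#'
#' The conditional genetic distance between two populations is the
#' shortest-path distance on the pruned population graph using edge
#' weights; `Inf` for pairs in different components.
#'
#' @param graph an igraph population graph with positive `weight`s.
#' @return symmetric k x k matrix with zero diagonal.
#' @export
cgd_distances <- function(graph) {
  w <- igraph::E(graph)$weight
  if (is.null(w) || any(w <= 0)) stop("graph must have positive edge weights")
  igraph::distances(graph, weights = w)
}
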