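#' Write a population graph to disk
#'
#' Two formats are supported: `"graphml"` (single file, vertex attributes
#' embedded) and `"edgelist"` — a three-column `u v w` weighted edge list
#' plus, when the graph carries vertex attributes, a companion
#' node-attribute CSV at `<path>.nodes.csv`.
#'
#' @param graph an igraph population graph with a `weight` edge attribute.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_popgraph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(u = el[, 1], v = el[, 2],
                     w = format(igraph::E(graph)$weight, digits = 15),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    attrs <- setdiff(igraph::vertex_attr_names(graph), "name")
    nd <- data.frame(Id = igraph::V(graph)$name, stringsAsFactors = FALSE)
    for (a in attrs) nd[[a]] <- igraph::vertex_attr(graph, a)
    utils::write.csv(nd, paste0(path, ".nodes.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a population graph from disk
#'
#' Counterpart of [write_popgraph()]. For `"edgelist"`, duplicate
#' undirected edges (`u v` and `v u`) collapse to one edge; if their
#' weights differ this is an error. A companion `<path>.nodes.csv` file,
#' when present, supplies vertex attributes and may declare isolated nodes.
#'
#' @param path input file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return an undirected igraph with a `weight` edge attribute.
#' @export
read_popgraph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    return(g)
  }
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge list must have columns: u v w")
  names(df)[1:3] <- c("u", "v", "w")
  df$w <- as.numeric(df$w)
  key <- ifelse(df$u < df$v, paste(df$u, df$v), paste(df$v, df$u))
  for (k in unique(key[duplicated(key)])) {
    ws <- df$w[key == k]
    if (diff(range(ws)) > 1e-12 * max(abs(ws)))
      stop("duplicate edge ", k, " with conflicting weights")
  }
  df <- df[!duplicated(key), ]
  nodes <- unique(c(df$u, df$v))
  attr_path <- paste0(path, ".nodes.csv")
  nd <- NULL
  if (file.exists(attr_path)) {
    nd <- utils::read.csv(attr_path, stringsAsFactors = FALSE)
    undeclared <- setdiff(nodes, nd$Id)
    if (length(undeclared))
      stop("edge list references undeclared node(s): ",
           paste(undeclared, collapse = ", "))
    nodes <- nd$Id
  }
  g <- igraph::graph_from_data_frame(df[c("u", "v")], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::E(g)$weight <- df$w
  if (!is.null(nd) && ncol(nd) > 1) {
    names(nd)[1] <- "Id"
    g <- attach_attributes(g, nd)
  }
  g
}
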