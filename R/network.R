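#' Parse an interaction edge file into an undirected simple graph
#'
#' Supports a plain two-column symbol TSV and the BioGRID Tab 2 layout
#' (columns "Official Symbol Interactor A/B" with per-interactor
#' organism ids). Self-loops are dropped and unordered duplicate pairs
#' collapsed.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect \code{"tsv2col"} or \code{"biogrid_tab2"}.
#' @param organism NCBI taxonomy id both interactors must carry
#'   (biogrid_tab2 only; default 9606, human).
#' @return An \code{igraph} undirected simple graph.
#' @export
parse_interactions <- function(path, dialect = c("tsv2col", "biogrid_tab2"),
                               organism = 9606) {
  dialect <- match.arg(dialect)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "biogrid_tab2") {
    need <- c("Official Symbol Interactor A", "Official Symbol Interactor B",
              "Organism Interactor A", "Organism Interactor B")
    missing <- setdiff(need, colnames(d))
    if (length(missing) > 0)
      stop("missing required BioGRID Tab 2 column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    d <- d[d[["Organism Interactor A"]] == organism &
             d[["Organism Interactor B"]] == organism, , drop = FALSE]
    a <- as.character(d[["Official Symbol Interactor A"]])
    b <- as.character(d[["Official Symbol Interactor B"]])
  } else {
    if (ncol(d) < 2L)
      stop("missing required columns: a two-column edge file is expected",
           call. = FALSE)
    a <- as.character(d[[1]])
    b <- as.character(d[[2]])
  }
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0) {
    warning("no edges after filtering: returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  uniq <- !duplicated(key)
  igraph::graph_from_edgelist(cbind(a[uniq], b[uniq]), directed = FALSE)
}

#' Induced interaction subnetwork
#'
#' Keeps edges whose endpoints both lie in \code{genes}; nodes left
#' without any surviving edge are dropped, so an n-gene set can yield a
#' smaller network.
#'
#' @param net an \code{igraph} graph.
#' @param genes character vector of gene symbols.
#' @return The induced \code{igraph} subgraph without isolated nodes.
#' @export
induced_network <- function(net, genes) {
  g <- igraph::induced_subgraph(net,
                                intersect(igraph::V(net)$name, genes))
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Node degree
#' @param net an \code{igraph} graph.
#' @return Named integer vector of edge-endpoint counts.
#' @export
node_degree <- function(net) igraph::degree(net)

#' Local clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected.
#' Nodes of degree < 2 have no neighbour pair; their coefficient is 0 by
#' default so every node contributes to pooled distributions, or NA when
#' \code{undefined_as_zero = FALSE}.
#'
#' @param net an \code{igraph} graph.
#' @param undefined_as_zero treat degree<2 nodes as 0 (default) or NA.
#' @return Named numeric vector in [0, 1].
#' @export
clustering_coefficient <- function(net, undefined_as_zero = TRUE) {
  cc <- igraph::transitivity(net, type = "local", isolates = "NaN")
  names(cc) <- igraph::V(net)$name
  if (undefined_as_zero) cc[is.nan(cc)] <- 0 else cc[is.nan(cc)] <- NA_real_
  cc
}

#' All-pairs shortest-path matrix with the disconnected-pair convention
#'
#' BFS distances; a pair with no connecting path is assigned distance
#' |V| - 1 (one less than the maximum possible node count on a path), so
#' closeness remains defined on disconnected graphs.
#'
#' @param net an \code{igraph} graph.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(net) {
  d <- igraph::distances(net)
  d[is.infinite(d)] <- igraph::vcount(net) - 1
  d
}

#' Closeness centrality
#'
#' Inverse of the average shortest-path length to all other nodes,
#' \code{(|V|-1) / sum_u d(v,u)}, with disconnected pairs entering at
#' distance |V| - 1 (see \code{\link{distance_matrix}}).
#'
#' @param net an \code{igraph} graph with at least 2 nodes.
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("closeness requires at least 2 nodes", call. = FALSE)
  d <- distance_matrix(net)
  (n - 1) / rowSums(d)
}

#' Node betweenness centrality (Brandes)
#'
#' Number of shortest paths passing through a node, accumulated by the
#' Brandes algorithm with endpoints excluded; each unordered pair counts
#' once. Dependencies accumulate only along realized paths, so the
#' disconnected-pair distance convention does not apply here.
#'
#' @param net an \code{igraph} graph.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net, directed = FALSE)
}

#' Edge betweenness centrality
#'
#' Number of shortest paths traversing each edge.
#'
#' @param net an \code{igraph} graph.
#' @return Numeric vector, one value per edge (ends as attributes in
#'   \code{names}-style "a|b" labels).
#' @export
edge_betweenness_centrality <- function(net) {
  eb <- igraph::edge_betweenness(net, directed = FALSE)
  names(eb) <- apply(igraph::as_edgelist(net), 1, paste, collapse = "|")
  eb
}

#' Normalize a vector by its maximum
#'
#' @param values numeric vector.
#' @return values / max(values); an all-zero vector is returned
#'   unchanged with a warning.
#' @export
normalize_by_max <- function(values) {
  mx <- max(values, na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) {
    warning("all-zero vector: max-normalization returns it unchanged")
    return(values)
  }
  values / mx
}

.CENTRALITY_MEASURES <- c("degree", "betweenness", "closeness", "clustcoef")

#' Per-node centrality table with max-normalized columns
#'
#' @param net an \code{igraph} graph.
#' @param measures subset of degree, betweenness, closeness, clustcoef.
#' @return data.frame with one row per node: each requested measure and
#'   its max-normalized counterpart (\code{normalized_*}).
#' @export
centrality_table <- function(net, measures = .CENTRALITY_MEASURES) {
  measures <- match.arg(measures, .CENTRALITY_MEASURES, several.ok = TRUE)
  out <- data.frame(node = igraph::V(net)$name, stringsAsFactors = FALSE)
  vals <- list()
  if ("degree" %in% measures) vals$degree <- node_degree(net)
  if ("betweenness" %in% measures) vals$betweenness <- betweenness_centrality(net)
  if ("closeness" %in% measures) vals$closeness <- closeness_centrality(net)
  if ("clustcoef" %in% measures) vals$clustcoef <- clustering_coefficient(net)
  for (m in names(vals)) {
    out[[m]] <- unname(vals[[m]])
    out[[paste0("normalized_", m)]] <-
      unname(suppressWarnings(normalize_by_max(vals[[m]])))
  }
  out
}

#' Sample an edge-subsampled null network ensemble
#'
#' Builds \code{n} random control networks, each of exactly \code{x}
#' distinct edges drawn uniformly without replacement from the source
#' network (the interactome of non-associated genes); a member's node
#' set is the endpoints of its sampled edges. Each member's centralities
#' are max-normalized within that member and pooled across the ensemble.
#'
#' @param source an \code{igraph} graph to subsample edges from.
#' @param x number of edges per member (must not exceed |E(source)|).
#' @param n number of members (default 100).
#' @param seed integer seed; the same seed reproduces identical members.
#' @param measures centrality measures to pool.
#' @return Object of class \code{null_ensemble}: list with
#'   \code{members} (edge-id vectors), \code{pooled} (data.frame of
#'   normalized node values across all members), \code{x}, \code{n},
#'   \code{seed}.
#' @export
sample_null_ensemble <- function(source, x, n = 100, seed = 1L,
                                 measures = .CENTRALITY_MEASURES) {
  ne <- igraph::ecount(source)
  if (x > ne)
    stop("cannot sample ", x, " edges from a network with ", ne, " edges",
         call. = FALSE)
  set.seed(seed)
  members <- vector("list", n)
  pooled <- vector("list", n)
  for (i in seq_len(n)) {
    eid <- sort(sample.int(ne, x))
    members[[i]] <- eid
    g <- igraph::subgraph_from_edges(source, eid, delete.vertices = TRUE)
    tab <- centrality_table(g, measures = measures)
    tab$member <- i
    pooled[[i]] <- tab
  }
  structure(list(members = members, pooled = do.call(rbind, pooled),
                 x = x, n = n, seed = seed, measures = measures),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Edge-subsampled null ensemble:", x$n, "networks of", x$x,
      "edges each (seed", x$seed, ")\n")
  invisible(x)
}

#' Compare observed centralities against the null ensemble
#'
#' Two-sided Mann-Whitney U test of the observed network's max-normalized
#' node values against the values pooled over all ensemble members.
#'
#' @param observed a \code{centrality_table} of the observed network.
#' @param ensemble a \code{\link{sample_null_ensemble}} result.
#' @param measure one of degree, betweenness, closeness, clustcoef.
#' @return Object of class \code{centrality_test}: list with measure,
#'   observed_median, null_median, U, p.
#' @export
compare_centrality <- function(observed, ensemble, measure) {
  measure <- match.arg(measure, .CENTRALITY_MEASURES)
  col <- paste0("normalized_", measure)
  obs <- observed[[col]]
  nul <- ensemble$pooled[[col]]
  if (length(obs) == 0 || length(nul) == 0)
    stop("empty observed or null value set", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(obs, nul))
  structure(list(measure = measure,
                 observed_median = stats::median(obs),
                 null_median = stats::median(nul),
                 U = unname(wt$statistic), p = wt$p.value),
            class = "centrality_test")
}

#' @export
print.centrality_test <- function(x, ...) {
  cat(sprintf("%s: observed median %.4g vs null median %.4g (U = %g, two-sided p = %.3g)\n",
              x$measure, x$observed_median, x$null_median, x$U, x$p))
  invisible(x)
}
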