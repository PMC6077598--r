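#' NetworkAnalyzer-style topology report
#'
#' Computes the standard whole-network topology parameter suite for an
#' undirected graph: node/edge counts, mean local clustering coefficient,
#' connected components, diameter and radius, Freeman degree centralization,
#' number of ordered node pairs at finite distance, characteristic path
#' length, mean number of neighbors, density, degree heterogeneity
#' (coefficient of variation of degree), isolated nodes, and the counts of
#' self-loops and multi-edge pairs removed before analysis.
#'
#' Conventions: the clustering coefficient is the unweighted mean of local
#' coefficients with degree-<2 nodes contributing 0; shortest paths are
#' counted over ordered pairs; the characteristic path length averages over
#' ordered pairs at finite distance.
#'
#' @param net An undirected [igraph::graph] with at least 2 nodes.
#' @return An object of class `topology_report` (a named list).
#' @examples
#' g <- igraph::make_full_graph(3)
#' topology_report(g)
#' @export
topology_report <- function(net) {
  if (igraph::is_directed(net)) net <- igraph::as_undirected(net, mode = "collapse")
  n <- igraph::vcount(net)
  if (n < 2) {
    np_stop("topology report needs at least 2 nodes",
            class = "netpharm_degenerate_input_error")
  }
  self_loops <- sum(igraph::which_loop(net))
  multi <- sum(igraph::which_multiple(net))
  g <- igraph::simplify(net)
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  avg_nb <- mean(deg)
  density <- if (n > 1) avg_nb / (n - 1) else 0
  d <- igraph::distances(g)
  finite_pairs <- sum(is.finite(d)) - n  # ordered, excluding self
  cpl <- if (finite_pairs > 0) sum(d[is.finite(d) & d > 0]) / finite_pairs else NA_real_
  dmax <- max(deg)
  centralization <- if (n > 2) (n / (n - 2)) * (dmax / (n - 1) - density) else 0
  het <- if (avg_nb > 0) sqrt(mean((deg - avg_nb)^2)) / avg_nb else NA_real_
  structure(list(
    n_nodes = n,
    n_edges = e,
    clustering_coefficient = igraph::transitivity(g, type = "localaverage",
                                                  isolates = "zero"),
    connected_components = igraph::count_components(g),
    diameter = igraph::diameter(g, unconnected = TRUE),
    radius = igraph::radius(g),
    centralization = centralization,
    shortest_paths = finite_pairs,
    characteristic_path_length = cpl,
    avg_neighbors = avg_nb,
    density = density,
    heterogeneity = het,
    isolated_nodes = sum(deg == 0),
    self_loops = self_loops,
    multiedge_pairs = multi
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network topology report\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-28s %s\n", gsub("_", " ", nm),
                if (is.numeric(val)) format(round(val, 3)) else val))
  }
  invisible(x)
}

#' Closed-form bookkeeping identities for a connected simple graph
#'
#' From the node count, edge count and maximum degree alone, returns the
#' identities that hold for any connected simple undirected graph: the mean
#' number of neighbors `2e/n`, the density `2e/(n(n-1))`, the number of
#' ordered node pairs `n(n-1)` (all at finite distance when connected), and
#' the Freeman degree centralization `(n/(n-2)) (d_max/(n-1) - density)`.
#'
#' @param n_nodes,n_edges,d_max Scalars describing the graph.
#' @return Named list: `avg_neighbors`, `density`, `ordered_pairs`,
#'   `centralization`.
#' @export
graph_summary_identities <- function(n_nodes, n_edges, d_max) {
  stopifnot(is_count(n_nodes), is_count(n_edges), is_count(d_max),
            n_nodes > 2)
  avg <- 2 * n_edges / n_nodes
  dens <- avg / (n_nodes - 1)
  list(
    avg_neighbors = avg,
    density = dens,
    ordered_pairs = n_nodes * (n_nodes - 1),
    centralization = (n_nodes / (n_nodes - 2)) * (d_max / (n_nodes - 1) - dens)
  )
}

#' Per-node centrality table
#'
#' Degree (neighbor count), betweenness (Brandes pair-dependency sums
#' normalized by `(n-1)(n-2)/2`), and closeness (number of reachable nodes
#' divided by the sum of distances to them, i.e. component-restricted
#' normalized closeness).
#'
#' @param net Undirected simple [igraph::graph].
#' @return Data frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
node_centralities <- function(net) {
  g <- igraph::simplify(net)
  data.frame(
    node = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
    degree = unname(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, normalized = TRUE)),
    closeness = unname(igraph::closeness(g, normalized = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Top-k centrality rankings
#'
#' Three independent descending rankings (degree, betweenness, closeness) of
#' the same centrality table; ties are broken by ascending node name for
#' reproducibility.
#'
#' @param net Undirected [igraph::graph].
#' @param k Number of rows per ranking; must not exceed the node count.
#' @return Named list of three data frames (`degree`, `betweenness`,
#'   `closeness`), each the top `k` rows of the full centrality table ordered
#'   by that metric.
#' @export
rank_centralities <- function(net, k = 30) {
  cent <- node_centralities(net)
  if (!is_count(k) || k > nrow(cent)) {
    np_stop("k = ", k, " exceeds the number of nodes (", nrow(cent), ")",
            class = "netpharm_bounds_error")
  }
  rank_one <- function(metric) {
    ord <- order(-cent[[metric]], cent$node)
    out <- cent[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(degree = rank_one("degree"),
       betweenness = rank_one("betweenness"),
       closeness = rank_one("closeness"))
}

#' Hub screening at a multiple of the mean degree
#'
#' Nodes whose degree is at least `multiplier` times the mean number of
#' neighbors are declared hubs (the conventional rule takes twice the mean
#' degree). The threshold comparison is inclusive.
#'
#' @param degrees Named integer vector of node degrees.
#' @param avg_neighbors Mean number of neighbors; defaults to
#'   `mean(degrees)`. Supply the whole-network mean when `degrees` covers
#'   only a subset of nodes.
#' @param multiplier Multiple of the mean degree defining the hub threshold.
#' @return Character vector of hub node names, ordered by descending degree
#'   (ties by ascending name).
#' @export
hub_screen <- function(degrees, avg_neighbors = mean(degrees),
                       multiplier = 2) {
  if (is.null(names(degrees))) {
    np_stop("`degrees` must be a named vector", class = "netpharm_domain_error")
  }
  stopifnot(avg_neighbors > 0, multiplier > 0)
  thr <- multiplier * avg_neighbors
  hubs <- degrees[degrees >= thr]
  names(hubs)[order(-hubs, names(hubs))]
}

#' Write a topology report or centrality table as TSV
#'
#' @param report A `topology_report`.
#' @param path Output path.
#' @export
write_topology_report <- function(report, path) {
  df <- data.frame(parameter = names(report),
                   value = vapply(report, function(v) format(v, digits = 12), ""),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
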