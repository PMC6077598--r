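# Independent brute-force oracles used to check the package's
# graph/statistics code. Deliberately naive implementations that share no
# code path with the functions under test.

# adjacency list from an igraph object (names only)
adj_list <- function(g) {
  nms <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  adj <- setNames(vector("list", length(nms)), nms)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  adj
}

# hand-rolled BFS distances from one source
bfs_dist <- function(adj, s) {
  d <- setNames(rep(Inf, length(adj)), names(adj))
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# component-restricted normalized closeness: reachable / sum(distances)
closeness_oracle <- function(g) {
  adj <- adj_list(g)
  vapply(names(adj), function(v) {
    d <- bfs_dist(adj, v)
    d <- d[names(d) != v]
    reach <- d[is.finite(d)]
    if (length(reach) == 0) NaN else length(reach) / sum(reach)
  }, 0)
}

# enumerate ALL shortest paths between s and t by depth-first search over
# simple paths, pruned at the BFS distance
all_shortest_paths_enum <- function(adj, s, t, dmax) {
  paths <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    if (length(path) - 1 >= dmax) return()
    for (w in adj[[v]]) {
      if (!(w %in% path)) recurse(c(path, w))
    }
  }
  recurse(s)
  paths[vapply(paths, length, 1L) == dmax + 1]
}

# normalized betweenness via exhaustive shortest-path enumeration
betweenness_oracle <- function(g) {
  adj <- adj_list(g)
  nms <- names(adj)
  n <- length(nms)
  btw <- setNames(rep(0, n), nms)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- nms[i]; t <- nms[j]
      d <- bfs_dist(adj, s)[t]
      if (is.infinite(d)) next
      paths <- all_shortest_paths_enum(adj, s, t, d)
      sigma <- length(paths)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        tab <- table(inner)
        btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / sigma
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# hypergeometric upper tail by direct summation of choose() terms
hyper_tail_oracle <- function(N, C, n, O) {
  ks <- O:min(C, n)
  sum(choose(C, ks) * choose(N - C, n - ks)) / choose(N, n)
}

# two-sided Fisher exact p by enumerating all tables with the observed
# margins and summing probabilities <= the observed one (with an epsilon
# for float ties)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  prob <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  ps <- vapply(xs, prob, 0)
  p_obs <- prob(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# random connected-ish simple graph with named vertices
random_test_graph <- function(n, p = 0.35) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

extdata <- function(f) system.file("extdata", f, package = "netpharm")

# the re-typed printed pathway table, with gene sets
pathway_table <- function() {
  read.delim(extdata("hjd_kegg_top10_pathways.tsv"), sep = "\t",
             stringsAsFactors = FALSE)
}

pathway_genes <- function(tab, name) {
  strsplit(tab$genes[tab$pathway == name], ";", fixed = TRUE)[[1]]
}
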