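#' Filter compound-target predictions by confidence score
#'
#' Keeps prediction records whose score is strictly greater than `score_min`
#' (the conventional cutoff for SVM-style target-prediction confidence is
#' 0.7, applied as a strict inequality).
#'
#' @param preds Data frame with columns `compound`, `target`, `score`.
#' @param score_min Strict lower bound on the confidence score.
#' @return The filtered data frame (possibly zero rows).
#' @export
filter_predictions <- function(preds, score_min = 0.7) {
  preds <- as.data.frame(preds)
  if (nrow(preds) == 0L) return(preds)
  req <- c("compound", "target", "score")
  miss <- setdiff(req, names(preds))
  if (length(miss) > 0) {
    np_stop("predictions: missing column(s) ", paste(miss, collapse = ", "),
            class = "netpharm_parse_error")
  }
  preds$score <- as.numeric(preds$score)
  if (any(!is.finite(preds$score))) {
    np_stop("predictions: non-finite score", class = "netpharm_domain_error")
  }
  preds[preds$score > score_min, , drop = FALSE]
}

#' Read a compound-target prediction table
#'
#' Tab-separated with header columns `compound`, `target`, `score`.
#'
#' @param path File path.
#' @return Data frame of predictions.
#' @export
read_predictions <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                  comment.char = "", stringsAsFactors = FALSE)
  miss <- setdiff(c("compound", "target", "score"), names(x))
  if (length(miss) > 0) {
    np_stop(basename(path), ": missing column(s) ",
            paste(miss, collapse = ", "), class = "netpharm_parse_error")
  }
  x$score <- as.numeric(x$score)
  x
}

#' Build the bipartite compound-target network
#'
#' Nodes are compounds and predicted targets; each surviving prediction
#' contributes one untyped undirected edge. Duplicate associations collapse
#' to a single edge; predictions whose compound is absent from the screened
#' library are skipped with a warning. Target symbols are case-folded to
#' upper case.
#'
#' @param compounds Data frame of screened (active) compounds with a `name`
#'   column.
#' @param preds Prediction data frame (`compound`, `target`, columns).
#' @return An [igraph::graph] with vertex attribute `kind`
#'   (`"compound"`/`"target"`) and edge attribute `type`
#'   (`"compound-target"`).
#' @export
build_compound_target_network <- function(compounds, preds) {
  compounds <- as.data.frame(compounds)
  preds <- as.data.frame(preds)
  known <- unique(trimws(compounds$name))
  pred_cmpd <- trimws(as.character(preds$compound))
  ok <- canonical(pred_cmpd) %in% canonical(known)
  if (any(!ok)) {
    np_warn(sum(!ok), " prediction(s) reference compounds absent from the ",
            "library; skipped")
  }
  preds <- preds[ok, , drop = FALSE]
  if (nrow(preds) == 0L) {
    np_warn("no valid compound-target associations; returning empty network")
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(g)
  }
  # map prediction compound labels back to library casing
  lut <- setNames(known, canonical(known))
  cmpd <- unname(lut[canonical(pred_cmpd[ok])])
  targ <- canonical(as.character(preds$target))
  clash <- intersect(unique(cmpd), unique(targ))
  if (length(clash) > 0) {
    np_stop("compound and target namespaces collide on: ",
            paste(head(clash, 3), collapse = ", "),
            class = "netpharm_domain_error")
  }
  el <- unique(data.frame(from = cmpd, to = targ, stringsAsFactors = FALSE))
  verts <- data.frame(
    name = c(unique(el$from), unique(el$to)),
    kind = c(rep("compound", length(unique(el$from))),
             rep("target", length(unique(el$to)))),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
  igraph::E(g)$type <- "compound-target"
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Restrict a compound-target network to disease targets
#'
#' Keeps only target nodes present in `disease` (case-folded match) and the
#' compounds that retain at least one edge to a surviving target.
#'
#' @param net Bipartite network from [build_compound_target_network()].
#' @param disease Character vector of disease-target gene symbols.
#' @return List with `network` (induced subgraph) and `targets` (retained
#'   target symbols, ordered as in the network).
#' @export
map_to_disease_targets <- function(net, disease) {
  disease <- gene_list(disease)
  kind <- igraph::V(net)$kind
  name <- igraph::V(net)$name
  keep_t <- name[kind == "target" & name %in% disease]
  if (length(keep_t) == 0L) {
    np_warn("no network target matches the disease-target list")
    return(list(network = igraph::make_empty_graph(0, directed = FALSE),
                targets = character(0)))
  }
  sub <- igraph::induced_subgraph(
    net, which(kind == "compound" | name %in% keep_t))
  deg <- igraph::degree(sub)
  sub <- igraph::induced_subgraph(
    sub, which(igraph::V(sub)$kind == "target" | deg > 0))
  list(network = sub,
       targets = igraph::V(sub)$name[igraph::V(sub)$kind == "target"])
}

#' Read / write a network edge list
#'
#' Supports SIF (`node1<TAB>type<TAB>node2`) and plain two-column TSV edge
#' lists (one edge per row, optional header ignored if non-numeric is fine
#' since node labels are strings; no header is assumed). Self-loops and
#' duplicate edges are dropped; their counts are reported via graph
#' attributes `self_loops_dropped` and `multiedges_dropped` and a message.
#'
#' @param path File path.
#' @param dialect `"sif"` or `"tsv"`.
#' @return An undirected simple [igraph::graph].
#' @export
read_network <- function(path, dialect = c("sif", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_need <- if (dialect == "sif") 3L else 2L
  bad <- which(vapply(parts, length, 1L) != ncol_need)
  if (length(bad) > 0) {
    np_stop(basename(path), ": line ", bad[1], " has ",
            length(parts[[bad[1]]]), " field(s); expected ", ncol_need,
            class = "netpharm_parse_error")
  }
  m <- do.call(rbind, parts)
  if (dialect == "sif") {
    el <- data.frame(from = m[, 1], to = m[, 3], type = m[, 2],
                     stringsAsFactors = FALSE)
  } else {
    el <- data.frame(from = m[, 1], to = m[, 2], type = "interaction",
                     stringsAsFactors = FALSE)
  }
  loops <- el$from == el$to
  a <- pmin(el$from, el$to)
  b <- pmax(el$from, el$to)
  dup <- duplicated(paste(a, b, sep = "\r")) & !loops
  n_loop <- sum(loops)
  n_dup <- sum(dup)
  if (n_loop + n_dup > 0) {
    message("read_network: dropped ", n_loop, " self-loop(s) and ",
            n_dup, " duplicate edge(s)")
  }
  el <- el[!loops & !dup, , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  g <- igraph::set_graph_attr(g, "self_loops_dropped", n_loop)
  igraph::set_graph_attr(g, "multiedges_dropped", n_dup)
}

#' @rdname read_network
#' @param net An igraph graph. Edge attribute `type` is used as the SIF
#'   relation column (default `"interaction"`).
#' @export
write_network <- function(net, path, dialect = c("sif", "tsv")) {
  dialect <- match.arg(dialect)
  el <- igraph::as_edgelist(net)
  type <- igraph::edge_attr(net, "type") %||% rep("interaction", nrow(el))
  lines <- if (dialect == "sif") {
    paste(el[, 1], type, el[, 2], sep = "\t")
  } else {
    paste(el[, 1], el[, 2], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
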