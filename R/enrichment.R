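#' Hypergeometric upper-tail probability
#'
#' The over-representation p-value: the probability of observing at least
#' `O` query genes in a category of size `C`, when `n` genes are drawn
#' without replacement from a universe of size `N`. Inclusive upper tail,
#' `P(X >= O)`; computed in log-space by `stats::phyper`.
#'
#' @param N Universe (reference) size.
#' @param C Category size (reference genes annotated to the category).
#' @param n Query size.
#' @param O Observed overlap.
#' @return The upper-tail probability; exactly 1 when `O = 0`.
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 3)  # 66/252
#' @export
hypergeom_upper_tail <- function(N, C, n, O) {
  stopifnot(is_count(N), is_count(C), is_count(n), is_count(O))
  if (C > N || n > N || O > min(C, n)) {
    np_stop("inconsistent hypergeometric bounds (N=", N, ", C=", C,
            ", n=", n, ", O=", O, ")", class = "netpharm_domain_error")
  }
  if (O == 0) return(1)
  phyper(O - 1, C, N - C, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjP_(i) = min_{j >= i} (m * p_(j) / j)` clipped at 1, reported in input
#' order. `m` may exceed the number of supplied p-values when only a subset
#' of the tested hypotheses is passed in.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Number of tested hypotheses (`>= length(p)`).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (!is_prob(p)) {
    np_stop("p-values must lie in [0, 1]", class = "netpharm_domain_error")
  }
  stopifnot(is_count(m), m >= length(p))
  if (length(p) == 0L) return(numeric(0))
  p.adjust(p, method = "BH", n = m)
}

#' Observed/expected enrichment ratio
#'
#' `R = O / E`, the ratio of the observed overlap to the expected overlap
#' `E = n C / N`; reported as 0 when the observed overlap is 0.
#'
#' @param O Observed overlap count.
#' @param E Expected overlap count (> 0).
#' @return The enrichment ratio.
#' @export
enrichment_ratio <- function(O, E) {
  stopifnot(is.numeric(O), is.numeric(E), all(E > 0))
  ifelse(O == 0, 0, O / E)
}

#' Assemble a gene-set collection
#'
#' @param categories Named list of character vectors (category gene sets).
#' @param reference Character vector: the reference universe. Defaults to
#'   the union of all category genes. Category genes outside the reference
#'   are dropped; categories left empty are not tested.
#' @return Object of class `geneset_collection`: list with `categories`
#'   (case-folded, reference-restricted), `reference`, and `m` (number of
#'   tested categories).
#' @export
geneset_collection <- function(categories, reference = NULL) {
  stopifnot(is.list(categories), !is.null(names(categories)),
            all(nzchar(names(categories))))
  cats <- lapply(categories, gene_list)
  reference <- if (is.null(reference)) {
    gene_list(unlist(cats, use.names = FALSE))
  } else {
    gene_list(reference)
  }
  cats <- lapply(cats, function(g) g[g %in% reference])
  keep <- vapply(cats, length, 1L) > 0
  structure(list(categories = cats[keep], reference = reference,
                 m = sum(keep)),
            class = "geneset_collection")
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description (ignored), then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short) > 0) {
    np_stop(basename(path), ": line ", short[1],
            " has fewer than 3 fields", class = "netpharm_parse_error")
  }
  setNames(lapply(parts, function(f) f[-(1:2)]),
           vapply(parts, `[[`, "", 1L))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a query gene list
#'
#' For each category: `C` = category size in the reference, `O` = overlap
#' with the query, `E = n C / N` the expected overlap, `R = O/E` the
#' enrichment ratio, `rawP` the hypergeometric upper-tail probability, and
#' `adjP` the Benjamini-Hochberg adjustment over the `m` tested categories.
#' Query genes outside the reference are dropped with a warning; `n` is the
#' retained query size. Results are sorted by ascending `rawP`, ties by
#' descending `R` then category name.
#'
#' @param query Character vector of gene symbols.
#' @param collection A [geneset_collection()].
#' @return Data frame of class `enrichment_result` with columns `category`,
#'   `C`, `O`, `E`, `R`, `rawP`, `adjP`, `genes` (semicolon-joined overlap).
#' @export
enrich <- function(query, collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  query <- gene_list(query)
  inside <- query %in% collection$reference
  if (any(!inside)) {
    np_warn(sum(!inside), " query gene(s) absent from the reference ",
            "universe; dropped")
  }
  query <- query[inside]
  if (length(query) == 0L) {
    np_stop("no query genes map to the reference universe",
            class = "netpharm_empty_input_error")
  }
  N <- length(collection$reference)
  n <- length(query)
  cats <- collection$categories
  res <- data.frame(
    category = names(cats),
    C = vapply(cats, length, 1L),
    O = vapply(cats, function(g) sum(query %in% g), 1L),
    stringsAsFactors = FALSE
  )
  res$E <- n * res$C / N
  res$R <- enrichment_ratio(res$O, res$E)
  res$rawP <- vapply(seq_len(nrow(res)), function(i) {
    hypergeom_upper_tail(N, res$C[i], n, res$O[i])
  }, 0)
  res$adjP <- bh_adjust(res$rawP, m = collection$m)
  res$genes <- vapply(cats, function(g) {
    paste(query[query %in% g], collapse = ";")
  }, "")
  ord <- order(res$rawP, -res$R, res$category)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Select the top enriched categories
#'
#' The first `k` results (in the `rawP`-sorted order produced by [enrich()])
#' whose adjusted p-value is strictly below `adjp_max` (the conventional
#' report takes the top 10 pathways with adjusted p < 0.01).
#'
#' @param results An `enrichment_result` data frame.
#' @param k Maximum number of rows.
#' @param adjp_max Strict upper bound on `adjP`.
#' @return The selected rows.
#' @export
select_top <- function(results, k = 10, adjp_max = 0.01) {
  stopifnot(is_count(k))
  pass <- results[results$adjP < adjp_max, , drop = FALSE]
  out <- head(pass, k)
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#'
#' Columns `category`, `C`, `O`, `E`, `R`, `rawP`, `adjP`, `genes`; full
#' numeric precision.
#'
#' @param results An `enrichment_result`.
#' @param path Output path.
#' @export
write_enrichment <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
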