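#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper p.adjust fisher.test pchisq rbeta rbinom rexp
#'   rlnorm runif setNames var uniroot
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

np_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "netpharm_error")))
}

np_warn <- function(...) warning(paste0(...), call. = FALSE)

# case-fold + trim used for all identifier matching
canonical <- function(x) toupper(trimws(x))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Read a one-symbol-per-line gene list
#'
#' Gene symbols are trimmed and case-folded to upper case; duplicates after
#' case-folding are dropped, keeping first occurrence order.
#'
#' @param path Path to a plain-text file, one symbol per line.
#' @return Character vector of unique upper-case gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  gene_list(x)
}

#' Canonicalize a character vector of gene symbols
#'
#' @param symbols Character vector.
#' @return Unique, upper-cased, trimmed symbols in first-occurrence order.
#' @export
gene_list <- function(symbols) {
  x <- canonical(as.character(symbols))
  x <- x[nzchar(x)]
  x[!duplicated(x)]
}

#' Write a gene list as plain text, one symbol per line
#'
#' @param genes Character vector.
#' @param path Output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Intersect two gene lists
#'
#' Case-folded intersection, ordered as in `a`. Used, e.g., to overlap a
#' signalling-pathway gene set with a disease pathway gene set.
#'
#' @param a,b Character vectors of gene symbols.
#' @return Character vector: the symbols of `a` also present in `b`.
#' @export
pathway_overlap <- function(a, b) {
  a <- gene_list(a)
  b <- gene_list(b)
  a[a %in% b]
}
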