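#' Tanimoto drug-likeness index
#'
#' Similarity of a compound's molecular-descriptor vector `a` to a reference
#' vector `b` (typically the average descriptor vector of a large drug
#' database), used as a drug-likeness (DL) index:
#' \deqn{f(A,B) = \frac{A \cdot B}{\|A\|^2 + \|B\|^2 - A \cdot B}}
#' For nonnegative vectors the value lies in \[0, 1\] and equals 1 iff the
#' vectors are identical (and nonzero).
#'
#' @param a,b Numeric descriptor vectors of equal length, all entries finite.
#' @return The Tanimoto index, a scalar.
#' @examples
#' tanimoto_dl(c(2, 1), c(1, 1))  # 0.75
#' @export
tanimoto_dl <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    np_stop("descriptor vectors differ in length (", length(a), " vs ",
            length(b), ")", class = "netpharm_dimension_error")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    np_stop("descriptor vectors must be finite", class = "netpharm_domain_error")
  }
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) {
    np_stop("Tanimoto index undefined: both descriptor vectors are zero",
            class = "netpharm_domain_error")
  }
  ab / denom
}

# validate a compound table; `where` names the source for error messages
validate_compounds <- function(x, where = "compound table") {
  req <- c("herb", "name", "ob", "dl")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    np_stop(where, ": missing column(s) ", paste(miss, collapse = ", "),
            class = "netpharm_parse_error")
  }
  for (col in c("ob", "dl")) {
    v <- x[[col]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        np_stop(where, ": non-numeric ", col, " value '", v[bad[1]],
                "' at data row ", bad[1], class = "netpharm_parse_error")
      }
      x[[col]] <- num
    }
    if (anyNA(x[[col]])) {
      np_stop(where, ": missing ", col, " value at data row ",
              which(is.na(x[[col]]))[1], class = "netpharm_parse_error")
    }
  }
  if (any(!nzchar(trimws(x$name)))) {
    np_stop(where, ": empty compound name", class = "netpharm_parse_error")
  }
  if (any(x$ob < 0)) {
    np_stop(where, ": negative oral bioavailability",
            class = "netpharm_domain_error")
  }
  if (any(x$dl < 0 | x$dl > 1)) {
    np_stop(where, ": drug-likeness outside [0, 1]",
            class = "netpharm_domain_error")
  }
  key <- paste(canonical(x$herb), canonical(x$name), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x$name[duplicated(key)][1]
    np_stop(where, ": duplicate (name, herb) entry '", dup, "'",
            class = "netpharm_parse_error")
  }
  x
}

#' Screen a compound library by oral bioavailability and drug-likeness
#'
#' Compounds with `ob >= ob_min` and `dl >= dl_min` (both inclusive) are
#' retained as active ingredients; all others are discarded. The defaults are
#' the standard ADME screening thresholds of 30% oral bioavailability and a
#' 0.18 drug-likeness index.
#'
#' If a `descriptors` column of semicolon-joined numbers is present together
#' with a `reference` descriptor vector, DL is recomputed via [tanimoto_dl()];
#' a supplied `dl` value wins over a disagreeing recomputation (warned when
#' they differ by more than `1e-6`).
#'
#' @param library Data frame with columns `herb`, `name`, `ob` (percent),
#'   `dl` (in \[0,1\]), optionally `descriptors`.
#' @param ob_min Oral bioavailability threshold in percent (inclusive).
#' @param dl_min Drug-likeness threshold (inclusive).
#' @param reference Optional numeric reference descriptor vector for
#'   recomputing DL from `descriptors`.
#' @return List with elements `retained` and `discarded`, both data frames in
#'   input order; together they partition the library.
#' @export
screen_compounds <- function(library, ob_min = 30, dl_min = 0.18,
                             reference = NULL) {
  if (is.null(library) || nrow(as.data.frame(library)) == 0L) {
    np_stop("compound library is empty", class = "netpharm_empty_input_error")
  }
  if (!is.numeric(ob_min) || !is.numeric(dl_min) ||
      !is.finite(ob_min) || !is.finite(dl_min) || ob_min < 0 || dl_min < 0) {
    np_stop("screening thresholds must be finite and nonnegative",
            class = "netpharm_domain_error")
  }
  library <- validate_compounds(as.data.frame(library))
  if (!is.null(reference) && "descriptors" %in% names(library)) {
    has_desc <- nzchar(library$descriptors %||% "")
    for (i in which(has_desc)) {
      vec <- as.numeric(strsplit(library$descriptors[i], ";", fixed = TRUE)[[1]])
      dl_comp <- tanimoto_dl(vec, reference)
      if (is.na(library$dl[i])) {
        library$dl[i] <- dl_comp
      } else if (abs(library$dl[i] - dl_comp) > 1e-6) {
        np_warn("compound '", library$name[i], "': supplied DL ",
                library$dl[i], " disagrees with descriptor-computed DL ",
                signif(dl_comp, 6), "; keeping supplied value")
      }
    }
  }
  keep <- library$ob >= ob_min & library$dl >= dl_min
  list(
    retained = library[keep, , drop = FALSE],
    discarded = library[!keep, , drop = FALSE]
  )
}

#' Read / write a compound table
#'
#' Tab-separated with header columns `herb`, `name`, `ob`, `dl` and an
#' optional `descriptors` column of semicolon-joined floats. Duplicate
#' (name, herb) rows (after trimming and case-folding) are rejected.
#'
#' @param path File path.
#' @return `read_compound_table()`: a validated data frame.
#' @export
read_compound_table <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                  check.names = FALSE, quote = "", comment.char = "")
  validate_compounds(x, where = basename(path))
}

#' @rdname read_compound_table
#' @param compounds Data frame as returned by [read_compound_table()].
#' @export
write_compound_table <- function(compounds, path) {
  compounds <- validate_compounds(as.data.frame(compounds))
  write.table(compounds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
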