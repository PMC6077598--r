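ALTERATION_TYPES <- c("amplification", "deep_deletion", "missense_mutation",
                      "truncating_mutation")

#' Construct an alteration matrix
#'
#' A sparse sample-by-gene record of somatic alteration events in the
#' cBioPortal style. `samples` should list the full profiled cohort
#' (including unaltered samples) since it is the denominator of all
#' frequencies; it defaults to the samples seen in `events`.
#'
#' @param events Data frame with columns `sample`, `gene`,
#'   `alteration_type` (one of amplification, deep_deletion,
#'   missense_mutation, truncating_mutation). May have zero rows.
#' @param samples Character vector of all profiled sample IDs.
#' @param genes Character vector of all queried gene symbols.
#' @return Object of class `alteration_matrix`.
#' @export
alteration_matrix <- function(events, samples = NULL, genes = NULL) {
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    miss <- setdiff(c("sample", "gene", "alteration_type"), names(events))
    if (length(miss) > 0) {
      np_stop("alteration events: missing column(s) ",
              paste(miss, collapse = ", "), class = "netpharm_parse_error")
    }
    events$gene <- canonical(events$gene)
    events$sample <- trimws(events$sample)
    bad <- setdiff(unique(events$alteration_type), ALTERATION_TYPES)
    if (length(bad) > 0) {
      np_stop("unknown alteration type(s): ", paste(bad, collapse = ", "),
              class = "netpharm_parse_error")
    }
    events <- unique(events[c("sample", "gene", "alteration_type")])
  } else {
    events <- data.frame(sample = character(0), gene = character(0),
                         alteration_type = character(0))
  }
  samples <- unique(trimws(samples %||% events$sample))
  genes <- gene_list(genes %||% events$gene)
  if (nrow(events) > 0) {
    if (!all(events$sample %in% samples)) {
      np_stop("alteration events reference undeclared samples",
              class = "netpharm_membership_error")
    }
    if (!all(events$gene %in% genes)) {
      np_stop("alteration events reference undeclared genes",
              class = "netpharm_membership_error")
    }
  }
  structure(list(samples = samples, genes = genes, events = events),
            class = "alteration_matrix")
}

#' Read an alteration table (MAF-like TSV)
#'
#' Columns `sample`, `gene`, `alteration_type`.
#'
#' @param path File path.
#' @param samples Optional full cohort sample list (see
#'   [alteration_matrix()]).
#' @param genes Optional full queried gene list.
#' @return An `alteration_matrix`.
#' @export
read_alteration_table <- function(path, samples = NULL, genes = NULL) {
  x <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                  comment.char = "", stringsAsFactors = FALSE)
  alteration_matrix(x, samples = samples, genes = genes)
}

#' Read a survival table
#'
#' TSV with columns `sample`, `os_months` (overall survival time, months)
#' and `os_event` (1 = death observed, 0 = censored).
#'
#' @param path File path.
#' @return Data frame with columns `sample`, `time`, `event`.
#' @export
read_survival_table <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                  comment.char = "", stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "os_months", "os_event"), names(x))
  if (length(miss) > 0) {
    np_stop(basename(path), ": missing column(s) ",
            paste(miss, collapse = ", "), class = "netpharm_parse_error")
  }
  out <- data.frame(sample = trimws(x$sample),
                    time = as.numeric(x$os_months),
                    event = as.integer(x$os_event),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$time)) || any(out$time < 0)) {
    np_stop(basename(path), ": survival times must be finite and >= 0",
            class = "netpharm_domain_error")
  }
  if (!all(out$event %in% c(0L, 1L))) {
    np_stop(basename(path), ": os_event must be 0 or 1",
            class = "netpharm_domain_error")
  }
  out
}

check_query_genes <- function(mat, query) {
  query <- gene_list(query)
  missing <- setdiff(query, mat$genes)
  if (length(missing) > 0) {
    np_stop("gene(s) not in alteration matrix: ",
            paste(missing, collapse = ", "),
            class = "netpharm_membership_error")
  }
  query
}

altered_samples_of <- function(mat, genes) {
  unique(mat$events$sample[mat$events$gene %in% genes])
}

#' Alteration frequency summary
#'
#' Per-gene alteration frequencies, the fraction of samples altered in at
#' least one query gene, and the IDs of those samples.
#'
#' @param mat An [alteration_matrix()].
#' @param query Genes to summarize (must be declared in `mat`); defaults to
#'   all genes.
#' @return List with `per_gene_freq` (named numeric), `altered_fraction`
#'   (scalar), `altered_samples` (character).
#' @export
alteration_summary <- function(mat, query = mat$genes) {
  stopifnot(inherits(mat, "alteration_matrix"))
  query <- check_query_genes(mat, query)
  n <- length(mat$samples)
  if (n == 0L) {
    np_stop("alteration matrix has no samples",
            class = "netpharm_degenerate_input_error")
  }
  per_gene <- vapply(query, function(g) {
    length(unique(mat$events$sample[mat$events$gene == g])) / n
  }, 0)
  altered <- altered_samples_of(mat, query)
  list(per_gene_freq = per_gene,
       altered_fraction = length(altered) / n,
       altered_samples = altered)
}

#' OncoPrint gene and sample ordering
#'
#' Genes are ordered by descending alteration frequency (ties keep query
#' order); samples are memo-sorted: each sample's altered/unaltered profile
#' over the ordered genes is treated as a binary string and sorted
#' descending, so samples altered in the most frequent genes come first.
#' Deterministic: ties keep the declared sample order.
#'
#' @inheritParams alteration_summary
#' @return List with `gene_order` and `sample_order` character vectors.
#' @export
oncoprint_order <- function(mat, query = mat$genes) {
  stopifnot(inherits(mat, "alteration_matrix"))
  query <- check_query_genes(mat, query)
  freq <- vapply(query, function(g) {
    length(unique(mat$events$sample[mat$events$gene == g]))
  }, 0L)
  gene_order <- query[order(-freq)]  # order() is stable: ties keep query order
  profile <- vapply(mat$samples, function(s) {
    altered_genes <- mat$events$gene[mat$events$sample == s]
    paste(as.integer(gene_order %in% altered_genes), collapse = "")
  }, "")
  sample_order <- mat$samples[order(-xtfrm(profile))]  # stable descending
  list(gene_order = gene_order, sample_order = sample_order)
}

#' Pairwise mutual exclusivity / co-occurrence test
#'
#' Builds the 2x2 altered/unaltered contingency table for two genes across
#' all samples and applies the two-sided Fisher exact test (the sum of
#' hypergeometric table probabilities not exceeding the observed one). The
#' log2 odds ratio uses the Haldane correction (+0.5 per cell) when any cell
#' is zero. The direction is `co-occurrence` (positive log-odds) or
#' `exclusivity` (negative) when p < 0.05, else `none`.
#'
#' @param mat An [alteration_matrix()].
#' @param gene_a,gene_b Gene symbols declared in `mat`.
#' @return List of class `mutex_result`: `gene_a`, `gene_b`, `table`
#'   (2x2 matrix: both, a-only, b-only, neither), `log2_odds`, `p`,
#'   `direction`.
#' @export
mutual_exclusivity <- function(mat, gene_a, gene_b) {
  stopifnot(inherits(mat, "alteration_matrix"))
  check_query_genes(mat, c(gene_a, gene_b))
  gene_a <- canonical(gene_a); gene_b <- canonical(gene_b)
  n <- length(mat$samples)
  if (n == 0L) {
    np_stop("alteration matrix has no samples",
            class = "netpharm_degenerate_input_error")
  }
  in_a <- mat$samples %in% altered_samples_of(mat, gene_a)
  in_b <- mat$samples %in% altered_samples_of(mat, gene_b)
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("a_altered", "a_unaltered"),
                                c("b_altered", "b_unaltered")))
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  cells <- as.numeric(tab)
  if (any(cells == 0)) cells <- cells + 0.5
  lo <- log2((cells[1] * cells[4]) / (cells[2] * cells[3]))
  direction <- if (p < 0.05) {
    if (lo > 0) "co-occurrence" else "exclusivity"
  } else "none"
  structure(list(gene_a = gene_a, gene_b = gene_b, table = tab,
                 log2_odds = lo, p = p, direction = direction),
            class = "mutex_result")
}

#' Kaplan-Meier product-limit survival curve
#'
#' `S(t)` drops by the factor `1 - d_i/n_i` at each distinct event time;
#' censored observations leave the risk set without contributing a drop.
#' Computed by [survival::survfit].
#'
#' @param records Data frame with columns `time` (>= 0) and `event`
#'   (1 = event, 0 = censored); at least one record.
#' @return Data frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, one row per distinct observed time.
#' @export
km_curve <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    np_stop("no survival records", class = "netpharm_empty_input_error")
  }
  if (any(records$time < 0) || any(!is.finite(records$time))) {
    np_stop("survival times must be finite and >= 0",
            class = "netpharm_domain_error")
  }
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1, conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed deaths in group A are compared
#' with those expected under the hypergeometric null given the pooled risk
#' set; the standardized sum is chi-square with 1 df (no continuity
#' correction). Computed by [survival::survdiff].
#'
#' @param group_a,group_b Data frames with columns `time`, `event`.
#' @return List: `chi_square`, `p`, `n_a`, `n_b`, `observed`, `expected`
#'   (per-group event counts).
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- as.data.frame(group_a)
  group_b <- as.data.frame(group_b)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) {
    np_stop("both groups must be nonempty", class = "netpharm_empty_input_error")
  }
  dat <- rbind(
    data.frame(time = group_a$time, event = group_a$event, group = "A"),
    data.frame(time = group_b$time, event = group_b$event, group = "B")
  )
  if (sum(dat$event) == 0L) {
    np_warn("no events in either group; log-rank p set to 1")
    return(list(chi_square = 0, p = 1, n_a = nrow(group_a),
                n_b = nrow(group_b), observed = c(A = 0, B = 0),
                expected = c(A = 0, B = 0)))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  chisq <- unname(sd$chisq)
  list(chi_square = chisq,
       p = pchisq(chisq, df = 1, lower.tail = FALSE),
       n_a = nrow(group_a), n_b = nrow(group_b),
       observed = setNames(sd$obs, c("A", "B")),
       expected = setNames(sd$exp, c("A", "B")))
}

#' Survival comparison of altered versus unaltered samples
#'
#' Partitions the cohort by whether a sample carries at least one alteration
#' in any query gene, then estimates a Kaplan-Meier curve per group and runs
#' the two-group log-rank test. Samples with alteration data but no survival
#' record are excluded (count reported via message).
#'
#' @param mat An [alteration_matrix()].
#' @param query Genes defining "altered".
#' @param records Survival data frame (`sample`, `time`, `event`); sample
#'   IDs must be declared in `mat`.
#' @return List: `km_altered`, `km_unaltered` (NULL when a partition is
#'   empty), `logrank` (NULL when either partition is empty), `n_altered`,
#'   `n_unaltered`.
#' @export
survival_by_alteration <- function(mat, query, records) {
  stopifnot(inherits(mat, "alteration_matrix"))
  query <- check_query_genes(mat, query)
  records <- as.data.frame(records)
  if (!all(records$sample %in% mat$samples)) {
    np_stop("survival records reference samples absent from the ",
            "alteration matrix", class = "netpharm_membership_error")
  }
  n_missing <- sum(!(mat$samples %in% records$sample))
  if (n_missing > 0) {
    message("survival_by_alteration: ", n_missing,
            " sample(s) lack survival data; excluded")
  }
  altered <- altered_samples_of(mat, query)
  rec_alt <- records[records$sample %in% altered, , drop = FALSE]
  rec_un <- records[!(records$sample %in% altered), , drop = FALSE]
  km_a <- if (nrow(rec_alt) > 0) km_curve(rec_alt) else NULL
  km_u <- if (nrow(rec_un) > 0) km_curve(rec_un) else NULL
  if (is.null(km_a) || is.null(km_u)) {
    np_warn("one survival partition is empty; log-rank test skipped")
    lr <- NULL
  } else {
    lr <- logrank_test(rec_alt, rec_un)
  }
  list(km_altered = km_a, km_unaltered = km_u, logrank = lr,
       n_altered = nrow(rec_alt), n_unaltered = nrow(rec_un))
}
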