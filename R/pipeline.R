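default_thresholds <- function() {
  list(ob_min = 30, dl_min = 0.18, score_min = 0.7, hub_multiplier = 2,
       top_k_centrality = 30, top_k_pathways = 10, adjp_max = 0.01)
}

#' Load and validate a pipeline configuration
#'
#' The config is a flat YAML file (or an equivalent named list) with an
#' `inputs` block of file paths (`compounds`, `predictions`,
#' `disease_targets`, `ppi`, `gmt`, `reference` optional, `alterations`
#' optional, `survival` optional), a `thresholds` block whose keys default
#' to the standard screening values (`ob_min` 30, `dl_min` 0.18,
#' `score_min` 0.7, `hub_multiplier` 2, `top_k_centrality` 30,
#' `top_k_pathways` 10, `adjp_max` 0.01), an optional `genomics_genes`
#' vector, and an `out_dir`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$thresholds <- modifyList(default_thresholds(),
                                  config$thresholds %||% list())
  req <- c("compounds", "predictions", "disease_targets", "ppi", "gmt")
  miss <- setdiff(req, names(config$inputs))
  if (length(miss) > 0) {
    np_stop("config: missing input path(s) ", paste(miss, collapse = ", "),
            class = "netpharm_config_error")
  }
  for (nm in names(config$inputs)) {
    p <- config$inputs[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      np_stop("config: input file for '", nm, "' not found: ", p,
              class = "netpharm_config_error")
    }
  }
  thr <- config$thresholds
  if (thr$ob_min < 0 || thr$dl_min < 0 || thr$hub_multiplier <= 0 ||
      thr$adjp_max <= 0 || thr$adjp_max > 1) {
    np_stop("config: thresholds out of range", class = "netpharm_config_error")
  }
  structure(config, class = c("pipeline_config", "list"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "netpharm_stage_error")) stop(e)
    np_stop("stage '", name, "' failed: ", conditionMessage(e),
            class = "netpharm_stage_error")
  })
}

#' Run the integrated analysis pipeline
#'
#' Executes the five stages in order: (1) ADME screening of the compound
#' library; (2) compound-target network construction, confidence filtering
#' and disease-target mapping; (3) PPI topology report, centrality rankings
#' and hub screening; (4) over-representation analysis of the PPI targets
#' against the gene-set collection; (5) alteration-matrix mining and
#' altered-versus-unaltered survival comparison. Stages with missing
#' optional inputs (alterations, survival) are skipped with a message. The
#' run is deterministic for fixed inputs.
#'
#' @param config A [pipeline_config()] (path or list).
#' @return Object of class `pipeline_report`: per-stage outputs, filter
#'   bookkeeping counts, and provenance (config hash, package and R
#'   versions).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  thr <- cfg$thresholds
  counts <- list()

  screened <- stage("compound_screen", {
    library_df <- read_compound_table(cfg$inputs$compounds)
    out <- screen_compounds(library_df, thr$ob_min, thr$dl_min)
    counts$compounds_in <- nrow(library_df)
    counts$compounds_retained <- nrow(out$retained)
    out
  })

  netstage <- stage("network_build", {
    preds <- read_predictions(cfg$inputs$predictions)
    kept <- filter_predictions(preds, thr$score_min)
    counts$predictions_in <- nrow(preds)
    counts$predictions_kept <- nrow(kept)
    disease <- read_gene_list(cfg$inputs$disease_targets)
    ct <- build_compound_target_network(screened$retained, kept)
    mapped <- map_to_disease_targets(ct, disease)
    counts$targets_mapped <- length(mapped$targets)
    list(compound_target = ct, mapped = mapped$network,
         cancer_targets = mapped$targets)
  })

  topo <- stage("topology", {
    ppi <- read_network(cfg$inputs$ppi, dialect = "sif")
    report <- topology_report(ppi)
    ranks <- rank_centralities(
      ppi, min(thr$top_k_centrality, igraph::vcount(ppi)))
    hubs <- hub_screen(igraph::degree(igraph::simplify(ppi)),
                       report$avg_neighbors, thr$hub_multiplier)
    counts$ppi_nodes <- report$n_nodes
    counts$hubs <- length(hubs)
    list(ppi = ppi, report = report, rankings = ranks, hubs = hubs)
  })

  enr <- stage("enrichment", {
    cats <- read_gmt(cfg$inputs$gmt)
    reference <- if (!is.null(cfg$inputs$reference)) {
      read_gene_list(cfg$inputs$reference)
    } else NULL
    coll <- geneset_collection(cats, reference)
    query <- gene_list(igraph::V(topo$ppi)$name)
    res <- enrich(query, coll)
    list(results = res,
         top = select_top(res, thr$top_k_pathways, thr$adjp_max))
  })

  genom <- if (is.null(cfg$inputs$alterations)) {
    message("run_pipeline: no alteration table configured; genomics stage skipped")
    NULL
  } else {
    stage("genomics", {
      surv <- if (!is.null(cfg$inputs$survival)) {
        read_survival_table(cfg$inputs$survival)
      } else NULL
      mat <- read_alteration_table(cfg$inputs$alterations,
                                   samples = surv$sample)
      genes <- gene_list(cfg$genomics_genes %||% topo$hubs)
      genes <- genes[genes %in% mat$genes]
      if (length(genes) == 0L) {
        np_stop("no genomics query gene present in the alteration matrix",
                class = "netpharm_config_error")
      }
      summary <- alteration_summary(mat, genes)
      ord <- oncoprint_order(mat, genes)
      pairs <- if (length(genes) >= 2) utils::combn(genes, 2) else NULL
      mutex <- if (!is.null(pairs)) {
        do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
          m <- mutual_exclusivity(mat, pairs[1, i], pairs[2, i])
          data.frame(gene_a = m$gene_a, gene_b = m$gene_b,
                     log2_odds = m$log2_odds, p = m$p,
                     direction = m$direction, stringsAsFactors = FALSE)
        }))
      } else NULL
      survival <- if (is.null(surv)) {
        message("run_pipeline: no survival table configured; survival ",
                "comparison skipped")
        NULL
      } else {
        survival_by_alteration(mat, genes, surv)
      }
      list(genes = genes, summary = summary, oncoprint = ord,
           mutex = mutex, survival = survival)
    })
  }

  structure(list(
    config = unclass(cfg),
    counts = counts,
    compounds = screened,
    network = netstage,
    topology = topo[c("report", "rankings", "hubs")],
    enrichment = enr,
    genomics = genom,
    provenance = list(
      config_hash = config_hash(cfg),
      package_version = as.character(utils::packageVersion("netpharm")),
      r_version = paste(R.version$major, R.version$minor, sep = "."))
  ), class = "pipeline_report")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("netpharm pipeline report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", gsub("_", " ", nm), x$counts[[nm]]))
  }
  cat("  hubs:", paste(x$topology$hubs, collapse = ", "), "\n")
  if (!is.null(x$enrichment)) {
    cat("  top pathways:", nrow(x$enrichment$top), "\n")
  }
  invisible(x)
}

#' Export a pipeline report to disk
#'
#' Writes the stage outputs as TSV tables (retained compounds, topology
#' parameter table, per-metric centrality rankings, hub list, enrichment
#' statistics, alteration summary, mutual-exclusivity table, per-group
#' Kaplan-Meier step functions), the mapped network as SIF, and a machine
#' JSON report. Re-export overwrites identically.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if absent); defaults to the
#'   config's `out_dir`.
#' @return Invisibly, the directory path.
#' @export
export_report <- function(report, out_dir = report$config$out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (is.null(out_dir)) {
    np_stop("no output directory configured", class = "netpharm_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_compound_table(report$compounds$retained, fp("retained_compounds.tsv"))
  write_network(report$network$mapped, fp("compound_disease_network.sif"))
  write_topology_report(report$topology$report, fp("topology_report.tsv"))
  for (metric in names(report$topology$rankings)) {
    write.table(report$topology$rankings[[metric]],
                fp(paste0("centrality_", metric, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gene_list(report$topology$hubs, fp("hubs.txt"))
  write_enrichment(report$enrichment$results, fp("enrichment.tsv"))
  write_enrichment(report$enrichment$top, fp("enrichment_top.tsv"))
  if (!is.null(report$genomics)) {
    g <- report$genomics
    write.table(data.frame(gene = names(g$summary$per_gene_freq),
                           alteration_frequency = g$summary$per_gene_freq),
                fp("alteration_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(g$mutex)) {
      write.table(g$mutex, fp("mutual_exclusivity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(g$survival$km_altered)) {
      write.table(g$survival$km_altered, fp("km_altered.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(g$survival$km_unaltered)) {
      write.table(g$survival$km_unaltered, fp("km_unaltered.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(report_to_json(report), fp("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# JSON-serializable view of a report (graphs reduced to counts)
report_to_json <- function(report) {
  g <- report$genomics
  list(
    counts = report$counts,
    thresholds = report$config$thresholds,
    retained_compounds = report$compounds$retained$name,
    cancer_targets = report$network$cancer_targets,
    topology = unclass(report$topology$report),
    hubs = report$topology$hubs,
    enrichment_top = as.data.frame(report$enrichment$top),
    genomics = if (is.null(g)) NULL else list(
      genes = g$genes,
      per_gene_freq = as.list(g$summary$per_gene_freq),
      altered_fraction = g$summary$altered_fraction,
      mutex = g$mutex,
      logrank = if (!is.null(g$survival$logrank)) {
        g$survival$logrank[c("chi_square", "p", "n_a", "n_b")]
      } else NULL
    ),
    provenance = report$provenance
  )
}
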