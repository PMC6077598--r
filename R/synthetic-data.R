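# Seeded generators emulating every pipeline input: OB/DL-distributed
# compound libraries, heavy-tailed compound-target maps, connected PPI
# graphs, gene-set universes with a planted enriched category, and
# alteration cohorts with exponential survival.

# Fixed per-generator substream offsets: regenerating one input never
# perturbs the others.
SUBSTREAMS <- c(compounds = 11L, targets = 23L, ppi = 37L, genesets = 53L,
                cohort = 71L, disease = 89L)

substream_seed <- function(seed, stream) {
  (seed + SUBSTREAMS[[stream]] * 1000003L) %% 2147483629L
}

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the scale of a four-herb formula study: per-herb compound
#' counts (48/143/140/98), a right-skewed oral-bioavailability law and a
#' bounded drug-likeness law calibrated so roughly a fifth of the library
#' passes the (30, 0.18) screen, 200 putative targets with a power-law
#' degree tail, a connected 98-node/1027-edge PPI graph, a 2000-gene
#' universe with 300 categories and one planted enriched category, and a
#' 100-sample cohort with per-gene alteration rate 0.13 (about 63% of
#' samples altered across a 7-gene query) and exponential survival with a
#' hazard ratio for altered samples.
#'
#' @param seed Root integer seed (< 2^30); every generator derives its own
#'   substream from it.
#' @param n_compounds Named integer vector of compounds per herb.
#' @param ob_meanlog,ob_sdlog Log-normal parameters of the oral
#'   bioavailability distribution (percent scale).
#' @param dl_shape1,dl_shape2 Beta parameters of the drug-likeness
#'   distribution on \[0, 1\].
#' @param ob_min,dl_min Screening thresholds used for ground-truth labels.
#' @param n_targets Number of putative targets.
#' @param target_degree_exponent Power-law exponent of the target degree
#'   distribution.
#' @param target_degree_xmin Lower cutoff of the target degree power law;
#'   together with the exponent this sets the mean compounds-per-target
#'   (about `xmin (a-1)/(a-2)` for exponent `a > 2`).
#' @param score_min Confidence threshold used downstream (strict).
#' @param ppi_nodes,ppi_edges Node and edge counts of the generated PPI.
#' @param n_genes Reference universe size.
#' @param n_categories Number of gene-set categories.
#' @param category_size_range Inclusive integer range of category sizes.
#' @param planted_enrichment_fold Sampling-weight fold of the planted
#'   category's genes in the query (1 = null).
#' @param query_size Query gene-list size for enrichment calibration.
#' @param disease_fraction Fraction of targets included in the synthetic
#'   disease-target list.
#' @param n_samples Cohort size.
#' @param per_gene_alteration_rate Marginal per-gene alteration probability.
#' @param planted_log_odds Pairwise log-odds of alteration co-occurrence
#'   (0 = independent).
#' @param baseline_hazard Exponential event hazard per month for unaltered
#'   samples.
#' @param hazard_ratio Hazard multiplier for altered samples (1 = null).
#' @param censoring_rate Exponential censoring hazard per month (0 = none).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_compounds = c(Huanglian = 48L, Huangqin = 143L,
                                             Huangbo = 140L, Zhizi = 98L),
                             ob_meanlog = log(27), ob_sdlog = 0.45,
                             dl_shape1 = 1.3, dl_shape2 = 4.5,
                             ob_min = 30, dl_min = 0.18,
                             n_targets = 200L,
                             target_degree_exponent = 2.3,
                             target_degree_xmin = 4L,
                             score_min = 0.7,
                             ppi_nodes = 98L, ppi_edges = 1027L,
                             n_genes = 2000L, n_categories = 300L,
                             category_size_range = c(50L, 200L),
                             planted_enrichment_fold = 5,
                             query_size = 98L,
                             disease_fraction = 0.6,
                             n_samples = 100L,
                             per_gene_alteration_rate = 0.13,
                             planted_log_odds = 0,
                             baseline_hazard = 0.02,
                             hazard_ratio = 2,
                             censoring_rate = 0.01) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed < 0 || seed >= 2^30) {
    np_stop("seed must be a single integer in [0, 2^30)",
            class = "netpharm_config_error")
  }
  cfg <- list(seed = as.integer(seed), n_compounds = n_compounds,
              ob_meanlog = ob_meanlog, ob_sdlog = ob_sdlog,
              dl_shape1 = dl_shape1, dl_shape2 = dl_shape2,
              ob_min = ob_min, dl_min = dl_min,
              n_targets = as.integer(n_targets),
              target_degree_exponent = target_degree_exponent,
              target_degree_xmin = as.integer(target_degree_xmin),
              score_min = score_min,
              ppi_nodes = as.integer(ppi_nodes),
              ppi_edges = as.integer(ppi_edges),
              n_genes = as.integer(n_genes),
              n_categories = as.integer(n_categories),
              category_size_range = as.integer(category_size_range),
              planted_enrichment_fold = planted_enrichment_fold,
              query_size = as.integer(query_size),
              disease_fraction = disease_fraction,
              n_samples = as.integer(n_samples),
              per_gene_alteration_rate = per_gene_alteration_rate,
              planted_log_odds = planted_log_odds,
              baseline_hazard = baseline_hazard,
              hazard_ratio = hazard_ratio,
              censoring_rate = censoring_rate)
  with(cfg, {
    if (is.null(names(n_compounds)) || any(n_compounds < 1)) {
      np_stop("n_compounds must be a named vector of positive counts",
              class = "netpharm_config_error")
    }
    if (ob_sdlog <= 0 || dl_shape1 <= 0 || dl_shape2 <= 0) {
      np_stop("invalid distribution parameters", class = "netpharm_config_error")
    }
    if (target_degree_exponent <= 1 || target_degree_xmin < 1) {
      np_stop("target degree law needs exponent > 1 and xmin >= 1",
              class = "netpharm_config_error")
    }
    if (ppi_edges > ppi_nodes * (ppi_nodes - 1) / 2 || ppi_edges < ppi_nodes - 1) {
      np_stop("ppi_edges incompatible with a connected simple graph on ",
              ppi_nodes, " nodes", class = "netpharm_config_error")
    }
    if (per_gene_alteration_rate < 0 || per_gene_alteration_rate > 1 ||
        disease_fraction < 0 || disease_fraction > 1) {
      np_stop("rates must lie in [0, 1]", class = "netpharm_config_error")
    }
    if (baseline_hazard <= 0 || hazard_ratio <= 0 || censoring_rate < 0 ||
        planted_enrichment_fold <= 0) {
      np_stop("hazards, hazard ratio and enrichment fold must be positive",
              class = "netpharm_config_error")
    }
  })
  structure(cfg, class = "generator_config")
}

#' The synthetic reference universe of gene symbols
#'
#' @param cfg A [generator_config()].
#' @return Character vector `G00001 ... G<n_genes>` (deterministic, no RNG).
#' @export
gen_universe <- function(cfg) {
  sprintf("G%05d", seq_len(cfg$n_genes))
}

#' Generate a synthetic herbal compound library
#'
#' Oral bioavailability is log-normal (right-skewed, percent scale) and
#' drug-likeness is Beta on \[0, 1\]; both are drawn independently per
#' compound.
#'
#' @param cfg A [generator_config()].
#' @return List: `compounds` (data frame `herb`, `name`, `ob`, `dl`) and
#'   `active` (logical ground-truth labels at the config thresholds).
#' @export
gen_compound_library <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(cfg$seed, "compounds"))
  herbs <- rep(names(cfg$n_compounds), cfg$n_compounds)
  n <- length(herbs)
  compounds <- data.frame(
    herb = herbs,
    name = sprintf("%s_cmpd%03d", herbs,
                   unlist(lapply(cfg$n_compounds, seq_len), use.names = FALSE)),
    ob = round(rlnorm(n, cfg$ob_meanlog, cfg$ob_sdlog), 2),
    dl = round(rbeta(n, cfg$dl_shape1, cfg$dl_shape2), 2),
    stringsAsFactors = FALSE
  )
  list(compounds = compounds,
       active = compounds$ob >= cfg$ob_min & compounds$dl >= cfg$dl_min)
}

# Discrete power-law degrees (Clauset-style continuous approximation):
# k = floor((xmin - 1/2) (1-u)^(-1/(alpha-1)) + 1/2)
rpowerlaw <- function(n, alpha, xmin = 1, cap = Inf) {
  u <- runif(n)
  k <- floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
  pmin(k, cap)
}

#' Generate a synthetic compound-target prediction map
#'
#' Target symbols are drawn from the reference universe; each target's
#' degree (number of interacting compounds) follows a discrete power law
#' with exponent `target_degree_exponent`, yielding the heavy-tailed hub
#' structure of real target maps. Confidence scores are uniform on
#' \[0, 1\].
#'
#' @param cfg A [generator_config()].
#' @param compounds Compound data frame (typically
#'   `gen_compound_library(cfg)$compounds`).
#' @return Data frame `compound`, `target`, `score` (one row per distinct
#'   association).
#' @export
gen_target_map <- function(cfg, compounds) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(cfg$seed, "targets"))
  universe <- gen_universe(cfg)
  targets <- sample(universe, cfg$n_targets)
  cmpd <- compounds$name
  deg <- rpowerlaw(cfg$n_targets, cfg$target_degree_exponent,
                   xmin = cfg$target_degree_xmin, cap = length(cmpd))
  out <- do.call(rbind, lapply(seq_len(cfg$n_targets), function(j) {
    data.frame(compound = sample(cmpd, deg[j]), target = targets[j],
               stringsAsFactors = FALSE)
  }))
  out$score <- runif(nrow(out))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic disease-target gene list
#'
#' A fraction of the prediction targets plus background genes from the
#' universe, emulating a curated disease-target catalogue that overlaps but
#' does not contain the predicted target set.
#'
#' @param cfg A [generator_config()].
#' @param targets Character vector of predicted target symbols.
#' @return Character vector of disease-target symbols.
#' @export
gen_disease_targets <- function(cfg, targets) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(cfg$seed, "disease"))
  targets <- gene_list(targets)
  n_in <- round(cfg$disease_fraction * length(targets))
  background <- setdiff(gen_universe(cfg), targets)
  gene_list(c(sample(targets, n_in),
              sample(background, min(length(background), n_in))))
}

#' Generate a connected PPI graph with exact node and edge counts
#'
#' Uniform over connected simple graphs with the requested counts, via
#' repeated uniform m-edge draws rejected until connected.
#'
#' @param cfg A [generator_config()].
#' @param nodes Optional character vector of node names (length
#'   `ppi_nodes`); defaults to `T001 ...`.
#' @return A connected simple undirected [igraph::graph].
#' @export
gen_ppi <- function(cfg, nodes = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(cfg$seed, "ppi"))
  n <- cfg$ppi_nodes
  if (is.null(nodes)) {
    nodes <- sprintf("T%03d", seq_len(n))
  }
  stopifnot(length(nodes) == n)
  for (i in seq_len(10000)) {
    g <- igraph::sample_gnm(n, cfg$ppi_edges)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- nodes
      igraph::E(g)$type <- "pp"
      return(g)
    }
  }
  np_stop("failed to draw a connected graph; edge count too sparse",
          class = "netpharm_config_error")
}

#' Generate a gene-set collection with one planted enriched category
#'
#' Categories are drawn uniformly from the universe at sizes uniform in
#' `category_size_range`. The query is sampled without replacement with
#' weight `planted_enrichment_fold` on the first category's genes and 1
#' elsewhere; a fold of 1 gives the hypergeometric null for every category.
#'
#' @param cfg A [generator_config()].
#' @return List: `collection` (a [geneset_collection()] whose reference is
#'   the full universe), `query` (character), `planted` (the planted
#'   category's name).
#' @export
gen_genesets <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(cfg$seed, "genesets"))
  universe <- gen_universe(cfg)
  sizes <- sample(seq(cfg$category_size_range[1], cfg$category_size_range[2]),
                  cfg$n_categories, replace = TRUE)
  cats <- lapply(sizes, function(s) sample(universe, s))
  names(cats) <- sprintf("PW%04d", seq_len(cfg$n_categories))
  planted <- names(cats)[1]
  w <- rep(1, cfg$n_genes)
  w[universe %in% cats[[planted]]] <- cfg$planted_enrichment_fold
  query <- sample(universe, cfg$query_size, prob = w)
  list(collection = geneset_collection(cats, reference = universe),
       query = query, planted = planted)
}

# Solve the shared-latent alteration rates (p0, p1) giving marginal rate p
# and pairwise log-odds lambda between two genes tied to the same latent.
shared_latent_rates <- function(p, lambda) {
  if (lambda == 0 || p == 0 || p == 1) return(c(p0 = p, p1 = p))
  pair_log_odds <- function(delta) {
    p1 <- p + delta; p0 <- p - delta
    p11 <- (p1^2 + p0^2) / 2
    p10 <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
    p00 <- ((1 - p1)^2 + (1 - p0)^2) / 2
    log(p11 * p00 / p10^2)
  }
  dmax <- min(p, 1 - p) - 1e-9
  target <- abs(lambda)
  if (pair_log_odds(dmax) < target) {
    np_warn("planted_log_odds ", lambda, " unattainable at rate ", p,
            "; using the maximum attainable dependence")
    delta <- dmax
  } else {
    delta <- uniroot(function(d) pair_log_odds(d) - target,
                     c(0, dmax), tol = 1e-10)$root
  }
  c(p0 = p - delta, p1 = p + delta)
}

#' Generate a synthetic alteration cohort with survival
#'
#' Per-gene Bernoulli alterations at the configured marginal rate; pairwise
#' dependence is induced by a shared per-sample latent state whose strength
#' is solved from `planted_log_odds` (positive values plant co-occurrence;
#' negative values plant exclusivity by flipping the latent for alternating
#' genes). Each alteration receives a random type. Survival is exponential
#' with the baseline hazard, multiplied by `hazard_ratio` for samples
#' altered in at least one query gene; censoring is independent exponential.
#'
#' @param cfg A [generator_config()].
#' @param query_genes Gene symbols of the cohort's queried genes.
#' @return List: `matrix` (an [alteration_matrix()]), `survival` (data
#'   frame `sample`, `time`, `event`), `altered` (ground-truth altered
#'   sample IDs).
#' @export
gen_cohort <- function(cfg, query_genes) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(cfg$seed, "cohort"))
  genes <- gene_list(query_genes)
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  rates <- shared_latent_rates(cfg$per_gene_alteration_rate,
                               cfg$planted_log_odds)
  latent <- rbinom(cfg$n_samples, 1, 0.5)
  flip <- if (cfg$planted_log_odds < 0) {
    seq_along(genes) %% 2 == 0
  } else {
    rep(FALSE, length(genes))
  }
  events <- list()
  altered_mask <- rep(FALSE, cfg$n_samples)
  for (j in seq_along(genes)) {
    lat <- if (flip[j]) 1 - latent else latent
    pj <- ifelse(lat == 1, rates["p1"], rates["p0"])
    hit <- runif(cfg$n_samples) < pj
    altered_mask <- altered_mask | hit
    if (any(hit)) {
      events[[j]] <- data.frame(
        sample = samples[hit], gene = genes[j],
        alteration_type = sample(ALTERATION_TYPES, sum(hit), replace = TRUE,
                                 prob = c(0.3, 0.2, 0.35, 0.15)),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(sample = character(0), gene = character(0),
               alteration_type = character(0))
  hazard <- cfg$baseline_hazard * ifelse(altered_mask, cfg$hazard_ratio, 1)
  t_event <- rexp(cfg$n_samples, rate = hazard)
  t_cens <- if (cfg$censoring_rate > 0) {
    rexp(cfg$n_samples, rate = cfg$censoring_rate)
  } else {
    rep(Inf, cfg$n_samples)
  }
  surv <- data.frame(sample = samples,
                     time = round(pmin(t_event, t_cens), 3),
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)
  list(matrix = alteration_matrix(events, samples = samples, genes = genes),
       survival = surv, altered = samples[altered_mask])
}

#' Write a full set of synthetic pipeline inputs to disk
#'
#' Emits every input file the analysis modules read (compound table,
#' prediction table, disease-target list, PPI SIF, GMT gene sets, reference
#' universe, alteration and survival tables), a ready-to-run pipeline
#' config, and a ground-truth JSON with the generator's bookkeeping.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named list of written file paths.
#' @export
generate_fixtures <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)

  lib <- gen_compound_library(cfg)
  write_compound_table(lib$compounds, fp("compounds.tsv"))
  preds <- gen_target_map(cfg, lib$compounds)
  write.table(preds, fp("predictions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  disease <- gen_disease_targets(cfg, unique(preds$target))
  write_gene_list(disease, fp("disease_targets.txt"))

  # PPI over the targets that survive screening + score filter + disease map
  active <- lib$compounds[lib$active, , drop = FALSE]
  kept <- filter_predictions(preds, cfg$score_min)
  net <- suppressWarnings(build_compound_target_network(active, kept))
  mapped <- suppressWarnings(map_to_disease_targets(net, disease))
  ppi_names <- mapped$targets
  if (length(ppi_names) >= cfg$ppi_nodes) {
    ppi_names <- ppi_names[seq_len(cfg$ppi_nodes)]
  } else {
    pool <- setdiff(disease, ppi_names)
    ppi_names <- c(ppi_names,
                   pool[seq_len(cfg$ppi_nodes - length(ppi_names))])
  }
  ppi <- gen_ppi(cfg, nodes = ppi_names)
  write_network(ppi, fp("ppi.sif"), dialect = "sif")

  # plant the enriched category over the PPI targets so the pipeline's own
  # query (the PPI node list) carries the planted signal
  gs <- gen_genesets(cfg)
  cats <- gs$collection$categories
  planted_size <- length(cats[[gs$planted]])
  n_in <- min(length(ppi_names), round(0.6 * planted_size))
  universe <- gen_universe(cfg)
  filler <- sample(setdiff(universe, ppi_names), planted_size - n_in)
  cats[[gs$planted]] <- c(sample(ppi_names, n_in), filler)
  write_gmt(cats, fp("pathways.gmt"))
  write_gene_list(gs$collection$reference, fp("reference.txt"))

  report <- topology_report(ppi)
  hubs <- hub_screen(igraph::degree(ppi), report$avg_neighbors)
  cohort_genes <- head(hubs, 7) %||% character(0)
  if (length(cohort_genes) < 2) cohort_genes <- head(ppi_names, 7)
  cohort <- gen_cohort(cfg, cohort_genes)
  write.table(data.frame(sample = cohort$matrix$events$sample,
                         gene = cohort$matrix$events$gene,
                         alteration_type = cohort$matrix$events$alteration_type),
              fp("alterations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = cohort$survival$sample,
                         os_months = cohort$survival$time,
                         os_event = cohort$survival$event),
              fp("survival.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  config <- list(
    inputs = list(compounds = fp("compounds.tsv"),
                  predictions = fp("predictions.tsv"),
                  disease_targets = fp("disease_targets.txt"),
                  ppi = fp("ppi.sif"),
                  gmt = fp("pathways.gmt"),
                  reference = fp("reference.txt"),
                  alterations = fp("alterations.tsv"),
                  survival = fp("survival.tsv")),
    thresholds = list(ob_min = cfg$ob_min, dl_min = cfg$dl_min,
                      score_min = cfg$score_min, hub_multiplier = 2,
                      top_k_centrality = 30, top_k_pathways = 10,
                      adjp_max = 0.01),
    genomics_genes = cohort_genes,
    out_dir = fp("results")
  )
  yaml::write_yaml(config, fp("config.yaml"))

  truth <- list(seed = cfg$seed,
                n_compounds = nrow(lib$compounds),
                n_active = sum(lib$active),
                active_names = lib$compounds$name[lib$active],
                n_predictions = nrow(preds),
                n_predictions_kept = nrow(kept),
                mapped_targets = mapped$targets,
                ppi_nodes = igraph::vcount(ppi),
                ppi_edges = igraph::ecount(ppi),
                planted_category = gs$planted,
                query = gs$query,
                cohort_genes = cohort_genes,
                altered_samples = cohort$altered,
                hazard_ratio = cfg$hazard_ratio)
  jsonlite::write_json(truth, fp("ground_truth.json"), auto_unbox = TRUE)

  invisible(c(lapply(config$inputs, identity),
              list(config = fp("config.yaml"),
                   ground_truth = fp("ground_truth.json"))))
}
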