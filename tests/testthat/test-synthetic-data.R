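test_that("generator config validates its parameters", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(seed = 2^31), class = "netpharm_config_error")
  expect_error(generator_config(ppi_nodes = 10, ppi_edges = 100),
               class = "netpharm_config_error")
  expect_error(generator_config(per_gene_alteration_rate = 1.5),
               class = "netpharm_config_error")
  expect_error(generator_config(target_degree_exponent = 0.9),
               class = "netpharm_config_error")
})

test_that("every generator is a pure function of the seed", {
  cfg <- generator_config(seed = 99)
  expect_identical(gen_compound_library(cfg), gen_compound_library(cfg))
  lib <- gen_compound_library(cfg)$compounds
  expect_identical(gen_target_map(cfg, lib), gen_target_map(cfg, lib))
  expect_identical(igraph::as_edgelist(gen_ppi(cfg)),
                   igraph::as_edgelist(gen_ppi(cfg)))
  expect_identical(gen_genesets(cfg)$query, gen_genesets(cfg)$query)
  expect_identical(gen_cohort(cfg, c("G00001", "G00002")),
                   gen_cohort(cfg, c("G00001", "G00002")))
  # different seeds differ
  cfg2 <- generator_config(seed = 100)
  expect_false(identical(gen_compound_library(cfg)$compounds$ob,
                         gen_compound_library(cfg2)$compounds$ob))
})

test_that("ground-truth activity labels agree with the screening module", {
  cfg <- generator_config(seed = 5,
                          n_compounds = c(A = 500L, B = 500L))
  lib <- gen_compound_library(cfg)
  screened <- screen_compounds(lib$compounds, cfg$ob_min, cfg$dl_min)
  expect_equal(lib$compounds$name[lib$active], screened$retained$name)
  expect_equal(sum(!lib$active), nrow(screened$discarded))

  # degenerate DL distribution concentrated above the threshold
  cfg2 <- generator_config(seed = 5, dl_shape1 = 5000, dl_shape2 = 5000)
  lib2 <- gen_compound_library(cfg2)  # Beta(5000,5000) ~ 0.5
  expect_true(all(lib2$compounds$dl >= 0.18))
})

test_that("target map has heavy-tailed degrees and uniform scores", {
  cfg <- generator_config(seed = 8, n_targets = 600L,
                          n_compounds = c(A = 2000L),
                          target_degree_exponent = 2.3,
                          target_degree_xmin = 4L)
  lib <- gen_compound_library(cfg)$compounds
  preds <- gen_target_map(cfg, lib)
  expect_gt(nrow(preds), 5000)
  deg <- table(preds$target)
  # discrete power-law MLE (Clauset continuous approximation) at the
  # generator's own xmin recovers the exponent
  d <- as.numeric(deg[deg >= cfg$target_degree_xmin])
  alpha_hat <- 1 + length(d) / sum(log(d / (cfg$target_degree_xmin - 0.5)))
  expect_lt(abs(alpha_hat - cfg$target_degree_exponent), 0.3)
  # scores uniform: strict >0.7 retention near 30%
  frac <- nrow(filter_predictions(preds, 0.7)) / nrow(preds)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(preds)) + 0.01)
})

test_that("PPI generator hits exact node and edge counts and is connected", {
  cfg <- generator_config(seed = 12)
  g <- gen_ppi(cfg)
  expect_equal(igraph::vcount(g), 98L)
  expect_equal(igraph::ecount(g), 1027L)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
  expect_equal(topology_report(g)$avg_neighbors, 2 * 1027 / 98)

  k3 <- generator_config(seed = 12, ppi_nodes = 3L, ppi_edges = 3L)
  g3 <- gen_ppi(k3)
  expect_equal(igraph::ecount(g3), 3L)
  expect_equal(topology_report(g3)$density, 1)

  for (s in 1:20) {
    cfg_s <- generator_config(seed = s, ppi_nodes = 30L, ppi_edges = 60L)
    expect_equal(igraph::ecount(gen_ppi(cfg_s)), 60L)
  }
})

test_that("null gene-set generator is calibrated at the nominal level", {
  n_sig <- 0L
  n_tot <- 0L
  for (r in 1:40) {
    cfg <- generator_config(seed = 6000 + r, n_genes = 1500,
                            n_categories = 100,
                            planted_enrichment_fold = 1, query_size = 90)
    gs <- gen_genesets(cfg)
    res <- enrich(gs$query, gs$collection)
    n_sig <- n_sig + sum(res$rawP < 0.05)
    n_tot <- n_tot + nrow(res)
  }
  rate <- n_sig / n_tot
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.075)
})

test_that("cohort generator recovers its planted parameters at large n", {
  genes <- sprintf("G%05d", 1:7)
  cfg <- generator_config(seed = 404, n_samples = 2000,
                          per_gene_alteration_rate = 0.13,
                          hazard_ratio = 1, censoring_rate = 0)
  cohort <- gen_cohort(cfg, genes)
  s <- alteration_summary(cohort$matrix, genes)
  mc_err <- 3 * sqrt(0.13 * 0.87 / 2000)
  expect_true(all(abs(s$per_gene_freq - 0.13) < mc_err))
  # hazard_ratio = 1, censoring 0: exponential mean 1/baseline_hazard
  expect_lt(abs(mean(cohort$survival$time) - 1 / cfg$baseline_hazard),
            3 * (1 / cfg$baseline_hazard) / sqrt(2000))
  expect_true(all(cohort$survival$event == 1))

  # independent alterations: pairwise Fisher p has no systematic signal
  cfg0 <- generator_config(seed = 405, n_samples = 500, planted_log_odds = 0)
  ps <- vapply(1:20, function(r) {
    co <- gen_cohort(generator_config(seed = 500 + r, n_samples = 300,
                                      planted_log_odds = 0), genes[1:2])
    mutual_exclusivity(co$matrix, genes[1], genes[2])$p
  }, 0)
  expect_gt(median(ps), 0.2)

  # planted positive log-odds produces co-occurrence
  co_pos <- gen_cohort(generator_config(seed = 406, n_samples = 3000,
                                        planted_log_odds = 1.5,
                                        per_gene_alteration_rate = 0.3),
                       genes[1:2])
  m <- mutual_exclusivity(co_pos$matrix, genes[1], genes[2])
  expect_gt(m$log2_odds, 0)
  expect_lt(m$p, 0.05)
})

test_that("fixture writer emits readable inputs consistent with ground truth", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(seed = 55)
  generate_fixtures(cfg, dir)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  lib <- read_compound_table(file.path(dir, "compounds.tsv"))
  expect_equal(nrow(lib), truth$n_compounds)
  screened <- screen_compounds(lib, cfg$ob_min, cfg$dl_min)
  expect_equal(screened$retained$name, truth$active_names)
  ppi <- read_network(file.path(dir, "ppi.sif"), "sif")
  expect_equal(igraph::vcount(ppi), truth$ppi_nodes)
  expect_equal(igraph::ecount(ppi), truth$ppi_edges)
  preds <- read_predictions(file.path(dir, "predictions.tsv"))
  expect_equal(nrow(preds), truth$n_predictions)
  expect_equal(nrow(filter_predictions(preds, cfg$score_min)),
               truth$n_predictions_kept)
})
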