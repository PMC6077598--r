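worked_matrix <- function() {
  events <- data.frame(
    sample = c("s1", "s2", "s2"),
    gene = c("A", "A", "B"),
    alteration_type = c("amplification", "missense_mutation",
                        "deep_deletion"))
  alteration_matrix(events, samples = c("s1", "s2", "s3", "s4"),
                    genes = c("A", "B", "C"))
}

test_that("alteration summary counts frequencies per gene and per sample", {
  mat <- worked_matrix()
  s <- alteration_summary(mat, c("A", "B", "C"))
  expect_equal(unname(s$per_gene_freq), c(0.5, 0.25, 0))
  expect_equal(s$altered_fraction, 0.5)
  expect_setequal(s$altered_samples, c("s1", "s2"))

  empty <- alteration_matrix(data.frame(), samples = c("s1", "s2"),
                             genes = c("A"))
  s0 <- alteration_summary(empty, "A")
  expect_equal(unname(s0$per_gene_freq), 0)
  expect_equal(s0$altered_fraction, 0)

  full <- alteration_matrix(
    expand.grid(sample = c("s1", "s2"), gene = c("A", "B"),
                alteration_type = "amplification",
                stringsAsFactors = FALSE))
  sf <- alteration_summary(full)
  expect_equal(unname(sf$per_gene_freq), c(1, 1))
  expect_equal(sf$altered_fraction, 1)

  expect_error(alteration_summary(mat, "ZZZ"),
               class = "netpharm_membership_error")
})

test_that("summary is invariant to sample and gene reordering", {
  mat <- worked_matrix()
  ev2 <- mat$events[c(3, 1, 2), ]
  mat2 <- alteration_matrix(ev2, samples = rev(mat$samples),
                            genes = rev(mat$genes))
  s1 <- alteration_summary(mat, c("A", "B"))
  s2 <- alteration_summary(mat2, c("A", "B"))
  expect_equal(s1$per_gene_freq, s2$per_gene_freq)
  expect_equal(s1$altered_fraction, s2$altered_fraction)
})

test_that("oncoprint memo-sort orders genes by frequency and samples by profile", {
  mat <- worked_matrix()
  ord <- oncoprint_order(mat, c("A", "B", "C"))
  expect_equal(ord$gene_order, c("A", "B", "C"))
  expect_equal(ord$sample_order, c("s2", "s1", "s3", "s4"))

  # permuting declared sample order leaves altered-before-unaltered intact
  mat2 <- alteration_matrix(mat$events, samples = c("s4", "s3", "s2", "s1"),
                            genes = mat$genes)
  ord2 <- oncoprint_order(mat2, c("A", "B", "C"))
  expect_equal(ord2$sample_order, c("s2", "s1", "s4", "s3"))

  single <- alteration_matrix(
    data.frame(sample = "s2", gene = "A", alteration_type = "amplification"),
    samples = c("s1", "s2", "s3"), genes = "A")
  expect_equal(oncoprint_order(single, "A")$sample_order,
               c("s2", "s1", "s3"))
})

mutex_from_counts <- function(both, a_only, b_only, neither) {
  mk <- function(n, prefix) if (n > 0) sprintf("%s%03d", prefix, seq_len(n)) else character(0)
  s_both <- mk(both, "b"); s_a <- mk(a_only, "a")
  s_b <- mk(b_only, "c"); s_n <- mk(neither, "n")
  events <- rbind(
    data.frame(sample = c(s_both, s_a), gene = "GA",
               alteration_type = "amplification"),
    data.frame(sample = c(s_both, s_b), gene = "GB",
               alteration_type = "amplification"))
  alteration_matrix(events, samples = c(s_both, s_a, s_b, s_n),
                    genes = c("GA", "GB"))
}

test_that("mutual exclusivity reproduces exact Fisher probabilities", {
  m1 <- mutual_exclusivity(mutex_from_counts(1, 1, 1, 1), "GA", "GB")
  expect_equal(m1$p, 1.0)
  expect_equal(m1$direction, "none")

  m2 <- mutual_exclusivity(mutex_from_counts(3, 0, 0, 3), "GA", "GB")
  expect_equal(m2$p, 0.1)  # 2/20 by enumeration
  expect_true(m2$log2_odds > 0)
  expect_equal(sum(m2$table), 6)

  # a gene against itself is perfect co-occurrence
  m3 <- mutual_exclusivity(mutex_from_counts(4, 0, 0, 4), "GA", "GA")
  expect_true(m3$log2_odds > 0)
  expect_equal(m3$table[1, 1] + m3$table[2, 2], 8)
})

test_that("Fisher p equals the exhaustive enumeration oracle on random tables", {
  set.seed(23)
  for (i in 1:40) {
    cnt <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    m <- mutual_exclusivity(mutex_from_counts(cnt[1], cnt[2], cnt[3], cnt[4]),
                            "GA", "GB")
    expect_equal(m$p, fisher_oracle(m$table), tolerance = 1e-9)
  }
})

test_that("Kaplan-Meier estimator follows product-limit bookkeeping", {
  # all censored -> flat at 1
  km0 <- km_curve(data.frame(time = c(1, 2, 3), event = 0))
  expect_true(all(km0$survival == 1))

  # deaths at 1 and 2, no censoring
  km1 <- km_curve(data.frame(time = c(1, 2), event = 1))
  expect_equal(km1$survival, c(0.5, 0))

  # censor at 1 shrinks the risk set: S(2) = 1 - 1/1 = 0
  km2 <- km_curve(data.frame(time = c(1, 2), event = c(0, 1)))
  expect_equal(km2$survival[km2$time == 2], 0)

  # non-increasing, in [0, 1]
  set.seed(19)
  km3 <- km_curve(data.frame(time = rexp(50), event = rbinom(50, 1, 0.7)))
  expect_true(all(diff(km3$survival) <= 1e-12))
  expect_true(all(km3$survival >= 0 & km3$survival <= 1))

  expect_error(km_curve(data.frame(time = -1, event = 1)),
               class = "netpharm_domain_error")
  expect_error(km_curve(data.frame()), class = "netpharm_empty_input_error")
})

logrank_oracle <- function(a, b) {
  # per-event-time O - E / V tabulation by hand
  dat <- rbind(cbind(a, g = 0), cbind(b, g = 1))
  times <- sort(unique(dat$time[dat$event == 1]))
  O_E <- 0; V <- 0
  for (t in times) {
    at_risk <- dat$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & dat$g == 0)
    d <- sum(dat$time == t & dat$event == 1)
    d1 <- sum(dat$time == t & dat$event == 1 & dat$g == 0)
    O_E <- O_E + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O_E^2 / V
}

test_that("log-rank statistic matches hand tabulation and is label-symmetric", {
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(3, 4), event = 1)
  lr <- logrank_test(a, b)
  expect_equal(lr$chi_square, logrank_oracle(a, b), tolerance = 1e-12)
  expect_equal(lr$p, pchisq(lr$chi_square, 1, lower.tail = FALSE))

  set.seed(37)
  g1 <- data.frame(time = round(rexp(30, 0.1), 2), event = rbinom(30, 1, 0.8))
  g2 <- data.frame(time = round(rexp(30, 0.2), 2), event = rbinom(30, 1, 0.8))
  lr12 <- logrank_test(g1, g2)
  lr21 <- logrank_test(g2, g1)
  expect_equal(lr12$chi_square, lr21$chi_square)
  expect_equal(lr12$p, lr21$p)
  expect_equal(lr12$chi_square, logrank_oracle(g1, g2), tolerance = 1e-9)

  same <- logrank_test(g1, g1)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  cens <- data.frame(time = c(1, 2), event = 0)
  expect_warning(lr0 <- logrank_test(cens, cens), "no events")
  expect_equal(lr0$p, 1)
})

test_that("survival comparison partitions by alteration status", {
  cfg <- generator_config(seed = 77, n_samples = 300, hazard_ratio = 3,
                          per_gene_alteration_rate = 0.13)
  cohort <- gen_cohort(cfg, sprintf("G%05d", 1:7))
  out <- survival_by_alteration(cohort$matrix, cohort$matrix$genes,
                                cohort$survival)
  expect_equal(out$n_altered, length(cohort$altered))
  expect_equal(out$n_altered + out$n_unaltered, 300)
  # planted worse survival in the altered arm: lower median survival
  med <- function(km) km$time[which(km$survival <= 0.5)[1]]
  expect_lt(med(out$km_altered), med(out$km_unaltered))
  expect_lt(out$logrank$p, 0.05)

  # all samples altered -> single curve plus warning
  all_alt <- alteration_matrix(
    data.frame(sample = c("s1", "s2"), gene = "A",
               alteration_type = "amplification"))
  rec <- data.frame(sample = c("s1", "s2"), time = c(3, 5), event = 1)
  expect_warning(one <- survival_by_alteration(all_alt, "A", rec),
                 "partition is empty")
  expect_null(one$km_unaltered)
  expect_null(one$logrank)

  expect_error(
    survival_by_alteration(all_alt, "A",
                           data.frame(sample = "zz", time = 1, event = 1)),
    class = "netpharm_membership_error")
})

test_that("alteration IO validates its schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgene\talteration_type",
               "s1\tTP53\tmissense_mutation"), path)
  mat <- read_alteration_table(path)
  expect_equal(mat$genes, "TP53")
  writeLines(c("sample\tgene\talteration_type", "s1\tTP53\tweird"), path)
  expect_error(read_alteration_table(path), class = "netpharm_parse_error")

  surv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tos_months\tos_event", "s1\t10.5\t1"), surv)
  rec <- read_survival_table(surv)
  expect_equal(rec$time, 10.5)
  writeLines(c("sample\tos_months\tos_event", "s1\t-2\t1"), surv)
  expect_error(read_survival_table(surv), class = "netpharm_domain_error")
})
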