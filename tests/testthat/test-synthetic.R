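test_that("annotations respect spacing, bounds and packing feasibility", {
  cfg <- synthetic_config(n_genes = 100L, chrom_len = 1e6, seed = 4)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$tss), 100L)
  expect_true(all(diff(sort(ann$tss$tss)) >= 8000))
  expect_true(all(ann$tss$tss >= cfg$flank &
                  ann$tss$tss <= cfg$chrom_len - cfg$flank))
  expect_length(intersect(ann$gene_sets$testis_specific,
                          ann$gene_sets$ovary_specific), 0L)
  expect_true(all(unlist(ann$gene_sets) %in% ann$tss$gene_id))
  expect_error(generate_annotation(
    synthetic_config(n_genes = 10000L, chrom_len = 1e6)),
    "infeasible packing")
})

test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- synthetic_config(n_genes = 60L, chrom_len = 2e6, seed = 123)
  ex1 <- simulate_experiment(cfg)
  ex2 <- simulate_experiment(cfg)
  expect_identical(ex1$annotation, ex2$annotation)
  expect_identical(ex1$truth, ex2$truth)
  expect_identical(ex1$tags$t1$k4$pos, ex2$tags$t1$k4$pos)
  expect_identical(ex1$tags$t2$k27$pos, ex2$tags$t2$k27$pos)
  expect_identical(ex1$expression, ex2$expression)
  # a different seed changes the tags
  ex3 <- simulate_experiment(synthetic_config(n_genes = 60L,
                                              chrom_len = 2e6, seed = 124))
  expect_false(identical(ex1$tags$t1$k4$pos, ex3$tags$t1$k4$pos))
})

test_that("with zero background all tags fall inside promoter windows", {
  cfg <- synthetic_config(n_genes = 1L, chrom_len = 20000L,
                          state_proportions = c(K4_ONLY = 0, K27_ONLY = 0,
                                                BIVALENT = 1, NEITHER = 0),
                          background_rate = 0, seed = 9)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg)
  expect_equal(as.character(truth$state_t0), "BIVALENT")
  tags <- simulate_tags(truth, ann, cfg)
  w <- promoter_windows(ann$tss, cfg$flank, ann$chrom_sizes)
  for (lib in tags) {
    expect_true(all(lib$pos >= w$start & lib$pos < w$end))
  }
  # a bivalent promoter is hot for both IP marks
  expect_gt(tags$k4$total_tags, 5 * tags$h3$total_tags)
  expect_gt(tags$k27$total_tags, 5 * tags$h3$total_tags)
})

test_that("truth states follow the configured proportions and transitions", {
  cfg <- synthetic_config(n_genes = 2000L, chrom_len = 2e7, seed = 15)
  truth <- simulate_truth(cfg)
  for (s in chromatin_states()) {
    p <- cfg$state_proportions[[s]]
    expect_lt(abs(mean(truth$state_t0 == s) - p),
              3 * sqrt(p * (1 - p) / 2000))
  }
  for (from in chromatin_states()) {
    sel <- truth$state_t0 == from
    n_r <- sum(sel)
    for (to in chromatin_states()) {
      p <- cfg$transition_matrix[from, to]
      expect_lte(abs(sum(truth$state_t1[sel] == to) - n_r * p),
                 3 * sqrt(max(n_r * p * (1 - p), 1)))
    }
  }
})

test_that("deeper libraries never hurt state recovery", {
  recovery <- function(lambda, seed) {
    cfg <- synthetic_config(n_genes = 100L, chrom_len = 1e7,
                            lambda_h3 = lambda, seed = seed)
    ann <- generate_annotation(cfg)
    truth <- simulate_truth(cfg)
    tags <- simulate_tags(truth, ann, cfg)
    w <- promoter_windows(ann$tss, cfg$flank, ann$chrom_sizes)
    st <- state_table(quantify_promoters(tags$k4, tags$k27, tags$h3, w), "t1")
    mean(as.character(st$state) ==
         as.character(truth$state_t0[match(st$gene_id, truth$gene_id)]))
  }
  seeds <- 1:20
  shallow <- vapply(seeds, function(s) recovery(3, s), numeric(1))
  deep <- vapply(seeds, function(s) recovery(6, s), numeric(1))
  expect_gte(mean(deep), mean(shallow))
})

test_that("simulated qPCR plates invert the delta-CT formula", {
  plate0 <- simulate_qpcr(c(tgt = 0.5), noise_sd_ct = 0, n_replicates = 2,
                          seed = 5)
  expect_equal(bound_unbound_ratio(plate0$ct_bound, plate0$ct_unbound),
               rep(0.5, 2))
  # byte-identical under a fixed seed
  expect_identical(plate0, simulate_qpcr(c(tgt = 0.5), noise_sd_ct = 0,
                                         n_replicates = 2, seed = 5))
  # with CT noise, the replicate mean stays within 3 SEM of the truth
  plate <- simulate_qpcr(c(tgt = 0.5), noise_sd_ct = 0.2, n_replicates = 10,
                         seed = 6)
  res <- analyze_qpcr(plate, protocol = "native", control_antibody = NULL)
  expect_lt(abs(res$enrichment - 0.5), 3 * res$sem + 1e-9)
})

test_that("negative-binomial overdispersion is available for stress tests", {
  cfg <- synthetic_config(n_genes = 50L, chrom_len = 5e6,
                          overdispersion = 2, seed = 77)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg)
  tags <- simulate_tags(truth, ann, cfg)
  w <- promoter_windows(ann$tss, cfg$flank, ann$chrom_sizes)
  c_h3 <- count_window_tags(tags$h3, w)
  # NB window counts are visibly overdispersed relative to Poisson
  expect_gt(var(c_h3) / mean(c_h3), 2)
})
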