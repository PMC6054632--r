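test_that("identical (config, seed) reproduces the dataset bit-for-bit", {
  cfg <- sim_config(n_genes = 100L, depth_pulse = 1e5, depth_chase = 1e5,
                    n_sets = 2L, set_size = 10L, planted_motif = "UGUGUG")
  a <- simulate_experiment(cfg, 11L)
  b <- simulate_experiment(cfg, 11L)
  expect_identical(a, b)
})

test_that("different seeds change counts but not the truth table", {
  cfg <- sim_config(n_genes = 100L, depth_pulse = 1e5, depth_chase = 1e5,
                    n_sets = 2L, set_size = 10L)
  a <- simulate_experiment(cfg, 1L)
  b <- simulate_experiment(cfg, 2L)
  expect_false(identical(a$counts, b$counts))
  expect_identical(a$truth, b$truth)
  expect_identical(a$gene_models, b$gene_models)
  expect_identical(a$gene_sets, b$gene_sets)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(simulate_experiment(sim_config(n_genes = 20L, n_sets = 0L,
                                           set_size = 0L,
                                           groups = null_groups(1L)), 9L))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("sample sheet covers every library exactly once, truth every gene", {
  ds <- small_sim(seed = 21L, n_genes = 80L)
  expect_setequal(ds$sample_sheet$library_id, colnames(ds$counts))
  expect_false(anyDuplicated(ds$sample_sheet$library_id) > 0)
  for (g in unique(ds$truth$group)) {
    expect_setequal(ds$truth$gene_id[ds$truth$group == g],
                    rownames(ds$counts))
  }
  expect_true(all(ds$gene_models$utr3_len_bp <= ds$gene_models$length_bp))
  expect_identical(nchar(ds$utr3[ds$gene_models$gene_id]),
                   setNames(as.integer(ds$gene_models$utr3_len_bp),
                            ds$gene_models$gene_id))
})

test_that("NB sampling matches the mean-variance law mu + phi mu^2", {
  cfg <- sim_config(n_genes = 3L, depth_pulse = 1e6, dispersion = 0.1,
                    n_sets = 0L, set_size = 0L, assays = "pulse",
                    half_life_log_sd = 0, alpha_log_sd = 0,
                    groups = list(sim_group("g", n_replicates = 800L)))
  ds <- simulate_experiment(cfg, 31L)
  mu <- rowMeans(ds$counts)
  v <- apply(ds$counts, 1, var)
  expect_true(all(mu >= 100))
  expect_equal(v, mu + 0.1 * mu^2, tolerance = 0.1)
})

test_that("expected stability index encodes decay plus the mass correction", {
  cfg <- sim_config(n_genes = 60L, dispersion = 0, n_sets = 2L,
                    set_size = 10L,
                    groups = list(sim_group("control"),
                                  sim_group("case", k_mult = c(oxphos = 2))))
  ds <- simulate_experiment(cfg, 41L)
  tr <- ds$truth
  ctl <- tr[tr$group == "control", ]
  # within a group, expected_index / exp(-k * 6) is a shared constant
  corr <- ctl$expected_index / exp(-ctl$k * 6)
  expect_lt(diff(range(corr)) / mean(corr), 1e-12)
  # noiseless counts realize the truth after quantification
  sa <- stability_analysis(ds$counts, ds$gene_models, ds$sample_sheet,
                           "case", "control")
  cas <- tr[tr$group == "case", ]
  expected_ratio <- cas$expected_index / ctl$expected_index
  got <- sa$records$ratio[match(cas$gene_id, sa$records$gene_id)]
  expect_equal(got, expected_ratio, tolerance = 1e-10)
})

test_that("depth rescaling leaves expected pairwise stability ratios fixed", {
  base <- sim_config(n_genes = 50L, dispersion = 0, n_sets = 0L,
                     set_size = 0L, groups = null_groups(2L))
  deep <- sim_config(n_genes = 50L, dispersion = 0, n_sets = 0L, set_size = 0L,
                     groups = null_groups(2L),
                     depth_pulse = 5e7, depth_chase = 5e7)
  a <- simulate_experiment(base, 1L)
  b <- simulate_experiment(deep, 1L)
  sa <- stability_analysis(a$counts, a$gene_models, a$sample_sheet,
                           "case", "control")$records
  sb <- stability_analysis(b$counts, b$gene_models, b$sample_sheet,
                           "case", "control")$records
  expect_equal(sa$ratio, sb$ratio, tolerance = 1e-9)
})

test_that("zero replicates and unknown effect sets are rejected", {
  expect_error(sim_group("g", 0L), "n_replicates")
  cfg <- sim_config(n_genes = 30L, n_sets = 1L, set_size = 5L,
                    groups = list(sim_group("a"),
                                  sim_group("b", k_mult = c(nope = 2))))
  expect_error(simulate_experiment(cfg, 1L), "unknown gene set 'nope'")
})

test_that("planted motif raises hit density in destabilized genes' UTRs", {
  cfg <- sim_config(n_genes = 400L, n_sets = 2L, set_size = 50L,
                    planted_motif = "UGUGUG", planted_motif_fold = 3,
                    utr_base_density = 1)
  ds <- simulate_experiment(cfg, 51L)
  planted <- unique(c(ds$gene_sets$ribosome, ds$gene_sets$oxphos))
  hits <- scan_motif_set(ds$utr3, "UGUGUG")
  kb <- nchar(ds$utr3) / 1000
  dens_planted <- sum(hits[planted]) / sum(kb[planted])
  bg <- setdiff(names(hits), planted)
  dens_bg <- sum(hits[bg]) / sum(kb[bg])
  expect_gt(dens_planted / dens_bg, 1.8)
})

test_that("protein table covers genes x groups x replicates with truth attrs", {
  ds <- small_sim(seed = 61L, n_genes = 120L)
  prot <- simulate_protein_table(ds$truth, coupling_slope = 0.8,
                                 noise_sd = 0.1,
                                 decoupled_sets = "ribosome",
                                 gene_sets = ds$gene_sets,
                                 n_replicates = 3L, seed = 9L)
  expect_equal(nrow(prot), nrow(ds$truth) * 3L)
  expect_true(all(prot$abundance > 0))
  expect_equal(attr(prot, "coupling_slope"), 0.8)
  expect_identical(attr(prot, "decoupled_sets"), "ribosome")
  expect_error(simulate_protein_table(ds$truth, decoupled_sets = "zzz",
                                      gene_sets = ds$gene_sets),
               "decoupled_sets")
})
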