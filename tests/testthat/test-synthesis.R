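test_that("size factors match their definition on forced cases", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("l1", "l2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- m
  m2[, 2] <- m[, 1] * 2
  f <- size_factors(m2)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(f))), 1)
})

test_that("size factors equal a literal re-implementation on random data", {
  # independent oracle: written straight from the definition
  sf_oracle <- function(counts) {
    ref <- apply(counts, 1, function(r) all(r > 0))
    g <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
    f <- apply(counts[ref, , drop = FALSE], 2,
               function(col) median(col / g))
    f / exp(mean(log(f)))
  }
  set.seed(21)
  counts <- matrix(rnbinom(50 * 6, mu = 40, size = 5), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("l%d", 1:6)))
  expect_identical(size_factors(counts), sf_oracle(counts))
})

test_that("no all-nonzero gene errors unless pseudo-reference is allowed", {
  m <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(m), "pseudo_reference")
  expect_silent(size_factors(m, pseudo_reference = TRUE))
})

test_that("log2FC follows the documented pseudocount formula exactly", {
  sheetless <- matrix(c(20, 40, 10, 20), nrow = 1,
                      dimnames = list("g", c("c1", "c2", "k1", "k2")))
  counts <- rbind(sheetless,
                  matrix(rep(c(30, 30, 30, 30), 3), nrow = 3, byrow = TRUE,
                         dimnames = list(c("s1", "s2", "s3"), NULL)))
  colnames(counts) <- c("c1", "c2", "k1", "k2")
  sf <- setNames(rep(1, 4), colnames(counts))
  disp <- data.frame(gene_id = rownames(counts), phi_mom = 0.1,
                     phi_used = 0.1)
  res <- nb_two_group_test(counts, c("c1", "c2"), c("k1", "k2"),
                           sf = sf, dispersions = disp)
  # case mean 30, control mean 15 -> log2((30+.5)/(15+.5)), attenuated
  expect_equal(res$log2fc[res$gene_id == "g"], log2(30.5 / 15.5))
  expect_gt(res$log2fc[res$gene_id == "g"], 0.9)
  expect_lt(res$log2fc[res$gene_id == "g"], 1.0)
})

test_that("identical groups give zero statistic and p = 1", {
  counts <- matrix(rep(c(25, 30, 25, 30), each = 4), nrow = 4,
                   dimnames = list(paste0("g", 1:4), c("a1", "a2", "b1", "b2")))
  sf <- setNames(rep(1, 4), colnames(counts))
  disp <- data.frame(gene_id = rownames(counts), phi_mom = 0.05,
                     phi_used = 0.05)
  res <- nb_two_group_test(counts, c("a1", "a2"), c("b1", "b2"),
                           sf = sf, dispersions = disp)
  expect_equal(res$log2fc, rep(0, 4))
  expect_equal(res$stat, rep(0, 4))
  expect_equal(res$p, rep(1, 4))
})

test_that("log2FC is antisymmetric under swapping case and control", {
  ds <- small_sim(seed = 31L, n_genes = 200L)
  sheet <- ds$sample_sheet
  pulse <- sheet[sheet$assay == "pulse", ]
  case_libs <- pulse$library_id[pulse$group == "case"]
  ctrl_libs <- pulse$library_id[pulse$group == "control"]
  counts <- ds$counts[, c(case_libs, ctrl_libs)]
  a <- nb_two_group_test(counts, case_libs, ctrl_libs)
  b <- nb_two_group_test(counts, ctrl_libs, case_libs)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
})

test_that("both-zero genes are flagged untested with p = 1", {
  counts <- matrix(c(0, 0, 0, 0, 5, 6, 7, 8), nrow = 2, byrow = TRUE,
                   dimnames = list(c("dead", "ok"),
                                   c("a1", "a2", "b1", "b2")))
  sf <- setNames(rep(1, 4), colnames(counts))
  disp <- data.frame(gene_id = rownames(counts), phi_mom = 0.05,
                     phi_used = 0.05)
  res <- nb_two_group_test(counts, c("a1", "a2"), c("b1", "b2"),
                           sf = sf, dispersions = disp)
  expect_false(res$tested[res$gene_id == "dead"])
  expect_equal(res$p[res$gene_id == "dead"], 1)
  expect_equal(res$log2fc[res$gene_id == "dead"], 0)
})

test_that("BH adjustment matches the hand-executed step-up case", {
  expect_equal(bh_adjust(c(0.005, 0.02, 0.03)), c(0.015, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)          # single p
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))  # ties collapse
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH agrees with a literal step-up oracle on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # permutation stability
  p <- runif(25)
  o <- sample(25)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("dispersion estimates recover the simulated dispersion scale", {
  cfg <- sim_config(n_genes = 500L, depth_pulse = 2e6, dispersion = 0.05,
                    n_sets = 0L, set_size = 0L, assays = "pulse",
                    groups = list(sim_group("control", 4L),
                                  sim_group("case", 4L)))
  ds <- simulate_experiment(cfg, 13L)
  disp <- estimate_dispersions(ds$counts,
                               ds$sample_sheet$group)
  med <- median(disp$phi_used[disp$mean_norm > 100])
  expect_gt(med, 0.02)
  expect_lt(med, 0.12)
  expect_true(all(disp$phi_used >= 1e-8))
})

test_that("power rises with effect size", {
  base <- sim_config(n_genes = 400L, depth_pulse = 2e6, assays = "pulse",
                     n_sets = 2L, set_size = 40L,
                     groups = list(sim_group("control", 4L),
                                   sim_group("case", 4L,
                                             alpha_mult = c(ribosome = 1.3))))
  strong <- sim_config(n_genes = 400L, depth_pulse = 2e6, assays = "pulse",
                       n_sets = 2L, set_size = 40L,
                       groups = list(sim_group("control", 4L),
                                     sim_group("case", 4L,
                                               alpha_mult = c(ribosome = 3))))
  hits <- sapply(list(base, strong), function(cfg) {
    ds <- simulate_experiment(cfg, 17L)
    res <- synthesis_analysis(ds$counts, ds$gene_models, ds$sample_sheet,
                              "case", "control")
    planted <- ds$gene_sets$ribosome
    sum(res$passes[res$gene_id %in% planted])
  })
  expect_gt(hits[2], hits[1])
})
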