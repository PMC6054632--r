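test_that("regression reproduces an exact line and a constant response", {
  r <- fit_stability_protein_regression(c(1, 2, 3), c(2, 4, 6),
                                        transform = "identity")
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  r <- fit_stability_protein_regression(c(1, 2, 3, 4), c(5, 5, 5, 5),
                                        transform = "identity")
  expect_equal(r$slope, 0)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
})

test_that("OLS matches the closed-form normal-equation oracle to 1e-10", {
  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(40)
    y <- 1.3 + 0.7 * x + rnorm(40)
    r <- fit_stability_protein_regression(exp(x), exp(y))  # log2 transform
    lx <- log2(exp(x)); ly <- log2(exp(y))
    beta <- cov(lx, ly) / var(lx)
    alpha <- mean(ly) - beta * mean(lx)
    expect_equal(r$slope, beta, tolerance = 1e-10)
    expect_equal(r$intercept, alpha, tolerance = 1e-10)
  }
})

test_that("extra-sum-of-squares F equals the squared slope t statistic", {
  set.seed(52)
  x <- rlnorm(30)
  y <- rlnorm(30)
  r <- fit_stability_protein_regression(x, y)
  fit <- lm(log2(y) ~ log2(x))
  tval <- summary(fit)$coefficients[2, "t value"]
  pval <- summary(fit)$coefficients[2, "Pr(>|t|)"]
  expect_equal(r$F, tval^2, tolerance = 1e-10)
  expect_equal(r$p, pval, tolerance = 1e-10)
})

test_that("zero predictor variance is an error", {
  expect_error(
    fit_stability_protein_regression(c(2, 2, 2), c(1, 2, 3),
                                     transform = "identity"),
    "zero variance")
})

test_that("noiseless coupled proteins recover the generating slope exactly", {
  ds <- small_sim(seed = 53L, n_genes = 200L)
  prot <- simulate_protein_table(ds$truth, coupling_slope = 1, noise_sd = 0,
                                 n_replicates = 1L, seed = 5L)
  pc <- prot[prot$group == "case", ]
  truth_case <- ds$truth[ds$truth$group == "case", ]
  s <- truth_case$expected_index[match(pc$gene_id, truth_case$gene_id)]
  r <- fit_stability_protein_regression(s, pc$abundance)
  expect_equal(r$slope, 1, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
})

test_that("concordance classification applies the 10% protein rule", {
  stab <- data.frame(gene_id = c("a", "b", "c", "d"),
                     class = c("destabilized", "destabilized",
                               "destabilized", "stabilized"))
  prot <- data.frame(gene_id = c("a", "b", "c", "d"),
                     rel_change = c(-0.20, 0.20, -0.05, 0.15))
  cs <- concordant_set(stab, prot)
  rec <- cs$records
  expect_true(rec$concordant[rec$gene_id == "a"])    # destab + down
  expect_false(rec$concordant[rec$gene_id == "b"])   # destab + up: discordant
  expect_false(rec$concordant[rec$gene_id == "c"])   # -5% -> unchanged
  expect_identical(rec$protein_direction[rec$gene_id == "c"], "unchanged")
  expect_true(rec$concordant[rec$gene_id == "d"])    # stab + up
  expect_equal(cs$summary$n_concordant, 2)
  expect_equal(cs$summary$fraction_of_stability_changes, 2 / 4)
  expect_equal(cs$summary$fraction_of_protein_changes, 2 / 3)
})

test_that("concordance is symmetric under relabeling directions", {
  stab <- data.frame(gene_id = paste0("g", 1:6),
                     class = rep(c("stabilized", "destabilized"), 3))
  prot <- data.frame(gene_id = paste0("g", 1:6),
                     rel_change = c(0.3, -0.3, 0.3, 0.3, -0.3, -0.3))
  flipped_stab <- stab
  flipped_stab$class <- ifelse(stab$class == "stabilized",
                               "destabilized", "stabilized")
  flipped_prot <- prot
  flipped_prot$rel_change <- -prot$rel_change
  a <- concordant_set(stab, prot)
  b <- concordant_set(flipped_stab, flipped_prot)
  expect_identical(a$records$concordant, b$records$concordant)
})

test_that("significance flag gates protein direction when required", {
  stab <- data.frame(gene_id = c("a", "b"), class = "destabilized")
  prot <- data.frame(gene_id = c("a", "b"), rel_change = c(-0.5, -0.5),
                     significant = c(TRUE, FALSE))
  cs <- concordant_set(stab, prot, require_significant = TRUE)
  expect_identical(cs$records$concordant, c(TRUE, FALSE))
  expect_error(concordant_set(stab, prot[, 1:2], require_significant = TRUE),
               "significant")
})

test_that("aggregate ANOVA reproduces closed-form F on forced groups", {
  mk <- function(vals_by_group) {
    rows <- do.call(rbind, lapply(names(vals_by_group), function(g) {
      data.frame(gene_id = "p1", group = g,
                 replicate = seq_along(vals_by_group[[g]]),
                 abundance = vals_by_group[[g]])
    }))
    rows
  }
  # identical groups: F = 0, p = 1
  pt <- mk(list(control = c(1, 2, 3), case = c(1, 2, 3)))
  r <- aggregate_pathway_compare(pt, list(path = "p1"), control = "control")
  expect_equal(r$F_anova, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  # {1,2} vs {3,4}: F = 8 on (1, 2) df (normalization by control mean 1.5
  # scales both groups equally and leaves F unchanged)
  pt <- mk(list(control = c(1, 2), case = c(3, 4)))
  r <- aggregate_pathway_compare(pt, list(path = "p1"), control = "control")
  expect_equal(r$F_anova, 8, tolerance = 1e-12)
  expect_equal(r$p, pf(8, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p, 0.1056, tolerance = 1e-3)
})

test_that("degenerate variance cases are flagged", {
  pt <- data.frame(gene_id = "p1",
                   group = rep(c("control", "case"), each = 2),
                   replicate = c(1, 2, 1, 2),
                   abundance = c(1, 1, 2, 2))
  r <- aggregate_pathway_compare(pt, list(path = "p1"), control = "control")
  expect_true(r$degenerate)
  expect_equal(r$p, 0)
  pt$abundance <- rep(1, 4)
  r <- aggregate_pathway_compare(pt, list(path = "p1"), control = "control")
  expect_false(r$degenerate)
  expect_equal(r$F_anova, 0)
  expect_equal(r$p, 1)
})

test_that("planted pathway-level protein reduction is detected", {
  ds <- small_sim(seed = 55L, n_genes = 300L)
  prot <- simulate_protein_table(ds$truth, coupling_slope = 0,
                                 noise_sd = 0.05, n_replicates = 3L,
                                 seed = 6L)
  # scale oxphos proteins down 0.7x in the case group
  idx <- prot$gene_id %in% ds$gene_sets$oxphos & prot$group == "case"
  prot$abundance[idx] <- prot$abundance[idx] * 0.7
  r <- aggregate_pathway_compare(prot, ds$gene_sets, control = "control",
                                 groups = c("case", "control"))
  expect_lt(r$q[r$pathway_name == "oxphos"], 0.05)
  expect_lt(r$mean_case[r$pathway_name == "oxphos"], 0.8)
})

test_that("concordant recovery improves as protein noise shrinks", {
  ds <- small_sim(seed = 56L, n_genes = 300L)
  stab <- stability_analysis(ds$counts, ds$gene_models, ds$sample_sheet,
                             "case", "control")
  frac <- vapply(c(1.5, 0.05), function(sd) {
    prot <- simulate_protein_table(ds$truth, coupling_slope = 1,
                                   noise_sd = sd, n_replicates = 3L,
                                   seed = 7L)
    pchg <- protein_changes(prot, "case", "control")
    cs <- concordant_set(stab$records, pchg)
    truly_dest <- ds$truth$gene_id[ds$truth$group == "case" &
      ds$truth$k > ds$truth$k[ds$truth$group == "control"]]
    rec <- cs$records
    dest <- rec$gene_id[rec$concordant & rec$stability_class == "destabilized"]
    length(intersect(dest, truly_dest)) / length(truly_dest)
  }, 0)
  expect_gt(frac[2], frac[1])
})
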