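test_that("simulation is deterministic under a fixed seed", {
  p <- simulationParams(n_genes = 200, pi_interaction = 0.1, seed = 42)
  ke1 <- simulateExperiment(p)
  ke2 <- simulateExperiment(p)
  expect_identical(expressionValues(ke1), expressionValues(ke2))
  expect_identical(as.data.frame(rowData(ke1)), as.data.frame(rowData(ke2)))
})

test_that("noiseless additive data are interpolated exactly by the additive model", {
  p <- simulationParams(n_genes = 60, pi_interaction = 0, sigma_noise = 0,
                        seed = 11)
  ke <- simulateExperiment(p)
  fits <- fitInteractionModels(ke)
  expect_true(all(fits$rss_additive < 1e-9))
  expect_true(all(fits$rss_interaction < 1e-9))
  # perfect fits of both models carry no evidence for an interaction
  expect_true(all(fits$p_value == 1))
})

test_that("assembled values equal design matrix times effects when noise is zero", {
  p <- simulationParams(n_genes = 40, pi_interaction = 0.5, sigma_noise = 0,
                        seed = 5)
  ke <- simulateExperiment(p)
  # interaction model must interpolate every gene, including interaction genes
  fits <- fitInteractionModels(ke)
  expect_true(all(fits$rss_interaction < 1e-9))
  # interaction genes show additive lack of fit
  isInt <- rowData(ke)$is_interaction[match(fits$gene_id, rownames(ke))]
  expect_true(all(fits$rss_additive[isInt] > 1e-6))
})

test_that("truth-table interaction fraction converges to pi_interaction", {
  p <- simulationParams(n_genes = 4000, pi_interaction = 0.3, seed = 9)
  ke <- simulateExperiment(p)
  k <- sum(rowData(ke)$is_interaction)
  ci <- binom.test(k, 4000, p = 0.3)$conf.int
  expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulationParams(pi_interaction = 1.5), "pi_interaction")
  expect_error(simulationParams(sigma_noise = -1), "deviations")
  expect_error(simulatePhysiology(5, 6, 0, -1), "sigma")
  expect_error(simulatePhysiology(1, 6, 0, 1), "size")
})

test_that("missingness option flags genes and fitting skips them", {
  p <- simulationParams(n_genes = 300, missing_rate = 0.02, seed = 2)
  ke <- simulateExperiment(p)
  miss <- hasMissing(ke)
  expect_true(any(miss))
  fits <- fitInteractionModels(ke)
  expect_equal(nrow(fits) + length(attr(fits, "skipped")), 300L)
  expect_setequal(attr(fits, "skipped"), rownames(ke)[miss])
})

test_that("physiology generator: separation, ties and determinism behave", {
  s <- simulatePhysiology(5, 6, shift = 100, sigma = 1, seed = 3)
  mw <- mannWhitneyExact(s$control, s$treated)
  expect_equal(mw$p_value, 2 / 462)
  # degenerate all-tied samples do not crash
  s0 <- simulatePhysiology(2, 2, shift = 0, sigma = 0, seed = 1)
  expect_equal(mannWhitneyExact(s0$control, s0$treated)$p_value, 1)
  expect_identical(simulatePhysiology(4, 4, 1, 2, seed = 8),
                   simulatePhysiology(4, 4, 1, 2, seed = 8))
})

test_that("physiology generator is calibrated under the null", {
  # exact two-sided Mann-Whitney p at sizes (5, 6): empirical type-I error
  # at alpha = 0.05 stays within its binomial envelope; the discrete
  # support makes the test conservative, never anti-conservative
  reps <- 2000
  hits <- 0L
  for (i in seq_len(reps)) {
    s <- simulatePhysiology(5, 6, shift = 0, sigma = 1, seed = i)
    if (mannWhitneyExact(s$control, s$treated)$p_value < 0.05)
      hits <- hits + 1L
  }
  ci <- binom.test(hits, reps)$conf.int
  # attainable rejection rate at alpha = .05 is P[p <= largest attainable
  # p below .05], which is <= .05 by construction
  expect_true(ci[1] <= 0.05)
  expect_gt(hits, 0L)
})

test_that("planted annotation enrichment matches its factor and is seeded", {
  genes <- sprintf("G%04d", 1:2000)
  sub <- genes[1:400]
  ann <- simulateAnnotation(genes, bins = c("A", "B", "C", "D"),
                            proportions = c(0.1, 0.3, 0.3, 0.3),
                            enriched_bin = "A", enrichment_factor = 4,
                            subset = sub, seed = 21)
  expect_identical(ann, simulateAnnotation(genes, c("A", "B", "C", "D"),
                                           c(0.1, 0.3, 0.3, 0.3), "A", 4,
                                           sub, seed = 21))
  fSub <- mean(ann$bin[ann$gene_id %in% sub] == "A")
  fBg <- mean(ann$bin[!ann$gene_id %in% sub] == "A")
  # weight 0.4 renormalised over 0.4+0.9: expected subset frequency .3077
  expect_gt(fSub / fBg, 2)
  expect_error(simulateAnnotation(genes, c("A", "B"), c(0.6, 0.6)),
               "sum to 1")
  expect_error(simulateAnnotation(genes, c("A", "B"), c(0.5, 0.5),
                                  subset = "NOPE"), "unknown gene")
})
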