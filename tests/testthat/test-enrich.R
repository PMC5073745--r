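test_that("normalized frequency is 1 when set and universe frequencies agree", {
  universe <- sprintf("G%02d", 1:20)
  # bin X covers half the universe and half the set
  ann <- data.frame(gene_id = universe,
                    bin = rep(c("X", "Y"), 10))
  gs <- universe[1:10]  # alternating pattern: 5 X, 5 Y
  e <- binEnrichment(gs, ann)
  expect_equal(e$normalized_frequency, c(1, 1))
})

test_that("extreme draws match the closed-form hypergeometric probability", {
  universe <- sprintf("G%02d", 1:20)
  binMembers <- universe[1:5]
  ann <- data.frame(gene_id = universe,
                    bin = ifelse(universe %in% binMembers, "hit", "other"))
  gs <- binMembers[1:4]  # 4 of 4 drawn from the 5-member bin
  e <- binEnrichment(gs, ann)
  hit <- e[e$bin == "hit", ]
  # P[X >= 4] = [C(5,4)C(15,0) + C(5,5)C(15,-1)] / C(20,4) = 5/4845
  expect_equal(hit$p_over, 5 / 4845, tolerance = 1e-12)
  expect_equal(hit$direction, "over")
  expect_true(hit$significant)
})

test_that("multi-bin genes count once per bin", {
  universe <- c("a", "b", "c", "d")
  ann <- data.frame(gene_id = c("a", "a", "b", "c", "d"),
                    bin = c("X", "Y", "X", "Y", "Y"))
  e <- binEnrichment(c("a", "b"), ann, universe = universe)
  expect_equal(e$n_in_set[e$bin == "X"], 2L)
  expect_equal(e$n_in_set[e$bin == "Y"], 1L)
  expect_gte(sum(e$n_in_set), 2L)
})

test_that("genes outside the universe are dropped with a warning", {
  ann <- data.frame(gene_id = c("a", "b", "c"), bin = "X")
  expect_warning(e <- binEnrichment(c("a", "zzz"), ann), "outside the universe")
  expect_equal(e$n_set[1], 1L)
  expect_error(binEnrichment(character(0), ann), "nonempty")
  expect_error(suppressWarnings(binEnrichment("zzz", ann)), "universe")
})

test_that("a planted enriched bin ranks first in nearly every seed", {
  genes <- sprintf("G%04d", 1:2000)
  sub <- genes[1:250]
  wins <- 0L
  nSeeds <- 20L
  for (s in seq_len(nSeeds)) {
    ann <- simulateAnnotation(genes, bins = c("plant", "B", "C", "D", "E"),
                              proportions = c(0.08, 0.23, 0.23, 0.23, 0.23),
                              enriched_bin = "plant", enrichment_factor = 4,
                              subset = sub, seed = s)
    e <- binEnrichment(sub, ann)
    top <- e$bin[which.min(e$p_value)]
    if (top == "plant" && e$significant[e$bin == "plant"]) wins <- wins + 1L
  }
  expect_gte(wins / nSeeds, 0.95)
})

test_that("enrichment p-values are invariant under gene relabeling", {
  genes <- sprintf("G%03d", 1:200)
  ann <- simulateAnnotation(genes, c("A", "B"), c(0.4, 0.6), seed = 2)
  gs <- genes[1:30]
  e1 <- binEnrichment(gs, ann)
  relabel <- setNames(sprintf("NEW%03d", 1:200), genes)
  ann2 <- data.frame(gene_id = unname(relabel[ann$gene_id]), bin = ann$bin)
  e2 <- binEnrichment(unname(relabel[gs]), ann2)
  expect_equal(e1$p_value, e2$p_value)
  expect_equal(e1$normalized_frequency, e2$normalized_frequency)
})

test_that("time-course enrichment reduces to single-set runs and skips empties", {
  genes <- sprintf("G%03d", 1:300)
  ann <- simulateAnnotation(genes, c("A", "B", "C"), c(0.2, 0.4, 0.4),
                            seed = 9)
  mkDeg <- function(up, down, tp)
    structure(list(timepoint = tp, up = up, down = down, alpha = 0.05,
                   table = data.frame()), class = "DEGSet")
  degs <- list("8" = mkDeg(genes[1:40], character(0), 8),
               "24" = mkDeg(character(0), character(0), 24))
  expect_message(tc <- enrichmentTimecourse(degs, ann), "omitted")
  expect_true(all(tc$timepoint == "8"))
  expect_true(all(tc$direction == "up"))
  solo <- binEnrichment(genes[1:40], ann)
  expect_equal(tc$p_value, solo$p_value)
  expect_equal(tc$bin, solo$bin)
})

test_that("signal planted at one timepoint is flagged only there", {
  genes <- sprintf("G%04d", 1:1500)
  sub <- genes[1:200]
  ann <- simulateAnnotation(genes, c("plant", "B", "C"),
                            c(0.1, 0.45, 0.45), enriched_bin = "plant",
                            enrichment_factor = 5, subset = sub, seed = 4)
  set.seed(31)
  randomSet <- sample(setdiff(genes, sub), 120)
  mkDeg <- function(up, tp)
    structure(list(timepoint = tp, up = up, down = character(0),
                   alpha = 0.05, table = data.frame()), class = "DEGSet")
  degs <- list("4" = mkDeg(randomSet, 4), "8" = mkDeg(sub, 8))
  tc <- enrichmentTimecourse(degs, ann)
  plantRows <- tc[tc$bin == "plant" & tc$direction == "up", ]
  expect_true(plantRows$significant[plantRows$timepoint == "8"])
  expect_false(plantRows$significant[plantRows$timepoint == "4"] &&
                 plantRows$normalized_frequency[plantRows$timepoint == "4"] > 1)
})

test_that("annotation files round-trip", {
  ann <- data.frame(gene_id = c("AT1G01010", "AT1G01020", "AT1G01020"),
                    bin = c("stress", "stress", "redox"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(ann, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(readAnnotation(f), ann)
  expect_error(readAnnotation(withr::local_tempfile(lines = "a\tb")),
               "gene_id")
})
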