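test_that("Venn partitions follow set algebra", {
  p <- vennPartition(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(unname(p[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(sum(p), 3L)  # |union|
  # identical sets: only the full intersection region is populated
  p2 <- vennPartition(list(X = letters[1:4], Y = letters[1:4]))
  expect_equal(unname(p2["X&Y"]), 4L)
  expect_equal(sum(p2), 4L)
  expect_error(vennPartition(list(a = "x")), "2 to 5")
  expect_error(vennPartition(rep(list(letters), 6)), "2 to 5")
})

test_that("five-set partitions sum to the union and reconstruct set sizes", {
  set.seed(12)
  pool <- sprintf("AT%dG%05d", sample(1:5, 600, TRUE), sample(1e5, 600))
  sizes <- c(t0.5 = 14, t2 = 47, t4 = 77, t8 = 275, t24 = 360)
  sets <- lapply(sizes, function(n) sample(pool, n))
  p <- vennPartition(sets)
  expect_equal(sum(p), length(unique(unlist(sets))))
  for (nm in names(sets))
    expect_equal(vennSetSize(p, nm), length(unique(sets[[nm]])))
})

test_that("hypergeometric overlap p matches exhaustive enumeration", {
  cases <- list(c(4, 5, 2, 12), c(6, 6, 3, 15), c(3, 8, 1, 10),
                c(5, 5, 5, 20), c(7, 4, 0, 14))
  for (cs in cases) {
    p <- overlapPvalue(cs[1], cs[2], cs[3], cs[4])$p_value
    expect_equal(p, hyperUpperEnum(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  # maximal overlap equals the point probability
  pMax <- overlapPvalue(4, 6, 4, 18)$p_value
  expect_equal(pMax, hyperUpperEnum(4, 6, 4, 18), tolerance = 1e-12)
})

test_that("the published 8h/24h DEG overlap is highly significant", {
  # 275- and 360-gene lists sharing 116 genes (50 down + 66 up) on the
  # 22089-gene array background
  ov <- overlapPvalue(275, 360, 116, 22089)
  expect_lt(ov$p_value, 0.0001)
  expect_lt(ov$expected, 5)
})

test_that("overlap p is monotone in k and respects its bounds", {
  ps <- vapply(0:5, function(k) overlapPvalue(5, 5, k, 1000)$p_value,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_gt(ps[1], 0.999)  # k = 0: upper tail is everything
  expect_error(overlapPvalue(5, 5, 6, 1000), "bounds")
  expect_error(overlapPvalue(5, 8, 1, 10), "bounds")  # k below forced minimum
  expect_error(overlapPvalue(2000, 5, 1, 1000), "universe")
  # pmf over the support sums to one
  for (cs in list(c(5, 5, 1000), c(275, 360, 22089), c(4, 9, 12))) {
    supp <- max(0, cs[1] + cs[2] - cs[3]):min(cs[1], cs[2])
    expect_equal(sum(dhyper(supp, cs[1], cs[3] - cs[1], cs[2])), 1,
                 tolerance = 1e-12)
  }
})

test_that("core-set extraction reports shared fractions as printed", {
  ref <- sprintf("G%03d", 1:467)
  ext <- list(study1 = sprintf("G%03d", 1:200),
              study2 = sprintf("G%03d", 150:363))
  cs <- coreSet(ref, ext)
  expect_equal(cs$n_shared, 363L)
  expect_equal(cs$label, "77.7 %")
  cs2 <- coreSet(ref, list(s = sprintf("G%03d", 1:109)), decimals = 0)
  expect_equal(cs2$label, "23 %")
  # reference contained in the union: 100 %
  expect_equal(coreSet(ref, list(all = ref))$fraction, 100)
  expect_equal(coreSet(ref, list())$n_shared, 0L)
  expect_error(coreSet(character(0), ext), "nonempty")
})

test_that("profile clustering merges by Euclidean distance with average linkage", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  tree <- profileHclust(m)
  expect_equal(tree$height[1], 0)  # identical profiles merge first, at 0
  m2 <- matrix(c(0, 1, 5), ncol = 1, dimnames = list(c("x", "y", "z"), NULL))
  t2 <- profileHclust(m2)
  first <- rownames(m2)[-t2$merge[1, ]]
  expect_setequal(first, c("x", "y"))  # d(x,y)=1 < d(y,z)=4 < d(x,z)=5
  expect_equal(t2$height, c(1, 4.5))   # average linkage: (4+5)/2
  expect_error(profileHclust(m2[1, , drop = FALSE]), ">= 2")
  expect_error(profileHclust(rbind(c(1, NA), c(0, 0))), "missing")
})

test_that("row permutation leaves the tree metric unchanged", {
  set.seed(3)
  m <- matrix(rnorm(40), nrow = 8,
              dimnames = list(sprintf("g%d", 1:8), NULL))
  t1 <- profileHclust(m)
  perm <- sample(nrow(m))
  t2 <- profileHclust(m[perm, ])
  c1 <- as.matrix(cophenetic(t1))
  c2 <- as.matrix(cophenetic(t2))[rownames(c1), colnames(c1)]
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("dendrograms serialize to Newick with merge-height branch lengths", {
  set.seed(5)
  m <- matrix(rnorm(20), nrow = 5, dimnames = list(sprintf("g%d", 1:5), NULL))
  tree <- profileHclust(m)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tree, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, rownames(m))
  expect_true(all(phy$edge.length >= 0))
})
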