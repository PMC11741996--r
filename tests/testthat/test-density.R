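test_that("epitope density is observed over expected binder count", {
  sets <- list(A = list(v = sprintf("pep%03d", 1:100)),
               B = list(v = character()))
  rep <- handRepertoire(sets, c(v = 10000), threshold = 1,
                        groups = c("g1", "g2"))
  expect_equal(epitopeDensity(rep, "v", "A"), 100 / (0.01 * 10000))
  expect_equal(epitopeDensity(rep, "v", "B"), 0)
  dt <- densityTable(rep)
  expect_equal(densities(dt)["v", "A"], 1)
  expect_equal(densities(dt)["v", "B"], 0)
})

test_that("mean density is the arithmetic mean over the virus subset", {
  m <- matrix(c(0.5, 1.5, 2, 1), 2, 2,
              dimnames = list(c("v1", "v2"), c("A", "B")))
  dt <- handDensityTable(m, groups = c("g1", "g2"))
  expect_equal(meanDensity(dt, "A"), 1)
  expect_equal(meanDensity(dt, "A", "v1"), 0.5)
  set.seed(7)
  m20 <- matrix(runif(20 * 2), 20, 2,
                dimnames = list(sprintf("v%02d", 1:20), c("A", "B")))
  dt20 <- handDensityTable(m20, groups = c("g1", "g2"))
  acc <- 0
  for (v in rownames(m20)) acc <- acc + m20[v, "A"]
  expect_equal(meanDensity(dt20, "A"), acc / 20)
})

test_that("densities under the calibration null centre on 1", {
  ref <- generateReferenceProteome(200, c(100, 250), seed = 111)
  ap <- generateAllelePanel(1, 4, seed = 112)
  vs <- generateVirusSet(10, 1, proteinsPerVirus = 4, proteinLength = 250,
                         seed = 113)
  pools <- referencePeptidePools(ref, 8:11)
  refs <- lapply(ap$panel@models, buildRankReference,
                 lengths = 8:11, perLengthCount = 5000, seed = 114,
                 pools = pools)
  rep <- buildRepertoire(ap$panel, vs$viruses, refs, lengths = 8:11,
                         threshold = 1)
  dt <- densityTable(rep)
  vals <- as.vector(densities(dt))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se + 0.05)
})

test_that("Mann-Whitney comparisons match exact enumeration for small untied groups", {
  set.seed(8)
  for (i in 1:12) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- round(rnorm(n1), 6); y <- round(rnorm(n2, 0.5), 6)
    ora <- exactMannWhitney(x, y)
    mine <- mhcRepertoire:::mannWhitneyU(x, y)
    expect_equal(mine$U, ora$U)
    expect_equal(mine$p, ora$p, tolerance = 1e-9)
  }
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1
  mw <- mhcRepertoire:::mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, exactMannWhitney(c(1, 2, 3), c(4, 5, 6))$p)
})

test_that("groupCompare performs all pairs with Bonferroni and honours bounds", {
  set.seed(9)
  m <- matrix(runif(5 * 8), 5, 8,
              dimnames = list(sprintf("v%d", 1:5), sprintf("A%d", 1:8)))
  dt <- handDensityTable(m, groups = rep(c("g1", "g2", "g3", "g4"), each = 2))
  cmp <- groupCompare(dt)
  expect_identical(nrow(cmp), 6L)          # choose(4, 2)
  expect_equal(cmp$pAdj, pmin(1, cmp$p * 6))
  expect_true(all(cmp$pAdj >= cmp$p))
  expect_true(all(cmp$pAdj <= 1))
  # identical multisets give p ~ 1 (U at its null mean)
  m2 <- cbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1))
  rownames(m2) <- sprintf("v%d", 1:4)
  cmp2 <- groupCompare(handDensityTable(m2, groups = c("gA", "gB")))
  expect_gt(cmp2$p, 0.9)
  expect_equal(cmp2$U, 4 * 4 / 2)
})

test_that("permutation test enumerates exactly for small panels", {
  m <- matrix(c(0.1, 0.2, 1.5, 1.7, 1.9, 2.1), 1, 6,
              dimnames = list("v", sprintf("A%d", 1:6)))
  dt <- handDensityTable(m, groups = c("f", "f", "o", "o", "o", "o"))
  res <- permutationTest(dt, "v", "f")
  expect_identical(res$method, "exact")
  # oracle: enumerate all 15 focal pairs
  prs <- utils::combn(6, 2)
  stats <- apply(prs, 2, function(ix) mean(m[1, ix]) - mean(m[1, -ix]))
  obs <- mean(m[1, 1:2]) - mean(m[1, 3:6])
  expect_equal(res$statistic, obs)
  expect_equal(res$p, mean(stats <= obs + 1e-12))
  expect_equal(res$p, 1 / 15)  # focal pair is the unique minimum
})

test_that("sampled permutation p-values are uniform under an exchangeable null", {
  set.seed(10)
  ps <- vapply(1:60, function(i) {
    m <- matrix(exp(rnorm(12)), 1, 12,
                dimnames = list("v", sprintf("A%02d", 1:12)))
    dt <- handDensityTable(m, groups = sample(rep(c("f", "o"), times = c(4, 8))))
    permutationTest(dt, "v", "f", nPerm = 400, seed = i)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sweep-candidate filtering applies the strict density rule", {
  al <- c(sprintf("f%d", 1:3), sprintf("o%02d", 1:12))
  m <- rbind(pass = c(rep(0.5, 3), rep(2.5, 12)),
             failFocal = c(0.5, 0.5, 1.0, rep(2.5, 12)),
             failCount = c(rep(0.5, 3), rep(2.5, 9), rep(1.5, 3)))
  colnames(m) <- al
  dt <- handDensityTable(m, groups = c(rep("f", 3), rep("o", 12)))
  hits <- sweepCandidateFilter(dt, al[1:3], al[4:15],
                               low = 1, high = 2, minCount = 10)
  expect_identical(hits, "pass")
  expect_error(sweepCandidateFilter(dt, al[1:3], al[3:15]), "disjoint")
})

test_that("random density tables agree with a brute-force filter oracle", {
  set.seed(12)
  for (i in 1:10) {
    m <- matrix(runif(8 * 10, 0, 3), 8, 10,
                dimnames = list(sprintf("v%d", 1:8), sprintf("A%02d", 1:10)))
    dt <- handDensityTable(m, groups = c(rep("f", 3), rep("o", 7)))
    low <- runif(1, 0.5, 1.5); high <- runif(1, 1.5, 2.5)
    mc <- sample(1:5, 1)
    hits <- sweepCandidateFilter(dt, colnames(m)[1:3], colnames(m)[4:10],
                                 low = low, high = high, minCount = mc)
    oracle <- rownames(m)[vapply(rownames(m), function(v)
      all(m[v, 1:3] < low) && sum(m[v, 4:10] > high) >= mc, TRUE)]
    expect_identical(hits, oracle)
  }
})

test_that("filter output shrinks monotonically in its parameters", {
  set.seed(13)
  m <- matrix(runif(10 * 10, 0, 3), 10, 10,
              dimnames = list(sprintf("v%d", 1:10), sprintf("A%02d", 1:10)))
  dt <- handDensityTable(m, groups = c(rep("f", 3), rep("o", 7)))
  base <- sweepCandidateFilter(dt, colnames(m)[1:3], colnames(m)[4:10],
                               low = 1.2, high = 1.8, minCount = 2)
  expect_true(all(sweepCandidateFilter(dt, colnames(m)[1:3], colnames(m)[4:10],
                                       low = 1.0, high = 1.8, minCount = 2)
                  %in% base))
  expect_true(all(sweepCandidateFilter(dt, colnames(m)[1:3], colnames(m)[4:10],
                                       low = 1.2, high = 2.2, minCount = 2)
                  %in% base))
  expect_true(all(sweepCandidateFilter(dt, colnames(m)[1:3], colnames(m)[4:10],
                                       low = 1.2, high = 1.8, minCount = 4)
                  %in% base))
})

test_that("self-presentation ratios behave at degenerate thresholds and null", {
  ref <- generateReferenceProteome(100, c(80, 160), seed = 121)
  m <- generateAllelePanel(1, 1, seed = 122)$panel@models[[1]]
  rr <- buildRankReference(m, ref, lengths = 8:11, perLengthCount = 2000,
                           seed = 123)
  short <- proteomeSet("self", c(tiny = "ACDEF", ok = randomSeqs(1, 60, seed = 9)))
  sp <- selfPresentation(short, m, rr, lengths = 8:11, threshold = 100)
  expect_identical(sp$totalProducts[1], 0L)
  expect_identical(sp$observed[1], 0L)
  expect_true(is.na(sp$ratio[1]))
  expect_equal(sp$ratio[2], 1)          # threshold 100%: everything binds
  # exchangeable-score null over many proteins: mean ratio near 1
  self <- generateReferenceProteome(200, c(80, 160), seed = 124,
                                    sourceId = "self")
  sp2 <- selfPresentation(self, m, rr, lengths = 8:11, threshold = 5)
  se <- stats::sd(sp2$ratio) / sqrt(nrow(sp2))
  expect_lt(abs(mean(sp2$ratio) - 1), 3 * se + 0.05)
})
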