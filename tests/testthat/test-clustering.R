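test_that("Jaccard index does direct set arithmetic with the both-empty convention", {
  expect_equal(jaccardIndex(c("p1", "p2", "p3"), c("p2", "p3", "p4")), 0.5)
  expect_equal(jaccardIndex(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccardIndex(c("a"), c("b")), 0)
  expect_equal(jaccardIndex(character(), character()), 1)
  expect_equal(jaccardIndex(character(), c("a")), 0)
})

test_that("functional distance averages per-virus Jaccard and converts to distance", {
  # planted per-virus similarities 1.0, 0.5, 0.0 -> D = 1 - 0.5
  sets <- list(
    A = list(v1 = c("p1", "p2"), v2 = c("q1", "q2"), v3 = c("r1")),
    B = list(v1 = c("p1", "p2"), v2 = c("q1", "q3"), v3 = c("s1")))
  rep <- handRepertoire(sets, c(v1 = 100, v2 = 100, v3 = 100))
  expect_equal(functionalDistance(rep, "A", "B"),
               1 - mean(c(1, 1 / 3, 0)))
  expect_equal(functionalDistance(rep, "A", "A"), 0)
  expect_equal(functionalDistance(rep, "A", "B", virusSubset = "v1"), 0)
  expect_error(functionalDistance(rep, "A", "B", virusSubset = character()),
               "non-empty")
})

test_that("distance matrices are symmetric, zero-diagonal, bounded and match a pair loop", {
  s <- list(
    A = list(v1 = c("a", "b"), v2 = c("c")),
    B = list(v1 = c("a"), v2 = character()),
    C = list(v1 = c("z"), v2 = c("c", "d")),
    D = list(v1 = character(), v2 = character()))
  rep <- handRepertoire(s, c(v1 = 50, v2 = 50))
  D <- functionalDistanceMatrix(rep)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(diag(D), setNames(rep(0, 4), names(s)))
  expect_equal(D, t(D))
  for (a in names(s)) for (b in names(s))
    expect_equal(D[a, b], functionalDistance(rep, a, b), tolerance = 1e-12)
  # the skip policy renormalizes over non-degenerate viruses
  Dskip <- functionalDistanceMatrix(rep, emptyPolicy = "skip")
  expect_equal(Dskip["B", "D"],
               functionalDistance(rep, "B", "D", emptyPolicy = "skip"))
})

test_that("UPGMA reproduces the forced 3-leaf merge order and heights", {
  D <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(D)
  hc <- attr(tr, "hclust")
  expect_equal(hc$height, c(0.2, 0.6))
  cph <- as.matrix(stats::cophenetic(tr))
  expect_equal(cph["A", "B"], 0.2)
  expect_equal(cph["A", "C"], 0.6)
  # node heights are half the merge distances
  expect_equal(max(nodeHeights <- ape::node.depth.edgelength(tr)), 0.3)
})

test_that("UPGMA cophenetic distances match average-linkage hclust on random matrices", {
  set.seed(91)
  for (i in 1:100) {
    n <- 7
    m <- matrix(runif(n * n), n, n)
    D <- (m + t(m)) / 2
    diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    mine <- as.matrix(stats::cophenetic(upgmaTree(D)))
    refhc <- stats::hclust(stats::as.dist(D), method = "average")
    refc <- as.matrix(stats::cophenetic(refhc))
    expect_equal(mine[rownames(refc), colnames(refc)], refc,
                 tolerance = 1e-9)
  }
})

test_that("every UPGMA tree is ultrametric with non-decreasing merge heights", {
  set.seed(92)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    m <- matrix(runif(n * n), n, n)
    D <- (m + t(m)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgmaTree(D)
    expect_true(all(diff(attr(tr, "hclust")$height) >= -1e-12))
    depths <- ape::node.depth.edgelength(tr)
    tipd <- depths[seq_len(n)]
    expect_lt(max(tipd) - min(tipd), 1e-9)
  }
})

test_that("UPGMA tie-breaking is deterministic under equal distances", {
  D <- matrix(0.4, 4, 4,
              dimnames = list(c("d", "b", "c", "a"), c("d", "b", "c", "a")))
  diag(D) <- 0
  t1 <- upgmaTree(D)
  t2 <- upgmaTree(D[c(3, 1, 4, 2), c(3, 1, 4, 2)])
  # first merge is always the lexicographically smallest pair (a, b),
  # whatever the input row order
  expect_true("a|b" %in% cladeSets(t1))
  expect_true("a|b" %in% cladeSets(t2))
  expect_equal(unname(sort(cladeSets(t1))), unname(sort(cladeSets(t2))))
})

test_that("bootstrap at fraction 1 reproduces the full tree with unit supports", {
  sets <- list(
    A = list(v1 = c("a", "b"), v2 = c("c", "d"), v3 = c("x")),
    B = list(v1 = c("a", "b"), v2 = c("c"), v3 = c("x", "y")),
    C = list(v1 = c("q"), v2 = c("r"), v3 = c("s")))
  rep <- handRepertoire(sets, c(v1 = 10, v2 = 10, v3 = 10))
  bs <- bootstrapSupports(rep, nReps = 20, fraction = 1, seed = 7)
  full <- upgmaTree(functionalDistanceMatrix(rep))
  for (key in cladeSets(full))
    expect_equal(unname(bs$frequencies[[key]]), 1)
  for (tr in bs$trees)
    expect_equal(unname(sort(cladeSets(tr))), unname(sort(cladeSets(full))))
})

test_that("bootstrap supports are reproducible under a fixed seed", {
  s <- list(
    A = list(v1 = c("a"), v2 = c("b"), v3 = c("c"), v4 = c("d")),
    B = list(v1 = c("a"), v2 = c("x"), v3 = c("c"), v4 = c("y")),
    C = list(v1 = c("z"), v2 = c("b"), v3 = c("w"), v4 = c("d")))
  rep <- handRepertoire(s, c(v1 = 5, v2 = 5, v3 = 5, v4 = 5))
  b1 <- bootstrapSupports(rep, nReps = 50, fraction = 0.5, seed = 13)
  b2 <- bootstrapSupports(rep, nReps = 50, fraction = 0.5, seed = 13)
  expect_identical(b1$frequencies, b2$frequencies)
})

test_that("consensus of identical trees is that tree with unit supports", {
  tr <- upgmaTree(matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
                         dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  cons <- extendedMajorityConsensus(list(tr, tr, tr))
  expect_equal(unname(sort(cladeSets(cons))), unname(sort(cladeSets(tr))))
  expect_true(all(as.numeric(cons$node.label) == 1))
})

test_that("a clade in 2 of 3 trees survives with support 2/3", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,B),(C,D));")
  t3 <- ape::read.tree(text = "((A,C),(B,D));")
  cons <- extendedMajorityConsensus(list(t1, t2, t3))
  cs <- cladeSets(cons)
  expect_true("A|B" %in% cs)
  lab <- cons$node.label[match("A|B", cs)]
  expect_equal(as.numeric(lab), 2 / 3, tolerance = 1e-6)
  expect_error(extendedMajorityConsensus(list(
    t1, ape::read.tree(text = "((A,B),(C,E));"))), "same leaf set")
})

test_that("consensus clades and supports match independent ape references", {
  for (seed in 1:10) {
    trees <- lapply(seed * 10 + 1:7, function(s2)
      randomRootedTree(c("A", "B", "C", "D", "E"), s2))
    cons <- extendedMajorityConsensus(trees)
    myClades <- cladeSets(cons)
    mySupport <- setNames(as.numeric(cons$node.label), myClades)

    # oracle clade frequencies via ape::prop.part (matching tips by label)
    pp <- ape::prop.part(trees, check.labels = TRUE)
    labs <- attr(pp, "labels")
    oracleFreq <- setNames(
      attr(pp, "number") / length(trees),
      vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "|"), ""))

    # every consensus clade carries its true frequency
    for (key in myClades) {
      want <- if (key %in% names(oracleFreq)) oracleFreq[[key]] else 0
      expect_equal(unname(mySupport[key]), want, tolerance = 1e-8,
                   label = sprintf("support of %s (seed %d)", key, seed))
    }

    # all majority clades appear, matching ape::consensus(p = 0.5)
    mcons <- ape::consensus(trees, p = 0.5, rooted = TRUE)
    for (key in setdiff(cladeSets(mcons),
                        paste(sort(mcons$tip.label), collapse = "|")))
      expect_true(key %in% myClades,
                  label = sprintf("majority clade %s (seed %d)", key, seed))

    # extended clades are mutually compatible
    sets <- strsplit(myClades, "|", fixed = TRUE)
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      expect_true(ov == 0 || ov == length(sets[[i]]) || ov == length(sets[[j]]))
    }
  }
})

test_that("Newick round-trip preserves topology, heights and supports", {
  two <- upgmaTree(matrix(c(0, .5, .5, 0), 2, 2,
                          dimnames = list(c("A", "B"), c("A", "B"))))
  expect_true(ape::write.tree(two) %in%
                c("(A:0.25,B:0.25);", "(B:0.25,A:0.25);"))
  set.seed(95)
  n <- 10
  m <- matrix(runif(n * n), n, n)
  D <- (m + t(m)) / 2; diag(D) <- 0
  dimnames(D) <- list(paste0("x", 1:n), paste0("x", 1:n))
  tr <- upgmaTree(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  tr2 <- readNewick(f)
  expect_equal(unname(sort(cladeSets(tr2))), unname(sort(cladeSets(tr))))
  c1 <- as.matrix(stats::cophenetic(tr))
  c2 <- as.matrix(stats::cophenetic(tr2))
  expect_equal(c2[rownames(c1), colnames(c1)], c1, tolerance = 1e-9)
  writeLines("((A:1,B:1;", f)
  expect_error(readNewick(f), "[Nn]ewick|parenth")
})

test_that("planted supertypes are recovered exactly on well-separated panels", {
  ref <- generateReferenceProteome(150, c(80, 200), seed = 101)
  ap <- generateAllelePanel(3, 3, anchorDivergence = 0.1, noiseScale = 0.3,
                            seed = 102)
  vs <- generateVirusSet(4, 1, proteinsPerVirus = 3, proteinLength = 150,
                         seed = 103)
  pools <- referencePeptidePools(ref, 8:11)
  refs <- lapply(ap$panel@models, buildRankReference,
                 lengths = 8:11, perLengthCount = 2000, seed = 104,
                 pools = pools)
  rep <- buildRepertoire(ap$panel, vs$viruses, refs, threshold = 2)
  cl <- treeClusters(upgmaTree(functionalDistanceMatrix(rep)), 3)
  expect_equal(mclust::adjustedRandIndex(cl, ap$supertypeLabels[names(cl)]), 1)
})
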