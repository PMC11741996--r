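test_that("generators are byte-identical under a fixed seed", {
  r1 <- generateReferenceProteome(20, c(50, 80), seed = 131)
  r2 <- generateReferenceProteome(20, c(50, 80), seed = 131)
  expect_identical(as.character(r1@aa), as.character(r2@aa))
  v1 <- generateVirusSet(2, 2, 2, 60, seed = 132)
  v2 <- generateVirusSet(2, 2, 2, 60, seed = 132)
  expect_identical(lapply(v1$viruses, function(v) as.character(v@aa)),
                   lapply(v2$viruses, function(v) as.character(v@aa)))
  p1 <- generateAllelePanel(2, 2, seed = 133)
  p2 <- generateAllelePanel(2, 2, seed = 133)
  peps <- randomPeptides(30, seed = 134)
  for (a in alleleNames(p1$panel))
    expect_identical(bindingScore(p1$panel@models[[a]], peps),
                     bindingScore(p2$panel@models[[a]], peps))
  # and FASTA output is byte-identical too
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(v1$viruses[[1]], f1)
  writeFasta(v2$viruses[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate generator settings behave analytically", {
  conc <- setNames(c(1, rep(0, 19)), AA_STANDARD)  # all-alanine background
  r <- generateReferenceProteome(5, c(30, 30), aaFreqs = conc, seed = 1)
  expect_true(all(as.character(r@aa) == strrep("A", 30)))
  v <- generateVirusSet(1, 2, 1, 50, mutationRate = 0, seed = 2)
  expect_equal(virusIdentity(v$viruses[[1]], v$viruses[[2]]), 100)
})

test_that("within-family identity tracks the substitution rate", {
  v <- generateVirusSet(1, 2, 2, 400, mutationRate = 0.05, seed = 141)
  id <- virusIdentity(v$viruses[[1]], v$viruses[[2]])
  # two members each ~5% diverged from the ancestor: expected identity
  # (1 - r)^2 + r^2/19 ~ 90.3%
  expect_lt(abs(id - 90.3), 3)
})

test_that("planted supertypes have disjoint anchors and near-zero cross-overlap", {
  ap <- generateAllelePanel(2, 2, anchorDivergence = 0, noiseScale = 0.4,
                            seed = 151)
  # divergence 0: identical models within a supertype
  peps <- randomPeptides(200, seed = 152)
  for (st in c("S01", "S02")) {
    a <- paste0(st, "_A01"); b <- paste0(st, "_A02")
    expect_identical(bindingScore(ap$panel@models[[a]], peps),
                     bindingScore(ap$panel@models[[b]], peps))
  }
  # distinct preferred anchor residues across supertypes
  m1 <- ap$panel@models[["S01_A01"]]; m2 <- ap$panel@models[["S02_A01"]]
  expect_false(names(which.max(m1@anchorP2)) == names(which.max(m2@anchorP2)))
  expect_false(names(which.max(m1@anchorC)) == names(which.max(m2@anchorC)))
  expect_error(generateAllelePanel(11, 1), "supertypes")
})

test_that("zero-divergence panels collapse to zero functional distance within supertypes", {
  ref <- generateReferenceProteome(80, c(60, 120), seed = 161)
  ap <- generateAllelePanel(2, 2, anchorDivergence = 0, seed = 162)
  vs <- generateVirusSet(2, 1, 2, 100, seed = 163)
  refs <- lapply(ap$panel@models, buildRankReference, referenceProteome = ref,
                 lengths = 8:9, perLengthCount = 1000, seed = 164)
  rep <- buildRepertoire(ap$panel, vs$viruses, refs, lengths = 8:9,
                         threshold = 2)
  D <- functionalDistanceMatrix(rep)
  expect_equal(D["S01_A01", "S01_A02"], 0)
  expect_equal(D["S02_A01", "S02_A02"], 0)
  expect_gt(D["S01_A01", "S02_A01"], 0.8)
})

test_that("sharpening 0 leaves the panel unchanged", {
  ap <- generateAllelePanel(2, 2, seed = 171)$panel
  ap0 <- makeLowDensitySupertype(ap, "S01", sharpening = 0)
  peps <- randomPeptides(100, seed = 172)
  for (a in alleleNames(ap))
    expect_identical(bindingScore(ap0@models[[a]], peps),
                     bindingScore(ap@models[[a]], peps))
  expect_error(makeLowDensitySupertype(ap, "S99"), "unknown supertype")
})

test_that("depleted residue frequencies are a valid rescaled background", {
  f <- depletedResidueFreqs(c("W", "C"), factor = 0.2)
  expect_equal(sum(f), 1)
  expect_equal(f[["W"]] / f[["A"]], 0.2)
  expect_identical(names(f), AA_STANDARD)
})

test_that("strong sharpening onto virus-depleted residues lowers the focal group's density", {
  ref <- generateReferenceProteome(200, c(100, 250), seed = 181)
  ap <- generateAllelePanel(2, 3, seed = 182)
  panel <- makeLowDensitySupertype(ap$panel, "S01", sharpening = 1)
  vs <- generateVirusSet(8, 1, proteinsPerVirus = 4, proteinLength = 250,
                         aaFreqs = depletedResidueFreqs(), seed = 183)
  pools <- referencePeptidePools(ref, 8:11)
  refs <- lapply(panel@models, buildRankReference,
                 lengths = 8:11, perLengthCount = 5000, seed = 184,
                 pools = pools)
  rep <- buildRepertoire(panel, vs$viruses, refs, threshold = 1)
  dt <- densityTable(rep)
  gl <- groupLabels(dt)
  focalMean <- mean(densities(dt)[, names(gl)[gl == "S01"]])
  otherMean <- mean(densities(dt)[, names(gl)[gl == "S02"]])
  expect_lt(focalMean, 0.7)
  expect_lt(focalMean, otherMean)
  cmp <- groupCompare(dt)
  expect_lt(cmp$pAdj[1], 0.05)
})
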