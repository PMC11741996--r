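# Independent oracles used across test files. These deliberately take the
# slowest, most literal route (full enumeration, brute-force set arithmetic)
# and share no code with the implementation.

# All global alignments of a and b, scored with BLOSUM62 and affine gap
# cost open + len * ext (end gaps charged). Returns the optimal score and
# the identities (matches / alignment length) of every co-optimal alignment.
enumerateAlignments <- function(a, b, gapOpen = 10, gapExt = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- get("BLOSUM62", envir = environment())
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  results <- new.env(parent = emptyenv())
  results$best <- -Inf
  results$identities <- numeric()
  rec <- function(i, j, score, matches, len, lastMove) {
    if (i > length(ca) && j > length(cb)) {
      if (score > results$best + 1e-9) {
        results$best <- score
        results$identities <- matches / len
      } else if (score > results$best - 1e-9) {
        results$identities <- c(results$identities, matches / len)
      }
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + S[ca[i], cb[j]],
          matches + (ca[i] == cb[j]), len + 1, "M")
    }
    if (i <= length(ca)) {
      cost <- if (lastMove == "D") gapExt else gapOpen + gapExt
      rec(i + 1, j, score - cost, matches, len + 1, "D")
    }
    if (j <= length(cb)) {
      cost <- if (lastMove == "I") gapExt else gapOpen + gapExt
      rec(i, j + 1, score - cost, matches, len + 1, "I")
    }
  }
  rec(1, 1, 0, 0, 0, "start")
  list(score = results$best, identities = 100 * unique(results$identities))
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled observations to the two groups (no ties assumed).
exactMannWhitney <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  Us <- apply(idx, 2, function(ix) {
    r <- rank(pool)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  })
  r <- rank(pool)
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pLe <- mean(Us <= Uobs + 1e-9)
  pGe <- mean(Us >= Uobs - 1e-9)
  list(U = Uobs, p = min(1, 2 * min(pLe, pGe)))
}

# Hand-build a BinderRepertoire from explicit peptide sets:
# sets[[allele]][[virus]] character vectors; totals named by virus.
handRepertoire <- function(sets, totals, threshold = 1,
                           groups = rep("G1", length(sets))) {
  alleles <- names(sets)
  viruses <- names(sets[[1]])
  new("BinderRepertoire",
      alleleNames = alleles,
      groupLabels = groups,
      virusIds = viruses,
      sets = sets,
      totalProducts = totals[viruses],
      uniqueProducts = totals[viruses],
      threshold = threshold,
      lengths = 8:11)
}

# Hand-build a DensityTable from a virus x allele matrix.
handDensityTable <- function(m, groups, threshold = 1) {
  new("DensityTable",
      densities = m,
      totalProducts = stats::setNames(rep(10000, nrow(m)), rownames(m)),
      groupLabels = stats::setNames(groups, colnames(m)),
      threshold = threshold)
}

randomSeqs <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(AA_STANDARD, len, replace = TRUE), collapse = ""), "")
}

# Random rooted binary tree on given tips (via random sequential joins).
randomRootedTree <- function(tips, seed) {
  set.seed(seed)
  nodes <- as.list(tips)
  while (length(nodes) > 1) {
    i <- sample(length(nodes), 2)
    merged <- sprintf("(%s,%s)", nodes[[i[1]]], nodes[[i[2]]])
    nodes <- c(nodes[-i], merged)
  }
  ape::read.tree(text = paste0(nodes[[1]], ";"))
}
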