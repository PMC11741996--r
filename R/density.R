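#' Epitope density for one (virus, allele) pair
#'
#' Density is the observed number of unique binder peptides divided by the
#' number expected by chance at the rank threshold: with a 1% threshold the
#' expected count is 1% of the virus's total digestion products. Density 1
#' means chance-level presentation; below 1, the allele presents the virus
#' poorly.
#'
#' @param repertoire A \linkS4class{BinderRepertoire}.
#' @param virus,allele Names selecting the entry.
#' @param threshold Rank threshold in percent; defaults to the repertoire's.
#' @return Non-negative density value.
#' @export
epitopeDensity <- function(repertoire, virus, allele,
                           threshold = repertoire@threshold) {
  stopifnot(is(repertoire, "BinderRepertoire"))
  total <- repertoire@totalProducts[[virus]]
  if (total == 0) stop("virus ", virus, " has zero digestion products")
  length(binderSet(repertoire, allele, virus)) / ((threshold / 100) * total)
}

#' Epitope density table for all (virus, allele) pairs
#'
#' @param repertoire A \linkS4class{BinderRepertoire}.
#' @return A \linkS4class{DensityTable} (viruses x alleles).
#' @export
densityTable <- function(repertoire) {
  stopifnot(is(repertoire, "BinderRepertoire"))
  thr <- repertoire@threshold
  if (thr <= 0) stop("density is undefined at a zero rank threshold")
  if (any(repertoire@totalProducts == 0))
    stop("virus(es) with zero digestion products: ",
         paste(names(which(repertoire@totalProducts == 0)), collapse = ", "))
  nB <- vapply(repertoire@alleleNames, function(a)
    vapply(repertoire@sets[[a]], length, 0L), integer(length(repertoire@virusIds)))
  dim(nB) <- c(length(repertoire@virusIds), length(repertoire@alleleNames))
  dens <- nB / ((thr / 100) * repertoire@totalProducts)
  dimnames(dens) <- list(repertoire@virusIds, repertoire@alleleNames)
  new("DensityTable",
      densities = dens,
      totalProducts = repertoire@totalProducts,
      groupLabels = setNames(repertoire@groupLabels, repertoire@alleleNames),
      threshold = thr)
}

#' Mean epitope density of an allele over viruses
#'
#' @param table A \linkS4class{DensityTable}.
#' @param allele Allele name.
#' @param virusSubset Optional character vector of virus ids (default: all).
#' @return Arithmetic mean density.
#' @export
meanDensity <- function(table, allele, virusSubset = NULL) {
  stopifnot(is(table, "DensityTable"))
  if (is.null(virusSubset)) virusSubset <- rownames(table@densities)
  if (!length(virusSubset)) stop("virus subset must be non-empty")
  mean(table@densities[virusSubset, allele])
}

# Two-sided Mann-Whitney U: exact (no ties, both n <= exactLimit) else
# tie-corrected normal approximation with continuity correction.
mannWhitneyU <- function(x, y, exactLimit = 25L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= exactLimit && n2 <= exactLimit) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(U = U1, p = p)
}

#' Pairwise group comparisons of epitope densities
#'
#' Compares every unordered pair of allele groups with a two-sided
#' Mann-Whitney U test (exact when group sizes are small and untied,
#' otherwise the tie-corrected normal approximation) and applies the
#' Bonferroni correction across all pairs. The observational unit is the
#' per-(allele, virus) density value pooled within each group; set
#' \code{unit = "allele_mean"} to compare per-allele mean densities instead.
#'
#' @param table A \linkS4class{DensityTable}.
#' @param virusSubset Optional virus id subset (default: all).
#' @param unit \code{"allele_virus"} (default) or \code{"allele_mean"}.
#' @return Data frame with one row per group pair: groupA, groupB, nA, nB,
#'   U (for the first group), p, and Bonferroni-adjusted pAdj.
#' @export
groupCompare <- function(table, virusSubset = NULL,
                         unit = c("allele_virus", "allele_mean")) {
  unit <- match.arg(unit)
  stopifnot(is(table, "DensityTable"))
  if (is.null(virusSubset)) virusSubset <- rownames(table@densities)
  groups <- unique(table@groupLabels)
  if (length(groups) < 2L) stop("at least 2 groups are required")
  values <- lapply(groups, function(g) {
    cols <- names(table@groupLabels)[table@groupLabels == g]
    m <- table@densities[virusSubset, cols, drop = FALSE]
    if (unit == "allele_virus") as.vector(m) else colMeans(m)
  })
  names(values) <- groups
  if (any(vapply(values, length, 0L) < 1L)) stop("empty group")
  prs <- combn(groups, 2L)
  res <- lapply(seq_len(ncol(prs)), function(i) {
    g1 <- prs[1L, i]; g2 <- prs[2L, i]
    mw <- mannWhitneyU(values[[g1]], values[[g2]])
    data.frame(groupA = g1, groupB = g2,
               nA = length(values[[g1]]), nB = length(values[[g2]]),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pAdj <- p.adjust(out$p, method = "bonferroni")
  out
}

#' Permutation test: is one allele group a poor presenter of a virus?
#'
#' Statistic: mean density of the focal group minus mean density of the
#' remaining alleles, for one virus. One-sided: small values mean the focal
#' group presents the virus less well. When the number of distinct focal
#' label assignments is small enough the test enumerates them all
#' exhaustively; otherwise it samples \code{nPerm} random assignments and
#' applies the +1 convention (the observed assignment counts as one
#' permutation, so p is never 0).
#'
#' @param table A \linkS4class{DensityTable}.
#' @param virus Virus id.
#' @param focalGroup Group label of the focal alleles (must be a non-empty
#'   proper subset of the panel).
#' @param nPerm Number of random permutations; default 10000.
#' @param seed Integer seed for the sampled permutations.
#' @return List with \code{statistic}, \code{p}, and \code{method}
#'   ("exact" or "sampled").
#' @export
permutationTest <- function(table, virus, focalGroup, nPerm = 10000L,
                            seed = 1L) {
  stopifnot(is(table, "DensityTable"))
  dens <- table@densities[virus, ]
  focal <- table@groupLabels == focalGroup
  k <- sum(focal); n <- length(dens)
  if (k == 0L || k == n) stop("focal group must be a non-empty proper subset")
  stat <- function(sel) mean(dens[sel]) - mean(dens[!sel])
  obs <- stat(focal)
  nComb <- choose(n, k)
  if (nComb <= nPerm) {
    sels <- combn(n, k)
    stats <- apply(sels, 2L, function(ix) {
      sel <- logical(n); sel[ix] <- TRUE; stat(sel)
    })
    p <- mean(stats <= obs + 1e-12)
    method <- "exact"
  } else {
    stats <- withSeed(seed, vapply(seq_len(nPerm - 1L), function(r) {
      sel <- logical(n); sel[sample(n, k)] <- TRUE; stat(sel)
    }, 0))
    p <- (1 + sum(stats <= obs + 1e-12)) / nPerm
    method <- "sampled"
  }
  list(statistic = obs, p = p, method = method)
}

#' Screen for sweep-candidate viruses
#'
#' A virus passes when its density is strictly below \code{low} for every
#' focal allele and strictly above \code{high} for at least \code{minCount}
#' of the other alleles — viruses poorly presented by the focal
#' specificity yet well presented by many others.
#'
#' @param table A \linkS4class{DensityTable}.
#' @param focalAlleles,otherAlleles Disjoint, non-empty allele name sets.
#' @param low Upper density bound for focal alleles; default 1.
#' @param high Lower density bound for the other alleles; default 2.
#' @param minCount Minimum number of other alleles above \code{high};
#'   default 10.
#' @return Character vector of passing virus ids.
#' @export
sweepCandidateFilter <- function(table, focalAlleles, otherAlleles,
                                 low = 1.0, high = 2.0, minCount = 10L) {
  stopifnot(is(table, "DensityTable"),
            length(focalAlleles) >= 1L, length(otherAlleles) >= 1L)
  if (length(intersect(focalAlleles, otherAlleles)))
    stop("focal and other allele sets must be disjoint")
  d <- table@densities
  pass <- vapply(rownames(d), function(v) {
    all(d[v, focalAlleles] < low) &&
      sum(d[v, otherAlleles] > high) >= minCount
  }, TRUE)
  rownames(d)[pass]
}

#' Self-proteome presentation per protein
#'
#' For each protein of a (host) self-proteome: the expected binder count at
#' the rank threshold (threshold fraction of that protein's digestion
#' products) and the observed binder count for one allele, plus their
#' ratio. Under the calibration null the ratios centre on 1.
#'
#' @param selfProteome A \linkS4class{ProteomeSet}.
#' @param model The allele's binding model.
#' @param reference The allele's \linkS4class{RankReference}.
#' @param lengths Digestion lengths; default 8:11.
#' @param threshold Rank threshold (percent); default 1.
#' @return Data frame with one row per protein: protein, totalProducts,
#'   expected, observed, ratio (NA when a protein yields no products).
#'   Observed counts binder windows with multiplicity, consistent with the
#'   expected count being a fraction of all windows.
#' @export
selfPresentation <- function(selfProteome, model, reference,
                             lengths = 8:11, threshold = 1.0) {
  stopifnot(is(selfProteome, "ProteomeSet"), is(reference, "RankReference"))
  ids <- names(selfProteome@aa)
  seqs <- as.character(selfProteome@aa)
  rows <- lapply(seq_along(ids), function(i) {
    windows <- unlist(lapply(as.integer(lengths), slideWindows,
                             s = seqs[[i]], mask = selfProteome@mask[[i]]),
                      use.names = FALSE)
    dg <- list(totalProducts = length(windows),
               uniqueProducts = unique(windows))
    expected <- (threshold / 100) * dg$totalProducts
    observed <- if (dg$totalProducts == 0) 0L else {
      rk <- percentileRank(bindingScore(model, dg$uniqueProducts), reference)
      sum(windows %in% dg$uniqueProducts[isBinder(rk, threshold)])
    }
    data.frame(protein = ids[[i]], totalProducts = dg$totalProducts,
               expected = expected, observed = observed,
               ratio = if (expected > 0) observed / expected else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a density table as TSV
#'
#' @param table A \linkS4class{DensityTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDensityTable <- function(table, path) {
  df <- data.frame(virus = rownames(table@densities), table@densities,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
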