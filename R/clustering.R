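#' Jaccard similarity of two peptide sets
#'
#' J = |A intersect B| / |A union B|. When both sets are empty the two
#' repertoires are indistinguishable for that virus and J is defined as 1
#' (configurable at the distance level via \code{emptyPolicy}).
#'
#' @param a,b Character vectors treated as sets (duplicates ignored).
#' @return Similarity in [0, 1].
#' @examples
#' jaccardIndex(c("p1", "p2", "p3"), c("p2", "p3", "p4"))  # 0.5
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

# Per-virus Jaccard similarities for every unordered allele pair:
# rows = pairs (in combn order), cols = viruses. NA marks both-empty pairs.
jaccardArray <- function(repertoire) {
  alleles <- repertoire@alleleNames
  vids <- repertoire@virusIds
  pairs <- combn(seq_along(alleles), 2L)
  J <- matrix(NA_real_, ncol(pairs), length(vids),
              dimnames = list(NULL, vids))
  for (v in seq_along(vids)) {
    setsv <- lapply(repertoire@sets, `[[`, v)
    for (p in seq_len(ncol(pairs))) {
      a <- setsv[[pairs[1L, p]]]; b <- setsv[[pairs[2L, p]]]
      u <- length(a) + length(b) - length(intersect(a, b))
      J[p, v] <- if (u == 0L) NA_real_ else length(intersect(a, b)) / u
    }
  }
  list(pairs = pairs, J = J)
}

pairMeanJ <- function(J, cols, emptyPolicy) {
  sub <- J[, cols, drop = FALSE]
  if (emptyPolicy == "identical") sub[is.na(sub)] <- 1
  m <- rowMeans(sub, na.rm = TRUE)
  m[is.nan(m)] <- 1  # every virus both-empty under "skip": identical repertoires
  m
}

#' Functional distance between two alleles
#'
#' D = 1 - mean over viruses of the per-virus Jaccard similarity of the two
#' alleles' binder sets.
#'
#' @param repertoire A \linkS4class{BinderRepertoire}.
#' @param alleleA,alleleB Allele names.
#' @param virusSubset Optional character vector of virus ids (default: all).
#' @param emptyPolicy Treatment of viruses where both sets are empty:
#'   \code{"identical"} counts them as J = 1; \code{"skip"} drops them and
#'   renormalizes over the remaining viruses.
#' @return Distance in [0, 1].
#' @export
functionalDistance <- function(repertoire, alleleA, alleleB,
                               virusSubset = NULL,
                               emptyPolicy = c("identical", "skip")) {
  emptyPolicy <- match.arg(emptyPolicy)
  stopifnot(is(repertoire, "BinderRepertoire"))
  if (is.null(virusSubset)) virusSubset <- repertoire@virusIds
  if (!length(virusSubset)) stop("virus subset must be non-empty")
  stopifnot(all(virusSubset %in% repertoire@virusIds))
  js <- vapply(virusSubset, function(v) {
    a <- repertoire@sets[[alleleA]][[v]]
    b <- repertoire@sets[[alleleB]][[v]]
    if (length(a) + length(b) == 0L) {
      if (emptyPolicy == "identical") 1 else NA_real_
    } else jaccardIndex(a, b)
  }, 0)
  m <- mean(js, na.rm = TRUE)
  if (is.nan(m)) m <- 1
  1 - m
}

#' Pairwise functional distance matrix
#'
#' @inheritParams functionalDistance
#' @return Symmetric numeric matrix with zero diagonal, dimnames = allele
#'   names, entries in [0, 1].
#' @export
functionalDistanceMatrix <- function(repertoire, virusSubset = NULL,
                                     emptyPolicy = c("identical", "skip")) {
  emptyPolicy <- match.arg(emptyPolicy)
  stopifnot(is(repertoire, "BinderRepertoire"))
  alleles <- repertoire@alleleNames
  if (length(alleles) < 2L) stop("at least 2 alleles are required")
  if (is.null(virusSubset)) virusSubset <- repertoire@virusIds
  if (!length(virusSubset)) stop("virus subset must be non-empty")
  ja <- jaccardArray(repertoire)
  meanJ <- pairMeanJ(ja$J, virusSubset, emptyPolicy)
  D <- matrix(0, length(alleles), length(alleles),
              dimnames = list(alleles, alleles))
  for (p in seq_len(ncol(ja$pairs))) {
    i <- ja$pairs[1L, p]; j <- ja$pairs[2L, p]
    D[i, j] <- D[j, i] <- 1 - meanJ[p]
  }
  D
}

# UPGMA merge table in hclust layout. Tie-break: among minimal-distance
# cluster pairs, the pair whose (smallest-leaf-name, smallest-leaf-name)
# key sorts lexicographically first.
upgmaMergeTable <- function(D) {
  labels <- rownames(D)
  n <- nrow(D)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  idx <- as.list(-(seq_len(n)))          # hclust index of each active cluster
  size <- rep(1L, n)
  lab <- labels                           # tie-break label (min leaf name)
  Dc <- D
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    na <- length(active)
    best <- NULL; bestd <- Inf
    for (ii in seq_len(na - 1L)) for (jj in (ii + 1L):na) {
      d <- Dc[ii, jj]
      if (d < bestd - 1e-12) {
        bestd <- d; best <- c(ii, jj)
      } else if (d <= bestd + 1e-12) {
        k1 <- sort(c(lab[active[ii]], lab[active[jj]]))
        k2 <- sort(c(lab[active[best[1L]]], lab[active[best[2L]]]))
        if (k1[1L] < k2[1L] || (k1[1L] == k2[1L] && k1[2L] < k2[2L])) {
          bestd <- min(bestd, d); best <- c(ii, jj)
        }
      }
    }
    ii <- best[1L]; jj <- best[2L]
    a <- active[ii]; b <- active[jj]
    merge[step, ] <- sort(c(idx[[a]], idx[[b]]))
    height[step] <- Dc[ii, jj]
    # weighted average linkage update
    newrow <- (size[a] * Dc[ii, ] + size[b] * Dc[jj, ]) / (size[a] + size[b])
    keep <- setdiff(seq_len(na), c(ii, jj))
    Dn <- rbind(cbind(Dc[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    size[a] <- size[a] + size[b]
    lab[a] <- min(lab[a], lab[b])
    idx[[a]] <- step
    active <- c(active[keep], a)
    Dc <- Dn
  }
  list(merge = merge, height = height, labels = labels)
}

hclustOrder <- function(merge) {
  rec <- function(i) {
    if (i < 0L) return(-i)
    c(rec(merge[i, 1L]), rec(merge[i, 2L]))
  }
  rec(nrow(merge))
}

#' UPGMA clustering of a functional distance matrix
#'
#' Average-linkage agglomerative clustering (weighted by cluster sizes)
#' producing an ultrametric rooted tree whose merge heights are half the
#' merge distances, so that cophenetic distances on the tree reproduce the
#' linkage distances. Ties between equally close cluster pairs are broken
#' deterministically by the lexicographically smallest name-sorted pair of
#' cluster labels.
#'
#' @param D Symmetric distance matrix with dimnames (e.g. from
#'   [functionalDistanceMatrix()]).
#' @return An \code{ape} \code{phylo} tree (rooted, ultrametric) with an
#'   \code{"hclust"} attribute holding the merge structure for use with
#'   [treeClusters()].
#' @export
upgmaTree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 2L)
  if (any(is.na(D))) stop("distance matrix contains NA/NaN")
  if (is.null(rownames(D))) stop("distance matrix must have dimnames")
  mt <- upgmaMergeTable(D)
  hc <- structure(list(merge = mt$merge, height = mt$height,
                       order = hclustOrder(mt$merge), labels = mt$labels,
                       method = "average", call = match.call(),
                       dist.method = "functional"),
                  class = "hclust")
  tree <- ape::as.phylo(hc)   # edge lengths from height/2: ultrametric
  attr(tree, "hclust") <- hc
  tree
}

#' Cut an UPGMA tree into k clusters
#'
#' @param tree A tree from [upgmaTree()].
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
treeClusters <- function(tree, k) {
  hc <- attr(tree, "hclust")
  if (is.null(hc)) stop("tree carries no merge structure (not from upgmaTree)")
  stats::cutree(hc, k = k)
}

#' Clades of a rooted tree as canonical keys
#'
#' Returns, for each internal node of a rooted tree, the set of tip labels
#' below it as a "|"-joined sorted key. Includes the root clade; excludes
#' singleton tips. These keys are how bootstrap clade frequencies are
#' tabulated.
#'
#' @param tree A rooted phylo tree.
#' @return Character vector of clade keys, named by internal node number.
#' @export
cladeSets <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tipsUnder <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tipsUnder[[i]] <- tree$tip.label[i]
  for (nd in sort(nodes, decreasing = TRUE)) {
    tipsUnder[[nd]] <- unlist(tipsUnder[kids[[as.character(nd)]]])
  }
  keys <- vapply(nodes, function(nd)
    paste(sort(tipsUnder[[nd]]), collapse = "|"), "")
  setNames(keys, nodes)
}

# Ultrametric node heights (distance from a node to its descendant leaves).
# Trees without branch lengths get unit-length edges.
nodeHeights <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- numeric(nnode)          # distance from root
  ord <- ape::reorder.phylo(tree, "cladewise")
  if (is.null(ord$edge.length)) ord$edge.length <- rep(1, nrow(ord$edge))
  for (e in seq_len(nrow(ord$edge)))
    depth[ord$edge[e, 2L]] <- depth[ord$edge[e, 1L]] + ord$edge.length[e]
  total <- max(depth[seq_len(ntip)])
  h <- total - depth
  setNames(h, seq_len(nnode))
}

#' Bootstrap support by virus subsampling
#'
#' Repeatedly subsamples a fraction of the viruses without replacement
#' (ceiling(fraction x N) per replicate, seeded), recomputes the functional
#' distance matrix restricted to the subsample, rebuilds the UPGMA tree,
#' and tabulates how often each clade of leaves recurs. The per-virus
#' Jaccard similarities are computed once and reused, so replicates only
#' re-average them.
#'
#' @param repertoire A \linkS4class{BinderRepertoire}.
#' @param nReps Number of bootstrap replicates; default 1000.
#' @param fraction Fraction of viruses per replicate in (0, 1]; default 0.2.
#' @param seed Integer seed.
#' @param emptyPolicy See [functionalDistance()].
#' @return List with \code{trees} (replicate phylo trees),
#'   \code{frequencies} (named numeric: clade key -> support in [0, 1]),
#'   and \code{n} (number of replicates).
#' @export
bootstrapSupports <- function(repertoire, nReps = 1000L, fraction = 0.2,
                              seed = 1L,
                              emptyPolicy = c("identical", "skip")) {
  emptyPolicy <- match.arg(emptyPolicy)
  stopifnot(fraction > 0, fraction <= 1, nReps >= 1L)
  alleles <- repertoire@alleleNames
  vids <- repertoire@virusIds
  m <- max(1L, as.integer(ceiling(fraction * length(vids))))
  ja <- jaccardArray(repertoire)
  subsets <- withSeed(seed, lapply(seq_len(nReps), function(r)
    sample(length(vids), m)))
  counts <- new.env(parent = emptyenv())
  trees <- vector("list", nReps)
  template <- matrix(0, length(alleles), length(alleles),
                     dimnames = list(alleles, alleles))
  for (r in seq_len(nReps)) {
    meanJ <- pairMeanJ(ja$J, subsets[[r]], emptyPolicy)
    D <- template
    D[t(ja$pairs)] <- 1 - meanJ
    D[t(ja$pairs[2:1, , drop = FALSE])] <- 1 - meanJ
    tr <- upgmaTree(D)
    trees[[r]] <- tr
    for (key in unique(cladeSets(tr)))
      assign(key, (if (exists(key, envir = counts)) get(key, envir = counts) else 0) + 1,
             envir = counts)
  }
  keys <- ls(counts)
  freq <- vapply(keys, get, 0, envir = counts) / nReps
  list(trees = trees, frequencies = sort(freq, decreasing = TRUE), n = nReps)
}

#' Bootstrap support of a specific clade
#'
#' @param supports Result of [bootstrapSupports()].
#' @param leaves Character vector of leaf names forming the clade.
#' @return Support in [0, 1] (0 when the clade never occurred).
#' @export
cladeSupport <- function(supports, leaves) {
  key <- paste(sort(leaves), collapse = "|")
  if (key %in% names(supports$frequencies)) supports$frequencies[[key]] else 0
}

cladesCompatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

#' Extended majority-rule consensus of rooted trees
#'
#' Includes every clade present in more than half of the input trees, then
#' greedily adds the remaining observed clades in order of decreasing
#' frequency (ties broken by smaller clade size, then lexicographically)
#' whenever they are compatible with everything already included. Node
#' support is the clade's frequency among the input trees; node heights are
#' averaged over the trees containing the clade (clamped to respect
#' parent-child monotonicity).
#'
#' @param trees List of rooted phylo trees on the same leaf set.
#' @return A rooted phylo tree with supports in \code{node.label}.
#' @export
extendedMajorityConsensus <- function(trees) {
  stopifnot(length(trees) >= 1L)
  leafSet <- sort(trees[[1L]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), leafSet))
      stop("all trees must share the same leaf set")
  nT <- length(trees)

  counts <- list(); heights <- list()
  for (tr in trees) {
    cs <- cladeSets(tr)
    hs <- nodeHeights(tr)
    for (i in seq_along(cs)) {
      key <- cs[[i]]
      counts[[key]] <- (counts[[key]] %||% 0) + 1
      heights[[key]] <- c(heights[[key]], hs[[names(cs)[i]]])
    }
  }
  keys <- names(counts)
  freq <- vapply(keys, function(k) counts[[k]] / nT, 0)
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, 0L)

  rootKey <- paste(leafSet, collapse = "|")
  included <- keys[freq > 0.5]
  if (!rootKey %in% included) included <- c(included, rootKey)
  rest <- setdiff(keys, included)
  rest <- rest[order(-freq[rest], sizes[rest], rest)]
  for (k in rest) {
    kl <- strsplit(k, "|", fixed = TRUE)[[1L]]
    ok <- all(vapply(included, function(ik)
      cladesCompatible(kl, strsplit(ik, "|", fixed = TRUE)[[1L]]), TRUE))
    if (ok) included <- c(included, k)
  }

  cladeH <- vapply(included, function(k)
    if (k %in% names(heights)) mean(heights[[k]]) else max(unlist(heights)), 0)
  cladeF <- vapply(included, function(k) freq[k] %||% 1, 0)
  cladeL <- strsplit(included, "|", fixed = TRUE)

  buildNode <- function(key, hParent) {
    members <- cladeL[[match(key, included)]]
    h <- min(cladeH[[key]], hParent)
    children <- character()
    # direct child clades: included proper subsets not nested in a larger
    # included proper subset of this clade
    subs <- included[vapply(cladeL, function(s)
      length(s) < length(members) && all(s %in% members), TRUE)]
    covered <- character()
    for (s in subs[order(-vapply(strsplit(subs, "|", fixed = TRUE), length, 0L))]) {
      sl <- strsplit(s, "|", fixed = TRUE)[[1L]]
      if (!any(sl %in% covered)) {
        child <- buildNode(s, h)
        children <- c(children,
                      sprintf("%s:%.10g", child$str, h - child$h))
        covered <- c(covered, sl)
      }
    }
    for (tip in setdiff(members, covered))
      children <- c(children, sprintf("%s:%.10g", tip, h))
    lab <- sprintf("%.10g", cladeF[[key]])
    list(str = sprintf("(%s)%s", paste(children, collapse = ","), lab),
         h = h)
  }
  nwk <- paste0(buildNode(rootKey, Inf)$str, ";")
  ape::read.tree(text = nwk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read trees in Newick format
#'
#' Thin wrappers over \code{ape}: branch lengths come from the ultrametric
#' heights and bootstrap supports are stored as internal node labels.
#'
#' @param tree A phylo tree.
#' @param path File path.
#' @return \code{writeNewick}: invisibly, \code{path}; \code{readNewick}:
#'   a phylo tree.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}

#' Write a distance matrix
#'
#' @param D Symmetric matrix with dimnames.
#' @param path Output path.
#' @param format \code{"tsv"} (header row and column of ids) or
#'   \code{"phylip"} (square PHYLIP matrix).
#' @return Invisibly, \code{path}.
#' @export
writeDistanceMatrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(D), D, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D)))
      writeLines(paste(formatC(rownames(D)[i], width = -10),
                       paste(formatC(D[i, ], format = "f", digits = 6),
                             collapse = " ")), con)
  }
  invisible(path)
}
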