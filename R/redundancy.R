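#' Percent identity of a Needleman-Wunsch global alignment
#'
#' Aligns two protein sequences globally with affine gap penalties
#' (defaults: BLOSUM62, gap open 10, gap extend 0.5) and returns the percent
#' identity computed as 100 x identical aligned positions / alignment length
#' including gap columns (the EMBOSS identity convention). End gaps are
#' penalized (true global alignment).
#'
#' @param seqA,seqB Non-empty protein sequences (character strings).
#' @param substitutionMatrix Name of, or an actual, substitution matrix.
#' @param gapOpening,gapExtension Affine gap penalties (positive costs; a
#'   gap of length g costs gapOpening + g * gapExtension).
#' @return Percent identity in [0, 100].
#' @examples
#' globalAlignIdentity("MKVL", "MKVL")  # 100
#' globalAlignIdentity("MKVL", "MKIL")  # 75
#' @export
globalAlignIdentity <- function(seqA, seqB, substitutionMatrix = "BLOSUM62",
                                gapOpening = 10, gapExtension = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    seqA, seqB, type = "global",
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  # identity over the full alignment length including end-gap columns
  # (Biostrings pid() drops end gaps from its denominator)
  alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / alnLen
}

#' Percent identity between two viruses
#'
#' The alignment substrate is the concatenation of each virus's protein
#' records in id-sorted order, making the result deterministic and invariant
#' to record order within a ProteomeSet.
#'
#' @param virusA,virusB \linkS4class{ProteomeSet} objects.
#' @param ... Passed to [globalAlignIdentity()].
#' @return Percent identity in [0, 100].
#' @export
virusIdentity <- function(virusA, virusB, ...) {
  globalAlignIdentity(concatSorted(virusA), concatSorted(virusB), ...)
}

concatSorted <- function(proteome) {
  stopifnot(is(proteome, "ProteomeSet"))
  seqs <- as.character(proteome@aa)
  paste(seqs[order(names(proteome@aa))], collapse = "")
}

#' Pairwise identity matrix for a set of viruses
#'
#' @param viruses List of \linkS4class{ProteomeSet} objects with unique
#'   source ids.
#' @param ... Passed to [globalAlignIdentity()].
#' @return Symmetric numeric matrix of percent identities with 100 on the
#'   diagonal, dimnames = virus source ids.
#' @export
identityMatrix <- function(viruses, ...) {
  ids <- vapply(viruses, sourceId, "")
  if (anyDuplicated(ids)) stop("duplicate virus source ids")
  n <- length(viruses)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    cats <- vapply(viruses, concatSorted, "")
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- globalAlignIdentity(cats[[i]], cats[[j]], ...)
    }
  }
  m
}

#' Collapse near-identical viruses
#'
#' Greedy redundancy reduction in input order: a virus is retained iff its
#' identity to every already-retained virus is at or below the threshold
#' (strictly greater identity collapses, so exactly-threshold pairs are both
#' retained). Collapsed viruses map to the first retained representative
#' that excluded them.
#'
#' @param viruses Ordered list of \linkS4class{ProteomeSet} objects.
#' @param threshold Percent identity threshold in (0, 100]; default 95.
#' @param idm Optional precomputed [identityMatrix()] (computed if missing).
#' @param ... Passed to [identityMatrix()] when it must be computed.
#' @return List with \code{retained} (the retained ProteomeSets),
#'   \code{retainedIds}, and \code{clusterMap} (named character mapping
#'   every virus id to its representative's id; retained viruses map to
#'   themselves).
#' @export
collapseViruses <- function(viruses, threshold = 95, idm = NULL, ...) {
  stopifnot(threshold > 0, threshold <= 100)
  ids <- vapply(viruses, sourceId, "")
  if (is.null(idm)) idm <- identityMatrix(viruses, ...)
  stopifnot(all(ids %in% rownames(idm)))
  keep <- integer()
  rep_of <- setNames(ids, ids)
  for (i in seq_along(viruses)) {
    excl <- keep[idm[ids[i], ids[keep]] > threshold]
    if (length(excl)) {
      rep_of[ids[i]] <- ids[excl[1L]]
    } else {
      keep <- c(keep, i)
    }
  }
  list(retained = viruses[keep],
       retainedIds = ids[keep],
       clusterMap = rep_of)
}
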