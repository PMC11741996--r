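#' Build a self-calibrated percentile-rank reference
#'
#' Digests a reference proteome into all products of the given lengths,
#' samples a fixed number of distinct peptides per length uniformly without
#' replacement (seeded), scores them with the allele's binding model, and
#' pools the scores into one sorted reference distribution. At the default
#' settings (5 lengths x 25,000 peptides) the pool holds 125,000 scores.
#'
#' @param model A binding model implementing [bindingScore()].
#' @param referenceProteome \linkS4class{ProteomeSet} of reference proteins.
#' @param lengths Peptide lengths digested for the reference; default 8:12.
#' @param perLengthCount Unique peptides sampled per length; default 25000.
#' @param seed Integer seed for the sampling.
#' @param alleleName Name recorded in the reference; defaults to the
#'   model's allele name when available.
#' @param pools Optional precomputed per-length unique-product pools (a
#'   named list, length -> character vector, as from
#'   [referencePeptidePools()]); avoids re-digesting the proteome when
#'   building references for many alleles.
#' @return A \linkS4class{RankReference}.
#' @seealso [percentileRank()], [isBinder()]
#' @export
buildRankReference <- function(model, referenceProteome = NULL, lengths = 8:12,
                               perLengthCount = 25000L, seed = 1L,
                               alleleName = NULL, pools = NULL) {
  stopifnot(perLengthCount >= 1L)
  if (is.null(alleleName))
    alleleName <- if (is(model, "SyntheticAlleleModel")) model@alleleName
                  else NA_character_
  lengths <- as.integer(lengths)
  if (is.null(pools)) {
    stopifnot(is(referenceProteome, "ProteomeSet"))
    pools <- referencePeptidePools(referenceProteome, lengths)
  }
  scores <- numeric()
  counts <- integer()
  for (k in lengths) {
    pool <- pools[[as.character(k)]]
    if (is.null(pool)) stop("no peptide pool for length ", k)
    if (length(pool) < perLengthCount)
      stop(sprintf(
        "insufficient unique digestion products at length %d: have %d, need %d (short by %d)",
        k, length(pool), perLengthCount, perLengthCount - length(pool)))
    picked <- withSeed(seed + k, sample(pool, perLengthCount))
    scores <- c(scores, bindingScore(model, picked))
    counts[as.character(k)] <- as.integer(perLengthCount)
  }
  new("RankReference",
      alleleName = as.character(alleleName),
      scores = sort(scores, decreasing = TRUE),
      perLengthCounts = counts,
      seed = as.integer(seed))
}

#' Unique digestion-product pools of a reference proteome
#'
#' Digests the proteome once per length and returns the unique products,
#' for reuse across [buildRankReference()] calls for different alleles.
#'
#' @param referenceProteome A \linkS4class{ProteomeSet}.
#' @param lengths Integer vector of peptide lengths.
#' @return Named list: length (as character) -> character vector of unique
#'   peptides.
#' @export
referencePeptidePools <- function(referenceProteome, lengths) {
  stopifnot(is(referenceProteome, "ProteomeSet"))
  pools <- lapply(as.integer(lengths), function(k)
    digestProteome(referenceProteome, k)$uniqueProducts)
  names(pools) <- as.character(as.integer(lengths))
  pools
}

#' Percentile rank of binding scores
#'
#' The rank of a score is the percentage of reference-pool scores strictly
#' greater than it: rank 0 means the score exceeds every reference score
#' (strongest binding), rank 100 means every pool member is strictly
#' greater. Ties with pool members do not count against the query.
#'
#' @param score Numeric vector of raw binding scores.
#' @param reference A \linkS4class{RankReference}.
#' @return Numeric vector of ranks in [0, 100], parallel to \code{score}.
#' @export
percentileRank <- function(score, reference) {
  stopifnot(is(reference, "RankReference"))
  asc <- rev(reference@scores)
  n <- length(asc)
  # findInterval on the ascending pool counts members <= score
  100 * (n - findInterval(score, asc)) / n
}

#' Binder call at a percentile-rank threshold
#'
#' A peptide is a binder when its rank is at or below the threshold
#' (inclusive: rank exactly 1.0 at the default 1% threshold is a binder).
#'
#' @param rank Numeric vector of percentile ranks in [0, 100].
#' @param threshold Rank threshold in percent; default 1.
#' @return Logical vector.
#' @export
isBinder <- function(rank, threshold = 1.0) {
  stopifnot(all(rank >= 0 & rank <= 100))
  rank <= threshold
}

#' Serialize / restore a RankReference
#'
#' Portable text format: a JSON header line (allele, seed, per-length
#' counts) followed by one score per line, sorted decreasing.
#'
#' @param reference A \linkS4class{RankReference}.
#' @param path File path.
#' @return \code{writeRankReference}: invisibly, \code{path};
#'   \code{readRankReference}: the restored \linkS4class{RankReference}.
#' @export
writeRankReference <- function(reference, path) {
  stopifnot(is(reference, "RankReference"))
  hdr <- jsonlite::toJSON(list(alleleName = reference@alleleName,
                               seed = reference@seed,
                               perLengthCounts = as.list(reference@perLengthCounts)),
                          auto_unbox = TRUE, digits = NA)
  writeLines(c(as.character(hdr),
               formatC(reference@scores, format = "g", digits = 17)), path)
  invisible(path)
}

#' @rdname writeRankReference
#' @export
readRankReference <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed rank reference file: ", path)
  hdr <- jsonlite::fromJSON(lines[[1L]])
  new("RankReference",
      alleleName = hdr$alleleName,
      scores = as.numeric(lines[-1L]),
      perLengthCounts = setNames(as.integer(unlist(hdr$perLengthCounts)),
                                 names(hdr$perLengthCounts)),
      seed = as.integer(hdr$seed))
}
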