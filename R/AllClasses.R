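#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern nmatch width
#' @importFrom ape read.tree write.tree
#' @importFrom stats runif setNames wilcox.test p.adjust cophenetic
#' @importFrom utils combn head read.delim write.table
NULL

#' The 20 standard amino acids
#'
#' One-letter codes of the 20 standard amino acids, the alphabet over which
#' all digestion products and binding models are defined.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' ProteomeSet: an identified set of protein sequences
#'
#' A set of amino-acid sequences from one source (a virus, a reference
#' database snapshot, or a host self-proteome). Sequences are held as a
#' \linkS4class{AAStringSet}; per-record masks flag positions carrying
#' nonstandard residues so that downstream digestion can exclude any peptide
#' window overlapping them.
#'
#' @slot sourceId Single string identifying the source (e.g. virus accession).
#' @slot aa \code{AAStringSet} of sequences; names are record ids, unique
#'   within the set.
#' @slot description Character vector of free-text descriptions, parallel to
#'   \code{aa}.
#' @slot hostTags Character vector of optional host annotations.
#' @slot mask List (parallel to \code{aa}) of integer vectors of masked
#'   1-based positions; integer(0) where nothing is masked.
#'
#' @seealso [readFasta()], [sanitizeProteome()], [digestProteome()]
#' @export
setClass("ProteomeSet",
  representation(
    sourceId    = "character",
    aa          = "AAStringSet",
    description = "character",
    hostTags    = "character",
    mask        = "list"
  )
)

setValidity("ProteomeSet", function(object) {
  msg <- character()
  if (length(object@sourceId) != 1L || !nzchar(object@sourceId))
    msg <- c(msg, "sourceId must be a single non-empty string")
  if (length(object@aa) < 1L)
    msg <- c(msg, "a ProteomeSet must contain at least one record")
  ids <- names(object@aa)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msg <- c(msg, "every record must have a non-empty id")
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate record id(s): %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@description) != length(object@aa))
    msg <- c(msg, "description must be parallel to the sequences")
  if (length(object@mask) != length(object@aa))
    msg <- c(msg, "mask must be parallel to the sequences")
  if (any(Biostrings::width(object@aa) == 0L))
    msg <- c(msg, "empty sequences are not allowed")
  if (length(msg)) msg else TRUE
})

#' AllelePanel: named alleles with group labels and binding models
#'
#' An ordered panel of MHC alleles, each carrying a free-text group label
#' (e.g. \code{"A02-HLA"}, \code{"non-A02-HLA"}, \code{"Patr"},
#' \code{"Gogo"}) and a binding model implementing [bindingScore()].
#'
#' @slot alleleNames Character vector of unique allele names.
#' @slot groupLabels Character vector of non-empty group labels, parallel to
#'   \code{alleleNames}.
#' @slot models Named list of binding-model objects, one per allele.
#'
#' @seealso [generateAllelePanel()], [readAllelePanel()]
#' @export
setClass("AllelePanel",
  representation(
    alleleNames = "character",
    groupLabels = "character",
    models      = "list"
  )
)

setValidity("AllelePanel", function(object) {
  msg <- character()
  n <- length(object@alleleNames)
  if (n < 1L) msg <- c(msg, "panel must contain at least one allele")
  if (anyDuplicated(object@alleleNames))
    msg <- c(msg, "allele names must be unique")
  if (length(object@groupLabels) != n || any(!nzchar(object@groupLabels)))
    msg <- c(msg, "every allele needs a non-empty group label")
  if (length(object@models) != n)
    msg <- c(msg, "models must be parallel to alleleNames")
  if (length(msg)) msg else TRUE
})

#' SyntheticAlleleModel: an anchor-motif peptide binding model
#'
#' A deterministic stand-in for an external binding predictor. The score of
#' a peptide is the sum of an anchor preference at the second (P2) position,
#' an anchor preference at the C-terminal position, the mean of a background
#' weight over the remaining positions, and a bounded deterministic
#' per-(allele, peptide) perturbation of magnitude \code{noiseScale} derived
#' from a keyed positional hash, so that scores are reproducible regardless
#' of call order.
#'
#' @slot alleleName Allele this model belongs to.
#' @slot supertypeId Planted supertype truth label (generator provenance).
#' @slot anchorP2 Named numeric of length 20: P2 anchor weights.
#' @slot anchorC Named numeric of length 20: C-terminal anchor weights.
#' @slot background Named numeric of length 20: background weights applied to
#'   the non-anchor positions.
#' @slot noiseScale Magnitude of the deterministic perturbation (>= 0).
#' @slot hashKey 20 x 12 numeric matrix keying the positional hash.
#'
#' @seealso [syntheticAlleleModel()], [bindingScore()]
#' @export
setClass("SyntheticAlleleModel",
  representation(
    alleleName  = "character",
    supertypeId = "character",
    anchorP2    = "numeric",
    anchorC     = "numeric",
    background  = "numeric",
    noiseScale  = "numeric",
    hashKey     = "matrix"
  )
)

setValidity("SyntheticAlleleModel", function(object) {
  msg <- character()
  for (sl in c("anchorP2", "anchorC", "background")) {
    w <- slot(object, sl)
    if (length(w) != 20L || !identical(sort(names(w)), sort(AA_STANDARD)))
      msg <- c(msg, sprintf("%s must be a numeric vector named by the 20 standard residues", sl))
  }
  if (length(object@noiseScale) != 1L || object@noiseScale < 0)
    msg <- c(msg, "noiseScale must be a single non-negative number")
  if (!identical(dim(object@hashKey), c(20L, 12L)))
    msg <- c(msg, "hashKey must be a 20 x 12 matrix")
  if (length(msg)) msg else TRUE
})

#' RankReference: an allele's self-calibrated percentile-rank pool
#'
#' The sorted pool of binding scores of reference peptides used to convert a
#' raw binding score into a percentile rank for one allele. At default
#' settings the pool holds 25,000 unique digestion products of each length
#' 8--12 from a reference proteome, i.e. 125,000 scores in total.
#'
#' @slot alleleName Allele the pool was built for.
#' @slot scores Numeric vector of reference scores, sorted decreasing.
#' @slot perLengthCounts Named integer vector: peptides sampled per length.
#' @slot seed Integer seed used for the (reproducible) sampling.
#'
#' @seealso [buildRankReference()], [percentileRank()]
#' @export
setClass("RankReference",
  representation(
    alleleName      = "character",
    scores          = "numeric",
    perLengthCounts = "integer",
    seed            = "integer"
  )
)

setValidity("RankReference", function(object) {
  msg <- character()
  if (length(object@scores) < 1L)
    msg <- c(msg, "reference pool must be non-empty")
  if (is.unsorted(rev(object@scores)))
    msg <- c(msg, "scores must be sorted decreasing")
  if (length(object@scores) != sum(object@perLengthCounts))
    msg <- c(msg, "pool size must equal the sum of per-length counts")
  if (length(msg)) msg else TRUE
})

#' BinderRepertoire: per-(allele, virus) sets of unique binder peptides
#'
#' For every allele in a panel and every virus, the set of unique digestion
#' products whose self-calibrated percentile rank is at or below the binder
#' threshold. Also records each virus's total (with multiplicity) and unique
#' digestion-product counts, which downstream density computations need.
#'
#' @slot alleleNames Ordered allele names.
#' @slot groupLabels Group labels parallel to \code{alleleNames}.
#' @slot virusIds Ordered virus ids.
#' @slot sets List of lists: \code{sets[[allele]][[virus]]} is a character
#'   vector of unique binder peptides.
#' @slot totalProducts Named numeric: per-virus total digestion products
#'   (windows with multiplicity).
#' @slot uniqueProducts Named numeric: per-virus unique digestion products.
#' @slot threshold Percentile-rank binder threshold used (percent).
#' @slot lengths Integer vector of peptide lengths digested.
#'
#' @seealso [buildRepertoire()], [functionalDistanceMatrix()], [densityTable()]
#' @export
setClass("BinderRepertoire",
  representation(
    alleleNames    = "character",
    groupLabels    = "character",
    virusIds       = "character",
    sets           = "list",
    totalProducts  = "numeric",
    uniqueProducts = "numeric",
    threshold      = "numeric",
    lengths        = "integer"
  )
)

setValidity("BinderRepertoire", function(object) {
  msg <- character()
  nA <- length(object@alleleNames); nV <- length(object@virusIds)
  if (length(object@sets) != nA)
    msg <- c(msg, "sets must have one entry per allele")
  else if (any(vapply(object@sets, length, 0L) != nV))
    msg <- c(msg, "every allele entry must have one peptide set per virus")
  if (length(object@totalProducts) != nV || length(object@uniqueProducts) != nV)
    msg <- c(msg, "product counts must be parallel to virusIds")
  if (object@threshold < 0 || object@threshold > 100)
    msg <- c(msg, "threshold must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' DensityTable: epitope densities per (virus, allele)
#'
#' Epitope density is the observed number of unique binder peptides divided
#' by the number expected by chance at the rank threshold (threshold
#' fraction times the virus's total digestion products). A density of 1
#' means the allele binds the virus exactly as often as chance predicts.
#'
#' @slot densities Numeric matrix, viruses in rows, alleles in columns.
#' @slot totalProducts Named numeric of per-virus total digestion products.
#' @slot groupLabels Named character of allele group labels.
#' @slot threshold Rank threshold (percent) the densities were computed at.
#'
#' @seealso [densityTable()], [groupCompare()], [sweepCandidateFilter()]
#' @export
setClass("DensityTable",
  representation(
    densities     = "matrix",
    totalProducts = "numeric",
    groupLabels   = "character",
    threshold     = "numeric"
  )
)

setValidity("DensityTable", function(object) {
  msg <- character()
  if (any(object@densities < 0))
    msg <- c(msg, "densities must be non-negative")
  if (length(object@groupLabels) != ncol(object@densities))
    msg <- c(msg, "one group label per allele column is required")
  if (length(object@totalProducts) != nrow(object@densities))
    msg <- c(msg, "one total product count per virus row is required")
  if (length(msg)) msg else TRUE
})
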