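SUPPORTED_LENGTHS <- 8:12

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Create a synthetic anchor-motif binding model
#'
#' The model scores a peptide as P2-anchor weight + C-terminal-anchor weight
#' + mean background weight over the remaining positions + a deterministic
#' bounded perturbation. The perturbation is \code{noiseScale * sin(k(p))},
#' where \code{k(p)} is a positional hash keyed by an allele-specific 20 x
#' 12 matrix drawn once from \code{seed}; it is a fixed function of
#' (allele, peptide), not an RNG stream, so scores never depend on call
#' order.
#'
#' @param alleleName Allele name.
#' @param anchorP2,anchorC Named numeric weight vectors over the 20 standard
#'   residues for the P2 and C-terminal anchor positions.
#' @param background Named numeric weight vector applied to the remaining
#'   positions.
#' @param noiseScale Magnitude of the deterministic perturbation.
#' @param seed Integer seed for the hash key.
#' @param supertypeId Optional planted supertype label.
#' @return A \linkS4class{SyntheticAlleleModel}.
#' @examples
#' w <- setNames(numeric(20), AA_STANDARD)
#' m <- syntheticAlleleModel("A1", w, w, w, noiseScale = 0, seed = 1)
#' bindingScore(m, "ACDEFGHK")  # 0
#' @export
syntheticAlleleModel <- function(alleleName, anchorP2, anchorC, background,
                                 noiseScale = 0.5, seed = 1L,
                                 supertypeId = NA_character_) {
  key <- withSeed(seed, matrix(runif(20L * 12L, -7, 7), 20L, 12L,
                               dimnames = list(AA_STANDARD, NULL)))
  new("SyntheticAlleleModel",
      alleleName = as.character(alleleName),
      supertypeId = as.character(supertypeId),
      anchorP2 = anchorP2[AA_STANDARD],
      anchorC = anchorC[AA_STANDARD],
      background = background[AA_STANDARD],
      noiseScale = noiseScale,
      hashKey = key)
}

# Residue-index matrix (n x L) for equal-length peptides.
encodePeptides <- function(peptides, L) {
  n <- length(peptides)
  M <- matrix(0L, n, L)
  for (i in seq_len(L)) {
    M[, i] <- match(substring(peptides, i, i), AA_STANDARD)
  }
  if (anyNA(M)) stop("peptide(s) contain non-standard residues")
  M
}

scoreEncoded <- function(model, M) {
  n <- nrow(M); L <- ncol(M)
  s <- unname(model@anchorP2[M[, 2L]] + model@anchorC[M[, L]])
  interior <- setdiff(seq_len(L), c(2L, L))
  bg <- model@background[as.vector(M[, interior, drop = FALSE])]
  dim(bg) <- c(n, length(interior))
  s <- s + rowMeans(bg)
  if (model@noiseScale > 0) {
    hv <- numeric(n)
    for (i in seq_len(L)) hv <- hv + model@hashKey[M[, i], i]
    s <- s + model@noiseScale * sin(hv)
  }
  s
}

#' @describeIn bindingScore Anchor-motif scoring; supported peptide lengths
#'   are 8--12.
#' @export
setMethod("bindingScore", "SyntheticAlleleModel", function(model, peptides, ...) {
  if (!length(peptides)) return(numeric())
  lens <- nchar(peptides)
  if (any(!lens %in% SUPPORTED_LENGTHS))
    stop("unsupported peptide length(s): ",
         paste(sort(unique(lens[!lens %in% SUPPORTED_LENGTHS])), collapse = ", "),
         " (supported: 8-12)")
  out <- numeric(length(peptides))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    out[idx] <- scoreEncoded(model, encodePeptides(peptides[idx], L))
  }
  out
})
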