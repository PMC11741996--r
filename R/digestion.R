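#' Digest a protein into overlapping peptides
#'
#' Emits every window of each requested length, skipping any window that
#' overlaps a masked (nonstandard-residue) position. \code{totalProducts}
#' counts windows with multiplicity; \code{uniqueProducts} is the set of
#' distinct peptide sequences. For an unmasked protein of length L and
#' window length k the number of windows is L - k + 1 (or 0 when k > L).
#'
#' @param residues Single protein sequence (standard residues, possibly with
#'   masked nonstandard positions).
#' @param lengths Integer vector of peptide lengths, e.g. \code{8:11} for
#'   viral digestion or \code{8:12} for the rank-reference digestion.
#' @param mask Integer vector of 1-based positions to exclude (any window
#'   overlapping one is dropped).
#' @param sourceId Identifier recorded in the result.
#' @return A list with elements \code{sourceId}, \code{totalProducts}
#'   (count) and \code{uniqueProducts} (character vector).
#' @examples
#' digest("ACDEFGHIKL", lengths = 8:11)$totalProducts  # 3 + 2 + 1 + 0
#' @export
digest <- function(residues, lengths, mask = integer(), sourceId = NA_character_) {
  stopifnot(length(residues) == 1L, length(lengths) >= 1L, all(lengths >= 1L))
  windows <- unlist(lapply(as.integer(lengths), slideWindows,
                           s = residues, mask = as.integer(mask)),
                    use.names = FALSE)
  list(sourceId = sourceId,
       totalProducts = length(windows),
       uniqueProducts = unique(windows))
}

slideWindows <- function(k, s, mask) {
  L <- nchar(s)
  n <- L - k + 1L
  if (n < 1L) return(character())
  starts <- seq_len(n)
  if (length(mask)) {
    ind <- integer(L)
    ind[mask] <- 1L
    cs <- c(0L, cumsum(ind))
    keep <- (cs[starts + k] - cs[starts]) == 0L
    starts <- starts[keep]
    if (!length(starts)) return(character())
  }
  substring(s, starts, starts + k - 1L)
}

#' Digest a whole proteome, pooling across its proteins
#'
#' Total products sum over records; unique products are the union over
#' records (invariant under record order). Masked positions recorded in the
#' ProteomeSet are honoured, so no digestion product ever contains a
#' nonstandard residue.
#'
#' @param proteome A \linkS4class{ProteomeSet}.
#' @param lengths Integer vector of peptide lengths.
#' @return A list with \code{sourceId}, \code{totalProducts} and
#'   \code{uniqueProducts} as in [digest()].
#' @export
digestProteome <- function(proteome, lengths) {
  stopifnot(is(proteome, "ProteomeSet"))
  seqs <- as.character(proteome@aa)
  per <- lapply(seq_along(seqs), function(i)
    digest(seqs[[i]], lengths, mask = proteome@mask[[i]]))
  list(sourceId = proteome@sourceId,
       totalProducts = sum(vapply(per, `[[`, 0L, "totalProducts")),
       uniqueProducts = unique(unlist(lapply(per, `[[`, "uniqueProducts"),
                                      use.names = FALSE)))
}
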