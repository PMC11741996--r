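#' Build per-(allele, virus) binder repertoires
#'
#' For every virus, digests its proteome into unique peptides of the viral
#' length range, scores each peptide with every allele's model, converts
#' scores to self-calibrated percentile ranks against that allele's
#' reference pool, and keeps the peptides at or below the binder threshold.
#' Peptide multiplicity is ignored: repertoires are sets of unique peptides
#' per virus, and a peptide occurring in two viruses contributes to both
#' viruses' sets independently.
#'
#' @param panel An \linkS4class{AllelePanel}.
#' @param viruses List of \linkS4class{ProteomeSet} objects.
#' @param references Named list of \linkS4class{RankReference} objects, one
#'   per panel allele.
#' @param lengths Viral digestion lengths; default 8:11.
#' @param threshold Percentile-rank binder threshold (percent); default 1.
#' @return A \linkS4class{BinderRepertoire}.
#' @export
buildRepertoire <- function(panel, viruses, references, lengths = 8:11,
                            threshold = 1.0) {
  stopifnot(is(panel, "AllelePanel"), length(viruses) >= 1L)
  alleles <- panel@alleleNames
  missing_ref <- setdiff(alleles, names(references))
  if (length(missing_ref))
    stop("missing rank reference for allele(s): ",
         paste(missing_ref, collapse = ", "))
  vids <- vapply(viruses, sourceId, "")
  if (anyDuplicated(vids)) stop("duplicate virus source ids")

  allSynthetic <- all(vapply(panel@models, is, TRUE, "SyntheticAlleleModel"))
  sets <- lapply(alleles, function(a) setNames(vector("list", length(vids)), vids))
  names(sets) <- alleles
  totals <- uniques <- setNames(numeric(length(vids)), vids)

  for (vi in seq_along(viruses)) {
    dg <- digestProteome(viruses[[vi]], lengths)
    totals[vi] <- dg$totalProducts
    uniques[vi] <- length(dg$uniqueProducts)
    peps <- dg$uniqueProducts
    if (!length(peps)) {
      for (a in alleles) sets[[a]][[vi]] <- character()
      next
    }
    if (allSynthetic) {
      lens <- nchar(peps)
      byLen <- split(seq_along(peps), lens)
      enc <- lapply(names(byLen), function(L)
        encodePeptides(peps[byLen[[L]]], as.integer(L)))
      for (a in alleles) {
        sc <- numeric(length(peps))
        for (li in seq_along(byLen))
          sc[byLen[[li]]] <- scoreEncoded(panel@models[[a]], enc[[li]])
        rk <- percentileRank(sc, references[[a]])
        sets[[a]][[vi]] <- peps[isBinder(rk, threshold)]
      }
    } else {
      for (a in alleles) {
        rk <- percentileRank(bindingScore(panel@models[[a]], peps),
                             references[[a]])
        sets[[a]][[vi]] <- peps[isBinder(rk, threshold)]
      }
    }
  }

  new("BinderRepertoire",
      alleleNames = alleles,
      groupLabels = panel@groupLabels,
      virusIds = vids,
      sets = sets,
      totalProducts = totals,
      uniqueProducts = uniques,
      threshold = threshold,
      lengths = as.integer(lengths))
}

#' Dump a repertoire as a long-format table
#'
#' @param repertoire A \linkS4class{BinderRepertoire}.
#' @param path Optional TSV output path.
#' @return Data frame with columns allele, virus, peptide (invisibly when
#'   \code{path} is given).
#' @export
repertoireTable <- function(repertoire, path = NULL) {
  stopifnot(is(repertoire, "BinderRepertoire"))
  rows <- list()
  for (a in repertoire@alleleNames) for (v in repertoire@virusIds) {
    p <- repertoire@sets[[a]][[v]]
    if (length(p))
      rows[[length(rows) + 1L]] <- data.frame(allele = a, virus = v,
                                              peptide = p,
                                              stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(allele = character(), virus = character(),
                        peptide = character(), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
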