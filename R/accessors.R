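#' Accessors for mhcRepertoire objects
#'
#' Small accessor generics: \code{sourceId} returns a ProteomeSet's source
#' identifier; \code{alleleNames} and \code{groupLabels} the panel/repertoire
#' allele annotation; \code{virusIds} the virus identifiers; \code{binderSet}
#' one (allele, virus) binder peptide set; \code{totalProducts} the per-virus
#' total digestion-product counts; \code{densities} the virus x allele
#' density matrix.
#'
#' @param x An object of the documented classes.
#' @param allele,virus Names selecting one repertoire entry.
#' @return See details per generic.
#' @name accessors
NULL

#' @rdname accessors
setMethod("sourceId", "ProteomeSet", function(x) x@sourceId)

#' @rdname accessors
setMethod("alleleNames", "AllelePanel", function(x) x@alleleNames)

#' @rdname accessors
setMethod("alleleNames", "BinderRepertoire", function(x) x@alleleNames)

#' @rdname accessors
setMethod("groupLabels", "AllelePanel",
          function(x) setNames(x@groupLabels, x@alleleNames))

#' @rdname accessors
setMethod("groupLabels", "BinderRepertoire",
          function(x) setNames(x@groupLabels, x@alleleNames))

#' @rdname accessors
setMethod("groupLabels", "DensityTable", function(x) x@groupLabels)

#' @rdname accessors
setMethod("virusIds", "BinderRepertoire", function(x) x@virusIds)

#' @rdname accessors
setMethod("binderSet", "BinderRepertoire", function(x, allele, virus) {
  if (!allele %in% x@alleleNames) stop("unknown allele: ", allele)
  if (!virus %in% x@virusIds) stop("unknown virus: ", virus)
  x@sets[[allele]][[virus]]
})

#' @rdname accessors
setMethod("totalProducts", "BinderRepertoire", function(x) x@totalProducts)

#' @rdname accessors
setMethod("totalProducts", "DensityTable", function(x) x@totalProducts)

#' @rdname accessors
setMethod("densities", "DensityTable", function(x) x@densities)

#' @describeIn accessors Number of records in a ProteomeSet.
setMethod("length", "ProteomeSet", function(x) length(x@aa))

#' @describeIn accessors Number of alleles in a panel.
setMethod("length", "AllelePanel", function(x) length(x@alleleNames))

setMethod("show", "ProteomeSet", function(object) {
  cat("ProteomeSet '", object@sourceId, "': ", length(object@aa),
      " protein(s), total length ", sum(Biostrings::width(object@aa)),
      " aa\n", sep = "")
  nm <- sum(vapply(object@mask, length, 0L))
  if (nm > 0L) cat("  ", nm, " masked position(s)\n", sep = "")
})

setMethod("show", "AllelePanel", function(object) {
  cat("AllelePanel with ", length(object@alleleNames), " allele(s) in ",
      length(unique(object@groupLabels)), " group(s)\n", sep = "")
  tab <- table(object@groupLabels)
  for (g in names(tab))
    cat("  ", g, ": ", tab[[g]], "\n", sep = "")
})

setMethod("show", "SyntheticAlleleModel", function(object) {
  cat("SyntheticAlleleModel '", object@alleleName, "' (supertype ",
      object@supertypeId, ")\n", sep = "")
  cat("  P2 anchor:    ", names(which.max(object@anchorP2)),
      " (", round(max(object@anchorP2), 2), ")\n", sep = "")
  cat("  C-term anchor:", names(which.max(object@anchorC)),
      " (", round(max(object@anchorC), 2), ")\n", sep = " ")
  cat("  noiseScale:   ", object@noiseScale, "\n", sep = "")
})

setMethod("show", "RankReference", function(object) {
  cat("RankReference for '", object@alleleName, "': pool of ",
      length(object@scores), " scores (",
      paste(sprintf("%s x len %s", object@perLengthCounts,
                    names(object@perLengthCounts)), collapse = ", "),
      ")\n", sep = "")
})

setMethod("show", "BinderRepertoire", function(object) {
  cat("BinderRepertoire: ", length(object@alleleNames), " allele(s) x ",
      length(object@virusIds), " virus(es), rank threshold ",
      object@threshold, "%\n", sep = "")
  sizes <- unlist(lapply(object@sets, vapply, length, 0L))
  cat("  binder set sizes: median ", stats::median(sizes), ", range [",
      min(sizes), ", ", max(sizes), "]\n", sep = "")
})

setMethod("show", "DensityTable", function(object) {
  cat("DensityTable: ", nrow(object@densities), " virus(es) x ",
      ncol(object@densities), " allele(s), threshold ",
      object@threshold, "%\n", sep = "")
  cat("  density range [", round(min(object@densities), 3), ", ",
      round(max(object@densities), 3), "]\n", sep = "")
})
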