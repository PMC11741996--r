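#' Score peptides with a binding model
#'
#' The binding-backend contract: given a model and a character vector of
#' peptides, return one real-valued binding score per peptide, higher
#' meaning stronger predicted binding. Implementations must be
#' deterministic: the same (model, peptide) pair always yields the same
#' score.
#'
#' @param model A binding-model object.
#' @param peptides Character vector of peptides over the standard 20-letter
#'   alphabet, lengths within the model's supported range.
#' @param ... Further arguments for methods.
#' @return Numeric vector of scores, parallel to \code{peptides}.
#' @seealso [syntheticAlleleModel()] for the built-in model.
#' @export
setGeneric("bindingScore", function(model, peptides, ...)
  standardGeneric("bindingScore"))

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setGeneric("alleleNames", function(x) standardGeneric("alleleNames"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("virusIds", function(x) standardGeneric("virusIds"))

#' @rdname accessors
#' @export
setGeneric("binderSet", function(x, allele, virus) standardGeneric("binderSet"))

#' @rdname accessors
#' @export
setGeneric("totalProducts", function(x) standardGeneric("totalProducts"))

#' @rdname accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))
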