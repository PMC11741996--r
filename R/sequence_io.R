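NONSTANDARD_AA <- c("X", "B", "Z", "J", "U", "O", "*")

#' Construct a ProteomeSet from sequences
#'
#' @param sourceId Single string identifying the source.
#' @param residues Named character vector of amino-acid sequences (names are
#'   record ids).
#' @param description Optional character vector of descriptions.
#' @param hostTags Optional character vector of host annotations.
#' @param policy How to treat nonstandard residues (X, B, Z, J, U, O, *):
#'   \code{"drop_nonstandard_peptides"} masks their positions so digestion
#'   skips any window overlapping them; \code{"reject"} raises an error.
#' @return A \linkS4class{ProteomeSet}.
#' @examples
#' p <- proteomeSet("v1", c(p1 = "MKVLAAGHIKLM"))
#' length(p)
#' @export
proteomeSet <- function(sourceId, residues, description = NULL,
                        hostTags = character(),
                        policy = c("drop_nonstandard_peptides", "reject")) {
  policy <- match.arg(policy)
  if (is.null(names(residues)) || any(!nzchar(names(residues))))
    stop("residues must be a named character vector (names are record ids)")
  if (is.null(description)) description <- rep("", length(residues))
  san <- lapply(residues, sanitizeResidues, policy = policy)
  seqs <- vapply(san, `[[`, "", "residues")
  masks <- lapply(san, `[[`, "mask")
  new("ProteomeSet",
      sourceId = as.character(sourceId),
      aa = Biostrings::AAStringSet(seqs),
      description = unname(as.character(description)),
      hostTags = as.character(hostTags),
      mask = unname(masks))
}

#' Validate residues and mask nonstandard positions
#'
#' Checks a sequence against the 20-letter standard alphabet. Under the
#' \code{drop_nonstandard_peptides} policy, positions holding X, B, Z, J, U,
#' O or * are recorded in a mask (so that digestion later excludes every
#' window overlapping them); under \code{reject} any such letter is an
#' error. Letters outside both sets are always an error.
#'
#' @param residues Single sequence string (upper-cased internally).
#' @param policy \code{"drop_nonstandard_peptides"} or \code{"reject"}.
#' @return List with \code{residues} (upper-cased, unmodified otherwise) and
#'   \code{mask} (integer positions of nonstandard residues).
#' @examples
#' sanitizeResidues("MKXV")$mask  # 3
#' @export
sanitizeResidues <- function(residues,
                             policy = c("drop_nonstandard_peptides", "reject")) {
  policy <- match.arg(policy)
  stopifnot(length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("empty sequence")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c(AA_STANDARD, NONSTANDARD_AA))
  if (any(bad))
    stop("invalid residue letter(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  nonstd <- which(chars %in% NONSTANDARD_AA)
  if (length(nonstd) && policy == "reject")
    stop("nonstandard residue(s) ",
         paste(unique(chars[nonstd]), collapse = ", "),
         " at position(s) ", paste(nonstd, collapse = ", "))
  list(residues = residues, mask = as.integer(nonstd))
}

#' Read a protein FASTA file into a ProteomeSet
#'
#' The header up to the first whitespace becomes the record id; the
#' remainder is kept as the description. Line wrapping is ignored.
#' Duplicate ids within one file and empty files are errors.
#'
#' @param path FASTA file path.
#' @param sourceId Source identifier; defaults to the file name without
#'   extension.
#' @param hostTags Optional host annotations.
#' @inheritParams proteomeSet
#' @return A \linkS4class{ProteomeSet}.
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path, sourceId = sub("\\.[^.]*$", "", basename(path)),
                      hostTags = character(),
                      policy = c("drop_nonstandard_peptides", "reject")) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  proteomeSet(sourceId, setNames(as.character(aa), ids),
              description = desc, hostTags = hostTags, policy = policy)
}

#' Write a ProteomeSet to a FASTA file
#'
#' Output is wrapped at 60 columns. Reading the file back with
#' [readFasta()] reproduces ids, descriptions and residues exactly.
#'
#' @param proteome A \linkS4class{ProteomeSet}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(proteome, path) {
  stopifnot(is(proteome, "ProteomeSet"))
  aa <- proteome@aa
  hdr <- ifelse(nzchar(proteome@description),
                paste(names(aa), proteome@description), names(aa))
  out <- setNames(aa, hdr)
  Biostrings::writeXStringSet(out, path, width = 60L)
  invisible(path)
}

#' Read an allele panel definition
#'
#' The panel file is tab-separated with columns \code{allele_name},
#' \code{group_label} and \code{model_spec}; lines starting with \code{#}
#' are comments. \code{model_spec} holds the JSON serialization of a
#' \linkS4class{SyntheticAlleleModel} (as written by [writeAllelePanel()]).
#'
#' @param path Panel TSV path.
#' @return An \linkS4class{AllelePanel}.
#' @export
readAllelePanel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, comment.char = "#", quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("allele_name", "group_label", "model_spec")
  if (!all(need %in% names(df)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  models <- lapply(df$model_spec, modelFromJSON)
  new("AllelePanel",
      alleleNames = df$allele_name,
      groupLabels = df$group_label,
      models = setNames(models, df$allele_name))
}

#' Write an allele panel definition
#'
#' @param panel An \linkS4class{AllelePanel} of synthetic models.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeAllelePanel <- function(panel, path) {
  stopifnot(is(panel, "AllelePanel"))
  spec <- vapply(panel@models, modelToJSON, "")
  df <- data.frame(allele_name = panel@alleleNames,
                   group_label = panel@groupLabels,
                   model_spec = unname(spec),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mhcRepertoire allele panel", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

modelToJSON <- function(model) {
  stopifnot(is(model, "SyntheticAlleleModel"))
  jsonlite::toJSON(list(
    alleleName = model@alleleName,
    supertypeId = model@supertypeId,
    anchorP2 = as.list(model@anchorP2),
    anchorC = as.list(model@anchorC),
    background = as.list(model@background),
    noiseScale = model@noiseScale,
    hashKey = model@hashKey
  ), auto_unbox = TRUE, digits = NA)
}

modelFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  new("SyntheticAlleleModel",
      alleleName = x$alleleName,
      supertypeId = x$supertypeId,
      anchorP2 = unlist(x$anchorP2)[AA_STANDARD],
      anchorC = unlist(x$anchorC)[AA_STANDARD],
      background = unlist(x$background)[AA_STANDARD],
      noiseScale = x$noiseScale,
      hashKey = matrix(as.numeric(x$hashKey), 20L, 12L,
                       dimnames = list(AA_STANDARD, NULL)))
}
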