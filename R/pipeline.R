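#' Default pipeline configuration
#'
#' Returns the run configuration with every analysis parameter at its
#' standard value: viral digestion lengths 8--11, reference digestion
#' lengths 8--12 with 25,000 peptides per length, 1% rank threshold, 95%
#' collapse threshold, 1000 bootstrap replicates on 20% of the viruses,
#' and the sweep-candidate filter at density < 1 for all focal alleles and
#' > 2 for at least 10 others.
#'
#' @param virusDir Directory of per-virus protein FASTA files.
#' @param referenceFasta Reference proteome FASTA for rank calibration.
#' @param panelFile Allele panel TSV.
#' @param outputDir Output directory (created if needed).
#' @param selfFasta Optional host self-proteome FASTA.
#' @param ... Overrides for any configuration entry.
#' @return Named list of configuration values.
#' @export
defaultRunConfig <- function(virusDir, referenceFasta, panelFile, outputDir,
                             selfFasta = NULL, ...) {
  cfg <- list(
    virusDir = virusDir, referenceFasta = referenceFasta,
    panelFile = panelFile, outputDir = outputDir, selfFasta = selfFasta,
    viralLengths = 8:11, referenceLengths = 8:12, perLengthCount = 25000L,
    rankThreshold = 1.0, collapseThreshold = 95.0,
    bootstrapReps = 1000L, bootstrapFraction = 0.2,
    filterLow = 1.0, filterHigh = 2.0, filterMinCount = 10L,
    focalGroup = NULL, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$rankThreshold > 0, cfg$rankThreshold <= 100,
            cfg$collapseThreshold > 0, cfg$collapseThreshold <= 100,
            cfg$bootstrapFraction > 0, cfg$bootstrapFraction <= 1)
  cfg
}

PIPELINE_STAGES <- c("collapse", "rankref", "repertoire", "cluster",
                     "density", "filter", "selfpres")

stageRequires <- list(
  collapse = character(), rankref = character(),
  repertoire = c("collapse", "rankref"),
  cluster = "repertoire", density = "repertoire",
  filter = "density", selfpres = "rankref")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' as plain text (TSV, FASTA, Newick) under the configured output
#' directory, plus a JSON manifest recording the configuration, seed and
#' per-stage counts. Stage dependencies are validated before any work, and
#' rerunning with an identical configuration and seed reproduces identical
#' outputs.
#'
#' @param config Configuration list from [defaultRunConfig()].
#' @param stages Subset of \code{c("collapse", "rankref", "repertoire",
#'   "cluster", "density", "filter", "selfpres")}; default all applicable.
#' @param verbose Print one progress line per stage; default TRUE.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, stages = PIPELINE_STAGES, verbose = TRUE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (is.null(config$selfFasta)) stages <- setdiff(stages, "selfpres")
  for (s in stages) {
    miss <- setdiff(stageRequires[[s]], stages)
    if (length(miss))
      stop("stage '", s, "' requires stage(s) ", paste(miss, collapse = ", "),
           " in the same run")
  }
  for (f in c(config$referenceFasta, config$panelFile))
    if (!file.exists(f)) stop("missing input: ", f)
  if (!dir.exists(config$virusDir)) stop("missing input: ", config$virusDir)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

  log1 <- function(...) if (verbose) message(sprintf(...))
  out <- function(f) file.path(config$outputDir, f)
  manifest <- list(config = config[setdiff(names(config), "outputDir")],
                   stages = list())
  state <- new.env(parent = emptyenv())

  panel <- readAllelePanel(config$panelFile)
  vfiles <- sort(list.files(config$virusDir, pattern = "\\.(fa|fasta)$",
                            full.names = TRUE))
  if (!length(vfiles)) stop("no FASTA files in ", config$virusDir)
  viruses <- lapply(vfiles, readFasta)

  if ("collapse" %in% stages) {
    idm <- identityMatrix(viruses)
    cl <- collapseViruses(viruses, config$collapseThreshold, idm = idm)
    writeDistanceMatrix(idm, out("identity_matrix.tsv"))
    write.table(data.frame(member_id = names(cl$clusterMap),
                           representative_id = unname(cl$clusterMap)),
                out("cluster_map.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$viruses <- cl$retained
    manifest$stages$collapse <- list(input = length(viruses),
                                     retained = length(cl$retained))
    log1("collapse: %d -> %d viruses", length(viruses), length(cl$retained))
  } else {
    state$viruses <- viruses
  }

  if ("rankref" %in% stages) {
    refProteome <- readFasta(config$referenceFasta)
    pools <- referencePeptidePools(refProteome, config$referenceLengths)
    refs <- list()
    for (a in panel@alleleNames) {
      refs[[a]] <- buildRankReference(
        panel@models[[a]], refProteome,
        lengths = config$referenceLengths,
        perLengthCount = config$perLengthCount,
        seed = config$seed, pools = pools)
      writeRankReference(refs[[a]], out(sprintf("rankref_%s.txt", a)))
    }
    state$references <- refs
    manifest$stages$rankref <- list(alleles = length(refs),
                                    poolSize = length(refs[[1L]]@scores))
    log1("rankref: %d alleles, pool %d", length(refs),
         length(refs[[1L]]@scores))
  }

  if ("repertoire" %in% stages) {
    rep <- buildRepertoire(panel, state$viruses, state$references,
                           lengths = config$viralLengths,
                           threshold = config$rankThreshold)
    repertoireTable(rep, out("repertoire.tsv"))
    state$repertoire <- rep
    manifest$stages$repertoire <- list(
      alleles = length(rep@alleleNames), viruses = length(rep@virusIds),
      binders = sum(unlist(lapply(rep@sets, vapply, length, 0L))))
    log1("repertoire: %d x %d, %d binder entries",
         length(rep@alleleNames), length(rep@virusIds),
         manifest$stages$repertoire$binders)
  }

  if ("cluster" %in% stages) {
    D <- functionalDistanceMatrix(state$repertoire)
    tree <- upgmaTree(D)
    bs <- bootstrapSupports(state$repertoire, nReps = config$bootstrapReps,
                            fraction = config$bootstrapFraction,
                            seed = config$seed)
    cons <- extendedMajorityConsensus(bs$trees)
    writeDistanceMatrix(D, out("functional_distance.tsv"))
    writeNewick(tree, out("upgma.nwk"))
    writeNewick(cons, out("consensus.nwk"))
    state$tree <- tree
    manifest$stages$cluster <- list(alleles = nrow(D),
                                    bootstrapReps = config$bootstrapReps)
    log1("cluster: UPGMA on %d alleles, %d bootstrap reps",
         nrow(D), config$bootstrapReps)
  }

  if ("density" %in% stages) {
    dt <- densityTable(state$repertoire)
    writeDensityTable(dt, out("density.tsv"))
    cmp <- groupCompare(dt)
    write.table(cmp, out("group_comparisons.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$densityTable <- dt
    manifest$stages$density <- list(viruses = nrow(dt@densities),
                                    alleles = ncol(dt@densities),
                                    comparisons = nrow(cmp))
    log1("density: %d x %d table, %d group comparisons",
         nrow(dt@densities), ncol(dt@densities), nrow(cmp))
  }

  if ("filter" %in% stages) {
    focal <- config$focalGroup %||% names(sort(table(panel@groupLabels)))[1L]
    gl <- groupLabels(state$densityTable)
    hits <- sweepCandidateFilter(
      state$densityTable,
      focalAlleles = names(gl)[gl == focal],
      otherAlleles = names(gl)[gl != focal],
      low = config$filterLow, high = config$filterHigh,
      minCount = config$filterMinCount)
    writeLines(hits, out("sweep_candidates.txt"))
    manifest$stages$filter <- list(focalGroup = focal, candidates = length(hits))
    log1("filter: %d sweep-candidate virus(es) [focal group %s]",
         length(hits), focal)
  }

  if ("selfpres" %in% stages) {
    self <- readFasta(config$selfFasta)
    tabs <- lapply(panel@alleleNames, function(a) {
      sp <- selfPresentation(self, panel@models[[a]], state$references[[a]],
                             lengths = config$viralLengths,
                             threshold = config$rankThreshold)
      cbind(allele = a, sp)
    })
    sp <- do.call(rbind, tabs)
    write.table(sp, out("self_presentation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$selfpres <- list(proteins = length(self),
                                     alleles = length(panel@alleleNames))
    log1("selfpres: %d proteins x %d alleles", length(self),
         length(panel@alleleNames))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(state = as.list(state), manifest = manifest))
}

#' Materialize a complete synthetic workspace
#'
#' Generates a reference proteome, a virus set with planted family
#' structure, an optional self-proteome and an allele panel with planted
#' supertypes, and writes them in the pipeline's input layout
#' (\code{reference.fasta}, \code{viruses/*.fasta}, \code{self.fasta},
#' \code{panel.tsv}).
#'
#' @param dir Workspace directory (created if needed).
#' @param seed Master seed; generator seeds are derived from it.
#' @param nReferenceProteins,referenceLengthRange Reference proteome size
#'   and length range.
#' @param nFamilies,membersPerFamily,proteinsPerVirus,proteinLength,
#'   mutationRate Virus set structure (see [generateVirusSet()]).
#' @param virusAaFreqs Residue background of the virus set; default
#'   uniform.
#' @param nSupertypes,allelesPerSupertype,anchorDivergence,noiseScale
#'   Allele panel structure (see [generateAllelePanel()]).
#' @param nSelfProteins Self-proteome size (0 to skip).
#' @return Invisibly, a list with the generated objects, their truth labels
#'   and the written paths.
#' @export
simulateWorkspace <- function(dir, seed = 1L,
                              nReferenceProteins = 5000L,
                              referenceLengthRange = c(100L, 600L),
                              nFamilies = 10L, membersPerFamily = 5L,
                              proteinsPerVirus = 10L, proteinLength = 300L,
                              mutationRate = 0.02,
                              virusAaFreqs = uniformAaFreqs(),
                              nSupertypes = 4L, allelesPerSupertype = 6L,
                              anchorDivergence = 0.3, noiseScale = 0.5,
                              nSelfProteins = 0L) {
  dir.create(file.path(dir, "viruses"), showWarnings = FALSE, recursive = TRUE)
  ref <- generateReferenceProteome(nReferenceProteins, referenceLengthRange,
                                   seed = seed)
  vs <- generateVirusSet(nFamilies, membersPerFamily, proteinsPerVirus,
                         proteinLength, mutationRate,
                         aaFreqs = virusAaFreqs, seed = seed + 1L)
  ap <- generateAllelePanel(nSupertypes, allelesPerSupertype,
                            anchorDivergence = anchorDivergence,
                            noiseScale = noiseScale, seed = seed + 2L)
  paths <- list(reference = file.path(dir, "reference.fasta"),
                panel = file.path(dir, "panel.tsv"),
                virusDir = file.path(dir, "viruses"))
  writeFasta(ref, paths$reference)
  for (v in vs$viruses)
    writeFasta(v, file.path(paths$virusDir, paste0(sourceId(v), ".fasta")))
  writeAllelePanel(ap$panel, paths$panel)
  self <- NULL
  if (nSelfProteins > 0L) {
    self <- generateReferenceProteome(nSelfProteins, referenceLengthRange,
                                      seed = seed + 3L, sourceId = "self")
    paths$self <- file.path(dir, "self.fasta")
    writeFasta(self, paths$self)
  }
  invisible(list(reference = ref, viruses = vs$viruses,
                 familyLabels = vs$familyLabels, panel = ap$panel,
                 supertypeLabels = ap$supertypeLabels, self = self,
                 paths = paths))
}
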