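#' Uniform amino-acid background frequencies
#'
#' @return Named numeric vector over the 20 standard residues summing to 1.
#' @export
uniformAaFreqs <- function() setNames(rep(1 / 20, 20L), AA_STANDARD)

#' Residue frequencies with selected residues depleted
#'
#' Real proteomes are not uniform: viral proteins in particular are poor in
#' tryptophan and cysteine. This helper builds a background in which the
#' given residues occur at a fraction of their uniform frequency, for
#' generating virus sets whose composition differs from the rank-reference
#' background.
#'
#' @param residues Residues to deplete; default W and C.
#' @param factor Multiplier on their uniform frequency, in [0, 1); default
#'   0.2.
#' @return Named numeric frequency vector summing to 1.
#' @export
depletedResidueFreqs <- function(residues = c("W", "C"), factor = 0.2) {
  stopifnot(all(residues %in% AA_STANDARD), factor >= 0, factor < 1)
  f <- setNames(rep(1, 20L), AA_STANDARD)
  f[residues] <- factor
  f / sum(f)
}

randomProteins <- function(n, lengthRange, aaFreqs) {
  cand <- seq(lengthRange[1L], lengthRange[2L])
  lens <- cand[sample.int(length(cand), n, replace = TRUE)]
  chars <- sample(AA_STANDARD, sum(lens), replace = TRUE, prob = aaFreqs)
  big <- paste(chars, collapse = "")
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

#' Generate a random reference proteome
#'
#' I.i.d. sequences from the background residue distribution with lengths
#' uniform over the configured range, emulating a random draw of database
#' proteins for rank-reference construction. At the default 5000 proteins
#' of 100--600 residues, every length 8--12 yields far more than 25,000
#' unique digestion products.
#'
#' @param nProteins Number of proteins; default 5000.
#' @param lengthRange Length range (uniform); default c(100, 600).
#' @param aaFreqs Residue background; default uniform.
#' @param seed Integer seed.
#' @param sourceId Source id of the resulting set; default "reference".
#' @return A \linkS4class{ProteomeSet}.
#' @export
generateReferenceProteome <- function(nProteins = 5000L,
                                      lengthRange = c(100L, 600L),
                                      aaFreqs = uniformAaFreqs(),
                                      seed = 1L, sourceId = "reference") {
  stopifnot(nProteins >= 1L, lengthRange[1L] >= 1L,
            lengthRange[2L] >= lengthRange[1L])
  seqs <- withSeed(seed, randomProteins(nProteins, lengthRange, aaFreqs))
  names(seqs) <- sprintf("ref%05d", seq_len(nProteins))
  proteomeSet(sourceId, seqs,
              description = rep("synthetic reference protein", nProteins))
}

mutateSequence <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    # substitute with a uniformly chosen different residue, so expected
    # identity to the ancestor is exactly 1 - rate
    repl <- vapply(chars[hit], function(ch)
      sample(setdiff(AA_STANDARD, ch), 1L), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Generate a virus set with planted family structure
#'
#' Each family is seeded by an independent random ancestor proteome; family
#' members are derived from the ancestor by substituting each site with the
#' given per-site probability (to a uniformly chosen different residue, so
#' member-to-ancestor identity is controlled analytically). Family labels
#' are returned as ground truth for redundancy-collapsing tests.
#'
#' @param nFamilies Number of virus families; default 10.
#' @param membersPerFamily Viruses per family; default 5.
#' @param proteinsPerVirus Proteins per virus; default 10.
#' @param proteinLength Protein length in residues; default 300.
#' @param mutationRate Per-site substitution probability within a family;
#'   default 0.02.
#' @param aaFreqs Residue background; default uniform.
#' @param seed Integer seed.
#' @return List with \code{viruses} (list of \linkS4class{ProteomeSet}) and
#'   \code{familyLabels} (named character: virus id -> family id).
#' @export
generateVirusSet <- function(nFamilies = 10L, membersPerFamily = 5L,
                             proteinsPerVirus = 10L, proteinLength = 300L,
                             mutationRate = 0.02,
                             aaFreqs = uniformAaFreqs(), seed = 1L) {
  stopifnot(nFamilies >= 1L, membersPerFamily >= 1L, proteinsPerVirus >= 1L,
            mutationRate >= 0, mutationRate <= 1)
  withSeed(seed, {
    viruses <- list()
    labels <- character()
    for (f in seq_len(nFamilies)) {
      anc <- randomProteins(proteinsPerVirus,
                            c(proteinLength, proteinLength), aaFreqs)
      for (m in seq_len(membersPerFamily)) {
        vid <- sprintf("fam%02d_v%02d", f, m)
        seqs <- vapply(anc, mutateSequence, "", rate = mutationRate)
        names(seqs) <- sprintf("%s_p%02d", vid, seq_along(seqs))
        viruses[[vid]] <- proteomeSet(vid, seqs)
        labels[vid] <- sprintf("fam%02d", f)
      }
    }
    list(viruses = viruses, familyLabels = labels)
  })
}

#' Generate an allele panel with planted supertype structure
#'
#' Each supertype gets an anchor archetype: one preferred residue at P2 and
#' one at the C-terminus (drawn so that no two supertypes share a preferred
#' residue at either position), carrying weight \code{anchorWeight} against
#' a zero background. Each allele is the archetype plus an independent
#' seeded Gaussian perturbation of magnitude \code{anchorDivergence} on all
#' weight tables. The deterministic noise key is shared within a supertype,
#' so alleles with zero divergence have literally identical models.
#'
#' @param nSupertypes Number of supertypes (<= 10, so both anchor positions
#'   can have distinct preferred residues); default 4.
#' @param allelesPerSupertype Alleles per supertype; default 6.
#' @param anchorWeight Weight of each preferred anchor residue; default 6.
#' @param anchorDivergence SD of the per-allele weight perturbation;
#'   default 0.3.
#' @param noiseScale Deterministic score perturbation magnitude; default
#'   0.5.
#' @param seed Integer seed.
#' @return List with \code{panel} (an \linkS4class{AllelePanel}; group
#'   labels are the supertype ids) and \code{supertypeLabels} (named
#'   character: allele -> supertype).
#' @export
generateAllelePanel <- function(nSupertypes = 4L, allelesPerSupertype = 6L,
                                anchorWeight = 6, anchorDivergence = 0.3,
                                noiseScale = 0.5, seed = 1L) {
  if (nSupertypes > 20L)
    stop("cannot assign distinct anchor residues to more than 20 supertypes")
  if (2L * nSupertypes > 20L)
    stop("at most 10 supertypes are supported (distinct residues at both anchor positions)")
  withSeed(seed, {
    permP2 <- sample(AA_STANDARD)
    permC <- sample(AA_STANDARD)
    names <- character(); groups <- character(); models <- list()
    for (st in seq_len(nSupertypes)) {
      stId <- sprintf("S%02d", st)
      archP2 <- setNames(numeric(20L), AA_STANDARD)
      archP2[permP2[st]] <- anchorWeight
      archC <- setNames(numeric(20L), AA_STANDARD)
      archC[permC[st]] <- anchorWeight
      archBg <- setNames(numeric(20L), AA_STANDARD)
      stSeed <- sample.int(2^30, 1L)
      for (a in seq_len(allelesPerSupertype)) {
        an <- sprintf("%s_A%02d", stId, a)
        pert <- function(w) w + anchorDivergence * stats::rnorm(20L)
        models[[an]] <- syntheticAlleleModel(
          an,
          anchorP2 = pert(archP2), anchorC = pert(archC),
          background = pert(archBg),
          noiseScale = noiseScale, seed = stSeed, supertypeId = stId)
        names <- c(names, an); groups <- c(groups, stId)
      }
    }
    list(panel = new("AllelePanel", alleleNames = names,
                     groupLabels = groups,
                     models = setNames(models, names)),
         supertypeLabels = setNames(groups, names))
  })
}

#' Sharpen one supertype towards virus-depleted anchor residues
#'
#' Emulates a supertype with systematically low epitope densities. The
#' focal supertype's anchor preferences are interpolated towards residues
#' that the virus set under-represents (see [depletedResidueFreqs()]): with
#' \code{sharpening = 0} the panel is returned unchanged; at strong
#' sharpening the focal alleles' favoured peptides become rare among viral
#' digestion products while their percentile-rank calibration (built on the
#' non-depleted reference background) is unaffected, so their observed
#' binder counts fall below the chance expectation.
#'
#' Note that sharpening by itself cannot lower a density: when viral and
#' reference peptides are exchangeable, self-calibrated ranks pin the
#' binder fraction at the threshold for any scoring function. The effect
#' requires the compositional mismatch between viruses and reference that
#' this helper targets.
#'
#' @param panel An \linkS4class{AllelePanel} from [generateAllelePanel()].
#' @param focalSupertype Group label of the supertype to modify.
#' @param sharpening Interpolation weight in [0, 1]; default 1.
#' @param rareResidues Length-2 character: target P2 and C-terminal anchor
#'   residues, expected to be depleted in the virus set; default W and C.
#' @param sharpWeight Anchor weight at full sharpening; default 9.
#' @return The modified \linkS4class{AllelePanel}.
#' @export
makeLowDensitySupertype <- function(panel, focalSupertype, sharpening = 1,
                                    rareResidues = c("W", "C"),
                                    sharpWeight = 9) {
  stopifnot(is(panel, "AllelePanel"), sharpening >= 0, sharpening <= 1,
            length(rareResidues) == 2L, all(rareResidues %in% AA_STANDARD))
  if (!focalSupertype %in% panel@groupLabels)
    stop("unknown supertype: ", focalSupertype)
  targetP2 <- setNames(numeric(20L), AA_STANDARD)
  targetP2[rareResidues[1L]] <- sharpWeight
  targetC <- setNames(numeric(20L), AA_STANDARD)
  targetC[rareResidues[2L]] <- sharpWeight
  for (i in which(panel@groupLabels == focalSupertype)) {
    m <- panel@models[[i]]
    m@anchorP2 <- (1 - sharpening) * m@anchorP2 + sharpening * targetP2
    m@anchorC <- (1 - sharpening) * m@anchorC + sharpening * targetC
    panel@models[[i]] <- m
  }
  panel
}

#' Random peptides from a background distribution
#'
#' Fresh i.i.d. peptides with lengths drawn uniformly from \code{lengths}
#' and residues from \code{aaFreqs} — the query distribution matching the
#' digestion products of a generated reference proteome, used for
#' calibration-null checks.
#'
#' @param n Number of peptides.
#' @param lengths Candidate lengths; default 8:12.
#' @param aaFreqs Residue background; default uniform.
#' @param seed Integer seed.
#' @return Character vector of peptides.
#' @export
randomPeptides <- function(n, lengths = 8:12, aaFreqs = uniformAaFreqs(),
                           seed = 1L) {
  withSeed(seed, {
    lens <- sample(as.integer(lengths), n, replace = TRUE)
    chars <- sample(AA_STANDARD, sum(lens), replace = TRUE, prob = aaFreqs)
    big <- paste(chars, collapse = "")
    ends <- cumsum(lens)
    substring(big, ends - lens + 1L, ends)
  })
}
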