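## Ground-truthed synthetic data: genome collections with planted TFs
## (family labels, per-route detectability, genomic context, EC and
## virulence labels), evidence tables consistent with the truth by
## construction, curated-catalog emulation, and labeled census panels for
## scaling-model recovery. All randomness flows from one seeded stream per
## bundle; identical config + seed gives identical output.

## Ten focal TF families (classic prokaryotic regulator families) with
## collection-wide frequencies proportional to their predicted genome-wide
## abundances, scaled so the ten cover ~60% of all TFs; the remainder is
## spread over minor families.
.FOCAL_FAMILY_ABUNDANCE <- c(
  PF00440 = 23556, PF00126 = 21219, PF12833 = 15987, PF00486 = 14418,
  PF00392 = 13086, PF00196 = 12782, PF01381 = 11931, PF02954 = 7103,
  PF00356 = 7063, PF01047 = 5841)

.MINOR_FAMILIES <- c("PF04397", sprintf("PF99%03d", 1:11))

#' Default TF family frequencies for synthetic genomes
#'
#' The ten focal families carry 60 percent of the TF mass in proportion to
#' their relative genome-wide abundances; the remaining 40 percent is
#' spread over twelve minor families (including the LytTR domain PF04397).
#'
#' @return named numeric vector summing to 1.
#' @export
defaultFamilyFreqs <- function() {
  major <- 0.60 * .FOCAL_FAMILY_ABUNDANCE / sum(.FOCAL_FAMILY_ABUNDANCE)
  minor <- rep(0.40 / length(.MINOR_FAMILIES), length(.MINOR_FAMILIES))
  names(minor) <- .MINOR_FAMILIES
  c(major, minor)
}

#' Default TF-associated PFAM accession list
#'
#' The synthetic stand-in for the curated list of 111 TF-associated PFAM
#' domain families: the generator's family accessions padded with unused
#' accessions to 111 entries.
#'
#' @return character vector of 111 accessions.
#' @export
defaultTfPfams <- function() {
  fams <- names(defaultFamilyFreqs())
  pad <- sprintf("PF98%03d", seq_len(111L - length(fams)))
  c(fams, pad)
}

#' Generator configuration
#'
#' Assembles and validates the configuration driving
#' [generateCollection()]. Defaults encode the study conditions the
#' analysis assumes: genome sizes log-uniform over 500–12000 ORFs, TF
#' counts following the power law \eqn{y = 0.0007\,x^{1.5283}} with
#' log-normal noise (sigma 0.2), short divergent intergenic gaps
#' (geometric, mean 60 bp), compact operon spacings well below the TU gap
#' threshold, and evidence tables with mandatory near-threshold decoys.
#'
#' @param n_genomes number of genomes.
#' @param orf_range (min, max) ORF counts, sampled log-uniformly.
#' @param scaling_a,scaling_b power-law prefactor and exponent for TF
#'   counts versus ORF counts.
#' @param noise_sigma log-scale standard deviation of multiplicative noise
#'   on TF counts.
#' @param family_freqs named TF family frequencies (must sum to at most 1;
#'   any remainder is spread over minor families).
#' @param divergent_frac,in_tu_frac fractions of TFs planted divergent and
#'   inside multi-gene transcription units; the rest are isolated.
#' @param operon_geom_p geometric parameter for operon run lengths
#'   (run length = 2 + Geom(p)).
#' @param intra_tu_gap_mean mean intra-operon intergenic gap in bp (gaps
#'   drawn uniformly in 5–40, comfortably under the 50 bp TU threshold).
#' @param divergent_gap_mean mean divergent intergenic gap in bp
#'   (geometric).
#' @param filler_gap_min minimum gap separating unrelated genes (bp),
#'   comfortably above the TU threshold.
#' @param domain_detectable_frac,ortho_detectable_frac probability that a
#'   planted TF is detectable by the domain route / the orthology route.
#' @param ec_class_freqs frequencies of the six EC classes among
#'   enzyme-associated proteins (transferases most abundant).
#' @param enzyme_frac fraction of proteins that are enzyme-associated.
#' @param virulence_frac fraction of proteins orthologous to the virulence
#'   reference.
#' @param n_catalog curated-catalog size used as orthology seed.
#' @param n_vf_proteins size of the virulence reference set.
#' @param gene_length fixed gene length in bp.
#' @param seed mandatory integer seed.
#' @return validated configuration list of class \code{generator_config}.
#' @export
generatorConfig <- function(n_genomes = 50L,
                            orf_range = c(500L, 12000L),
                            scaling_a = 7e-4,
                            scaling_b = 1.5283,
                            noise_sigma = 0.2,
                            family_freqs = defaultFamilyFreqs(),
                            divergent_frac = 0.25,
                            in_tu_frac = 0.30,
                            operon_geom_p = 0.5,
                            intra_tu_gap_mean = 20L,
                            divergent_gap_mean = 60L,
                            filler_gap_min = 150L,
                            domain_detectable_frac = 0.9,
                            ortho_detectable_frac = 0.8,
                            ec_class_freqs = c(0.18, 0.35, 0.20, 0.12,
                                               0.08, 0.07),
                            enzyme_frac = 0.12,
                            virulence_frac = 0.10,
                            n_catalog = 668L,
                            n_vf_proteins = 120L,
                            gene_length = 900L,
                            seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory")
  fr <- c(divergent_frac, in_tu_frac, domain_detectable_frac,
          ortho_detectable_frac, enzyme_frac, virulence_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (divergent_frac + in_tu_frac > 1)
    stop("divergent_frac + in_tu_frac must not exceed 1")
  if (sum(family_freqs) > 1 + 1e-9)
    stop("family_freqs must sum to at most 1")
  if (sum(family_freqs) < 1 - 1e-9) {
    pad <- setdiff(.MINOR_FAMILIES, names(family_freqs))
    if (!length(pad)) stop("family_freqs sum below 1 with no room to pad")
    add <- rep((1 - sum(family_freqs)) / length(pad), length(pad))
    names(add) <- pad
    family_freqs <- c(family_freqs, add)
  }
  if (abs(sum(ec_class_freqs) - 1) > 1e-6)
    stop("ec_class_freqs must sum to 1")
  if (orf_range[1L] < 10L || orf_range[2L] < orf_range[1L])
    stop("invalid orf_range")
  structure(list(
    n_genomes = as.integer(n_genomes), orf_range = as.integer(orf_range),
    scaling_a = scaling_a, scaling_b = scaling_b, noise_sigma = noise_sigma,
    family_freqs = family_freqs, divergent_frac = divergent_frac,
    in_tu_frac = in_tu_frac, operon_geom_p = operon_geom_p,
    intra_tu_gap_mean = as.integer(intra_tu_gap_mean),
    divergent_gap_mean = as.integer(divergent_gap_mean),
    filler_gap_min = as.integer(filler_gap_min),
    domain_detectable_frac = domain_detectable_frac,
    ortho_detectable_frac = ortho_detectable_frac,
    ec_class_freqs = ec_class_freqs, enzyme_frac = enzyme_frac,
    virulence_frac = virulence_frac, n_catalog = as.integer(n_catalog),
    n_vf_proteins = as.integer(n_vf_proteins),
    gene_length = as.integer(gene_length), seed = as.integer(seed)),
    class = "generator_config")
}

#' Sample census-level scaling points
#'
#' Draws (ORF count, TF count) pairs under the collection's abundance
#' model: ORF counts log-uniform over \code{orfRange}, TF counts
#' \code{round(a * n^b * exp(eps))} with \code{eps ~ Normal(0, sigma^2)},
#' clipped to \code{[0, n_orfs]}. This is the census-level view of
#' [generateCollection()] and is cheap at large n, which makes it the tool
#' for scaling-law parameter-recovery experiments.
#'
#' @param nGenomes number of genomes.
#' @param orfRange (min, max) ORF counts.
#' @param a,b power-law prefactor and exponent.
#' @param sigma log-scale noise standard deviation.
#' @param seed integer seed (optional; current RNG state used if missing).
#' @return data.frame with columns \code{genome_id}, \code{n_orfs},
#'   \code{n_tfs}.
#' @export
generateScalingPoints <- function(nGenomes, orfRange = c(500L, 12000L),
                                  a = 7e-4, b = 1.5283, sigma = 0.2,
                                  seed = NULL) {
  draw <- function() {
    nOrfs <- round(exp(stats::runif(nGenomes, log(orfRange[1L]),
                                    log(orfRange[2L]))))
    eps <- if (sigma > 0) stats::rnorm(nGenomes, 0, sigma) else 0
    nTfs <- round(a * nOrfs^b * exp(eps))
    nTfs <- pmin(pmax(nTfs, 0L), nOrfs)
    data.frame(genome_id = sprintf("g%04d", seq_len(nGenomes)),
               n_orfs = as.integer(nOrfs), n_tfs = as.integer(nTfs),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

## Catalog generation internals (uses the caller's RNG stream) ---------------

.CATALOG_FAMILY_FREQS <- c(
  PF00440 = 0.098, PF00486 = 0.079, PF00126 = 0.070, PF00392 = 0.055,
  PF00196 = 0.050, PF01381 = 0.048, PF12833 = 0.045, PF01047 = 0.040,
  PF02954 = 0.038, PF00356 = 0.035)

.CATALOG_SPECIES <- c(
  "Escherichia coli K-12", "Bacillus subtilis 168",
  "Corynebacterium glutamicum", "Streptomyces coelicolor",
  "Mycobacterium tuberculosis", "Staphylococcus aureus",
  "Pseudomonas aeruginosa", "Salmonella enterica",
  "Agrobacterium tumefaciens", "Sinorhizobium meliloti",
  "Vibrio cholerae", "Listeria monocytogenes",
  "Sulfolobus solfataricus", "Methanocaldococcus jannaschii")

.genCatalog <- function(n, familyFreqs, roleFreqs, domainCountFreqs,
                        evidenceWeights) {
  fams <- names(familyFreqs)
  if (sum(familyFreqs) < 1 - 1e-9) {
    pad <- setdiff(.MINOR_FAMILIES, fams)
    add <- rep((1 - sum(familyFreqs)) / length(pad), length(pad))
    names(add) <- pad
    familyFreqs <- c(familyFreqs, add)
    fams <- names(familyFreqs)
  }
  fam <- sample(fams, n, replace = TRUE, prob = familyFreqs)
  role <- sample(names(roleFreqs), n, replace = TRUE, prob = roleFreqs)
  nd <- sample(seq_along(domainCountFreqs), n, replace = TRUE,
               prob = domainCountFreqs)
  accessory <- sprintf("PF97%03d", 1:40)
  allPf <- lapply(seq_len(n), function(i) {
    if (nd[i] == 1L) fam[i]
    else c(fam[i], sample(accessory, nd[i] - 1L))
  })
  evCodes <- evidenceCodes()$code
  nev <- sample(1:3, n, replace = TRUE)
  ev <- lapply(nev, function(k)
    sample(evCodes, k, replace = FALSE, prob = evidenceWeights))
  new("TFCatalog", entries = S4Vectors::DataFrame(
    tf_id = sprintf("TF%04d", seq_len(n)),
    species = sample(.CATALOG_SPECIES, n, replace = TRUE),
    family_pfam = fam,
    all_pfams = IRanges::CharacterList(allPf),
    n_domains = nd, role = role,
    evidence = IRanges::CharacterList(ev)))
}

#' Generate a synthetic curated TF catalog
#'
#' Draws catalog entries with configurable family, role, domain-count and
#' evidence-code frequencies. Defaults reflect a literature-curated
#' collection of prokaryotic regulators: families led by TetR/AcrR (9.8
#' percent) and OmpR/PhoB (7.9 percent); roles 29.4 percent repressors,
#' 23.9 percent dual, 18.1 percent activators, 28.6 percent undefined;
#' domain counts dominated by one- (41.77 percent) and two-domain (50.22
#' percent) architectures; one to three evidence codes per entry, weighted
#' by how common each evidence class is in curated collections.
#'
#' @param n catalog size (default 668).
#' @param familyFreqs named family frequencies (sum at most 1; remainder
#'   spread over minor families).
#' @param roleFreqs named role frequencies (must sum to 1 within 1e-6).
#' @param domainCountFreqs frequencies for 1, 2, ... domains (sum 1).
#' @param seed integer seed.
#' @return a [TFCatalog-class] of \code{n} entries.
#' @export
generateCatalog <- function(n = 668L,
                            familyFreqs = .CATALOG_FAMILY_FREQS,
                            roleFreqs = c(repressor = 0.294, dual = 0.239,
                                          activator = 0.181,
                                          undefined = 0.286),
                            domainCountFreqs = c(0.4177, 0.5022, 0.0603,
                                                 0.009, 0.002, 0.004,
                                                 0.0028),
                            seed = 1L) {
  if (abs(sum(roleFreqs) - 1) > 1e-6)
    stop("roleFreqs must sum to 1")
  domainCountFreqs <- domainCountFreqs / sum(domainCountFreqs)
  if (sum(familyFreqs) > 1 + 1e-9)
    stop("familyFreqs must sum to at most 1")
  ev <- evidenceCodes()
  evW <- c(245, 292, 165, 6, 6, 11, 25, 119, 2,
           108, 257, 21, 6, 26, 15, 4, 38)
  withr::with_seed(seed,
    .genCatalog(n, familyFreqs, roleFreqs, domainCountFreqs, evW))
}

## One genome's gene layout. Returns a data.frame of genes in replicon
## order plus per-gene truth columns. Blocks: divergent pair, operon run,
## isolated TF with an upstream same-strand guard, or filler gene; blocks
## are shuffled and separated by gaps well above the TU threshold so the
## planted context is exactly recoverable.
.layoutGenome <- function(genomeId, nOrfs, nTfs, cfg) {
  relation <- if (nTfs) sample(c("divergent", "in_tu", "isolated"), nTfs,
                               replace = TRUE,
                               prob = c(cfg$divergent_frac, cfg$in_tu_frac,
                                        1 - cfg$divergent_frac -
                                          cfg$in_tu_frac))
              else character()
  runLen <- ifelse(relation == "in_tu",
                   2L + stats::rgeom(nTfs, cfg$operon_geom_p), 0L)
  blockLen <- ifelse(relation == "divergent", 2L,
                     ifelse(relation == "in_tu", runLen, 2L))
  if (sum(blockLen) > nOrfs)
    stop("genome ", genomeId, " infeasible: ", sum(blockLen),
         " genes needed for ", nTfs, " TFs but only ", nOrfs, " ORFs")
  nFill <- nOrfs - sum(blockLen)
  nBlocks <- nTfs + nFill
  ## block table: TF blocks first, then single-gene fillers, then shuffle
  bType <- c(relation, rep("filler", nFill))
  bLen <- c(blockLen, rep(1L, nFill))
  bStrand <- sample(c("+", "-"), nBlocks, replace = TRUE)
  bTf <- c(seq_len(nTfs), rep(NA_integer_, nFill))
  ord <- sample(nBlocks)
  bType <- bType[ord]; bLen <- bLen[ord]; bStrand <- bStrand[ord]
  bTf <- bTf[ord]

  ## expand to genes
  gBlock <- rep(seq_len(nBlocks), bLen)
  gLocal <- sequence(bLen)
  n <- length(gBlock)
  gStrand <- bStrand[gBlock]
  ## divergent blocks are always laid out (-, +); the TF side depends on
  ## the block strand draw: "+" puts the TF on the right gene, "-" on the
  ## left gene — both are valid divergent geometries
  isDiv <- bType[gBlock] == "divergent"
  gStrand[isDiv & gLocal == 1L] <- "-"
  gStrand[isDiv & gLocal == 2L] <- "+"
  ## TF flag per gene
  gTf <- rep(NA_integer_, n)
  divTfLocal <- ifelse(bStrand == "+", 2L, 1L)       # divergent blocks
  isoTfLocal <- ifelse(bStrand == "+", 2L, 1L)       # guard is upstream
  resample <- function(x) x[sample.int(length(x), 1L)]
  tuTfLocal <- vapply(seq_len(nBlocks), function(i) {
    if (bType[i] != "in_tu") return(NA_integer_)
    if (bStrand[i] == "+") resample(2:bLen[i])
    else resample(seq_len(bLen[i] - 1L))
  }, integer(1))
  tfLocal <- ifelse(bType == "divergent", divTfLocal,
                    ifelse(bType == "isolated", isoTfLocal, tuTfLocal))
  hit <- !is.na(bTf[gBlock]) & gLocal == tfLocal[gBlock]
  gTf[hit] <- bTf[gBlock][hit]

  ## gaps before each gene
  interGap <- function(k) cfg$filler_gap_min +
    stats::rgeom(k, 1 / 100)
  gGap <- integer(n)
  firstOfBlock <- gLocal == 1L
  gGap[firstOfBlock] <- interGap(sum(firstOfBlock))
  divGapIdx <- isDiv & gLocal == 2L
  gGap[divGapIdx] <- stats::rgeom(sum(divGapIdx),
                                  1 / (cfg$divergent_gap_mean + 1))
  tuIdx <- bType[gBlock] == "in_tu" & gLocal > 1L
  gGap[tuIdx] <- sample(5:40, sum(tuIdx), replace = TRUE)
  isoIdx <- bType[gBlock] == "isolated" & gLocal == 2L
  gGap[isoIdx] <- interGap(sum(isoIdx))

  starts <- cumsum(as.numeric(gGap)) + cfg$gene_length *
    (seq_len(n) - 1) + 1
  if (max(starts) + cfg$gene_length > .Machine$integer.max)
    stop("genome ", genomeId, " infeasible: replicon exceeds ",
         "coordinate range")
  divGap <- rep(NA_integer_, n)
  divGap[which(divGapIdx) - 1L] <- gGap[divGapIdx]  # partner gene row
  divGap[divGapIdx] <- gGap[divGapIdx]
  data.frame(
    genome_id = genomeId,
    replicon_id = paste0(genomeId, "_chr"),
    gene_id = sprintf("%s_gene%05d", genomeId, seq_len(n)),
    protein_id = sprintf("%s_p%05d", genomeId, seq_len(n)),
    start = as.integer(starts),
    end = as.integer(starts) + cfg$gene_length - 1L,
    strand = gStrand,
    tf_index = gTf,
    relation = ifelse(is.na(gTf), NA_character_, bType[gBlock]),
    divergent_gap = ifelse(is.na(gTf), NA_integer_, divGap),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic genome collection with ground truth
#'
#' Builds a complete, internally consistent input bundle: per genome, an
#' ORF count drawn log-uniformly and a TF count from the configured power
#' law with multiplicative noise; genes laid out on one circular replicon
#' with planted divergent pairs (short geometric gaps), operon runs
#' (compact same-strand spacings) and isolated TFs; and evidence tables —
#' domain hits, similarity hits against the synthetic curated catalog and
#' against the virulence reference, and EC assignments — emitted so that
#' every truth flag is realisable from the evidence. Each bundle includes
#' near-threshold decoys (E-values and coverages straddling the 1e-3, 1e-5
#' and 0.70 cutoffs) so boundary behaviour is always exercised.
#'
#' @param config a \code{generator_config} from [generatorConfig()].
#' @return a [GenomeCollection-class].
#' @export
generateCollection <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, .generateCollection(config))
}

.generateCollection <- function(cfg) {
  catalog <- .genCatalog(cfg$n_catalog, .CATALOG_FAMILY_FREQS,
                         c(repressor = 0.294, dual = 0.239,
                           activator = 0.181, undefined = 0.286),
                         c(0.4177, 0.5022, 0.0603, 0.009, 0.002, 0.004,
                           0.0028) / 0.9988,
                         c(245, 292, 165, 6, 6, 11, 25, 119, 2,
                           108, 257, 21, 6, 26, 15, 4, 38))
  catalogByFam <- split(catalogEntries(catalog)$tf_id,
                        catalogEntries(catalog)$family_pfam)
  tfPfams <- defaultTfPfams()
  nonTfPfam <- "PF96001"
  vfIds <- sprintf("VF%04d", seq_len(cfg$n_vf_proteins))

  pts <- local({
    nOrfs <- round(exp(stats::runif(cfg$n_genomes, log(cfg$orf_range[1L]),
                                    log(cfg$orf_range[2L]))))
    eps <- if (cfg$noise_sigma > 0)
      stats::rnorm(cfg$n_genomes, 0, cfg$noise_sigma) else 0
    nTfs <- round(cfg$scaling_a * nOrfs^cfg$scaling_b * exp(eps))
    ## keep the layout feasible: every TF block needs at most ~4 genes
    nTfs <- pmin(pmax(nTfs, 0L), floor(nOrfs / 5))
    data.frame(genome_id = sprintf("g%04d", seq_len(cfg$n_genomes)),
               n_orfs = as.integer(nOrfs), n_tfs = as.integer(nTfs))
  })

  genomes <- vector("list", cfg$n_genomes)
  domHits <- list(); simAB <- list(); simBA <- list()
  vfAB <- list(); vfBA <- list(); truth <- list()
  for (i in seq_len(cfg$n_genomes)) {
    g <- pts$genome_id[i]
    lay <- .layoutGenome(g, pts$n_orfs[i], pts$n_tfs[i], cfg)
    tfRows <- which(!is.na(lay$tf_index))
    nTf <- length(tfRows)
    fam <- rep(NA_character_, nrow(lay))
    domDet <- rep(NA, nrow(lay)); orthoDet <- rep(NA, nrow(lay))
    if (nTf) {
      fam[tfRows] <- sample(names(cfg$family_freqs), nTf, replace = TRUE,
                            prob = cfg$family_freqs)
      domDet[tfRows] <- stats::runif(nTf) < cfg$domain_detectable_frac
      orthoDet[tfRows] <- stats::runif(nTf) < cfg$ortho_detectable_frac
      ## orthology needs a distinct catalog partner per protein so mutual
      ## bests do not collide; excess TFs fall back to domain-only truth
      oIdx <- tfRows[which(orthoDet[tfRows])]
      if (length(oIdx) > length(catalog)) {
        drop <- oIdx[(length(catalog) + 1L):length(oIdx)]
        orthoDet[drop] <- FALSE
        oIdx <- oIdx[seq_len(length(catalog))]
      }
      partners <- sample(catalogEntries(catalog)$tf_id, length(oIdx))

      ## domain evidence
      dIdx <- tfRows[which(domDet[tfRows])]
      if (length(dIdx)) {
        e <- 10^-stats::runif(length(dIdx), 4, 30)
        domHits[[length(domHits) + 1L]] <- data.frame(
          protein_id = lay$protein_id[dIdx], pfam_acc = fam[dIdx],
          clan_acc = "CL0123", e_value = e,
          bit_score = round(stats::runif(length(dIdx), 60, 300), 1),
          ali_start = 5L, ali_end = 80L, stringsAsFactors = FALSE)
        ## boundary-pass decoy: an extra hit at exactly the E-value cutoff
        ## on an already-detectable TF (clan-overlap style second hit)
        domHits[[length(domHits) + 1L]] <- data.frame(
          protein_id = lay$protein_id[dIdx[1L]], pfam_acc = fam[dIdx[1L]],
          clan_acc = "CL0123", e_value = 1e-3, bit_score = 20.1,
          ali_start = 6L, ali_end = 70L, stringsAsFactors = FALSE)
      }
      ## just-above-threshold decoy on a non-detectable TF or non-TF
      nd <- tfRows[which(!domDet[tfRows])]
      decoyP <- if (length(nd)) lay$protein_id[nd[1L]]
                else lay$protein_id[setdiff(seq_len(nrow(lay)),
                                            tfRows)[1L]]
      domHits[[length(domHits) + 1L]] <- data.frame(
        protein_id = decoyP, pfam_acc = sample(tfPfams, 1L),
        clan_acc = "", e_value = 1.5e-3, bit_score = 18.2,
        ali_start = 1L, ali_end = 60L, stringsAsFactors = FALSE)
      ## strong hit to a non-TF PFAM never qualifies
      domHits[[length(domHits) + 1L]] <- data.frame(
        protein_id = lay$protein_id[setdiff(seq_len(nrow(lay)),
                                            tfRows)[2L]],
        pfam_acc = nonTfPfam, clan_acc = "", e_value = 1e-25,
        bit_score = 210, ali_start = 1L, ali_end = 90L,
        stringsAsFactors = FALSE)

      ## orthology evidence (mutual best, quantised spans over length 300)
      if (length(oIdx)) {
        span <- sample(240:297, length(oIdx), replace = TRUE)
        e <- 10^-stats::runif(length(oIdx), 6, 40)
        bit <- round(stats::runif(length(oIdx), 150, 400), 1)
        simAB[[length(simAB) + 1L]] <- data.frame(
          query_id = lay$protein_id[oIdx], subject_id = partners,
          e_value = e, bit_score = bit, query_cov = span / 300,
          subject_cov = span / 300, stringsAsFactors = FALSE)
        simBA[[length(simBA) + 1L]] <- data.frame(
          query_id = partners, subject_id = lay$protein_id[oIdx],
          e_value = e, bit_score = bit, query_cov = span / 300,
          subject_cov = span / 300, stringsAsFactors = FALSE)
        ## exact-boundary pair: qualifies at e = 1e-5 and coverage 0.70
        simAB[[length(simAB) + 1L]] <- data.frame(
          query_id = lay$protein_id[oIdx[1L]], subject_id = partners[1L],
          e_value = 1e-5, bit_score = 30, query_cov = 210 / 300,
          subject_cov = 210 / 300, stringsAsFactors = FALSE)
        simBA[[length(simBA) + 1L]] <- data.frame(
          query_id = partners[1L], subject_id = lay$protein_id[oIdx[1L]],
          e_value = 1e-5, bit_score = 30, query_cov = 210 / 300,
          subject_cov = 210 / 300, stringsAsFactors = FALSE)
      }
      ## decoys that must NOT produce orthologs: low coverage, weak
      ## e-value, and a one-directional best
      spare <- catalogEntries(catalog)$tf_id[
        !(catalogEntries(catalog)$tf_id %in% partners)]
      nonTfP <- lay$protein_id[setdiff(seq_len(nrow(lay)), tfRows)]
      if (length(spare) >= 3L && length(nonTfP) >= 5L) {
        dec <- data.frame(
          query_id = nonTfP[3:5], subject_id = spare[1:3],
          e_value = c(1e-30, 1e-4, 1e-30),
          bit_score = c(250, 250, 250),
          query_cov = c(195, 270, 270) / 300,
          subject_cov = c(195, 270, 270) / 300,
          stringsAsFactors = FALSE)
        simAB[[length(simAB) + 1L]] <- dec
        ## reciprocate only the first two (low-cov and weak-e); the third
        ## stays one-directional
        simBA[[length(simBA) + 1L]] <- data.frame(
          query_id = dec$subject_id[1:2], subject_id = dec$query_id[1:2],
          e_value = dec$e_value[1:2], bit_score = dec$bit_score[1:2],
          query_cov = dec$query_cov[1:2],
          subject_cov = dec$subject_cov[1:2], stringsAsFactors = FALSE)
      }
    }
    ## virulence labels over all proteins
    vir <- stats::runif(nrow(lay)) < cfg$virulence_frac
    vIdx <- which(vir)
    if (length(vIdx) > length(vfIds)) {
      vir[vIdx[(length(vfIds) + 1L):length(vIdx)]] <- FALSE
      vIdx <- vIdx[seq_len(length(vfIds))]
    }
    if (length(vIdx)) {
      vPart <- sample(vfIds, length(vIdx))
      span <- sample(225:297, length(vIdx), replace = TRUE)
      e <- 10^-stats::runif(length(vIdx), 6, 40)
      bit <- round(stats::runif(length(vIdx), 150, 400), 1)
      vfAB[[length(vfAB) + 1L]] <- data.frame(
        query_id = lay$protein_id[vIdx], subject_id = vPart,
        e_value = e, bit_score = bit, query_cov = span / 300,
        subject_cov = span / 300, stringsAsFactors = FALSE)
      vfBA[[length(vfBA) + 1L]] <- data.frame(
        query_id = vPart, subject_id = lay$protein_id[vIdx],
        e_value = e, bit_score = bit, query_cov = span / 300,
        subject_cov = span / 300, stringsAsFactors = FALSE)
    }
    ## low-coverage virulence decoy
    nonVir <- which(!vir)
    if (length(nonVir)) {
      vd <- lay$protein_id[nonVir[1L]]
      vfAB[[length(vfAB) + 1L]] <- data.frame(
        query_id = vd, subject_id = vfIds[1L], e_value = 1e-30,
        bit_score = 300, query_cov = 180 / 300, subject_cov = 180 / 300,
        stringsAsFactors = FALSE)
    }
    ## enzyme labels
    enz <- stats::runif(nrow(lay)) < cfg$enzyme_frac
    ecClass <- rep(NA_integer_, nrow(lay))
    ecClass[enz] <- sample(1:6, sum(enz), replace = TRUE,
                           prob = cfg$ec_class_freqs)

    lay$family <- fam
    lay$domain_detectable <- domDet
    lay$orthology_detectable <- orthoDet
    lay$ec_class <- ecClass
    lay$virulence <- vir
    genomes[[i]] <- lay
    truth[[i]] <- data.frame(
      genome_id = g, protein_id = lay$protein_id, gene_id = lay$gene_id,
      is_tf = !is.na(lay$tf_index), family = fam,
      domain_detectable = domDet, orthology_detectable = orthoDet,
      context_relation = lay$relation, divergent_gap = lay$divergent_gap,
      ec_class = ecClass, virulence = vir, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, genomes)
  gr <- GenomicRanges::GRanges(
    seqnames = all$replicon_id,
    ranges = IRanges::IRanges(all$start, all$end),
    strand = all$strand)
  GenomicRanges::mcols(gr)$gene_id <- all$gene_id
  GenomicRanges::mcols(gr)$protein_id <- all$protein_id
  GenomicRanges::mcols(gr)$genome_id <- all$genome_id
  ## circular replicons: length = span plus a terminal filler-scale gap
  repEnd <- tapply(all$end, all$replicon_id, max)
  sl <- stats::setNames(as.integer(repEnd) + 500L, names(repEnd))
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  GenomeInfoDb::isCircular(gr) <- rep(TRUE,
                                      length(GenomeInfoDb::seqlevels(gr)))
  bindRows <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(query_id = character(), subject_id = character(),
               e_value = numeric(), bit_score = numeric(),
               query_cov = numeric(), subject_cov = numeric(),
               stringsAsFactors = FALSE)
  dh <- if (length(domHits)) do.call(rbind, domHits) else
    data.frame(protein_id = character(), pfam_acc = character(),
               clan_acc = character(), e_value = numeric(),
               bit_score = numeric(), ali_start = integer(),
               ali_end = integer(), stringsAsFactors = FALSE)
  ec <- do.call(rbind, lapply(truth, function(tr) {
    idx <- which(!is.na(tr$ec_class))
    if (!length(idx)) return(NULL)
    data.frame(protein_id = tr$protein_id[idx],
               ec = paste0(tr$ec_class[idx], ".",
                           sample(1:9, length(idx), replace = TRUE), ".",
                           sample(1:9, length(idx), replace = TRUE), ".",
                           sample(c(as.character(1:20), "-"), length(idx),
                                  replace = TRUE)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ec))
    ec <- data.frame(protein_id = character(), ec = character(),
                     stringsAsFactors = FALSE)
  new("GenomeCollection", genes = gr, domainHits = dh,
      simCatalogAB = bindRows(simAB), simCatalogBA = bindRows(simBA),
      simVFAB = bindRows(vfAB), simVFBA = bindRows(vfBA),
      ecTable = ec, catalog = catalog, tfPfams = tfPfams,
      truth = do.call(rbind, truth), config = unclass(cfg))
}

#' Generate labeled census panels per division
#'
#' Builds a census (genome sizes and TF counts) for several taxonomic
#' divisions, each generated under its declared abundance model — power
#' law with multiplicative log-normal noise, or straight line with
#' additive Gaussian noise — for model-selection recovery experiments.
#'
#' @param divisions data.frame with columns \code{division}, \code{model}
#'   (\code{"power"} or \code{"linear"}), \code{a}, \code{b}, \code{sigma}
#'   (log-scale sd for power; absolute count sd for linear). Defaults to
#'   four power and four linear divisions with realistic parameters.
#' @param nGenomes genomes per division (default 50).
#' @param orfRange (min, max) ORF counts.
#' @param seed integer seed.
#' @return census data.frame (\code{genome_id}, \code{n_orfs},
#'   \code{n_tfs}, \code{division}) with the true model labels in
#'   \code{attr(, "models")}.
#' @export
generateDivisionPanel <- function(divisions = NULL, nGenomes = 50L,
                                  orfRange = c(1000L, 12000L), seed = 1L) {
  if (is.null(divisions))
    divisions <- data.frame(
      division = c("gammaproteobacteria", "alphaproteobacteria",
                   "betaproteobacteria", "cyanobacteria",
                   "actinobacteria", "firmicutes",
                   "deltaproteobacteria", "euryarchaeota"),
      model = rep(c("power", "linear"), each = 4L),
      a = c(7e-4, 5e-4, 6e-4, 4e-4, -60, -40, -50, -45),
      b = c(1.5283, 1.55, 1.60, 1.70, 0.070, 0.050, 0.060, 0.055),
      sigma = c(0.2, 0.2, 0.2, 0.2, 8, 8, 8, 8),
      stringsAsFactors = FALSE)
  if (!all(divisions$model %in% c("power", "linear")))
    stop("model must be power or linear")
  if (length(unique(divisions$model)) < 2L)
    stop("need at least two divisions with distinct model types")
  withr::with_seed(seed, {
    panels <- lapply(seq_len(nrow(divisions)), function(i) {
      dv <- divisions[i, ]
      nOrfs <- round(exp(stats::runif(nGenomes, log(orfRange[1L]),
                                      log(orfRange[2L]))))
      if (dv$model == "power") {
        eps <- if (dv$sigma > 0) stats::rnorm(nGenomes, 0, dv$sigma) else 0
        y <- round(dv$a * nOrfs^dv$b * exp(eps))
      } else {
        eps <- if (dv$sigma > 0) stats::rnorm(nGenomes, 0, dv$sigma) else 0
        y <- round(dv$a + dv$b * nOrfs + eps)
      }
      data.frame(genome_id = sprintf("%s_g%04d", dv$division,
                                     seq_len(nGenomes)),
                 n_orfs = as.integer(nOrfs),
                 n_tfs = as.integer(pmin(pmax(y, 1L), nOrfs)),
                 division = dv$division, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, panels)
    attr(out, "models") <- stats::setNames(divisions$model,
                                           divisions$division)
    out
  })
}

#' Write a genome collection to disk in external formats
#'
#' Emits exactly the formats the readers consume: one GFF3 of gene
#' coordinates, domain hits as TSV, similarity hits as BLAST outfmt-6
#' tables with companion sequence-length TSVs (all proteins have nominal
#' length 300), the EC table, the catalog TSV, the TF-PFAM list, the
#' virulence reference id list, and the ground truth as JSON.
#'
#' @param collection a [GenomeCollection-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeCollection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  writeGeneAnnotations(collection@genes, pth("genes.gff3"))
  writeDomainHits(collection@domainHits, pth("domain_hits.tsv"))
  writeOut6 <- function(h, path) {
    if (!nrow(h)) {
      file.create(path)
      return(invisible(path))
    }
    qend <- as.integer(round(h$query_cov * 300))
    send <- as.integer(round(h$subject_cov * 300))
    writeLines(paste(h$query_id, h$subject_id, "55.0", qend, 10, 1,
                     1, qend, 1, send,
                     format(h$e_value, scientific = TRUE, digits = 10),
                     h$bit_score, sep = "\t"), path)
    invisible(path)
  }
  writeOut6(collection@simCatalogAB, pth("sim_catalog_ab.tsv"))
  writeOut6(collection@simCatalogBA, pth("sim_catalog_ba.tsv"))
  writeOut6(collection@simVFAB, pth("sim_vf_ab.tsv"))
  writeOut6(collection@simVFBA, pth("sim_vf_ba.tsv"))
  prot <- GenomicRanges::mcols(collection@genes)$protein_id
  writeTsv(data.frame(id = prot, length = 300L), pth("proteome_lengths.tsv"))
  writeTsv(data.frame(id = catalogEntries(collection@catalog)$tf_id,
                      length = 300L), pth("catalog_lengths.tsv"))
  writeTsv(data.frame(id = sprintf("VF%04d",
                                   seq_len(collection@config$n_vf_proteins)),
                      length = 300L), pth("vf_lengths.tsv"))
  writeTsv(collection@ecTable, pth("ec.tsv"))
  writeCatalog(collection@catalog, pth("catalog.tsv"))
  writeLines(collection@tfPfams, pth("tf_pfams.txt"))
  jsonlite::write_json(collection@truth, pth("truth.json"),
                       dataframe = "rows",
                       na = "null", auto_unbox = TRUE, digits = NA)
  lv <- GenomeInfoDb::seqlevels(collection@genes)
  gm <- GenomicRanges::mcols(collection@genes)$genome_id
  writeTsv(data.frame(
    replicon_id = lv,
    genome_id = gm[match(lv, as.character(seqnames(collection@genes)))],
    length = as.integer(GenomeInfoDb::seqlengths(collection@genes)),
    circular = TRUE), pth("replicons.tsv"))
  files <- c(genes = pth("genes.gff3"), domain_hits = pth("domain_hits.tsv"),
             sim_catalog_ab = pth("sim_catalog_ab.tsv"),
             sim_catalog_ba = pth("sim_catalog_ba.tsv"),
             sim_vf_ab = pth("sim_vf_ab.tsv"),
             sim_vf_ba = pth("sim_vf_ba.tsv"),
             proteome_lengths = pth("proteome_lengths.tsv"),
             catalog_lengths = pth("catalog_lengths.tsv"),
             vf_lengths = pth("vf_lengths.tsv"),
             ec = pth("ec.tsv"), catalog = pth("catalog.tsv"),
             tf_pfams = pth("tf_pfams.txt"), truth = pth("truth.json"),
             replicons = pth("replicons.tsv"))
  invisible(files)
}
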