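## End-to-end orchestration over files: stage functions (predict, context,
## annotate, enrich, scaling, report) that read prior stage outputs and a
## monolithic runner that chains them. Staged and monolithic execution are
## equivalent by construction and property-tested.

.PIPELINE_OUTPUTS <- c(
  predictions = "predictions.tsv", census = "census.tsv",
  tus = "tus.tsv", context = "context.tsv",
  divergent_hist = "divergent_hist.tsv",
  family_context = "family_context.tsv",
  ec_distribution = "ec_distribution.tsv",
  virulence_summary = "virulence_summary.tsv",
  enrichment = "enrichment.tsv", scaling = "scaling.tsv")

#' Pipeline configuration
#'
#' Collects input paths, output directory and thresholds for
#' [runPipeline()]/[runStage()]. Input file names default to the layout
#' written by [writeCollection()] under \code{inputDir}. Thresholds
#' default to the standard cutoffs: domain E-value 1e-3, orthology
#' E-value 1e-5 with two-sided coverage 0.70, TU gap 50 bp, enrichment
#' FDR 0.05, and the 10 most abundant families for the context table.
#'
#' @param inputDir directory holding the input bundle.
#' @param outDir output directory (created on demand).
#' @param domain_e_max,ortho_e_max,cov_min,tu_gap_max,alpha,top_k_families
#'   analysis thresholds.
#' @param circular treat replicons as circular (default TRUE).
#' @param background enrichment background: \code{"neighbors"} (pooled
#'   divergent neighbors of the top families) or \code{"all"} proteins.
#' @param division_map_path optional TSV (genome_id, division).
#' @param pfam2go_path optional pfam2go mapping file.
#' @param seed seed recorded for stochastic stages (fixture generation).
#' @param ... named overrides for individual input file paths (e.g.
#'   \code{genes = "custom.gff3"}).
#' @return validated configuration list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(inputDir, outDir,
                           domain_e_max = 1e-3, ortho_e_max = 1e-5,
                           cov_min = 0.70, tu_gap_max = 50L,
                           alpha = 0.05, top_k_families = 10L,
                           circular = TRUE,
                           background = c("neighbors", "all"),
                           division_map_path = NULL,
                           pfam2go_path = NULL, seed = 1L, ...) {
  background <- match.arg(background)
  if (domain_e_max <= 0 || ortho_e_max <= 0)
    stop("E-value thresholds must be positive")
  if (cov_min <= 0 || cov_min > 1)
    stop("cov_min must lie in (0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (tu_gap_max < 0) stop("tu_gap_max must be nonnegative")
  if (top_k_families < 1) stop("top_k_families must be >= 1")
  files <- list(
    genes = "genes.gff3", domain_hits = "domain_hits.tsv",
    sim_catalog_ab = "sim_catalog_ab.tsv",
    sim_catalog_ba = "sim_catalog_ba.tsv",
    sim_vf_ab = "sim_vf_ab.tsv", sim_vf_ba = "sim_vf_ba.tsv",
    proteome_lengths = "proteome_lengths.tsv",
    catalog_lengths = "catalog_lengths.tsv",
    vf_lengths = "vf_lengths.tsv", ec = "ec.tsv",
    catalog = "catalog.tsv", tf_pfams = "tf_pfams.txt",
    replicons = "replicons.tsv")
  over <- list(...)
  bad <- setdiff(names(over), names(files))
  if (length(bad))
    stop("unknown input override(s): ", paste(bad, collapse = ", "))
  files[names(over)] <- over
  paths <- lapply(files, function(f)
    if (grepl("^/", f)) f else file.path(inputDir, f))
  structure(list(
    input_dir = inputDir, out_dir = outDir, paths = paths,
    domain_e_max = domain_e_max, ortho_e_max = ortho_e_max,
    cov_min = cov_min, tu_gap_max = as.integer(tu_gap_max),
    alpha = alpha, top_k_families = as.integer(top_k_families),
    circular = circular, background = background,
    division_map_path = division_map_path,
    pfam2go_path = pfam2go_path, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file whose keys mirror the [pipelineConfig()] arguments;
#' \code{overrides} (e.g. parsed command-line flags) take precedence over
#' file values, which take precedence over defaults.
#'
#' @param path YAML file.
#' @param overrides named list of overriding values.
#' @return a \code{pipeline_config}.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipelineConfig, vals)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.requireInputs <- function(config, keys) {
  for (k in keys) {
    p <- config$paths[[k]]
    if (!file.exists(p)) stop("missing input: ", p)
  }
}

.requireArtifacts <- function(config, keys) {
  for (k in keys) {
    p <- file.path(config$out_dir, .PIPELINE_OUTPUTS[[k]])
    if (!file.exists(p))
      stop("stage dependency missing: ", p,
           " (run the producing stage first)")
  }
}

.outPath <- function(config, key)
  file.path(config$out_dir, .PIPELINE_OUTPUTS[[key]])

.loadGenes <- function(config) {
  reps <- readTsv(config$paths$replicons)
  gr <- parseGeneAnnotations(config$paths$genes, genomeId = NA_character_,
                             proteinAttr = "protein_id")
  idx <- match(as.character(seqnames(gr)), reps$replicon_id)
  if (anyNA(idx))
    stop("replicon map does not cover all replicons in ",
         config$paths$genes)
  GenomicRanges::mcols(gr)$genome_id <- reps$genome_id[idx]
  sl <- stats::setNames(as.integer(reps$length), reps$replicon_id)
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  GenomeInfoDb::isCircular(gr) <-
    as.logical(reps$circular[match(GenomeInfoDb::seqlevels(gr),
                                   reps$replicon_id)])
  gr
}

.lengthMap <- function(path) {
  d <- readTsv(path)
  stats::setNames(as.integer(d$length), d$id)
}

.perGenomeRBH <- function(hitsAB, hitsBA, genomeOf, eMax, covMin) {
  if (!nrow(hitsAB)) return(character())
  gq <- genomeOf[hitsAB$query_id]
  gs <- genomeOf[hitsBA$subject_id]
  out <- lapply(unique(gq[!is.na(gq)]), function(g) {
    findOrthologsRBH(hitsAB[!is.na(gq) & gq == g, , drop = FALSE],
                     hitsBA[!is.na(gs) & gs == g, , drop = FALSE],
                     eMax = eMax, covMin = covMin)$a_id
  })
  unique(unlist(out))
}

#' Run one pipeline stage
#'
#' Stages: \code{"fixtures"} (generate a synthetic input bundle into the
#' input directory), \code{"predict"} (TF calls and census),
#' \code{"context"} (TUs, context calls, divergent-distance histogram),
#' \code{"annotate"} (family context table, EC distributions, virulence
#' summary), \code{"enrich"} (neighbor-PFAM enrichment),
#' \code{"scaling"} (abundance fits and per-division model selection) and
#' \code{"report"} (manifest with config hash and row counts). Each stage
#' reads the outputs of its prerequisites from the output directory and
#' fails naming the missing artifact when invoked too early.
#'
#' @param stage stage name.
#' @param config a \code{pipeline_config}.
#' @return the stage's main result, invisibly.
#' @export
runStage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, c("fixtures", "predict", "context", "annotate",
                              "enrich", "scaling", "report"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         fixtures = .stageFixtures(config),
         predict = .stagePredict(config),
         context = .stageContext(config),
         annotate = .stageAnnotate(config),
         enrich = .stageEnrich(config),
         scaling = .stageScaling(config),
         report = .stageReport(config))
}

.stageFixtures <- function(config) {
  coll <- generateCollection(generatorConfig(seed = config$seed))
  invisible(writeCollection(coll, config$input_dir))
}

.stagePredict <- function(config) {
  .requireInputs(config, c("genes", "domain_hits", "sim_catalog_ab",
                           "sim_catalog_ba", "proteome_lengths",
                           "catalog_lengths", "tf_pfams", "replicons"))
  genes <- .loadGenes(config)
  tfPfams <- readPfamList(config$paths$tf_pfams)
  dom <- parseDomainHits(config$paths$domain_hits)
  plen <- .lengthMap(config$paths$proteome_lengths)
  clen <- .lengthMap(config$paths$catalog_lengths)
  simAB <- parseSimilarityHits(config$paths$sim_catalog_ab, plen, clen)
  simBA <- parseSimilarityHits(config$paths$sim_catalog_ba, clen, plen)
  genomeOf <- stats::setNames(GenomicRanges::mcols(genes)$genome_id,
                              GenomicRanges::mcols(genes)$protein_id)
  sets <- lapply(sort(unique(GenomicRanges::mcols(genes)$genome_id)),
                 function(g) {
    pids <- GenomicRanges::mcols(genes)$protein_id[
      GenomicRanges::mcols(genes)$genome_id == g]
    domCalls <- assignTFByDomain(dom[dom$protein_id %in% pids, ,
                                     drop = FALSE],
                                 tfPfams, eMax = config$domain_e_max)
    orthoIds <- findOrthologsRBH(
      simAB[simAB$query_id %in% pids, , drop = FALSE],
      simBA[simBA$subject_id %in% pids, , drop = FALSE],
      eMax = config$ortho_e_max, covMin = config$cov_min)$a_id
    mergePredictions(domCalls, orthoIds, g)
  })
  preds <- combinePredictions(sets)
  divMap <- NULL
  if (!is.null(config$division_map_path)) {
    dm <- readTsv(config$division_map_path)
    divMap <- stats::setNames(dm$division, dm$genome_id)
  }
  cen <- tfCensus(preds, genes, divMap)
  writeTsv(tfPredictions(preds), .outPath(config, "predictions"))
  writeTsv(cen, .outPath(config, "census"))
  invisible(preds)
}

.stageContext <- function(config) {
  .requireInputs(config, c("genes", "replicons"))
  .requireArtifacts(config, "predictions")
  genes <- .loadGenes(config)
  preds <- readTsv(.outPath(config, "predictions"))
  tus <- predictTUs(genes, gapMax = config$tu_gap_max,
                    circular = config$circular)
  tfGenes <- GenomicRanges::mcols(genes)$gene_id[
    GenomicRanges::mcols(genes)$protein_id %in% preds$protein_id]
  calls <- classifyTFContext(tfGenes, genes, tus,
                             gapMax = config$tu_gap_max,
                             circular = config$circular)
  gm <- stats::setNames(GenomicRanges::mcols(genes)$genome_id,
                        GenomicRanges::mcols(genes)$gene_id)
  calls$genome_id <- unname(gm[calls$tf_gene_id])
  hist <- divergentDistanceHistogram(calls)
  writeTsv(data.frame(tu_id = tus$tu_id, replicon_id = tus$replicon_id,
                      strand = tus$strand, n_genes = tus$n_genes,
                      gene_ids = vapply(as.list(tus$gene_ids), paste,
                                        character(1), collapse = ",")),
           .outPath(config, "tus"))
  writeTsv(calls, .outPath(config, "context"))
  h <- hist
  h$frac_within_100 <- attr(hist, "fracWithin100")
  writeTsv(h, .outPath(config, "divergent_hist"))
  invisible(calls)
}

.stageAnnotate <- function(config) {
  .requireInputs(config, c("genes", "ec", "sim_vf_ab", "sim_vf_ba",
                           "proteome_lengths", "vf_lengths", "replicons"))
  .requireArtifacts(config, c("predictions", "context"))
  genes <- .loadGenes(config)
  predsDf <- readTsv(.outPath(config, "predictions"))
  preds <- new("TFPredictionSet", predictions = S4Vectors::DataFrame(predsDf))
  calls <- readTsv(.outPath(config, "context"))
  prot <- GenomicRanges::mcols(genes)$protein_id
  ec <- joinEC(prot, readTsv(config$paths$ec))
  plen <- .lengthMap(config$paths$proteome_lengths)
  vlen <- .lengthMap(config$paths$vf_lengths)
  vAB <- parseSimilarityHits(config$paths$sim_vf_ab, plen, vlen)
  vBA <- parseSimilarityHits(config$paths$sim_vf_ba, vlen, plen)
  genomeOf <- stats::setNames(GenomicRanges::mcols(genes)$genome_id, prot)
  vfFlags <- .perGenomeRBH(vAB, vBA, genomeOf,
                           eMax = config$ortho_e_max,
                           covMin = config$cov_min)
  gene2prot <- stats::setNames(prot, GenomicRanges::mcols(genes)$gene_id)
  fam <- familyContextTable(preds, calls, ecFlags = ec$protein_id,
                            vfFlags = vfFlags,
                            topK = config$top_k_families,
                            partnerProteins = gene2prot)
  writeTsv(fam, .outPath(config, "family_context"))
  ## EC class distributions for TF proteins and divergent-neighbor proteins
  tfEc <- ec[ec$protein_id %in% predsDf$protein_id, , drop = FALSE]
  nb <- gene2prot[calls$partner_gene_id[calls$relation == "divergent"]]
  nbEc <- ec[ec$protein_id %in% nb, , drop = FALSE]
  distRow <- function(set, ann) {
    if (!nrow(ann)) return(NULL)
    d <- ecClassDistribution(ann)
    data.frame(set = set, ec_class = as.integer(names(d)), fraction = d,
               stringsAsFactors = FALSE)
  }
  ecd <- rbind(distRow("tf", tfEc), distRow("divergent_neighbor", nbEc))
  if (is.null(ecd))
    ecd <- data.frame(set = character(), ec_class = integer(),
                      fraction = numeric())
  writeTsv(ecd, .outPath(config, "ec_distribution"))
  vs <- data.frame(
    set = c("tf", "divergent_neighbor"),
    n = c(sum(predsDf$protein_id %in% vfFlags),
          sum(nb %in% vfFlags, na.rm = TRUE)),
    total = c(nrow(predsDf), sum(!is.na(nb))))
  vs$fraction <- ifelse(vs$total > 0, vs$n / vs$total, 0)
  writeTsv(vs, .outPath(config, "virulence_summary"))
  invisible(fam)
}

.stageEnrich <- function(config) {
  .requireInputs(config, c("genes", "domain_hits", "replicons"))
  .requireArtifacts(config, c("predictions", "context"))
  genes <- .loadGenes(config)
  predsDf <- readTsv(.outPath(config, "predictions"))
  calls <- readTsv(.outPath(config, "context"))
  dom <- parseDomainHits(config$paths$domain_hits)
  p2g <- if (!is.null(config$pfam2go_path))
    parsePfam2Go(config$pfam2go_path) else NULL
  gene2prot <- stats::setNames(GenomicRanges::mcols(genes)$protein_id,
                               GenomicRanges::mcols(genes)$gene_id)
  cnt <- sort(table(predsDf$family_pfam), decreasing = TRUE)
  fams <- names(cnt)[seq_len(min(config$top_k_families, length(cnt)))]
  neighborsOf <- function(famSel) {
    pids <- predsDf$protein_id[!is.na(predsDf$family_pfam) &
                                 predsDf$family_pfam %in% famSel]
    sel <- calls$relation == "divergent" & calls$tf_protein_id %in% pids
    unique(stats::na.omit(unname(gene2prot[calls$partner_gene_id[sel]])))
  }
  background <- if (config$background == "all")
    unique(GenomicRanges::mcols(genes)$protein_id)
  else neighborsOf(fams)
  res <- lapply(fams, function(fm) {
    fg <- neighborsOf(fm)
    if (!length(fg)) return(NULL)
    enrichNeighborPfams(fg, union(background, fg), dom, pfam2go = p2g,
                        alpha = config$alpha, familyPfam = fm)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- enrichNeighborPfams(character(), character(),
                               data.frame(protein_id = character(),
                                          pfam_acc = character()))
  writeTsv(out, .outPath(config, "enrichment"))
  invisible(out)
}

.stageScaling <- function(config) {
  .requireArtifacts(config, "census")
  cen <- readTsv(.outPath(config, "census"))
  fits <- fitScaling(cen)
  fits$division <- "all"
  if (!all(is.na(cen$division))) {
    sel <- selectModelPerDivision(cen)
    perDiv <- do.call(rbind, lapply(sel$division, function(dv) {
      f <- fitScaling(cen[cen$division == dv, , drop = FALSE])
      f$division <- dv
      f
    }))
    fits <- rbind(fits, perDiv)
    attr(fits, "selection") <- sel
  }
  writeTsv(fits, .outPath(config, "scaling"))
  invisible(fits)
}

.stageReport <- function(config) {
  .requireArtifacts(config, names(.PIPELINE_OUTPUTS))
  counts <- vapply(names(.PIPELINE_OUTPUTS), function(k) {
    nrow(readTsv(.outPath(config, k)))
  }, integer(1))
  manifest <- list(
    config = unclass(config), config_hash = .configHash(config),
    outputs = as.list(stats::setNames(as.integer(counts),
                                      .PIPELINE_OUTPUTS)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the full pipeline
#'
#' Chains the predict, context, annotate, enrich, scaling and report
#' stages on an existing input bundle, validating all inputs up front and
#' removing partial outputs on failure. Rerunning with the same
#' configuration reproduces identical outputs.
#'
#' @param config a \code{pipeline_config} from [pipelineConfig()].
#' @return the report manifest, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  .requireInputs(config, names(config$paths))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- c(file.path(config$out_dir, .PIPELINE_OUTPUTS),
               file.path(config$out_dir, "manifest.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(created))
  for (stage in c("predict", "context", "annotate", "enrich", "scaling"))
    runStage(stage, config)
  manifest <- runStage("report", config)
  ok <- TRUE
  invisible(manifest)
}
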