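#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Roles recognised for a curated regulator. "undefined" holds entries whose
## regulatory mode has not been resolved experimentally.
.TF_ROLES <- c("activator", "repressor", "dual", "undefined")

## Provenance classes for a merged TF call.
.PROVENANCE <- c("domain_only", "orthology_only", "both")

#' Curated transcription-factor catalog
#'
#' A \code{TFCatalog} holds a collection of experimentally validated
#' DNA-binding transcription factors: one row per protein, with its species,
#' PFAM domain architecture, regulatory role and the experimental evidence
#' codes supporting it. It is the gold-standard seed set for orthology-based
#' TF prediction and the reference for descriptive statistics (domain-count
#' distribution, role distribution, family frequencies).
#'
#' @slot entries A \code{\link[S4Vectors]{DataFrame}} with columns
#'   \code{tf_id}, \code{species}, \code{family_pfam}, \code{all_pfams}
#'   (CharacterList), \code{n_domains}, \code{role} and \code{evidence}
#'   (CharacterList of evidence codes).
#'
#' @seealso [readCatalog()], [generateCatalog()], [classifyEvidence()]
#' @export
setClass("TFCatalog", representation(entries = "DataFrame"))

setValidity("TFCatalog", function(object) {
  e <- object@entries
  need <- c("tf_id", "species", "family_pfam", "all_pfams", "n_domains",
            "role", "evidence")
  miss <- setdiff(need, colnames(e))
  if (length(miss))
    return(paste("missing catalog columns:", paste(miss, collapse = ", ")))
  if (nrow(e) == 0L)
    return(TRUE)
  if (anyDuplicated(e$tf_id))
    return("duplicated tf_id values")
  if (any(e$n_domains < 1L))
    return("n_domains must be >= 1")
  if (any(e$n_domains != lengths(e$all_pfams)))
    return("n_domains must equal length(all_pfams)")
  infam <- mapply(function(f, all) f %in% all, e$family_pfam,
                  as.list(e$all_pfams))
  if (!all(infam))
    return("family_pfam must be one of all_pfams")
  if (!all(e$role %in% .TF_ROLES))
    return(paste("role must be one of:", paste(.TF_ROLES, collapse = ", ")))
  codes <- unique(unlist(as.list(e$evidence)))
  bad <- setdiff(codes, evidenceCodes()$code)
  if (length(bad))
    return(paste("unknown evidence codes:", paste(bad, collapse = ", ")))
  TRUE
})

#' Merged per-genome TF predictions
#'
#' A \code{TFPredictionSet} holds the merged output of the two prediction
#' routes for one or more genomes: each protein called as a TF, the PFAM
#' family assigned by the domain route (where available), the provenance
#' class (\code{domain_only}, \code{orthology_only}, \code{both}) and the
#' best supporting E-value.
#'
#' @slot predictions A \code{DataFrame} with columns \code{genome_id},
#'   \code{protein_id}, \code{family_pfam} (may be \code{NA} for
#'   orthology-only calls), \code{provenance} and \code{best_e}.
#'
#' @seealso [mergePredictions()], [tfCensus()], [provenanceCounts()]
#' @export
setClass("TFPredictionSet", representation(predictions = "DataFrame"))

setValidity("TFPredictionSet", function(object) {
  p <- object@predictions
  need <- c("genome_id", "protein_id", "family_pfam", "provenance", "best_e")
  miss <- setdiff(need, colnames(p))
  if (length(miss))
    return(paste("missing prediction columns:", paste(miss, collapse = ", ")))
  if (nrow(p) == 0L)
    return(TRUE)
  if (anyDuplicated(paste(p$genome_id, p$protein_id)))
    return("duplicated (genome_id, protein_id) prediction")
  if (!all(p$provenance %in% .PROVENANCE))
    return("provenance must be domain_only, orthology_only or both")
  dom <- p$provenance %in% c("domain_only", "both")
  if (any(dom & (is.na(p$family_pfam) | p$family_pfam == "")))
    return("domain-supported predictions must carry a family_pfam")
  if (any(!is.na(p$best_e) & p$best_e <= 0))
    return("best_e must be positive")
  TRUE
})

#' Synthetic genome collection with ground truth
#'
#' A \code{GenomeCollection} bundles everything the pipeline consumes for a
#' set of genomes — gene coordinates, domain-hit and similarity-hit evidence
#' tables, EC annotations, the curated catalog and the virulence reference —
#' together with the planted ground truth (which proteins are TFs, by which
#' route each is detectable, its genomic context and functional labels) and
#' the generator configuration that produced it.
#'
#' @slot genes \code{GRanges} of all genes (mcols: \code{gene_id},
#'   \code{protein_id}, \code{genome_id}).
#' @slot domainHits data.frame of protein-to-PFAM hits.
#' @slot simCatalogAB,simCatalogBA data.frames of similarity hits, proteome
#'   vs catalog and catalog vs proteome.
#' @slot simVFAB,simVFBA data.frames of similarity hits vs the virulence
#'   reference set, both directions.
#' @slot ecTable data.frame of protein-to-EC assignments.
#' @slot catalog the \code{TFCatalog} used as orthology seed.
#' @slot tfPfams character vector of TF-associated PFAM accessions.
#' @slot truth data.frame of per-protein ground truth.
#' @slot config the generator configuration list.
#'
#' @seealso [generateCollection()], [writeCollection()]
#' @export
setClass("GenomeCollection",
         representation(genes = "GRanges",
                        domainHits = "data.frame",
                        simCatalogAB = "data.frame",
                        simCatalogBA = "data.frame",
                        simVFAB = "data.frame",
                        simVFBA = "data.frame",
                        ecTable = "data.frame",
                        catalog = "TFCatalog",
                        tfPfams = "character",
                        truth = "data.frame",
                        config = "list"))

setValidity("GenomeCollection", function(object) {
  tr <- object@truth
  if (nrow(tr) && !all(c("genome_id", "protein_id", "is_tf") %in% colnames(tr)))
    return("truth must carry genome_id, protein_id, is_tf")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "TFCatalog", function(object) {
  e <- object@entries
  cat("TFCatalog with", nrow(e), "entries\n")
  if (nrow(e)) {
    cat("  species:", length(unique(e$species)), "\n")
    cat("  families:", length(unique(e$family_pfam)), "\n")
    rl <- table(factor(e$role, levels = .TF_ROLES))
    cat("  roles:", paste(names(rl), as.integer(rl), sep = "=",
                          collapse = " "), "\n")
  }
})

setMethod("show", "TFPredictionSet", function(object) {
  p <- object@predictions
  cat("TFPredictionSet:", nrow(p), "TF calls in",
      length(unique(p$genome_id)), "genome(s)\n")
  if (nrow(p)) {
    pv <- table(factor(p$provenance, levels = .PROVENANCE))
    cat("  provenance:", paste(names(pv), as.integer(pv), sep = "=",
                               collapse = " "), "\n")
  }
})

setMethod("show", "GenomeCollection", function(object) {
  cat("GenomeCollection:", length(unique(object@truth$genome_id)),
      "genome(s),", length(object@genes), "genes,",
      sum(object@truth$is_tf), "planted TFs\n")
})

## ---- accessors -------------------------------------------------------------

#' @describeIn TFCatalog number of catalog entries
#' @param x a \code{TFCatalog}
#' @export
setMethod("length", "TFCatalog", function(x) nrow(x@entries))

#' Accessors for package classes
#'
#' \code{catalogEntries} returns the entry table of a \code{TFCatalog};
#' \code{tfPredictions} returns the prediction table of a
#' \code{TFPredictionSet}; \code{provenanceCounts} tabulates its provenance
#' partition; \code{collectionGenes} and \code{collectionTruth} return the
#' gene ranges and ground-truth table of a \code{GenomeCollection}.
#'
#' @param x the object to access.
#' @return A \code{DataFrame}, \code{data.frame}, \code{GRanges} or named
#'   integer vector as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
catalogEntries <- function(x) {
  stopifnot(is(x, "TFCatalog"))
  x@entries
}

#' @rdname accessors
#' @export
tfPredictions <- function(x) {
  stopifnot(is(x, "TFPredictionSet"))
  as.data.frame(x@predictions)
}

#' @rdname accessors
#' @export
provenanceCounts <- function(x) {
  stopifnot(is(x, "TFPredictionSet"))
  p <- x@predictions
  cnt <- table(factor(p$provenance, levels = .PROVENANCE))
  out <- as.integer(cnt)
  names(out) <- names(cnt)
  out
}

#' @rdname accessors
#' @export
collectionGenes <- function(x) {
  stopifnot(is(x, "GenomeCollection"))
  x@genes
}

#' @rdname accessors
#' @export
collectionTruth <- function(x) {
  stopifnot(is(x, "GenomeCollection"))
  x@truth
}
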