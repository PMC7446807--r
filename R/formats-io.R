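## Readers and writers for the external formats the pipeline touches.
## All coordinates are 1-based inclusive (GFF3 convention); all distance
## arithmetic elsewhere in the package assumes this.

#' @importFrom GenomicRanges GRanges mcols mcols<- strand start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom utils read.delim write.table
NULL

.stripVersion <- function(acc) sub("\\.\\d+$", "", acc)

#' Parse gene annotations from GFF3
#'
#' Reads gene coordinates from a GFF3 file and returns them as a sorted
#' \code{GRanges}. Records with a strand other than \code{+}/\code{-} or
#' with \code{end < start} are rejected individually (the parse continues)
#' and the number of rejected records is reported and stored in
#' \code{metadata()$nRejected}. Row-level rejection with diagnostics is the
#' reason this reader works from the raw nine-column table rather than a
#' whole-file importer that aborts on the first invalid record.
#'
#' @param path path to a GFF3 file (plain or gzipped).
#' @param genomeId genome identifier attached to every record.
#' @param feature feature type(s) to keep (default \code{"CDS"}; falls back
#'   to \code{"gene"} when the file has no CDS features).
#' @param proteinAttr attribute holding the protein identifier (default
#'   \code{"ID"}).
#' @return \code{GRanges} sorted by (replicon, start) with mcols
#'   \code{gene_id}, \code{protein_id}, \code{genome_id};
#'   \code{metadata()$nRejected} counts rejected rows.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'              "chr1\t.\tCDS\t100\t900\t.\t-\t.\tID=p1"), gff)
#' parseGeneAnnotations(gff, "g1")
#' @export
parseGeneAnnotations <- function(path, genomeId, feature = "CDS",
                                 proteinAttr = "ID") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    gr <- GRanges()
    S4Vectors::metadata(gr)$nRejected <- 0L
    return(gr)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(f)
  bad_shape <- ncols < 9L
  if (any(bad_shape))
    message(sum(bad_shape), " GFF3 line(s) with fewer than 9 columns rejected")
  f <- f[!bad_shape]
  m <- do.call(rbind, lapply(f, `[`, 1:9))
  type <- m[, 3L]
  keep_type <- type %in% feature
  if (!any(keep_type) && "gene" %in% type)
    keep_type <- type == "gene"
  m <- m[keep_type, , drop = FALSE]
  if (!nrow(m)) {
    gr <- GRanges()
    S4Vectors::metadata(gr)$nRejected <- sum(bad_shape)
    return(gr)
  }
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  strand <- m[, 7L]
  attr_id <- function(attrs, key) {
    pat <- paste0("(^|;)\\s*", key, "=([^;]+)")
    hit <- regmatches(attrs, regexec(pat, attrs))
    vapply(hit, function(h) if (length(h) >= 3L) h[3L] else NA_character_,
           character(1))
  }
  pid <- attr_id(m[, 9L], proteinAttr)
  if (all(is.na(pid)) && proteinAttr != "ID")
    pid <- attr_id(m[, 9L], "ID")
  gid <- attr_id(m[, 9L], "ID")
  gid[is.na(gid)] <- pid[is.na(gid)]

  ok <- !is.na(start) & !is.na(end) & start >= 1L & end >= start &
    strand %in% c("+", "-") & !is.na(gid)
  nrej <- sum(!ok) + sum(bad_shape)
  if (any(!ok))
    message(sum(!ok), " gene record(s) rejected (bad coordinates, strand, ",
            "or missing ID)")
  gr <- GRanges(seqnames = m[ok, 1L],
                ranges = IRanges(start = start[ok], end = end[ok]),
                strand = strand[ok])
  mcols(gr)$gene_id <- gid[ok]
  mcols(gr)$protein_id <- pid[ok]
  mcols(gr)$genome_id <- genomeId
  if (anyDuplicated(mcols(gr)$gene_id))
    stop("duplicated gene ids within genome ", genomeId)
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  S4Vectors::metadata(gr)$nRejected <- nrej
  gr
}

#' Write gene annotations as GFF3
#'
#' @param genes \code{GRanges} as returned by [parseGeneAnnotations()].
#' @param path output path.
#' @param feature feature type written (default \code{"CDS"}).
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotations <- function(genes, path, feature = "CDS") {
  lines <- "##gff-version 3"
  if (length(genes)) {
    attrs <- paste0("ID=", mcols(genes)$gene_id)
    pid <- mcols(genes)$protein_id
    if (!is.null(pid))
      attrs <- paste0(attrs, ";protein_id=", pid)
    lines <- c(lines, paste(
      as.character(seqnames(genes)), "TFRepertoire", feature,
      start(genes), end(genes), ".", as.character(strand(genes)), ".",
      attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse protein-to-PFAM domain hits
#'
#' Reads a whitespace/tab-delimited domain-hit table with columns
#' \code{protein_id pfam_acc clan_acc e_value bit_score ali_start ali_end}
#' (a minimal domtblout-like layout; a header row naming the first column
#' \code{protein_id} is tolerated). Accession version suffixes
#' (\code{PF00126.27}) are normalised to the bare accession so lists of
#' TF-associated families match across PFAM releases. Rows with a
#' non-numeric or non-positive E-value, or an alignment with
#' \code{ali_end < ali_start}, are rejected with a diagnostic; the rejected
#' count is stored in \code{attr(, "nRejected")}.
#'
#' @param path path to the table.
#' @return data.frame with columns \code{protein_id}, \code{pfam_acc},
#'   \code{clan_acc}, \code{e_value}, \code{bit_score}, \code{ali_start},
#'   \code{ali_end}.
#' @export
parseDomainHits <- function(path) {
  empty <- data.frame(protein_id = character(), pfam_acc = character(),
                      clan_acc = character(), e_value = numeric(),
                      bit_score = numeric(), ali_start = integer(),
                      ali_end = integer(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  lines <- lines[!grepl("^protein_id\\b", lines)]
  if (!length(lines)) {
    attr(empty, "nRejected") <- 0L
    return(empty)
  }
  f <- strsplit(trimws(lines), "[\t ]+")
  ok_shape <- lengths(f) >= 7L
  m <- do.call(rbind, lapply(f[ok_shape], `[`, 1:7))
  ev <- suppressWarnings(as.numeric(m[, 4L]))
  bs <- suppressWarnings(as.numeric(m[, 5L]))
  a1 <- suppressWarnings(as.integer(m[, 6L]))
  a2 <- suppressWarnings(as.integer(m[, 7L]))
  ok <- !is.na(ev) & ev > 0 & !is.na(bs) & !is.na(a1) & !is.na(a2) &
    a1 >= 1L & a2 >= a1
  nrej <- sum(!ok_shape) + sum(!ok)
  if (nrej)
    message(nrej, " domain-hit row(s) rejected (malformed columns or ",
            "invalid e-value/alignment)")
  out <- data.frame(protein_id = m[ok, 1L],
                    pfam_acc = .stripVersion(m[ok, 2L]),
                    clan_acc = ifelse(m[ok, 3L] %in% c("-", ""), "",
                                      m[ok, 3L]),
                    e_value = ev[ok], bit_score = bs[ok],
                    ali_start = a1[ok], ali_end = a2[ok],
                    stringsAsFactors = FALSE)
  attr(out, "nRejected") <- nrej
  out
}

#' Write a domain-hit table
#'
#' @param hits data.frame as returned by [parseDomainHits()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDomainHits <- function(hits, path) {
  h <- hits
  h$clan_acc[h$clan_acc == ""] <- "-"
  write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Parse all-vs-all similarity hits (BLAST tabular)
#'
#' Reads a BLAST outfmt-6-like table (\code{qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore}) and computes
#' per-side coverages as aligned span over sequence length. Both sides are
#' stored so downstream policy can require one- or two-sided coverage.
#'
#' @param path path to the table.
#' @param queryLengths,subjectLengths named integer vectors of sequence
#'   lengths; a hit referencing an id absent from its map is an error.
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{e_value}, \code{bit_score}, \code{query_cov}, \code{subject_cov}.
#' @export
parseSimilarityHits <- function(path, queryLengths, subjectLengths) {
  d <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) NULL)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      e_value = numeric(), bit_score = numeric(),
                      query_cov = numeric(), subject_cov = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(d) || !nrow(d)) {
    attr(empty, "nRejected") <- 0L
    return(empty)
  }
  if (ncol(d) < 12L)
    stop("similarity table must have the 12 BLAST outfmt-6 columns")
  q <- as.character(d[[1L]]); s <- as.character(d[[2L]])
  unknown_q <- setdiff(q, names(queryLengths))
  if (length(unknown_q))
    stop("unknown sequence ", unknown_q[1L])
  unknown_s <- setdiff(s, names(subjectLengths))
  if (length(unknown_s))
    stop("unknown sequence ", unknown_s[1L])
  ev <- suppressWarnings(as.numeric(d[[11L]]))
  bs <- suppressWarnings(as.numeric(d[[12L]]))
  qspan <- abs(as.integer(d[[8L]]) - as.integer(d[[7L]])) + 1L
  sspan <- abs(as.integer(d[[10L]]) - as.integer(d[[9L]])) + 1L
  ok <- !is.na(ev) & ev > 0 & !is.na(bs)
  if (any(!ok))
    message(sum(!ok), " similarity row(s) rejected (invalid e-value/score)")
  out <- data.frame(query_id = q[ok], subject_id = s[ok],
                    e_value = ev[ok], bit_score = bs[ok],
                    query_cov = qspan[ok] / unname(queryLengths[q[ok]]),
                    subject_cov = sspan[ok] / unname(subjectLengths[s[ok]]),
                    stringsAsFactors = FALSE)
  if (any(out$query_cov > 1 | out$subject_cov > 1))
    stop("alignment span exceeds sequence length; check the length maps")
  attr(out, "nRejected") <- sum(!ok)
  out
}

#' Parse a pfam2go mapping file
#'
#' Reads the standard pfam2go flat-text dialect, e.g.
#' \code{Pfam:PF00126 HTH_1 > GO:DNA binding ; GO:0003677}, one entry per
#' (PFAM, GO) pair. Comment lines starting with \code{!} are skipped; lines
#' without a GO id are skipped with a diagnostic.
#'
#' @param path path to the pfam2go file.
#' @return data.frame with columns \code{pfam_acc}, \code{go_id},
#'   \code{go_term}.
#' @export
parsePfam2Go <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]
  pat <- "^Pfam:(PF\\d+)(\\.\\d+)?\\s+\\S+\\s*>\\s*GO:(.*?)\\s*;\\s*(GO:\\d{7})\\s*$"
  m <- regmatches(lines, regexec(pat, lines))
  ok <- lengths(m) == 5L
  if (any(!ok))
    message(sum(!ok), " pfam2go line(s) without a GO id skipped")
  out <- data.frame(
    pfam_acc = vapply(m[ok], `[`, character(1), 2L),
    go_id = vapply(m[ok], `[`, character(1), 5L),
    go_term = vapply(m[ok], `[`, character(1), 4L),
    stringsAsFactors = FALSE)
  attr(out, "nRejected") <- sum(!ok)
  out
}

#' Read a one-accession-per-line PFAM list
#'
#' @param path path to the list file.
#' @return character vector of version-stripped accessions.
#' @export
readPfamList <- function(path) {
  x <- trimws(readLines(path))
  unique(.stripVersion(x[nzchar(x) & !grepl("^#", x)]))
}

#' Write/read simple TSV tables
#'
#' Thin wrappers used for all tabular pipeline outputs: tab-separated,
#' header row, no quoting.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{writeTsv} returns \code{path} invisibly; \code{readTsv}
#'   returns a data.frame.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
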