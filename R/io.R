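#' Read a CTSS file
#'
#' Reads a BED-like CTSS file (one CAGE transcription start site per line:
#' chromosome, position, strand, raw tag count; whitespace- or tab-delimited)
#' into a CTSS table. Positions are taken as 0-based by default; set
#' `one_based = TRUE` for the 1-based dialect.
#'
#' @param path path to the CTSS file.
#' @param sample_id label for the sample/tissue the file belongs to.
#' @param one_based logical; if TRUE input positions are 1-based and are
#'   shifted to the internal 0-based convention.
#' @return a `data.table` with columns `sample_id`, `chrom`, `pos` (0-based),
#'   `strand`, `count`, `tpm` (NA until normalized), sorted by
#'   (chrom, strand, pos).
#' @export
read_ctss <- function(path, sample_id, one_based = FALSE) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("CTSS file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) {
    return(ctss_table(character(), integer(), character(), integer(),
                      sample_id = sample_id))
  }
  tab <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "auto",
                        colClasses = list(character = 1, integer = 2,
                                          character = 3, integer = 4))),
    error = function(e) NULL)
  if (is.null(tab) || ncol(tab) != 4L ||
      !is.numeric(tab[[2L]]) || !is.numeric(tab[[4L]]) ||
      anyNA(tab[[2L]]) || anyNA(tab[[4L]]) ||
      !all(tab[[3L]] %in% c("+", "-"))) {
    bad <- .first_malformed_ctss_line(path)
    stop("malformed CTSS line ", bad, " in ", path)
  }
  data.table::setnames(tab, c("chrom", "pos", "strand", "count"))
  if (one_based) tab[, pos := pos - 1L]
  bad_count <- which(tab$count < 1L)
  if (length(bad_count)) {
    stop("count < 1 on line ", bad_count[1L], " of ", path)
  }
  ctss_table(tab$chrom, tab$pos, tab$strand, tab$count, sample_id = sample_id)
}

.first_malformed_ctss_line <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 4L || is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[4L]))) || !f[3L] %in% c("+", "-"))
      return(i)
  }
  1L
}

#' Construct a CTSS table from vectors
#'
#' @param chrom,pos,strand,count record fields; `pos` is 0-based.
#' @param tpm optional normalized signal (tags per million); NA when not yet
#'   normalized.
#' @param sample_id sample label, recycled into a column.
#' @return sorted, validated CTSS `data.table`.
#' @export
ctss_table <- function(chrom, pos, strand, count, tpm = NA_real_, sample_id) {
  tab <- data.table::data.table(
    sample_id = as.character(sample_id),
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand), count = as.integer(count),
    tpm = as.numeric(tpm))
  if (nrow(tab)) {
    if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(tab$count < 1L)) stop("raw counts must be >= 1")
    if (anyDuplicated(tab, by = c("chrom", "pos", "strand")))
      stop("duplicate (chrom, pos, strand) records in CTSS table")
    ok <- is.na(tab$tpm) | (is.finite(tab$tpm) & tab$tpm >= 0)
    if (!all(ok)) stop("tpm values must be finite and >= 0")
  }
  data.table::setorder(tab, chrom, strand, pos)
  tab[]
}

#' Write a CTSS table
#'
#' Writes chrom, pos, strand, count (and tpm when normalized) as a
#' tab-separated file with no header; round-trips through [read_ctss()].
#'
#' @param ctss CTSS table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ctss <- function(ctss, path) {
  cols <- c("chrom", "pos", "strand", "count")
  if (any(!is.na(ctss$tpm))) cols <- c(cols, "tpm")
  data.table::fwrite(ctss[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Transcript model constructor
#'
#' Exons are 0-based half-open intervals ordered 5' to 3' in transcript
#' orientation (for a minus-strand transcript the first exon has the highest
#' genomic coordinates). `cds_start` is the transcript-relative 0-based offset
#' of the first CDS base (so the 5'UTR leader length equals `cds_start`), or
#' NA for non-coding transcripts.
#'
#' @param gene_id,transcript_id,chrom,strand labels.
#' @param exons two-column integer matrix (start, end), 0-based half-open.
#' @param cds_start transcript-relative CDS offset or NA.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             cds_start = NA_integer_) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) stop("exon end must exceed start")
  gord <- order(exons[, 1L])
  sorted <- exons[gord, , drop = FALSE]
  if (nrow(sorted) > 1L &&
      any(sorted[-1L, 1L] < sorted[-nrow(sorted), 2L]))
    stop("overlapping exons within transcript ", transcript_id)
  len <- sum(exons[, 2L] - exons[, 1L])
  if (!is.na(cds_start) && (cds_start < 0L || cds_start >= len))
    stop("cds_start outside transcript length for ", transcript_id)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_start = if (is.na(cds_start)) NA_integer_
                             else as.integer(cds_start)),
            class = "transcript_model")
}

#' Total exonic length of a transcript model
#' @param tx a `transcript_model`.
#' @return integer length in bp.
#' @export
transcript_length <- function(tx) sum(tx$exons[, "end"] - tx$exons[, "start"])

#' Gene model constructor
#'
#' @param gene_id,chrom,strand labels.
#' @param transcripts list of [transcript_model()] objects.
#' @return object of class `gene_model` with a span covering all exons.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  allex <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(allex[, "start"]), end = max(allex[, "end"]),
                 transcripts = transcripts),
            class = "gene_model")
}

#' Parse transcript and gene models from a GTF file
#'
#' Imports exon and CDS features (1-based closed GTF coordinates become
#' internal 0-based half-open intervals) and assembles [gene_model()] objects.
#' Minus-strand exon chains are ordered 5' to 3' in transcript orientation,
#' and `cds_start` is the transcript-relative offset of the most 5' CDS base.
#'
#' @param path path to a GTF file.
#' @return named list of `gene_model` objects.
#' @export
parse_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type %in% c("exon", "CDS")]
  if (!length(gr)) stop("no exon/CDS features in ", path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id))
    stop("exon/CDS feature without transcript_id in ", path)
  if (is.null(mc$gene_id) || anyNA(mc$gene_id))
    stop("exon/CDS feature without gene_id in ", path)
  feat <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    gene_id = mc$gene_id, transcript_id = mc$transcript_id)
  if (!all(feat$strand %in% c("+", "-")))
    stop("exon/CDS feature with undefined strand in ", path)

  tx_models <- lapply(split(feat, feat$transcript_id), .build_transcript)
  by_gene <- split(tx_models, vapply(tx_models, `[[`, "", "gene_id"))
  genes <- lapply(by_gene, function(txs) {
    gene_model(txs[[1L]]$gene_id, txs[[1L]]$chrom, txs[[1L]]$strand,
               transcripts = txs)
  })
  genes[order(names(genes))]
}

.build_transcript <- function(feat) {
  ex <- feat[feat$type == "exon"]
  if (!nrow(ex)) stop("transcript ", feat$transcript_id[1L], " has no exons")
  minus <- ex$strand[1L] == "-"
  data.table::setorder(ex, start)
  exons <- as.matrix(ex[, c("start", "end")])
  if (minus) exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  cds <- feat[feat$type == "CDS"]
  cds_start <- NA_integer_
  if (nrow(cds)) {
    g <- if (minus) max(cds$end) - 1L else min(cds$start)
    cds_start <- genomic_to_transcript(g, exons, ex$strand[1L])
    if (is.na(cds_start))
      stop("CDS start outside exons for transcript ", feat$transcript_id[1L])
  }
  transcript_model(feat$gene_id[1L], feat$transcript_id[1L], feat$chrom[1L],
                   ex$strand[1L], exons, cds_start)
}

#' Map a genomic position to a transcript-relative offset
#'
#' @param gpos 0-based genomic position.
#' @param exons exon matrix in transcript (5' to 3') order.
#' @param strand "+" or "-".
#' @return 0-based transcript offset, or NA when `gpos` is not exonic.
#' @export
genomic_to_transcript <- function(gpos, exons, strand) {
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1L]; e <- exons[i, 2L]
    if (gpos >= s && gpos < e) {
      within <- if (strand == "+") gpos - s else (e - 1L) - gpos
      return(off + as.integer(within))
    }
    off <- off + (e - s)
  }
  NA_integer_
}

#' Write a promoter report table
#'
#' Tab-separated report with one row per promoter: TSS name, width in bp,
#' genomic position class, GC content and cross-tissue distribution class.
#' Round-trips losslessly through [read_promoter_table()].
#'
#' @param records data.frame with columns `name`, `width`, `position_class`,
#'   `gc`, `distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_promoter_table <- function(records, path) {
  need <- c("name", "width", "position_class", "gc", "distribution")
  records <- as.data.frame(records)
  missing_cols <- setdiff(need, colnames(records))
  if (length(missing_cols))
    stop("promoter records lack required field(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(records) && anyNA(records[, need]))
    stop("unset required field in promoter records")
  data.table::fwrite(records[, need], path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a promoter report table written by [write_promoter_table()]
#' @param path path to the TSV report.
#' @return data.table of promoter records.
#' @export
read_promoter_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c(1, 3, 5),
                                             integer = 2, numeric = 4))
  data.table::setnames(tab, c("name", "width", "position_class", "gc",
                              "distribution"))
  tab[]
}

#' Export intervals as BED6
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score`, `strand`. Scores are capped at 1000 as per
#'   the BED convention.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_bed6 <- function(intervals, path) {
  intervals <- as.data.frame(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = intervals$strand)
  S4Vectors::mcols(gr)$name <- as.character(intervals$name)
  S4Vectors::mcols(gr)$score <- pmin(1000, round(intervals$score))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are retained and bootstrap supports, when present, are
#' emitted as internal node labels. `parse_newick(to_newick(t))` reproduces
#' the topology, branch lengths and supports.
#'
#' @param tree an `ape::phylo` tree.
#' @param path optional output path; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

#' Parse a Newick string or file
#' @param x Newick string, or a path to a Newick file.
#' @return an `ape::phylo` tree.
#' @export
parse_newick <- function(x) {
  if (length(x) == 1L && file.exists(x)) ape::read.tree(x)
  else ape::read.tree(text = x)
}
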