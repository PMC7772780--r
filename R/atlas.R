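#' Assign consensus clusters to genes
#'
#' A cluster is assigned to a gene when its span overlaps the gene span
#' extended by `upstream_flank` bp on the gene's 5' side and the strands
#' match. When several genes qualify, the gene with the largest overlap wins
#' (ties broken by lexicographic gene id); clusters with no qualifying gene
#' stay unassigned, which is a valid outcome for intergenic TSS activity.
#'
#' @param consensus consensus table from [aggregate_clusters()].
#' @param genes list of [gene_model()] objects.
#' @param upstream_flank bp added upstream of the annotated gene start
#'   (default 500), since promoters often sit just 5' of annotation.
#' @return the consensus table with a `gene_id` column (NA when unassigned).
#' @export
assign_to_genes <- function(consensus, genes, upstream_flank = 500L) {
  out <- data.table::copy(consensus)
  out[, gene_id := NA_character_]
  if (nrow(out) == 0L || length(genes) == 0L) return(out[])
  best <- rep(0L, nrow(out))
  genes <- genes[order(vapply(genes, `[[`, "", "gene_id"))]
  for (g in genes) {
    gs <- if (g$strand == "+") g$start - upstream_flank else g$start
    ge <- if (g$strand == "+") g$end else g$end + upstream_flank
    ov <- pmin(out$end, ge) - pmax(out$start, gs)
    ov[out$chrom != g$chrom | out$strand != g$strand] <- 0L
    take <- ov > best   # strict: first gene in id order keeps ties
    best[take] <- ov[take]
    out[take, gene_id := g$gene_id]
  }
  out[]
}

#' Number promoters per gene in 5' to 3' order
#'
#' Within each gene, assigned promoters are named `p1.<GENE>` .. `pN.<GENE>`
#' in the 5' to 3' order of the gene's transcriptional orientation (so on a
#' minus-strand gene p1 has the highest genomic coordinate).
#'
#' @param promoters consensus table with a `gene_id` column (see
#'   [assign_to_genes()]).
#' @return the table with a `name` column (NA for unassigned clusters).
#' @export
name_promoters <- function(promoters) {
  out <- data.table::copy(promoters)
  out[, name := NA_character_]
  assigned <- which(!is.na(out$gene_id))
  if (!length(assigned)) return(out[])
  sub <- out[assigned]
  # 5' coordinate of each promoter in gene orientation
  key <- ifelse(sub$strand == "-", -as.numeric(sub$start), as.numeric(sub$start))
  ord <- order(sub$gene_id, key)
  rank_in_gene <- stats::ave(seq_along(ord), sub$gene_id[ord],
                             FUN = seq_along)
  nm <- sprintf("p%d.%s", rank_in_gene, sub$gene_id[ord])
  out[assigned[ord], name := nm]
  out[]
}

#' Classify the genomic position of a promoter within a transcript
#'
#' Uses the midpoint of the cluster span: inside an exon and 5' of the CDS
#' start it is a 5'UTR promoter; inside an exon at or after the CDS start it
#' is a coding-exon (internal) promoter; between exons it is intronic;
#' outside the transcript span it is intergenic/flank. For non-coding
#' transcripts (no CDS) exonic hits are reported simply as "exon".
#'
#' @param record list or one-row data.frame with `start`, `end` (the cluster
#'   span, 0-based half-open).
#' @param transcript a [transcript_model()].
#' @return one of "five_prime_utr", "coding_exon", "exon", "intron",
#'   "intergenic".
#' @export
classify_position <- function(record, transcript) {
  mid <- as.integer(floor((record$start + record$end - 1L) / 2))
  ex <- transcript$exons
  lo <- min(ex[, "start"]); hi <- max(ex[, "end"])
  if (mid < lo || mid >= hi) return("intergenic")
  rel <- genomic_to_transcript(mid, ex, transcript$strand)
  if (is.na(rel)) return("intron")
  if (is.na(transcript$cds_start)) return("exon")
  if (rel < transcript$cds_start) "five_prime_utr" else "coding_exon"
}

#' Longest annotated transcript of a gene
#' @param gene a [gene_model()].
#' @return the transcript with the largest exonic length (first on ties).
#' @export
longest_transcript <- function(gene) {
  lens <- vapply(gene$transcripts, transcript_length, integer(1))
  gene$transcripts[[which.max(lens)]]
}

#' Breadth-classification thresholds
#'
#' @param median_floor promoters whose cross-tissue median tpm falls below
#'   this floor are non-ubiquitous (default 0.2 tpm).
#' @param fold ubiquitous promoters whose maximum exceeds `fold` times the
#'   median are non-uniform (default 10).
#' @return a `breadth_thresholds` list.
#' @export
breadth_thresholds <- function(median_floor = 0.2, fold = 10) {
  stopifnot(median_floor > 0, fold > 1)
  structure(list(median_floor = median_floor, fold = fold),
            class = "breadth_thresholds")
}

#' Classify cross-tissue expression breadth
#'
#' Three-way rule on a promoter's tissue expression profile: median below
#' `median_floor` is non-ubiquitous; otherwise a maximum strictly greater
#' than `fold` times the median is ubiquitous-nonuniform, and a maximum at or
#' below it (including the exact tie) is ubiquitous-uniform.
#'
#' @param expression named numeric vector of tissue tpm values, or a matrix
#'   with one row per promoter and one column per tissue.
#' @param thresholds a [breadth_thresholds()].
#' @return character class(es): "non_ubiquitous", "ubiquitous_uniform" or
#'   "ubiquitous_nonuniform".
#' @export
classify_breadth <- function(expression, thresholds = breadth_thresholds()) {
  if (is.matrix(expression)) {
    if (ncol(expression) == 0L) stop("empty expression profile")
    med <- apply(expression, 1L, stats::median)
    mx <- apply(expression, 1L, max)
  } else {
    if (length(expression) == 0L) stop("empty expression profile")
    med <- stats::median(expression)
    mx <- max(expression)
  }
  .breadth_rule(med, mx, thresholds)
}

.breadth_rule <- function(med, mx, thresholds) {
  ifelse(med < thresholds$median_floor, "non_ubiquitous",
         ifelse(mx > thresholds$fold * med, "ubiquitous_nonuniform",
                "ubiquitous_uniform"))
}

#' Per-group width summaries of genomic intervals
#'
#' @param start,end interval bounds, 0-based half-open.
#' @param group label per interval.
#' @return list with `summary` (a `data.table` of per-group median width and
#'   count) and `widths` (per-group width lists).
#' @export
width_summaries <- function(start, end, group) {
  if (length(start) == 0L) stop("empty interval group")
  stopifnot(length(start) == length(end), length(start) == length(group))
  w <- end - start
  dt <- data.table::data.table(group = as.character(group), width = w)
  summary <- dt[, .(median_width = stats::median(width), n = .N),
                by = group]
  list(summary = summary[], widths = split(w, as.character(group)))
}

#' GC content of each consensus cluster span
#'
#' @param consensus consensus table.
#' @param genome a `Biostrings::DNAStringSet` named by chromosome (or a FASTA
#'   path).
#' @return numeric vector of GC fractions (NA for chromosomes absent from the
#'   genome).
#' @export
promoter_gc <- function(consensus, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- rep(NA_real_, nrow(consensus))
  ok <- which(consensus$chrom %in% names(genome))
  for (i in ok) {
    seq <- Biostrings::subseq(genome[[consensus$chrom[i]]],
                              consensus$start[i] + 1L, consensus$end[i])
    out[i] <- gc_content(as.character(seq))
  }
  out
}

#' Build the promoter atlas from consensus clusters
#'
#' Combines gene assignment, per-gene promoter naming, positional
#' classification against each gene's longest transcript, span GC content
#' and expression-breadth classification into one promoter table.
#'
#' @param consensus consensus table from [aggregate_clusters()].
#' @param expr expression matrix from [expression_matrix()].
#' @param genes list of [gene_model()] objects.
#' @param genome optional genome (`DNAStringSet` or FASTA path) for GC
#'   content.
#' @param thresholds a [breadth_thresholds()].
#' @param upstream_flank passed to [assign_to_genes()].
#' @return promoter `data.table`: consensus columns plus `gene_id`, `name`,
#'   `position_class`, `gc`, `median_tpm`, `max_tpm`, `breadth_class`.
#' @export
build_promoter_atlas <- function(consensus, expr, genes, genome = NULL,
                                 thresholds = breadth_thresholds(),
                                 upstream_flank = 500L) {
  atlas <- assign_to_genes(consensus, genes, upstream_flank)
  atlas <- name_promoters(atlas)
  atlas[, position_class := "intergenic"]
  gene_index <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  for (i in which(!is.na(atlas$gene_id))) {
    tx <- longest_transcript(gene_index[[atlas$gene_id[i]]])
    atlas[i, position_class := classify_position(atlas[i], tx)]
  }
  atlas[, gc := if (is.null(genome)) NA_real_ else promoter_gc(atlas, genome)]
  expr <- expr[atlas$consensus_id, , drop = FALSE]
  atlas[, median_tpm := apply(expr, 1L, stats::median)]
  atlas[, max_tpm := do.call(pmax, as.data.frame(expr))]
  atlas[, breadth_class := .breadth_rule(median_tpm, max_tpm, thresholds)]
  atlas[]
}
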