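#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); `N` bases are excluded from the
#' denominator. High-GC leaders are one of the primary-structure features
#' that reduce 5'UTR translatability.
#'
#' @param seq nucleotide string over ACGTN (case-insensitive).
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  s <- strsplit(toupper(seq), "")[[1L]]
  if (!all(s %in% c("A", "C", "G", "T", "N")))
    stop("non-IUPAC character in sequence (alphabet ACGTN)")
  denom <- sum(s != "N")
  if (denom == 0L) stop("sequence contains only N bases")
  sum(s %in% c("G", "C")) / denom
}

#' Reconstruct the spliced 5'UTR leader of a transcript
#'
#' Concatenates the exon sequences in transcript orientation
#' (reverse-complemented for minus-strand transcripts) and truncates at the
#' CDS start, so the leader length equals `cds_start`.
#'
#' @param transcript a [transcript_model()] with `cds_start` set.
#' @param genome a `Biostrings::DNAStringSet` named by chromosome, or a FASTA
#'   path.
#' @return list with `transcript_id`, `leader_seq` (character) and
#'   `length_bp` (== `cds_start`).
#' @export
reconstruct_5utr <- function(transcript, genome) {
  if (is.na(transcript$cds_start))
    stop("cds_start unset: transcript ", transcript$transcript_id,
         " is non-coding")
  full <- spliced_sequence(transcript, genome)
  leader <- substr(full, 1L, transcript$cds_start)
  list(transcript_id = transcript$transcript_id, leader_seq = leader,
       length_bp = nchar(leader))
}

#' Spliced transcript sequence from a genome
#'
#' @inheritParams reconstruct_5utr
#' @return character transcript sequence, 5' to 3'.
#' @export
spliced_sequence <- function(transcript, genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!transcript$chrom %in% names(genome))
    stop("chromosome ", transcript$chrom, " absent from genome")
  chrom_seq <- genome[[transcript$chrom]]
  ex <- transcript$exons
  if (any(ex[, "start"] < 0L) || any(ex[, "end"] > length(chrom_seq)))
    stop("exon outside genome bounds for ", transcript$transcript_id)
  pieces <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    sub <- Biostrings::subseq(chrom_seq, ex[i, "start"] + 1L, ex[i, "end"])
    if (transcript$strand == "-") sub <- Biostrings::reverseComplement(sub)
    pieces[i] <- as.character(sub)
  }
  paste(pieces, collapse = "")
}

.check_acgt <- function(seq, what = "sequence") {
  if (nchar(seq) && !grepl("^[ACGT]*$", seq))
    stop(what, " must be uppercase ACGT")
}

.STOPS <- c("TAA", "TAG", "TGA")

#' Find upstream open reading frames in a 5'UTR leader
#'
#' Every ATG whose A lies within the leader opens a candidate uORF;
#' translation proceeds in frame through the leader and, when the stop falls
#' downstream of the leader, into `downstream_seq` (the CDS region), stopping
#' at the first TAA/TAG/TGA. Candidates with no in-frame stop anywhere in the
#' transcript are reported with `has_stop = FALSE`. Overlapping and nested
#' uORFs are all reported; near-cognate (non-ATG) starts are ignored.
#'
#' @param leader_seq 5'UTR leader (uppercase ACGT).
#' @param downstream_seq sequence downstream of the leader (uppercase ACGT;
#'   may be empty).
#' @return `data.table` with `start_offset` (0-based offset of the A of ATG
#'   within the leader), `aa_length` (peptide length excluding the stop) and
#'   `has_stop`.
#' @export
find_uorfs <- function(leader_seq, downstream_seq = "") {
  .check_acgt(leader_seq, "leader_seq")
  .check_acgt(downstream_seq, "downstream_seq")
  empty <- data.table::data.table(start_offset = integer(),
                                  aa_length = integer(),
                                  has_stop = logical())
  if (nchar(leader_seq) == 0L) return(empty)
  full <- paste0(leader_seq, downstream_seq)
  # the A of the ATG must lie within the leader; T/G may fall downstream
  starts <- as.integer(gregexpr("ATG", full, fixed = TRUE)[[1L]])
  starts <- starts[starts > 0L & starts <= nchar(leader_seq)]
  if (!length(starts)) return(empty)
  recs <- lapply(starts, function(s) {
    n_codons <- (nchar(full) - s + 1L) %/% 3L
    cod_starts <- s + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(full, cod_starts, cod_starts + 2L)
    stop_i <- which(codons %in% .STOPS)[1L]
    if (is.na(stop_i)) {
      list(start_offset = s - 1L, aa_length = n_codons, has_stop = FALSE)
    } else {
      list(start_offset = s - 1L, aa_length = stop_i - 1L, has_stop = TRUE)
    }
  })
  data.table::rbindlist(recs)
}

#' Number of uORFs in a leader
#'
#' Counts only uORFs with an in-frame stop (open-ended candidates are
#' reported by [find_uorfs()] but not counted).
#'
#' @inheritParams find_uorfs
#' @return integer count.
#' @export
count_uorfs <- function(leader_seq, downstream_seq = "") {
  sum(find_uorfs(leader_seq, downstream_seq)$has_stop)
}

#' Longest open reading frame of a sequence
#'
#' Scans all three forward frames for ATG..stop spans and returns the one
#' with the maximal nucleotide length (stop codon included), breaking ties
#' toward the most 5' start.
#'
#' @param seq nucleotide sequence (uppercase ACGT).
#' @return list with `start_offset` (0-based), `nt_length` (including the
#'   stop codon), `aa_length` (excluding the stop) and `has_stop = TRUE`;
#'   or NULL when the sequence contains no complete ORF.
#' @export
longest_orf <- function(seq) {
  .check_acgt(seq, "seq")
  best <- NULL
  n <- nchar(seq)
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 2L) next
    cod_starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, cod_starts, cod_starts + 2L)
    atg_i <- which(codons == "ATG")
    stop_i <- which(codons %in% .STOPS)
    if (!length(atg_i) || !length(stop_i)) next
    # first stop strictly after each ATG
    nxt <- stop_i[findInterval(atg_i, stop_i) + 1L]
    ok <- !is.na(nxt)
    for (k in which(ok)) {
      nt_len <- (nxt[k] - atg_i[k] + 1L) * 3L
      start0 <- cod_starts[atg_i[k]] - 1L
      if (is.null(best) || nt_len > best$nt_length ||
          (nt_len == best$nt_length && start0 < best$start_offset)) {
        best <- list(start_offset = start0, nt_length = nt_len,
                     aa_length = nxt[k] - atg_i[k], has_stop = TRUE)
      }
    }
  }
  best
}

#' Check a splice junction against the canonical GT/AG rule
#'
#' @param donor_seq first intronic bases at the 5' splice site (>= 2 bases).
#' @param acceptor_seq last intronic bases at the 3' splice site (>= 2
#'   bases).
#' @return TRUE iff the intron starts with GT and ends with AG.
#' @export
check_canonical_junction <- function(donor_seq, acceptor_seq) {
  donor_seq <- toupper(donor_seq); acceptor_seq <- toupper(acceptor_seq)
  if (any(nchar(donor_seq) < 2L) || any(nchar(acceptor_seq) < 2L))
    stop("donor and acceptor sequences must have length >= 2")
  startsWith(donor_seq, "GT") & endsWith(acceptor_seq, "AG")
}

#' Full 5'UTR report for a transcript
#'
#' Reconstructs the leader and computes its length, GC content and uORF
#' census (uORF stops may fall downstream of the leader, inside the CDS).
#'
#' @inheritParams reconstruct_5utr
#' @return list with `transcript_id`, `leader_seq`, `length_bp`, `gc`,
#'   `uorfs` (the [find_uorfs()] table) and `n_uorfs` (stop-containing
#'   uORFs).
#' @export
utr_report <- function(transcript, genome) {
  full <- spliced_sequence(transcript, genome)
  leader <- substr(full, 1L, transcript$cds_start)
  if (is.na(transcript$cds_start))
    stop("cds_start unset: transcript ", transcript$transcript_id,
         " is non-coding")
  downstream <- substr(full, transcript$cds_start + 1L, nchar(full))
  uorfs <- find_uorfs(leader, downstream)
  list(transcript_id = transcript$transcript_id, leader_seq = leader,
       length_bp = nchar(leader),
       gc = if (nchar(leader)) gc_content(leader) else NA_real_,
       uorfs = uorfs, n_uorfs = sum(uorfs$has_stop))
}
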