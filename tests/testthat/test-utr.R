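test_that("gc_content counts G+C over unambiguous bases", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGTN"), 0.5)   # N excluded from denominator
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("ACGX"), "non-IUPAC")
})

test_that("gc + at partition N-free sequences; gc is revcomp-invariant", {
  set.seed(4)
  for (i in 1:20) {
    s <- random_dna(sample(10:200, 1))
    gc <- gc_content(s)
    at <- {
      ch <- strsplit(s, "")[[1]]
      mean(ch %in% c("A", "T"))
    }
    expect_equal(gc + at, 1)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gc_content(rc), gc)
  }
})

test_that("5'UTR reconstruction splices exons and truncates at the CDS", {
  # toy plus-strand gene: exons [0,10) and [20,30), cds_start 15 ->
  # leader = first 10 bases + 5 bases after the junction
  chrom <- "ACGTACGTAC" # exon 1
  chrom <- paste0(chrom, "NNNNNNNNNN", "GGCCTTAAGG")
  chrom <- gsub("N", "T", chrom)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  tx <- transcript_model("g", "t", "chr1", "+",
                         rbind(c(0L, 10L), c(20L, 30L)), cds_start = 15L)
  r <- reconstruct_5utr(tx, genome)
  expect_equal(r$leader_seq, paste0("ACGTACGTAC", "GGCCT"))
  expect_equal(r$length_bp, 15L)

  tx0 <- transcript_model("g", "t", "chr1", "+", rbind(c(0L, 10L)),
                          cds_start = 0L)
  expect_equal(reconstruct_5utr(tx0, genome)$leader_seq, "")

  txnc <- transcript_model("g", "t", "chr1", "+", rbind(c(0L, 10L)), NA)
  expect_error(reconstruct_5utr(txnc, genome), "non-coding")
  txoob <- transcript_model("g", "t", "chr1", "+", rbind(c(0L, 99L)),
                            cds_start = 5L)
  expect_error(reconstruct_5utr(txoob, genome), "bounds")
})

test_that("minus-strand leaders are reverse-complemented exon chains", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTT"))
  # minus-strand transcript over [0,12): 5' exon is [6,12)
  tx <- transcript_model("g", "t", "chr1", "-",
                         rbind(c(6L, 12L), c(0L, 6L)), cds_start = 6L)
  r <- reconstruct_5utr(tx, genome)
  expect_equal(r$leader_seq, "AAACCC")   # revcomp of GGGTTT
})

test_that("leader length always equals cds_start on simulated loci", {
  for (seed in 1:5) {
    loc <- simulate_utr_locus(sample(1:40, sample(0:3, 1)),
                              leader_length = sample(200:800, 1),
                              seed = seed)
    r <- reconstruct_5utr(loc$transcript, loc$genome)
    expect_equal(r$length_bp, loc$transcript$cds_start)
  }
})

test_that("uORF detection matches hand-translated examples", {
  expect_equal(nrow(find_uorfs("CCCCCCCC")), 0L)
  rec <- find_uorfs("ATGAAATGA")
  stop_recs <- rec[rec$has_stop == TRUE, ]
  expect_equal(nrow(stop_recs), 1L)
  expect_equal(stop_recs$aa_length, 2L)    # Met-Lys
  expect_equal(stop_recs$start_offset, 0L)

  both <- find_uorfs("ATGATGTAAGGGTAG")
  expect_equal(both$start_offset, c(0L, 3L))
  expect_true(all(both$has_stop))

  # stop downstream of the leader, inside the CDS region
  spanning <- find_uorfs("CCATGCC", "CTAAGG")
  expect_equal(spanning$aa_length, 2L)
  expect_true(spanning$has_stop)
})

test_that("uORF and longest-ORF scans match brute force on random input", {
  set.seed(606)
  for (i in 1:200) {
    s <- random_dna(sample(30:150, 1))
    down <- random_dna(sample(0:60, 1))
    mine <- find_uorfs(s, down)
    oracle <- bf_uorfs(s, down)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0L)
    } else {
      expect_equal(as.data.frame(mine), oracle)
    }
    lo <- longest_orf(s)
    blo <- bf_longest_orf(s)
    if (is.null(blo)) {
      expect_null(lo)
    } else {
      expect_equal(lo$nt_length, blo$nt_length)
      expect_equal(lo$start_offset, blo$start_offset)
    }
  }
})

test_that("longest ORF handles edge cases and dominates uORF lengths", {
  expect_null(longest_orf("CCCCCC"))
  orf <- longest_orf("ATGTAA")
  expect_equal(orf$nt_length, 6L)
  expect_equal(orf$aa_length, 1L)
  set.seed(77)
  for (i in 1:20) {
    s <- random_dna(300)
    lo <- longest_orf(s)
    if (is.null(lo)) next
    u <- find_uorfs(s)
    closed <- u[u$has_stop == TRUE, ]
    if (nrow(closed))
      expect_gte(lo$nt_length, max(closed$aa_length + 1L) * 3L)
  }
})

test_that("splice junctions are checked against the GT/AG rule", {
  expect_true(check_canonical_junction("GTTAGTGCTC", "ATTTTTATCTTTCAG"))
  expect_true(check_canonical_junction("GTGAGTGCGT", "TATCCCTGCCCACAG"))
  expect_false(check_canonical_junction("CTTAGT", "TTTTAG"))
  expect_false(check_canonical_junction("GTTAGT", "TTTTGA"))
  expect_error(check_canonical_junction("G", "AG"), "length")
})
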