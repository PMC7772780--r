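toy_gene <- function(gene_id = "G", strand = "+", chrom = "chr1") {
  exons <- rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L))
  if (strand == "-") exons <- exons[3:1, ]
  tx <- transcript_model(gene_id, paste0(gene_id, ".t"), chrom, strand,
                         exons, cds_start = 150L)
  gene_model(gene_id, chrom, strand, list(tx))
}

mk_cc <- function(start, end, strand = "+", chrom = "chr1") {
  data.table::data.table(consensus_id = sprintf("cc%03d", seq_along(start)),
                         chrom = chrom, strand = strand,
                         start = as.integer(start), end = as.integer(end),
                         width = as.integer(end - start),
                         n_samples = 1L)
}

test_that("clusters are assigned to the gene with the largest overlap", {
  g <- toy_gene()
  inside <- assign_to_genes(mk_cc(50, 80), list(g))
  expect_equal(inside$gene_id, "G")

  opposite <- assign_to_genes(mk_cc(50, 80, strand = "-"), list(g))
  expect_true(is.na(opposite$gene_id))

  # gene A overlapped by 30 bp, gene B by 10 bp -> A wins
  ga <- gene_model("A", "chr1", "+", list(transcript_model(
    "A", "A.t", "chr1", "+", rbind(c(1000L, 1030L)), NA)))
  gb <- gene_model("B", "chr1", "+", list(transcript_model(
    "B", "B.t", "chr1", "+", rbind(c(1020L, 1100L)), NA)))
  cc <- mk_cc(1000, 1030)
  expect_equal(assign_to_genes(cc, list(gb, ga), upstream_flank = 0)$gene_id,
               "A")
})

test_that("the upstream flank catches promoters 5' of the annotation", {
  g <- toy_gene()   # span [0, 500) on +
  up <- mk_cc(-400, -350)
  expect_equal(assign_to_genes(up, list(g), upstream_flank = 500)$gene_id,
               "G")
  expect_true(is.na(assign_to_genes(up, list(g),
                                    upstream_flank = 10)$gene_id))
})

test_that("promoters are numbered p1..pN in transcriptional orientation", {
  g <- toy_gene()
  cc <- assign_to_genes(mk_cc(c(450, 200), c(470, 240)), list(g))
  named <- name_promoters(cc)
  expect_equal(named$name[named$start == 200L], "p1.G")
  expect_equal(named$name[named$start == 450L], "p2.G")

  gm <- toy_gene(strand = "-")
  ccm <- assign_to_genes(mk_cc(c(200, 500), c(240, 520), strand = "-"),
                         list(gm))
  namedm <- name_promoters(ccm)
  expect_equal(namedm$name[namedm$start == 500L], "p1.G")
  expect_equal(namedm$name[namedm$start == 200L], "p2.G")
})

test_that("p-numbering is a bijection and input-order invariant", {
  set.seed(17)
  g <- toy_gene()
  cc <- assign_to_genes(mk_cc(seq(0, 450, by = 50) + 1,
                              seq(0, 450, by = 50) + 20), list(g))
  named <- name_promoters(cc)
  ranks <- as.integer(sub("^p(\\d+)\\..*$", "\\1", named$name))
  expect_setequal(ranks, seq_len(nrow(named)))
  perm <- cc[sample(nrow(cc)), ]
  renamed <- name_promoters(perm)
  expect_equal(renamed[order(start)]$name, named[order(start)]$name)
})

test_that("positional classes follow the midpoint against the transcript", {
  g <- toy_gene()
  tx <- longest_transcript(g)
  expect_equal(classify_position(list(start = 10L, end = 30L), tx),
               "five_prime_utr")                      # rel midpoint < 150
  expect_equal(classify_position(list(start = 260L, end = 280L), tx),
               "coding_exon")                         # rel midpoint >= 150
  expect_equal(classify_position(list(start = 320L, end = 340L), tx),
               "intron")                              # between exons
  expect_equal(classify_position(list(start = 500L, end = 502L), tx),
               "intergenic")                          # 1 bp past last exon
  ncrna <- transcript_model("N", "N.t", "chr1", "+", rbind(c(0L, 100L)), NA)
  expect_equal(classify_position(list(start = 10L, end = 30L), ncrna),
               "exon")
})

test_that("breadth classes follow the median/max three-branch rule", {
  expect_equal(classify_breadth(rep(0, 8)), "non_ubiquitous")
  expect_equal(classify_breadth(c(rep(1, 7), 12)), "ubiquitous_nonuniform")
  expect_equal(classify_breadth(rep(1, 8)), "ubiquitous_uniform")
  # selective for one tissue, all others silent -> non-ubiquitous
  expect_equal(classify_breadth(c(20, rep(0, 7))), "non_ubiquitous")
  # boundary: max exactly fold x median is uniform (strict > for nonuniform)
  expect_equal(classify_breadth(c(rep(1, 7), 10)), "ubiquitous_uniform")
  # boundary: median exactly at the floor is not below it
  expect_equal(classify_breadth(rep(0.2, 8)), "ubiquitous_uniform")
  expect_error(classify_breadth(numeric(0)), "empty")
})

test_that("breadth classification is scale-free above the median floor", {
  set.seed(23)
  for (i in 1:200) {
    prof <- runif(8, 0.5, 30)
    if (i %% 2 == 0) prof[sample(8, 1)] <- prof[sample(8, 1)] * 20
    base_class <- classify_breadth(prof)
    scaled <- classify_breadth(prof * 7)
    expect_equal(scaled, base_class)  # both profiles sit above the floor
  }
})

test_that("width summaries return per-group medians", {
  one <- width_summaries(0L, 225L, "pyd")
  expect_equal(one$summary$median_width, 225)
  two <- width_summaries(c(0L, 0L), c(320L, 1029L), c("short", "long"))
  expect_equal(two$summary$median_width[two$summary$group == "short"], 320)
  expect_equal(two$summary$median_width[two$summary$group == "long"], 1029)
  three <- width_summaries(rep(0L, 3), c(1L, 2L, 3L), rep("g", 3))
  expect_equal(three$summary$median_width, 2)
  expect_error(width_summaries(integer(0), integer(0), character(0)),
               "empty")
})

test_that("promoter GC is computed over the consensus span", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATATGCGCGC"))
  cc <- mk_cc(c(0, 4), c(4, 10))
  expect_equal(promoter_gc(cc, genome), c(0, 1))
  cc_missing <- mk_cc(0, 4, chrom = "chrZ")
  expect_true(is.na(promoter_gc(cc_missing, genome)))
})

test_that("the atlas combines assignment, naming, class and breadth", {
  g <- toy_gene()
  cc <- mk_cc(c(10, 260), c(30, 280))
  expr <- matrix(c(5, 5, 5, 5, 0.1, 0.1, 0.1, 0.1), nrow = 2, byrow = TRUE,
                 dimnames = list(cc$consensus_id,
                                 c("kidney", "liver", "lung", "brain")))
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(600)))
  atlas <- build_promoter_atlas(cc, expr, list(g), genome = genome)
  expect_equal(atlas$name, c("p1.G", "p2.G"))
  expect_equal(atlas$position_class, c("five_prime_utr", "coding_exon"))
  expect_equal(atlas$breadth_class,
               c("ubiquitous_uniform", "non_ubiquitous"))
  expect_true(all(atlas$gc >= 0 & atlas$gc <= 1))
})
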