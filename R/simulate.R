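#' Simulation configuration for synthetic multi-tissue CAGE experiments
#'
#' The generator emulates the statistical structure of a multi-tissue CAGE
#' experiment: per-tissue libraries whose per-position tag counts follow a
#' discrete power law, promoters planted as clustered TSS positions with a
#' discrete-Laplace positional kernel, tissue expression profiles drawn from
#' the three expression-breadth categories, and optional Poisson count noise.
#'
#' @param tissues tissue labels; defaults to the eight-organ panel (kidney,
#'   intestine, heart, lung, bone marrow, liver, brain, spleen).
#' @param n_genes number of simulated genes.
#' @param promoters_per_gene candidate promoter counts per gene (subset of
#'   1..8).
#' @param promoter_mix sampling probabilities over `promoters_per_gene`.
#' @param category_mix probabilities of the three breadth categories
#'   (non_ubiquitous, ubiquitous_uniform, ubiquitous_nonuniform); must sum
#'   to 1.
#' @param base_tpm scale (tags per million) of an active planted promoter.
#' @param count_alpha power-law exponent of per-position tag counts.
#' @param pos_spread scale (bp) of the discrete-Laplace displacement of tags
#'   around the planted center; 0 stacks all tags on one position.
#' @param noise logical; apply Poisson noise to planted tag masses.
#' @param lib_total target per-tissue library size in tags; background
#'   positions are sized so each library's pooled count marginal follows the
#'   power law and totals approximately `lib_total`.
#' @param bg_positions number of background positions per tissue, or NULL to
#'   derive it from `lib_total` (0 disables background).
#' @param promoter_spacing bp between planted promoter centers within a
#'   gene; must stay above twice the 20-bp clustering framework so planted
#'   promoters remain identifiable.
#' @param seed integer seed (required; identical configs give identical
#'   output).
#' @return a `sim_config` list.
#' @export
sim_config <- function(tissues = c("kidney", "intestine", "heart", "lung",
                                   "bone_marrow", "liver", "brain",
                                   "spleen"),
                       n_genes = 50L,
                       promoters_per_gene = 1:3,
                       promoter_mix = c(0.5, 0.3, 0.2),
                       category_mix = c(non_ubiquitous = 1 / 3,
                                        ubiquitous_uniform = 1 / 3,
                                        ubiquitous_nonuniform = 1 / 3),
                       base_tpm = 15,
                       count_alpha = 1.14,
                       pos_spread = 3,
                       noise = TRUE,
                       lib_total = 1e6,
                       bg_positions = NULL,
                       promoter_spacing = 1200L,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(length(tissues) >= 2L, n_genes >= 1L,
            all(promoters_per_gene %in% 1:8),
            length(promoter_mix) == length(promoters_per_gene),
            abs(sum(category_mix) - 1) < 1e-8, length(category_mix) == 3L,
            base_tpm > 0, count_alpha > 0, pos_spread >= 0, lib_total > 0)
  if (promoter_spacing < 2L * 20L)
    stop("planted promoters closer than twice the 20-bp clustering ",
         "framework would not be identifiable")
  structure(list(tissues = tissues, n_genes = as.integer(n_genes),
                 promoters_per_gene = as.integer(promoters_per_gene),
                 promoter_mix = promoter_mix,
                 category_mix = category_mix, base_tpm = base_tpm,
                 count_alpha = count_alpha, pos_spread = pos_spread,
                 noise = noise, lib_total = lib_total,
                 bg_positions = bg_positions,
                 promoter_spacing = as.integer(promoter_spacing),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Discrete power-law deviates: floor(U^(-1/alpha)) has
# P(X >= x) = x^(-alpha) exactly for integer x >= 1.
rpower_counts <- function(n, alpha, xmax = 1e5) {
  pmin(floor(runif(n)^(-1 / alpha)), xmax)
}

# Discrete Laplace (double-geometric) displacements with scale `spread`.
rdlaplace <- function(n, spread) {
  if (spread <= 0) return(integer(n))
  p <- 1 - exp(-1 / spread)
  stats::rgeom(n, p) - stats::rgeom(n, p)
}

# Expected tissue profile (tpm) for one promoter of a given category.
.draw_profile <- function(category, tissues, base_tpm) {
  k <- length(tissues)
  prof <- numeric(k)
  if (category == "non_ubiquitous") {
    act <- sample.int(k, sample(1:2, 1L))
    prof[act] <- base_tpm * stats::runif(length(act), 0.5, 2)
  } else if (category == "ubiquitous_uniform") {
    prof <- base_tpm * stats::runif(k, 0.7, 1.4)
  } else {
    b <- 0.3 * base_tpm
    prof <- b * stats::runif(k, 0.8, 1.25)
    prof[sample.int(k, 1L)] <- 20 * b
  }
  stats::setNames(prof, tissues)
}

# Per-position counts for one promoter/tissue: power-law counts trimmed to
# the target mass, larger counts placed nearer the center (sharp-peak shape).
.place_tags <- function(mass, center, cfg) {
  if (mass <= 0) return(NULL)
  counts <- integer(0)
  while (sum(counts) < mass)
    counts <- c(counts, rpower_counts(max(8L, ceiling(mass / 4)),
                                      cfg$count_alpha))
  cum <- cumsum(counts)
  last <- which(cum >= mass)[1L]
  counts <- counts[seq_len(last)]
  counts[last] <- counts[last] - (cum[last] - mass)
  counts <- counts[counts > 0L]
  disp <- rdlaplace(length(counts), cfg$pos_spread)
  disp <- disp[order(abs(disp))]
  counts <- sort(counts, decreasing = TRUE)
  dt <- data.table::data.table(pos = center + disp, count = counts)
  dt[, .(count = sum(count)), by = pos]
}

#' Simulate a multi-tissue CAGE experiment with planted ground truth
#'
#' Plants promoters in synthetic genes, draws a tissue expression profile per
#' promoter from the configured breadth-category mix, converts expected tpm
#' into tag masses at the configured library scale, scatters tags around each
#' center with a discrete-Laplace kernel and power-law per-position counts
#' (optionally Poisson-noised), and adds a background of singleton-scale
#' power-law positions on a separate contig so each library's pooled count
#' marginal follows the configured power law. Truth categories are computed
#' by applying the breadth rule to the expected (noise-free) profiles, so
#' category recovery is a well-posed statistic.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, per-tissue CTSS files,
#'   truth TSV, gene GTF and genome FASTA are written there.
#' @return list with `ctss` (named list of CTSS tables per tissue), `truth`
#'   (per-promoter table: `promoter_id`, `gene_id`, `chrom`, `strand`,
#'   `center`, `category`, and one `tpm.<tissue>` column per tissue),
#'   `genes` (list of [gene_model()]), `genome`
#'   (`Biostrings::DNAStringSet` covering the gene contig), and `files`
#'   (paths, when written).
#' @export
simulate_ctss_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, .simulate_ctss_impl(cfg, out_dir))
}

.simulate_ctss_impl <- function(cfg, out_dir) {
  max_k <- max(cfg$promoters_per_gene)
  gene_len <- 600L + cfg$promoter_spacing * max_k
  gene_gap <- 5000L
  pitch <- gene_len + gene_gap

  genes <- vector("list", cfg$n_genes)
  truth_rows <- list()
  thresholds <- breadth_thresholds()
  cats <- names(cfg$category_mix)
  if (is.null(cats)) cats <- c("non_ubiquitous", "ubiquitous_uniform",
                               "ubiquitous_nonuniform")
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%03d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    gstart <- 1000L + (g - 1L) * pitch
    gend <- gstart + gene_len
    genes[[g]] <- .toy_gene(gid, "chr1", strand, gstart, gend,
                            cfg$promoter_spacing)
    n_prom <- cfg$promoters_per_gene[
      sample.int(length(cfg$promoters_per_gene), 1L,
                 prob = cfg$promoter_mix)]
    for (k in seq_len(n_prom)) {
      center <- if (strand == "+")
        gstart + 150L + (k - 1L) * cfg$promoter_spacing
      else gend - 151L - (k - 1L) * cfg$promoter_spacing
      category <- sample(cats, 1L, prob = cfg$category_mix)
      prof <- .draw_profile(category, cfg$tissues, cfg$base_tpm)
      truth_rows[[length(truth_rows) + 1L]] <- c(
        list(promoter_id = sprintf("%s.p%d", gid, k), gene_id = gid,
             chrom = "chr1", strand = strand, center = center,
             category = unname(classify_breadth(prof, thresholds))),
        as.list(stats::setNames(prof, paste0("tpm.", cfg$tissues))))
    }
  }
  truth <- data.table::rbindlist(truth_rows)

  n_bg <- cfg$bg_positions
  if (is.null(n_bg)) {
    s_alpha <- sum(seq_len(1e6)^(-cfg$count_alpha))
    n_bg <- round(cfg$lib_total / s_alpha)
  }
  bg_span <- max(1000L, n_bg * 1000)

  tags_per_tpm <- cfg$lib_total / 1e6
  ctss <- stats::setNames(vector("list", length(cfg$tissues)), cfg$tissues)
  for (t in cfg$tissues) {
    planted <- vector("list", nrow(truth))
    exp_tpm <- truth[[paste0("tpm.", t)]]
    for (i in seq_len(nrow(truth))) {
      m <- exp_tpm[i] * tags_per_tpm
      mass <- if (cfg$noise) stats::rpois(1L, m) else round(m)
      placed <- .place_tags(mass, truth$center[i], cfg)
      if (!is.null(placed)) {
        placed[, `:=`(chrom = "chr1", strand = truth$strand[i])]
        planted[[i]] <- placed
      }
    }
    pieces <- data.table::rbindlist(planted[!vapply(planted, is.null, TRUE)])
    if (n_bg > 0L) {
      bg <- data.table::data.table(
        pos = sample.int(bg_span, n_bg),
        count = as.integer(rpower_counts(n_bg, cfg$count_alpha)),
        chrom = "chrU",
        strand = sample(c("+", "-"), n_bg, replace = TRUE))
      pieces <- data.table::rbindlist(list(pieces, bg), use.names = TRUE)
    }
    ctss[[t]] <- ctss_table(pieces$chrom, pieces$pos, pieces$strand,
                            pieces$count, sample_id = t)
  }

  genome_len <- 1000L + cfg$n_genes * pitch + 1000L
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
          collapse = ""), "chr1"))

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ctss_paths <- file.path(out_dir, paste0(names(ctss), ".ctss"))
    for (i in seq_along(ctss)) write_ctss(ctss[[i]], ctss_paths[i])
    truth_path <- file.path(out_dir, "truth.tsv")
    data.table::fwrite(truth, truth_path, sep = "\t")
    gtf_path <- file.path(out_dir, "genes.gtf")
    write_gtf(genes, gtf_path)
    fa_path <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fa_path)
    files <- list(ctss = stats::setNames(ctss_paths, names(ctss)),
                  truth = truth_path, gtf = gtf_path, fasta = fa_path)
  }
  list(ctss = ctss, truth = truth, genes = genes, genome = genome,
       files = files)
}

# Toy gene: exons tiled at the promoter spacing from the transcript 5' end
# (so planted promoter k sits 150 bp into exon k), CDS starting 250 bases
# into the transcript (so promoter 1 is a 5'UTR promoter and later ones are
# internal).
.toy_gene <- function(gid, chrom, strand, gstart, gend, spacing) {
  if (spacing >= 300L) {
    we <- min(400L, spacing - 100L)        # exon width; intron fills the rest
    n_ex <- (gend - gstart - we) %/% spacing + 1L
    if (strand == "+") {
      s <- gstart + spacing * (seq_len(n_ex) - 1L)
      exons <- cbind(start = s, end = s + we)
    } else {
      e <- gend - spacing * (seq_len(n_ex) - 1L)
      exons <- cbind(start = e - we, end = e)  # rows already 5' to 3'
    }
  } else {
    exons <- cbind(start = gstart, end = gend)
  }
  tx <- transcript_model(gid, paste0(gid, ".t1"), chrom, strand, exons,
                         cds_start = 250L)
  gene_model(gid, chrom, strand, list(tx))
}

#' Write gene models as a GTF file
#'
#' Emits exon and CDS features with gene_id/transcript_id attributes;
#' round-trips through [parse_gtf_transcripts()].
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) for (tx in g$transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id, tx$transcript_id)
    ex <- tx$exons
    lines <- c(lines, sprintf("%s\tcageatlas\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom, ex[, "start"] + 1L, ex[, "end"],
                              tx$strand, attrs))
    if (!is.na(tx$cds_start)) {
      cds <- .cds_genomic_blocks(tx)
      lines <- c(lines, sprintf("%s\tcageatlas\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                tx$chrom, cds[, "start"] + 1L, cds[, "end"],
                                tx$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Genomic blocks (0-based half-open) covered by the CDS of a transcript,
# taken here as everything from cds_start to the transcript 3' end.
.cds_genomic_blocks <- function(tx) {
  ex <- tx$exons
  blocks <- NULL
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    len <- ex[i, "end"] - ex[i, "start"]
    lo <- max(tx$cds_start - off, 0L)      # transcript-relative within exon
    if (lo < len) {
      if (tx$strand == "+") {
        blocks <- rbind(blocks, c(start = ex[i, "start"] + lo,
                                  end = ex[i, "end"]))
      } else {
        blocks <- rbind(blocks, c(start = ex[i, "start"],
                                  end = ex[i, "end"] - lo))
      }
    }
    off <- off + len
  }
  colnames(blocks) <- c("start", "end")
  blocks
}

# ATG-free random background: never emit G right after a trailing "AT".
.atg_free_seq <- function(n) {
  if (n <= 0L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    pool <- c("A", "C", "G", "T")
    if (i >= 3L && out[i - 2L] == "A" && out[i - 1L] == "T")
      pool <- c("A", "C", "T")
    out[i] <- sample(pool, 1L)
  }
  paste(out, collapse = "")
}

# One planted uORF segment of `aa` residues: ATG + (aa-1) alanine codons +
# TAG. The codon set {GCC, GCA, GCT} creates no ATG in any frame, including
# across segment boundaries.
.uorf_segment <- function(aa) {
  fillers <- sample(c("GCC", "GCA", "GCT"), aa - 1L, replace = TRUE)
  paste0("ATG", paste(fillers, collapse = ""), "TAG")
}

#' Simulate a toy 5'UTR locus with planted uORFs and splice junctions
#'
#' Builds a multi-exon gene whose spliced leader contains exactly the planted
#' uORFs (the background sequence is ATG-free by construction) and whose
#' introns are canonical (GT..AG) with probability `canonical_fraction`.
#' The emitted truth lists the expected [find_uorfs()] and
#' [check_canonical_junction()] outputs, making the UTR toolkit testable end
#' to end without external annotation.
#'
#' @param planted_uorf_lengths uORF peptide lengths in amino acids (may be
#'   empty).
#' @param canonical_fraction probability that each junction is canonical.
#' @param leader_length total spliced leader length in bp.
#' @param n_exons number of exons the transcript is split into.
#' @param seed integer seed.
#' @param out_dir optional directory for FASTA/GTF/junction-table output.
#' @return list with `genome`, `genes`, `transcript`, `junctions`
#'   (`intron_id`, `donor_seq` (10 bases), `acceptor_seq` (15 bases),
#'   `canonical`), `truth` (planted uORF lengths, leader length and
#'   sequence), and `files` when written.
#' @export
simulate_utr_locus <- function(planted_uorf_lengths = integer(),
                               canonical_fraction = 1,
                               leader_length = 600L, n_exons = 4L,
                               seed = 1L, out_dir = NULL) {
  stopifnot(all(planted_uorf_lengths >= 1L), n_exons >= 1L,
            canonical_fraction >= 0, canonical_fraction <= 1)
  with_seed(seed, .simulate_utr_impl(as.integer(planted_uorf_lengths),
                                     canonical_fraction,
                                     as.integer(leader_length),
                                     as.integer(n_exons), out_dir))
}

.simulate_utr_impl <- function(uorf_aa, canonical_fraction, leader_length,
                               n_exons, out_dir) {
  seg <- vapply(uorf_aa, .uorf_segment, "")
  seg_len <- nchar(seg)
  if (sum(seg_len) > leader_length)
    stop("infeasible packing: planted uORFs exceed the requested leader ",
         "length")
  n_seg <- length(seg)
  slack <- leader_length - sum(seg_len)
  gaps <- if (n_seg == 0L) slack else {
    cuts <- sort(sample.int(slack + 1L, n_seg, replace = TRUE) - 1L)
    diff(c(0L, cuts, slack))
  }
  parts <- character(0)
  for (i in seq_len(n_seg))
    parts <- c(parts, .atg_free_seq(gaps[i]), seg[i])
  leader <- paste0(paste(parts, collapse = ""),
                   .atg_free_seq(slack - if (n_seg) sum(gaps[seq_len(n_seg)])
                                         else 0L))
  leader <- substr(leader, 1L, leader_length)
  stopifnot(nchar(leader) == leader_length)

  cds <- paste0("ATG", paste(sample(c("GCC", "GCA", "GCT"), 40L,
                                    replace = TRUE), collapse = ""), "TAG")
  trailer <- .atg_free_seq(60L)
  tx_seq <- paste0(leader, cds, trailer)
  tx_len <- nchar(tx_seq)

  cuts <- unique(round(seq(0L, tx_len, length.out = n_exons + 1L)))
  exon_seqs <- substring(tx_seq, head(cuts, -1L) + 1L, cuts[-1L])
  n_introns <- length(exon_seqs) - 1L
  canonical <- if (n_introns > 0L)
    stats::runif(n_introns) <= canonical_fraction else logical(0)
  introns <- vapply(seq_len(n_introns), function(i) {
    core <- .atg_free_seq(80L)
    donor2 <- if (canonical[i]) "GT" else "CT"
    paste0(donor2, core, "AG")
  }, "")

  gpos <- 100L   # 0-based offset of exon 1 on the contig
  exons <- NULL
  genome_parts <- .atg_free_seq(gpos)
  off <- gpos
  for (i in seq_along(exon_seqs)) {
    exons <- rbind(exons, c(start = off, end = off + nchar(exon_seqs[i])))
    genome_parts <- paste0(genome_parts, exon_seqs[i])
    off <- off + nchar(exon_seqs[i])
    if (i <= n_introns) {
      genome_parts <- paste0(genome_parts, introns[i])
      off <- off + nchar(introns[i])
    }
  }
  genome_parts <- paste0(genome_parts, .atg_free_seq(100L))
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_parts, "chrT"))

  tx <- transcript_model("UTRG", "UTRG.t1", "chrT", "+", exons,
                         cds_start = leader_length)
  gene <- gene_model("UTRG", "chrT", "+", list(tx))
  junctions <- data.table::data.table(
    intron_id = seq_len(n_introns),
    donor_seq = substr(introns, 1L, 10L),
    acceptor_seq = substring(introns, nchar(introns) - 14L),
    canonical = canonical)
  truth <- list(uorf_lengths = uorf_aa, leader_length = leader_length,
                leader_seq = leader)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "utr_locus.fa")
    gtf <- file.path(out_dir, "utr_locus.gtf")
    jt <- file.path(out_dir, "junctions.tsv")
    Biostrings::writeXStringSet(genome, fa)
    write_gtf(list(gene), gtf)
    data.table::fwrite(junctions, jt, sep = "\t")
    files <- list(fasta = fa, gtf = gtf, junctions = jt)
  }
  list(genome = genome, genes = list(gene), transcript = tx,
       junctions = junctions, truth = truth, files = files)
}
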