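# Independent brute-force oracles and random-instance generators used across
# the suite. These deliberately avoid the package's own algorithms.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# uORF census by scanning every leader position and translating codon by
# codon with substr() only.
bf_uorfs <- function(leader, downstream = "") {
  full <- paste0(leader, downstream)
  out <- NULL
  for (s in seq_len(nchar(leader))) {
    if (substr(full, s, s + 2L) != "ATG") next
    aa <- 0L; has <- FALSE; p <- s
    while (p + 2L <= nchar(full)) {
      cod <- substr(full, p, p + 2L)
      if (cod %in% STOP_CODONS) { has <- TRUE; break }
      aa <- aa + 1L
      p <- p + 3L
    }
    out <- rbind(out, data.frame(start_offset = s - 1L, aa_length = aa,
                                 has_stop = has))
  }
  out
}

# Longest ORF by enumerating every ATG and its first in-frame stop.
bf_longest_orf <- function(seq) {
  best <- NULL
  for (s in seq_len(max(0L, nchar(seq) - 2L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    p <- s + 3L
    while (p + 2L <= nchar(seq)) {
      cod <- substr(seq, p, p + 2L)
      if (cod %in% STOP_CODONS) {
        len <- p + 2L - s + 1L
        if (is.null(best) || len > best$nt_length)
          best <- list(start_offset = s - 1L, nt_length = len)
        break
      }
      p <- p + 3L
    }
  }
  best
}

# Single-linkage clustering at threshold max_dist via graph connected
# components (igraph), independent of the sorted-gap sweep.
bf_cluster_members <- function(ctss, max_dist) {
  out <- list()
  keys <- unique(ctss[, c("chrom", "strand")])
  for (k in seq_len(nrow(keys))) {
    sub <- ctss[ctss$chrom == keys$chrom[k] & ctss$strand == keys$strand[k], ]
    adj <- abs(outer(sub$pos, sub$pos, `-`)) <= max_dist
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    for (m in split(sub$pos, memb))
      out[[length(out) + 1L]] <- sort(m)
  }
  out[order(vapply(out, `[`, numeric(1), 1L))]
}

# Member position sets of the package's tag clusters.
pkg_cluster_members <- function(ctss, clusters) {
  out <- list()
  for (i in seq_len(nrow(clusters))) {
    m <- ctss$pos[ctss$chrom == clusters$chrom[i] &
                  ctss$strand == clusters$strand[i] &
                  ctss$pos >= clusters$start[i] &
                  ctss$pos < clusters$end[i]]
    out[[i]] <- sort(m)
  }
  out[order(vapply(out, `[`, numeric(1), 1L))]
}

# Direct three-branch breadth rule.
bf_breadth <- function(profile, floor = 0.2, fold = 10) {
  if (median(profile) < floor) return("non_ubiquitous")
  if (max(profile) > fold * median(profile)) return("ubiquitous_nonuniform")
  "ubiquitous_uniform"
}

# Random normalized CTSS table on a couple of chromosomes/strands.
random_ctss <- function(n, span = 3000L, sample_id = "s1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  key <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE))
  pos <- sample.int(span, n, replace = TRUE)
  dup <- duplicated(paste(key$chrom, pos, key$strand))
  ctss_table(key$chrom[!dup], pos[!dup], key$strand[!dup],
             count = sample(1:50, sum(!dup), replace = TRUE),
             tpm = runif(sum(!dup), 0.01, 20), sample_id = sample_id)
}

# Independent greedy nearest-first one-to-one matcher.
bf_match_metrics <- function(atlas, truth, tol_bp = 10) {
  rec_pos <- ifelse(is.na(atlas$dominant_pos),
                    floor((atlas$start + atlas$end - 1) / 2),
                    atlas$dominant_pos)
  cand <- NULL
  for (j in seq_len(nrow(truth))) for (i in seq_len(nrow(atlas))) {
    if (atlas$chrom[i] == truth$chrom[j] &&
        atlas$strand[i] == truth$strand[j] &&
        abs(rec_pos[i] - truth$center[j]) <= tol_bp)
      cand <- rbind(cand, data.frame(i = i, j = j,
                                     d = abs(rec_pos[i] - truth$center[j])))
  }
  used_i <- used_j <- integer(0)
  matches <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$d, cand$j, cand$i), ]
    for (r in seq_len(nrow(cand))) {
      if (cand$i[r] %in% used_i || cand$j[r] %in% used_j) next
      used_i <- c(used_i, cand$i[r]); used_j <- c(used_j, cand$j[r])
      matches <- rbind(matches, cand[r, ])
    }
  }
  nm <- if (is.null(matches)) 0L else nrow(matches)
  list(recall = nm / nrow(truth), precision = nm / nrow(atlas),
       mean_abs_error = if (nm) mean(matches$d) else NA_real_,
       agreement = if (nm)
         mean(atlas$breadth_class[matches$i] == truth$category[matches$j])
       else NA_real_)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
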