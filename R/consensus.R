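#' Aggregate per-sample tag clusters into consensus promoters
#'
#' Tag clusters reaching `tpm_threshold` in at least one sample are projected
#' as their interquantile ranges; ranges on one (chrom, strand) whose gap is
#' at most `agg_dist` are merged transitively, and each consensus span is the
#' union of the merged ranges. Consensus clusters are the operational
#' definition of a promoter: cross-sample aggregations of TSS activity.
#'
#' @param clusters a tag-cluster table from [cluster_ctss()], or a list of
#'   such tables (one per sample). All inputs must share the quantile
#'   convention recorded in their `q_low`/`q_up` attributes.
#' @param tpm_threshold minimum cluster tpm (in any one sample) for a tag
#'   cluster to seed a consensus cluster; 2 tpm by default.
#' @param agg_dist maximum gap (bp) between interquantile ranges merged into
#'   one consensus cluster; 100 bp by default.
#' @return `data.table` with columns `consensus_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open union span), `width`, `n_samples`
#'   (samples contributing a qualifying tag cluster), sorted by
#'   (chrom, strand, start).
#' @export
aggregate_clusters <- function(clusters, tpm_threshold = 2, agg_dist = 100L) {
  if (data.table::is.data.table(clusters)) clusters <- list(clusters)
  conv <- unique(lapply(clusters, function(x)
    c(attr(x, "q_low") %||% NA_real_, attr(x, "q_up") %||% NA_real_)))
  if (length(conv) > 1L)
    stop("mixed quantile conventions across per-sample cluster tables")
  dt <- data.table::rbindlist(clusters, use.names = TRUE)
  empty <- data.table::data.table(
    consensus_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), width = integer(),
    n_samples = integer())
  if (nrow(dt) == 0L) return(empty)
  dt <- dt[total_tpm >= tpm_threshold]
  if (nrow(dt) == 0L) return(empty)
  data.table::setorder(dt, chrom, strand, q_low_pos, q_high_pos)
  # transitive merge on the running maximum of range ends within the key
  dt[, runmax := cummax(q_high_pos), by = .(chrom, strand)]
  prev_max <- c(-Inf, dt$runmax[-nrow(dt)])
  key_change <- c(TRUE, dt$chrom[-1L] != dt$chrom[-nrow(dt)] |
                        dt$strand[-1L] != dt$strand[-nrow(dt)])
  new_grp <- key_change | (dt$q_low_pos - prev_max) > agg_dist
  dt[, grp := cumsum(new_grp)]
  out <- dt[, .(chrom = chrom[1L], strand = strand[1L],
                start = min(q_low_pos), end = max(q_high_pos) + 1L,
                n_samples = data.table::uniqueN(sample_id)), by = grp]
  out[, `:=`(width = end - start, grp = NULL)]
  data.table::setorder(out, chrom, strand, start)
  out[, consensus_id := sprintf("cc%06d", .I)]
  data.table::setcolorder(out, c("consensus_id", "chrom", "strand", "start",
                                 "end", "width", "n_samples"))
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Match CTSS records to the consensus span containing them (spans within one
# (chrom, strand) are disjoint and sorted, so findInterval suffices).
.consensus_hits <- function(consensus, ctss) {
  hits <- vector("list", 0L)
  keys <- unique(consensus[, .(chrom, strand)])
  for (k in seq_len(nrow(keys))) {
    cc <- consensus[chrom == keys$chrom[k] & strand == keys$strand[k]]
    data.table::setorder(cc, start)
    sub <- ctss[chrom == keys$chrom[k] & strand == keys$strand[k]]
    if (nrow(sub) == 0L) next
    idx <- findInterval(sub$pos, cc$start)
    ok <- idx >= 1L & sub$pos < cc$end[pmax(idx, 1L)]
    if (!any(ok)) next
    hits[[length(hits) + 1L]] <- data.table::data.table(
      consensus_id = cc$consensus_id[idx[ok]],
      sample_id = sub$sample_id[ok], pos = sub$pos[ok], tpm = sub$tpm[ok],
      strand = keys$strand[k])
  }
  if (!length(hits)) return(data.table::data.table(
    consensus_id = character(), sample_id = character(), pos = integer(),
    tpm = numeric(), strand = character()))
  data.table::rbindlist(hits)
}

#' Cross-tissue expression matrix for consensus clusters
#'
#' Expression of a consensus cluster in a tissue is the sum of that tissue's
#' normalized CTSS signal falling within the consensus span on the matching
#' strand; this recomputation from CTSS (rather than summing member tag
#' clusters) captures sub-threshold signal in tissues where the promoter is
#' weak, which the median-based breadth classification needs.
#'
#' @param consensus consensus table from [aggregate_clusters()].
#' @param ctss_tables list of normalized CTSS tables, one per tissue.
#' @return numeric matrix with one row per `consensus_id` and one column per
#'   tissue (0 where a tissue has no tags in the span).
#' @export
expression_matrix <- function(consensus, ctss_tables) {
  tissues <- vapply(ctss_tables, function(x)
    if (nrow(x)) x$sample_id[1L] else NA_character_, "")
  if (!is.null(names(ctss_tables))) tissues <- names(ctss_tables)
  if (anyDuplicated(stats::na.omit(tissues)))
    stop("tissue label collision in CTSS tables")
  mat <- matrix(0, nrow = nrow(consensus), ncol = length(ctss_tables),
                dimnames = list(consensus$consensus_id, tissues))
  if (nrow(consensus) == 0L) return(mat)
  hits <- .consensus_hits(consensus, data.table::rbindlist(ctss_tables))
  if (nrow(hits)) {
    agg <- hits[, .(tpm = sum(tpm)), by = .(consensus_id, sample_id)]
    mat[cbind(match(agg$consensus_id, rownames(mat)),
              match(agg$sample_id, colnames(mat)))] <- agg$tpm
  }
  mat
}

#' Pooled dominant position of each consensus cluster
#'
#' The position with the maximal tpm pooled across all tissues; ties are
#' broken toward the transcript 5' end.
#'
#' @inheritParams expression_matrix
#' @return integer vector named by `consensus_id` (NA where no CTSS falls in
#'   the span).
#' @export
consensus_dominant <- function(consensus, ctss_tables) {
  out <- stats::setNames(rep(NA_integer_, nrow(consensus)),
                         consensus$consensus_id)
  hits <- .consensus_hits(consensus, data.table::rbindlist(ctss_tables))
  if (nrow(hits) == 0L) return(out)
  pooled <- hits[, .(tpm = sum(tpm)), by = .(consensus_id, pos, strand)]
  data.table::setorder(pooled, consensus_id, pos)
  pooled[, mxv := max(tpm), by = consensus_id]
  pooled <- pooled[tpm >= mxv - abs(mxv) * 1e-12]
  dom <- pooled[, .(pos = if (strand[1L] == "-") pos[.N] else pos[1L]),
                by = consensus_id]
  out[dom$consensus_id] <- dom$pos
  out
}
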