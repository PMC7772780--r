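#' Cluster CTSS positions into per-sample tag clusters
#'
#' Strand-aware single-linkage distance clustering: within each
#' (chrom, strand), consecutive CTSS whose positional gap is at most
#' `max_dist` are merged transitively, so adjacent clusters are separated by
#' more than `max_dist`. Each cluster carries its genomic span, dominant
#' (maximal-tpm) position, total tpm and the positions of the `q_low`/`q_up`
#' cumulative-signal quantiles whose distance is the interquantile width, a
#' robust promoter width.
#'
#' @param ctss normalized CTSS table (the `tpm` column must be set; see
#'   [normalize_to_reference()]).
#' @param max_dist maximum gap (bp) between successive CTSS merged into one
#'   cluster; 20 bp by default.
#' @param q_low,q_up cumulative-signal quantiles bounding the interquantile
#'   range (defaults 0.1 and 0.9).
#' @return a `data.table` of tag clusters sorted by (chrom, strand, start)
#'   with columns `sample_id`, `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), `dominant_pos`, `total_tpm`, `q_low_pos`, `q_high_pos`,
#'   `iq_width`, `n_ctss`. The quantile convention is recorded in the
#'   `q_low`/`q_up` attributes.
#' @export
cluster_ctss <- function(ctss, max_dist = 20L, q_low = 0.1, q_up = 0.9) {
  stopifnot(max_dist >= 0, q_low > 0, q_up > q_low, q_up <= 1)
  if (nrow(ctss) == 0L) return(.empty_cluster_table(q_low, q_up))
  if (anyNA(ctss$tpm))
    stop("tpm unset: normalize the CTSS table before clustering")
  dt <- data.table::as.data.table(ctss)
  data.table::setorder(dt, sample_id, chrom, strand, pos)
  new_grp <- c(TRUE,
               dt$sample_id[-1L] != dt$sample_id[-nrow(dt)] |
               dt$chrom[-1L] != dt$chrom[-nrow(dt)] |
               dt$strand[-1L] != dt$strand[-nrow(dt)] |
               (dt$pos[-1L] - dt$pos[-nrow(dt)]) > max_dist)
  dt[, grp := cumsum(new_grp)]
  out <- .summarize_clusters(dt, q_low, q_up)
  data.table::setorder(out, chrom, strand, start)
  data.table::setattr(out, "q_low", q_low)
  data.table::setattr(out, "q_up", q_up)
  out[]
}

.empty_cluster_table <- function(q_low, q_up) {
  out <- data.table::data.table(
    sample_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), dominant_pos = integer(),
    total_tpm = numeric(), q_low_pos = integer(), q_high_pos = integer(),
    iq_width = integer(), n_ctss = integer())
  data.table::setattr(out, "q_low", q_low)
  data.table::setattr(out, "q_up", q_up)
  out
}

# Vectorized per-cluster summaries: no per-group closures so that millions of
# mostly-singleton clusters stay fast (grouped sum/max use data.table gforce,
# running sums use the global-cumsum-minus-offset trick).
.summarize_clusters <- function(dt, q_low, q_up) {
  first <- !duplicated(dt$grp)
  sizes <- tabulate(dt$grp)
  dt[, total_tpm := sum(tpm), by = grp]
  dt[, mxv := max(tpm), by = grp]
  gcs <- cumsum(dt$tpm)
  base <- rep((gcs - dt$tpm)[first], sizes)
  cs <- gcs - base
  eps <- 1e-9 * dt$total_tpm
  pick_first <- function(flag) {
    idx <- which(flag)
    idx[!duplicated(dt$grp[idx])]
  }
  qlow_idx <- pick_first(cs >= q_low * dt$total_tpm - eps)
  qup_idx <- pick_first(cs >= q_up * dt$total_tpm - eps)
  # dominant: maximal tpm; ties broken toward the transcript 5' end
  # (first position on '+', last on '-')
  idx <- which(dt$tpm >= dt$mxv - abs(dt$mxv) * 1e-12)
  dom_first <- idx[!duplicated(dt$grp[idx])]
  dom_last <- idx[!duplicated(dt$grp[idx], fromLast = TRUE)]
  dom_idx <- ifelse(dt$strand[first] == "-", dom_last, dom_first)
  out <- data.table::data.table(
    sample_id = dt$sample_id[first],
    chrom = dt$chrom[first],
    strand = dt$strand[first],
    start = dt$pos[first],
    end = dt$pos[cumsum(sizes)] + 1L,
    dominant_pos = dt$pos[dom_idx],
    total_tpm = dt$total_tpm[first],
    q_low_pos = dt$pos[qlow_idx],
    q_high_pos = dt$pos[qup_idx],
    n_ctss = sizes)
  out[, iq_width := q_high_pos - q_low_pos + 1L]
  data.table::setcolorder(out, c("sample_id", "chrom", "strand", "start",
                                 "end", "dominant_pos", "total_tpm",
                                 "q_low_pos", "q_high_pos", "iq_width",
                                 "n_ctss"))
  out
}

#' Signal quantile positions of one tag cluster
#'
#' The low (high) quantile position is the smallest member position at which
#' the running tpm sum reaches `q_low` (`q_up`) of the cluster total.
#'
#' @param pos member CTSS positions (will be ordered).
#' @param tpm member tpm values aligned with `pos`.
#' @param q_low,q_up quantiles in (0, 1], `q_low < q_up`.
#' @return list with `q_low_pos`, `q_high_pos` and `iq_width`
#'   (`q_high_pos - q_low_pos + 1`).
#' @export
compute_quantiles <- function(pos, tpm, q_low = 0.1, q_up = 0.9) {
  if (length(pos) == 0L) stop("empty cluster member list")
  stopifnot(length(pos) == length(tpm), all(tpm >= 0), sum(tpm) > 0)
  o <- order(pos)
  pos <- pos[o]; tpm <- tpm[o]
  total <- sum(tpm)
  cs <- cumsum(tpm)
  eps <- 1e-9 * total
  ql <- pos[which(cs >= q_low * total - eps)[1L]]
  qh <- pos[which(cs >= q_up * total - eps)[1L]]
  list(q_low_pos = ql, q_high_pos = qh, iq_width = qh - ql + 1L)
}
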