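#' Pipeline configuration
#'
#' Central home for every numeric threshold of the promoter-atlas pipeline:
#' the reference power law (alpha 1.14, T = 1e7), the 20-bp TSS clustering
#' framework, the 0.1-0.9 signal quantiles, the 2-tpm consensus threshold
#' with 100-bp aggregation distance, and the breadth rule (0.2-tpm median
#' floor, 10x fold).
#'
#' @param alpha_ref,total_T reference power law (see [norm_config()]).
#' @param fit_min_count smallest raw count entering the per-sample fit.
#' @param max_dist TSS clustering distance (bp).
#' @param q_low,q_up interquantile bounds.
#' @param tpm_threshold,agg_dist consensus aggregation parameters.
#' @param median_floor,fold breadth-classification thresholds.
#' @param upstream_flank gene-assignment upstream flank (bp).
#' @param bootstrap_B pseudoreplicates for downstream bootstrap analyses.
#' @param seed global seed; stages derive child seeds via [derive_seed()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha_ref = 1.14, total_T = 1e7,
                            fit_min_count = 2L, max_dist = 20L,
                            q_low = 0.1, q_up = 0.9, tpm_threshold = 2,
                            agg_dist = 100L, median_floor = 0.2, fold = 10,
                            upstream_flank = 500L, bootstrap_B = 100L,
                            seed = 1L) {
  stopifnot(alpha_ref > 0, total_T > 0, max_dist > 0, q_low > 0,
            q_low < q_up, q_up <= 1, tpm_threshold > 0, agg_dist > 0,
            median_floor > 0, fold > 1, upstream_flank >= 0,
            bootstrap_B >= 1)
  structure(list(alpha_ref = alpha_ref, total_T = total_T,
                 fit_min_count = as.integer(fit_min_count),
                 max_dist = as.integer(max_dist), q_low = q_low, q_up = q_up,
                 tpm_threshold = tpm_threshold,
                 agg_dist = as.integer(agg_dist),
                 median_floor = median_floor, fold = fold,
                 upstream_flank = as.integer(upstream_flank),
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the promoter-atlas pipeline end to end
#'
#' normalize -> cluster -> consensus -> expression -> atlas. The pipeline is
#' a pure function of its inputs and configuration: repeated runs produce
#' identical results.
#'
#' @param ctss named list of CTSS tables (one per tissue), or a named
#'   character vector of CTSS file paths.
#' @param genes list of [gene_model()] objects, or a GTF path.
#' @param genome optional `Biostrings::DNAStringSet` or FASTA path (enables
#'   promoter GC content).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given the normalized CTSS,
#'   per-sample cluster BED6, consensus TSV/BED6, promoter atlas TSV and a
#'   run log are written there.
#' @return list with `atlas` (promoter table incl. `dominant_pos`),
#'   `consensus`, `expression` (matrix), `clusters` (per-sample tag-cluster
#'   tables), `fits` (per-sample power-law fits) and `config`.
#' @export
run_pipeline <- function(ctss, genes, genome = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(ctss)) {
    if (is.null(names(ctss))) stop("ctss paths must be named by tissue")
    ctss <- .stage("read_ctss", mapply(read_ctss, ctss, names(ctss),
                                       SIMPLIFY = FALSE))
  }
  if (length(ctss) < 2L)
    stop("pipeline stage 'input' failed: at least 2 tissues are required ",
         "(expression breadth is undefined for a single tissue)",
         call. = FALSE)
  if (is.character(genes)) genes <- .stage("parse_gtf",
                                           parse_gtf_transcripts(genes))

  ncfg <- norm_config(config$alpha_ref, config$total_T, config$fit_min_count)
  fits <- .stage("normalize", lapply(ctss, fit_power_law, config = ncfg))
  normalized <- .stage("normalize", mapply(
    normalize_to_reference, ctss, fits,
    MoreArgs = list(config = ncfg), SIMPLIFY = FALSE))

  clusters <- .stage("cluster", lapply(
    normalized, cluster_ctss, max_dist = config$max_dist,
    q_low = config$q_low, q_up = config$q_up))

  consensus <- .stage("consensus", aggregate_clusters(
    clusters, tpm_threshold = config$tpm_threshold,
    agg_dist = config$agg_dist))
  expr <- .stage("expression", expression_matrix(consensus, normalized))
  dom <- .stage("expression", consensus_dominant(consensus, normalized))

  atlas <- .stage("atlas", build_promoter_atlas(
    consensus, expr, genes, genome = genome,
    thresholds = breadth_thresholds(config$median_floor, config$fold),
    upstream_flank = config$upstream_flank))
  atlas[, dominant_pos := dom[atlas$consensus_id]]

  if (!is.null(out_dir)) .write_pipeline_outputs(out_dir, normalized,
                                                 clusters, consensus, atlas,
                                                 config)
  list(atlas = atlas[], consensus = consensus, expression = expr,
       clusters = clusters, fits = fits, config = config)
}

.write_pipeline_outputs <- function(out_dir, normalized, clusters,
                                    consensus, atlas, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (t in names(normalized))
    write_ctss(normalized[[t]], file.path(out_dir,
                                          paste0(t, ".normalized.ctss")))
  for (t in names(clusters)) {
    cl <- clusters[[t]]
    if (nrow(cl))
      export_bed6(data.table::data.table(
        chrom = cl$chrom, start = cl$start, end = cl$end,
        name = sprintf("%s:%d", t, seq_len(nrow(cl))),
        score = cl$total_tpm, strand = cl$strand),
        file.path(out_dir, paste0(t, ".clusters.bed")))
  }
  data.table::fwrite(consensus, file.path(out_dir, "consensus.tsv"),
                     sep = "\t")
  if (nrow(consensus))
    export_bed6(data.table::data.table(
      chrom = consensus$chrom, start = consensus$start,
      end = consensus$end, name = consensus$consensus_id,
      score = rep(0, nrow(consensus)), strand = consensus$strand),
      file.path(out_dir, "consensus.bed"))
  data.table::fwrite(atlas, file.path(out_dir, "promoter_atlas.tsv"),
                     sep = "\t")
  log_lines <- c(
    sprintf("cageatlas run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("config: %s", paste(sprintf("%s=%s", names(unclass(config)),
                                        unlist(config)), collapse = " ")),
    sprintf("samples: %d", length(normalized)),
    sprintf("ctss records: %d",
            sum(vapply(normalized, nrow, integer(1)))),
    sprintf("tag clusters: %d", sum(vapply(clusters, nrow, integer(1)))),
    sprintf("consensus clusters: %d", nrow(consensus)),
    sprintf("assigned promoters: %d", sum(!is.na(atlas$gene_id))))
  writeLines(log_lines, file.path(out_dir, "run.log"))
}

#' Score a recovered promoter atlas against planted truth
#'
#' Matches recovered promoters (by pooled dominant position) to planted
#' centers within `tol_bp`, one-to-one nearest-first, and reports recall over
#' planted promoters, precision over recovered clusters, mean absolute
#' position error over matches, and the fraction of matches whose recovered
#' breadth class equals the planted category. A run with no planted
#' promoters and an empty atlas scores 1.0 on all metrics (vacuously
#' perfect).
#'
#' @param atlas promoter table from [run_pipeline()] (needs `dominant_pos`).
#' @param truth planted-truth table from [simulate_ctss_experiment()].
#' @param tol_bp matching tolerance in bp (default 10).
#' @return list with `n_truth`, `n_recovered`, `n_matched`, `recall`,
#'   `precision`, `mean_abs_error`, `category_agreement` and the `matches`
#'   table.
#' @export
score_against_truth <- function(atlas, truth, tol_bp = 10L) {
  n_truth <- nrow(truth); n_rec <- nrow(atlas)
  if (n_truth == 0L && n_rec == 0L) {
    return(list(n_truth = 0L, n_recovered = 0L, n_matched = 0L,
                recall = 1, precision = 1, mean_abs_error = 0,
                category_agreement = 1,
                matches = data.table::data.table()))
  }
  rec_pos <- atlas$dominant_pos
  rec_pos[is.na(rec_pos)] <-
    floor((atlas$start + atlas$end - 1L) / 2)[is.na(rec_pos)]
  pairs <- list()
  for (j in seq_len(n_truth)) {
    cand <- which(atlas$chrom == truth$chrom[j] &
                  atlas$strand == truth$strand[j] &
                  abs(rec_pos - truth$center[j]) <= tol_bp)
    if (length(cand))
      pairs[[length(pairs) + 1L]] <- data.table::data.table(
        rec = cand, tru = j,
        dist = abs(rec_pos[cand] - truth$center[j]))
  }
  matches <- data.table::data.table(rec = integer(), tru = integer(),
                                    dist = numeric())
  if (length(pairs)) {
    all_pairs <- data.table::rbindlist(pairs)
    data.table::setorder(all_pairs, dist, tru, rec)
    used_rec <- logical(n_rec); used_tru <- logical(n_truth)
    keep_rows <- logical(nrow(all_pairs))
    for (r in seq_len(nrow(all_pairs))) {
      i <- all_pairs$rec[r]; j <- all_pairs$tru[r]
      if (!used_rec[i] && !used_tru[j]) {
        used_rec[i] <- TRUE; used_tru[j] <- TRUE; keep_rows[r] <- TRUE
      }
    }
    matches <- all_pairs[keep_rows]
  }
  n_matched <- nrow(matches)
  agreement <- if (n_matched)
    mean(atlas$breadth_class[matches$rec] == truth$category[matches$tru])
  else NA_real_
  list(n_truth = n_truth, n_recovered = n_rec, n_matched = n_matched,
       recall = if (n_truth) n_matched / n_truth else 1,
       precision = if (n_rec) n_matched / n_rec else 1,
       mean_abs_error = if (n_matched) mean(matches$dist) else NA_real_,
       category_agreement = agreement, matches = matches)
}
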