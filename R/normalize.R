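#' Normalization configuration
#'
#' Houses the reference power law used to make CAGE libraries of different
#' depths comparable: tag counts are rank-matched onto a law whose
#' reverse-cumulative distribution has slope `alpha_ref` and whose implied
#' total tag count is `total_T`, then expressed as tags per million (tpm).
#' The defaults (alpha 1.14, T = 1e7) are the reference constants used for
#' FANTOM5-scale libraries; downstream thresholds (2 tpm consensus floor,
#' 0.2 tpm breadth floor) assume this scale.
#'
#' @param alpha_ref slope of the reference reverse-cumulative power law.
#' @param total_T implied total tag count of the reference law.
#' @param fit_min_count smallest raw count entering the per-sample fit;
#'   singleton positions dominate CAGE libraries and bias the slope, so the
#'   default fits counts >= 2.
#' @param ref_xmax upper limit of the discrete summation that anchors the
#'   reference intercept.
#' @return a `norm_config` list.
#' @export
norm_config <- function(alpha_ref = 1.14, total_T = 1e7, fit_min_count = 2L,
                        ref_xmax = 1e6) {
  stopifnot(alpha_ref > 0, total_T > 0, fit_min_count >= 1)
  structure(list(alpha_ref = alpha_ref, total_T = total_T,
                 fit_min_count = as.integer(fit_min_count),
                 ref_xmax = ref_xmax),
            class = "norm_config")
}

# Intercept c_ref of the reference law revcum(x) = c_ref * x^(-alpha_ref),
# chosen so its implied total tag count equals total_T. For integer counts
# the total equals sum over x of revcum(x) (Abel summation), evaluated by
# discrete summation over 1..ref_xmax.
reference_intercept <- function(config) {
  x <- seq_len(config$ref_xmax)
  config$total_T / sum(x^(-config$alpha_ref))
}

#' Fit a power law to a sample's tag-count distribution
#'
#' Least squares of log10 reverse-cumulative counts on log10 count over the
#' distinct raw counts >= `fit_min_count`, where `revcum(x)` is the number of
#' positions with count >= x; each distinct count is weighted by the number
#' of positions observed at it, so the sparse high-count staircase does not
#' dominate the slope. The fitted law is `revcum(x) ~ c_s * x^(-alpha_s)`.
#'
#' @param ctss CTSS table with raw counts (see [read_ctss()]).
#' @param config a [norm_config()].
#' @return a `power_law_fit` list with `alpha_s`, `c_s`, `fit_range`,
#'   `n_points`.
#' @export
fit_power_law <- function(ctss, config = norm_config()) {
  fit_power_law_values(ctss$count, min_value = config$fit_min_count)
}

#' Fit a power law to arbitrary positive signal values
#'
#' Lower-level engine behind [fit_power_law()]; also usable to refit
#' normalized (non-integer) signal when checking the normalization contract.
#'
#' @param values positive signal values (raw counts or rescaled tpm).
#' @param min_value smallest value entering the fit.
#' @return a `power_law_fit` list.
#' @export
fit_power_law_values <- function(values, min_value = 2) {
  values <- values[values >= min_value]
  r <- rle(sort(values))
  x <- r$values
  if (length(x) < 2L)
    stop("degenerate power-law fit: fewer than 2 distinct values >= ",
         min_value)
  # revcum(x_i) = number of retained positions with value >= x_i
  revcum <- rev(cumsum(rev(r$lengths)))
  fit <- stats::lm(log10(revcum) ~ log10(x), weights = r$lengths)
  alpha_s <- -unname(stats::coef(fit)[2L])
  c_s <- 10^unname(stats::coef(fit)[1L])
  if (!is.finite(alpha_s) || alpha_s <= 0)
    stop("degenerate power-law fit: non-positive slope")
  structure(list(alpha_s = alpha_s, c_s = c_s,
                 fit_range = range(x), n_points = length(x)),
            class = "power_law_fit")
}

#' Map raw tag counts onto the reference power law
#'
#' Each raw count x is rank-matched onto the reference law:
#' `z(x) = (c_s * x^(-alpha_s) / c_ref)^(-1/alpha_ref)`, i.e. the value at
#' which the reference law has the same reverse-cumulative count as the
#' fitted sample law has at x. The normalized signal is reported as tags per
#' million of the reference total: `tpm = z * 1e6 / total_T`. The mapping is
#' strictly increasing in x, so within-sample rank order is preserved
#' exactly; records and coordinates are unchanged.
#'
#' @param ctss CTSS table the fit was computed from.
#' @param fit a `power_law_fit` from [fit_power_law()].
#' @param config a [norm_config()].
#' @return the CTSS table with the `tpm` column filled.
#' @export
normalize_to_reference <- function(ctss, fit, config = norm_config()) {
  if (!inherits(fit, "power_law_fit"))
    stop("normalize_to_reference requires a power_law_fit")
  out <- data.table::copy(ctss)
  out[, tpm := normalized_tpm(count, fit, config)]
  out[]
}

#' Closed-form count-to-tpm mapping under a fitted and a reference law
#'
#' @param x raw counts (positive numeric).
#' @param fit a `power_law_fit`.
#' @param config a [norm_config()].
#' @return normalized signal in tags per million.
#' @export
normalized_tpm <- function(x, fit, config = norm_config()) {
  c_ref <- reference_intercept(config)
  z <- (fit$c_s * x^(-fit$alpha_s) / c_ref)^(-1 / config$alpha_ref)
  z * 1e6 / config$total_T
}
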