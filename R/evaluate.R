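# Replicate-level evaluation metrics: type I error, power at empirical
# alpha, localization.

#' Empirical type I error with exact binomial confidence interval
#'
#' @param null_p P-values from null-model replicates.
#' @param alpha Nominal level (default 0.05). A replicate counts as a false
#'   positive when `p < alpha` (strict).
#' @return List with `rate`, `n`, and `ci` (exact binomial 95% CI).
#' @export
type_i_error <- function(null_p, alpha = 0.05) {
  if (length(null_p) == 0L) stop("empty p-value vector", call. = FALSE)
  k <- sum(null_p < alpha)
  ci <- stats::binom.test(k, length(null_p))$conf.int
  list(rate = k / length(null_p), n = length(null_p), ci = as.numeric(ci))
}

#' Power at an empirical type I error rate
#'
#' For a fair comparison across test procedures with different finite-sample
#' calibration, the rejection threshold is set at the empirical
#' `alpha`-quantile of null-replicate p-values (lower order-statistic
#' convention: the `floor(alpha * n)`-th smallest null p-value), and power
#' is the fraction of alternative-replicate p-values at or below that
#' threshold.
#'
#' @param null_p P-values from null-model replicates.
#' @param alt_p P-values from alternative-model replicates.
#' @param alpha Target type I error rate (default 0.05).
#' @return List with `power`, `threshold`, `alpha`, and the replicate
#'   counts.
#' @export
empirical_power <- function(null_p, alt_p, alpha = 0.05) {
  if (length(null_p) == 0L || length(alt_p) == 0L)
    stop("empty p-value vector", call. = FALSE)
  k <- max(1L, floor(alpha * length(null_p)))
  threshold <- sort(null_p)[k]
  list(power = mean(alt_p <= threshold), threshold = threshold,
       alpha = alpha, n_null = length(null_p), n_alt = length(alt_p))
}

#' Localization rate over replicates
#'
#' Fraction of replicate outcomes whose best (minimum corrected p) window
#' or tied window set half-overlapped the causal sub-region (see
#' [localize()]). Replicates without a causal sub-region count as not
#' localized.
#'
#' @param localized Logical vector of per-replicate localization flags
#'   (`NA` treated as `FALSE`).
#' @return Fraction in `[0, 1]`.
#' @export
localization_rate <- function(localized) {
  if (length(localized) == 0L) stop("no outcomes", call. = FALSE)
  mean(localized %in% TRUE)
}

#' Summarize a sliding-window study by window size
#'
#' Aggregates replicate outcomes into a per-window-size table of detection
#' power and localization rate. Sizes analyzed in fewer than `min_reps`
#' replicates (e.g., sizes longer than most replicates' variant counts) are
#' excluded from the summary.
#'
#' @param outcomes Data frame of replicate outcomes with columns `size`,
#'   `detected` (logical), and optionally `localized` (logical) and
#'   `min_p_corrected`.
#' @param min_reps Minimum number of analyzable replicates for a size to be
#'   reported (default 700).
#' @return Data frame with columns `size`, `n_reps`, `power`, and
#'   `localization_rate` (NA when no localization flags are present).
#' @export
summarize_window_sizes <- function(outcomes, min_reps = 700) {
  if (nrow(outcomes) == 0L) stop("no outcomes", call. = FALSE)
  sizes <- sort(unique(outcomes$size))
  rows <- lapply(sizes, function(s) {
    o <- outcomes[outcomes$size == s, , drop = FALSE]
    if (nrow(o) < min_reps) return(NULL)
    data.frame(size = s, n_reps = nrow(o), power = mean(o$detected),
               localization_rate = if (is.null(o$localized)) NA_real_
                                   else localization_rate(o$localized))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(size = integer(), n_reps = integer(),
                      power = numeric(), localization_rate = numeric())
  out
}

#' Map causal variant indices into an analysis index range
#'
#' Given the identifiers of the variants actually analyzed (in order) and
#' the identifiers of the causal variants, returns the 0-based half-open
#' interval of analysis indices spanned by the causal set, suitable as
#' `causal_range` for [localize()]. Returns `NULL` when no causal variant
#' was analyzed.
#'
#' @param analysis_ids Character vector of analyzed variant ids, in window
#'   index order (e.g., `dmaf_scan()$variant_ids`).
#' @param causal_ids Character vector of causal variant ids.
#' @return Length-2 integer vector `[start, stop)` or `NULL`.
#' @export
causal_index_range <- function(analysis_ids, causal_ids) {
  idx <- which(analysis_ids %in% causal_ids)
  if (length(idx) == 0L) return(NULL)
  c(min(idx) - 1L, max(idx))
}
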