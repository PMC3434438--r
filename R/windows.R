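# Sliding-window scan with step-down permutation multiple-test correction.

#' Enumerate sliding windows over a variant index range
#'
#' Windows are defined in variant-index space (numbers of consecutive SNVs,
#' not base pairs) as 0-based half-open intervals `[start, stop)`. Windows
#' start at 0 and advance by `max(5, round(0.10 * window_size))` variants
#' (round half up); if the last regular window stops short of the region
#' end, one final window anchored at `n_variants - window_size` is appended
#' so every variant belongs to at least one window.
#'
#' @param n_variants Number of analysis variants.
#' @param window_size Window length in variants, between 1 and `n_variants`.
#' @return Data frame with columns `start`, `stop` (0-based half-open) and
#'   `size`, in genomic order without duplicates.
#' @examples
#' enumerate_windows(30, 10)   # step 5
#' enumerate_windows(250, 100) # step 10 (10% of the window length)
#' @export
enumerate_windows <- function(n_variants, window_size) {
  n_variants <- as.integer(n_variants)
  window_size <- as.integer(window_size)
  if (window_size < 1L) stop("'window_size' must be positive", call. = FALSE)
  if (window_size > n_variants)
    stop("window size (", window_size, ") exceeds the number of analysis ",
         "variants (", n_variants, "): region too small", call. = FALSE)
  step <- max(5L, as.integer(round_half_up(0.10 * window_size)))
  starts <- seq.int(0L, n_variants - window_size, by = step)
  if (max(starts) + window_size < n_variants)
    starts <- c(starts, n_variants - window_size)
  starts <- sort(unique(starts))
  data.frame(start = starts, stop = starts + window_size, size = window_size)
}

# Empirical p of each value in `x` against a reference null sample:
# p = #{null >= x} / length(null).
emp_p <- function(x, null_sorted) {
  B <- length(null_sorted)
  (B - findInterval(x, null_sorted, left.open = TRUE)) / B
}

# Core of the two-set permutation construction, reused by dmaf_scan().
# V: m windows x (1 + B1 + B2) statistics (column 1 observed, then the two
# shared permutation sets). Second-set p-values are referenced to each
# window's first-set null distribution.
pvalue_matrix_from_stats <- function(V, B1, B2) {
  m <- nrow(V)
  V_obs <- V[, 1L]
  p_obs <- numeric(m)
  M <- matrix(0, m, B2)
  for (i in seq_len(m)) {
    null_i <- sort.int(V[i, 1L + seq_len(B1)], method = "quick")
    p_obs[i] <- emp_p(V_obs[i], null_i)
    M[i, ] <- emp_p(V[i, 1L + B1 + seq_len(B2)], null_i)
  }
  list(p_obs = p_obs, M = M, statistic = V_obs)
}

#' Window-level permutation p-value matrix
#'
#' Runs the two-permutation-set construction behind the step-down
#' correction. A first set of `B1` shared phenotype relabelings (the same
#' relabeling applied to every window) yields each window's null
#' distribution of the DMAF statistic and the observed empirical p-value. A
#' second, independent set of `B2` shared relabelings is then evaluated
#' against each window's first-set null distribution, filling the m x B2
#' p-value matrix `M` whose column minima drive [stepdown_correct()].
#'
#' @inheritParams dmaf_test
#' @param windows Data frame from [enumerate_windows()] (columns `start`,
#'   `stop`, 0-based half-open, indexing the columns of `genotypes` after
#'   monomorphic variants are dropped).
#' @param B1,B2 Sizes of the two permutation sets (defaults 1000).
#' @return List with `p_obs` (observed empirical p per window), `M` (m x B2
#'   matrix) and `statistic` (observed V per window).
#' @export
build_pvalue_matrix <- function(genotypes, status, windows,
                                flavor = c("abs", "sq"),
                                B1 = 1000, B2 = 1000, seed = NULL) {
  flavor <- match.arg(flavor)
  counts <- as_counts(genotypes)
  status <- check_status(status, nrow(counts))
  if (B1 < 1L || B2 < 1L) stop("'B1' and 'B2' must be >= 1", call. = FALSE)

  stats <- variant_stats(counts, status)
  keep <- which(stats$polymorphic)
  ori <- orient_minor(counts)
  w <- dmaf_weights(stats[keep, ])

  P <- with_seed(seed, perm_matrix(status, B1 + B2))
  C <- dmaf_contrib(ori$counts[, keep, drop = FALSE], P, w, flavor)
  V <- window_stats(C, windows)
  pvalue_matrix_from_stats(V, B1, B2)
}

# Window sums of the contribution matrix via a cumulative-sum trick.
window_stats <- function(C, windows) {
  CS <- apply(C, 2L, cumsum)
  if (is.null(dim(CS))) CS <- matrix(CS, nrow = 1L)
  CS0 <- rbind(0, CS)
  CS0[windows$stop + 1L, , drop = FALSE] -
    CS0[windows$start + 1L, , drop = FALSE]
}

#' Step-down permutation multiple-test correction
#'
#' Westfall-Young style step-down correction across the windows of one size.
#' Observed p-values are sorted ascending and the rows of `M` reordered
#' identically. The smallest p-value is compared against the column minima
#' of the full `M`: its corrected value is the proportion of minima strictly
#' smaller. The top row is then removed, the column minima recomputed, and
#' for `j > 1` the corrected value is
#' `max(corrected[j-1], #\{M_min < p_(j)\} / B2)`, which enforces
#' monotonicity. Results are returned in the original window order.
#'
#' @param observed_p Numeric vector of observed empirical p-values, length m.
#' @param M m x B2 permutation p-value matrix (see [build_pvalue_matrix()]).
#' @return Numeric vector of corrected p-values, original window order.
#' @examples
#' stepdown_correct(c(0.05, 0.35),
#'                  rbind(c(0.2, 0.5, 0.1), c(0.4, 0.3, 0.6)))
#' @export
stepdown_correct <- function(observed_p, M) {
  M <- as.matrix(M)
  m <- length(observed_p)
  if (nrow(M) != m)
    stop("nrow(M) must equal length(observed_p)", call. = FALSE)
  B2 <- ncol(M)
  ord <- order(observed_p)
  Ms <- M[ord, , drop = FALSE]
  # suffix column minima: minima over rows j..m of the sorted matrix
  suf <- Ms
  if (m > 1L)
    for (i in (m - 1L):1L) suf[i, ] <- pmin(suf[i, ], suf[i + 1L, ])
  p_sorted <- observed_p[ord]
  corr <- vapply(seq_len(m),
                 function(j) sum(suf[j, ] < p_sorted[j]) / B2, numeric(1))
  corr <- cummax(corr)
  out <- numeric(m)
  out[ord] <- corr
  out
}

#' Sliding-window DMAF scan
#'
#' Enumerates sliding windows for each requested window size, computes the
#' DMAF statistic and its permutation p-value per window, and applies the
#' step-down correction across the windows of each size. Both permutation
#' sets are shared across windows (one phenotype relabeling per column),
#' which the column-minimum construction requires; no correction is applied
#' across the different window sizes.
#'
#' @inheritParams dmaf_test
#' @param window_sizes Integer vector of window lengths (in variants).
#'   Sizes exceeding the number of analysis variants are skipped with a
#'   message.
#' @param variants `"all"` (default) or `"rare"`: the variant filter applied
#'   before windowing.
#' @param B1,B2 First/second permutation set sizes (defaults 1000).
#' @param alpha Significance level for the per-size detection flag
#'   (default 0.05).
#' @return An object of class `dmaf_scan`: a list with `results` (one data
#'   frame per analyzed size: window coordinates in variant-index and
#'   base-pair space, statistic, `p_raw`, `p_corrected`), `detected` (named
#'   logical per size: any corrected p < alpha), `analysis_index` (columns
#'   of the input matrix analyzed), `variant_ids`, `positions`, and the call
#'   parameters.
#' @seealso [localize()], [stepdown_correct()]
#' @export
dmaf_scan <- function(genotypes, status, window_sizes, variants = "all",
                      rare_threshold = 0.05, flavor = c("abs", "sq"),
                      B1 = 1000, B2 = 1000, alpha = 0.05, seed = NULL) {
  flavor <- match.arg(flavor)
  gm <- if (inherits(genotypes, "genotype_matrix")) genotypes
        else genotype_matrix(genotypes)
  counts <- gm$counts
  status <- check_status(status, nrow(counts))

  stats <- variant_stats(counts, status, rare_threshold)
  keep <- resolve_variant_set(variants, stats, rare_threshold)
  ori <- orient_minor(counts)
  w <- dmaf_weights(stats[keep, ])
  Jk <- length(keep)

  P <- with_seed(seed, perm_matrix(status, B1 + B2))
  C <- dmaf_contrib(ori$counts[, keep, drop = FALSE], P, w, flavor)

  results <- list()
  detected <- logical(0)
  skipped <- integer(0)
  for (size in sort(unique(as.integer(window_sizes)))) {
    if (size > Jk) {
      message("skipping window size ", size, ": only ", Jk,
              " analysis variants")
      skipped <- c(skipped, size)
      next
    }
    wins <- enumerate_windows(Jk, size)
    V <- window_stats(C, wins)
    pm <- pvalue_matrix_from_stats(V, B1, B2)
    p_corr <- stepdown_correct(pm$p_obs, pm$M)
    res <- data.frame(
      window = seq_len(nrow(wins)),
      start = wins$start, stop = wins$stop,
      start_variant = wins$start + 1L, stop_variant = wins$stop,
      start_bp = gm$positions[keep][wins$start + 1L],
      stop_bp = gm$positions[keep][wins$stop],
      statistic = pm$statistic, p_raw = pm$p_obs, p_corrected = p_corr)
    results[[as.character(size)]] <- res
    detected[as.character(size)] <- any(p_corr < alpha)
  }
  if (length(results) == 0L)
    stop("no window size could be analyzed", call. = FALSE)

  structure(list(results = results, detected = detected,
                 sizes = as.integer(names(results)), skipped = skipped,
                 analysis_index = keep,
                 variant_ids = gm$variant_ids[keep],
                 positions = gm$positions[keep],
                 n_variants = Jk, variants = variants, flavor = flavor,
                 B1 = B1, B2 = B2, alpha = alpha, seed = seed),
            class = "dmaf_scan")
}

#' @export
print.dmaf_scan <- function(x, ...) {
  cat(sprintf("Sliding-window DMAF_%s scan: %d analysis variants (%s)\n",
              x$flavor, x$n_variants, x$variants))
  cat(sprintf("  permutations: B1 = %d, B2 = %d; alpha = %g\n",
              x$B1, x$B2, x$alpha))
  for (s in names(x$results)) {
    r <- x$results[[s]]
    best <- which.min(r$p_corrected)
    cat(sprintf(
      "  size %3s: %3d windows, min corrected p = %.4g at variants %d-%d%s\n",
      s, nrow(r), r$p_corrected[best], r$start_variant[best],
      r$stop_variant[best],
      if (x$detected[[s]]) "  *" else ""))
  }
  if (length(x$skipped))
    cat("  skipped sizes (region too small):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dmaf_scan <- function(object, ...) {
  do.call(rbind, lapply(names(object$results), function(s) {
    r <- object$results[[s]]
    best <- which.min(r$p_corrected)
    data.frame(size = as.integer(s), n_windows = nrow(r),
               min_p_corrected = r$p_corrected[best],
               best_start = r$start_variant[best],
               best_stop = r$stop_variant[best],
               detected = object$detected[[s]], row.names = NULL)
  }))
}

#' Plot a sliding-window scan
#'
#' Plots `-log10` corrected p-values against window midpoint (in kb), one
#' line per window size.
#'
#' @param x A `dmaf_scan` object.
#' @param ... Further arguments passed to [graphics::matplot()]-style base
#'   plotting (ignored except `main`).
#' @export
plot.dmaf_scan <- function(x, ...) {
  sizes <- names(x$results)
  cols <- grDevices::hcl.colors(max(3L, length(sizes)), "Dark 3")
  args <- list(...)
  main <- if (!is.null(args$main)) args$main else "Sliding-window DMAF scan"
  ylim <- c(0, max(1, vapply(x$results, function(r)
    max(-log10(pmax(r$p_corrected, 1 / x$B2))), numeric(1))))
  xlim <- range(x$positions) / 1000
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "Position (kb)",
                 ylab = expression(-log[10] ~ "corrected p"), main = main)
  for (i in seq_along(sizes)) {
    r <- x$results[[sizes[i]]]
    mid <- (r$start_bp + r$stop_bp) / 2000
    graphics::lines(mid, -log10(pmax(r$p_corrected, 1 / x$B2)),
                    col = cols[i], type = "b", pch = 16, cex = 0.5)
  }
  graphics::abline(h = -log10(x$alpha), lty = 2, col = "grey40")
  graphics::legend("topright", legend = paste("size", sizes),
                   col = cols[seq_along(sizes)], lty = 1, bty = "n")
  invisible(x)
}

#' Localization of the best window against a causal sub-region
#'
#' Takes the window (or tied set of windows) attaining the minimum corrected
#' p-value; the span of a tied set is the union extent from the smallest
#' start to the largest stop. Returns `TRUE` when the overlap between that
#' span and the causal range, measured in markers, is at least half the
#' span's length (boundary inclusive).
#'
#' @param results Data frame for one window size from [dmaf_scan()] (needs
#'   columns `start`, `stop`, `p_corrected`; 0-based half-open intervals in
#'   analysis-variant index space).
#' @param causal_range Length-2 vector, the causal sub-region as a 0-based
#'   half-open index interval `[start, stop)` in the same index space.
#'   `NULL` or an empty interval returns `FALSE`.
#' @return Logical.
#' @examples
#' r <- data.frame(start = c(10, 30), stop = c(20, 40),
#'                 p_corrected = c(0.01, 0.5))
#' localize(r, c(15, 40))  # overlap 5 = half of 10 -> TRUE
#' @export
localize <- function(results, causal_range) {
  if (nrow(results) == 0L) stop("empty results", call. = FALSE)
  if (is.null(causal_range) || diff(causal_range) <= 0) return(FALSE)
  best <- which(results$p_corrected == min(results$p_corrected))
  span <- c(min(results$start[best]), max(results$stop[best]))
  len <- span[2] - span[1]
  ov <- max(0, min(span[2], causal_range[2]) - max(span[1], causal_range[1]))
  ov >= len / 2
}
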