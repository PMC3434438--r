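# Per-variant frequency summaries and MAF-based weights.

# Orient a counts matrix to the minor allele (pooled frequency <= 0.5).
# Returns the oriented matrix plus pooled MAF q, non-missing subject count n,
# which columns were flipped, and which are polymorphic.
orient_minor <- function(counts) {
  nm <- !is.na(counts)
  n_j <- colSums(nm)
  alt <- colSums(counts, na.rm = TRUE)
  p <- ifelse(n_j > 0, alt / (2 * n_j), 0)
  flip <- p > 0.5
  if (any(flip)) counts[, flip] <- 2L - counts[, flip]
  q <- pmin(p, 1 - p)
  q[n_j == 0] <- 0
  list(counts = counts, q = q, n = n_j, flipped = flip, poly = q > 0)
}

#' Per-variant case/control minor allele frequencies
#'
#' Computes, for every variant, the case MAF `X`, control MAF `Y`, pooled MAF
#' `q`, the number of subjects with a non-missing genotype `n`, and flags for
#' rarity and polymorphism. Frequencies are computed over non-missing
#' genotypes within each group, and the minor allele is oriented by the
#' pooled (cases + controls) frequency, so `q <= 0.5`. Monomorphic variants
#' (`q == 0`, including all-missing columns) are flagged `polymorphic =
#' FALSE` and must be excluded before weighting.
#'
#' @param genotypes A [genotype_matrix()] or a subjects x variants count
#'   matrix.
#' @param status Binary phenotype vector (1 = case, 0 = control), aligned to
#'   the subject order of `genotypes`.
#' @param rare_threshold Pooled-MAF threshold at or below which a variant is
#'   flagged rare (default 0.05).
#'
#' @return A data frame with one row per variant: `variant_id`, `X`, `Y`,
#'   `q`, `n`, `rare`, `polymorphic`.
#' @seealso [dmaf_weights()], [classify_rare()], [dmaf_test()]
#' @examples
#' g <- rbind(c(1, 0), c(1, 0), c(0, 0), c(0, 0))
#' variant_stats(g, c(1, 1, 0, 0))
#' @export
variant_stats <- function(genotypes, status, rare_threshold = 0.05) {
  counts <- as_counts(genotypes)
  if (ncol(counts) == 0L)
    stop("genotype matrix has no variants", call. = FALSE)
  status <- check_status(status, nrow(counts))
  ori <- orient_minor(counts)
  oc <- ori$counts
  case <- status == 1L

  nm <- !is.na(oc)
  n_case <- colSums(nm[case, , drop = FALSE])
  n_ctrl <- colSums(nm[!case, , drop = FALSE])
  a_case <- colSums(oc[case, , drop = FALSE], na.rm = TRUE)
  a_ctrl <- colSums(oc[!case, , drop = FALSE], na.rm = TRUE)
  X <- ifelse(n_case > 0, a_case / (2 * n_case), NA_real_)
  Y <- ifelse(n_ctrl > 0, a_ctrl / (2 * n_ctrl), NA_real_)

  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(counts)))
  data.frame(variant_id = ids, X = X, Y = Y, q = ori$q, n = ori$n,
             rare = ori$poly & ori$q <= rare_threshold,
             polymorphic = ori$poly, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' MAF-based variant weights
#'
#' The weight for variant `j` is `w_j = 1 / sqrt(n_j * q_j * (1 - q_j))`,
#' where `n_j` is the number of subjects genotyped at the variant and `q_j`
#' its pooled MAF. Rarer variants receive larger weights; the weight diverges
#' as `q -> 0`, so monomorphic variants must be removed first.
#'
#' @param stats Data frame from [variant_stats()] (or any data frame with
#'   numeric columns `q` and `n`).
#' @return Numeric vector of strictly positive, finite weights.
#' @examples
#' dmaf_weights(data.frame(q = 0.25, n = 4))  # 1/sqrt(4*0.25*0.75)
#' @export
dmaf_weights <- function(stats) {
  q <- stats$q
  n <- stats$n
  if (any(q <= 0 | q >= 1))
    stop("monomorphic variant (q = 0 or 1) passed to dmaf_weights(); ",
         "exclude non-polymorphic variants first", call. = FALSE)
  1 / sqrt(n * q * (1 - q))
}

#' Select rare variants by pooled MAF
#'
#' @param stats Data frame from [variant_stats()].
#' @param threshold Pooled-MAF cutoff in (0, 0.5]; a variant is rare when
#'   `q <= threshold` (boundary inclusive). Default 0.05.
#' @return Integer vector of variant indices (polymorphic variants only).
#' @export
classify_rare <- function(stats, threshold = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 0.5)
    stop("'threshold' must be a single value in (0, 0.5]", call. = FALSE)
  which(stats$polymorphic & stats$q <= threshold)
}
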