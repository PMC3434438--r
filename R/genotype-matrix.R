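#' Construct a genotype matrix
#'
#' The basic data unit consumed by every test in the package: a subjects x
#' variants matrix of diploid minor/alternate allele counts (0, 1, 2), with
#' `NA` for missing genotypes, together with sample identifiers, variant
#' identifiers and base-pair positions.
#'
#' @param counts Integer matrix, subjects in rows, variants in columns.
#'   Non-missing entries must be 0, 1 or 2.
#' @param sample_ids Character vector of unique subject identifiers
#'   (default: row names of `counts`, or `ind1, ind2, ...`).
#' @param variant_ids Character vector of unique variant identifiers
#'   (default: column names of `counts`, or `v1, v2, ...`).
#' @param positions Numeric vector of 1-based base-pair coordinates, one per
#'   variant, nondecreasing. Defaults to `1:J`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `counts`, `sample_ids`, `variant_ids` and `positions`.
#' @examples
#' g <- genotype_matrix(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, NA)))
#' g
#' @export
genotype_matrix <- function(counts, sample_ids = NULL, variant_ids = NULL,
                            positions = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0L) stop("genotype matrix has no variants", call. = FALSE)
  if (nrow(counts) == 0L) stop("genotype matrix has no subjects", call. = FALSE)
  storage.mode(counts) <- "integer"
  bad <- !is.na(counts) & !(counts == 0L | counts == 1L | counts == 2L)
  if (any(bad))
    stop("genotype counts must be 0, 1, 2 or NA; found ",
         paste(unique(counts[bad]), collapse = ", "), call. = FALSE)

  if (is.null(sample_ids)) sample_ids <- rownames(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(counts)))
  if (is.null(variant_ids)) variant_ids <- colnames(counts)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  variant_ids <- as.character(variant_ids)
  if (length(sample_ids) != nrow(counts))
    stop("sample_ids length does not match rows of counts", call. = FALSE)
  if (length(variant_ids) != ncol(counts))
    stop("variant_ids length does not match columns of counts", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique", call. = FALSE)

  if (is.null(positions)) positions <- seq_len(ncol(counts))
  positions <- as.numeric(positions)
  if (length(positions) != ncol(counts))
    stop("positions length does not match columns of counts", call. = FALSE)
  if (is.unsorted(positions))
    stop("positions must be nondecreasing", call. = FALSE)

  dimnames(counts) <- list(sample_ids, variant_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 variant_ids = variant_ids, positions = positions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$counts), "subjects x", ncol(x$counts),
      "variants\n")
  miss <- mean(is.na(x$counts))
  cat(sprintf("  positions %g..%g bp, %.2f%% missing genotypes\n",
              min(x$positions), max(x$positions), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

# Coerce inputs accepted by user-facing functions to a plain counts matrix.
as_counts <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) return(genotypes$counts)
  m <- as.matrix(genotypes)
  storage.mode(m) <- "integer"
  m
}
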