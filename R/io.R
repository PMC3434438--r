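# Readers and writers: VCF genotypes, ms-format haplotypes, phenotype
# tables, result tables.

#' Read a VCF into a genotype matrix
#'
#' Parses diploid GT fields to alternate-allele counts (0/1/2); `./.` and
#' `.` become missing. Phased separators are treated like unphased ones.
#' Multiallelic records (comma in ALT) are skipped with a warning by
#' default. Sample order is preserved.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param multiallelic `"skip"` (default) or `"error"`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L)
    stop("VCF contains no variant records: ", path, call. = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2L)
    stop("VCF contains no sample genotypes: ", path, call. = FALSE)

  multi <- grepl(",", v@fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multiallelic record(s) in ", path, call. = FALSE)
    warning("skipping ", sum(multi), " multiallelic record(s)")
    v <- v[!multi, ]
    if (nrow(v@fix) == 0L)
      stop("no biallelic variants left after filtering", call. = FALSE)
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "./." = NA_integer_, "." = NA_integer_, "./1" = NA_integer_,
           "1/." = NA_integer_, "0/." = NA_integer_, "./0" = NA_integer_)
  vals <- lut[gt]
  unknown <- !(gt %in% names(lut)) & !is.na(gt)
  if (any(unknown))
    stop("unsupported GT value(s): ",
         paste(utils::head(unique(gt[unknown]), 5), collapse = ", "),
         call. = FALSE)
  counts <- t(matrix(vals, nrow = nrow(gt), ncol = ncol(gt)))

  pos <- as.numeric(v@fix[, "POS"])
  ids <- v@fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(v@fix[noid, "CHROM"], ":", v@fix[noid, "POS"])
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_matrix(counts, sample_ids = colnames(gt), variant_ids = ids,
                  positions = pos)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCF 4.2 with GT-only FORMAT and placeholder
#' REF/ALT alleles (`A`/`T`); counts 0/1/2 become `0/0`, `0/1`, `1/1` and
#' missing becomes `./.`. Round-trips through [read_vcf()].
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @param chrom Chromosome label (default `"1"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, chrom = "1") {
  gm <- if (inherits(genotypes, "genotype_matrix")) genotypes
        else genotype_matrix(genotypes)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  counts <- gm$counts
  body <- matrix("./.", nrow = ncol(counts), ncol = nrow(counts))
  ok <- !is.na(counts)
  body[t(ok)] <- gt_code[as.character(t(counts)[t(ok)])]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=dmafscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t"),
    paste(chrom, format(gm$positions, scientific = FALSE, trim = TRUE),
          gm$variant_ids, "A", "T", ".", ".", ".", "GT",
          apply(body, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read ms-format haplotypes
#'
#' Parses the classic coalescent-simulator text format: replicate blocks
#' introduced by `//`, a `segsites:` count, a `positions:` line of relative
#' coordinates in `[0, 1]`, and one 0/1 row per chromosome. Positions are
#' scaled to base pairs by the region length (rounded; coordinates are made
#' strictly increasing by bumping rounding collisions). Consecutive
#' haplotype pairs form diploid individuals.
#'
#' @param path Path to an ms-format file.
#' @param length_bp Region length used to scale relative positions to bp.
#' @return A [region_pool()], or a list of pools when the file holds
#'   several replicate blocks.
#' @export
read_ms <- function(path, length_bp) {
  lines <- readLines(path)
  seg_idx <- grep("^segsites:", lines)
  if (length(seg_idx) == 0L)
    stop("no 'segsites:' line found in ", path, call. = FALSE)
  pools <- lapply(seg_idx, function(i) {
    J <- as.integer(sub("^segsites:\\s*", "", lines[i]))
    if (J == 0L)
      stop("replicate with zero segregating sites in ", path, call. = FALSE)
    if (!grepl("^positions:", lines[i + 1L]))
      stop("missing 'positions:' line after segsites in ", path,
           call. = FALSE)
    rel <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "",
                                          lines[i + 1L])), "\\s+")[[1L]])
    if (length(rel) != J)
      stop("positions count does not match segsites in ", path,
           call. = FALSE)
    rest <- lines[seq.int(i + 2L, length(lines))]
    is_hap <- grepl("^[01]+$", rest)
    block_end <- which(!is_hap)
    hap <- if (length(block_end)) rest[seq_len(block_end[1L] - 1L)] else rest
    if (length(hap) == 0L) stop("no haplotype rows in ", path, call. = FALSE)
    if (any(nchar(hap) != J))
      stop("haplotype row length does not match segsites in ", path,
           call. = FALSE)
    H <- matrix(utf8ToInt(paste(hap, collapse = "")) - 48L,
                ncol = J, byrow = TRUE)
    pos <- round(rel * length_bp)
    pos[pos < 1] <- 1
    if (J > 1L)                      # break rounding ties, keep increasing
      for (k in 2:J) if (pos[k] <= pos[k - 1L]) pos[k] <- pos[k - 1L] + 1
    region_pool(H, pos, length_bp)
  })
  if (length(pools) == 1L) pools[[1L]] else pools
}

#' Write a haplotype pool in ms format
#'
#' @param pool A [region_pool()] (haplotypes must be present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(pool, path) {
  if (is.null(pool$haplotypes)) stop("pool has no haplotypes", call. = FALSE)
  H <- pool$haplotypes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ms %d 1", nrow(H)),
               format(pool$seed %||% 0), "", "//",
               sprintf("segsites: %d", ncol(H)),
               paste("positions:",
                     paste(format(pool$positions / pool$length_bp,
                                  digits = 8, scientific = FALSE,
                                  trim = TRUE), collapse = " "))), con)
  writeLines(apply(H, 1L, paste, collapse = ""), con)
  invisible(path)
}

#' Read a phenotype table aligned to genotype samples
#'
#' Expects a tab-separated file with columns `sample_id` and `status`
#' (0/1). Rows are aligned to the supplied sample order by id, not file
#' order; samples missing a phenotype, or phenotype rows without a
#' genotyped sample, are errors that name the offending ids.
#'
#' @param path Path to the TSV file.
#' @param sample_ids Genotype sample order to align to.
#' @return Integer 0/1 status vector aligned to `sample_ids`.
#' @export
read_phenotype <- function(path, sample_ids) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(tab)))
    stop("phenotype file must have columns 'sample_id' and 'status'",
         call. = FALSE)
  tab$sample_id <- as.character(tab$sample_id)
  extra <- setdiff(tab$sample_id, sample_ids)
  if (length(extra))
    stop("phenotype rows without genotyped sample: ",
         paste(utils::head(extra, 10), collapse = ", "), call. = FALSE)
  miss <- setdiff(sample_ids, tab$sample_id)
  if (length(miss))
    stop("samples without phenotype: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  status <- tab$status[match(sample_ids, tab$sample_id)]
  if (!all(status %in% c(0, 1)))
    stop("phenotype status must be binary 0/1", call. = FALSE)
  as.integer(status)
}

#' Write a phenotype table
#'
#' @param status 0/1 status vector.
#' @param sample_ids Sample identifiers.
#' @param path Output path (TSV with columns `sample_id`, `status`).
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(status, sample_ids, path) {
  utils::write.table(data.frame(sample_id = sample_ids, status = status),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dichotomize a quantitative phenotype at its median
#'
#' Values strictly above the median become 1 ("resistant"-style upper
#' half), values at or below the median become 0; exact ties at the median
#' therefore go to the lower group. For an even number of distinct values
#' this yields an exact 50/50 split.
#'
#' @param values Numeric vector with no missing values.
#' @return Integer 0/1 vector.
#' @examples
#' dichotomize_median(c(1, 2, 3, 4))  # 0 0 1 1
#' @export
dichotomize_median <- function(values) {
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  if (length(unique(values)) < 2L)
    stop("constant phenotype cannot be split", call. = FALSE)
  as.integer(values > stats::median(values))
}

#' Write test or scan results as TSV
#'
#' `write_test_tsv()` appends/writes a one-row summary of a [dmaf_test()];
#' `write_scan_tsv()` writes the per-window table of one window size from a
#' [dmaf_scan()] (1-based inclusive variant coordinates plus bp spans).
#'
#' @param x A `dmaf_test` or `dmaf_scan` object.
#' @param path Output path.
#' @param size Window size to export (for scans).
#' @return `path`, invisibly.
#' @export
write_test_tsv <- function(x, path) {
  row <- data.frame(
    variant_set = paste0(length(x$variant_set), " variants"),
    flavor = x$flavor, n_variants = length(x$variant_set),
    statistic = unname(x$statistic), p_value = x$p.value,
    n_perm = x$n_perm, seed = x$seed %||% NA)
  utils::write.table(row, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_test_tsv
#' @export
write_scan_tsv <- function(x, path, size = x$sizes[1L]) {
  r <- x$results[[as.character(size)]]
  if (is.null(r)) stop("size ", size, " not in scan results", call. = FALSE)
  out <- data.frame(window_index = r$window,
                    start_variant = r$start_variant,
                    stop_variant = r$stop_variant,
                    start_bp = r$start_bp, stop_bp = r$stop_bp,
                    statistic = r$statistic, p_raw = r$p_raw,
                    p_corrected = r$p_corrected)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
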