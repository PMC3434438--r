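# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# With seed = NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# round() uses banker's rounding; window steps need deterministic half-up.
round_half_up <- function(x) floor(x + 0.5)

# Derive k reproducible sub-seeds (< 2^31) from one user seed.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

check_status <- function(status, n_subjects) {
  status <- as.integer(status)
  if (length(status) != n_subjects)
    stop("phenotype length (", length(status), ") does not match number of subjects (",
         n_subjects, ")", call. = FALSE)
  if (anyNA(status) || !all(status %in% c(0L, 1L)))
    stop("phenotype status must be binary 0/1 with no missing values", call. = FALSE)
  if (sum(status) == 0L || sum(status) == length(status))
    stop("need at least one case and one control", call. = FALSE)
  status
}
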