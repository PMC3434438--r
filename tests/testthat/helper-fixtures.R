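# Fixtures and independent oracles shared across the test files.

# Random genotype matrix with allele frequencies drawn to include rare and
# common variants; optional missingness.
rand_genotypes <- function(n, J, miss = 0, maf_range = c(0.02, 0.4)) {
  f <- runif(J, maf_range[1], maf_range[2])
  g <- vapply(f, function(p) rbinom(n, 2L, p), integer(n))
  if (miss > 0) g[runif(length(g)) < miss] <- NA_integer_
  g
}

balanced_status <- function(n) rep(c(1L, 0L), length.out = n)

# Independent brute-force DMAF statistic: no shared code with the package
# internals (direct frequency arithmetic per group).
brute_V <- function(g, status, flavor = "abs", set = seq_len(ncol(g))) {
  V <- 0
  for (j in set) {
    x <- g[, j]
    nm <- !is.na(x)
    p_all <- sum(x[nm]) / (2 * sum(nm))
    xx <- if (p_all > 0.5) 2 - x else x
    q <- min(p_all, 1 - p_all)
    if (q == 0) next
    ca <- xx[status == 1 & nm]
    co <- xx[status == 0 & nm]
    X <- sum(ca) / (2 * length(ca))
    Y <- sum(co) / (2 * length(co))
    w <- 1 / sqrt(sum(nm) * q * (1 - q))
    d <- X - Y
    V <- V + w * (if (flavor == "abs") abs(d) else d^2)
  }
  V
}

# Exact permutation p-value by exhaustive enumeration of all case
# assignments (for small n).
exact_perm_p <- function(g, status, flavor = "abs") {
  n <- length(status)
  k <- sum(status)
  V_obs <- brute_V(g, status, flavor)
  sets <- utils::combn(n, k)
  Vs <- apply(sets, 2, function(idx) {
    st <- integer(n)
    st[idx] <- 1L
    brute_V(g, st, flavor)
  })
  mean(Vs >= V_obs)
}

# Small synthetic haplotype pool constructed directly (no engine).
toy_pool <- function(n_dip = 300, J = 60, length_bp = 5e4, seed = 99) {
  withr::with_seed(seed, {
    f <- exp(runif(J, log(0.002), log(0.45)))
    H <- vapply(f, function(p) rbinom(2 * n_dip, 1L, p), integer(2 * n_dip))
    pos <- sort(sample.int(length_bp, J))
    suppressWarnings(region_pool(H, pos, length_bp))
  })
}
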