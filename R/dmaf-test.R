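# DMAF statistic and its permutation test.

# Per-variant, per-permutation weighted contributions to the statistic.
#
# counts: oriented subjects x J matrix (NA allowed); perms: subjects x B
# matrix whose columns are 0/1 case-indicator vectors (column 1 is usually
# the observed phenotype); w: length-J weights. Returns the J x B matrix
# C[j, b] = w_j * D_j under relabeling b, where D_j = |X_j - Y_j| (abs) or
# (X_j - Y_j)^2 (sq), with group MAFs computed over non-missing genotypes.
# Weights, orientation and q are those of the observed data and are held
# fixed across permutations (they are phenotype-free).
dmaf_contrib <- function(counts, perms, w, flavor = c("abs", "sq")) {
  flavor <- match.arg(flavor)
  has_na <- anyNA(counts)
  G0 <- counts
  if (has_na) G0[is.na(G0)] <- 0L
  storage.mode(G0) <- "double"
  storage.mode(perms) <- "double"

  a_case <- crossprod(G0, perms)          # J x B case minor-allele counts
  a_tot <- colSums(G0)
  if (has_na) {
    Z <- matrix(1, nrow(counts), ncol(counts))
    Z[is.na(counts)] <- 0
    n_case <- crossprod(Z, perms)         # non-missing cases per variant/perm
    n_ctrl <- colSums(Z) - n_case
    d <- a_case / (2 * n_case) - (a_tot - a_case) / (2 * n_ctrl)
    # a group with no genotyped subjects carries no frequency information
    d[n_case == 0 | n_ctrl == 0] <- 0
  } else {
    nc <- colSums(perms)
    nu <- nrow(counts) - nc
    d <- sweep(a_case, 2, 2 * nc, "/") -
      sweep(sweep(a_case, 1, a_tot, "-"), 2, -2 * nu, "/")
  }
  D <- if (flavor == "abs") abs(d) else d * d
  D * w
}

# One observed column plus n_perm uniform relabelings of the status vector.
perm_matrix <- function(status, n_perm) {
  P <- matrix(0, length(status), n_perm + 1L)
  P[, 1L] <- status
  for (b in seq_len(n_perm)) P[, b + 1L] <- sample(status)
  P
}

resolve_variant_set <- function(variants, stats, rare_threshold) {
  poly <- which(stats$polymorphic)
  if (is.character(variants)) {
    variants <- match.arg(variants, c("all", "rare"))
    set <- if (variants == "all") poly else classify_rare(stats, rare_threshold)
  } else {
    set <- as.integer(variants)
    if (any(is.na(set)) || any(set < 1L) || any(set > nrow(stats)))
      stop("variant indices out of range", call. = FALSE)
    dropped <- setdiff(set, poly)
    if (length(dropped))
      set <- intersect(set, poly)
  }
  if (length(set) == 0L)
    stop("no polymorphic variants left to test after filtering", call. = FALSE)
  sort(unique(set))
}

#' DMAF test statistic for a fixed variant set
#'
#' `V = sum_{j in A} w_j D_j`, where `D_j = |X_j - Y_j|` (`flavor = "abs"`)
#' or `(X_j - Y_j)^2` (`flavor = "sq"`), `A` the set of variants of interest.
#'
#' @param stats Data frame from [variant_stats()].
#' @param weights Weights from [dmaf_weights()] computed on the polymorphic
#'   subset, or a vector aligned to the rows of `stats` (entries outside the
#'   variant set are ignored).
#' @param variant_set Integer indices (rows of `stats`) to aggregate over;
#'   must be nonempty and polymorphic.
#' @param flavor `"abs"` or `"sq"`.
#' @return The nonnegative statistic `V`.
#' @examples
#' g <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
#' s <- variant_stats(g, c(1, 1, 0, 0))
#' dmaf_statistic(s, dmaf_weights(s), 1:2)
#' @export
dmaf_statistic <- function(stats, weights, variant_set,
                           flavor = c("abs", "sq")) {
  flavor <- match.arg(flavor)
  if (length(variant_set) == 0L)
    stop("empty variant set: nothing to test", call. = FALSE)
  variant_set <- as.integer(variant_set)
  if (!all(stats$polymorphic[variant_set]))
    stop("variant set contains monomorphic variants", call. = FALSE)
  d <- stats$X[variant_set] - stats$Y[variant_set]
  D <- if (flavor == "abs") abs(d) else d * d
  sum(weights[variant_set] * D)
}

#' DMAF permutation test
#'
#' Region-based case-control association test aggregating the per-variant
#' difference in minor allele frequency between cases and controls. The
#' statistic `V` (see [dmaf_statistic()]) weights each variant by
#' `1/sqrt(n_j q_j (1-q_j))`, so rare variants contribute more. Significance
#' is assessed by permuting case-control labels: group frequencies `X_j`,
#' `Y_j` are recomputed under each relabeling while the pooled MAF,
#' orientation and weights stay fixed at their observed (phenotype-free)
#' values.
#'
#' The default empirical p-value is `#\{V_perm >= V_obs\} / n_perm` (ties
#' count as extreme, so `p = 0` is possible); `plus_one = TRUE` switches to
#' the `(r + 1)/(n + 1)` convention.
#'
#' @param genotypes A [genotype_matrix()] or counts matrix.
#' @param status Binary phenotype (1 = case, 0 = control).
#' @param variants `"all"` (default), `"rare"`, or explicit variant indices.
#'   Monomorphic variants are always dropped.
#' @param rare_threshold Pooled-MAF cutoff used when `variants = "rare"`.
#' @param flavor `"abs"` (default) or `"sq"`.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional integer seed; a fixed seed makes the result
#'   bit-reproducible.
#' @param plus_one Use the `(r + 1)/(n + 1)` p-value convention.
#' @return An object of classes `dmaf_test` and `htest` with the statistic,
#'   `p.value`, permutation count, the analyzed variant indices
#'   (`$variant_set`) and the permutation null statistics (`$null_dist`).
#' @examples
#' set.seed(1)
#' g <- matrix(rbinom(200, 2, 0.1), nrow = 20)
#' dmaf_test(g, rep(c(1, 0), each = 10), n_perm = 200, seed = 42)
#' @export
dmaf_test <- function(genotypes, status, variants = "all",
                      rare_threshold = 0.05, flavor = c("abs", "sq"),
                      n_perm = 1000, seed = NULL, plus_one = FALSE) {
  flavor <- match.arg(flavor)
  counts <- as_counts(genotypes)
  status <- check_status(status, nrow(counts))
  if (n_perm < 1L) stop("'n_perm' must be at least 1", call. = FALSE)

  stats <- variant_stats(counts, status, rare_threshold)
  set <- resolve_variant_set(variants, stats, rare_threshold)
  ori <- orient_minor(counts)
  w_all <- rep(NA_real_, ncol(counts))
  w_all[stats$polymorphic] <- dmaf_weights(stats[stats$polymorphic, ])

  P <- with_seed(seed, perm_matrix(status, n_perm))
  C <- dmaf_contrib(ori$counts[, set, drop = FALSE], P, w_all[set], flavor)
  V <- colSums(C)
  V_obs <- V[1L]
  V_null <- V[-1L]
  p <- if (plus_one) (sum(V_null >= V_obs) + 1) / (n_perm + 1)
       else sum(V_null >= V_obs) / n_perm

  structure(list(
    statistic = c(V = V_obs), p.value = p,
    parameter = c(n_perm = n_perm, n_variants = length(set)),
    method = sprintf("DMAF_%s permutation test (%s variants)", flavor,
                     if (is.character(variants)) variants else "selected"),
    data.name = sprintf("%d cases, %d controls, %d variants analyzed",
                        sum(status), sum(status == 0L), length(set)),
    flavor = flavor, variant_set = set, n_perm = n_perm, seed = seed,
    null_dist = V_null, variant_stats = stats
  ), class = c("dmaf_test", "htest"))
}

#' SKAT-style score statistic (verification oracle)
#'
#' Computes `Q = sum_j w_j * (g_j' (y - ybar))^2`, the covariate-free score
#' form of the sequence kernel association test statistic. With equal case
#' and control counts and shared weights, `Q` is exactly proportional to the
#' DMAF statistic of flavor `"sq"`; the function exists to verify that
#' equivalence and is not itself the association test.
#'
#' @param genotypes A [genotype_matrix()] or counts matrix (no missing
#'   genotypes).
#' @param status Binary phenotype.
#' @param weights Per-variant weights (aligned to columns of `genotypes`).
#' @return The nonnegative scalar `Q`.
#' @export
skat_q <- function(genotypes, status, weights) {
  G <- as_counts(genotypes)
  if (anyNA(G)) stop("skat_q() requires complete genotypes", call. = FALSE)
  status <- as.numeric(status)
  storage.mode(G) <- "double"
  yc <- status - mean(status)
  sum(weights * drop(crossprod(G, yc))^2)
}
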