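# Coalescent haplotype pools and case/control phenotype simulation.

#' Region simulation parameters
#'
#' Parameters of one neutral coalescent region. Defaults reproduce the
#' reference design: a 50-kb region, mutation rate 1e-8 per bp per
#' generation, effective population size 10,000 diploids, background
#' recombination 1 cM/Mb, and a pool of 100,000 diploid individuals.
#' Regions with a recombination hotspot add a short interval (2 kb at
#' 15 cM/Mb by default, placed at the region midpoint) that interrupts
#' linkage disequilibrium.
#'
#' @param length_bp Region length in base pairs.
#' @param mu Mutation rate, mutations/bp/generation.
#' @param Ne Effective population size (diploids).
#' @param recomb_cM_Mb Background recombination rate in cM/Mb.
#' @param hotspot `NULL`, or a list with `start_bp`, `length_bp`, and
#'   `rate_cM_Mb` describing a recombination hotspot inside the region.
#' @param n_diploids Number of diploid individuals in the simulated pool.
#' @return A list of class `region_params`.
#' @export
region_params <- function(length_bp = 5e4, mu = 1e-8, Ne = 1e4,
                          recomb_cM_Mb = 1, hotspot = NULL,
                          n_diploids = 1e5) {
  if (!is.null(hotspot)) {
    hotspot <- as.list(hotspot)
    if (is.null(hotspot$start_bp))
      hotspot$start_bp <- (length_bp - hotspot$length_bp %||% 2000) / 2
    hotspot$length_bp <- hotspot$length_bp %||% 2000
    hotspot$rate_cM_Mb <- hotspot$rate_cM_Mb %||% 15
    if (hotspot$start_bp < 0 ||
        hotspot$start_bp + hotspot$length_bp > length_bp)
      stop("hotspot interval must lie within the region", call. = FALSE)
  }
  if (any(c(length_bp, mu, Ne, recomb_cM_Mb, n_diploids) < 0))
    stop("region parameters must be nonnegative", call. = FALSE)
  structure(list(length_bp = length_bp, mu = mu, Ne = Ne,
                 recomb_cM_Mb = recomb_cM_Mb, hotspot = hotspot,
                 n_diploids = as.integer(n_diploids)),
            class = "region_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Haplotype pool container
#'
#' Wraps a binary haplotype matrix (chromosomes x variants; consecutive
#' pairs of rows form diploid individuals) into a `region_pool`: pooled MAFs
#' are computed, monomorphic columns are dropped (with a warning), and the
#' diploid genotype matrix is materialized. Columns whose carried (e.g.,
#' derived) allele is the major allele are flipped so that haplotype and
#' genotype entries always count the minor allele: the disease models
#' assign effects per minor-allele copy, so a near-fixed derived allele
#' must not masquerade as a rare variant.
#'
#' @param haplotypes 0/1 matrix, `2 * n_diploids` rows.
#' @param positions Base-pair coordinate per variant (1-based,
#'   nondecreasing).
#' @param length_bp Region length in bp.
#' @param params Optional [region_params()] the pool was simulated under.
#' @param seed Optional seed recorded for reproducibility.
#' @return An object of class `region_pool` with elements `haplotypes`,
#'   `genotypes` (n_diploids x J minor-allele counts), `positions`, `maf`,
#'   `n_diploids`, `length_bp`, `params`, `seed`.
#' @export
region_pool <- function(haplotypes, positions, length_bp,
                        params = NULL, seed = NULL) {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L)
    stop("odd number of haplotypes: cannot form diploids", call. = FALSE)
  if (length(positions) != ncol(haplotypes))
    stop("positions length does not match variant count", call. = FALSE)
  storage.mode(haplotypes) <- "integer"
  nh <- nrow(haplotypes)
  f <- colSums(haplotypes) / nh
  mono <- f == 0 | f == 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic column(s) dropped from pool")
    haplotypes <- haplotypes[, !mono, drop = FALSE]
    positions <- positions[!mono]
    f <- f[!mono]
  }
  if (ncol(haplotypes) == 0L) stop("pool has no polymorphic variants",
                                   call. = FALSE)
  flip <- f > 0.5
  if (any(flip)) {
    haplotypes[, flip] <- 1L - haplotypes[, flip]
    f[flip] <- 1 - f[flip]
  }
  odd <- seq.int(1L, nh, by = 2L)
  genotypes <- haplotypes[odd, , drop = FALSE] +
    haplotypes[odd + 1L, , drop = FALSE]
  colnames(genotypes) <- paste0("v", seq_len(ncol(genotypes)))
  structure(list(haplotypes = haplotypes, genotypes = genotypes,
                 positions = as.numeric(positions), maf = f,
                 flipped = flip,
                 n_diploids = nh %/% 2L, length_bp = length_bp,
                 params = params, seed = seed),
            class = "region_pool")
}

#' @export
print.region_pool <- function(x, ...) {
  cat("Haplotype pool:", 2L * x$n_diploids, "chromosomes,",
      ncol(x$haplotypes), "polymorphic variants over",
      x$length_bp / 1000, "kb\n")
  cat(sprintf("  rare (MAF <= 0.05): %d variants; median MAF %.4g\n",
              sum(x$maf <= 0.05), stats::median(x$maf)))
  invisible(x)
}

find_python <- function() {
  py <- Sys.getenv("DMAFSCAN_PYTHON", Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  py
}

#' Simulate a neutral coalescent region
#'
#' Generates a haplotype pool for one region, either by delegating to the
#' msprime coalescent engine (through the bundled Python helper) or by
#' reading a user-supplied ms-format file. The simulation is neutral
#' (no selection), infinite-sites style, and deterministic for a given
#' seed.
#'
#' @param params A [region_params()] object.
#' @param seed Integer seed for the engine (required when simulating;
#'   drawn from the session RNG if `NULL`).
#' @param ms_file Path to an existing ms-format file to read instead of
#'   simulating. Its first replicate block is used.
#' @param sites_only If `TRUE`, run the engine but return only the
#'   segregating-site count (integer) without materializing haplotypes;
#'   useful for yield-calibration studies.
#' @return A [region_pool()], or an integer count when
#'   `sites_only = TRUE`.
#' @examples
#' \dontrun{
#' pool <- simulate_region(region_params(n_diploids = 1000), seed = 1)
#' }
#' @export
simulate_region <- function(params = region_params(), seed = NULL,
                            ms_file = NULL, sites_only = FALSE) {
  if (!is.null(ms_file)) {
    pools <- read_ms(ms_file, length_bp = params$length_bp)
    pool <- if (inherits(pools, "region_pool")) pools else pools[[1L]]
    pool$params <- params
    return(pool)
  }
  py <- find_python()
  if (!nzchar(py))
    stop("no python interpreter found and no 'ms_file' supplied; ",
         "install msprime or provide ms-format input", call. = FALSE)
  script <- system.file("python", "simulate_region.py", package = "dmafscan")
  if (seed %||% 0 > .Machine$integer.max - 2)
    stop("seed too large", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 2L, 1L)
  hs <- params$hotspot
  out <- tempfile(fileext = ".ms")
  on.exit(unlink(out), add = TRUE)
  args <- c(script, out, format(params$length_bp), format(params$mu),
            format(params$Ne), format(params$n_diploids),
            format(params$recomb_cM_Mb),
            format(hs$start_bp %||% 0), format(hs$length_bp %||% 0),
            format(hs$rate_cM_Mb %||% 0),
            format(as.integer(seed)), if (sites_only) "1" else "0")
  res <- suppressWarnings(system2(py, shQuote(args), stdout = TRUE,
                                  stderr = TRUE))
  code <- attr(res, "status") %||% 0L
  if (code != 0L)
    stop("coalescent engine failed (is msprime installed?):\n",
         paste(res, collapse = "\n"), call. = FALSE)
  if (sites_only) {
    line <- grep("^segsites ", res, value = TRUE)
    return(as.integer(sub("^segsites ", "", line[1L])))
  }
  pool <- read_ms(out, length_bp = params$length_bp)
  if (!inherits(pool, "region_pool")) pool <- pool[[1L]]
  pool$params <- params
  pool$seed <- seed
  pool
}

#' Disease-model specifications
#'
#' Enumerated case/control phenotype models on a haplotype pool:
#' \describe{
#'   \item{A, B, C}{Half of the rare variants (pooled MAF at or below 0.05,
#'     0.04, 0.06 respectively) are risk variants; the rest are neutral.}
#'   \item{D}{All rare variants (MAF <= 0.05) are causal: half risk, half
#'     protective.}
#'   \item{E, F}{As A and D, plus one additional risk variant: the variant
#'     with pooled MAF closest to 0.10 among those above the rare
#'     threshold, adding a low-frequency causal effect.}
#'   \item{G}{Rare variants (MAF <= 0.05) are split into thirds by
#'     position; the middle third are all risk variants (sub-region
#'     effect-size schedule), everything else neutral.}
#'   \item{H}{As G, but the middle third is half risk, half protective.}
#'   \item{null}{No causal variants.}
#' }
#' Effect sizes depend on the variant's pooled MAF. Whole-region models
#' (A-F): OR 1.5 for MAF > 0.01, 1.7 for 0.001 <= MAF <= 0.01, 2.0 for
#' MAF < 0.001. Sub-region models (G, H): 1.7 / 2.0 / 2.2 on the same bins.
#' Protective ORs are the reciprocals. The target population prevalence is
#' 10%.
#'
#' @param name One of `"A"` to `"H"` or `"null"`.
#' @return A list of class `sim_model` with fields `name`,
#'   `causal_maf_threshold`, `protective_fraction`, `or_schedule`
#'   (`"whole-region"` or `"sub-region"`), `sub_region`, `extra_low_freq`,
#'   `prevalence`.
#' @export
sim_model <- function(name = c("A", "B", "C", "D", "E", "F", "G", "H",
                               "null")) {
  name <- match.arg(name)
  def <- switch(name,
    A = list(thr = 0.05, prot = 0,   sched = "whole-region", sub = FALSE, extra = FALSE),
    B = list(thr = 0.04, prot = 0,   sched = "whole-region", sub = FALSE, extra = FALSE),
    C = list(thr = 0.06, prot = 0,   sched = "whole-region", sub = FALSE, extra = FALSE),
    D = list(thr = 0.05, prot = 0.5, sched = "whole-region", sub = FALSE, extra = FALSE),
    E = list(thr = 0.05, prot = 0,   sched = "whole-region", sub = FALSE, extra = TRUE),
    F = list(thr = 0.05, prot = 0.5, sched = "whole-region", sub = FALSE, extra = TRUE),
    G = list(thr = 0.05, prot = 0,   sched = "sub-region",   sub = TRUE,  extra = FALSE),
    H = list(thr = 0.05, prot = 0.5, sched = "sub-region",   sub = TRUE,  extra = FALSE),
    null = list(thr = 0.05, prot = 0, sched = "whole-region", sub = FALSE, extra = FALSE))
  structure(list(name = name, causal_maf_threshold = def$thr,
                 protective_fraction = def$prot, or_schedule = def$sched,
                 sub_region = def$sub, extra_low_freq = def$extra,
                 prevalence = 0.10),
            class = "sim_model")
}

#' Effect size (odds ratio) for a causal variant
#'
#' Rarer variants are assigned larger effects. Whole-region schedule: OR
#' 1.5 for MAF > 0.01, 1.7 for 0.001 <= MAF <= 0.01, 2.0 for MAF < 0.001.
#' Sub-region schedule: 1.7, 2.0, 2.2 on the same bins. Protective variants
#' get the reciprocal OR; neutral variants OR 1.
#'
#' @param maf Pooled MAF(s) in (0, 0.5].
#' @param direction `"risk"`, `"protective"` or `"neutral"` (recycled).
#' @param schedule `"whole-region"` or `"sub-region"`.
#' @return Numeric vector of per-allele odds ratios.
#' @examples
#' or_for_variant(0.02, "risk", "whole-region")        # 1.5
#' or_for_variant(0.005, "protective", "whole-region") # 1/1.7
#' @export
or_for_variant <- function(maf, direction,
                           schedule = c("whole-region", "sub-region")) {
  schedule <- match.arg(schedule)
  tiers <- if (schedule == "whole-region") c(1.5, 1.7, 2.0)
           else c(1.7, 2.0, 2.2)
  bin <- ifelse(maf > 0.01, 1L, ifelse(maf >= 0.001, 2L, 3L))
  or <- tiers[bin]
  n <- max(length(maf), length(direction))
  direction <- rep_len(direction, n)
  or <- rep_len(or, n)
  or[direction == "protective"] <- 1 / or[direction == "protective"]
  or[direction == "neutral"] <- 1
  or
}

# Middle-third split of k rare variants: remainder goes to the middle tier
# first, then the first, then the last.
third_sizes <- function(k) {
  base <- k %/% 3L
  rem <- k %% 3L
  c(first = base + as.integer(rem >= 2L),
    middle = base + as.integer(rem >= 1L),
    last = base)
}

#' Assign causal variants under a disease model
#'
#' Applies a [sim_model()] to a pool: selects the causal variants among the
#' rare set, splits them into risk and protective (risk gets the extra on
#' odd counts), and attaches per-variant odds ratios from the model's
#' effect-size schedule. Sub-region models (G, H) split the rare variants
#' into positional thirds and make only the middle third causal.
#'
#' @param pool A [region_pool()].
#' @param model A [sim_model()] (or model name).
#' @param seed Optional seed controlling the random choice of causal
#'   variants.
#' @return An object of class `causal_annotation`: per-variant `direction`
#'   (`"risk"`, `"protective"`, `"neutral"`) and `or`, index vectors
#'   `risk`, `protective`, `causal`, and for sub-region models
#'   `sub_region`, the 0-based half-open interval of the causal middle
#'   third in pool variant-index space.
#' @export
assign_causal <- function(pool, model, seed = NULL) {
  if (is.character(model)) model <- sim_model(model)
  J <- ncol(pool$genotypes)
  maf <- pool$maf
  rare <- which(maf <= model$causal_maf_threshold)
  direction <- rep("neutral", J)
  sub_region <- NULL

  if (model$name != "null") {
    if (length(rare) < 3L)
      stop("fewer than 3 rare variants under the model threshold",
           call. = FALSE)
    with_seed(seed, {
      if (model$sub_region) {
        sz <- third_sizes(length(rare))
        mid <- rare[seq.int(sz[["first"]] + 1L,
                            sz[["first"]] + sz[["middle"]])]
        if (model$protective_fraction > 0) {
          risk <- sort(sample(mid, ceiling(length(mid) / 2)))
          direction[risk] <- "risk"
          direction[setdiff(mid, risk)] <- "protective"
        } else {
          direction[mid] <- "risk"
        }
        sub_region <- c(min(mid) - 1L, max(mid))
      } else {
        if (model$protective_fraction > 0) {
          risk <- sort(sample(rare, ceiling(length(rare) / 2)))
          direction[risk] <- "risk"
          direction[setdiff(rare, risk)] <- "protective"
        } else {
          direction[sort(sample(rare, ceiling(length(rare) / 2)))] <- "risk"
        }
        if (model$extra_low_freq) {
          cand <- which(maf > model$causal_maf_threshold)
          if (length(cand)) {
            direction[cand[which.min(abs(maf[cand] - 0.10))]] <- "risk"
          } else {
            warning("no variant above the rare threshold; ",
                    "low-frequency causal variant not added")
          }
        }
      }
    })
  }

  or <- or_for_variant(maf, direction, model$or_schedule)
  structure(list(direction = direction, or = or,
                 risk = which(direction == "risk"),
                 protective = which(direction == "protective"),
                 causal = which(direction != "neutral"),
                 sub_region = sub_region, model = model$name,
                 threshold = model$causal_maf_threshold, seed = seed),
            class = "causal_annotation")
}

#' @export
print.causal_annotation <- function(x, ...) {
  cat(sprintf("Causal annotation (model %s): %d risk, %d protective, of %d variants\n",
              x$model, length(x$risk), length(x$protective),
              length(x$direction)))
  if (!is.null(x$sub_region))
    cat("  causal sub-region: variant indices [", x$sub_region[1], ", ",
        x$sub_region[2], ")\n", sep = "")
  invisible(x)
}

#' Per-individual multiplicative risk multiplier
#'
#' `R_i = prod_j OR_j^g_ij` over the causal variants; the case probability
#' is `min(c * R_i, 1)` once the baseline `c` is calibrated. Precomputing
#' this vector saves work across repeated [sample_case_control()] draws on
#' the same pool and annotation.
#'
#' @inheritParams calibrate_baseline
#' @return Numeric vector, one multiplier per pool individual.
#' @export
risk_multiplier <- function(pool, annotation) {
  causal <- annotation$causal
  if (length(causal) == 0L) return(rep(1, nrow(pool$genotypes)))
  G <- pool$genotypes[, causal, drop = FALSE]
  storage.mode(G) <- "double"
  exp(drop(G %*% log(annotation$or[causal])))
}

#' Disease probability under the odds-multiplicative model
#'
#' `p_i = c R_i / (1 + c R_i)` for baseline odds `c` and per-individual
#' risk multiplier `R_i` (see [risk_multiplier()]).
#'
#' @param c Baseline odds constant (from [calibrate_baseline()]).
#' @param risk Per-individual multiplicative risk.
#' @return Vector of case probabilities in (0, 1].
#' @export
case_probability <- function(c, risk) {
  odds <- c * risk
  p <- odds / (1 + odds)
  p[is.infinite(odds)] <- 1
  p
}

#' Calibrate the baseline disease odds to a target prevalence
#'
#' The genetic effect is multiplicative on the odds of disease: individual
#' `i` has odds `c * R_i` with `R_i = prod_j OR_j^g_ij` over the causal
#' variants, hence case probability `c R_i / (1 + c R_i)`. The baseline
#' constant `c` is solved by monotone bisection so that the pool mean case
#' probability equals the target prevalence to within `tol`. With no causal
#' variants `c` is exactly the prevalence odds
#' (`prevalence / (1 - prevalence)`).
#'
#' Because the effect parameters are odds ratios, compounding them on the
#' odds scale keeps every probability in (0, 1) without truncation;
#' compounding them on the probability scale instead inflates the trait
#' variance contributed by LD-clustered rare alleles (see the methods
#' vignette).
#'
#' @param pool A [region_pool()].
#' @param annotation A [assign_causal()] annotation.
#' @param prevalence Target population prevalence (default 0.10).
#' @param tol Convergence tolerance on the achieved prevalence.
#' @return The baseline odds constant `c`.
#' @export
calibrate_baseline <- function(pool, annotation, prevalence = 0.10,
                               tol = 1e-6) {
  R <- risk_multiplier(pool, annotation)
  if (all(R == 1)) return(prevalence / (1 - prevalence))
  f <- function(cc) mean(case_probability(cc, R))
  lo <- 0
  hi <- prevalence / (1 - prevalence)
  it <- 0L
  while (f(hi) < prevalence) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 60L)
      stop("target prevalence unreachable", call. = FALSE)
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) < prevalence) lo <- mid else hi <- mid
    if (abs(f(mid) - prevalence) < tol) break
  }
  (lo + hi) / 2
}

#' Draw a case/control study from a pool
#'
#' Every pool individual's status is drawn Bernoulli with probability
#' `c R_i / (1 + c R_i)` (odds-multiplicative risk); `n_case` cases and
#' `n_ctrl` controls are then sampled uniformly without replacement from
#' the realized groups. Variants monomorphic within the sample are retained
#' in the genotype matrix (the tests drop them downstream).
#'
#' @inheritParams calibrate_baseline
#' @param c Baseline constant from [calibrate_baseline()].
#' @param n_case,n_ctrl Numbers of cases and controls to sample.
#' @param seed Optional seed.
#' @param risk Optional precomputed per-individual risk multiplier (from
#'   repeated draws on the same pool/annotation); computed if `NULL`.
#' @return List with `genotypes` (a [genotype_matrix()]), `status` (aligned
#'   0/1 vector), and `index` (pool rows sampled).
#' @export
sample_case_control <- function(pool, annotation, c, n_case, n_ctrl,
                                seed = NULL, risk = NULL) {
  if (is.null(risk)) risk <- risk_multiplier(pool, annotation)
  p <- case_probability(c, risk)
  with_seed(seed, {
    y <- stats::rbinom(length(p), 1L, p)
    cases <- which(y == 1L)
    ctrls <- which(y == 0L)
    if (length(cases) < n_case || length(ctrls) < n_ctrl)
      stop("pool realized too few cases (", length(cases), ") or controls (",
           length(ctrls), ") for the requested sample", call. = FALSE)
    idx <- c(sample(cases, n_case), sample(ctrls, n_ctrl))
  })
  gm <- genotype_matrix(pool$genotypes[idx, , drop = FALSE],
                        sample_ids = paste0("ind", idx),
                        variant_ids = colnames(pool$genotypes),
                        positions = pool$positions)
  list(genotypes = gm, status = rep(c(1L, 0L), c(n_case, n_ctrl)),
       index = idx)
}

#' Nagelkerke pseudo R-squared of a variant set
#'
#' Proportion of trait variance explained by a set of variants, measured as
#' the Nagelkerke rescaled likelihood-ratio pseudo R-squared comparing an
#' intercept-only logistic model with the model containing the per-variant
#' allele counts: `(1 - (L0/L1)^(2/N)) / (1 - L0^(2/N))`.
#'
#' @param genotypes A [genotype_matrix()] or numeric matrix of allele
#'   counts at the variants of interest (subjects x variants).
#' @param status Binary phenotype.
#' @return The pseudo R-squared in `[0, 1]`. Complete separation triggers a
#'   warning and the value is capped at 1.
#' @export
nagelkerke_r2 <- function(genotypes, status) {
  G <- as_counts(genotypes)
  storage.mode(G) <- "double"
  status <- as.integer(status)
  if (ncol(G) == 0L) stop("no variants supplied", call. = FALSE)
  N <- length(status)
  fit1 <- logistic_loglik(cbind(1, G), status)
  ll1 <- fit1$loglik
  p0 <- mean(status)
  ll0 <- sum(status) * log(p0) + sum(status == 0L) * log(1 - p0)
  r2 <- (1 - exp(2 / N * (ll0 - ll1))) / (1 - exp(2 / N * ll0))
  if (fit1$separation) warning("possible complete separation; R^2 capped at 1")
  min(max(r2, 0), 1)
}

# Maximized log-likelihood of a logistic regression via damped Newton
# (Levenberg-style) on sparse genotype designs. stats::glm.fit is
# equivalent in exact arithmetic but its dense per-iteration QR is
# prohibitively slow at pool scale (1e5 subjects x hundreds of mostly-zero
# rare-variant columns), and undamped scoring oscillates when singleton
# carriers quasi-separate the outcome.
logistic_loglik <- function(X, y, maxit = 200L, tol = 1e-8) {
  X <- Matrix::Matrix(X, sparse = TRUE)
  y <- as.numeric(y)
  ll <- function(eta) sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  eta <- as.numeric(X %*% beta)
  ll_cur <- ll(eta)
  lambda <- 1e-6
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    H <- as.matrix(Matrix::crossprod(X, X * w))
    g <- as.numeric(Matrix::crossprod(X, y - mu))
    improved <- FALSE
    for (k in 1:30) {                     # increase damping until ascent
      delta <- tryCatch(solve(H + diag(lambda * (diag(H) + 1e-12)),
                              g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        eta_new <- as.numeric(X %*% (beta + delta))
        ll_new <- ll(eta_new)
        if (ll_new >= ll_cur) {
          beta <- beta + as.numeric(delta)
          converged <- abs(ll_new - ll_cur) < tol * (abs(ll_new) + 0.1)
          eta <- eta_new
          ll_cur <- ll_new
          lambda <- max(lambda / 10, 1e-10)
          improved <- TRUE
          if (converged) return(finish_loglik(ll_cur, eta))
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) break                  # no ascent direction found
  }
  finish_loglik(ll_cur, eta)
}

finish_loglik <- function(ll, eta) {
  mu <- stats::plogis(eta)
  list(loglik = ll, separation = any(mu < 1e-8 | mu > 1 - 1e-8))
}
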