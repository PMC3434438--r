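# The toy pools here are built directly from Bernoulli haplotypes; engine
# integration (msprime) is exercised once at small scale at the end.

test_that("effect-size schedules map MAF bins to the documented ORs", {
  expect_equal(or_for_variant(0.02, "risk", "whole-region"), 1.5)
  expect_equal(or_for_variant(0.005, "risk", "whole-region"), 1.7)
  expect_equal(or_for_variant(0.0005, "risk", "whole-region"), 2.0)
  expect_equal(or_for_variant(0.02, "risk", "sub-region"), 1.7)
  expect_equal(or_for_variant(0.005, "risk", "sub-region"), 2.0)
  expect_equal(or_for_variant(0.0005, "risk", "sub-region"), 2.2)
  expect_equal(or_for_variant(0.005, "protective", "whole-region"), 1 / 1.7)
  expect_equal(or_for_variant(0.2, "neutral", "whole-region"), 1)
  # boundary: MAF exactly 0.001 and 0.01 fall in the middle tier
  expect_equal(or_for_variant(c(0.001, 0.01), "risk", "whole-region"),
               c(1.7, 1.7))
})

test_that("protective ORs are exact reciprocals per MAF bin", {
  pool <- toy_pool()
  for (m in c("D", "F", "H")) {
    ann <- assign_causal(pool, m, seed = 3)
    expect_gt(length(ann$protective), 0)
    sched <- sim_model(m)$or_schedule
    risk_or <- or_for_variant(pool$maf[ann$protective], "risk", sched)
    expect_equal(ann$or[ann$protective], 1 / risk_or)
  }
})

test_that("causal assignment counts follow the model definitions", {
  pool <- toy_pool()
  k <- sum(pool$maf <= 0.05)

  annA <- assign_causal(pool, "A", seed = 1)
  expect_equal(length(annA$risk), ceiling(k / 2))
  expect_equal(length(annA$protective), 0L)
  expect_true(all(pool$maf[annA$risk] <= 0.05))

  annD <- assign_causal(pool, "D", seed = 1)
  expect_equal(length(annD$risk), ceiling(k / 2))
  expect_equal(length(annD$protective), k - ceiling(k / 2))

  kB <- sum(pool$maf <= 0.04)
  annB <- assign_causal(pool, "B", seed = 1)
  expect_equal(length(annB$risk), ceiling(kB / 2))

  # E adds exactly one low-frequency risk variant above the rare threshold
  annE <- assign_causal(pool, "E", seed = 1)
  expect_equal(length(annE$risk), ceiling(k / 2) + 1L)
  extra <- setdiff(annE$risk, which(pool$maf <= 0.05))
  expect_length(extra, 1L)
  expect_gt(pool$maf[extra], 0.05)

  annF <- assign_causal(pool, "F", seed = 1)
  expect_equal(length(annF$risk), ceiling(k / 2) + 1L)
  expect_equal(length(annF$protective), k - ceiling(k / 2))

  ann0 <- assign_causal(pool, "null", seed = 1)
  expect_length(ann0$causal, 0L)
  expect_true(all(ann0$or == 1))
})

test_that("sub-region models make the positional middle third causal", {
  pool <- toy_pool()
  rare <- which(pool$maf <= 0.05)
  k <- length(rare)
  base <- k %/% 3
  mid_n <- base + as.integer(k %% 3 >= 1)

  annG <- assign_causal(pool, "G", seed = 2)
  expect_equal(length(annG$risk), mid_n)
  expect_length(annG$protective, 0)
  # causal variants are contiguous in rare-rank space (a positional third)
  ranks <- match(annG$risk, rare)
  expect_equal(ranks, seq(min(ranks), max(ranks)))
  expect_equal(min(ranks), base + as.integer(k %% 3 >= 2) + 1)

  annH <- assign_causal(pool, "H", seed = 2)
  expect_equal(length(annH$risk), ceiling(mid_n / 2))
  expect_equal(length(annH$protective), mid_n - ceiling(mid_n / 2))
  expect_setequal(c(annH$risk, annH$protective), annG$risk)
  # the recorded sub-region spans the causal middle third
  expect_equal(annG$sub_region, c(min(annG$risk) - 1L, max(annG$risk)))
})

test_that("baseline calibration hits the target prevalence", {
  pool <- toy_pool()
  # no causal variants: closed form, c = prevalence odds
  expect_equal(calibrate_baseline(pool, assign_causal(pool, "null"), 0.10),
               0.10 / 0.90)

  ann <- assign_causal(pool, "G", seed = 5)
  cc <- calibrate_baseline(pool, ann, 0.10, tol = 1e-9)
  R <- exp(as.matrix(pool$genotypes[, ann$causal]) %*%
             log(ann$or[ann$causal]))
  expect_equal(mean(cc * R / (1 + cc * R)), 0.10, tolerance = 1e-6)
})

test_that("calibration matches a hand-enumerated 10-individual toy pool", {
  # one causal variant with OR = 2; genotypes fixed by hand
  g_causal <- c(0, 0, 0, 0, 0, 1, 1, 1, 2, 2)
  H <- matrix(0L, 20, 2)
  H[, 1] <- rep(c(0L, 1L), 10)                 # filler polymorphic column
  H[cbind(c(11, 13, 15, 17, 18, 19, 20), 2)] <- 1L
  pool <- region_pool(H, c(100, 200), 5e4)
  stopifnot(identical(as.integer(pool$genotypes[, 2]), as.integer(g_causal)))
  ann <- list(direction = c("neutral", "risk"), or = c(1, 2),
              causal = 2L, risk = 2L, protective = integer(0))
  class(ann) <- "causal_annotation"
  cc <- calibrate_baseline(pool, ann, 0.10, tol = 1e-9)
  # independent oracle: solve mean over the 10 enumerated individuals of
  # c 2^g / (1 + c 2^g) = 0.10 directly
  oracle <- uniroot(function(c)
    mean(c * 2^g_causal / (1 + c * 2^g_causal)) - 0.10,
    c(1e-6, 1), tol = 1e-12)$root
  expect_equal(cc, oracle, tolerance = 1e-5)
})

test_that("case/control sampling respects realized groups and odds saturation", {
  pool <- toy_pool()
  ann <- assign_causal(pool, "A", seed = 9)
  cc <- calibrate_baseline(pool, ann, 0.10)
  st <- sample_case_control(pool, ann, cc, 30, 30, seed = 4)
  expect_equal(sum(st$status), 30)
  expect_equal(dim(st$genotypes)[1], 60L)
  expect_equal(dim(st$genotypes)[2], ncol(pool$genotypes))
  # deterministic per seed
  st2 <- sample_case_control(pool, ann, cc, 30, 30, seed = 4)
  expect_identical(st$index, st2$index)
  expect_error(sample_case_control(pool, ann, cc, 10 * pool$n_diploids, 1),
               "too few")
  # odds saturation: a huge baseline makes everyone a near-certain case
  everyone <- sample_case_control(pool, ann, 1e9, 5, 0, seed = 1)
  expect_true(all(everyone$status[seq_len(5)] == 1))
})

test_that("null-model replicates keep the DMAF test calibrated", {
  pool <- toy_pool(n_dip = 400, J = 50)
  ann <- assign_causal(pool, "null")
  p <- withr::with_seed(1234, replicate(200, {
    st <- sample_case_control(pool, ann, 0.5, 50, 50)
    dmaf_test(st$genotypes, st$status, n_perm = 150)$p.value
  }))
  rate <- mean(p < 0.05)
  band <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(rate, band[1])
  expect_lte(rate, band[2] + 0.02)
})

test_that("doubling causal log-ORs does not decrease power", {
  pool <- toy_pool(n_dip = 2000, J = 50, seed = 7)
  ann <- assign_causal(pool, "A", seed = 1)
  ann2 <- ann
  ann2$or <- ann$or^2                       # double every causal log-OR
  run_power <- function(a, seeds) {
    cc <- calibrate_baseline(pool, a, 0.10)
    mean(vapply(seeds, function(s) {
      st <- sample_case_control(pool, a, cc, 60, 60, seed = s)
      dmaf_test(st$genotypes, st$status, variants = "rare", n_perm = 100,
                seed = s)$p.value < 0.05
    }, logical(1)))
  }
  seeds <- 1:200
  expect_gte(run_power(ann2, seeds), run_power(ann, seeds))
})

test_that("Nagelkerke R2 spans its theoretical range", {
  pool <- toy_pool(n_dip = 300, J = 40)
  ann <- assign_causal(pool, "A", seed = 2)
  # permuted phenotype: no association -> R2 near 0
  st <- withr::with_seed(5, rbinom(pool$n_diploids, 1, 0.1))
  # rare singletons can quasi-separate; only the magnitude matters here
  r2_null <- suppressWarnings(nagelkerke_r2(pool$genotypes[, ann$causal], st))
  expect_lt(r2_null, 0.05)
  # perfect single-variant prediction -> R2 = 1
  g <- cbind(c(rep(2, 6), rep(0, 6)))
  y <- c(rep(1, 6), rep(0, 6))
  expect_warning(r2 <- nagelkerke_r2(g, y), "separation")
  expect_equal(r2, 1, tolerance = 1e-6)
})

test_that("msprime engine round-trips through ms format deterministically", {
  skip_if(!nzchar(dmafscan:::find_python()), "no python interpreter")
  params <- region_params(n_diploids = 400)
  a <- simulate_region(params, seed = 42)
  b <- simulate_region(params, seed = 42)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$positions, b$positions)
  expect_s3_class(a, "region_pool")
  expect_true(all(a$maf > 0 & a$maf <= 0.5))
  expect_true(!is.unsorted(a$positions))
  expect_equal(nrow(a$haplotypes), 800)
  # zero mutation rate -> no variants (engine reports zero sites)
  expect_equal(simulate_region(region_params(mu = 0, n_diploids = 50),
                               seed = 1, sites_only = TRUE), 0L)
})
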