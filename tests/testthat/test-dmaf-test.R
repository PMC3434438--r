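test_that("statistic matches hand arithmetic and the brute-force oracle", {
  # variant 1: X=0.5, Y=0, q=0.25, n=4 -> w ~ 1.1547, D = 0.5
  g <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  st <- c(1, 1, 0, 0)
  s <- variant_stats(g, st)
  w <- dmaf_weights(s)
  expect_equal(dmaf_statistic(s, w, 1L), 1 / sqrt(4 * 0.25 * 0.75) * 0.5,
               tolerance = 1e-12)
  # variant 2 has X = Y -> contributes zero
  expect_equal(dmaf_statistic(s, w, 1:2), dmaf_statistic(s, w, 1L))
  expect_error(dmaf_statistic(s, w, integer(0)), "empty")

  set.seed(21)
  for (flavor in c("abs", "sq")) {
    gg <- rand_genotypes(40, 15, miss = 0.1)
    ss <- balanced_status(40)
    stats <- variant_stats(gg, ss)
    keep <- which(stats$polymorphic)
    ww <- rep(NA_real_, 15)
    ww[keep] <- dmaf_weights(stats[keep, ])
    expect_equal(dmaf_statistic(stats, ww, keep, flavor),
                 brute_V(gg, ss, flavor), tolerance = 1e-12)
  }
})

test_that("zero case-control difference gives V = 0 for both flavors", {
  g <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  st <- c(1, 0, 1, 0)
  s <- variant_stats(g, st)
  w <- dmaf_weights(s)
  expect_equal(dmaf_statistic(s, w, 1:2, "abs"), 0)
  expect_equal(dmaf_statistic(s, w, 1:2, "sq"), 0)
})

test_that("statistic and p-value are invariant to allele-coding flips", {
  set.seed(31)
  g <- rand_genotypes(30, 10)
  st <- balanced_status(30)
  gf <- g
  gf[, c(2, 5, 9)] <- 2L - gf[, c(2, 5, 9)]
  t1 <- dmaf_test(g, st, n_perm = 100, seed = 7)
  t2 <- dmaf_test(gf, st, n_perm = 100, seed = 7)
  expect_identical(t1$statistic, t2$statistic)
  expect_identical(t1$p.value, t2$p.value)
})

test_that("Monte-Carlo p converges to the exhaustive enumeration p", {
  set.seed(41)
  for (rep in 1:3) {
    g <- rand_genotypes(8, 6, maf_range = c(0.1, 0.45))
    st <- rep(c(1L, 0L), each = 4)
    p_exact <- exact_perm_p(g, st)
    res <- dmaf_test(g, st, n_perm = 4000, seed = 100 + rep)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$p.value - p_exact), max(3 * se, 0.02))
  }
})

test_that("p-value conventions and extreme cases behave as documented", {
  # a strong signal on 20 subjects: none of the drawn relabelings reaches
  # the observed statistic, so the ties-as-extreme convention can give p = 0
  g <- cbind(c(rep(2, 9), 1, rep(0, 10)), c(rep(1, 10), rep(0, 10)))
  st <- rep(c(1L, 0L), each = 10)
  res <- dmaf_test(g, st, n_perm = 100, seed = 1)
  expect_true(all(res$null_dist < unname(res$statistic)))
  expect_equal(res$p.value, 0)
  res1 <- dmaf_test(g, st, n_perm = 100, seed = 1, plus_one = TRUE)
  expect_equal(res1$p.value, 1 / 101)
})

test_that("case-control label swap leaves the abs-flavor p unchanged", {
  set.seed(51)
  g <- rand_genotypes(24, 12)
  st <- c(rep(1L, 10), rep(0L, 14))  # unequal groups on purpose
  a <- dmaf_test(g, st, n_perm = 300, seed = 9)
  b <- dmaf_test(g, 1L - st, n_perm = 300, seed = 9)
  expect_equal(a$p.value, b$p.value)
  expect_equal(unname(a$statistic), unname(b$statistic))
})

test_that("fixed seed reproduces the test bit-exactly", {
  set.seed(61)
  g <- rand_genotypes(30, 10, miss = 0.05)
  st <- balanced_status(30)
  a <- dmaf_test(g, st, n_perm = 200, seed = 123)
  b <- dmaf_test(g, st, n_perm = 200, seed = 123)
  expect_identical(a$null_dist, b$null_dist)
  expect_identical(a$p.value, b$p.value)
})

test_that("null genotypes give calibrated p-values", {
  # phenotype independent of genotype: rejection rate at 0.05 should sit in
  # the 99% binomial band (the ties-as-extreme convention is mildly liberal)
  set.seed(71)
  n_rep <- 400
  p <- numeric(n_rep)
  st <- balanced_status(40)
  for (r in seq_len(n_rep)) {
    g <- rand_genotypes(40, 20, maf_range = c(0.02, 0.3))
    p[r] <- dmaf_test(g, st, n_perm = 200)$p.value
  }
  rate <- mean(p < 0.05)
  band <- qbinom(c(0.005, 0.995), n_rep, 0.05) / n_rep
  expect_gte(rate, band[1])
  expect_lte(rate, band[2] + 0.02)  # allowance for the liberal tie rule
})

test_that("rare-variant filtering restricts the analyzed set", {
  set.seed(81)
  g <- cbind(rand_genotypes(40, 4, maf_range = c(0.3, 0.45)),
             rand_genotypes(40, 4, maf_range = c(0.01, 0.03)))
  st <- balanced_status(40)
  res <- dmaf_test(g, st, variants = "rare", n_perm = 50, seed = 2)
  s <- variant_stats(g, st)
  expect_setequal(res$variant_set, classify_rare(s, 0.05))
})
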