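test_that("window enumeration follows the 5-SNV / 10% step rule", {
  w <- enumerate_windows(30, 10)
  expect_equal(w$start, c(0, 5, 10, 15, 20))
  expect_equal(w$stop - w$start, rep(10, 5))

  w <- enumerate_windows(250, 100)
  expect_equal(unique(diff(w$start)), 10)  # 10% of 100 > 5

  w <- enumerate_windows(40, 40)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$stop), c(0, 40))

  # terminal window anchored to the region end when the grid undershoots
  w <- enumerate_windows(33, 10)
  expect_equal(utils::tail(w$start, 1), 23)
  expect_true(all(diff(w$start) > 0))

  expect_error(enumerate_windows(5, 10), "too small")
})

test_that("step-down correction reproduces the hand-traced example", {
  M <- rbind(c(0.2, 0.5, 0.1), c(0.4, 0.3, 0.6))
  corr <- stepdown_correct(c(0.05, 0.35), M)
  expect_equal(corr, c(0, 1 / 3))
  expect_error(stepdown_correct(c(0.1, 0.2, 0.3), M), "nrow")
})

test_that("corrected p-values are monotone and bounded by single-step maxT", {
  set.seed(101)
  for (rep in 1:20) {
    m <- sample(2:12, 1)
    B <- 50
    M <- matrix(runif(m * B), m, B)
    p <- runif(m)
    corr <- stepdown_correct(p, M)
    ord <- order(p)
    expect_true(all(diff(corr[ord]) >= -1e-12))
    expect_true(all(corr >= 0 & corr <= 1))
    # single-step maxT: every p compared to minima of the full matrix
    full_min <- apply(M, 2, min)
    ss <- cummax(vapply(p[ord], function(pp) mean(full_min < pp),
                        numeric(1)))
    expect_true(all(corr[ord] <= ss + 1e-12))
  }
})

test_that("all-1 observed p-values stay within [0, 1] and nondecreasing", {
  set.seed(102)
  M <- matrix(runif(5 * 40), 5, 40)
  corr <- stepdown_correct(rep(1, 5), M)
  expect_true(all(corr <= 1))
  expect_true(all(diff(corr[order(rep(1, 5))]) >= 0))
})

test_that("p-value matrix uses one shared relabeling per column", {
  # duplicated windows must produce identical matrix rows: the same
  # permuted phenotype is applied to every window of a column
  set.seed(103)
  g <- rand_genotypes(40, 20)
  st <- balanced_status(40)
  wins <- data.frame(start = c(0, 5, 0), stop = c(10, 15, 10))
  pm <- build_pvalue_matrix(g, st, wins, B1 = 50, B2 = 50, seed = 4)
  expect_identical(pm$M[1, ], pm$M[3, ])
  expect_identical(pm$p_obs[1], pm$p_obs[3])
  expect_true(all(pm$M >= 0 & pm$M <= 1))
})

test_that("a single window reduces to the plain permutation test", {
  set.seed(104)
  g <- rand_genotypes(30, 12)
  st <- balanced_status(30)
  scan <- dmaf_scan(g, st, window_sizes = 12, B1 = 200, B2 = 50, seed = 77)
  res <- scan$results[["12"]]
  expect_equal(nrow(res), 1L)
  ref <- dmaf_test(g, st, n_perm = 200, seed = 77)
  expect_equal(res$p_raw, ref$p.value)
  expect_equal(res$statistic, unname(ref$statistic))
})

test_that("scan is deterministic for a fixed seed and skips oversized windows", {
  set.seed(105)
  g <- rand_genotypes(30, 15)
  st <- balanced_status(30)
  a <- dmaf_scan(g, st, c(5, 10), B1 = 60, B2 = 60, seed = 11)
  b <- dmaf_scan(g, st, c(5, 10), B1 = 60, B2 = 60, seed = 11)
  expect_identical(a$results, b$results)
  expect_message(
    s <- dmaf_scan(g, st, c(10, 50), B1 = 30, B2 = 30, seed = 1),
    "skipping window size 50")
  expect_equal(s$skipped, 50L)
})

test_that("single-window observed p-values are uniform under the null", {
  # one window per replicate, fresh genotypes and labels each time
  set.seed(106)
  p <- replicate(150, {
    g <- rand_genotypes(24, 8)
    st <- sample(balanced_status(24))
    dmaf_test(g, st, n_perm = 120)$p.value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("an injected strong signal is localized by the best window", {
  set.seed(107)
  n <- 120
  st <- balanced_status(n)
  g <- rand_genotypes(n, 40, maf_range = c(0.05, 0.3))
  # spike a strong case-enriched block at variants 21-30
  for (j in 21:30) g[, j] <- ifelse(st == 1, rbinom(n, 2, 0.35),
                                    rbinom(n, 2, 0.05))
  scan <- dmaf_scan(g, st, window_sizes = 10, B1 = 300, B2 = 100,
                    seed = 5)
  res <- scan$results[["10"]]
  best <- res[which.min(res$p_corrected), ]
  expect_true(best$start < 30 & best$stop > 20)  # overlaps the spike
  expect_true(localize(res, c(20, 30)))
})

test_that("localization implements the half-overlap rule with tie sets", {
  r <- data.frame(start = c(10, 30), stop = c(20, 40),
                  p_corrected = c(0.01, 0.5))
  expect_true(localize(r, c(15, 40)))    # overlap 5 = half of 10
  expect_true(localize(r, c(8, 25)))     # fully inside
  expect_false(localize(r, c(21, 29)))   # disjoint
  expect_false(localize(r, NULL))        # no causal region
  # tied windows form a set spanning their union
  r2 <- data.frame(start = c(0, 20), stop = c(10, 30),
                   p_corrected = c(0.01, 0.01))
  expect_true(localize(r2, c(0, 15)))    # overlap 15 >= 30/2
  expect_false(localize(r2, c(0, 10)))   # overlap 10 < 15
})
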