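# Brute-force sums-of-squares oracles, independent of the aov-based path.
brute_one_way <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values); T_ <- nlevels(groups)
  n_i <- tapply(values, groups, length)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ss_b <- sum(n_i * (means - gm)^2)
  ss_w <- sum((values - means[groups])^2)
  ms_b <- ss_b / (T_ - 1); ms_w <- ss_w / (N - T_)
  n0 <- (N - sum(n_i^2) / N) / (T_ - 1)
  list(ms_w = ms_w, ms_b = ms_b, n0 = n0,
       var_b = max(0, (ms_b - ms_w) / n0))
}

brute_two_way <- function(a, b) {
  T_ <- length(a); y <- c(a, b); gm <- mean(y)
  mm <- c(mean(a), mean(b)); tm <- (a + b) / 2
  ss_m <- T_ * sum((mm - gm)^2)
  ss_t <- 2 * sum((tm - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ms_m <- ss_m / 1; ms_t <- ss_t / (T_ - 1)
  ms_r <- (ss_tot - ss_m - ss_t) / (T_ - 1)
  vm <- max(0, (ms_m - ms_r) / T_); vt <- max(0, (ms_t - ms_r) / 2)
  if (vm + vt == 0) 0 else 100 * vm / (vm + vt)
}

test_that("one-way components equal a hand ANOVA on the printed toy set", {
  v <- c(0, 2, 10, 12); g <- c(1, 1, 2, 2)
  vc <- within_between(v, g, scale = "reading")
  # by hand: MS_within = 2, group means 1 and 11, MS_between = 100,
  # n0 = 2, between component = (100 - 2)/2 = 49
  expect_equal(vc$var_within, 2)
  expect_equal(vc$var_between, 49)
  expect_equal(vc$pct_total_within, 100 * 2 / 51)
  # mean scale divides the within component by n0
  vcm <- within_between(v, g, scale = "mean")
  expect_equal(vcm$pct_total_within, 100 * 1 / 50)
  # cross-check against the independent brute-force path on random sets
  set.seed(3)
  for (i in 1:10) {
    n_i <- sample(2:6, 4, replace = TRUE)
    values <- rnorm(sum(n_i))
    groups <- rep(seq_along(n_i), n_i)
    ref <- brute_one_way(values, groups)
    vc <- within_between(values, groups, scale = "reading")
    expect_equal(vc$var_within, ref$ms_w, tolerance = 1e-12)
    expect_equal(vc$var_between, ref$var_b, tolerance = 1e-12)
  }
})

test_that("degenerate and limiting one-way cases behave as documented", {
  vc <- within_between(rep(5, 8), rep(1:2, each = 4))
  expect_true(vc$degenerate)
  expect_equal(vc$pct_total_within, 0)
  # widely separated tumor means push the within share to zero
  v <- c(rnorm(5, 0, 1), rnorm(5, 1e4, 1))
  expect_lt(within_between(v, rep(1:2, each = 5))$pct_total_within, 0.1)
  expect_error(within_between(1:5, rep(1, 5)), "insufficient")
  expect_error(within_between(c(1, 2, 3), c(1, 1, 2)), "insufficient")
})

test_that("between-methods share matches hand-computed mean squares", {
  # identical estimates: zero method variance
  bm <- between_methods(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_equal(bm$pct_total_methods, 0)
  # constant offset across distinct tumors: positive method component
  a <- c(0.2, 0.4, 0.6); b <- a + 0.1
  bm <- between_methods(a, b)
  expect_gt(bm$var_method, 0)
  expect_equal(bm$pct_total_methods, brute_two_way(a, b))
  expect_equal(bm$pct_total_methods, 100 * (0.015 / 3) /
                 (0.015 / 3 + 0.08 / 2))
  # random paired sets agree with brute force
  set.seed(5)
  for (i in 1:10) {
    a <- runif(6); b <- runif(6)
    expect_equal(between_methods(a, b)$pct_total_methods,
                 brute_two_way(a, b), tolerance = 1e-10)
  }
  expect_error(between_methods(1:3 / 10, 1:4 / 10), "mismatched")
})

test_that("within-variance share falls with added tracks on a solved
           domain pair", {
  d1 <- generate_domain(synth_params(seed = 21, n_vessels = 12),
                        small_geometry(50))
  d2 <- generate_domain(synth_params(seed = 22, n_vessels = 30),
                        small_geometry(50))
  co <- suppressWarnings(solve_cohort(list(d1, d2)))
  vt <- suppressWarnings(
    variance_vs_tracks(co, "uniform", max_tracks = 4, seed = 1))
  expect_equal(vt$n_tracks, 1:4)
  expect_true(all(vt$pct_total_within >= 0 & vt$pct_total_within <= 100))
  # deterministic strategy: repeat run identical
  vt2 <- suppressWarnings(
    variance_vs_tracks(co, "uniform", max_tracks = 4, seed = 1))
  expect_identical(vt, vt2)
})

test_that("normality diagnostics behave under null, heavy tails and
           degeneracy", {
  rejections <- 0; heavy <- 0
  for (i in 1:60) {
    set.seed(i)
    nc <- normality_check(rnorm(300), rep(1:3, each = 100))
    if (nc$p_value < 0.05) rejections <- rejections + 1
    set.seed(i)
    nh <- normality_check(rt(300, df = 2))
    if (nh$p_value < 0.05) heavy <- heavy + 1
  }
  expect_lte(rejections / 60, 0.10)
  expect_gt(heavy / 60, 0.5)
  expect_true(normality_check(rep(2, 50))$degenerate)
})
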