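test_that("the oxygen modification factor matches direct substitution", {
  p <- radiosensitivity_params()
  expect_equal(omf(0, p), 1 / 3)
  expect_equal(omf(3, p), (1 / 3) * (3 * 3 + 3) / (3 + 3))  # = 2/3
  expect_equal(omf(1e6, p), 1, tolerance = 1e-5)
  expect_equal(omf(Inf, p), 1)
  # strictly increasing and bounded on a fine grid
  grid <- seq(0, 500, by = 0.25)
  v <- omf(grid, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 1 / 3 & v < 1))
  expect_error(omf(-1, p), "nonnegative")
})

test_that("survival matches the LQ form and its worked example", {
  p <- radiosensitivity_params()
  # alpha = 0.3, beta = 0.03, D = 2, OMF = 1: exp(-0.72), the 48% case
  expect_equal(survival_fraction(2, Inf, p), exp(-0.72), tolerance = 1e-12)
  expect_equal(survival_fraction(0, 0, p), 1)
  # independent scalar evaluation at anoxia
  o <- 1 / 3
  expect_equal(survival_fraction(2, 0, p),
               exp(-0.3 * o * 2 - 0.03 * (o * 2)^2), tolerance = 1e-12)
  expect_error(survival_fraction(-1, 5, p), "nonnegative")
})

test_that("weighted survival equals a brute-force per-cell loop", {
  p <- radiosensitivity_params()
  set.seed(11)
  pmap <- matrix(rexp(2500, rate = 1 / 20), 50, 50)
  for (D in c(2, 4, 8)) {
    brute <- 0
    for (i in seq_along(pmap))
      brute <- brute + exp(-p$alpha * omf(pmap[i], p) * D -
                             p$beta * (omf(pmap[i], p) * D)^2)
    brute <- brute / length(pmap)
    expect_equal(weighted_survival(pmap, D, p), brute, tolerance = 1e-12)
  }
  # constant profile reduces to the scalar survival
  expect_equal(weighted_survival(rep(7, 10), 3, p),
               survival_fraction(3, 7, p))
  # two compartments, equal weights
  expect_equal(weighted_survival(c(0, Inf), 2, p),
               mean(c(survival_fraction(2, 0, p),
                      survival_fraction(2, Inf, p))))
  expect_error(weighted_survival(c(1, 2), 2, p, weights = c(0, 0)),
               "positive sum")
})

test_that("the histogram compression stays within its discretization
           bound", {
  p <- radiosensitivity_params()
  set.seed(13)
  K <- matrix(runif(2500), 50, 50)
  tumor <- matrix(TRUE, 50, 50)
  pmap <- K[tumor] / max(K) * 100
  h <- pO2_histogram(K, tumor)
  expect_equal(sum(h$counts), sum(tumor))
  D <- 4
  sf_map <- weighted_survival(pmap, D, p)
  sf_hist <- weighted_survival(h$mids, D, p, weights = h$counts)
  # brute-force bound: worst per-cell deviation from its bin centre
  bin <- pmin(findInterval(pmap, h$breaks, rightmost.closed = TRUE), 20)
  dev <- abs(survival_fraction(D, pmap, p) -
               survival_fraction(D, h$mids[bin], p))
  expect_lte(abs(sf_map - sf_hist), mean(dev) + 1e-15)
})

test_that("oxygen histograms bin the mapped field as labelled", {
  tumor <- matrix(TRUE, 10, 10)
  h <- pO2_histogram(matrix(42, 10, 10), tumor)    # uniform: all at max
  expect_equal(h$counts[20], 100)
  expect_equal(sum(h$counts[1:19]), 0)
  # half the cells below 5% of max land in the first bin
  K <- matrix(c(rep(0.01, 50), rep(1, 50)), 10, 10)
  h <- pO2_histogram(K, tumor)
  expect_gte(sum(h$counts[1]), 50)
})

test_that("scenario curves reproduce the six oxygenation cases", {
  d <- generate_domain(synth_params(seed = 15, n_vessels = 15),
                       small_geometry(50))
  f <- solve_to_stationary_hypoxia(d)
  curves <- scenario_curves(f$K, d$tumor_mask, doses = seq(0, 10, by = 1))
  expect_setequal(unique(curves$scenario),
                  c("normoxic", "anoxic", "hypoxic", "binary",
                    "histogram", "heterogeneous"))
  # normoxic case at 2 Gy by direct substitution: OMF(60) = 183/189,
  # close to (but distinguishable from) the OMF = 1 benchmark exp(-0.72)
  sf2 <- curves$SF[curves$scenario == "normoxic" & curves$dose == 2]
  o60 <- (3 * 60 + 3) / (3 * (60 + 3))
  expect_equal(sf2, exp(-0.3 * o60 * 2 - 0.03 * (o60 * 2)^2),
               tolerance = 1e-12)
  expect_equal(sf2, exp(-0.72), tolerance = 0.03)
  for (s in unique(curves$scenario)) {
    sf <- curves$SF[curves$scenario == s]
    expect_true(all(diff(sf) < 0))              # strictly falling in dose
    # oxygenated tissue is the most radiosensitive
    expect_true(all(curves$SF[curves$scenario == "normoxic"] <= sf))
  }
})
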