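# Solver correctness is checked against independent oracles: exact
# conservation of the stencil, the closed-form uniform steady state, and
# a direct linear solve of the stationary one-dimensional system.

test_that("a uniform field without reactions is a fixed point", {
  g <- small_geometry(20)
  tumor <- matrix(TRUE, 20, 20)
  d <- vascular_domain(tumor, tumor, tumor, g)
  p <- solver_params(r = 0, phi = 0, eta = 0, rho = 0, gamma = 0, D_c = 0)
  st <- manual_state(matrix(3.7, 20, 20), matrix(1, 20, 20))
  st <- iterate_steps(st, d, p, 50)
  expect_equal(st$K, matrix(3.7, 20, 20), tolerance = 1e-14)
})

test_that("the source/sink-free scheme conserves mass to 1e-12 per step", {
  g <- small_geometry(30)
  tumor <- matrix(TRUE, 30, 30)
  d <- vascular_domain(tumor, tumor, tumor, g)
  p <- solver_params(r = 0, phi = 0, eta = 0, rho = 0, gamma = 0, D_c = 0)
  set.seed(1)
  st <- manual_state(matrix(runif(900), 30, 30), matrix(0, 30, 30))
  total0 <- sum(st$K)
  for (s in 1:100) {
    st <- iterate_steps(st, d, p, 1)
    expect_lt(abs(sum(st$K) - total0) / total0, 1e-12)
  }
})

test_that("a uniform source relaxes to the closed-form balance r/(phi c)", {
  g <- small_geometry(20)
  tumor <- matrix(TRUE, 20, 20)
  d <- vascular_domain(tumor, tumor, tumor, g)   # m_p = 1 everywhere
  p <- solver_params(rho = 0, gamma = 0, D_c = 0)  # c frozen
  c_uniform <- matrix(p$c_lim, 20, 20)
  st <- iterate_steps(manual_state(matrix(0, 20, 20), c_uniform), d, p, 4000)
  K_expected <- p$r / (p$phi * p$c_lim)
  expect_equal(max(abs(st$K - K_expected)) / K_expected, 0,
               tolerance = 1e-6)
})

test_that("the stationary 1-D profile matches a direct linear solve", {
  n <- 40
  g <- small_geometry(n)
  tumor <- matrix(TRUE, n, n)
  # one fully perfused row: the solution varies along rows only
  v <- matrix(FALSE, n, n); v[12, ] <- TRUE
  d <- vascular_domain(v, v, tumor, g)
  p <- solver_params(rho = 0, gamma = 0, D_c = 0)
  c_uniform <- matrix(p$c_lim, n, n)
  st <- iterate_steps(manual_state(matrix(0, n, n), c_uniform), d, p, 30000)
  expect_lt(max(abs(st$K - rowMeans(st$K))), 1e-12 * max(st$K))  # 1-D indeed
  # independent oracle: direct solve of the tridiagonal stationary system
  sc <- oxymap:::solver_scales(p, g)
  A <- matrix(0, n, n)
  for (i in 1:n) {
    A[i, i] <- -2 - sc$phi * p$c_lim
    if (i > 1) A[i, i - 1] <- 1
    if (i < n) A[i, i + 1] <- 1
  }
  A[1, 1] <- A[1, 1] + 1      # reflecting ends
  A[n, n] <- A[n, n] + 1
  b <- -sc$r * as.numeric(seq_len(n) == 12)
  K_direct <- solve(A, b)
  expect_equal(st$K[, 1], K_direct, tolerance = 1e-8)
})

test_that("fields stay nonnegative under the default time step", {
  for (s in 1:3) {
    d <- generate_domain(synth_params(seed = s, n_vessels = 15),
                         small_geometry(40))
    st <- initialize_fields(d, solver_params())
    st <- iterate_steps(st, d, solver_params(), 500)
    expect_gte(min(st$K), 0)
    expect_gte(min(st$c), 0)
  }
})

test_that("an unstable time step raises a stability error", {
  d <- generate_domain(synth_params(seed = 1, n_vessels = 15),
                       small_geometry(40))
  dx_cm <- d$geometry$spacing_mm / 10
  p <- solver_params(dt = 2 * dx_cm^2 / 2.5e-5)   # far past the bound
  st <- initialize_fields(d, p)
  expect_error(iterate_steps(st, d, p, 2000), "stability error")
})

test_that("hypoxic fractions are invariant to the intravascular oxygen
           scale", {
  d <- generate_domain(synth_params(seed = 4, n_vessels = 15),
                       small_geometry(40))
  # the oxygen equation is linear in (r, K_vessel) given c, so a joint
  # rescaling multiplies the whole field and leaves every relative
  # quantity exactly unchanged
  f1 <- solve_to_stationary_hypoxia(d, solver_params(K_vessel = 1))
  f5 <- solve_to_stationary_hypoxia(
    d, solver_params(K_vessel = 5, r = 5 * solver_params()$r))
  expect_identical(f1$trace$HP10, f5$trace$HP10)
  expect_equal(f5$K, 5 * f1$K, tolerance = 1e-12)
  # K_vessel alone only sets the initial transient; the stationary
  # fractions it leads to are the same within the solver tolerance
  fk <- solve_to_stationary_hypoxia(d, solver_params(K_vessel = 7))
  last <- function(f) unlist(f$trace[nrow(f$trace), -1])
  expect_equal(last(fk), last(f1), tolerance = 0.005)
})

test_that("degenerate and trivial domains are handled", {
  g <- small_geometry(40)
  tumor <- oxymap:::make_tumor_mask("ellipse", g)
  # fully perfused tumor: every tumor cell is a source, no hypoxia
  d <- vascular_domain(tumor, tumor, tumor, g)
  f <- solve_to_stationary_hypoxia(d)
  expect_equal(f$trace$HP10[nrow(f$trace)], 0)
  # no perfused vessels: flagged degenerate, HP = 1
  v <- matrix(FALSE, 40, 40); v[20, 20] <- TRUE
  d0 <- vascular_domain(v, matrix(FALSE, 40, 40), tumor, g)
  expect_warning(f0 <- solve_to_stationary_hypoxia(d0), "degenerate")
  expect_true(f0$degenerate)
  expect_equal(f0$trace$HP10[nrow(f0$trace)], 1)
})

test_that("non-convergence raises an error carrying the trace", {
  d <- generate_domain(synth_params(seed = 2, n_vessels = 15),
                       small_geometry(40))
  err <- tryCatch(
    solve_to_stationary_hypoxia(d, solver_params(tol_hp = 1e-12,
                                                 max_steps = 600L)),
    error = function(e) e)
  expect_s3_class(err, "oxymap_convergence_error")
  expect_true(is.data.frame(err$trace))
})
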