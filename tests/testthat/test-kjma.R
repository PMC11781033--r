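random_params <- function() {
  # random draw within the allowed bounds (log-uniform for v, I0)
  process_params(v = 10^runif(1, -3, 1), I0 = 10^runif(1, -5, 0),
                 alpha = runif(1, 0, 5))
}

test_that("replicated fraction over time matches an independent integral oracle", {
  # f(t) = 1 - exp(-2 v I0 int_0^t t'^a (t - t') dt'), evaluated numerically
  oracle_f <- function(t, p) {
    if (t == 0) return(0)
    g <- integrate(function(u) u^p$alpha * (t - u), 0, t, rel.tol = 1e-12)$value
    1 - exp(-2 * p$v * p$I0 * g)
  }
  p <- process_params(1, 0.03, 0)
  expect_equal(replicated_fraction_theory(5, p), 1 - exp(-0.75), tolerance = 1e-12)
  expect_equal(replicated_fraction_theory(5, p), oracle_f(5, p), tolerance = 1e-9)
  expect_equal(replicated_fraction_theory(0, p), 0)
  p0 <- process_params(1e-10, 0.03, 1.7)  # v at the lower bound: ~no growth
  expect_lt(replicated_fraction_theory(100, p0), 1e-4)
  set.seed(21)
  for (i in 1:20) {
    pr <- random_params()
    t <- runif(1, 0.1, 20)
    expect_equal(replicated_fraction_theory(t, pr), oracle_f(t, pr),
                 tolerance = 1e-8)
    # strictly increasing in t
    expect_gt(replicated_fraction_theory(t * 1.01, pr) -
                replicated_fraction_theory(t, pr), -1e-15)
  }
})

test_that("time inversion round-trips with the forward formula", {
  p <- process_params(1, 0.03, 0)
  expect_equal(invert_time(1 - exp(-0.75), p), 5, tolerance = 1e-10)
  expect_equal(invert_time(0, p), 0)
  expect_error(invert_time(1, p), "f must be")
  set.seed(22)
  for (i in 1:200) {
    pr <- random_params()
    f <- runif(1, 0, 0.99)
    t <- invert_time(f, pr)
    expect_lt(abs(replicated_fraction_theory(t, pr) - f), 1e-10 * max(f, 1e-3))
  }
})

test_that("correlation function matches its integral form and boundary limits", {
  # C(r,t) = 1 - 2 phi + phi^2 exp(I0 int_0^{t - r/2v} u^a (2v(t-u) - r) du)
  oracle_C <- function(r, t, p) {
    phi <- 1 - replicated_fraction_theory(t, p)
    if (r >= 2 * p$v * t) return((1 - phi)^2)
    g <- integrate(function(u) u^p$alpha * (2 * p$v * (t - u) - r),
                   0, t - r / (2 * p$v), rel.tol = 1e-12)$value
    1 - 2 * phi + phi^2 * exp(p$I0 * g)
  }
  p <- process_params(1, 0.03, 0)
  phi <- exp(-0.75)
  expect_equal(correlation_theory(5, 5, p),
               1 - 2 * phi + phi^2 * exp(0.75 * 0.25), tolerance = 1e-12)
  expect_equal(correlation_theory(5, 5, p), oracle_C(5, 5, p), tolerance = 1e-9)
  set.seed(23)
  for (i in 1:20) {
    pr <- random_params()
    t <- runif(1, 0.5, 15)
    r <- runif(1, 0, 3 * pr$v * t)
    expect_equal(correlation_theory(r, t, pr), oracle_C(r, t, pr),
                 tolerance = 1e-8)
  }
})

test_that("analytic identities C(0,t) = f and C(2vt,t) = f^2 hold exactly", {
  set.seed(24)
  for (i in 1:1000) {
    pr <- random_params()
    t <- runif(1, 0.1, 20)
    f <- replicated_fraction_theory(t, pr)
    expect_lt(abs(correlation_theory(0, t, pr) - f), 1e-12)
    expect_lt(abs(correlation_theory(2 * pr$v * t, t, pr) - f^2), 1e-12)
  }
})

test_that("correlation is non-increasing in lag and constant beyond 2vt", {
  set.seed(25)
  for (i in 1:50) {
    pr <- random_params()
    t <- runif(1, 0.5, 15)
    r <- seq(0, 3 * pr$v * t, length.out = 200)
    C <- correlation_theory(r, t, pr)
    expect_true(all(diff(C) <= 1e-12))
    beyond <- r >= 2 * pr$v * t
    f <- replicated_fraction_theory(t, pr)
    expect_true(all(abs(C[beyond] - f^2) < 1e-12))
  }
})

test_that("theoretical initiation rate composes I(t) with inverted time", {
  p0 <- process_params(1, 0.01, 0)
  expect_equal(initiation_rate_theory(c(0.1, 0.5, 0.9), p0), rep(0.01, 3))
  p1 <- process_params(1, 0.01, 1)
  t_half <- (6 * log(2) / 0.02)^(1 / 3)
  expect_equal(initiation_rate_theory(0.5, p1), 0.01 * t_half, tolerance = 1e-12)
  expect_equal(initiation_rate_theory(0, p1), 0)
})

test_that("mixture correlation and initiation are convex combinations", {
  fast <- process_params(1.2, 0.005, 1)
  slow <- process_params(0.2, 0.04, 1)
  r <- seq(0, 25, by = 1)
  f <- 0.45
  for (th in c(0, 0.5, 1)) {
    mx <- mixture_model(fast, slow, theta = c(f5 = th))
    C1 <- correlation_theory(r, invert_time(f, fast), fast)
    C2 <- correlation_theory(r, invert_time(f, slow), slow)
    expect_equal(mixture_correlation(r, f, mx, "f5"), th * C1 + (1 - th) * C2)
    expect_equal(mixture_initiation(f, mx, "f5"),
                 th * initiation_rate_theory(f, fast) +
                   (1 - th) * initiation_rate_theory(f, slow))
  }
  mx <- mixture_model(fast, slow, theta = c(f5 = 0.5))
  # both components equal f at r = 0, so the mixture does too
  expect_equal(mixture_correlation(0, f, mx, "f5"), f, tolerance = 1e-12)
  expect_error(mixture_correlation(0, f, mx, "f9"), "no theta")
  expect_error(mixture_model(fast, slow, theta = c(f1 = 1.2)), "0, 1")
})

test_that("parameters outside the fit bounds are rejected", {
  expect_error(process_params(11, 0.01, 0), "bounds")
  expect_error(process_params(1, 2, 0), "bounds")
  expect_error(process_params(1, 0.01, 6), "bounds")
})
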