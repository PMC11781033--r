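## Closed-form 1-D KJMA nucleation-and-growth model of DNA replication:
## replicated fraction over time, its analytic inverse, the two-point
## correlation function, the theoretical initiation rate, and the two-process
## mixture.

#' Bounds of the fit variables
#'
#' Lower and upper bounds used both to validate process parameters and to
#' constrain the genetic-algorithm search: v in \[1e-10, 10\] kb/min, I0 in
#' \[1e-15, 1\], alpha in \[0, 5\].
#'
#' @return List with `lower` and `upper` named vectors (`v`, `I0`, `alpha`).
#' @export
param_bounds <- function() {
  list(lower = c(v = 1e-10, I0 = 1e-15, alpha = 0),
       upper = c(v = 10, I0 = 1, alpha = 5))
}

#' Replication process parameters
#'
#' One nucleation-and-growth process: fork speed `v` (kb/min), initiation
#' strength `I0` and exponent `alpha` of the time-dependent initiation rate
#' `I(t) = I0 t^alpha` (per kb of unreplicated DNA per minute). The raw `I0`
#' is stored; its unit, kb^-1 min^-(alpha+1), depends on alpha.
#'
#' @param v Fork speed (kb/min).
#' @param I0 Initiation strength.
#' @param alpha Initiation-rate exponent (dimensionless).
#' @return Object of class `process_params`.
#' @export
process_params <- function(v, I0, alpha = 0) {
  stop_if_not_scalar(v, "v"); stop_if_not_scalar(I0, "I0")
  stop_if_not_scalar(alpha, "alpha")
  b <- param_bounds()
  p <- c(v = v, I0 = I0, alpha = alpha)
  if (any(p < b$lower - 1e-12) || any(p > b$upper + 1e-12)) {
    stop("parameters outside the allowed bounds", call. = FALSE)
  }
  structure(list(v = v, I0 = I0, alpha = alpha), class = "process_params")
}

#' @export
print.process_params <- function(x, ...) {
  cat(sprintf("<process: v = %.4g kb/min, I0 = %.4g, alpha = %.3g>\n",
              x$v, x$I0, x$alpha))
  invisible(x)
}

## exponent of the survival probability: 2 v I0 t^(a+2) / ((a+1)(a+2))
kjma_exponent <- function(t, params) {
  2 * params$v * params$I0 * t^(params$alpha + 2) /
    ((params$alpha + 1) * (params$alpha + 2))
}

#' Theoretical replicated fraction over time
#'
#' `f(t) = 1 - exp(-2 v I0 t^(a+2) / ((a+1)(a+2)))`: the fraction of a long
#' fiber replicated at time t when origins fire at rate `I0 t^a` per kb of
#' unreplicated DNA and forks progress at `v` in both directions.
#'
#' @param t Time(s) since S-phase start (minutes), >= 0.
#' @param params A [process_params()].
#' @return f in \[0, 1), vectorized over `t`.
#' @export
replicated_fraction_theory <- function(t, params) {
  stopifnot(inherits(params, "process_params"), all(t >= 0))
  1 - exp(-kjma_exponent(t, params))
}

#' Analytic time inversion of the replicated fraction
#'
#' `t(f) = ((a+1)(a+2) log(1/(1-f)) / (2 v I0))^(1/(a+2))`, the exact inverse
#' of [replicated_fraction_theory()].
#'
#' @param f Replicated fraction(s) in \[0, 1).
#' @param params A [process_params()].
#' @return Time(s) in minutes.
#' @export
invert_time <- function(f, params) {
  stopifnot(inherits(params, "process_params"))
  if (any(f < 0 | f >= 1)) stop("f must be in [0, 1)", call. = FALSE)
  if (params$v * params$I0 <= 0 && any(f > 0)) {
    stop("v * I0 = 0 cannot produce f > 0", call. = FALSE)
  }
  a <- params$alpha
  t <- ((a + 1) * (a + 2) * log1p(-f) / (-2 * params$v * params$I0))^(1 / (a + 2))
  t[f == 0] <- 0
  t
}

#' Theoretical auto-correlation of the replication signal
#'
#' Two-point correlation of the replication state at separation r and time t:
#' `C(r,t) = 1 - 2 phi + phi^2 exp(E (1 - r / (2 v t))^(a+2))` with
#' `phi = 1 - f(t)` and `E = 2 v I0 t^(a+2)/((a+1)(a+2)) = log(1/phi)`. The
#' closed form holds for `r < 2 v t`, the maximum eye length at time t; beyond
#' it points are independent and the boundary value `f(t)^2` is returned, its
#' exact limit. `C(0, t) = f(t)` identically and C is non-increasing in r.
#'
#' @param r Lag distance(s) in kb, >= 0 (vectorized).
#' @param t Time (minutes), > 0.
#' @param params A [process_params()].
#' @return C(r, t) values in \[0, 1\].
#' @export
correlation_theory <- function(r, t, params) {
  stopifnot(inherits(params, "process_params"), all(r >= 0))
  stop_if_not_scalar(t, "t", positive = TRUE)
  E <- kjma_exponent(t, params)
  phi <- exp(-E)
  f <- 1 - phi
  lmax <- 2 * params$v * t
  inside <- r < lmax
  C <- rep(f^2, length(r))
  ## phi^2 exp(E s) written as exp(E (s - 2)); stable when E is huge (f ~ 1)
  C[inside] <- 1 - 2 * phi +
    exp(E * ((1 - r[inside] / lmax)^(params$alpha + 2) - 2))
  C
}

#' Theoretical initiation rate at a given replicated fraction
#'
#' `I(f) = I0 t(f)^alpha` with t from [invert_time()]; constant `I0` when
#' alpha = 0.
#'
#' @param f Replicated fraction(s) in \[0, 1).
#' @param params A [process_params()].
#' @return Initiation rate(s) in kb^-1 min^-1.
#' @export
initiation_rate_theory <- function(f, params) {
  stopifnot(inherits(params, "process_params"))
  if (params$alpha == 0) return(rep(params$I0, length(f)))
  params$I0 * invert_time(f, params)^params$alpha
}

#' Two-process mixture model
#'
#' Holds the fast and slow process parameters and the per-bin mixing value
#' Theta(f) in \[0, 1\] (weight of the fast process).
#'
#' @param fast,slow [process_params()] objects.
#' @param theta Named numeric vector, one value in \[0, 1\] per bin id.
#' @return Object of class `mixture_model`.
#' @export
mixture_model <- function(fast, slow, theta) {
  stopifnot(inherits(fast, "process_params"), inherits(slow, "process_params"))
  if (is.null(names(theta)) || anyNA(names(theta))) {
    stop("theta must be named by bin id", call. = FALSE)
  }
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]", call. = FALSE)
  structure(list(fast = fast, slow = slow, theta = theta),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("<two-process mixture>\n  fast: ")
  print(x$fast)
  cat("  slow: ")
  print(x$slow)
  cat(sprintf("  theta: %s\n",
              paste(sprintf("%s=%.2f", names(x$theta), x$theta), collapse = " ")))
  invisible(x)
}

theta_for_bin <- function(mixture, bin_id) {
  idx <- match(as.character(bin_id), names(mixture$theta))
  if (is.na(idx)) stop(sprintf("no theta for bin '%s'", bin_id), call. = FALSE)
  mixture$theta[[idx]]
}

#' Mixture auto-correlation at equal replicated fraction
#'
#' `C(r, f) = Theta C1(r, f) + (1 - Theta) C2(r, f)`. Each component is
#' evaluated at its own time `t_i = invert_time(f, params_i)`, so the two
#' processes are compared at equal replicated fraction rather than equal
#' time.
#'
#' @param r Lag(s) in kb.
#' @param f Replicated fraction in \[0, 1).
#' @param mixture A [mixture_model()].
#' @param bin_id Bin whose Theta applies.
#' @return Mixture C(r, f) values.
#' @export
mixture_correlation <- function(r, f, mixture, bin_id) {
  stopifnot(inherits(mixture, "mixture_model"))
  th <- theta_for_bin(mixture, bin_id)
  t1 <- invert_time(f, mixture$fast)
  t2 <- invert_time(f, mixture$slow)
  th * correlation_theory(r, t1, mixture$fast) +
    (1 - th) * correlation_theory(r, t2, mixture$slow)
}

#' Mixture initiation rate at a given replicated fraction
#'
#' Theta-weighted combination of the two processes' theoretical initiation
#' rates at the same replicated fraction.
#'
#' @inheritParams mixture_correlation
#' @return Initiation rate in kb^-1 min^-1.
#' @export
mixture_initiation <- function(f, mixture, bin_id) {
  stopifnot(inherits(mixture, "mixture_model"))
  th <- theta_for_bin(mixture, bin_id)
  th * initiation_rate_theory(f, mixture$fast) +
    (1 - th) * initiation_rate_theory(f, mixture$slow)
}
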