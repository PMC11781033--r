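## Parameter estimation: reduced chi-square objective over the per-bin
## correlation profiles plus the initiation-rate curve, minimized by an
## island-model genetic algorithm. Supports a single process, a free
## two-process mixture, and the two constrained variants (shared fork speed
## or shared initiation rate).

#' Reduced chi-square
#'
#' `sum(((data - model) / sigma)^2) / (n_points - n_params)`.
#'
#' @param model,data Matched numeric vectors.
#' @param sigma Per-point standard deviations (> 0).
#' @param n_params Number of free parameters.
#' @return Scalar reduced chi-square.
#' @export
reduced_chi2 <- function(model, data, sigma, n_params) {
  stopifnot(length(model) == length(data), length(sigma) == length(data))
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  dof <- length(data) - n_params
  if (dof <= 0) stop("degrees of freedom must be positive", call. = FALSE)
  sum(((data - model) / sigma)^2) / dof
}

#' Genetic-algorithm configuration
#'
#' Island-model GA: `n_subpops` subpopulations of `subpop_size` individuals;
#' every `migration_interval` generations the best `migration_fraction` of
#' each island replaces the worst of the next island on a ring. Each
#' generation keeps `elite_per_gen` elite children, fills
#' `crossover_fraction` of the remainder by scattered (uniform-mask)
#' crossover between roulette-selected parents and the rest by uniform
#' within-bounds mutation. The run stops after `max_generations` or when the
#' best fitness reaches `target_fitness`.
#'
#' @param n_subpops,subpop_size Island count and size (defaults 10 x 10).
#' @param migration_fraction,migration_interval Ring-migration settings
#'   (defaults 0.1 every 50 generations).
#' @param elite_per_gen Elite children per island per generation (default 1).
#' @param crossover_fraction Fraction of non-elite children from crossover
#'   (default 0.6; the rest are mutants).
#' @param mutation_rate Per-gene probability that a mutant child resamples
#'   that gene uniformly within bounds (default 0.4).
#' @param max_generations Generation cap (default 3000).
#' @param target_fitness Early-stopping fitness (default 0.5).
#' @param seed Integer seed; the run is fully deterministic given the config.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(n_subpops = 10, subpop_size = 10,
                      migration_fraction = 0.1, migration_interval = 50,
                      elite_per_gen = 1, crossover_fraction = 0.6,
                      mutation_rate = 0.4, max_generations = 3000,
                      target_fitness = 0.5, seed = 1) {
  stopifnot(migration_fraction >= 0, migration_fraction <= 1,
            crossover_fraction >= 0, crossover_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elite_per_gen >= 0, elite_per_gen < subpop_size)
  structure(list(n_subpops = as.integer(n_subpops),
                 subpop_size = as.integer(subpop_size),
                 migration_fraction = migration_fraction,
                 migration_interval = as.integer(migration_interval),
                 elite_per_gen = as.integer(elite_per_gen),
                 crossover_fraction = crossover_fraction,
                 mutation_rate = mutation_rate,
                 max_generations = as.integer(max_generations),
                 target_fitness = target_fitness,
                 seed = as.integer(seed)),
            class = "ga_config")
}

## rank-based roulette weights: selection probability proportional to
## (n - rank + 1), robust to the magnitude swings of a chi-square objective
rank_weights <- function(fitness) {
  n <- length(fitness)
  (n - rank(fitness, ties.method = "first") + 1)
}

#' Minimize an objective with the island-model genetic algorithm
#'
#' @param fn Objective function of a numeric vector; non-finite values are
#'   treated as +Inf.
#' @param lower,upper Bounds (numeric vectors of equal length).
#' @param config A [ga_config()].
#' @return List: `par`, `value`, `generations`, `converged` (target fitness
#'   reached), `best_trace` (best fitness per generation, non-increasing).
#' @export
ga_minimize <- function(fn, lower, upper, config = ga_config()) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  d <- length(lower)
  span <- upper - lower
  safe_fn <- function(x) {
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
  }
  with_seed(config$seed, {
    K <- config$n_subpops
    n <- config$subpop_size
    pops <- lapply(seq_len(K), function(k) {
      matrix(runif(n * d, rep(lower, each = n), rep(upper, each = n)),
             nrow = n, ncol = d)
    })
    fits <- lapply(pops, function(p) apply(p, 1, safe_fn))
    n_elite <- config$elite_per_gen
    n_child <- n - n_elite
    n_cross <- round(config$crossover_fraction * n_child)
    n_mut <- n_child - n_cross
    best_trace <- numeric(0)
    gen <- 0L
    converged <- FALSE
    repeat {
      gen <- gen + 1L
      for (k in seq_len(K)) {
        pop <- pops[[k]]
        fit <- fits[[k]]
        ord <- order(fit)
        w <- rank_weights(fit)
        pick <- function(m) sample.int(n, m, replace = TRUE, prob = w)
        children <- matrix(0, nrow = n_child, ncol = d)
        if (n_cross > 0) {
          p1 <- pop[pick(n_cross), , drop = FALSE]
          p2 <- pop[pick(n_cross), , drop = FALSE]
          mask <- matrix(runif(n_cross * d) < 0.5, n_cross, d)
          children[seq_len(n_cross), ] <- ifelse(mask, p1, p2)
        }
        if (n_mut > 0) {
          par <- pop[pick(n_mut), , drop = FALSE]
          mut <- matrix(runif(n_mut * d) < config$mutation_rate, n_mut, d)
          new <- matrix(runif(n_mut * d, rep(lower, each = n_mut),
                              rep(upper, each = n_mut)), n_mut, d)
          children[n_cross + seq_len(n_mut), ] <- ifelse(mut, new, par)
        }
        child_fit <- apply(children, 1, safe_fn)
        keep <- ord[seq_len(n_elite)]
        pops[[k]] <- rbind(pop[keep, , drop = FALSE], children)
        fits[[k]] <- c(fit[keep], child_fit)
      }
      if (K > 1L && config$migration_interval > 0L &&
          gen %% config$migration_interval == 0L) {
        n_mig <- max(1L, round(config$migration_fraction * n))
        sel_best <- lapply(seq_len(K), function(k) {
          order(fits[[k]])[seq_len(n_mig)]
        })
        mig_x <- lapply(seq_len(K), function(k) pops[[k]][sel_best[[k]], , drop = FALSE])
        mig_f <- lapply(seq_len(K), function(k) fits[[k]][sel_best[[k]]])
        for (k in seq_len(K)) {
          dest <- k %% K + 1L
          worst <- order(fits[[dest]], decreasing = TRUE)[seq_len(n_mig)]
          pops[[dest]][worst, ] <- mig_x[[k]]
          fits[[dest]][worst] <- mig_f[[k]]
        }
      }
      best <- min(vapply(fits, min, numeric(1)))
      best_trace <- c(best_trace, best)
      if (best <= config$target_fitness) { converged <- TRUE; break }
      if (gen >= config$max_generations) break
    }
    k_best <- which.min(vapply(fits, min, numeric(1)))
    i_best <- which.min(fits[[k_best]])
    list(par = pops[[k_best]][i_best, ],
         value = fits[[k_best]][i_best],
         generations = gen,
         converged = converged,
         best_trace = best_trace)
  })
}

## ---- fit problem assembly ---------------------------------------------

model_kinds <- c("single", "dual", "dual_shared_v", "dual_shared_I")

## number of process parameters (theta excluded) per model kind
n_process_params <- function(kind) {
  switch(kind, single = 3L, dual = 6L, dual_shared_v = 5L, dual_shared_I = 4L)
}

#' Assemble a fit problem from binned observables
#'
#' Collects the per-bin mean correlation profiles and the initiation curve
#' into the data vectors and sigma weights used by the fitting objective.
#' Because the fitted curves are bin means, each point is weighted by the
#' standard error of that mean (across-fiber SD / sqrt(n)), floored at
#' `sigma_floor_frac` of the observable's dynamic range (missing SDs, e.g.
#' single-fiber bins, get the floor). Correlation lags are truncated at
#' `r_max_fit`.
#'
#' @param profiles Named list of per-bin `correlation_profile`s (see
#'   [bin_profiles()]).
#' @param init_curve Data frame from [bin_initiation_curve()].
#' @param kind One of `"single"`, `"dual"`, `"dual_shared_v"`,
#'   `"dual_shared_I"`.
#' @param r_max_fit Largest lag (kb) used in the fit (default 40).
#' @param sigma_floor_frac Sigma floor as a fraction of each observable's
#'   dynamic range (default 0.01).
#' @param init_model `"detectable"` (default) compares the data to the
#'   model's observable initiation rate — the plain rate times the
#'   probability that a new eye has not instantly merged with neighbouring
#'   replicated DNA, which the small-eye estimator cannot count — or
#'   `"raw"` for the uncorrected `I(t)`.
#' @param eye_threshold_kb Eye-length threshold used by the estimator (kb),
#'   sets the scale of the detectability correction (default 3).
#' @return Object of class `fit_problem`.
#' @export
fit_problem <- function(profiles, init_curve, kind = "single",
                        r_max_fit = 40, sigma_floor_frac = 0.01,
                        init_model = c("detectable", "raw"),
                        eye_threshold_kb = 3) {
  init_model <- match.arg(init_model)
  kind <- match.arg(kind, model_kinds)
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
  bins <- intersect(names(profiles), init_curve$bin_id)
  if (length(bins) == 0L) stop("profiles and initiation curve share no bins", call. = FALSE)
  allC <- unlist(lapply(profiles[bins], function(p) p$C))
  floorC <- max(sigma_floor_frac * (max(allC) - min(allC)), 1e-6)
  bin_data <- lapply(bins, function(b) {
    p <- profiles[[b]]
    keep <- p$lags_kb <= r_max_fit
    seC <- if (is.null(p$sd)) rep(NA_real_, sum(keep)) else p$sd[keep] / sqrt(p$n)
    list(bin_id = b, f = p$f, lags = p$lags_kb[keep], C = p$C[keep],
         sigma = pmax(ifelse(is.na(seC), floorC, seC), floorC))
  })
  names(bin_data) <- bins
  ic <- init_curve[match(bins, init_curve$bin_id), , drop = FALSE]
  floorI <- max(sigma_floor_frac * (max(ic$I) - min(ic$I)),
                sigma_floor_frac * max(ic$I), 1e-9)
  seI <- ic$sd / sqrt(ic$n_fibers)
  sigI <- pmax(ifelse(is.na(seI), floorI, seI), floorI)
  n_points <- sum(vapply(bin_data, function(b) length(b$C), integer(1))) + nrow(ic)
  n_free <- n_process_params(kind) + if (kind == "single") 0L else length(bins)
  if (n_points - n_free <= 0L) stop("not enough data points for the model", call. = FALSE)
  structure(list(kind = kind, bins = bins, bin_data = bin_data,
                 init = data.frame(bin_id = ic$bin_id, f = ic$mean_f,
                                   I = ic$I, sigma = sigI),
                 init_model = init_model, eye_threshold_kb = eye_threshold_kb,
                 n_free = n_free, n_points = n_points),
            class = "fit_problem")
}

## GA search space: v and I0 in log10 (bounds span many decades), alpha and
## theta linear.
ga_space <- function(kind, n_bins) {
  b <- param_bounds()
  proc <- function() list(lower = c(log10(b$lower["v"]), log10(b$lower["I0"]), b$lower["alpha"]),
                          upper = c(log10(b$upper["v"]), log10(b$upper["I0"]), b$upper["alpha"]),
                          names = c("log10_v", "log10_I0", "alpha"))
  p <- proc()
  sp <- switch(kind,
    single = list(lower = p$lower, upper = p$upper, names = p$names),
    dual = list(lower = c(p$lower, p$lower), upper = c(p$upper, p$upper),
                names = c(paste0(p$names, "_1"), paste0(p$names, "_2"))),
    dual_shared_v = list(
      lower = c(p$lower[1], p$lower[2:3], p$lower[2:3]),
      upper = c(p$upper[1], p$upper[2:3], p$upper[2:3]),
      names = c("log10_v", "log10_I0_1", "alpha_1", "log10_I0_2", "alpha_2")),
    dual_shared_I = list(
      lower = c(p$lower[1], p$lower[1], p$lower[2:3]),
      upper = c(p$upper[1], p$upper[1], p$upper[2:3]),
      names = c("log10_v_1", "log10_v_2", "log10_I0", "alpha")))
  if (kind != "single") {
    sp$lower <- c(sp$lower, rep(0, n_bins))
    sp$upper <- c(sp$upper, rep(1, n_bins))
    sp$names <- c(sp$names, paste0("theta_", seq_len(n_bins)))
  }
  sp$lower <- unname(sp$lower); sp$upper <- unname(sp$upper)
  sp
}

## decode a GA vector into one or two process parameter sets (+ theta)
decode_params <- function(par, kind, n_bins) {
  pp <- function(lv, lI, a) list(v = 10^lv, I0 = 10^lI, alpha = a)
  switch(kind,
    single = list(p1 = pp(par[1], par[2], par[3]), theta = NULL),
    dual = list(p1 = pp(par[1], par[2], par[3]),
                p2 = pp(par[4], par[5], par[6]),
                theta = par[6 + seq_len(n_bins)]),
    dual_shared_v = list(p1 = pp(par[1], par[2], par[3]),
                         p2 = pp(par[1], par[4], par[5]),
                         theta = par[5 + seq_len(n_bins)]),
    dual_shared_I = list(p1 = pp(par[1], par[3], par[4]),
                         p2 = pp(par[2], par[3], par[4]),
                         theta = par[4 + seq_len(n_bins)]))
}

## closed-form model curves for a bare (unclassed) parameter list
raw_invert_time <- function(f, p) {
  a <- p$alpha
  ((a + 1) * (a + 2) * log1p(-f) / (-2 * p$v * p$I0))^(1 / (a + 2))
}

raw_correlation <- function(r, t, p) {
  E <- 2 * p$v * p$I0 * t^(p$alpha + 2) / ((p$alpha + 1) * (p$alpha + 2))
  phi <- exp(-E)
  lmax <- 2 * p$v * t
  C <- rep((1 - phi)^2, length(r))
  inside <- r < lmax
  C[inside] <- 1 - 2 * phi + exp(E * ((1 - r[inside] / lmax)^(p$alpha + 2) - 2))
  C
}

raw_initiation <- function(f, p) {
  if (p$alpha == 0) return(rep(p$I0, length(f)))
  p$I0 * raw_invert_time(f, p)^p$alpha
}

## Observable initiation rate: what the small-eye estimator measures. A new
## eye is only counted as a separate track while the points flanking it
## (about one eye threshold apart) are still unreplicated; conditioning on
## that survival gives I_obs = I(t) * S2(theta, t) / phi(t), with S2 the
## two-point survival probability implicit in the correlation formula. For
## fast forks (2vt >> theta) the factor tends to 1.
raw_initiation_observable <- function(f, p, eye_kb) {
  t <- raw_invert_time(f, p)
  E <- -log1p(-f)
  phi <- 1 - f
  lmax <- 2 * p$v * t
  surv <- ifelse(eye_kb < lmax,
                 phi * exp(E * (1 - eye_kb / lmax)^(p$alpha + 2)),
                 phi)
  raw_initiation(f, p) * surv
}

## model prediction for every data point of the problem (C curves then I)
model_prediction <- function(par, problem) {
  dec <- decode_params(par, problem$kind, length(problem$bins))
  out_C <- vector("list", length(problem$bin_data))
  for (i in seq_along(problem$bin_data)) {
    bd <- problem$bin_data[[i]]
    t1 <- raw_invert_time(bd$f, dec$p1)
    C1 <- raw_correlation(bd$lags, t1, dec$p1)
    if (problem$kind == "single") {
      out_C[[i]] <- C1
    } else {
      t2 <- raw_invert_time(bd$f, dec$p2)
      C2 <- raw_correlation(bd$lags, t2, dec$p2)
      th <- dec$theta[i]
      out_C[[i]] <- th * C1 + (1 - th) * C2
    }
  }
  fI <- problem$init$f
  imod <- if (identical(problem$init_model, "raw")) {
    function(f, p) raw_initiation(f, p)
  } else {
    function(f, p) raw_initiation_observable(f, p, problem$eye_threshold_kb)
  }
  I1 <- imod(fI, dec$p1)
  I_model <- if (problem$kind == "single") {
    I1
  } else {
    dec$theta * I1 + (1 - dec$theta) * imod(fI, dec$p2)
  }
  list(C = out_C, I = I_model)
}

#' Reduced chi-square objective of a fit problem
#'
#' Returns the function of the GA search vector (log10 v, log10 I0, alpha,
#' and for mixtures one theta per bin) that [fit_single_process()] and
#' [fit_dual_process()] minimize.
#'
#' @param problem A [fit_problem()].
#' @return Function mapping a parameter vector to the reduced chi-square.
#' @export
fit_objective <- function(problem) {
  stopifnot(inherits(problem, "fit_problem"))
  data_C <- lapply(problem$bin_data, function(b) b$C)
  sig_C <- lapply(problem$bin_data, function(b) b$sigma)
  dof <- problem$n_points - problem$n_free
  function(par) {
    m <- model_prediction(par, problem)
    ss <- 0
    for (i in seq_along(data_C)) {
      ss <- ss + sum(((data_C[[i]] - m$C[[i]]) / sig_C[[i]])^2)
    }
    ss <- ss + sum(((problem$init$I - m$I) / problem$init$sigma)^2)
    if (!is.finite(ss)) return(Inf)
    ss / dof
  }
}

as_fit_result <- function(res, problem, ga) {
  kind <- problem$kind
  n_bins <- length(problem$bins)
  dec <- decode_params(res$par, kind, n_bins)
  clamp <- function(p) {
    b <- param_bounds()
    process_params(min(max(p$v, b$lower["v"]), b$upper["v"]),
                   min(max(p$I0, b$lower["I0"]), b$upper["I0"]),
                   min(max(p$alpha, b$lower["alpha"]), b$upper["alpha"]))
  }
  if (kind == "single") {
    params <- clamp(dec$p1)
  } else {
    p1 <- clamp(dec$p1); p2 <- clamp(dec$p2)
    theta <- pmin(pmax(dec$theta, 0), 1)
    names(theta) <- problem$bins
    ## fast process = larger fork speed, by convention first
    if (p1$v >= p2$v) {
      params <- mixture_model(fast = p1, slow = p2, theta = theta)
    } else {
      params <- mixture_model(fast = p2, slow = p1, theta = 1 - theta)
    }
  }
  structure(list(kind = kind, params = params, fitness = res$value,
                 generations = res$generations, converged = res$converged,
                 best_trace = res$best_trace, problem = problem,
                 ga = ga, par = res$par),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s-process fit: reduced chi-square = %.4g after %d generations%s>\n",
              x$kind, x$fitness, x$generations,
              if (x$converged) ", converged" else ""))
  print(x$params)
  invisible(x)
}

#' Fit a single replication process to binned observables
#'
#' Jointly fits all bins' mean auto-correlation profiles C(r, f) and the
#' initiation curve I(f) with one process (free variables v, I0, alpha). The
#' model time of each bin is obtained by inverting the replicated-fraction
#' formula at the bin's mean f.
#'
#' @param profiles Named per-bin profiles ([bin_profiles()]).
#' @param init_curve Initiation curve ([bin_initiation_curve()]).
#' @param ga A [ga_config()].
#' @param ... Passed to [fit_problem()] (`r_max_fit`, `sigma_floor_frac`).
#' @return A `fit_result` with `params` a [process_params()].
#' @export
fit_single_process <- function(profiles, init_curve, ga = ga_config(), ...) {
  problem <- fit_problem(profiles, init_curve, kind = "single", ...)
  sp <- ga_space("single", 0L)
  res <- ga_minimize(fit_objective(problem), sp$lower, sp$upper, ga)
  as_fit_result(res, problem, ga)
}

#' Fit a two-process mixture to binned observables
#'
#' Fits `C(r, f) = Theta(f) C1(r, f) + (1 - Theta(f)) C2(r, f)` and the
#' Theta-weighted initiation curve, with one free Theta per bin. `kind`
#' selects the free mixture (6 process parameters), a shared fork speed
#' (`dual_shared_v`) or a shared initiation rate I0, alpha
#' (`dual_shared_I`). In the result the process with the larger fitted fork
#' speed is reported as `fast` and Theta is its weight.
#'
#' @inheritParams fit_single_process
#' @param kind `"dual"`, `"dual_shared_v"` or `"dual_shared_I"`.
#' @return A `fit_result` with `params` a [mixture_model()].
#' @export
fit_dual_process <- function(profiles, init_curve, kind = "dual",
                             ga = ga_config(), ...) {
  kind <- match.arg(kind, model_kinds[-1])
  problem <- fit_problem(profiles, init_curve, kind = kind, ...)
  sp <- ga_space(kind, length(problem$bins))
  res <- ga_minimize(fit_objective(problem), sp$lower, sp$upper, ga)
  as_fit_result(res, problem, ga)
}
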