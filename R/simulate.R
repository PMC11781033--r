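## Monte Carlo lattice simulator of replicating DNA fibers. Each fiber is a
## 1-D array of blocks (default 150 x 1 kb). Per step, every active fork
## converts one adjacent unreplicated block, then origins fire in
## unreplicated blocks with probability P(t); a newly fired origin becomes
## visible only at the following step, when its two forks start converting.
## The step duration is the time a single fork needs to replicate one block,
## 1/v (for block_kb = 1).

#' Per-step firing probability from an initiation rate
#'
#' `P(t) = min(1, I(t) * block_kb * dt)`: the probability that an
#' unreplicated block fires during one simulation step of duration `dt`
#' minutes. Values above 1 saturate (with a warning at call time).
#'
#' @param I_of_t Either a constant rate (kb^-1 min^-1), a
#'   [process_params()] (giving `I(t) = I0 t^alpha`), or a function of time.
#' @param block_kb Block size (kb).
#' @param dt Step duration (minutes).
#' @return A function `P(t)` returning the capped probability.
#' @export
p_from_rate <- function(I_of_t, block_kb = 1, dt = 1) {
  stop_if_not_scalar(block_kb, "block_kb", positive = TRUE)
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  rate <- if (inherits(I_of_t, "process_params")) {
    function(t) I_of_t$I0 * t^I_of_t$alpha
  } else if (is.function(I_of_t)) {
    I_of_t
  } else {
    stop_if_not_scalar(I_of_t, "I_of_t")
    if (I_of_t < 0) stop("initiation rate must be >= 0", call. = FALSE)
    function(t) rep(I_of_t, length(t))
  }
  warned <- FALSE
  function(t) {
    p <- rate(t) * block_kb * dt
    if (any(p > 1)) {
      if (!warned) {
        warning("firing probability saturated at 1; initiation rate too high for the step size")
        warned <<- TRUE
      }
      p <- pmin(p, 1)
    }
    pmax(p, 0)
  }
}

#' Simulator configuration
#'
#' @param n_fibers Number of fibers (default 100).
#' @param n_blocks Blocks per fiber (default 150).
#' @param block_kb Block size in kb (default 1).
#' @param v Fork speed (kb/min); the step duration is `block_kb / v`.
#' @param initiation Constant rate, [process_params()] or function of time
#'   (kb^-1 min^-1), converted to a per-step probability by [p_from_rate()].
#' @param snapshot_times Times (minutes) at which to record each fiber; a
#'   snapshot is taken at the first step whose mid-step time reaches the
#'   requested time.
#' @param snapshot_f Alternative: record a fiber when its replicated fraction
#'   first reaches a target; one target per fiber, recycled over
#'   `snapshot_f`.
#' @param seed Integer seed; per-fiber substreams are derived from it.
#' @param group Optional label stored on every record.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_fibers = 100, n_blocks = 150, block_kb = 1, v = 1,
                       initiation = 0.03, snapshot_times = NULL,
                       snapshot_f = NULL, seed = 1, group = NULL) {
  stop_if_not_scalar(v, "v", positive = TRUE)
  if (is.null(snapshot_times) && is.null(snapshot_f)) {
    stop("give snapshot_times or snapshot_f", call. = FALSE)
  }
  if (!is.null(snapshot_f) && any(snapshot_f <= 0 | snapshot_f >= 1)) {
    stop("snapshot_f targets must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_fibers = as.integer(n_fibers),
                 n_blocks = as.integer(n_blocks),
                 block_kb = block_kb, v = v, initiation = initiation,
                 snapshot_times = snapshot_times, snapshot_f = snapshot_f,
                 seed = as.integer(seed), group = group),
            class = "sim_config")
}

## Core per-fiber engine. p_step(k) gives the firing probability for step k.
## Returns list(step = snapshot step, signal = 0/1 vector) for each snapshot.
## Snapshots: either at the steps in snapshot_steps (recorded after the
## step's fork moves and firing), or at the first step where f >= target_f.
## forced_origins: optional 2-column matrix (step, block) of deterministic
## firings, used to probe the growth rules in isolation.
simulate_fiber_signal <- function(n_blocks, p_step, snapshot_steps = NULL,
                                  target_f = NULL, max_steps = 100000L,
                                  forced_origins = NULL) {
  x <- integer(n_blocks)
  fork_pos <- integer(0)
  fork_dir <- integer(0)
  snaps <- list()
  want <- sort(unique(as.integer(snapshot_steps)))
  k <- 0L
  repeat {
    k <- k + 1L
    ## forks move: each converts its next unreplicated block or terminates
    if (length(fork_pos)) {
      keep <- rep(FALSE, length(fork_pos))
      for (i in seq_along(fork_pos)) {
        pos <- fork_pos[i]
        if (pos >= 1L && pos <= n_blocks && x[pos] == 0L) {
          x[pos] <- 1L
          fork_pos[i] <- pos + fork_dir[i]
          keep[i] <- TRUE
        }
      }
      fork_pos <- fork_pos[keep]
      fork_dir <- fork_dir[keep]
    }
    ## origins fire in unreplicated blocks; visible only at the next step
    p <- p_step(k)
    fired <- integer(0)
    if (p > 0) {
      unrep <- which(x == 0L)
      if (length(unrep)) fired <- unrep[runif(length(unrep)) < p]
    }
    if (!is.null(forced_origins)) {
      forc <- forced_origins[forced_origins[, 1] == k, 2]
      fired <- union(fired, forc[x[forc] == 0L])
    }
    if (length(fired)) {
      fork_pos <- c(fork_pos, fired, fired - 1L)
      fork_dir <- c(fork_dir, rep(1L, length(fired)), rep(-1L, length(fired)))
    }
    if (!is.null(target_f)) {
      if (mean(x) >= target_f) return(list(list(step = k, signal = x)))
    } else {
      if (k %in% want) snaps[[length(snaps) + 1L]] <- list(step = k, signal = x)
      if (k >= max(want)) return(snaps)
    }
    if (k >= max_steps) {
      stop("fiber did not reach the target replicated fraction", call. = FALSE)
    }
  }
}

## Mid-step time of step k: the k-th synchronous update represents the
## continuous interval ((k-1) dt, k dt]; centring it halves the O(dt)
## discretization offset between the lattice and the continuum model.
mid_step_time <- function(k, dt) (k - 0.5) * dt

#' Continuum time of a lattice state
#'
#' For a constant initiation rate the expected interior unreplicated
#' fraction after k synchronous steps is `(1-p)^(k(k-1))`, which matches the
#' closed-form kinetics evaluated at `t = sqrt(k (k-1)) dt` — approximately
#' the mid-step time `(k - 1/2) dt` for large k, and exactly 0 at k = 1
#' (firing is invisible for one step). Use this mapping when comparing
#' lattice snapshots against the analytic model.
#'
#' @param step Step index k >= 1.
#' @param dt Step duration (minutes).
#' @return Effective continuum time(s).
#' @export
lattice_time <- function(step, dt = 1) sqrt(step * (step - 1)) * dt

#' Simulate replicating fibers
#'
#' Runs the lattice nucleation-and-growth simulation for each fiber of the
#' configuration and returns one [fiber_record()] per fiber and snapshot.
#' Identical seeds give identical output, and fiber i's trajectory does not
#' depend on `n_fibers`.
#'
#' @param config A [sim_config()].
#' @return List of fiber records; each carries attributes `time` (minutes,
#'   mid-step convention), `step` and `source_fiber`.
#' @export
simulate_fibers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dt <- config$block_kb / config$v
  pfun <- p_from_rate(config$initiation, config$block_kb, dt)
  p_step <- function(k) pfun(mid_step_time(k, dt))
  snapshot_steps <- NULL
  if (!is.null(config$snapshot_times)) {
    ## first step whose mid-step time reaches the requested time
    snapshot_steps <- pmax(1L, as.integer(ceiling(config$snapshot_times / dt + 0.5 - 1e-9)))
  }
  out <- list()
  for (i in seq_len(config$n_fibers)) {
    target <- if (!is.null(config$snapshot_f)) {
      config$snapshot_f[(i - 1L) %% length(config$snapshot_f) + 1L]
    } else {
      NULL
    }
    snaps <- with_seed(substream_seed(config$seed, i), {
      simulate_fiber_signal(config$n_blocks, p_step,
                            snapshot_steps = snapshot_steps,
                            target_f = target)
    })
    for (s in snaps) {
      time <- mid_step_time(s$step, dt)
      rec <- fiber_record(sprintf("sim%04d_s%d", i, s$step),
                          signal = s$signal,
                          resolution_kb = config$block_kb,
                          group = config$group)
      attr(rec, "time") <- time
      attr(rec, "step") <- s$step
      attr(rec, "source_fiber") <- i
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Synthetic two-process dataset with ground-truth labels
#'
#' Simulates fibers that each replicate entirely under one of two processes
#' (typically fast-fork/low-initiation versus slow-fork/high-initiation),
#' snapshotting each fiber when it first reaches a target replicated fraction
#' so that all fraction bins are populated. Labels are retained for recovery
#' scoring.
#'
#' @param params_fast,params_slow [process_params()] for the two processes.
#' @param prop_fast Proportion of fibers drawn from the fast process.
#' @param n_fibers Total number of fibers.
#' @param n_blocks,block_kb Fiber geometry.
#' @param targets_f Replicated-fraction targets cycled over fibers (default:
#'   midpoints of the seven default bins).
#' @param seed Integer seed.
#' @return List with `fibers` (list of fiber records) and `labels` (data
#'   frame `fiber_id`, `label`, `target_f`).
#' @export
generate_mixture_dataset <- function(params_fast, params_slow,
                                     prop_fast = 0.5, n_fibers = 200,
                                     n_blocks = 150, block_kb = 1,
                                     targets_f = NULL, seed = 1) {
  stopifnot(inherits(params_fast, "process_params"),
            inherits(params_slow, "process_params"),
            prop_fast >= 0, prop_fast <= 1)
  if (is.null(targets_f)) {
    e <- bin_scheme()$edges
    targets_f <- (head(e, -1) + tail(e, -1)) / 2
  }
  labels <- with_seed(substream_seed(seed, 0), {
    ifelse(runif(n_fibers) < prop_fast, "fast", "slow")
  })
  fibers <- vector("list", n_fibers)
  targ <- targets_f[(seq_len(n_fibers) - 1L) %% length(targets_f) + 1L]
  for (i in seq_len(n_fibers)) {
    par <- if (labels[i] == "fast") params_fast else params_slow
    cfg <- sim_config(n_fibers = 1, n_blocks = n_blocks, block_kb = block_kb,
                      v = par$v, initiation = par,
                      snapshot_f = targ[i],
                      seed = substream_seed(seed, i), group = labels[i])
    rec <- simulate_fibers(cfg)[[1]]
    rec$fiber_id <- sprintf("mix%04d_%s", i, labels[i])
    fibers[[i]] <- rec
  }
  list(fibers = fibers,
       labels = data.frame(fiber_id = vapply(fibers, function(x) x$fiber_id, character(1)),
                           label = labels, target_f = targ,
                           stringsAsFactors = FALSE))
}
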