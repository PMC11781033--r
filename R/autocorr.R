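## Unbiased auto-correlation of binarized fiber signals, bin-averaged
## profiles and pairwise similarity matrices.

#' Unbiased auto-correlation of a binary signal
#'
#' For a signal x of length N, `C(r) = sum(x[n + r] x[n]) / (N - r)` over the
#' overlapping part, the unbiased lagged-product estimator. Signals are not
#' mean-centred, so for a binary signal `C(0)` equals the replicated fraction
#' f and all values lie in \[0, 1\]. `C(-r) = C(r)`; only r >= 0 is returned.
#'
#' @param signal 0/1 vector.
#' @param max_lag Largest lag in units (default: `min(25 / resolution_kb,
#'   N - 1)`); must be `< length(signal)`.
#' @param resolution_kb kb per signal unit, used to express lags in kb.
#' @param f Replicated fraction to attach (default: computed from the signal).
#' @return A `correlation_profile`: list with `lags_kb`, `C`, `f`, `n` (= 1),
#'   `sd` (NULL for a single fiber).
#' @export
autocorrelation <- function(signal, max_lag = NULL, resolution_kb = 1,
                            f = NULL) {
  signal <- as.numeric(signal)
  N <- length(signal)
  if (N == 0L) stop("empty signal", call. = FALSE)
  if (is.null(max_lag)) max_lag <- min(floor(25 / resolution_kb), N - 1L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag >= N) {
    stop("max_lag must satisfy 0 <= max_lag < length(signal)", call. = FALSE)
  }
  C <- vapply(0:max_lag, function(r) {
    sum(signal[seq_len(N - r)] * signal[seq_len(N - r) + r]) / (N - r)
  }, numeric(1))
  structure(list(lags_kb = (0:max_lag) * resolution_kb, C = C,
                 f = f %||% mean(signal), n = 1L, sd = NULL),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation profile: %d lags (0..%g kb), f = %.3f, n = %d>\n",
              length(x$lags_kb), max(x$lags_kb), x$f, x$n))
  invisible(x)
}

#' Auto-correlation profile of one fiber record
#'
#' @param fiber A [fiber_record()].
#' @param max_lag_kb Largest lag in kb (default 25).
#' @return A `correlation_profile`.
#' @export
fiber_profile <- function(fiber, max_lag_kb = 25) {
  stopifnot(inherits(fiber, "fiber_record"))
  res <- fiber$resolution_kb
  max_lag <- min(floor(max_lag_kb / res), length(fiber$signal) - 1L)
  autocorrelation(fiber$signal, max_lag = max_lag, resolution_kb = res)
}

#' Stack correlation profiles into a matrix
#'
#' @param profiles List of `correlation_profile`s on the same lag grid.
#' @return Numeric matrix, one row per profile, columns named by lag.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  lags <- profiles[[1]]$lags_kb
  for (p in profiles) {
    if (!isTRUE(all.equal(p$lags_kb, lags))) {
      stop("profiles are not on a common lag grid", call. = FALSE)
    }
  }
  m <- do.call(rbind, lapply(profiles, function(p) p$C))
  colnames(m) <- paste0("r", lags)
  rownames(m) <- names(profiles)
  m
}

#' Mean auto-correlation profile of a set of fibers
#'
#' Per-lag mean and standard deviation across profiles (uniform weight per
#' fiber); the attached f is the mean of the member fractions. The SD of a
#' single profile is `NA`.
#'
#' @param profiles Non-empty list of `correlation_profile`s on a common grid.
#' @return A `correlation_profile` with `n` and per-lag `sd`.
#' @export
bin_mean_profile <- function(profiles) {
  if (length(profiles) == 0L) stop("empty bin", call. = FALSE)
  m <- profile_matrix(profiles)
  structure(list(lags_kb = profiles[[1]]$lags_kb,
                 C = unname(colMeans(m)),
                 f = mean(vapply(profiles, function(p) p$f, numeric(1))),
                 n = nrow(m),
                 sd = if (nrow(m) > 1L) unname(apply(m, 2, sd)) else rep(NA_real_, ncol(m))),
            class = "correlation_profile")
}

#' Per-bin mean profiles for a set of fibers
#'
#' Convenience wrapper: assigns fibers to bins, computes each fiber's
#' auto-correlation and averages within bins.
#'
#' @param fibers List of fiber records.
#' @param scheme A [bin_scheme()].
#' @param max_lag_kb Largest lag (kb), default 25.
#' @return Named list of `correlation_profile`s (one per non-empty bin, in
#'   scheme order); each carries attribute-free fields `n` and `sd`.
#' @export
bin_profiles <- function(fibers, scheme = bin_scheme(), max_lag_kb = 25) {
  tab <- assign_bins(fibers, scheme)
  keep <- which(!is.na(tab$bin_id))
  if (length(keep) == 0L) stop("no fibers pass the bin filters", call. = FALSE)
  prof <- lapply(fibers[keep], fiber_profile, max_lag_kb = max_lag_kb)
  sp <- split(prof, tab$bin_id[keep])
  sp <- sp[order(match(names(sp), scheme$bin_ids))]
  lapply(sp, bin_mean_profile)
}

#' Pairwise similarity matrix of correlation profiles
#'
#' `s_ij = 1 - Pearson correlation` between the two C(r) curves: 0 for
#' perfectly similar profiles, 1 for unrelated ones, up to 2 for
#' anti-correlated ones. Profiles with zero variance (constant C) have no
#' defined correlation and are excluded with a warning.
#'
#' @param profiles List of >= 2 `correlation_profile`s on a common lag grid,
#'   or a numeric matrix with one profile per row.
#' @return Symmetric matrix with zero diagonal; row/column names follow the
#'   input names.
#' @export
similarity_matrix <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (nrow(m) < 2L) stop("need at least two profiles", call. = FALSE)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("excluding %d constant profile(s) with undefined correlation",
                    sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
    if (nrow(m) < 2L) stop("fewer than two non-constant profiles", call. = FALSE)
  }
  s <- 1 - stats::cor(t(m))
  diag(s) <- 0
  s
}
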