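## Per-fiber classification: similarity distance of each fiber's
## auto-correlation profile to the correlation curves of the two fitted
## processes, and the fast/slow assignment (the off-diagonal scatter view).

#' Similarity distances of a fiber profile to the two model curves
#'
#' Computes `s = 1 - Pearson correlation` between the fiber's C(r) and the
#' model curve of each process, both evaluated on the fiber's lag grid at
#' the bin's mean replicated fraction. A zero-variance fiber profile has no
#' defined correlation; both distances are `NA` (with a warning), which
#' downstream labels as ambiguous.
#'
#' @param fiber_profile A `correlation_profile` (or bare numeric C values).
#' @param model_fast,model_slow Model C(r) values on the same lag grid.
#' @return Named numeric: `s_fast`, `s_slow`, each in \[0, 2\].
#' @export
similarity_to_processes <- function(fiber_profile, model_fast, model_slow) {
  C <- if (inherits(fiber_profile, "correlation_profile")) fiber_profile$C else as.numeric(fiber_profile)
  stopifnot(length(model_fast) == length(C), length(model_slow) == length(C))
  if (stats::var(C) == 0) {
    warning("zero-variance fiber profile: similarity undefined")
    return(c(s_fast = NA_real_, s_slow = NA_real_))
  }
  c(s_fast = 1 - stats::cor(C, model_fast),
    s_slow = 1 - stats::cor(C, model_slow))
}

#' Assign a fiber to the fast or slow process
#'
#' A fiber is `fast` when its distance to the fast-process curve is smaller
#' than to the slow one by more than `ambiguity_band`, `slow` in the
#' opposite case, and `ambiguous` within the band (points on the diagonal
#' are equally similar to both processes). Missing distances give
#' `ambiguous`.
#'
#' @param s_fast,s_slow Similarity distances.
#' @param ambiguity_band Half-width of the ambiguous zone around the
#'   diagonal (default 0: strict diagonal).
#' @return `"fast"`, `"slow"` or `"ambiguous"` (vectorized).
#' @export
assign_process <- function(s_fast, s_slow, ambiguity_band = 0) {
  stopifnot(ambiguity_band >= 0, length(s_fast) == length(s_slow))
  out <- rep("ambiguous", length(s_fast))
  ok <- is.finite(s_fast) & is.finite(s_slow)
  out[ok & s_fast < s_slow - ambiguity_band] <- "fast"
  out[ok & s_slow < s_fast - ambiguity_band] <- "slow"
  out
}

#' Classify binned fibers against a fitted two-process mixture
#'
#' For every fiber that passes the bin filters, computes its
#' auto-correlation profile, evaluates the fast and slow model curves at the
#' fiber's bin mean f on the same lag grid, and assigns the fiber by
#' similarity distance.
#'
#' @param fibers List of [fiber_record()]s.
#' @param mixture A [mixture_model()] (e.g. from [fit_dual_process()]).
#' @param scheme A [bin_scheme()].
#' @param max_lag_kb Lag grid limit (kb), default 25.
#' @param ambiguity_band Passed to [assign_process()].
#' @return Data frame: `fiber_id`, `bin_id`, `f`, `s_fast`, `s_slow`,
#'   `label`.
#' @export
classify_fibers <- function(fibers, mixture, scheme = bin_scheme(),
                            max_lag_kb = 25, ambiguity_band = 0) {
  stopifnot(inherits(mixture, "mixture_model"))
  tab <- assign_bins(fibers, scheme)
  keep <- which(!is.na(tab$bin_id))
  if (length(keep) == 0L) stop("no fibers pass the bin filters", call. = FALSE)
  prof <- lapply(fibers[keep], fiber_profile, max_lag_kb = max_lag_kb)
  bin_f <- tapply(tab$f[keep], tab$bin_id[keep], mean)
  res <- lapply(seq_along(keep), function(j) {
    b <- tab$bin_id[keep[j]]
    f_bin <- bin_f[[b]]
    lags <- prof[[j]]$lags_kb
    cf <- correlation_theory(lags, invert_time(f_bin, mixture$fast), mixture$fast)
    cs <- correlation_theory(lags, invert_time(f_bin, mixture$slow), mixture$slow)
    suppressWarnings(similarity_to_processes(prof[[j]], cf, cs))
  })
  s <- do.call(rbind, res)
  n_flat <- sum(!is.finite(s[, 1]))
  if (n_flat > 0) {
    warning(sprintf("%d fiber(s) with zero-variance profiles marked ambiguous", n_flat))
  }
  data.frame(fiber_id = tab$fiber_id[keep],
             bin_id = tab$bin_id[keep],
             f = tab$f[keep],
             s_fast = s[, "s_fast"], s_slow = s[, "s_slow"],
             label = assign_process(s[, "s_fast"], s[, "s_slow"], ambiguity_band),
             stringsAsFactors = FALSE)
}

#' Per-bin summary of process assignments
#'
#' @param assignments Data frame from [classify_fibers()].
#' @return List: `table` (the assignments) and `summary` (per bin: counts
#'   and fast/slow/ambiguous fractions).
#' @export
scatter_table <- function(assignments) {
  stopifnot(all(c("bin_id", "label") %in% names(assignments)))
  sp <- split(assignments, assignments$bin_id)
  summary <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    data.frame(bin_id = d$bin_id[1], n_fibers = n,
               frac_fast = mean(d$label == "fast"),
               frac_slow = mean(d$label == "slow"),
               frac_ambiguous = mean(d$label == "ambiguous"))
  }))
  rownames(summary) <- NULL
  list(table = assignments, summary = summary)
}
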