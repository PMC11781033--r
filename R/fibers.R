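## Single-molecule fiber records: track validation, binarization, replicated
## fractions, initiation counting and replicated-fraction binning.

#' Validate and merge replicated tracks on one fiber
#'
#' Tracks are fiber-local, 0-based, half-open intervals `[start_kb, end_kb)`
#' in kb. Overlapping or abutting tracks are merged into one (they describe a
#' single replicated stretch); a track extending beyond the fiber end is an
#' error because the record cannot be trusted.
#'
#' @param tracks A two-column matrix or data frame (`start_kb`, `end_kb`), or
#'   `NULL`/zero rows for an unreplicated fiber.
#' @param length_kb Fiber length in kb.
#' @return A data frame with columns `start_kb`, `end_kb`, sorted and
#'   non-overlapping.
#' @export
validate_tracks <- function(tracks, length_kb) {
  stop_if_not_scalar(length_kb, "length_kb", positive = TRUE)
  if (is.null(tracks) || NROW(tracks) == 0L) {
    return(data.frame(start_kb = numeric(0), end_kb = numeric(0)))
  }
  tracks <- as.data.frame(tracks)
  if (ncol(tracks) < 2L) stop("tracks need start and end columns", call. = FALSE)
  names(tracks)[1:2] <- c("start_kb", "end_kb")
  st <- as.numeric(tracks$start_kb)
  en <- as.numeric(tracks$end_kb)
  if (anyNA(st) || anyNA(en)) stop("tracks contain missing coordinates", call. = FALSE)
  if (any(st < 0)) stop("track start < 0", call. = FALSE)
  if (any(en <= st)) stop("track end must exceed track start", call. = FALSE)
  if (any(en > length_kb + 1e-9)) {
    stop(sprintf("track end %.3f kb exceeds fiber length %.3f kb",
                 max(en), length_kb), call. = FALSE)
  }
  o <- order(st, en)
  st <- st[o]; en <- en[o]
  # merge overlapping/abutting intervals
  ms <- st[1]; me <- en[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(st) > 1L) {
    for (i in 2:length(st)) {
      if (st[i] <= me) {
        me <- max(me, en[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- st[i]; me <- en[i]
      }
    }
  }
  data.frame(start_kb = c(out_s, ms), end_kb = c(out_e, me))
}

#' Binarize the replicated tracks of a fiber
#'
#' The fiber is divided into units of `resolution_kb` (the last unit may be
#' shorter). A unit scores 1 when at least half of it is covered by a
#' replicated track, 0 otherwise.
#'
#' @param length_kb Fiber length (kb).
#' @param tracks Replicated intervals, see [validate_tracks()].
#' @param resolution_kb Unit size in kb (default 1).
#' @return Integer vector of 0/1 of length `ceiling(length_kb / resolution_kb)`.
#' @examples
#' binarize_fiber(4, cbind(0, 2))        # 1 1 0 0
#' binarize_fiber(3, cbind(0.4, 1.2))    # 1 0 0
#' @export
binarize_fiber <- function(length_kb, tracks, resolution_kb = 1) {
  stop_if_not_scalar(resolution_kb, "resolution_kb", positive = TRUE)
  tracks <- validate_tracks(tracks, length_kb)
  n <- as.integer(ceiling(length_kb / resolution_kb - 1e-9))
  starts <- (seq_len(n) - 1) * resolution_kb
  ends <- pmin(starts + resolution_kb, length_kb)
  cov <- numeric(n)
  for (i in seq_len(nrow(tracks))) {
    cov <- cov + pmax(0, pmin(ends, tracks$end_kb[i]) - pmax(starts, tracks$start_kb[i]))
  }
  as.integer(cov >= 0.5 * (ends - starts))
}

#' Replicated fraction of a binary signal
#'
#' @param signal 0/1 vector (1 = replicated).
#' @return Mean of the signal, in \[0, 1\].
#' @export
replicated_fraction <- function(signal) {
  if (length(signal) == 0L) stop("empty signal", call. = FALSE)
  if (!all(signal %in% c(0, 1))) stop("signal must be binary 0/1", call. = FALSE)
  mean(signal)
}

#' Recover replicated intervals from a binary signal
#'
#' Inverse of [binarize_fiber()] at the unit level: maximal runs of 1s become
#' tracks in kb coordinates.
#'
#' @param signal 0/1 vector.
#' @param resolution_kb Unit size in kb.
#' @return Data frame `start_kb`, `end_kb`.
#' @export
tracks_from_signal <- function(signal, resolution_kb = 1) {
  r <- rle(as.integer(signal))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  data.frame(start_kb = starts[keep] * resolution_kb,
             end_kb = ends[keep] * resolution_kb)
}

#' Count new initiation events on a fiber
#'
#' New initiations are replication eyes strictly shorter than
#' `eye_threshold_kb` (default 3 kb): tracks too short to be older than the
#' detectability window.
#'
#' @param tracks Replicated intervals (see [validate_tracks()]); assumed
#'   already merged.
#' @param eye_threshold_kb Strict upper bound on eye length (kb).
#' @return Integer count.
#' @export
count_new_initiations <- function(tracks, eye_threshold_kb = 3) {
  stop_if_not_scalar(eye_threshold_kb, "eye_threshold_kb", positive = TRUE)
  if (is.null(tracks) || NROW(tracks) == 0L) return(0L)
  tracks <- as.data.frame(tracks)
  len <- as.numeric(tracks[[2]]) - as.numeric(tracks[[1]])
  sum(len < eye_threshold_kb)
}

#' Initiation rate of one fiber
#'
#' `I = N / (L (1 - f) dt)`: new initiations per kb of unreplicated DNA per
#' minute. `dt_min` is the time window in which an initiation stays detectable
#' as a short eye; 3 min corresponds to the 3 kb eye threshold at a typical
#' fork speed of ~0.5 kb/min (an eye of age `dt` has length `2 v dt`).
#'
#' @param N Number of new initiations (eyes below threshold).
#' @param L_kb Fiber length (kb).
#' @param f Replicated fraction, in \[0, 1).
#' @param dt_min Detectability window (minutes), default 3.
#' @return Initiation rate in kb^-1 min^-1.
#' @export
initiation_rate <- function(N, L_kb, f, dt_min = 3) {
  stop_if_not_scalar(L_kb, "L_kb", positive = TRUE)
  stop_if_not_scalar(dt_min, "dt_min", positive = TRUE)
  stop_if_not_scalar(f, "f")
  if (f < 0 || f >= 1) stop("f must be in [0, 1): no unreplicated DNA at f = 1", call. = FALSE)
  if (N < 0) stop("N must be >= 0", call. = FALSE)
  N / (L_kb * (1 - f) * dt_min)
}

#' Detectability window for lattice-simulated fibers
#'
#' On a lattice with blocks of `block_kb` and one block converted per fork per
#' step, an eye of age m steps is 2 m blocks long; eyes below the threshold
#' are therefore at most `ceiling(thr / (2 block)) - 1` steps old, which fixes
#' the time window to use in [initiation_rate()] for simulated data.
#'
#' @param eye_threshold_kb Eye-length threshold (kb).
#' @param v Fork speed (kb/min).
#' @param block_kb Lattice block size (kb).
#' @return Window in minutes.
#' @export
detectability_window <- function(eye_threshold_kb = 3, v = 1, block_kb = 1) {
  m <- ceiling(eye_threshold_kb / (2 * block_kb)) - 1
  if (m < 1) stop("eye threshold below one lattice growth step", call. = FALSE)
  m * block_kb / v
}

#' Construct a fiber record
#'
#' A fiber record holds one DNA molecule: its id, length, replicated tracks,
#' the binarized signal at a fixed resolution and the replicated fraction f.
#' Either `tracks` or `signal` may be given; the other is derived.
#'
#' @param fiber_id Label.
#' @param length_kb Fiber length (kb). Defaults to `length(signal) *
#'   resolution_kb` when only a signal is given.
#' @param tracks Replicated intervals (optional).
#' @param signal Binary signal (optional).
#' @param resolution_kb Unit size (kb), default 1.
#' @param group Optional experiment/timepoint label.
#' @return An object of class `fiber_record`.
#' @export
fiber_record <- function(fiber_id, length_kb = NULL, tracks = NULL,
                         signal = NULL, resolution_kb = 1, group = NULL) {
  if (is.null(tracks) && is.null(signal)) {
    stop("need tracks or signal", call. = FALSE)
  }
  if (is.null(signal)) {
    signal <- binarize_fiber(length_kb, tracks, resolution_kb)
    tracks <- validate_tracks(tracks, length_kb)
  } else {
    signal <- as.integer(signal)
    if (!all(signal %in% c(0L, 1L))) stop("signal must be binary 0/1", call. = FALSE)
    if (is.null(length_kb)) length_kb <- length(signal) * resolution_kb
    if (is.null(tracks)) {
      tracks <- tracks_from_signal(signal, resolution_kb)
    } else {
      tracks <- validate_tracks(tracks, length_kb)
    }
  }
  structure(list(fiber_id = as.character(fiber_id),
                 length_kb = length_kb,
                 tracks = tracks,
                 signal = signal,
                 resolution_kb = resolution_kb,
                 f = replicated_fraction(signal),
                 group = group),
            class = "fiber_record")
}

#' @export
print.fiber_record <- function(x, ...) {
  cat(sprintf("<fiber %s: %.0f kb, %d tracks, f = %.3f%s>\n",
              x$fiber_id, x$length_kb, nrow(x$tracks), x$f,
              if (is.null(x$group)) "" else paste0(", group ", x$group)))
  invisible(x)
}

#' Summary table of a list of fiber records
#'
#' @param fibers List of [fiber_record()] objects.
#' @return Data frame with `fiber_id`, `length_kb`, `f`, `n_tracks`, `group`.
#' @export
fiber_table <- function(fibers) {
  stopifnot(length(fibers) > 0L)
  data.frame(
    fiber_id = vapply(fibers, function(x) x$fiber_id, character(1)),
    length_kb = vapply(fibers, function(x) x$length_kb, numeric(1)),
    f = vapply(fibers, function(x) x$f, numeric(1)),
    n_tracks = vapply(fibers, function(x) nrow(x$tracks), integer(1)),
    group = vapply(fibers, function(x) x$group %||% NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Replicated-fraction bin scheme
#'
#' Default bins follow the seven half-open intervals f1 = (0, 0.11], ...,
#' f7 = (0.64, 0.75] with a > 80 kb fiber-length filter, so fully
#' unreplicated fibers and fibers above 75% replication are excluded.
#'
#' @param edges Strictly increasing bin boundaries in (0, 1\]; bin i is
#'   `(edges[i], edges[i+1]]`.
#' @param min_length_kb Only fibers strictly longer than this are kept.
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme <- function(edges = c(0, 0.11, 0.21, 0.32, 0.42, 0.54, 0.64, 0.75),
                       min_length_kb = 80) {
  stopifnot(is.numeric(edges), length(edges) >= 2L, all(diff(edges) > 0),
            edges[1] >= 0, edges[length(edges)] <= 1)
  structure(list(edges = edges,
                 min_length_kb = min_length_kb,
                 f_min = edges[1],
                 f_max = edges[length(edges)],
                 bin_ids = paste0("f", seq_len(length(edges) - 1L))),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin scheme: %d bins on (%g, %g], fibers > %g kb>\n",
              length(x$bin_ids), x$f_min, x$f_max, x$min_length_kb))
  invisible(x)
}

#' Assign fibers to replicated-fraction bins
#'
#' Fibers failing the length filter or with f outside `(f_min, f_max]` get
#' `NA`; every retained fiber lands in exactly one bin (half-open intervals
#' `(lo, hi]`).
#'
#' @param fibers List of fiber records, or a data frame with columns
#'   `fiber_id`, `length_kb`, `f`.
#' @param scheme A [bin_scheme()].
#' @return The fiber table with a `bin_id` column (`NA` = excluded).
#' @export
assign_bins <- function(fibers, scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  tab <- if (is.data.frame(fibers)) fibers else fiber_table(fibers)
  bin <- as.character(cut(tab$f, breaks = scheme$edges,
                          labels = scheme$bin_ids, right = TRUE))
  bin[tab$length_kb <= scheme$min_length_kb] <- NA_character_
  tab$bin_id <- bin
  tab
}

#' Per-bin initiation-rate curve
#'
#' Averages the per-fiber initiation rate (eyes below the eye threshold,
#' normalized by unreplicated length and the detectability window) within each
#' replicated-fraction bin. The dispersion of a single fiber is reported as
#' `NA`, not 0.
#'
#' @param fibers List of fiber records.
#' @param scheme A [bin_scheme()].
#' @param eye_threshold_kb Eye-length threshold (kb), default 3.
#' @param dt_min Detectability window (minutes), default 3.
#' @return Data frame: `bin_id`, `mean_f`, `I`, `sd`, `n_fibers`, ordered by
#'   bin; empty bins are absent.
#' @export
bin_initiation_curve <- function(fibers, scheme = bin_scheme(),
                                 eye_threshold_kb = 3, dt_min = 3) {
  tab <- assign_bins(fibers, scheme)
  I <- vapply(fibers, function(x) {
    initiation_rate(count_new_initiations(x$tracks, eye_threshold_kb),
                    x$length_kb, x$f, dt_min)
  }, numeric(1))
  keep <- !is.na(tab$bin_id)
  if (!any(keep)) {
    return(data.frame(bin_id = character(0), mean_f = numeric(0),
                      I = numeric(0), sd = numeric(0), n_fibers = integer(0)))
  }
  sp <- split(data.frame(f = tab$f[keep], I = I[keep]), tab$bin_id[keep])
  out <- do.call(rbind, lapply(names(sp), function(b) {
    d <- sp[[b]]
    data.frame(bin_id = b, mean_f = mean(d$f), I = mean(d$I),
               sd = if (nrow(d) > 1L) sd(d$I) else NA_real_,
               n_fibers = nrow(d))
  }))
  out[order(match(out$bin_id, scheme$bin_ids)), , drop = FALSE]
}
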