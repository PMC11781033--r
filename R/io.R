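## Readers/writers for the canonical tab-delimited formats and the
## end-to-end pipeline. All tables are TSV with a header row, '.' decimals
## and kb units.

#' Read a fiber table
#'
#' Two dialects are supported. `"tracks"`: one row per replicated track with
#' columns `fiber_id`, `fiber_length_kb`, `track_start_kb`, `track_end_kb`;
#' fibers without tracks appear once with empty track fields; rows sharing a
#' `fiber_id` are combined into one record (overlapping tracks merged with a
#' warning). `"signal"`: columns `fiber_id`, `signal` with a comma-separated
#' 0/1 value per unit. Malformed rows or records are rejected with a warning
#' that names the offending lines.
#'
#' @param path File path.
#' @param dialect `"tracks"` or `"signal"`.
#' @param resolution_kb Unit size (kb) used for binarization, default 1.
#' @return List of [fiber_record()]s.
#' @export
read_fiber_table <- function(path, dialect = c("tracks", "signal"),
                             resolution_kb = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (dialect == "signal") {
    stopifnot(all(c("fiber_id", "signal") %in% names(tab)))
    return(lapply(seq_len(nrow(tab)), function(i) {
      sig <- as.integer(strsplit(tab$signal[i], ",", fixed = TRUE)[[1]])
      fiber_record(tab$fiber_id[i], signal = sig, resolution_kb = resolution_kb)
    }))
  }
  stopifnot(all(c("fiber_id", "fiber_length_kb", "track_start_kb", "track_end_kb") %in% names(tab)))
  tab$.line <- seq_len(nrow(tab)) + 1L  # 1-based file lines incl. header
  has_track <- !(is.na(tab$track_start_kb) & is.na(tab$track_end_kb))
  bad_row <- has_track & (is.na(tab$track_start_kb) | is.na(tab$track_end_kb) |
                            tab$track_end_kb <= tab$track_start_kb |
                            tab$track_start_kb < 0)
  if (any(bad_row)) {
    warning(sprintf("rejected %d malformed track row(s) at line(s) %s",
                    sum(bad_row), paste(tab$.line[bad_row], collapse = ", ")))
    tab <- tab[!bad_row, , drop = FALSE]
    has_track <- has_track[!bad_row]
  }
  fibers <- list()
  for (id in unique(tab$fiber_id)) {
    rows <- tab[tab$fiber_id == id, , drop = FALSE]
    L <- rows$fiber_length_kb[1]
    tr <- rows[!(is.na(rows$track_start_kb) & is.na(rows$track_end_kb)),
               c("track_start_kb", "track_end_kb"), drop = FALSE]
    n_raw <- nrow(tr)
    rec <- tryCatch({
      merged <- validate_tracks(if (n_raw) data.frame(start_kb = tr$track_start_kb,
                                                      end_kb = tr$track_end_kb) else NULL, L)
      if (n_raw > nrow(merged)) {
        warning(sprintf("fiber '%s': merged %d overlapping/abutting track(s)",
                        id, n_raw - nrow(merged)))
      }
      fiber_record(id, L, tracks = merged, resolution_kb = resolution_kb)
    }, error = function(e) {
      warning(sprintf("rejected fiber '%s' (lines %s): %s", id,
                      paste(rows$.line, collapse = ", "), conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) fibers[[length(fibers) + 1L]] <- rec
  }
  if (length(fibers) == 0L) stop("no valid fiber records in input", call. = FALSE)
  fibers
}

#' Write a fiber table in the tracks dialect
#'
#' @param fibers List of fiber records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(fibers, path) {
  rows <- do.call(rbind, lapply(fibers, function(x) {
    if (nrow(x$tracks) == 0L) {
      data.frame(fiber_id = x$fiber_id, fiber_length_kb = x$length_kb,
                 track_start_kb = NA_real_, track_end_kb = NA_real_)
    } else {
      data.frame(fiber_id = x$fiber_id, fiber_length_kb = x$length_kb,
                 track_start_kb = x$tracks$start_kb,
                 track_end_kb = x$tracks$end_kb)
    }
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

profiles_to_table <- function(profiles) {
  do.call(rbind, lapply(names(profiles), function(b) {
    p <- profiles[[b]]
    data.frame(bin_id = b, lag_kb = p$lags_kb, C = p$C,
               sd = if (is.null(p$sd)) NA_real_ else p$sd, n = p$n, f = p$f)
  }))
}

#' Run the full analysis pipeline
#'
#' Chains binning, per-bin auto-correlation profiles, the initiation curve,
#' the model fit, per-bin clustering and (for mixture fits) per-fiber
#' classification, writing one file per stage into `outdir`: `binned.tsv`,
#' `profiles.tsv`, `init.tsv`, `fit.json`, `clusters.tsv`,
#' `assignments.tsv`, `config.json` and `run.log`. Outputs are deterministic
#' given the same inputs, configuration and seed.
#'
#' @param fibers List of fiber records, or a path read with
#'   [read_fiber_table()].
#' @param outdir Output directory (created if needed).
#' @param scheme A [bin_scheme()].
#' @param kind Model kind, see [fit_dual_process()]; `"single"` skips
#'   classification.
#' @param max_lag_kb Profile lag limit (kb), default 25.
#' @param r_max_fit Fit lag limit (kb), default 40.
#' @param eye_threshold_kb,dt_min Initiation-rate settings (defaults 3 kb,
#'   3 min).
#' @param ga A [ga_config()]; its seed is the pipeline seed.
#' @param cluster_k_range Candidate cluster counts per bin (default 2:5).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(fibers, outdir, scheme = bin_scheme(),
                         kind = "dual", max_lag_kb = 25, r_max_fit = 40,
                         eye_threshold_kb = 3, dt_min = 3,
                         ga = ga_config(), cluster_k_range = 2:5) {
  if (is.character(fibers)) fibers <- read_fiber_table(fibers)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  cat(sprintf("pipeline start seed=%d kind=%s\n", ga$seed, kind), file = logf)
  say <- function(...) cat(sprintf(...), file = logf, append = TRUE)

  binned <- assign_bins(fibers, scheme)
  say("binning: %d fibers in, %d retained (%d excluded by length/f filters)\n",
      nrow(binned), sum(!is.na(binned$bin_id)), sum(is.na(binned$bin_id)))
  write_tsv(binned, file.path(outdir, "binned.tsv"))

  profiles <- bin_profiles(fibers, scheme, max_lag_kb = max(max_lag_kb, r_max_fit))
  write_tsv(profiles_to_table(profiles), file.path(outdir, "profiles.tsv"))
  say("profiles: %d bins populated\n", length(profiles))

  init_curve <- bin_initiation_curve(fibers, scheme, eye_threshold_kb, dt_min)
  write_tsv(init_curve, file.path(outdir, "init.tsv"))

  fit <- if (kind == "single") {
    fit_single_process(profiles, init_curve, ga = ga, r_max_fit = r_max_fit)
  } else {
    fit_dual_process(profiles, init_curve, kind = kind, ga = ga,
                     r_max_fit = r_max_fit)
  }
  say("fit: kind=%s chi2=%.5g generations=%d converged=%s\n",
      kind, fit$fitness, fit$generations, fit$converged)
  fit_json <- if (kind == "single") {
    list(kind = kind, params = unclass(fit$params), fitness = fit$fitness,
         generations = fit$generations, converged = fit$converged,
         seed = ga$seed)
  } else {
    list(kind = kind, fast = unclass(fit$params$fast),
         slow = unclass(fit$params$slow),
         theta = as.list(fit$params$theta), fitness = fit$fitness,
         generations = fit$generations, converged = fit$converged,
         seed = ga$seed)
  }
  jsonlite::write_json(fit_json, file.path(outdir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  keep <- which(!is.na(binned$bin_id))
  prof_fibers <- lapply(fibers[keep], fiber_profile, max_lag_kb = max_lag_kb)
  clusters <- list()
  for (b in names(profiles)) {
    idx <- which(binned$bin_id[keep] == b)
    if (length(idx) < 4L) next
    mat <- profile_matrix(prof_fibers[idx])
    rownames(mat) <- binned$fiber_id[keep][idx]
    sol <- tryCatch(choose_k(mat, cluster_k_range), error = function(e) NULL)
    if (!is.null(sol)) clusters[[b]] <- sol
  }
  if (length(clusters)) {
    ctab <- do.call(rbind, lapply(names(clusters), function(b) {
      s <- clusters[[b]]
      data.frame(bin_id = b, fiber_id = names(s$assignments),
                 cluster_id = s$assignments, silhouette = s$silhouette)
    }))
    write_tsv(ctab, file.path(outdir, "clusters.tsv"))
    say("clustering: %d bins clustered\n", length(clusters))
  }

  assignments <- NULL
  if (kind != "single") {
    assignments <- classify_fibers(fibers, fit$params, scheme, max_lag_kb)
    st <- scatter_table(assignments)
    write_tsv(st$table, file.path(outdir, "assignments.tsv"))
    say("classification: %d fibers, fractions fast/slow/ambiguous = %s\n",
        nrow(assignments),
        paste(round(colMeans(st$summary[, c("frac_fast", "frac_slow", "frac_ambiguous")]), 3),
              collapse = "/"))
  }

  jsonlite::write_json(
    list(kind = kind, seed = ga$seed, max_lag_kb = max_lag_kb,
         r_max_fit = r_max_fit, eye_threshold_kb = eye_threshold_kb,
         dt_min = dt_min, bin_edges = scheme$edges,
         min_length_kb = scheme$min_length_kb),
    file.path(outdir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  say("pipeline done\n")
  invisible(list(binned = binned, profiles = profiles,
                 init_curve = init_curve, fit = fit, clusters = clusters,
                 assignments = assignments))
}
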