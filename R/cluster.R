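## Unsupervised structure in per-bin correlation profiles: PCA variance
## spectra, WPGMA hierarchical clustering under the correlation distance,
## and silhouette-based choice of the number of clusters.

#' Explained-variance spectrum of a profile matrix
#'
#' PCA on the mean-centred (not standardized: all columns share units)
#' matrix of auto-correlation profiles, one fiber per row.
#'
#' @param profile_matrix Numeric matrix (or list of profiles, stacked with
#'   [profile_matrix()]).
#' @return Vector of non-negative explained-variance fractions, descending
#'   and summing to 1.
#' @export
pca_variance <- function(profile_matrix) {
  m <- if (is.matrix(profile_matrix)) profile_matrix else profile_matrix(profile_matrix)
  if (nrow(m) < 2L) stop("need at least two profiles for PCA", call. = FALSE)
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  if (sum(ev) == 0) stop("zero total variance: all profiles identical", call. = FALSE)
  ev / sum(ev)
}

## correlation distance (1 - Pearson) between profile rows, dropping
## zero-variance rows as in similarity_matrix()
correlation_distance <- function(m) {
  s <- similarity_matrix(m)
  list(D = s, kept = rownames(s) %||% seq_len(nrow(s)))
}

#' Silhouette values for a clustering
#'
#' `S_i = (b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean distance from
#' point i to the other members of its cluster and `b_i` the smallest mean
#' distance to another cluster. Members of singleton clusters get `S_i = 0`
#' (their within-cluster distance is undefined).
#'
#' @param assignments Integer/character cluster id per point (>= 2 distinct).
#' @param distance_matrix Square symmetric distance matrix.
#' @return List: `S` (per point, in \[-1, 1\]) and `mean`.
#' @export
silhouette_values <- function(assignments, distance_matrix) {
  D <- as.matrix(distance_matrix)
  n <- nrow(D)
  stopifnot(length(assignments) == n)
  cl <- as.character(assignments)
  ids <- unique(cl)
  if (length(ids) < 2L) stop("need at least two clusters", call. = FALSE)
  S <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) { S[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ids, cl[i]), function(g) {
      mean(D[i, cl == g])
    }, numeric(1)))
    S[i] <- (b - a) / max(a, b)
  }
  list(S = S, mean = mean(S))
}

#' WPGMA hierarchical clustering of correlation profiles
#'
#' Agglomerates profiles under the distance 1 - Pearson correlation with
#' weighted-average (WPGMA) linkage and cuts the tree into exactly `k`
#' clusters. Clusters are renumbered by size, smallest first, so cluster 1
#' is the minority group. Zero-variance profiles are excluded (with a
#' warning) before clustering.
#'
#' @param profiles List of profiles or a profile matrix.
#' @param k Number of clusters, between 2 and the number of usable profiles.
#' @return Object of class `cluster_solution`: `k`, `assignments` (named by
#'   fiber when names are available), `sizes`, `mean_profiles`, `silhouette`
#'   (per point), `mean_silhouette`, `merge_heights`.
#' @export
hierarchical_clusters <- function(profiles, k = 2) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("excluding %d constant profile(s) before clustering", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  n <- nrow(m)
  if (k < 2L || k > n) stop("k must be between 2 and the number of profiles", call. = FALSE)
  D <- 1 - stats::cor(t(m))
  hc <- stats::hclust(stats::as.dist(D), method = "mcquitty")
  raw <- stats::cutree(hc, k = k)
  ## smaller cluster first (stable on ties)
  sizes <- tabulate(raw, nbins = k)
  relabel <- integer(k)
  relabel[order(sizes, seq_len(k))] <- seq_len(k)
  assignments <- relabel[raw]
  names(assignments) <- rownames(m)
  sil <- silhouette_values(assignments, D)
  mean_profiles <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(m[assignments == g, , drop = FALSE])
  }))
  rownames(mean_profiles) <- paste0("cluster", seq_len(k))
  structure(list(k = k, assignments = assignments,
                 sizes = as.integer(table(assignments)),
                 mean_profiles = mean_profiles,
                 silhouette = sil$S, mean_silhouette = sil$mean,
                 merge_heights = hc$height),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<clustering: k = %d, sizes = %s, mean silhouette = %.3f>\n",
              x$k, paste(x$sizes, collapse = "/"), x$mean_silhouette))
  invisible(x)
}

#' Choose the number of clusters by mean silhouette
#'
#' Cuts the WPGMA tree into each k of `k_range`, scores every solution by
#' its mean silhouette under the correlation distance and returns the best;
#' ties go to the smallest k (parsimony).
#'
#' @param profiles List of profiles or a profile matrix.
#' @param k_range Candidate cluster counts (default 2:5).
#' @return The best `cluster_solution`, with the score table in
#'   `$k_scores`.
#' @export
choose_k <- function(profiles, k_range = 2:5) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(m) - 1L]
  if (length(k_range) == 0L) stop("not enough profiles for any candidate k", call. = FALSE)
  sols <- lapply(k_range, function(k) hierarchical_clusters(m, k))
  scores <- vapply(sols, function(s) s$mean_silhouette, numeric(1))
  best <- which.max(scores)  # which.max takes the first (smallest k) on ties
  sol <- sols[[best]]
  sol$k_scores <- data.frame(k = k_range, mean_silhouette = scores)
  sol
}
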