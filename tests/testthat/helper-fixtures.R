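## Shared fixtures built in code at test time.

## small random set of valid tracks on a fiber of length L
random_tracks <- function(L, n_max = 5) {
  n <- sample.int(n_max, 1)
  pts <- sort(runif(2 * n, 0, L))
  tr <- data.frame(start_kb = pts[seq(1, 2 * n, 2)], end_kb = pts[seq(2, 2 * n, 2)])
  tr[tr$end_kb > tr$start_kb, , drop = FALSE]
}

## naive double-loop auto-correlation oracle (unbiased lagged products)
autocorr_oracle <- function(x, max_lag) {
  N <- length(x)
  sapply(0:max_lag, function(r) {
    acc <- 0
    for (n in seq_len(N - r)) acc <- acc + x[n] * x[n + r]
    acc / (N - r)
  })
}

## two well-separated processes used across clustering/classification tests
fast_params <- function() process_params(v = 1.2, I0 = 0.005, alpha = 1)
slow_params <- function() process_params(v = 0.2, I0 = 0.04, alpha = 1)

## cached small mixture dataset (generated once per test run)
mixture_fixture <- local({
  cache <- NULL
  function(n_fibers = 140, seed = 2024) {
    if (is.null(cache)) {
      cache <<- suppressWarnings(generate_mixture_dataset(
        fast_params(), slow_params(), prop_fast = 0.5,
        n_fibers = n_fibers, seed = seed))
    }
    cache
  }
})
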