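# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Gaussian two-cluster feature blocks that a linear SVM separates easily.
make_separable_block <- function(n_per_class = 120, p = 6, sep = 4,
                                 seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(rnorm(n_per_class * p, mean = sep / 2), ncol = p),
      matrix(rnorm(n_per_class * p, mean = -sep / 2), ncol = p)
    )
    lab <- factor(rep(c("integrated", "segregated"), each = n_per_class),
                  levels = c("integrated", "segregated"))
    ord <- sample(nrow(X))
    list(
      features = feature_matrix(time = seq_len(nrow(X)) / 100, X = X[ord, ]),
      labels = lab[ord]
    )
  })
}

# Deterministic sawtooth gaze trace with exactly known fast phases: slow
# drift opposite to fast_dir at `v` deg/s, fast phases of `fast_len` samples
# covering `fast_ext` deg, repeated every `period` samples.
make_sawtooth_trace <- function(duration = 10, rate = 1000, v = 1.9,
                                fast_len = 30, fast_ext = 3,
                                period = 1500, fast_dir = -1,
                                noise_sd = 0, seed = 1) {
  n <- duration * rate
  vel <- rep(-fast_dir * v / rate, n)
  fast <- rep(FALSE, n)
  starts <- seq(period, n - fast_len, by = period)
  for (s in starts) {
    vel[s:(s + fast_len - 1)] <- fast_dir * fast_ext / fast_len
    fast[s:(s + fast_len - 1)] <- TRUE
  }
  x <- cumsum(vel)
  if (noise_sd > 0) x <- x + withr::with_seed(seed, rnorm(n, 0, noise_sd))
  list(trace = gaze_trace(t = (seq_len(n) - 1) / rate, x = x, rate = rate),
       fast = fast, starts = starts, fast_len = fast_len)
}

# Quick constant-state latent trace.
constant_latent <- function(state = 1L, duration = 10, rate = 1000) {
  okncouple:::new_percept_trace(rep(as.integer(state), duration * rate), rate)
}

# Report trace straight from integer codes.
report_from_codes <- function(codes, rate = 100) {
  okncouple:::new_report_trace(as.integer(codes), rate)
}
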