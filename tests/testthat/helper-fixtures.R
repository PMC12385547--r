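# Shared fixtures: small phantoms and deterministic stacks built in code.

# noise-free, motion-free single-repetition phantom (default anatomy)
clean_phantom <- function(...) {
  phantom_spec(noise_sigma = 0, motion_model = "none", n_repetitions = 1, ...)
}

# quick-generation noisy phantom with fewer repetitions
fast_noisy_phantom <- function(seed = 1, n_repetitions = 8L, ...) {
  phantom_spec(seed = seed, n_repetitions = n_repetitions, ...)
}

# deterministic tiny multi-volume stack: constant images with known values
toy_stack <- function(values = c(10, 5, 5, 5, 5, 5, 5), nr = 9, nc = 9,
                      b = 750) {
  nvol <- length(values)
  vox <- array(rep(values, each = nr * nc), c(nr, nc, nvol))
  meta <- data.frame(volume = seq_len(nvol),
                     b = c(0, rep(b, nvol - 1)),
                     direction_index = seq_len(nvol) - 1L,
                     repetition = 1L)
  dwi_stack(vox, c(0.78, 0.78), meta)
}

# random symmetric positive-definite tensor 6-vector (units of 1e-3 mm^2/s)
random_spd_tensor <- function() {
  A <- matrix(rnorm(9, sd = 0.5), 3, 3)
  D <- crossprod(A) + diag(3) * 0.2
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# independent brute-force two-way ANOVA sums of squares for an n x k matrix
brute_force_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)))
}
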