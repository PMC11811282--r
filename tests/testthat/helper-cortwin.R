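# Shared factories for small test networks and datasets.

tiny_spec <- function(...) {
  network_spec(n_regions = 2, channels_per_region = 2, q1 = 1, q2 = 2,
               q3 = 2, p1 = 4, p2 = 5, tau1 = 2, tau2 = 4,
               meta_prior = 0.01, ...)
}

# random forward-pass ingredients for a spec
tiny_problem <- function(spec, T = 6, seed = 42) {
  set.seed(seed)
  list(x = matrix(runif(n_channels(spec) * T, -0.5, 0.5),
                  n_channels(spec), T),
       alpha = rnorm(cortwin:::alpha_length(spec, T), 0, 0.3),
       eps = cortwin:::draw_eps(spec, T))
}

# two-channel deterministic sinusoid target for convergence tests
sinusoid_sequence <- function(T = 100) {
  tt <- seq_len(T)
  x <- rbind(0.5 * sin(2 * pi * tt / 25), 0.4 * sin(2 * pi * tt / 50 + 1))
  signal_sequence(x, sampling_rate = 100, condition = "awake",
                  individual = "I1", region_map = rep("R1", 2))
}

# numeric central-difference gradient of f at par over coordinates idx
num_grad <- function(f, par, idx, h = 1e-6) {
  vapply(idx, function(i) {
    p1 <- par; p2 <- par
    p1[i] <- p1[i] + h; p2[i] <- p2[i] - h
    (f(p1) - f(p2)) / (2 * h)
  }, numeric(1))
}

# brute-force silhouette oracle: direct transcription of the defining
# averages, independent of the package implementation
silhouette_brute <- function(points, labels) {
  points <- as.matrix(points); labels <- as.character(labels)
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) return(0)
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(lb) {
      mean(vapply(which(labels == lb), function(j) d(i, j), numeric(1)))
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}
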