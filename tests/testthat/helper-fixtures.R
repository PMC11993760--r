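# Shared fixtures: all generated in code at test time.

flat_profile <- function(n = 1.4, samples = 256) {
  build_profile(surface_params(W = 100, H = 0, W_V = 0, u_h = 0, u_w = 1,
                               n = n), 1, samples)
}

skin_presets <- function() {
  table1_presets()[c("sample1", "sample2", "sample3", "sample4")]
}

# brute-force first-intersection oracle: scans every polyline segment
brute_force_hit <- function(profile, origin, direction, eps = 1e-6) {
  d <- direction / sqrt(sum(direction^2))
  x <- profile$x
  h <- profile$h
  best_t <- Inf
  best <- NULL
  m <- length(x)
  for (i in seq_len(m - 1)) {
    x1 <- x[i]; x2 <- x[i + 1]; h1 <- h[i]; h2 <- h[i + 1]
    s <- (h2 - h1) / (x2 - x1)
    denom <- d[2] - d[1] * s
    if (abs(denom) < 1e-15) next
    t <- (h1 + (origin[1] - x1) * s - origin[2]) / denom
    if (t < eps) next
    xi <- origin[1] + t * d[1]
    if (xi < x1 - 1e-12 || xi > x2 + 1e-12) next
    if (t < best_t) {
      best_t <- t
      best <- list(t = t, x = xi, z = origin[2] + t * d[2],
                   normal = c(-s, 1) / sqrt(1 + s^2))
    }
  }
  best
}
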