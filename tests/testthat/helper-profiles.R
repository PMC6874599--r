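# Fixture builders used across test files.  Everything is generated in code;
# no stored fixtures.

# a single-impact profile tibble from a 3 x T sample matrix
profile_from_matrix <- function(m, id = "p1", dt = 1) {
  tibble::tibble(
    impact_id = id,
    time_ms = (seq_len(ncol(m)) - 1) * dt,
    wx = m[1, ], wy = m[2, ], wz = m[3, ]
  )
}

# extract the 3 x T matrix of one impact from a profile tibble
matrix_from_profile <- function(profiles, id = profiles$impact_id[1]) {
  d <- profiles[profiles$impact_id == id, ]
  rbind(d$wx, d$wy, d$wz)
}

# a smooth random multi-impact tibble: sum of sinusoid channels, T samples
random_profiles <- function(n, T = 40, amp = 10, prefix = "r") {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    m <- matrix(0, 3, T)
    tt <- seq_len(T) / T
    for (ch in 1:3) {
      m[ch, ] <- amp * (stats::runif(1, 0.2, 1) * sinpi(tt * stats::runif(1, 1, 3)) +
                          stats::runif(1, -0.3, 0.3))
    }
    profile_from_matrix(m, sprintf("%s%04d", prefix, i))
  }))
}

# a single smooth pulse along a fixed direction with exact sampled peak A
pulse_profile <- function(A = 30, Td = 20, dir = c(1, 0, 0), id = "pulse") {
  u <- dir / sqrt(sum(dir^2))
  t1 <- seq(0, Td)
  v <- A * sin(pi * t1 / Td)^2
  v <- v * (A / max(v))
  profile_from_matrix(outer(u, v), id)
}
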