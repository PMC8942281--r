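# Shared fixtures, built in code. Heavier simulated datasets are cached per
# session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A straight equatorial trip: eastward at `v` m/s, step dt seconds.
straight_trip <- function(n = 100, v = 10, dt = 1, trip_id = "line") {
  m_per_deg <- 6371000 * pi / 180
  lon <- (seq_len(n) - 1) * v * dt / m_per_deg
  new_trip(t = (seq_len(n) - 1) * dt, lon = lon, lat = rep(0, n),
           dive = rep(FALSE, n), observed = rep(TRUE, n),
           coverage = rep(1, n), trip_id = trip_id, dt = dt)
}

# A seeded random-walk trip (small area, used for FPT oracles).
random_trip <- function(n = 60, seed = 1, dt = 1) {
  withr::local_seed(seed)
  m_per_deg <- 6371000 * pi / 180
  step <- stats::rgamma(n, shape = 2, rate = 0.2)       # ~10 m steps
  ang <- stats::runif(n, -pi, pi)
  x <- cumsum(step * cos(ang)) / m_per_deg
  y <- cumsum(step * sin(ang)) / m_per_deg
  new_trip(t = (seq_len(n) - 1) * dt, lon = x, lat = y,
           dive = rep(c(FALSE, TRUE), length.out = n),
           observed = rep(TRUE, n), coverage = rep(1, n),
           trip_id = paste0("rw", seed), dt = dt)
}

# A synthetic window set where the dive label is determined by the speed
# channel (separable toy problem for the training tests).
separable_windows <- function(n = 200, L = 20, seed = 1) {
  withr::local_seed(seed)
  x <- array(stats::rnorm(3 * L * n), c(3, L, n))
  x[3, , ] <- abs(x[3, , ]) / max(abs(x[3, , ]))       # coverage in [0,1]
  y <- matrix(as.numeric(x[1, , ] > 0.8), L, n)
  ns <- structure(list(speed_mean = 0, speed_sd = 1, fitted_on = "toy"),
                  class = "norm_stats")
  structure(list(x = x, y = y, trip_id = rep("toy", n),
                 start = rep(1L, n), L = L, norm_stats = ns),
            class = "dive_windows")
}

# Simulated booby-like dataset shared by training / experiment tests.
booby_trips_small <- function() {
  fixture("booby_small", function() {
    simulate_trips("booby_pescadores", 12, seed = 7, duration = 2400)
  })
}
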