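# Seeded movement simulator: paired GPS + depth records with ground-truth
# behavioural states, emulating dual GPS/TDR deployments on seabirds.

METERS_PER_DEGREE <- 6371000 * pi / 180  # 111194.93 m per degree of latitude

#' Simulate one foraging trip
#'
#' Runs the four-state behavioural chain of `config` at 1-s steps for
#' `duration` seconds, draws per-second displacements from the active state's
#' gamma speed and von Mises turning-angle distributions, and integrates the
#' track from the colony of origin. Seconds spent in the DIVE state carry a
#' half-sine depth excursion exceeding the 2-m dive threshold for the whole
#' bout; all other seconds have zero depth. REST speeds are truncated below
#' 1 m/s and all speeds are capped at 29 m/s so consecutive-fix ground speeds
#' stay physically plausible.
#'
#' @param config A `sim_config`, e.g. from [preset_config()].
#' @param duration Trip duration in seconds (at least 600).
#' @param seed Integer seed; identical `(config, duration, seed)` give
#'   byte-identical output.
#' @return An object of class `dive_deployment`: a list with `gps`
#'   (data.frame `t, lon, lat`), `depth` (data.frame `t, depth`), and
#'   `states` (character vector of true per-second states).
#' @examples
#' cfg <- preset_config("booby_pescadores", seed = 1)
#' dep <- simulate_trip(cfg, duration = 1200, seed = 7)
#' mean(dep$depth$depth > 2)  # realized dive fraction
#' @export
simulate_trip <- function(config, duration, seed = 1L) {
  validate_sim_config(config)
  duration <- as.integer(duration)
  if (duration < 600) stop("duration must be at least 600 s")
  with_seed(seed, {
    n <- duration
    states_i <- simulate_state_chain(config, n)
    sp <- config$speed_model
    speed <- numeric(n)
    turn <- numeric(n)
    for (k in seq_along(SIM_STATES)) {
      idx <- which(states_i == k)
      if (!length(idx)) next
      s <- stats::rgamma(length(idx), shape = gamma_shape(sp$mean[k], sp$sd[k]),
                         rate = gamma_rate(sp$mean[k], sp$sd[k]))
      s <- if (SIM_STATES[k] == "REST") pmin(s, 0.99) else pmin(s, 29)
      speed[idx] <- s
      turn[idx] <- rvonmises(length(idx), config$angle_model$mu[k],
                             config$angle_model$kappa[k])
    }
    heading <- stats::runif(1, -pi, pi) + cumsum(turn)
    dx <- speed * sin(heading)
    dy <- speed * cos(heading)
    lat <- config$colony_origin[["lat"]] + cumsum(dy) / METERS_PER_DEGREE
    lon <- config$colony_origin[["lon"]] +
      cumsum(dx / (METERS_PER_DEGREE * cos(lat * pi / 180)))
    depth <- dive_depth_profile(states_i, config)
    t <- seq_len(n) - 1L
    structure(list(
      gps = data.frame(t = t, lon = lon, lat = lat),
      depth = data.frame(t = t, depth = depth),
      states = SIM_STATES[states_i],
      species_tag = config$species_tag,
      seed = as.integer(seed)
    ), class = "dive_deployment")
  })
}

# Sample the per-second state chain via its embedded-jump representation
# (geometric sojourns), which is equivalent in law to stepping the 1-s chain
# but vectorizes. Initial state is drawn from the stationary distribution.
simulate_state_chain <- function(config, n) {
  tm <- config$transition_matrix
  K <- nrow(tm)
  p_leave <- 1 - diag(tm)
  jump <- sweep(tm, 1, ifelse(p_leave > 0, p_leave, 1), `/`)
  diag(jump) <- 0
  out <- integer(n)
  state <- sample.int(K, 1, prob = pmax(config$stationary, 0))
  total <- 0L
  while (total < n) {
    if (p_leave[state] <= 0) {        # absorbing state
      out[(total + 1L):n] <- state
      break
    }
    dwell <- stats::rgeom(1, p_leave[state]) + 1L
    dwell <- min(dwell, n - total)
    out[(total + 1L):(total + dwell)] <- state
    total <- total + dwell
    if (total < n) state <- sample.int(K, 1, prob = jump[state, ])
  }
  out
}

# Half-sine depth excursions for each DIVE bout: depth stays strictly above
# the 2-m threshold for the whole bout and peaks at a level sampled from the
# configured range. Only the threshold crossing matters downstream.
dive_depth_profile <- function(states_i, config) {
  depth <- numeric(length(states_i))
  dive_k <- match("DIVE", SIM_STATES)
  r <- rle(states_i)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pr <- config$dive_depth_model$peak_range
  for (b in which(r$values == dive_k)) {
    d <- r$lengths[b]
    peak <- stats::runif(1, pr[1], pr[2])
    k <- seq_len(d)
    depth[starts[b]:ends[b]] <- 2 + (peak - 2) * sin(pi * (k - 0.5) / d)
  }
  depth
}

#' Delete GPS fixes in bursty runs to emulate submersion gaps
#'
#' Removes contiguous runs of GPS fixes (geometric run lengths with the given
#' mean) until the deleted proportion matches `gap_fraction` to within half a
#' percentage point. The first and last fix are always retained and the depth
#' stream is untouched.
#'
#' @param dep A `dive_deployment`.
#' @param gap_fraction Target proportion of deleted fixes in `[0, 1)`.
#' @param mean_gap_length Mean gap run length in seconds.
#' @param seed Integer seed.
#' @return The deployment with thinned `gps`; `gap_fraction = 0` returns the
#'   input unchanged.
#' @export
apply_gaps <- function(dep, gap_fraction, mean_gap_length = 10, seed = 1L) {
  stopifnot(inherits(dep, "dive_deployment"))
  if (gap_fraction < 0 || gap_fraction >= 1) {
    stop("gap_fraction must be in [0, 1)")
  }
  if (gap_fraction == 0) return(dep)
  n <- nrow(dep$gps)
  target <- round(gap_fraction * n)
  if (target < 1) return(dep)
  with_seed(seed, {
    deleted <- logical(n)
    n_del <- 0L
    guard <- 0L
    while (n_del < target && guard < 50L * n) {
      guard <- guard + 1L
      len <- stats::rgeom(1, 1 / mean_gap_length) + 1L
      start <- sample.int(n - 2L, 1) + 1L      # never the endpoints
      run <- start:min(start + len - 1L, n - 1L)
      run <- run[!deleted[run]]
      if (!length(run)) next
      need <- target - n_del
      if (length(run) > need) run <- run[seq_len(need)]
      deleted[run] <- TRUE
      n_del <- n_del + length(run)
    }
    dep$gps <- dep$gps[!deleted, , drop = FALSE]
    rownames(dep$gps) <- NULL
    dep
  })
}

#' Simulate a multi-trip deployment dataset
#'
#' Draws `n_trips` trip durations from the configured trip-duration
#' distribution (normal, truncated at 600 s), simulates each trip with its own
#' derived seed, and optionally thins GPS fixes to the configured gap
#' fraction.
#'
#' @param config A `sim_config`.
#' @param n_trips Number of trips.
#' @param seed Master seed; per-trip seeds are derived from it.
#' @param with_gaps Apply the configured gap fraction (default `TRUE`).
#' @param duration Optional fixed duration in seconds for every trip
#'   (overrides the configured trip-duration distribution).
#' @return List of `dive_deployment` objects.
#' @export
simulate_dataset <- function(config, n_trips, seed = 1L, with_gaps = TRUE,
                             duration = NULL) {
  validate_sim_config(config)
  with_seed(seed, {
    durs <- if (is.null(duration)) {
      pmax(600, round(stats::rnorm(n_trips, config$trip_duration[["mean"]],
                                   config$trip_duration[["sd"]])))
    } else rep(as.integer(duration), n_trips)
    sub_seeds <- sample.int(.Machine$integer.max %/% 2L, 2L * n_trips)
    lapply(seq_len(n_trips), function(i) {
      dep <- simulate_trip(config, durs[i], seed = sub_seeds[2L * i - 1L])
      dep$trip_id <- sprintf("%s_trip%03d", config$species_tag, i)
      if (with_gaps && config$gap_fraction > 0) {
        dep <- apply_gaps(dep, config$gap_fraction, config$mean_gap_length,
                          seed = sub_seeds[2L * i])
      }
      dep
    })
  })
}

#' Write a deployment to GPS/TDR CSV files
#'
#' GPS rows are `timestamp,lon,lat,trip_id` with ISO-8601 UTC timestamps;
#' TDR rows are `timestamp,depth_m`; the optional truth file holds
#' `timestamp,state,dive`.
#'
#' @param dep A `dive_deployment`.
#' @param gps_file,tdr_file,truth_file Output paths (`truth_file` optional).
#' @param origin POSIXct epoch for second 0.
#' @return Invisibly, the GPS path.
#' @export
write_deployment_csv <- function(dep, gps_file, tdr_file, truth_file = NULL,
                                 origin = as.POSIXct("2020-01-01",
                                                     tz = "UTC")) {
  stopifnot(inherits(dep, "dive_deployment"))
  iso <- function(t) format(origin + t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  gps <- data.frame(timestamp = iso(dep$gps$t), lon = dep$gps$lon,
                    lat = dep$gps$lat,
                    trip_id = dep$trip_id %||% "trip001")
  utils::write.csv(gps, gps_file, row.names = FALSE, quote = FALSE)
  tdr <- data.frame(timestamp = iso(dep$depth$t), depth_m = dep$depth$depth)
  utils::write.csv(tdr, tdr_file, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_file)) {
    truth <- data.frame(timestamp = iso(dep$depth$t), state = dep$states,
                        dive = as.integer(dep$depth$depth > 2))
    utils::write.csv(truth, truth_file, row.names = FALSE, quote = FALSE)
  }
  invisible(gps_file)
}

#' Read a deployment from GPS/TDR CSV files
#'
#' Inverse of [write_deployment_csv()]; timestamps are converted back to
#' seconds relative to the first GPS fix.
#'
#' @param gps_file,tdr_file CSV paths with the schemas written by
#'   [write_deployment_csv()].
#' @return A `dive_deployment` (without `states`).
#' @export
read_deployment_csv <- function(gps_file, tdr_file) {
  gps <- utils::read.csv(gps_file)
  tdr <- utils::read.csv(tdr_file)
  t0 <- as.POSIXct(gps$timestamp[1], format = "%Y-%m-%dT%H:%M:%SZ",
                   tz = "UTC")
  secs <- function(ts) as.numeric(difftime(
    as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), t0,
    units = "secs"))
  structure(list(
    gps = data.frame(t = secs(gps$timestamp), lon = gps$lon, lat = gps$lat),
    depth = data.frame(t = secs(tdr$timestamp), depth = tdr$depth_m),
    states = NULL,
    trip_id = if ("trip_id" %in% names(gps)) gps$trip_id[1] else "trip001"
  ), class = "dive_deployment")
}
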