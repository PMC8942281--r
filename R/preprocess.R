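# Preprocessing: raw GPS + depth streams to regularly sampled, labelled,
# coverage-annotated trips at 1-s resolution, and downsampling to the 5/15/30-s
# analysis resolutions.

#' Construct a regular trip object
#'
#' A trip is a data.frame with columns `t, lon, lat, dive, observed, coverage`
#' and attributes `trip_id` and `dt`. Timestamps must form an arithmetic
#' sequence with step `dt`.
#'
#' @param t,lon,lat Per-position timestamp (s) and WGS84 coordinates (deg).
#' @param dive Logical dive label per position.
#' @param observed Logical; `FALSE` marks linearly interpolated positions.
#' @param coverage Proportion of expected fixes recorded in each position's
#'   window, in `[0, 1]`.
#' @param trip_id Trip identifier.
#' @param dt Sampling interval (s).
#' @return A `dive_trip` data.frame.
#' @export
new_trip <- function(t, lon, lat, dive, observed, coverage, trip_id, dt) {
  tr <- data.frame(t = t, lon = lon, lat = lat, dive = as.logical(dive),
                   observed = as.logical(observed),
                   coverage = as.numeric(coverage))
  attr(tr, "trip_id") <- as.character(trip_id)
  attr(tr, "dt") <- as.numeric(dt)
  class(tr) <- c("dive_trip", "data.frame")
  validate_trip(tr)
}

#' @keywords internal
validate_trip <- function(tr) {
  stopifnot(inherits(tr, "dive_trip"))
  dt <- attr(tr, "dt")
  if (nrow(tr) < 2) stop("a trip needs at least 2 positions")
  if (max(abs(diff(tr$t) - dt)) > 1e-9) {
    stop("trip timestamps must be regular with step dt = ", dt)
  }
  if (any(tr$coverage < -1e-12 | tr$coverage > 1 + 1e-12)) {
    stop("coverage must lie in [0, 1]")
  }
  if (anyNA(tr$dive)) stop("dive label must be defined at every position")
  tr
}

trip_id <- function(tr) attr(tr, "trip_id")
trip_dt <- function(tr) attr(tr, "dt")

#' Split a GPS stream into foraging trips
#'
#' Returns the maximal runs of consecutive fixes lying further than
#' `min_distance` from the colony and spanning at least `min_duration`.
#'
#' @param fixes data.frame with columns `t, lon, lat`, time-sorted.
#' @param colony Numeric `c(lon, lat)` of the colony.
#' @param min_distance Distance threshold (m, default 1000).
#' @param min_duration Duration threshold (s, default 600).
#' @return List of data.frames (raw trips); empty input gives an empty list.
#' @export
split_trips <- function(fixes, colony, min_distance = 1000,
                        min_duration = 600) {
  if (is.null(fixes) || nrow(fixes) == 0) return(list())
  if (is.unsorted(fixes$t)) stop("fixes must be time-sorted")
  d <- haversine_m(fixes$lon, fixes$lat, colony[1], colony[2])
  away <- d > min_distance
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i <- starts[k]:ends[k]
    if (length(i) >= 2 && fixes$t[max(i)] - fixes$t[min(i)] >= min_duration) {
      out[[length(out) + 1L]] <- fixes[i, , drop = FALSE]
    }
  }
  out
}

#' Linearly interpolate a raw trip to 1-s resolution
#'
#' Produces one position for every integer second between the first and last
#' fix, with coordinates linearly interpolated between bracketing recorded
#' fixes. `observed` is `TRUE` exactly at seconds that carry a recorded fix
#' (nearest fix within 0.5 s).
#'
#' @param fixes data.frame with columns `t, lon, lat` (at least 2 fixes).
#' @return data.frame `t, lon, lat, observed` at 1-s resolution.
#' @export
interpolate_1s <- function(fixes) {
  if (nrow(fixes) < 2) stop("interpolation needs at least 2 fixes")
  if (is.unsorted(fixes$t, strictly = TRUE)) {
    stop("fix timestamps must be strictly increasing")
  }
  grid <- seq(ceiling(fixes$t[1]), floor(fixes$t[nrow(fixes)]))
  lon <- stats::approx(fixes$t, fixes$lon, xout = grid)$y
  lat <- stats::approx(fixes$t, fixes$lat, xout = grid)$y
  idx <- findInterval(grid, fixes$t)
  d_lo <- abs(grid - fixes$t[pmax(idx, 1L)])
  d_hi <- abs(fixes$t[pmin(idx + 1L, nrow(fixes))] - grid)
  observed <- pmin(d_lo, d_hi) <= 0.5
  data.frame(t = grid, lon = lon, lat = lat, observed = observed)
}

#' Label seconds as dives from a depth stream
#'
#' A second is a dive when the nearest depth sample is strictly greater than
#' `threshold` metres.
#'
#' @param depth data.frame with columns `t, depth` (depth in m, `>= 0`).
#' @param t_grid Seconds at which to evaluate the label.
#' @param threshold Dive threshold in metres (default 2).
#' @return Logical vector along `t_grid`.
#' @export
label_dives <- function(depth, t_grid, threshold = 2) {
  if (is.null(depth) || nrow(depth) == 0) stop("empty depth stream")
  if (any(depth$depth < 0)) stop("depth must be >= 0")
  idx <- findInterval(t_grid, depth$t, all.inside = TRUE)
  use_hi <- abs(depth$t[pmin(idx + 1L, nrow(depth))] - t_grid) <
    abs(t_grid - depth$t[idx])
  nearest <- ifelse(use_hi, pmin(idx + 1L, nrow(depth)), idx)
  depth$depth[nearest] > threshold
}

#' Coverage ratio of a resampled trip
#'
#' For each position of a `dt`-resampled trip, the proportion of the `dt`
#' 1-s slots in that position's window that carry a recorded fix.
#'
#' @param observed Logical mask at 1-s resolution.
#' @param dt Resampling interval (s).
#' @return Numeric coverage per resampled position (`floor(n/dt)` values);
#'   for `dt = 1` the 0/1 observed mask itself.
#' @export
coverage_ratio <- function(observed, dt) {
  if (dt == 1) return(as.numeric(observed))
  n_out <- length(observed) %/% dt
  if (n_out == 0) return(numeric(0))
  m <- matrix(observed[seq_len(n_out * dt)], nrow = dt)
  colMeans(m)
}

#' Assemble a 1-s trip from a raw deployment
#'
#' Interpolates the (possibly gappy) GPS stream to 1-s resolution, labels
#' dives from the depth stream with the 2-m rule, and annotates coverage.
#'
#' @param dep A `dive_deployment` (simulated or read from CSV).
#' @param threshold Dive depth threshold (m).
#' @return A `dive_trip` at `dt = 1`.
#' @export
process_deployment <- function(dep, threshold = 2) {
  stopifnot(inherits(dep, "dive_deployment"))
  reg <- interpolate_1s(dep$gps)
  dive <- label_dives(dep$depth, reg$t, threshold = threshold)
  new_trip(reg$t, reg$lon, reg$lat, dive, reg$observed,
           as.numeric(reg$observed),
           trip_id = dep$trip_id %||% "trip001", dt = 1)
}

#' Downsample a 1-s trip to a coarser resolution
#'
#' Keeps every `dt`-th position's coordinates (decimation); the dive label of
#' a window is the OR over its `dt` seconds (a window containing at least one
#' dive is a dive), coverage is the window mean and `observed` the window OR.
#'
#' @param tr A `dive_trip` at `dt = 1`.
#' @param dt Target resolution, one of 5, 15, 30 s (any `dt >= 2` with
#'   `allow_any_dt = TRUE`).
#' @param allow_any_dt Permit non-standard resolutions.
#' @return A `dive_trip` at resolution `dt`.
#' @export
downsample <- function(tr, dt, allow_any_dt = FALSE) {
  stopifnot(inherits(tr, "dive_trip"))
  if (trip_dt(tr) != 1) stop("downsample expects a 1-s trip")
  if (!dt %in% c(5, 15, 30) && !allow_any_dt) {
    stop("dt must be one of 5, 15, 30 (or set allow_any_dt = TRUE)")
  }
  n_out <- nrow(tr) %/% dt
  if (n_out < 2) stop("trip too short to downsample at dt = ", dt)
  keep <- seq_len(n_out) * dt
  win <- function(x, f) {
    m <- matrix(x[seq_len(n_out * dt)], nrow = dt)
    apply(m, 2, f)
  }
  new_trip(tr$t[keep], tr$lon[keep], tr$lat[keep],
           dive = win(tr$dive, any),
           observed = win(tr$observed, any),
           coverage = win(tr$coverage, mean),
           trip_id = trip_id(tr), dt = dt)
}

#' Partition trips into train/validation/test sets
#'
#' Seeded random partition at trip level with target fractions 50/30/20;
#' realized counts follow largest-remainder rounding.
#'
#' @param trips List of trips (or a character vector of trip ids).
#' @param fractions Numeric length-3 target fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `validation`, `test` (trip ids), plus the
#'   fractions and seed used.
#' @export
split_dataset <- function(trips, fractions = c(0.5, 0.3, 0.2), seed = 1L) {
  ids <- if (is.character(trips)) trips else vapply(trips, trip_id, "")
  n <- length(ids)
  if (n < 3) stop("need at least 3 trips to split")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  counts <- floor(n * fractions)
  rem <- n * fractions - counts
  short <- n - sum(counts)
  if (short > 0) {
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }
  with_seed(seed, {
    perm <- sample(ids)
    list(train = sort(perm[seq_len(counts[1])]),
         validation = sort(perm[counts[1] + seq_len(counts[2])]),
         test = sort(perm[counts[1] + counts[2] + seq_len(counts[3])]),
         fractions = fractions, seed = as.integer(seed))
  })
}

#' Write a processed trip to CSV (plus JSON sidecar)
#'
#' @param tr A `dive_trip`.
#' @param file CSV path; a `.json` sidecar with `trip_id` and `dt` is written
#'   alongside.
#' @return Invisibly, `file`.
#' @export
write_trip_csv <- function(tr, file) {
  stopifnot(inherits(tr, "dive_trip"))
  utils::write.csv(as.data.frame(tr), file, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", ".json", file)
  jsonlite::write_json(list(trip_id = trip_id(tr), dt = trip_dt(tr)),
                       side, auto_unbox = TRUE)
  invisible(file)
}

#' Read a processed trip from CSV
#'
#' @param file CSV written by [write_trip_csv()]; the `.json` sidecar is read
#'   if present, else `trip_id`/`dt` must be supplied.
#' @param trip_id,dt Overrides when no sidecar exists.
#' @return A `dive_trip`.
#' @export
read_trip_csv <- function(file, trip_id = NULL, dt = NULL) {
  x <- utils::read.csv(file)
  side <- sub("\\.csv$", ".json", file)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    trip_id <- trip_id %||% meta$trip_id
    dt <- dt %||% meta$dt
  }
  if (is.null(trip_id) || is.null(dt)) stop("trip_id and dt required")
  new_trip(x$t, x$lon, x$lat, x$dive, x$observed, x$coverage, trip_id, dt)
}
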