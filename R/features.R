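# Input channels for the networks: step speed, turning angle and coverage,
# cut into fixed-length windows.

#' Step speed of a regular trip
#'
#' `speed[i]` is the haversine distance from position `i-1` to `i` divided by
#' the sampling interval; the first position copies the second.
#'
#' @param tr A `dive_trip`.
#' @return Numeric speed (m/s) per position.
#' @export
step_speed <- function(tr) {
  stopifnot(inherits(tr, "dive_trip"))
  n <- nrow(tr)
  if (n < 2) stop("trip of length < 2")
  d <- haversine_m(tr$lon[-n], tr$lat[-n], tr$lon[-1], tr$lat[-1])
  sp <- c(d[1], d) / trip_dt(tr)
  sp
}

#' Turning angle of a regular trip
#'
#' The signed change of heading at each interior position: the difference
#' between the bearing into the position and the bearing out of it, wrapped
#' to `(-pi, pi]` with left (counter-clockwise) turns positive. Endpoints are
#' set to 0; trips shorter than 3 positions return all zeros.
#'
#' @param tr A `dive_trip`.
#' @return Numeric angle (rad) per position.
#' @export
turning_angle <- function(tr) {
  stopifnot(inherits(tr, "dive_trip"))
  n <- nrow(tr)
  if (n < 3) return(numeric(n))
  b <- bearing_rad(tr$lon[-n], tr$lat[-n], tr$lon[-1], tr$lat[-1])
  ang <- numeric(n)
  ang[2:(n - 1)] <- wrap_angle(b[1:(n - 2)] - b[2:(n - 1)])
  ang[!is.finite(ang)] <- 0        # zero-length steps have no bearing
  ang
}

#' Fit speed-normalization statistics on training trips
#'
#' Mean and standard deviation of step speed pooled over all positions of the
#' training trips; the sd is floored at 1e-6. The statistics are fitted once
#' on the training split and reused unchanged on validation and test data.
#'
#' @param trips List of `dive_trip` objects.
#' @param fitted_on Dataset tag stored for provenance.
#' @return An object of class `norm_stats`.
#' @export
fit_norm_stats <- function(trips, fitted_on = "train") {
  if (length(trips) < 1) stop("need at least one trip")
  sp <- unlist(lapply(trips, step_speed))
  structure(list(speed_mean = mean(sp),
                 speed_sd = max(stats::sd(sp), 1e-6),
                 fitted_on = fitted_on),
            class = "norm_stats")
}

#' Cut trips into fixed-length feature windows
#'
#' Each window is a 3 x L matrix of channels: z-scored step speed, turning
#' angle scaled by 1/pi, and raw coverage; plus the L dive labels. Windows
#' start at positions `1, 1+stride, 1+2*stride, ...`.
#'
#' @param trips A `dive_trip` or list of them (all at one resolution).
#' @param norm_stats A `norm_stats` object (from the training split).
#' @param L Window length in positions (default 20).
#' @param stride Window stride in positions (default `L/2` for training;
#'   inference uses stride 1).
#' @return An object of class `dive_windows`: list with `x` (array
#'   `3 x L x N`), `y` (`L x N` 0/1 matrix), `trip_id`, `start` (1-based
#'   start position of each window), `L` and `norm_stats`. Trips shorter than
#'   `L` contribute nothing (with a warning if all are too short).
#' @export
make_windows <- function(trips, norm_stats, L = 20, stride = max(1, L %/% 2)) {
  if (inherits(trips, "dive_trip")) trips <- list(trips)
  stopifnot(inherits(norm_stats, "norm_stats"))
  xs <- list(); ys <- list(); ids <- character(0); starts <- integer(0)
  for (tr in trips) {
    n <- nrow(tr)
    if (n < L) next
    sp <- (step_speed(tr) - norm_stats$speed_mean) / norm_stats$speed_sd
    ang <- turning_angle(tr) / pi
    cov <- tr$coverage
    st <- seq.int(1L, n - L + 1L, by = stride)
    idx <- outer(seq_len(L) - 1L, st, `+`)       # L x n_windows positions
    x <- array(0, c(3, L, length(st)))
    x[1, , ] <- sp[idx]
    x[2, , ] <- ang[idx]
    x[3, , ] <- cov[idx]
    y <- matrix(as.numeric(tr$dive[idx]), L, length(st))
    xs[[length(xs) + 1L]] <- x
    ys[[length(ys) + 1L]] <- y
    ids <- c(ids, rep(trip_id(tr), length(st)))
    starts <- c(starts, st)
  }
  if (!length(xs)) {
    warning("no trip reaches the window length L = ", L)
    return(structure(list(x = array(0, c(3, L, 0)), y = matrix(0, L, 0),
                          trip_id = character(0), start = integer(0),
                          L = L, norm_stats = norm_stats),
                     class = "dive_windows"))
  }
  N <- sum(vapply(xs, function(a) dim(a)[3], 0))
  x_all <- array(0, c(3, L, N))
  y_all <- matrix(0, L, N)
  at <- 0L
  for (k in seq_along(xs)) {
    nk <- dim(xs[[k]])[3]
    x_all[, , at + seq_len(nk)] <- xs[[k]]
    y_all[, at + seq_len(nk)] <- ys[[k]]
    at <- at + nk
  }
  structure(list(x = x_all, y = y_all, trip_id = ids, start = starts,
                 L = L, norm_stats = norm_stats),
            class = "dive_windows")
}

#' Number of windows in a window set
#' @param ws A `dive_windows` object.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$x)[3]

# Subset a window set (used for shuffling/batching).
windows_subset <- function(ws, idx) {
  structure(list(x = ws$x[, , idx, drop = FALSE],
                 y = ws$y[, idx, drop = FALSE],
                 trip_id = ws$trip_id[idx], start = ws$start[idx],
                 L = ws$L, norm_stats = ws$norm_stats),
            class = "dive_windows")
}

# Concatenate window sets (same L and norm stats).
windows_bind <- function(a, b) {
  stopifnot(a$L == b$L)
  N <- n_windows(a) + n_windows(b)
  x <- array(0, c(3, a$L, N)); y <- matrix(0, a$L, N)
  x[, , seq_len(n_windows(a))] <- a$x
  y[, seq_len(n_windows(a))] <- a$y
  if (n_windows(b)) {
    x[, , n_windows(a) + seq_len(n_windows(b))] <- b$x
    y[, n_windows(a) + seq_len(n_windows(b))] <- b$y
  }
  structure(list(x = x, y = y, trip_id = c(a$trip_id, b$trip_id),
                 start = c(a$start, b$start), L = a$L,
                 norm_stats = a$norm_stats),
            class = "dive_windows")
}
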