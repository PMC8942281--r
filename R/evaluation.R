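# Evaluation: ROC/AUC, binary cross-entropy, F-score, and spatial evaluation
# via weighted kernel-density dive maps compared by mean squared error.

#' Exact ROC curve
#'
#' Built from the sorted unique scores with ties grouped; the curve starts at
#' (0, 0) and ends at (1, 1).
#'
#' @param p Scores (dive probabilities).
#' @param y Binary labels; both classes must be present.
#' @return An object of class `roc_curve`: data.frame with `threshold`
#'   (descending), `fpr`, `tpr`.
#' @export
roc_curve <- function(p, y) {
  y <- as.numeric(y)
  if (length(p) != length(y)) stop("p and y must have equal length")
  P <- sum(y == 1)
  N <- sum(y == 0)
  if (P == 0 || N == 0) stop("both classes must be present")
  o <- order(p, decreasing = TRUE)
  ps <- p[o]
  ys <- y[o]
  last <- c(which(diff(ps) != 0), length(ps))
  tp <- cumsum(ys)[last]
  fp <- cumsum(1 - ys)[last]
  out <- data.frame(threshold = c(Inf, ps[last]),
                    fpr = c(0, fp / N),
                    tpr = c(0, tp / P))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the ROC curve (composite trapezoidal rule)
#'
#' Integrates the ROC curve along the false-positive-rate axis; equals the
#' tie-corrected pairwise concordance (Mann-Whitney) statistic.
#'
#' @param curve A `roc_curve`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  x <- curve$fpr
  yy <- curve$tpr
  sum(diff(x) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Unweighted binary cross-entropy metric
#'
#' @param p Probabilities (clipped to `[1e-7, 1 - 1e-7]`).
#' @param y Binary labels.
#' @return Scalar mean cross-entropy.
#' @export
bce_metric <- function(p, y) weighted_bce(p, y, w = 1)

#' F-score of the dive class at a probability threshold
#'
#' Harmonic mean of precision and recall for the positive class, predicting
#' a dive when `p >= threshold`. Returns 0 with a warning when nothing is
#' predicted positive.
#'
#' @param p Probabilities.
#' @param y Binary labels (both classes present).
#' @param threshold Decision threshold (default 0.5).
#' @return F-score in `[0, 1]`.
#' @export
f_score <- function(p, y, threshold = 0.5) {
  y <- as.numeric(y)
  pred <- p >= threshold
  tp <- sum(pred & y == 1)
  fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1)
  if (tp + fp == 0) {
    warning("no predicted positives at threshold ", threshold)
    return(0)
  }
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Weighted kernel-density dive map
#'
#' Isotropic Gaussian KDE in degree space on a regular lon/lat grid, with
#' dive probabilities as weights; the map is renormalized so that the grid
#' integral (cell value times cell area in square degrees) is one.
#'
#' @param lon,lat Positions (degrees).
#' @param weights Non-negative weights (dive probabilities); not all zero.
#' @param grid Optional `density_grid_spec` from [make_grid_spec()] so that
#'   several maps share one grid; default spans the data plus 3 bandwidths.
#' @param grid_step Cell size in degrees (default 0.01).
#' @param bandwidth Gaussian kernel sd in degrees (default 0.25).
#' @return An object of class `density_grid` (`lon`, `lat` cell centres and
#'   the `values` matrix, lon by lat).
#' @export
kde_map <- function(lon, lat, weights, grid = NULL, grid_step = 0.01,
                    bandwidth = 0.25) {
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("weights must not all be zero")
  if (is.null(grid)) {
    grid <- make_grid_spec(range(lon), range(lat), grid_step, bandwidth)
  }
  w <- weights / sum(weights)
  klon <- stats::dnorm(outer(grid$lon, lon, `-`), sd = grid$bandwidth)
  klat <- stats::dnorm(outer(lat, grid$lat, `-`), sd = grid$bandwidth)
  vals <- klon %*% (w * klat)
  vals <- vals / (sum(vals) * grid$step^2)
  structure(list(lon = grid$lon, lat = grid$lat, step = grid$step,
                 bandwidth = grid$bandwidth, values = vals),
            class = "density_grid")
}

#' Define a shared lon/lat grid for density maps
#'
#' Cell edges are snapped to multiples of `grid_step`; the extent is padded
#' by three bandwidths so kernel mass is captured.
#'
#' @param lon_range,lat_range Ranges (degrees).
#' @param grid_step Cell size (degrees).
#' @param bandwidth Kernel sd (degrees).
#' @return A `density_grid_spec` with cell-centre vectors.
#' @export
make_grid_spec <- function(lon_range, lat_range, grid_step = 0.01,
                           bandwidth = 0.25) {
  pad <- 3 * bandwidth
  lo <- function(x) floor((x - pad) / grid_step) * grid_step
  hi <- function(x) ceiling((x + pad) / grid_step) * grid_step
  lon_edges <- seq(lo(lon_range[1]), hi(lon_range[2]), by = grid_step)
  lat_edges <- seq(lo(lat_range[1]), hi(lat_range[2]), by = grid_step)
  structure(list(lon = lon_edges[-1] - grid_step / 2,
                 lat = lat_edges[-1] - grid_step / 2,
                 step = grid_step, bandwidth = bandwidth),
            class = "density_grid_spec")
}

#' Mean squared error between two density maps
#'
#' @param est,ref `density_grid` objects on the identical grid.
#' @return Mean over cells of the squared density difference.
#' @export
map_mse <- function(est, ref) {
  stopifnot(inherits(est, "density_grid"), inherits(ref, "density_grid"))
  if (length(est$lon) != length(ref$lon) ||
      length(est$lat) != length(ref$lat) ||
      max(abs(est$lon - ref$lon)) > 1e-9 ||
      max(abs(est$lat - ref$lat)) > 1e-9) {
    stop("density grids do not match")
  }
  mean((est$values - ref$values)^2)
}

#' Export a density grid as a lon/lat/density data.frame
#'
#' @param grid A `density_grid`.
#' @return data.frame with columns `lon`, `lat`, `density`.
#' @export
grid_as_df <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  data.frame(lon = rep(grid$lon, times = length(grid$lat)),
             lat = rep(grid$lat, each = length(grid$lon)),
             density = as.vector(grid$values))
}

# Pooled classification metrics over a list of dive_probs / trips.
pooled_metrics <- function(prob_list, trip_list) {
  p <- unlist(lapply(prob_list, function(d) d$p_dive))
  y <- unlist(lapply(trip_list, function(tr) as.numeric(tr$dive)))
  list(auc = auc(roc_curve(p, y)),
       bce = bce_metric(p, y),
       f_score = suppressWarnings(f_score(p, y)))
}
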