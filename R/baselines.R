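# Benchmark baselines: first-passage time (FPT) dive probability and a
# gamma / von Mises hidden Markov model with posterior dive probability.

## --- First-passage time ---------------------------------------------------

#' First-passage time through a circle of given radius
#'
#' For each position, the time the trajectory spends inside the circle of
#' radius `radius` centred on it: the interval between the backward and
#' forward first exits, with linear interpolation of the exact crossing time
#' between fixes. Sides that never exit are truncated at the trip boundary.
#' Long passage times flag area-restricted search.
#'
#' @param tr A `dive_trip`.
#' @param radius Circle radius in metres (`> 0`).
#' @return Numeric passage time (s) per position.
#' @examples
#' # a straight line at constant speed v has FPT = 2 * radius / v inside
#' @export
fpt <- function(tr, radius) {
  if (any(radius <= 0)) stop("radius must be positive")
  fpt_multi(tr, radius)[, 1]
}

# FPT for a whole grid of radii at once: one distance scan per position.
fpt_multi <- function(tr, radii) {
  stopifnot(inherits(tr, "dive_trip"))
  if (any(radii <= 0)) stop("radius must be positive")
  n <- nrow(tr)
  t <- tr$t
  out <- matrix(0, n, length(radii))
  for (i in seq_len(n)) {
    tf <- side_crossing(tr, i, seq.int(i, n), t, radii)
    tb <- side_crossing(tr, i, seq.int(i, 1L), t, radii)
    out[i, ] <- tf - tb
  }
  out
}

# Crossing time of each radius along one side of position i (indices ordered
# outward from i). Never-exiting radii are truncated at the last index.
side_crossing <- function(tr, i, idx, t, radii) {
  d <- haversine_m(tr$lon[i], tr$lat[i], tr$lon[idx], tr$lat[idx])
  M <- cummax(d)
  j <- findInterval(radii - 1e-9, M) + 1L
  tx <- numeric(length(radii))
  inside <- j > length(idx)
  tx[inside] <- t[idx[length(idx)]]
  out <- which(!inside)
  if (length(out)) {
    jj <- j[out]
    d0 <- d[jj - 1L]
    d1 <- d[jj]
    frac <- (radii[out] - d0) / (d1 - d0)
    t0 <- t[idx[jj - 1L]]
    t1 <- t[idx[jj]]
    tx[out] <- t0 + frac * (t1 - t0)
  }
  tx
}

#' Default candidate-radius grid for FPT
#'
#' Twenty log-spaced radii spanning the 1st percentile of per-step distances
#' up to 100 times their 99th percentile.
#'
#' @param tr A `dive_trip`.
#' @param n Number of radii.
#' @return Numeric vector of radii (m).
#' @export
default_radii <- function(tr, n = 20) {
  steps <- step_speed(tr) * trip_dt(tr)
  steps <- steps[steps > 0]
  if (!length(steps)) steps <- 1
  q <- stats::quantile(steps, c(0.01, 0.99), names = FALSE)
  exp(seq(log(max(q[1], 0.1)), log(q[2] * 100), length.out = n))
}

#' Select the FPT radius maximizing the variance of passage times
#'
#' Following the classical first-passage-time analysis, computes FPT over a
#' grid of candidate radii and returns the radius maximizing the variance of
#' log passage times (`use_log = FALSE` switches to raw passage times). Ties
#' go to the smaller radius; if every radius yields constant passage times
#' the median radius is returned with a warning.
#'
#' @param tr A `dive_trip`.
#' @param candidate_radii Radii grid (m), at least 2 values; default
#'   [default_radii()].
#' @param use_log Use variance of log FPT (default `TRUE`).
#' @return Selected radius, with the profile (`radii`, `variance`) attached
#'   as attributes.
#' @export
fpt_select_radius <- function(tr, candidate_radii = default_radii(tr),
                              use_log = TRUE) {
  if (length(candidate_radii) < 2) stop("need at least 2 candidate radii")
  candidate_radii <- sort(candidate_radii)
  mat <- fpt_multi(tr, candidate_radii)
  v <- apply(mat, 2, function(col) {
    if (use_log) stats::var(log(pmax(col, 1e-9))) else stats::var(col)
  })
  if (all(v < 1e-12 | !is.finite(v))) {
    warning("passage times constant at every radius; falling back to the ",
            "median radius")
    sel <- stats::median(candidate_radii)
  } else {
    sel <- candidate_radii[which.max(v)]
  }
  attr(sel, "radii") <- candidate_radii
  attr(sel, "variance") <- v
  sel
}

#' Convert passage times to dive probabilities by min-max normalization
#'
#' `p = (fpt - min) / (max - min)` per trip; constant passage times give a
#' flat 0.5 with a warning.
#'
#' @param times Passage times (finite, non-empty).
#' @return Probabilities in `[0, 1]`.
#' @export
fpt_probability <- function(times) {
  if (!length(times)) stop("empty passage-time input")
  if (!all(is.finite(times))) stop("passage times must be finite")
  rng <- range(times)
  if (diff(rng) < 1e-12) {
    warning("constant passage times; returning flat 0.5")
    return(rep(0.5, length(times)))
  }
  (times - rng[1]) / diff(rng)
}

#' FPT dive probabilities for one trip
#'
#' Radius selection (variance-maximizing) followed by min-max conversion.
#'
#' @param tr A `dive_trip`.
#' @param candidate_radii Optional radii grid.
#' @return A `dive_probs` data.frame like [predict_trip()].
#' @export
fpt_predict_trip <- function(tr, candidate_radii = default_radii(tr)) {
  r <- fpt_select_radius(tr, candidate_radii)
  p <- fpt_probability(fpt(tr, as.numeric(r)))
  out <- data.frame(t = tr$t, lon = tr$lon, lat = tr$lat, p_dive = p)
  attr(out, "trip_id") <- trip_id(tr)
  attr(out, "dt") <- trip_dt(tr)
  attr(out, "radius") <- as.numeric(r)
  class(out) <- c("dive_probs", "data.frame")
  out
}

## --- Hidden Markov model --------------------------------------------------

# Observations for the HMM: per transition j (j = 1..n-1), the step length
# from position j to j+1 (floored at 1e-3 m) and the turning angle between
# segments j-1 and j (NA for the first segment or zero-length steps).
hmm_observations <- function(tr) {
  n <- nrow(tr)
  step <- pmax(step_speed(tr)[-1] * trip_dt(tr), 1e-3)
  ang <- turning_angle(tr)
  angle <- c(NA_real_, ang[2:(n - 1)])
  list(step = step, angle = angle)
}

hmm_log_emissions <- function(obs, spec) {
  K <- spec$n_states
  T_ <- length(obs$step)
  le <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    le[, k] <- stats::dgamma(obs$step,
                             shape = gamma_shape(spec$step_gamma$mean[k],
                                                 spec$step_gamma$sd[k]),
                             rate = gamma_rate(spec$step_gamma$mean[k],
                                               spec$step_gamma$sd[k]),
                             log = TRUE)
    ok <- !is.na(obs$angle)
    le[ok, k] <- le[ok, k] + log(dvonmises(obs$angle[ok],
                                           spec$angle_vm$mu[k],
                                           spec$angle_vm$kappa[k]))
  }
  le
}

# Scaled forward-backward for one observation sequence.
hmm_forward_backward <- function(le, tpm, delta) {
  T_ <- nrow(le)
  K <- ncol(le)
  e <- exp(le - apply(le, 1, max))
  lmax <- apply(le, 1, max)
  alpha <- matrix(0, T_, K)
  cvec <- numeric(T_)
  a <- delta * e[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:T_) {
    a <- (alpha[t - 1, ] %*% tpm) * e[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, T_, K)
  beta[T_, ] <- 1
  for (t in (T_ - 1):1) {
    beta[t, ] <- as.vector(tpm %*% (e[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  loglik <- sum(log(cvec)) + sum(lmax)
  list(alpha = alpha, beta = beta, gamma = gamma, cvec = cvec, e = e,
       loglik = loglik)
}

#' Fit a gamma / von Mises hidden Markov model to trips
#'
#' Baum-Welch EM on step-length (gamma) and turning-angle (von Mises)
#' emissions over one or several trips at a single resolution. Initialization
#' seeds state step-length means on a quantile split; the best of `restarts`
#' seeded restarts is returned. The log-likelihood is non-decreasing over EM
#' iterations (exact weighted M-steps).
#'
#' @param trips A `dive_trip`, a list of them, or raw observation sequences:
#'   a list with elements `step` and `angle` (angle `NA` where undefined), or
#'   a list of such lists.
#' @param n_states Number of behavioural states (3 for booby-like, 4 for
#'   cormorant-like datasets).
#' @param seed Integer seed for the restarts.
#' @param restarts Number of EM restarts (default 5).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-6).
#' @return An object of class `dive_hmm`.
#' @export
hmm_fit <- function(trips, n_states, seed = 1L, restarts = 5,
                    max_iter = 500, tol = 1e-6) {
  if (inherits(trips, "dive_trip")) trips <- list(trips)
  obs <- if (!is.null(trips$step)) {
    list(list(step = trips$step, angle = trips$angle))
  } else if (all(vapply(trips, function(x) inherits(x, "dive_trip"), TRUE))) {
    lapply(trips, hmm_observations)
  } else {
    trips
  }
  steps <- unlist(lapply(obs, `[[`, "step"))
  if (stats::sd(steps) < 1e-12) {
    stop("degenerate data: all step lengths are equal")
  }
  K <- as.integer(n_states)
  qs <- stats::quantile(steps, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      mean0 <- qs * exp(stats::runif(K, -0.3, 0.3))
      sd0 <- pmax(mean0 * 0.8, 1e-3)
      kappa0 <- stats::runif(K, 0.3, 2)
      init <- list(
        n_states = K,
        step_gamma = data.frame(mean = mean0, sd = sd0),
        angle_vm = data.frame(mu = rep(0, K), kappa = kappa0),
        tpm = matrix(1 / K, K, K),
        delta = rep(1 / K, K)
      )
      fit <- hmm_em(obs, init, max_iter, tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best$seed <- as.integer(seed)
    best$dt <- if (inherits(trips[[1]], "dive_trip")) trip_dt(trips[[1]])
    class(best) <- "dive_hmm"
    best
  })
}

# One EM run from a given initialization.
hmm_em <- function(obs, spec, max_iter, tol) {
  K <- spec$n_states
  ll_hist <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    les <- lapply(obs, hmm_log_emissions, spec = spec)
    fbs <- lapply(les, hmm_forward_backward, tpm = spec$tpm,
                  delta = spec$delta)
    ll <- sum(vapply(fbs, `[[`, 0, "loglik"))
    ll_hist <- c(ll_hist, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    # accumulate sufficient statistics
    xi_sum <- matrix(0, K, K)
    delta_sum <- numeric(K)
    g_all <- list()
    for (s in seq_along(obs)) {
      fb <- fbs[[s]]
      T_ <- nrow(fb$gamma)
      delta_sum <- delta_sum + fb$gamma[1, ]
      eb <- (fb$e * fb$beta / fb$cvec)[2:T_, , drop = FALSE]
      xi_sum <- xi_sum +
        spec$tpm * (t(fb$alpha[seq_len(T_ - 1), , drop = FALSE]) %*% eb)
      g_all[[s]] <- fb$gamma
    }
    gam <- do.call(rbind, g_all)
    step_all <- unlist(lapply(obs, `[[`, "step"))
    ang_all <- unlist(lapply(obs, `[[`, "angle"))
    for (k in seq_len(K)) {
      gk <- gamma_mle_weighted(step_all, gam[, k])
      spec$step_gamma$mean[k] <- gk$mean
      spec$step_gamma$sd[k] <- gk$sd
      ok <- !is.na(ang_all)
      vk <- vm_mle_weighted(ang_all[ok], gam[ok, k])
      spec$angle_vm$mu[k] <- vk$mu
      spec$angle_vm$kappa[k] <- min(vk$kappa, 500)
    }
    spec$tpm <- xi_sum / rowSums(xi_sum)
    spec$delta <- delta_sum / sum(delta_sum)
  }
  spec$loglik <- ll_hist[length(ll_hist)]
  spec$loglik_history <- ll_hist
  spec$converged <- length(ll_hist) < max_iter
  spec$dive_state <- NA_integer_
  spec
}

#' Posterior state probabilities for a trip
#'
#' Forward-backward smoothing probabilities, mapped back to positions (the
#' first position copies the second). Rows sum to one.
#'
#' @param spec A fitted `dive_hmm`.
#' @param tr A `dive_trip`.
#' @return Matrix `n_positions x n_states`.
#' @export
hmm_posterior <- function(spec, tr) {
  stopifnot(inherits(spec, "dive_hmm"))
  obs <- hmm_observations(tr)
  le <- hmm_log_emissions(obs, spec)
  fb <- hmm_forward_backward(le, spec$tpm, spec$delta)
  rbind(fb$gamma[1, , drop = FALSE], fb$gamma)
}

#' Choose which HMM state represents diving
#'
#' With labelled training trips, picks the state whose posterior maximizes
#' the AUC against the dive labels (supervised rule); without labels, the
#' state with the smallest mean step length.
#'
#' @param spec A fitted `dive_hmm`.
#' @param train_trips Optional list of labelled `dive_trip`s.
#' @return The spec with `dive_state` set.
#' @export
hmm_select_dive_state <- function(spec, train_trips = NULL) {
  stopifnot(inherits(spec, "dive_hmm"))
  if (is.null(train_trips)) {
    spec$dive_state <- which.min(spec$step_gamma$mean)
    return(spec)
  }
  if (inherits(train_trips, "dive_trip")) train_trips <- list(train_trips)
  y <- unlist(lapply(train_trips, function(tr) tr$dive))
  post <- do.call(rbind, lapply(train_trips, function(tr)
    hmm_posterior(spec, tr)))
  aucs <- vapply(seq_len(spec$n_states), function(k) {
    auc(roc_curve(post[, k], y))
  }, 0)
  spec$dive_state <- which.max(aucs)
  spec
}

#' Posterior dive probability for a trip
#'
#' The forward-backward posterior of the dive state (selected beforehand via
#' [hmm_select_dive_state()], or here if training trips are supplied).
#'
#' @param spec A fitted `dive_hmm`.
#' @param tr A `dive_trip`.
#' @param train_trips Optional labelled trips for supervised state selection.
#' @return A `dive_probs` data.frame.
#' @export
hmm_dive_probability <- function(spec, tr, train_trips = NULL) {
  stopifnot(inherits(spec, "dive_hmm"))
  if (is.na(spec$dive_state) || !is.null(train_trips)) {
    spec <- hmm_select_dive_state(spec, train_trips)
  }
  post <- hmm_posterior(spec, tr)
  out <- data.frame(t = tr$t, lon = tr$lon, lat = tr$lat,
                    p_dive = post[, spec$dive_state])
  attr(out, "trip_id") <- trip_id(tr)
  attr(out, "dt") <- trip_dt(tr)
  class(out) <- c("dive_probs", "data.frame")
  out
}

#' Simulate observations from an HMM specification
#'
#' Draws a state chain from the transition matrix and emissions from the
#' per-state gamma / von Mises models (used for parameter-recovery studies).
#'
#' @param spec A `dive_hmm`-like list (`n_states`, `step_gamma`, `angle_vm`,
#'   `tpm`, `delta`).
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return List with `step`, `angle` and `states`.
#' @export
hmm_simulate <- function(spec, n, seed = 1L) {
  K <- spec$n_states
  with_seed(seed, {
    states <- integer(n)
    states[1] <- sample.int(K, 1, prob = spec$delta)
    for (t in 2:n) {
      states[t] <- sample.int(K, 1, prob = spec$tpm[states[t - 1], ])
    }
    step <- stats::rgamma(n,
                          shape = gamma_shape(spec$step_gamma$mean,
                                              spec$step_gamma$sd)[states],
                          rate = gamma_rate(spec$step_gamma$mean,
                                            spec$step_gamma$sd)[states])
    angle <- numeric(n)
    for (k in seq_len(K)) {
      idx <- which(states == k)
      if (length(idx)) {
        angle[idx] <- rvonmises(length(idx), spec$angle_vm$mu[k],
                                spec$angle_vm$kappa[k])
      }
    }
    list(step = step, angle = angle, states = states)
  })
}

#' @export
print.dive_hmm <- function(x, ...) {
  cat("<dive_hmm>", x$n_states, "states, log-likelihood",
      round(x$loglik, 2), "\n")
  print(cbind(step_mean = x$step_gamma$mean, step_sd = x$step_gamma$sd,
              angle_kappa = x$angle_vm$kappa))
  invisible(x)
}
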