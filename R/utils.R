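# Internal helpers shared across modules.

EARTH_RADIUS_M <- 6371000

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `expr`, and restores the caller's RNG state
#' so that seeded package functions do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Haversine distance (m) between consecutive points or point pairs.
haversine_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

# Initial bearing (radians, clockwise from north) from point 1 to point 2.
bearing_rad <- function(lon1, lat1, lon2, lat2) {
  geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)) * pi / 180
}

# Wrap an angle (rad) to (-pi, pi]; -pi maps to +pi.
wrap_angle <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

## --- circular statistics (von Mises) ------------------------------------

# von Mises density on (-pi, pi].
dvonmises <- function(x, mu = 0, kappa = 1) {
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE) *
                                exp(kappa))
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    k <- sum(ok)
    if (k > 0) {
      u3 <- stats::runif(k)
      theta <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle(out + mu)
}

# Ratio A(kappa) = I1(kappa)/I0(kappa).
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# Invert A(kappa) = r: Fisher's approximation refined by Newton steps.
vm_a1inv <- function(r) {
  if (r >= 1 - 1e-10) return(1e6)
  if (r <= 1e-10) return(0)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  for (i in 1:10) {
    a <- vm_a1(k)
    # d A / d kappa = 1 - A/kappa - A^2
    da <- 1 - a / k - a^2
    step <- (a - r) / da
    k <- max(k - step, 1e-8)
    if (abs(step) < 1e-12) break
  }
  k
}

# Gamma distribution parametrized by mean and sd.
gamma_shape <- function(mean, sd) (mean / sd)^2
gamma_rate  <- function(mean, sd) mean / sd^2

# Weighted gamma maximum-likelihood fit (Newton on the shape), returning
# mean/sd parametrization. Weights need not be normalized.
gamma_mle_weighted <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  ml <- sum(w * log(x)) / sw
  s <- log(m) - ml
  if (!is.finite(s) || s <= 1e-12) {
    shape <- 1e6
  } else {
    shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    for (i in 1:50) {
      step <- (log(shape) - digamma(shape) - s) / (1 / shape - trigamma(shape))
      shape <- max(shape - step, 1e-8)
      if (abs(step) < 1e-10 * max(1, shape)) break
    }
  }
  rate <- shape / m
  list(mean = m, sd = sqrt(shape) / rate, shape = shape, rate = rate)
}

# Weighted von Mises maximum-likelihood fit.
vm_mle_weighted <- function(theta, w) {
  sw <- sum(w)
  c0 <- sum(w * cos(theta)) / sw
  s0 <- sum(w * sin(theta)) / sw
  mu <- atan2(s0, c0)
  r <- sqrt(c0^2 + s0^2)
  list(mu = mu, kappa = vm_a1inv(r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
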