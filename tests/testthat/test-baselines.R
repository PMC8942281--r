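# Baselines: first-passage time and the gamma / von Mises hidden Markov
# model.

test_that("FPT matches the straight-line closed form 2r/v", {
  tr <- straight_trip(101, v = 10, dt = 1)     # 1000 m long
  f <- fpt(tr, 50)
  # interior points: 5 s out on each side
  expect_equal(f[20:80], rep(10, 61), tolerance = 1e-6)
  # near the start the backward exit is truncated at the boundary
  expect_equal(f[1], 5, tolerance = 1e-6)
  expect_error(fpt(tr, -1), "positive")
})

test_that("a stationary trip never exits: FPT is the full trip duration", {
  n <- 30
  still <- new_trip(t = 0:(n - 1), lon = rep(0, n), lat = rep(0, n),
                    dive = rep(FALSE, n), observed = rep(TRUE, n),
                    coverage = rep(1, n), trip_id = "still", dt = 1)
  expect_equal(fpt(still, 100), rep(n - 1, n))
})

test_that("FPT agrees exactly with the brute-force circle-exit oracle", {
  withr::local_seed(99)
  for (rep in 1:50) {
    tr <- random_trip(n = sample(20:50, 1), seed = rep)
    r <- runif(1, 5, 200)
    expect_equal(fpt(tr, r), fpt_oracle(tr, r), tolerance = 1e-8)
  }
})

test_that("FPT is invariant to time reversal at interior positions", {
  tr <- random_trip(40, seed = 17)
  rev_tr <- new_trip(t = tr$t, lon = rev(tr$lon), lat = rev(tr$lat),
                     dive = tr$dive, observed = tr$observed,
                     coverage = tr$coverage, trip_id = "rev", dt = 1)
  expect_equal(fpt(tr, 30), rev(fpt(rev_tr, 30)), tolerance = 1e-8)
})

test_that("radius selection maximizes variance with ties to the smaller", {
  tr <- random_trip(80, seed = 5)
  sel <- fpt_select_radius(tr)
  v <- attr(sel, "variance")
  radii <- attr(sel, "radii")
  expect_identical(as.numeric(sel), radii[which.max(v)])
  # duplicated candidate radii tie; the first (smaller index) wins
  sel2 <- fpt_select_radius(tr, c(30, 30, 1e6))
  expect_equal(as.numeric(sel2), 30)
  expect_error(fpt_select_radius(tr, 50), "at least 2")
  # stationary trip: constant FPT at every radius, median fallback + warning
  still <- new_trip(t = 0:29, lon = rep(0, 30), lat = rep(0, 30),
                    dive = rep(FALSE, 30), observed = rep(TRUE, 30),
                    coverage = rep(1, 30), trip_id = "s", dt = 1)
  expect_warning(fb <- fpt_select_radius(still, c(10, 20, 40)), "constant")
  expect_equal(as.numeric(fb), 20)
})

test_that("min-max normalization maps passage times to [0,1]", {
  expect_equal(fpt_probability(c(10, 20, 30)), c(0, 0.5, 1))
  expect_warning(p <- fpt_probability(rep(7, 5)), "constant")
  expect_equal(p, rep(0.5, 5))
  withr::local_seed(1)
  x <- rexp(100)
  p <- fpt_probability(x)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(fpt_probability(numeric(0)), "empty")
})

test_that("a one-state fit equals the closed-form pooled MLE", {
  withr::local_seed(11)
  obs <- list(step = rgamma(2000, shape = 3, rate = 0.5),
              angle = c(NA, divetrace:::rvonmises(1999, 0.4, 2)))
  fit <- hmm_fit(obs, n_states = 1, seed = 1, restarts = 1)
  g <- divetrace:::gamma_mle_weighted(obs$step, rep(1, 2000))
  v <- divetrace:::vm_mle_weighted(obs$angle[-1], rep(1, 1999))
  expect_equal(fit$step_gamma$mean, g$mean, tolerance = 1e-6)
  expect_equal(fit$step_gamma$sd, g$sd, tolerance = 1e-6)
  expect_equal(fit$angle_vm$mu, v$mu, tolerance = 1e-6)
  expect_equal(fit$angle_vm$kappa, v$kappa, tolerance = 1e-4)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  truth <- list(n_states = 2,
                step_gamma = data.frame(mean = c(5, 50), sd = c(3, 20)),
                angle_vm = data.frame(mu = c(0, 0), kappa = c(0.5, 5)),
                tpm = matrix(c(0.9, 0.1, 0.1, 0.9), 2),
                delta = c(0.5, 0.5))
  obs <- hmm_simulate(truth, 3000, seed = 2)
  fit <- hmm_fit(obs, n_states = 2, seed = 3, restarts = 2, max_iter = 80)
  expect_true(all(diff(fit$loglik_history) > -1e-8))
  expect_error(hmm_fit(list(step = rep(2, 100), angle = rep(0, 100)),
                       n_states = 2), "degenerate")
})

test_that("forward-backward posteriors match exhaustive enumeration (T<=8)", {
  withr::local_seed(21)
  K <- 3; T_ <- 7
  spec <- list(n_states = K,
               step_gamma = data.frame(mean = c(2, 10, 40),
                                       sd = c(1.5, 4, 12)),
               angle_vm = data.frame(mu = c(0, 0.5, -0.5),
                                     kappa = c(0.3, 1.5, 6)),
               tpm = matrix(c(.8, .1, .1, .2, .6, .2, .1, .3, .6), 3,
                            byrow = TRUE),
               delta = c(0.5, 0.3, 0.2))
  obs <- hmm_simulate(spec, T_, seed = 4)
  obs$angle[1] <- NA
  le <- divetrace:::hmm_log_emissions(obs, spec)
  fb <- divetrace:::hmm_forward_backward(le, spec$tpm, spec$delta)
  post <- hmm_posterior_oracle(obs, spec)
  expect_equal(fb$gamma, post, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(rowSums(fb$gamma), rep(1, T_), tolerance = 1e-10)
})

test_that("well-separated emissions give near-0/1 posteriors", {
  spec <- list(n_states = 3,
               step_gamma = data.frame(mean = c(1, 100, 10000),
                                       sd = c(0.2, 10, 500)),
               angle_vm = data.frame(mu = c(0, 0, 0), kappa = c(1, 1, 1)),
               tpm = matrix(1 / 3, 3, 3),
               delta = rep(1 / 3, 3))
  obs <- hmm_simulate(spec, 2000, seed = 6)
  le <- divetrace:::hmm_log_emissions(obs, spec)
  fb <- divetrace:::hmm_forward_backward(le, spec$tpm, spec$delta)
  decoded <- max.col(fb$gamma)
  expect_gte(mean(decoded == obs$states), 0.99)
})

test_that("posteriors over trips sum to one and pick a sensible dive state", {
  trips <- lapply(booby_trips_small()[1:6], function(t) downsample(t, 5))
  fit <- hmm_fit(trips, n_states = 3, seed = 1, restarts = 2, max_iter = 60)
  post <- hmm_posterior(fit, trips[[1]])
  expect_equal(rowSums(post), rep(1, nrow(trips[[1]])), tolerance = 1e-10)
  expect_equal(nrow(post), nrow(trips[[1]]))
  # unsupervised rule: smallest mean step
  fit_u <- hmm_select_dive_state(fit)
  expect_identical(fit_u$dive_state, which.min(fit_u$step_gamma$mean))
  # supervised rule returns a valid state and dive probabilities in [0,1]
  fit_s <- hmm_select_dive_state(fit, trips)
  probs <- hmm_dive_probability(fit_s, trips[[2]])
  expect_true(all(probs$p_dive >= 0 & probs$p_dive <= 1))
})

test_that("hmm_fit is invariant to trip ordering", {
  trips <- lapply(booby_trips_small()[1:4], function(t) downsample(t, 5))
  a <- hmm_fit(trips, n_states = 2, seed = 5, restarts = 1, max_iter = 40)
  b <- hmm_fit(rev(trips), n_states = 2, seed = 5, restarts = 1,
               max_iter = 40)
  expect_equal(a$step_gamma, b$step_gamma, tolerance = 1e-6)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-6)
})
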