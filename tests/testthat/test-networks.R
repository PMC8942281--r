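# Architectures: parameter budgets, output contract, structure, gradients.

test_that("parameter counts match the fixed layer tables exactly", {
  expect_identical(count_parameters("CNNET"), 4865)
  expect_identical(count_parameters("UNET"), 20041)
  expect_identical(count_parameters("FCNET"), 567620)
  # printed budgets: 5k and 20k after rounding; the dense net is ~500k
  expect_equal(round(count_parameters("CNNET"), -3), 5000)
  expect_equal(round(count_parameters("UNET"), -3), 20000)
  expect_gte(count_parameters("FCNET"), 450000)
  expect_lte(count_parameters("FCNET"), 650000)
  expect_error(architecture_spec("LSTM"), "unknown architecture")
})

test_that("built bundles hold exactly as many weights as the spec declares", {
  for (kind in c("FCNET", "CNNET", "UNET")) {
    m <- build_network(kind, seed = 1)
    expect_identical(divetrace:::n_model_parameters(m),
                     count_parameters(kind))
  }
})

test_that("forward maps a 3x20 window to 20 probabilities in (0,1)", {
  set.seed(1)
  x <- matrix(rnorm(60), 3, 20)
  xb <- array(rnorm(3 * 20 * 7), c(3, 20, 7))
  for (kind in c("FCNET", "CNNET", "UNET")) {
    m <- build_network(kind, seed = 2)
    p <- forward(m, x)
    expect_length(p, 20)
    expect_true(all(p > 0 & p < 1))
    pb <- forward(m, xb)
    expect_equal(dim(pb), c(20, 7))
    expect_identical(forward(m, x), p)            # purity
    m2 <- build_network(kind, seed = 2)
    expect_identical(m2$params, m$params)          # seeded init
    expect_false(identical(build_network(kind, 3)$params, m$params))
  }
  expect_error(forward(build_network("CNNET", 1), matrix(0, 2, 20)), "3 x 20")
  expect_error(forward(build_network("CNNET", 1), matrix(NaN, 3, 20)),
               "finite")
})

test_that("CNNET on all-zero input equals the hand-propagated bias path", {
  m <- build_network("CNNET", seed = 5)
  p <- forward(m, matrix(0, 3, 20))
  # propagate biases by hand: zero input => conv output is the bias, but
  # edge positions lose kernel taps only for the *input* term, so the bias
  # path is constant across positions
  h1 <- pmax(m$params$c1$b, 0)
  # interior positions see all 3 taps of the constant h1 signal
  h2_int <- pmax(apply(m$params$c2$W, 1, function(wk) sum(wk * h1)) +
                   m$params$c2$b, 0)
  h3_int <- pmax(apply(m$params$c3$W, 1, function(wk) sum(wk * h2_int)) +
                   m$params$c3$b, 0)
  z_int <- sum(m$params$head$W[1, , 1] * h3_int) + m$params$head$b
  expect_equal(p[10], 1 / (1 + exp(-z_int)), tolerance = 1e-12)
  # and the output is symmetric about the window centre on symmetric input
  expect_equal(p[5:16], rev(p[5:16]), tolerance = 1e-12)
})

test_that("UNet compresses 20 -> 10 -> 20 and doubles channels at the skip", {
  m <- build_network("UNET", seed = 1)
  x <- array(rnorm(3 * 20 * 2), c(3, 20, 2))
  fw <- divetrace:::net_forward(m$spec, m$params, x)
  expect_equal(dim(fw$cache$re2$out), c(24, 20, 2))   # encoder scale
  expect_equal(dim(fw$cache$pool$out), c(24, 10, 2))  # pooled scale
  expect_equal(dim(fw$cache$rb2$out), c(48, 10, 2))   # bottleneck
  expect_equal(dim(fw$cache$up$out), c(24, 20, 2))    # upsampled back
  expect_equal(fw$cache$d1$cache$dims[1], 48)         # skip doubles channels
  expect_equal(dim(fw$cache$d1$out), c(24, 20, 2))    # decoder output
})

test_that("backpropagated gradients match finite differences", {
  set.seed(42)
  x <- array(rnorm(3 * 20 * 3), c(3, 20, 3))
  y <- matrix(rbinom(60, 1, 0.3), 20, 3)
  h <- 1e-5
  for (kind in c("FCNET", "CNNET", "UNET")) {
    m <- build_network(kind, seed = 4)
    fw <- divetrace:::net_forward(m$spec, m$params, x)
    dz <- divetrace:::wbce_logit_grad(fw$p, y, 30)
    grads <- divetrace:::net_backward(m$spec, m$params, x, fw$cache, dz)
    for (nm in names(m$params)) {
      i <- sample(length(m$params[[nm]]$W), 1)
      mp <- m; mp$params[[nm]]$W[i] <- mp$params[[nm]]$W[i] + h
      mm <- m; mm$params[[nm]]$W[i] <- mm$params[[nm]]$W[i] - h
      fd <- (weighted_bce(forward(mp, x), y, 30) -
               weighted_bce(forward(mm, x), y, 30)) / (2 * h)
      bp <- grads[[nm]]$gW[i]
      expect_lt(abs(fd - bp) / max(abs(fd), abs(bp), 1e-8), 1e-4)
    }
  }
})

test_that("model bundles round-trip bit-exactly through serialization", {
  m <- build_network("UNET", seed = 11)
  m$norm_stats <- structure(list(speed_mean = 1, speed_sd = 2,
                                 fitted_on = "x"), class = "norm_stats")
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, f)
  expect_identical(load_model(f), m)
  # loading validates the parameter-count invariant
  bad <- m
  bad$params$head <- NULL
  saveRDS(bad, f)
  expect_error(load_model(f), "inconsistent")
})
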