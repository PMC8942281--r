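# Preprocessing: trip splitting, 1-s interpolation, dive labelling,
# coverage, downsampling, dataset splits.

test_that("interpolate_1s fills every second and marks observed fixes", {
  fixes <- data.frame(t = c(0, 10), lon = c(0, 0.001), lat = c(0, 0))
  out <- interpolate_1s(fixes)
  expect_equal(nrow(out), 11)
  expect_equal(out$lon[out$t == 5], 0.0005)
  expect_identical(out$observed, c(TRUE, rep(FALSE, 9), TRUE))

  # idempotence on already-regular input
  reg <- data.frame(t = 0:5, lon = seq(0, 0.005, by = 0.001), lat = 0)
  out2 <- interpolate_1s(reg)
  expect_equal(out2$lon, reg$lon)
  expect_true(all(out2$observed))

  # 3 fixes with 4-s gaps: 9 positions, 6 interpolated
  fx <- data.frame(t = c(0, 4, 8), lon = c(0, 1e-3, 2e-3), lat = 0)
  out3 <- interpolate_1s(fx)
  expect_equal(nrow(out3), 9)
  expect_equal(sum(!out3$observed), 6)

  expect_error(interpolate_1s(data.frame(t = 0, lon = 0, lat = 0)),
               "at least 2")
})

test_that("label_dives applies the strict 2-m rule", {
  depth <- data.frame(t = 0:3, depth = c(0, 2.0, 2.5, 1.9))
  expect_identical(label_dives(depth, 0:3), c(FALSE, FALSE, TRUE, FALSE))
  zero <- data.frame(t = 0:5, depth = rep(0, 6))
  expect_identical(label_dives(zero, 0:5), rep(FALSE, 6))
  expect_error(label_dives(data.frame(t = numeric(0), depth = numeric(0)),
                           0:3), "empty")
})

test_that("coverage_ratio is the observed proportion per window", {
  expect_equal(coverage_ratio(rep(TRUE, 20), 5), rep(1, 4))
  mask <- c(rep(TRUE, 45), rep(FALSE, 15))
  expect_equal(coverage_ratio(mask, 60), 0.75)
  expect_equal(coverage_ratio(rep(FALSE, 10), 5), c(0, 0))
  expect_equal(coverage_ratio(c(TRUE, FALSE, TRUE), 1), c(1, 0, 1))
})

test_that("downsample ORs dive labels, averages coverage, decimates", {
  n <- 60
  tr <- straight_trip(n)
  tr$dive[13] <- TRUE                       # one dive second
  ds5 <- downsample(tr, 5)
  expect_equal(nrow(ds5), 12)
  expect_identical(which(ds5$dive), 3L)     # window (10,15] catches it
  ds15 <- downsample(tr, 15)
  expect_equal(nrow(ds15), 4)
  expect_identical(which(ds15$dive), 1L)
  expect_equal(diff(ds15$t), rep(15, 3))

  tr$dive[] <- FALSE
  expect_false(any(downsample(tr, 5)$dive))

  expect_error(downsample(tr, 7), "allow_any_dt")
  expect_s3_class(downsample(tr, 7, allow_any_dt = TRUE), "dive_trip")
})

test_that("dive labels are conserved (>=1, <=k) at every resolution", {
  withr::local_seed(42)
  for (rep in 1:10) {
    tr <- straight_trip(120)
    k <- sample(1:8, 1)
    tr$dive[sample(120, k)] <- TRUE
    for (dt in c(5, 15, 30)) {
      ds <- downsample(tr, dt)
      expect_gte(sum(ds$dive), 1)
      expect_lte(sum(ds$dive), k)
    }
  }
})

test_that("coverage of a fully observed trip is 1 at every resolution", {
  tr <- straight_trip(180)
  for (dt in c(5, 15, 30)) {
    expect_equal(downsample(tr, dt)$coverage,
                 rep(1, 180 %/% dt), ignore_attr = TRUE)
  }
})

test_that("split_trips finds excursions beyond the colony radius", {
  colony <- c(0, 0)
  m_per_deg <- 6371000 * pi / 180
  far <- 2000 / m_per_deg                    # ~2 km in degrees
  # all fixes at the colony
  home <- data.frame(t = 0:100, lon = 0, lat = 0)
  expect_length(split_trips(home, colony), 0)
  # one 20-min excursion
  one <- data.frame(t = seq(0, 3000, by = 60),
                    lon = c(rep(0, 10), rep(far, 25), rep(0, 16)), lat = 0)
  expect_length(split_trips(one, colony, min_duration = 600), 1)
  # two excursions separated by a colony visit
  two <- data.frame(t = seq(0, 6000, by = 60),
                    lon = c(rep(0, 5), rep(far, 30), rep(0, 10),
                            rep(far, 30), rep(0, 26)), lat = 0)
  trips <- split_trips(two, colony, min_duration = 600)
  expect_length(trips, 2)
  expect_length(split_trips(two[0, ], colony), 0)
})

test_that("split_dataset partitions trips 50/30/20 deterministically", {
  ids <- sprintf("trip%03d", 1:10)
  sp <- split_dataset(ids, seed = 3)
  expect_length(sp$train, 5)
  expect_length(sp$validation, 3)
  expect_length(sp$test, 2)
  expect_identical(sort(c(sp$train, sp$validation, sp$test)), ids)
  expect_identical(split_dataset(ids, seed = 3), sp)
  expect_false(identical(split_dataset(ids, seed = 4)$train, sp$train))

  big <- split_dataset(sprintf("t%03d", 1:297), seed = 1)
  expect_length(big$train, 149)
  expect_length(big$validation, 89)
  expect_length(big$test, 59)

  expect_error(split_dataset(ids[1:2]), "at least 3")
})

test_that("process_deployment + downsample keep timestamps regular", {
  cfg <- preset_config("booby_pescadores", seed = 1)
  dep <- apply_gaps(simulate_trip(cfg, 1500, seed = 4), 0.1,
                    mean_gap_length = 8, seed = 2)
  tr <- process_deployment(dep)
  expect_s3_class(tr, "dive_trip")
  expect_equal(unique(diff(tr$t)), 1)
  expect_true(any(!tr$observed))            # gaps became interpolated seconds
  expect_equal(tr$coverage, as.numeric(tr$observed))
  for (dt in c(5, 15, 30)) {
    ds <- downsample(tr, dt)
    expect_equal(unique(diff(ds$t)), dt)
    expect_true(all(ds$coverage >= 0 & ds$coverage <= 1))
  }
})

test_that("trips round-trip through the CSV + JSON sidecar", {
  tr <- straight_trip(50)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "trip.csv")
  write_trip_csv(tr, f)
  back <- read_trip_csv(f)
  expect_equal(back$lon, tr$lon, tolerance = 1e-9)
  expect_identical(attr(back, "trip_id"), attr(tr, "trip_id"))
  expect_identical(attr(back, "dt"), 1)
})
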