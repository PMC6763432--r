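# PAINT post-processing: fiducial tracking, LOESS drift, rendering, radial
# correlation, trans-synaptic profiles.

test_that("fiducial identification finds persistent tracks and ignores transients", {
  set.seed(1)
  frames <- 800L
  fid <- data.frame(frame = (0:(frames - 1))[runif(frames) < 0.95])
  fid$x_nm <- 1000 + rnorm(nrow(fid), 0, 10)
  fid$y_nm <- 2000 + rnorm(nrow(fid), 0, 10)
  # transient binding events, mean lifetime ~3 frames
  ev <- do.call(rbind, lapply(1:120, function(i) {
    f0 <- sample(0:(frames - 5), 1)
    life <- rpois(1, 2) + 1L
    data.frame(frame = f0:(f0 + life - 1L),
               x_nm = runif(1, 3000, 30000) + rnorm(life, 0, 10),
               y_nm = runif(1, 3000, 30000) + rnorm(life, 0, 10))
  }))
  locs <- rbind(fid, ev)
  tracks <- identify_fiducials(locs, persistence_frac = 0.5)
  expect_equal(length(tracks), 1L)
  expect_gt(nrow(tracks[[1]]), 0.9 * frames)

  # two fiducials far apart give two disjoint tracks
  fid2 <- fid; fid2$x_nm <- fid2$x_nm + 5000
  tracks2 <- identify_fiducials(rbind(fid, fid2), persistence_frac = 0.5)
  expect_equal(length(tracks2), 2L)

  expect_error(identify_fiducials(ev, persistence_frac = 0.5),
               "no fiducials")
})

test_that("LOESS drift estimation smooths noise and tracks planted drift", {
  set.seed(2)
  frames <- 2000L
  f <- 0:(frames - 1)
  # stationary fiducial: recovered drift is mostly zero
  tr0 <- list(data.frame(frame = f, x_nm = rnorm(frames, 0, 10),
                         y_nm = rnorm(frames, 0, 10)))
  d0 <- estimate_drift_loess(tr0)
  expect_lt(sqrt(mean(d0$dx^2 + d0$dy^2)), 3)

  # linear drift 0.5 nm/frame
  drift <- 0.5 * f
  tr1 <- list(data.frame(frame = f, x_nm = drift + rnorm(frames, 0, 10),
                         y_nm = rnorm(frames, 0, 10)))
  d1 <- estimate_drift_loess(tr1)
  expect_lt(sqrt(mean((d1$dx - drift)^2)), 5)

  # averaging two fiducials reduces the error
  tr2 <- c(tr1, list(data.frame(frame = f,
                                x_nm = 5000 + drift + rnorm(frames, 0, 10),
                                y_nm = 3000 + rnorm(frames, 0, 10))))
  d2 <- estimate_drift_loess(tr2)
  rms1 <- sqrt(mean((d1$dx - drift)^2))
  rms2 <- sqrt(mean((d2$dx - drift)^2))
  expect_lt(rms2, rms1)

  short <- list(data.frame(frame = 0:4, x_nm = rnorm(5), y_nm = rnorm(5)))
  expect_warning(expect_error(estimate_drift_loess(short), "no usable"),
                 "excluded")
})

test_that("drift correction is exact, invertible and bounded by localization precision", {
  locs <- data.frame(frame = 0:99, x_nm = rnorm(100, 0, 5),
                     y_nm = rnorm(100, 0, 5))
  zero <- data.frame(frame = 0:99, dx = 0, dy = 0)
  expect_equal(correct_drift(locs, zero), locs)

  traj <- data.frame(frame = 0:99, dx = cumsum(rnorm(100, 0, 1)),
                     dy = cumsum(rnorm(100, 0, 1)))
  round_trip <- correct_drift(correct_drift(locs, traj),
                              negate_trajectory(traj))
  expect_equal(round_trip, locs, tolerance = 1e-12)

  bad <- data.frame(frame = 120, x_nm = 0, y_nm = 0)
  expect_error(correct_drift(bad, traj), "cover")

  # end-to-end: simulated smooth drift removed to a small residual
  cfg <- paint_config(frames = 3000L, sigma_loc_nm = 10,
                      fiducials = data.frame(x_nm = c(0, 20000),
                                             y_nm = c(0, 15000)),
                      drift = list(mode = "random_walk", step_nm = 0.5,
                                   smooth_frames = 200L), seed = 7L)
  sim <- simulate_localization_dataset(cfg)
  tracks <- identify_fiducials(sim$locs)
  est <- estimate_drift_loess(tracks, frames = 3000L)
  corr <- correct_drift(sim$locs, est)
  f1 <- corr[corr$kind == "fiducial" & corr$source_id == 1L, ]
  scatter <- sqrt(mean((f1$x_nm - mean(f1$x_nm))^2 +
                         (f1$y_nm - mean(f1$y_nm))^2))
  expect_lt(scatter, 1.2 * 10 * sqrt(2))
})

test_that("histogram rendering conserves counts and handles single events", {
  one <- data.frame(frame = 0L, x_nm = 10, y_nm = 10)
  img <- render_histogram(one, bin_nm = 5.4, smooth_sigma_bins = 0)
  expect_equal(sum(img$image), 1)
  expect_equal(max(img$image), 1)

  set.seed(3)
  locs <- data.frame(frame = 0:999, x_nm = rnorm(1000, 0, 50),
                     y_nm = rnorm(1000, 0, 50))
  raw <- render_histogram(locs, bin_nm = 5.4, smooth_sigma_bins = 0)
  expect_equal(sum(raw$image), 1000)
  sm <- render_histogram(locs, bin_nm = 5.4, smooth_sigma_bins = 1)
  expect_equal(sm$mass_fraction, 1, tolerance = 1e-3)

  expect_error(render_histogram(locs[0, ]), "empty")
})

test_that("radial correlation has unit baseline on independent images and the Gaussian closed form", {
  set.seed(4)
  mkimg <- function(m) structure(list(image = m, bin_nm = 10, x0_nm = 0,
                                      y0_nm = 0, n = sum(m),
                                      mass_fraction = 1),
                                 class = "sr_image")
  A <- mkimg(matrix(runif(200^2), 200, 200))
  B <- mkimg(matrix(runif(200^2), 200, 200))
  rc <- radial_cross_correlation(A, B, max_r_nm = 400)
  expect_lt(max(abs(rc$corr - 1)), 0.05)

  # single Gaussian blob, A = B: 1/e decay at 2 sigma (sqrt(2) sigma
  # autocorrelation width)
  xg <- outer(rep(1, 256), 1:256); yg <- outer(1:256, rep(1, 256))
  sigma_bins <- 8            # 80 nm at 10 nm bins
  blob <- exp(-((xg - 128)^2 + (yg - 128)^2) / (2 * sigma_bins^2))
  G <- mkimg(blob)
  rcg <- radial_cross_correlation(G, G, max_r_nm = 800)
  expect_equal(rcg$decay_length_nm, 2 * sigma_bins * 10, tolerance = 0.2)

  empty <- mkimg(matrix(0, 256, 256))
  expect_error(radial_cross_correlation(empty, G), "empty")
})

test_that("trans-synaptic profiles recover medians, offsets and Gaussian widths", {
  set.seed(5)
  sym <- data.frame(frame = 0L, x_nm = rnorm(3000, 0, 40),
                    y_nm = rnorm(3000, 0, 40))
  pr <- transsynaptic_profile(list(s = sym), center = c(0, 0),
                              axis_angle = 0, bin_nm = 10)
  expect_lt(abs(pr$s$median_nm), 10)

  pre <- data.frame(frame = 0L, x_nm = rnorm(3000, -75, 25),
                    y_nm = rnorm(3000, 0, 60))
  post <- data.frame(frame = 0L, x_nm = rnorm(3000, 75, 25),
                     y_nm = rnorm(3000, 0, 60))
  pr2 <- transsynaptic_profile(list(pre = pre, post = post),
                               center = c(0, 0), axis_angle = 0)
  expect_equal(pr2$post$median_nm - pr2$pre$median_nm, 150, tolerance = 10)
  expect_equal(pr2$pre$fwhm_nm, 2.3548 * 25, tolerance = 3)

  few <- data.frame(frame = 0L, x_nm = rnorm(10, 0, 20),
                    y_nm = rnorm(10, 0, 20))
  pr3 <- transsynaptic_profile(list(f = few), center = c(0, 0))
  expect_true(is.na(pr3$f$fwhm_nm))
  expect_false(is.na(pr3$f$median_nm))
})
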