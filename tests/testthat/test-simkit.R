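test_that("simulation is deterministic under a fixed seed", {
  cfg <- simConfig(nFrames = 200, rngSeed = 11, bleachLifetime = 40,
                   blinkOnLifetime = 5, blinkOffLifetime = 0.5)
  a <- simulateTrajectories(cfg, 10)
  b <- simulateTrajectories(cfg, 10)
  expect_identical(a, b)
  set.seed(99)                     # render uses the ambient RNG stream
  ka <- renderKymograph(a, cfg)
  set.seed(99)
  kb <- renderKymograph(b, cfg)
  expect_identical(kymoImage(ka), kymoImage(kb))
  da <- simulateDwellTimes(5, 40, 300, 50, seed = 3)
  db <- simulateDwellTimes(5, 40, 300, 50, seed = 3)
  expect_identical(da, db)
})

test_that("degenerate motion gives a constant position", {
  cfg <- simConfig(nFrames = 50, diffusionCoefficient = 0,
                   localizationSigma = 0, motileFraction = 0, rngSeed = 1)
  sim <- simulateTrajectories(cfg, 3)
  for (id in unique(sim$tracks$particle_id)) {
    x <- sim$tracks$position_um[sim$tracks$particle_id == id]
    expect_equal(diff(range(x)), 0)
  }
})

test_that("one-frame increment variance matches 2*D*dt for Brownian motion", {
  cfg <- simConfig(nFrames = 10001, diffusionCoefficient = 0.02, alpha = 1,
                   localizationSigma = 0, motileFraction = 1,
                   dnaLength = 1e6, rngSeed = 3)
  sim <- simulateTrajectories(cfg, 1)
  inc2 <- diff(sim$tracks$position_um)^2
  expect_lt(abs(mean(inc2) - 0.004) / 0.004, 0.05)
})

test_that("scaled Brownian increments pass a KS normality check", {
  cfg <- simConfig(nFrames = 2001, diffusionCoefficient = 0.02, alpha = 1,
                   localizationSigma = 0, motileFraction = 1,
                   dnaLength = 1e6, rngSeed = 13)
  sim <- simulateTrajectories(cfg, 1)
  z <- diff(sim$tracks$position_um) / sqrt(2 * 0.02 * 0.1)
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("anomalous increments reproduce the power-law MSD scaling", {
  set.seed(21)
  reps <- replicate(40, {
    x <- cumsum(fgnIncrements(512, H = 0.65, sigma2 = 1))
    vapply(c(2, 4, 8), function(n) mean(diff(x, lag = n)^2), numeric(1))
  })
  emp <- rowMeans(reps)
  expect_equal(emp, c(2, 4, 8)^1.3, tolerance = 0.08)
})

test_that("track durations follow the bleaching lifetime", {
  cfg <- simConfig(nFrames = 5000, bleachLifetime = 40.4,
                   motileFraction = 0, rngSeed = 4)
  sim <- simulateTrajectories(cfg, 2000)
  dur <- sim$truth$particles$end_time_s
  se <- 40.4 / sqrt(2000)
  expect_lt(abs(mean(dur) - 40.4), 3 * se)
})

test_that("truth covers every rendered frame and dwell equals the span", {
  cfg <- simConfig(nFrames = 100, bleachLifetime = 20, blinkOnLifetime = 3,
                   blinkOffLifetime = 0.5, rngSeed = 7)
  sim <- simulateTrajectories(cfg, 20)
  obs <- merge(sim$tracks[, c("particle_id", "frame")],
               sim$truth$positions[, c("particle_id", "frame", "visible")],
               by = c("particle_id", "frame"))
  expect_equal(nrow(obs), nrow(sim$tracks))
  p <- sim$truth$particles
  expect_true(all(abs(p$true_dwell_s -
                      pmin(p$bind_time_s, p$bleach_time_s, 100 * 0.1)) < 1e-12))
})

test_that("dwell simulation obeys the competing-risks mean across a grid", {
  for (tp in list(c(5, Inf), c(2.8, 40.4), c(10, 20))) {
    d <- simulateDwellTimes(tp[1], tp[2], 1e4, 1e4, seed = 5)
    tauEff <- 1 / (1 / tp[1] + 1 / tp[2])
    se <- tauEff / sqrt(1e4)
    expect_lt(abs(mean(d$duration_s) - tauEff), 3 * se)
  }
})

test_that("dwells are censored exactly at the observation window", {
  d <- simulateDwellTimes(200, Inf, 300, 2000, seed = 6)
  expect_true(all(d$duration_s <= 300))
  expect_identical(d$censored, d$duration_s == 300)
  expect_error(simulateDwellTimes(5, 40, -1, 10), "observationWindow")
  expect_error(simulateDwellTimes(-5, 40, 300, 10), "lifetimes")
})

test_that("kymograph rendering matches its definition", {
  cfg <- simConfig(nFrames = 20, rngSeed = 1)
  empty <- data.frame(frame = integer(), position_um = numeric(),
                      visible = logical())
  k0 <- renderKymograph(empty, cfg, nPixels = 30, shotNoise = FALSE,
                        offset = 7)
  expect_true(all(kymoImage(k0) == 7))
  pos <- data.frame(frame = 0:19, position_um = 1.23, visible = TRUE)
  k1 <- renderKymograph(pos, cfg, nPixels = 30, shotNoise = FALSE)
  img <- kymoImage(k1)
  # pixel centres at (i - 0.5) * pixelSize: 1.23 um falls in pixel 13
  expect_true(all(apply(img, 2, which.max) == 13))
})

test_that("shot-noise photon counts are Poisson with the photon-rate mean", {
  cfg <- simConfig(nFrames = 500, photonRate = 500, rngSeed = 2)
  pos <- data.frame(frame = 0:499, position_um = 1.0, visible = TRUE)
  set.seed(31)
  k <- renderKymograph(pos, cfg, nPixels = 20, shotNoise = TRUE, offset = 0)
  img <- kymoImage(k)
  expect_true(all(img >= 0) && all(img == floor(img)))
  perFrame <- colSums(img)
  mu <- 500 * 0.1
  se <- sqrt(mu / 500)
  expect_lt(abs(mean(perFrame) - mu), 3 * se)
})

test_that("damage layouts follow the array and fiducial rules", {
  expect_length(sites(makeDamageLayout("array", spacing = 2, length = 20)), 10)
  fm <- makeDamageLayout("fiducial", length = 48.5,
    sitePositions = c(1.2, 5, 9, 13, 17, 21, 25, 29, 29.4, 40),
    resolutionLimit = 1, beadMargin = 2)
  expect_length(sites(fm), 8)
  expect_length(sites(makeDamageLayout("fiducial", length = 10,
    sitePositions = numeric(0))), 0)
  expect_error(makeDamageLayout("array", spacing = -1, length = 20), "spacing")
})

test_that("isotherm simulation reduces to the quadratic model", {
  grid <- c(0, 1, 2, 4, 8, 16, 32)
  pts <- simulateIsotherm(6, 8, grid, noiseSd = 0)
  expect_equal(pts$percent_bound, fractionBoundModel(8, grid, 6))
  expect_equal(pts$percent_bound[1], 0)
  expect_error(simulateIsotherm(6, 8, grid, noiseSd = -1), "noiseSd")
  noisy <- simulateIsotherm(6, 8, c(0, 1, 2, 3, 4, 6, 8, 12, 20, 32),
                            noiseSd = 2, seed = 8)
  expect_lt(abs(kd(fitKd(noisy)) - 6) / 6, 0.15)
})
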