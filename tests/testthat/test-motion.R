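test_that("computeMsd reproduces the hand-computed example", {
  m <- computeMsd(c(0, 1, 2, 3), 0.1, maxLagFraction = 1)
  expect_equal(msdLags(m), c(0.1, 0.2, 0.3))
  expect_equal(msdValues(m), c(1, 4, 9))
})

test_that("computeMsd of a constant track is identically zero", {
  m <- computeMsd(rep(2.5, 40), 0.1)
  expect_true(all(msdValues(m) == 0))
})

test_that("computeMsd equals the brute-force double loop to machine precision", {
  set.seed(42)
  for (i in 1:20) {
    x <- cumsum(rnorm(200))
    m <- computeMsd(x, 0.1, maxLagFraction = 0.5)
    expect_equal(msdValues(m), msdBruteForce(x, 0.1, length(msdLags(m))),
                 tolerance = 1e-12)
  }
})

test_that("non-uniform sampling is a precondition error", {
  expect_error(computeMsd(c(0, 1, 2), 0.1, frames = c(0L, 1L, 3L)),
               "uniform")
  expect_error(computeMsd(1, 0.1), "at least 2")
})

test_that("a noiseless linear MSD is fit exactly", {
  t <- (1:25) * 0.1
  m <- new("MsdCurve", lag = t, msd = 2 * 0.02 * t, nFrames = 100L,
           nPairs = as.integer(100 - 1:25))
  f <- fitDiffusion(m)
  expect_equal(diffusionCoefficient(f), 0.02, tolerance = 1e-6)
  expect_equal(alphaExponent(f), 1, tolerance = 1e-6)
  expect_equal(f@intercept, 0, tolerance = 1e-8)
  expect_equal(rSquared(f), 1, tolerance = 1e-9)
  expect_true(isAccepted(f))
})

test_that("a ballistic track recovers alpha = 2 and 2D = v^2", {
  x <- 0.1 * (0:199) * 0.1              # x = v t with v = 0.1 um/s, 10 fps
  m <- computeMsd(x, 0.1)
  f <- fitDiffusion(m)
  expect_equal(alphaExponent(f), 2, tolerance = 1e-6)
  expect_equal(2 * diffusionCoefficient(f), 0.01, tolerance = 1e-6)
})

test_that("the R^2 and coverage filters reject fits", {
  # sawtooth MSD: no power law fits it well
  t <- (1:20) * 0.1
  m <- new("MsdCurve", lag = t, msd = 0.1 + 0.05 * rep(c(1, -1), 10),
           nFrames = 80L, nPairs = as.integer(80 - 1:20))
  f <- fitDiffusion(m)
  expect_lt(rSquared(f), 0.8)
  expect_false(isAccepted(f))
  # clean curve but truncated below 10% coverage: never accepted
  t2 <- (1:5) * 0.1
  m2 <- new("MsdCurve", lag = t2, msd = 2 * 0.02 * t2, nFrames = 400L,
            nPairs = as.integer(400 - 1:5))
  f2 <- fitDiffusion(m2)
  expect_lt(f2@fractionUsed, 0.10)
  expect_false(isAccepted(f2))
})

test_that("localization noise inflates the intercept, not D", {
  set.seed(10)
  fitOnce <- function(sigma) {
    x <- cumsum(c(0, rnorm(299, 0, sqrt(2 * 0.0211 * 0.1)))) +
      rnorm(300, 0, sigma)
    f <- fitDiffusion(computeMsd(x, 0.1))
    c(D = diffusionCoefficient(f), y = f@intercept)
  }
  clean <- rowMeans(replicate(25, fitOnce(0)))
  noisy <- rowMeans(replicate(25, fitOnce(0.05)))
  expect_gt(noisy["y"], clean["y"] + 0.05^2)        # intercept rises ~2*sigma^2
  expect_lt(abs(noisy["D"] - clean["D"]) / clean["D"], 0.35)
})

test_that("phase segmentation handles degenerate and composite tracks", {
  set.seed(8)
  pure <- makeTrack("P", 0:99, rnorm(100, 2, 0.02))
  ph <- segmentPhases(pure, localizationSigma = 0.02)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$label, "stationary")
  # 100 stationary then 100 diffusive frames: boundary within +/- 10 frames
  x2 <- 2 + cumsum(rnorm(100, 0, sqrt(2 * 0.02 * 0.1)))
  comp <- makeTrack("C", 0:199, c(rnorm(100, 2, 0.02),
                                  x2 + rnorm(100, 0, 0.02)))
  ph2 <- segmentPhases(comp, localizationSigma = 0.02, windowFrames = 25,
                       minPhaseFrames = 25)
  expect_equal(ph2$label[1], "stationary")
  expect_true(any(ph2$label == "motile"))
  boundary <- ph2$end_frame[1]
  expect_lt(abs(boundary - 100), 10)
  # 5-frame track with min length 10 -> excluded
  short <- makeTrack("S", 0:4, rnorm(5))
  expect_equal(nrow(segmentPhases(short, minPhaseFrames = 10)), 0)
})

test_that("behavior classification returns exact 2x2 counts", {
  empty <- classifyBehavior(makeTrack("x", integer(0), numeric(0)),
                            data.frame(track_id = character(),
                                       label = character(),
                                       accepted = logical()), 30)
  expect_equal(sum(empty$count), 0)
  # all particles persist with zero motile phases -> stationary-persistent
  tr <- rbind(makeTrack("A", 0:299, rnorm(300, 1, 0.02), censored = TRUE),
              makeTrack("B", 0:299, rnorm(300, 3, 0.02), censored = TRUE))
  ph <- analyzeMotion(tr, 0.1, localizationSigma = 0.02)
  beh <- classifyBehavior(tr, ph, 30)
  expect_equal(beh$count[beh$motility == "stationary" &
                         beh$fate == "persistent"], 2L)
  expect_equal(sum(beh$count), 2L)
  # planted flags recovered exactly
  set.seed(3)
  tr2 <- rbind(brownianTrack("M", 300, 0.05, sigmaLoc = 0.02),
               makeTrack("S", 0:299, rnorm(300, 5, 0.02), censored = TRUE))
  ph2 <- analyzeMotion(tr2, 0.1, localizationSigma = 0.02)
  beh2 <- classifyBehavior(tr2, ph2, 30)
  per <- attr(beh2, "particles")
  expect_equal(per$motility[per$particle_id == "M"], "motile")
  expect_equal(per$fate[per$particle_id == "M"], "dissociated")
  expect_equal(per$motility[per$particle_id == "S"], "stationary")
  expect_equal(per$fate[per$particle_id == "S"], "persistent")
})
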