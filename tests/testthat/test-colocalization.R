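test_that("identical track lists are 100% colocalized", {
  a <- rbind(makeTrack("p1", 0:49, rep(1, 50)),
             makeTrack("p2", 0:49, rep(4, 50)))
  b <- a
  b$channel <- "B"
  r <- callColocalization(a, b)
  expect_equal(unname(colocCounts(r)[["colocalized"]]), 2L)
  expect_equal(unname(colocFractions(r)[["fraction_of_molecules"]]), 1)
})

test_that("an empty channel gives zero colocalization", {
  a <- makeTrack("p1", 0:49, rep(1, 50))
  b <- makeTrack(character(0), integer(0), numeric(0), channel = "B")
  r <- callColocalization(a, b)
  expect_equal(unname(colocCounts(r)[["colocalized"]]), 0L)
  expect_equal(unname(colocCounts(r)[["a_only"]]), 1L)
})

test_that("greedy pairing matches the exhaustive oracle on small instances", {
  set.seed(23)
  for (rep in 1:5) {
    offsets <- matrix(runif(25, 0, 1.2), 5, 5)
    a <- do.call(rbind, lapply(1:5, function(i)
      makeTrack(paste0("a", i), 0:99, rep(i * 2, 100))))
    b <- do.call(rbind, lapply(1:5, function(j)
      makeTrack(paste0("b", j), 0:99,
                rep(2 * ((j + rep) %% 5 + 1) + runif(1, 0, 0.8), 100),
                channel = "B")))
    r <- callColocalization(a, b, distanceThreshold = 0.5, minOverlap = 1)
    # oracle: overlap matrix with NA where below threshold
    om <- matrix(-Inf, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      xa <- a$position_um[a$particle_id == paste0("a", i)]
      xb <- b$position_um[b$particle_id == paste0("b", j)]
      ov <- sum(abs(xa - xb) <= 0.5) * 0.1
      if (ov >= 1) om[i, j] <- ov
    }
    best <- colocBruteForce(om)
    nBest <- if (is.null(best$pairs)) 0L else nrow(best$pairs)
    expect_equal(unname(colocCounts(r)[["colocalized"]]), nBest)
  }
})

test_that("colocalization is symmetric under channel swap", {
  set.seed(24)
  a <- rbind(makeTrack("a1", 0:99, rep(1, 100)),
             makeTrack("a2", 0:99, rep(5, 100)),
             makeTrack("a3", 0:99, rep(9, 100)))
  b <- rbind(makeTrack("b1", 0:99, rep(1.2, 100), channel = "B"),
             makeTrack("b2", 0:99, rep(20, 100), channel = "B"))
  r1 <- callColocalization(a, b)
  r2 <- callColocalization(b, a)
  expect_equal(unname(colocCounts(r1)[["colocalized"]]),
               unname(colocCounts(r2)[["colocalized"]]))
  expect_equal(unname(colocCounts(r1)[["a_only"]]),
               unname(colocCounts(r2)[["b_only"]]))
})

test_that("a planted colocalized fraction is recovered", {
  set.seed(25)
  n <- 100; f <- 0.25
  nC <- round(f * n)
  mk <- function(i, x, ch) makeTrack(paste0(ch, i), 0:49, rep(x, 50),
                                     channel = ch)
  xs <- seq(1, by = 3, length.out = n)
  a <- do.call(rbind, lapply(1:n, function(i) mk(i, xs[i], "A")))
  # first nC B particles sit on A positions; the rest are far away
  bx <- c(xs[seq_len(nC)], xs[-seq_len(nC)] + 1.4)
  b <- do.call(rbind, lapply(1:n, function(i) mk(i, bx[i], "B")))
  r <- callColocalization(a, b, distanceThreshold = 0.5, minOverlap = 1)
  expect_equal(unname(colocCounts(r)[["colocalized"]]), nC)
  expect_equal(unname(colocFractions(r)[["fraction_of_molecules"]]), f)
})

test_that("on-target classification follows the distance window", {
  fm <- makeDamageLayout("array", spacing = 2, length = 20)
  ev <- data.frame(position = c(2, 2.4, 2.6, 11))
  out <- classifyOnTarget(ev, fm, window = 0.5)
  expect_equal(out$on_target, c(TRUE, TRUE, FALSE, FALSE))
  emptyMap <- makeDamageLayout("fiducial", length = 10,
                               sitePositions = numeric(0))
  expect_warning(out2 <- classifyOnTarget(ev, emptyMap, window = 1),
                 "empty fiducial")
  expect_false(any(out2$on_target))
})

test_that("uniform events match the geometric on-target expectation", {
  fm <- makeDamageLayout("fiducial", length = 48.5,
    sitePositions = c(5, 10, 15, 20, 25, 30, 35, 40),
    resolutionLimit = 0, beadMargin = 0)
  set.seed(26)
  w <- 0.5
  n <- 1e4
  ev <- classifyOnTarget(data.frame(position = runif(n, 0, 48.5)), fm,
                         window = w)
  p <- 8 * 2 * w / 48.5
  ci <- qbinom(c(0.005, 0.995), n, p) / n
  frac <- attr(ev, "fraction_on_target")
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("dual-color behavior tables have consistent fractions", {
  a <- rbind(makeTrack("a1", 0:299, rnorm(300, 1, 0.02), censored = TRUE),
             makeTrack("a2", 0:299, rnorm(300, 5, 0.02), censored = TRUE))
  b <- makeTrack("b1", 0:299, rnorm(300, 1, 0.02), channel = "B",
                 censored = TRUE)
  r <- callColocalization(a, b)
  phA <- analyzeMotion(a, 0.1, localizationSigma = 0.02)
  phB <- analyzeMotion(b, 0.1, localizationSigma = 0.02)
  behA <- classifyBehavior(a, phA, 30)
  behB <- classifyBehavior(b, phB, 30)
  s <- summarizeDualColor(r, behA, behB)
  expect_named(s, c("a_only", "b_only", "colocalized"))
  expect_equal(sum(s$colocalized$count), 1)
  expect_equal(sum(s$colocalized$fraction), 1)
  expect_equal(sum(s$a_only$count), 1)
  # empty dataset: no division by zero
  r0 <- callColocalization(makeTrack(character(0), integer(0), numeric(0)),
                           makeTrack(character(0), integer(0), numeric(0),
                                     channel = "B"))
  beh0 <- classifyBehavior(makeTrack(character(0), integer(0), numeric(0)),
                           data.frame(track_id = character(),
                                      label = character(),
                                      accepted = logical()), 30)
  s0 <- summarizeDualColor(r0, beh0, beh0)
  expect_true(all(is.na(s0$a_only$fraction)))
})
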