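test_that("normalizeDistribution centers and scales with the population sd", {
  expect_equal(normalizeDistribution(c(2, 4, 6)),
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-12)
  v <- rnorm(100)
  nv <- normalizeDistribution(v)
  expect_lt(abs(mean(nv)), 1e-9)
  expect_lt(abs(sqrt(mean((nv - mean(nv))^2)) - 1), 1e-9)
  # idempotence
  expect_equal(normalizeDistribution(nv), nv, tolerance = 1e-9)
})

test_that("constant input raises a degenerate-distribution condition", {
  expect_error(normalizeDistribution(c(5, 5, 5)),
               class = "shapescreen_degenerate")
  expect_error(normalizeDistribution(3), class = "shapescreen_degenerate")
})

test_that("normalization and moments are invariant to positive affine maps", {
  set.seed(3)
  for (i in 1:20) {
    v <- rgamma(150, shape = 2, scale = 30)
    a <- runif(1, 0.2, 5)
    b <- runif(1, -50, 50)
    w <- applyAffineArtifact(v, a, b)
    expect_lt(max(abs(normalizeDistribution(w) - normalizeDistribution(v))),
              1e-9)
    mv <- distributionMoments(v)
    mw <- distributionMoments(w)
    expect_lt(abs(mv$skewness - mw$skewness), 1e-9)
    expect_lt(abs(mv$kurtosis - mw$kurtosis), 1e-9)
    # normalization leaves the shape moments untouched
    mn <- distributionMoments(normalizeDistribution(v))
    expect_lt(abs(mv$skewness - mn$skewness), 1e-9)
    expect_lt(abs(mv$kurtosis - mn$kurtosis), 1e-9)
  }
})

test_that("moments match direct central-moment sums", {
  expect_equal(distributionMoments(c(-1, 0, 1))$skewness, 0)
  v <- c(0, 0, 0, 1)
  m <- distributionMoments(v)
  d <- v - mean(v)
  expect_equal(m$mean, 0.25)
  expect_equal(m$variance, mean(d^2))
  expect_equal(m$skewness, mean(d^3) / mean(d^2)^1.5)
  expect_equal(m$kurtosis, mean(d^4) / mean(d^2)^2)
  # degenerate and short inputs are flagged, not errors
  expect_true("kurtosis" %in% distributionMoments(c(1, 2, 3))$flags)
  expect_setequal(distributionMoments(c(2, 2, 2, 2))$flags,
                  c("skewness", "kurtosis"))
})

test_that("anovaF reproduces an explicit sum-of-squares computation", {
  # no between-group variance
  expect_equal(anovaF(c(1, 2, 3, 1, 2, 3),
                      rep(c("a", "b"), each = 3))$fStatistic, 0)
  set.seed(5)
  vals <- rnorm(300)
  grp <- rep(letters[1:10], each = 30)
  a <- anovaF(vals, grp)
  gm <- tapply(vals, grp, mean)
  ssb <- sum(30 * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  fOracle <- (ssb / 9) / (ssw / 290)
  expect_lt(abs(a$fStatistic - fOracle), 1e-9)
  expect_identical(a$dfBetween, 9L)
  expect_identical(a$dfWithin, 290L)
})

test_that("anovaF flags degenerate data and drops undersized groups", {
  a <- anovaF(rep(c(1, 2), each = 4), rep(c("a", "b"), each = 4))
  expect_true(a$flagged)
  expect_true(is.na(a$fStatistic))
  expect_warning(anovaF(c(1, 2, 5, 1, 2), c("a", "a", "b", "b", "c")),
                 "dropping")
  expect_error(suppressWarnings(anovaF(c(1, 2, 3), c("a", "a", "b"))),
               "at least 2 groups")
})

test_that("log rescaling before normalization breaks affine equivalence", {
  set.seed(9)
  base <- rgamma(400, shape = 2, scale = 40) + 5
  wells <- list(w1 = base, w2 = 2 * base + 200, w3 = 3 * base)
  ck <- rescaleConvergenceCheck(wells, transform = "log")
  byPair <- function(a, b)
    ck[ck$well_a == a & ck$well_b == b, ]
  # affine copies collapse under plain normalization (D is a step
  # function, so float noise can still move a few pooled points by one
  # ECDF step of 1/400)
  expect_true(all(ck$d_plain < 0.02))
  # differing offsets survive the log pre-transform
  expect_gt(byPair("w1", "w2")$d_transformed, 0.05)
  # pure scale becomes a shift under log, removed by normalization
  expect_lt(byPair("w1", "w3")$d_transformed, 0.02)
  expect_error(rescaleConvergenceCheck(list(a = c(-1, 2), b = c(1, 2)),
                                       "log"), "positive")
})

test_that("partialNormalize matches neighbor-average statistics", {
  set.seed(21)
  vals <- lapply(1:9, function(i) rnorm(80, mean = i, sd = i / 3))
  names(vals) <- sprintf("W%02d", 1:9)
  pos <- data.frame(well_id = names(vals),
                    row = rep(1:3, each = 3), col = rep(1:3, times = 3))
  # center well: all 8 neighbors
  out <- partialNormalize(vals, pos, "W05")
  nb <- names(vals)[-5]
  expect_equal(mean(out), mean(vapply(vals[nb], mean, 0)),
               tolerance = 1e-9)
  expect_equal(mean((out - mean(out))^2),
               mean(vapply(vals[nb], function(v) mean((v - mean(v))^2), 0)),
               tolerance = 1e-9)
  # corner well: the 3 existing neighbors only
  out1 <- partialNormalize(vals, pos, "W01")
  nb1 <- c("W02", "W04", "W05")
  expect_equal(mean(out1), mean(vapply(vals[nb1], mean, 0)),
               tolerance = 1e-9)
  expect_equal(mean((out1 - mean(out1))^2),
               mean(vapply(vals[nb1], function(v)
                 mean((v - mean(v))^2), 0)), tolerance = 1e-9)
  # unit-statistics neighbors reduce to plain normalization
  vals2 <- vals
  for (w in nb) vals2[[w]] <- normalizeDistribution(vals2[[w]])
  expect_equal(partialNormalize(vals2, pos, "W05"),
               normalizeDistribution(vals2[["W05"]]), tolerance = 1e-9)
})

test_that("row artifacts inflate mean-F but not skewness-F on intensity features", {
  cfg <- smallConfig(seed = 31, hitFraction = 0,
                     artifact = artifactSpec(rowOffset = 0.5,
                                             rowScale = 0.3))
  scr <- generateScreen(cfg)
  dg <- diagnosticsReport(scr, features = c("I1", "G2"),
                          measures = c("mean", "skewness"),
                          grouping = "row")
  med <- function(f, m) median(dg$f[dg$feature == f & dg$measure == m])
  expect_gt(med("I1", "mean") / med("I1", "skewness"), 3)
  expect_lt(med("G2", "mean") / med("G2", "skewness"), 3)
})
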