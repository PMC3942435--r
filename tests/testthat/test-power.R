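test_that("bin probabilities reduce to binomials in the degenerate cases", {
  p <- binProbabilities(h = 1, alpha = 0, beta0 = 0.4, sigma = 0)
  expect_equal(p$hit[4], 0.6^3, tolerance = 1e-12)   # 3-of-3
  expect_equal(p$hit[1], 0.4^3, tolerance = 1e-12)   # 0-of-3
  p2 <- binProbabilities(h = 0, alpha = 0.1, beta0 = 0.5, sigma = 0.1)
  expect_equal(sum(p2$mixture[3:4]), 3 * 0.01 * 0.9 + 0.001,
               tolerance = 1e-12)
  expect_error(binProbabilities(1.2, 0.1, 0.5, 0.1),
               class = "shapescreen_domain")
})

test_that("bin probabilities sum to one for arbitrary valid parameters", {
  set.seed(81)
  for (i in 1:50) {
    p <- binProbabilities(runif(1), runif(1), runif(1), runif(1, 0, 0.5))
    expect_lt(abs(sum(p$hit) - 1), 1e-10)
    expect_lt(abs(sum(p$negative) - 1), 1e-10)
    expect_lt(abs(sum(p$mixture) - 1), 1e-10)
  }
})

test_that("bin probabilities match a Monte-Carlo of the generative process", {
  set.seed(82)
  n <- 200000
  h <- 0.2; alpha <- 0.05; beta0 <- 0.5; sigma <- 0.2
  isHit <- runif(n) < h
  beta <- shapescreen:::.rtrunc01(n, beta0, sigma)
  pUp <- ifelse(isHit, 1 - beta, alpha)
  k <- rbinom(n, 3, pUp)
  mc <- tabulate(k + 1L, 4L) / n
  p <- binProbabilities(h, alpha, beta0, sigma)$mixture
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(mc - p) < 4 * se))
})

test_that("triplicate bins are exact counts with the right monotonicity", {
  gs <- data.frame(gene = paste0("g", 1:4), feature = "f",
                   z1 = c(4, 4, 4, 0), z2 = c(4, 4, 0, 0),
                   z3 = c(4, 0, 0, 0))
  b <- binsFromScores(gs, 3)
  expect_equal(unlist(b[1, c("n0", "n1", "n2", "n3")], use.names = FALSE),
               c(1, 1, 1, 1))
  b2 <- binsFromScores(gs, -1)
  expect_equal(b2$n3, 4)
  expect_equal(b2$n0 + b2$n1 + b2$n2, 0)

  set.seed(83)
  z <- matrix(rnorm(300), ncol = 3)
  gsr <- data.frame(gene = paste0("g", 1:100), feature = "f",
                    z1 = z[, 1], z2 = z[, 2], z3 = z[, 3])
  bs <- binsFromScores(gsr, seq(-1, 2, 0.5))
  # independent per-gene recount
  for (i in seq_len(nrow(bs))) {
    k <- vapply(1:100, function(g) sum(z[g, ] > bs$threshold[i]), 0L)
    expect_equal(unlist(bs[i, c("n0", "n1", "n2", "n3")],
                        use.names = FALSE),
                 vapply(0:3, function(j) sum(k == j), 0L))
  }
  expect_true(all(diff(bs$n3) <= 0))
  expect_true(all(diff(bs$n0) >= 0))
})

test_that("noiseless bins are fit to their degeneracy width", {
  # the shared-h system is only 'almost' determined: for bins generated
  # exactly from the model, h is identified up to a narrow interval in
  # which every threshold can be reproduced exactly
  hTrue <- 0.15
  th <- c(1, 2, 3, 4, 5)
  al <- c(0.30, 0.10, 0.02, 0.004, 0.001)
  b0 <- c(0.10, 0.25, 0.40, 0.55, 0.70)
  sg <- c(0.10, 0.12, 0.15, 0.17, 0.20)
  bins <- do.call(rbind, lapply(seq_along(th), function(i) {
    p <- binProbabilities(hTrue, al[i], b0[i], sg[i])$mixture
    data.frame(threshold = th[i], n0 = p[1], n1 = p[2], n2 = p[3],
               n3 = p[4], total = 1)
  }))
  fit <- fitPowerModel(bins, seed = 1)
  expect_lt(abs(fit@h - hTrue), 0.02)
  expect_lt(sum(fit@table$residual), 1e-6)
  expect_true(all(abs(fit@table$alpha - al) < 5e-3))
  expect_false(fit@underDetermined)
  # restarting the final fits from a different seed agrees
  fit2 <- fitPowerModel(bins, seed = 99)
  expect_lt(abs(fit@h - fit2@h), 0.02)
  expect_true(all(abs(fit@table$alpha - fit2@table$alpha) < 5e-3))
})

test_that("an all-negative screen is recovered as h near 0", {
  set.seed(84)
  n <- 20000
  z <- matrix(rnorm(3 * n), ncol = 3)
  gs <- data.frame(gene = sprintf("g%05d", 1:n), feature = "f",
                   z1 = z[, 1], z2 = z[, 2], z3 = z[, 3])
  bins <- binsFromScores(gs, c(1, 1.5, 2, 2.5))
  fit <- fitPowerModel(bins, seed = 1)
  expect_lte(fit@h, 0.02)
  for (i in seq_len(nrow(bins))) {
    emp <- mean(z > bins$threshold[i])
    expect_lt(abs(fit@table$alpha[i] - emp), 0.01)
  }
})

test_that("a single threshold is flagged under-determined", {
  p <- binProbabilities(0.2, 0.1, 0.4, 0.1)$mixture
  bins <- data.frame(threshold = 3, n0 = p[1], n1 = p[2], n2 = p[3],
                     n3 = p[4], total = 1)
  fit <- fitPowerModel(bins, hGrid = seq(0, 0.4, 0.1), seed = 1)
  expect_true(fit@underDetermined)
})

test_that("TP/FP curves clip bands and interpolate at a requested FP", {
  tab <- data.frame(threshold = 1:3, alpha = c(0.3, 0.1, 0.02),
                    beta0 = c(0.3, 0.5, 0.95), sigma = c(0.1, 0.1, 0.1),
                    residual = 0, converged = TRUE)
  fit <- new("PowerFit", h = 0.2, table = tab, converged = TRUE,
             underDetermined = FALSE, details = list())
  crv <- tpFpCurve(fit)
  expect_equal(crv$tp_mean[2], 0.5)
  expect_equal(crv$tp_lo[2], 0.4)
  expect_equal(crv$tp_hi[2], 0.6)
  expect_equal(crv$tp_hi[3], 0.15)  # clipped at 1 - 0.95 + 0.1
  crvF <- tpFpCurve(fit, fpTarget = 0.2)
  expect_equal(unname(attr(crvF, "atFP")["tp_mean"]), 0.6,
               tolerance = 1e-9)
  # sigma = 0 collapses the band onto the mean
  tab$sigma <- 0
  fit0 <- new("PowerFit", h = 0.2, table = tab, converged = TRUE,
              underDetermined = FALSE, details = list())
  crv0 <- tpFpCurve(fit0)
  expect_equal(crv0$tp_lo, crv0$tp_hi)
  expect_error(tpFpCurve(fit, fpTarget = 0.9), "outside")
})

test_that("score-level screen simulation matches its stated error rates", {
  gs <- simulateGeneScores(nGenes = 50000, h = 0.15, alpha = 0.05,
                           threshold = 3, beta0 = 0.4, sigma = 0.15,
                           seed = 7)
  tr <- attr(gs, "truth")
  z <- as.matrix(gs[, c("z1", "z2", "z3")])
  # negatives exceed threshold 3 at rate alpha
  fpEmp <- mean(z[!tr$is_hit, ] > 3)
  expect_lt(abs(fpEmp - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!tr$is_hit) / 3))
  # hit replicates fall below threshold at about their beta
  # a hit replicate misses when the gene fails to respond (prob beta) and
  # the null draw stays below threshold (prob 1 - alpha = 0.95)
  betaEmp <- mean(z[tr$is_hit, ] <= 3)
  expect_lt(abs(betaEmp - 0.95 * mean(tr$beta[tr$is_hit])), 0.02)
})
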