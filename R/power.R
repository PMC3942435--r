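# Cached 64-node Gauss-Legendre rule on [-1, 1].
.glCache <- new.env(parent = emptyenv())
.glRule <- function(n = 64L) {
  key <- as.character(n)
  if (is.null(.glCache[[key]]))
    .glCache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .glCache[[key]]
}

# E[(1 - beta)^k beta^(3 - k)] for k = 0..3 under a Gaussian for beta with
# mean beta0, sd sigma, truncated to [0, 1]. Quadrature in standardized
# z-space so narrow distributions are resolved; numerator and normalizer
# share nodes, so the four averages sum to exactly 1.
.betaBinMoments <- function(beta0, sigma, nNodes = 64L) {
  if (sigma < 1e-8) {
    b <- min(max(beta0, 0), 1)
    return(vapply(0:3, function(k) (1 - b)^k * b^(3 - k), 0))
  }
  lo <- max((0 - beta0) / sigma, -8)
  hi <- min((1 - beta0) / sigma, 8)
  if (lo >= hi) {  # support entirely outside [0, 1]: collapse to boundary
    b <- if (beta0 > 0.5) 1 else 0
    return(vapply(0:3, function(k) (1 - b)^k * b^(3 - k), 0))
  }
  gl <- .glRule(nNodes)
  zz <- (lo + hi) / 2 + (hi - lo) / 2 * gl$x
  ww <- (hi - lo) / 2 * gl$w * dnorm(zz)
  beta <- beta0 + sigma * zz
  om <- 1 - beta
  c(sum(ww * beta^3), sum(ww * om * beta^2), sum(ww * om^2 * beta),
    sum(ww * om^3)) / sum(ww)
}

#' Triplicate-bin probabilities under the screening mixture model
#'
#' The model behind power inference: a fraction `h` of genes are true
#' hits. At a fixed threshold, each hit gene has a gene-specific
#' false-negative rate \eqn{\beta} drawn from a Gaussian with mean
#' \eqn{\beta_0} and sd \eqn{\sigma} (truncated to \[0, 1\]), so the
#' probability that it lands above threshold in exactly k of 3 replicates
#' is \eqn{\binom{3}{k} \langle (1-\beta)^k \beta^{3-k} \rangle}, the
#' brackets denoting the average over the \eqn{\beta} distribution
#' (computed by 64-node Gauss-Legendre quadrature). Negatives exceed the
#' threshold independently with false-positive rate \eqn{\alpha}, giving
#' binomial bin probabilities. The observable bin fractions are the
#' h-weighted mixture.
#'
#' @param h hit fraction in \[0, 1\].
#' @param alpha false-positive rate in \[0, 1\].
#' @param beta0 mean false-negative rate in \[0, 1\].
#' @param sigma sd of the false-negative rate (>= 0).
#' @return list with numeric(4) components `hit`, `negative` and
#'   `mixture`: probabilities of appearing above threshold 0, 1, 2, 3
#'   times. Each component sums to 1.
#' @examples
#' binProbabilities(h = 1, alpha = 0, beta0 = 0.4, sigma = 0)$hit
#' # sigma = 0 reduces to binomial: P(3) = 0.6^3
#' @export
binProbabilities <- function(h, alpha, beta0, sigma) {
  if (h < 0 || h > 1 || alpha < 0 || alpha > 1 || beta0 < 0 || beta0 > 1 ||
      sigma < 0)
    .stop2("shapescreen_domain",
           "parameters out of domain: h, alpha, beta0 in [0,1], sigma >= 0")
  ch <- choose(3, 0:3)
  pHit <- ch * .betaBinMoments(beta0, sigma)
  pNeg <- ch * alpha^(0:3) * (1 - alpha)^(3:0)
  list(hit = pHit, negative = pNeg,
       mixture = h * pHit + (1 - h) * pNeg)
}

#' Count triplicate bins over a threshold grid
#'
#' For each threshold, counts how many genes have exactly 0, 1, 2 or 3
#' replicate Z-scores strictly above it. Genes with incomplete triplicates
#' are excluded (with a message).
#'
#' @param geneScores a [geneScoreTable()] `data.frame` (single feature).
#' @param thresholds numeric threshold grid.
#' @return `data.frame` with columns `threshold`, `n0`, `n1`, `n2`, `n3`,
#'   `total`.
#' @export
binsFromScores <- function(geneScores, thresholds) {
  z <- as.matrix(geneScores[, c("z1", "z2", "z3")])
  keep <- rowSums(!is.na(z)) == 3L
  if (any(!keep))
    message(sprintf("excluding %d gene(s) with incomplete triplicates",
                    sum(!keep)))
  z <- z[keep, , drop = FALSE]
  out <- lapply(thresholds, function(t) {
    k <- rowSums(z > t)
    cnt <- tabulate(k + 1L, nbins = 4L)
    data.frame(threshold = t, n0 = cnt[1], n1 = cnt[2], n2 = cnt[3],
               n3 = cnt[4], total = nrow(z))
  })
  do.call(rbind, out)
}

# Sum of squared errors between observed bin fractions and the model at one
# threshold, for fixed h.
.binSS <- function(par, h, frac) {
  p <- h * choose(3, 0:3) * .betaBinMoments(par[2], par[3]) +
    (1 - h) * choose(3, 0:3) * par[1]^(0:3) * (1 - par[1])^(3:0)
  sum((frac - p)^2)
}

# Fit (alpha, beta0, sigma) at one threshold for fixed h; multi-start
# bounded optimization, optionally warm-started. `factr` is the L-BFGS-B
# tolerance: loose during the h profile scan, tight for the final fits.
.fitThreshold <- function(frac, h, nStarts = 3L, warm = NULL,
                          factr = 1e4) {
  lower <- c(1e-8, 0, 0)
  upper <- c(1, 1, 0.6)
  # moment-based default start: per-replicate exceedance rate
  rate <- sum(frac * (0:3)) / 3
  starts <- list(c(min(rate, 0.99), 0.5, 0.15),
                 c(min(rate, 0.99), 0.3, 0.1),
                 c(max(rate / 2, 1e-4), 0.7, 0.2))
  if (!is.null(warm)) starts <- c(list(warm), starts)
  nExtra <- nStarts - length(starts)
  if (nExtra > 0)
    starts <- c(starts, lapply(seq_len(nExtra), function(i)
      c(runif(1, 1e-4, 0.5), runif(1), runif(1, 0, 0.4))))
  starts <- starts[seq_len(min(max(nStarts, 1L), length(starts)))]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, .binSS, h = h, frac = frac, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = factr, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  best
}

#' Fit the triplicate mixture model jointly across thresholds
#'
#' Least-squares fit of the [binProbabilities()] model to observed
#' triplicate bin fractions: the hit fraction `h` is shared across all
#' thresholds while \eqn{(\alpha, \beta_0, \sigma)} are fitted per
#' threshold. At any single threshold four normalized bins carry three
#' degrees of freedom against four unknowns; sharing `h` across thresholds
#' makes the system "almost" determined, and the fit is performed by
#' profiling: for each candidate `h` on a grid the per-threshold
#' parameters are optimized (bounded L-BFGS-B, warm-started along the
#' profile), the total residual is minimized over `h` by golden-section
#' refinement, and the final per-threshold fits are re-run with `nStarts`
#' seeded restarts.
#'
#' @param bins a [binsFromScores()] `data.frame`.
#' @param hGrid candidate grid for the profile over `h`.
#' @param nStarts restarts for the final per-threshold fits (default 10).
#' @param seed seed for the random restarts.
#' @return a [PowerFit-class]; `underDetermined` is `TRUE` when only one
#'   threshold is supplied, and `converged` is `FALSE` when any
#'   per-threshold optimizer failed.
#' @export
fitPowerModel <- function(bins, hGrid = seq(0, 0.6, by = 0.04),
                          nStarts = 10L, seed = 1L) {
  set.seed(seed)
  fracs <- lapply(seq_len(nrow(bins)), function(i)
    as.numeric(bins[i, c("n0", "n1", "n2", "n3")]) / bins$total[i])
  nT <- length(fracs)

  # warm starts persist across profile evaluations: solutions move smoothly
  # with h, so one warm-started refinement per threshold suffices after the
  # first (multi-start) evaluation.
  warmEnv <- new.env(parent = emptyenv())
  warmEnv$w <- NULL
  profile <- function(h, factr = 1e5) {
    fits <- vector("list", nT)
    for (i in seq_len(nT))
      fits[[i]] <- .fitThreshold(fracs[[i]], h, nStarts = 3L,
                                 warm = warmEnv$w[[i]], factr = factr)
    warmEnv$w <- lapply(fits, function(f) if (is.null(f)) NULL else f$par)
    list(ss = sum(vapply(fits, function(f)
      if (is.null(f)) Inf else f$value, 0)), fits = fits)
  }

  ssGrid <- vapply(hGrid, function(h) profile(h)$ss, 0)
  # Parsimony tie-break: in the flat direction of the model (e.g. a null
  # screen, where any h fits the bins with beta = 1 - alpha) least squares
  # alone does not pin h down; among h whose profiled residual is within a
  # factor of 2 of the minimum, the smallest is taken.
  minSS <- min(ssGrid)
  tied <- which(ssGrid <= 2 * minSS + 1e-12)
  iBest <- tied[1]
  hHat <- if (length(tied) > 2L) {
    hGrid[iBest]
  } else {
    lo <- hGrid[max(1L, iBest - 1L)]
    hi <- hGrid[min(length(hGrid), iBest + 1L)]
    if (lo < hi) {
      opt <- optimize(function(h) profile(h)$ss, c(lo, hi), tol = 1e-4)
      if (opt$objective <= ssGrid[iBest]) opt$minimum else hGrid[iBest]
    } else hGrid[iBest]
  }

  final <- vector("list", nT)
  for (i in seq_len(nT))
    final[[i]] <- .fitThreshold(fracs[[i]], hHat, nStarts = nStarts)
  ok <- !vapply(final, is.null, TRUE)
  tab <- data.frame(
    threshold = bins$threshold,
    alpha = vapply(final, function(f) if (is.null(f)) NA_real_ else
      f$par[1], 0),
    beta0 = vapply(final, function(f) if (is.null(f)) NA_real_ else
      f$par[2], 0),
    sigma = vapply(final, function(f) if (is.null(f)) NA_real_ else
      f$par[3], 0),
    residual = vapply(final, function(f) if (is.null(f)) NA_real_ else
      f$value, 0),
    converged = ok & vapply(final, function(f) if (is.null(f)) FALSE else
      f$convergence == 0 || f$value < 1e-9, TRUE))
  .PowerFit(h = hHat, table = tab, converged = all(tab$converged),
            underDetermined = nT < 2L,
            details = list(hGrid = hGrid, ssGrid = ssGrid))
}

#' True-positive / false-positive curves from a power fit
#'
#' Per threshold: FP rate \eqn{\alpha}, mean TP rate \eqn{1 - \beta_0} and
#' the TP band \eqn{1 - \beta_0 \pm \sigma} clipped to \[0, 1\]. When
#' `fpTarget` is given, the TP values at that FP rate are obtained by
#' linear interpolation along the fitted \eqn{\alpha(t)} curve.
#'
#' @param fit a [PowerFit-class].
#' @param fpTarget optional FP rate at which to evaluate the TP band.
#' @return `data.frame` with columns `threshold`, `fp`, `tp_mean`,
#'   `tp_lo`, `tp_hi`; if `fpTarget` is given, attribute `"atFP"` holds
#'   the interpolated `tp_mean`, `tp_lo`, `tp_hi` at that FP rate.
#' @export
tpFpCurve <- function(fit, fpTarget = NULL) {
  tab <- fit@table
  clip <- function(x) pmin(pmax(x, 0), 1)
  out <- data.frame(threshold = tab$threshold, fp = tab$alpha,
                    tp_mean = clip(1 - tab$beta0),
                    tp_lo = clip(1 - tab$beta0 - tab$sigma),
                    tp_hi = clip(1 - tab$beta0 + tab$sigma))
  if (!is.null(fpTarget)) {
    ok <- is.finite(out$fp)
    o <- out[ok, ][order(out$fp[ok]), ]
    if (fpTarget < min(o$fp) || fpTarget > max(o$fp))
      stop(sprintf("requested FP %.3g outside fitted range [%.3g, %.3g]",
                   fpTarget, min(o$fp), max(o$fp)))
    atFP <- c(tp_mean = approx(o$fp, o$tp_mean, xout = fpTarget,
                               ties = mean)$y,
              tp_lo = approx(o$fp, o$tp_lo, xout = fpTarget,
                             ties = mean)$y,
              tp_hi = approx(o$fp, o$tp_hi, xout = fpTarget,
                             ties = mean)$y)
    attr(out, "atFP") <- atFP
  }
  out
}
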