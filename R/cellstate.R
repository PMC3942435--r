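#' Classifier/output correlation score for one well
#'
#' Sorts a well's cells into three classifier percentile bins (A: 5-15%,
#' B: 45-55%, C: 85-95%), computes the mean output value in each bin
#' (\eqn{m_A, m_B, m_C}) and the correlation score
#' \eqn{y = (m_A - m_B)/(m_B - m_C)}. A feature is a good classifier
#' candidate for a perturbation when it is itself unaffected; an output
#' responds state-dependently when the binned populations respond
#' differentially, which shows up as a shifted y in perturbed wells.
#'
#' @param classifier,output numeric per-cell values (same length).
#' @param minCells minimum cells for a valid score (default 30).
#' @param guard the score is invalid when \eqn{|m_B - m_C|} is below
#'   `guard * sd(output)` (default guard 1e-6), protecting against
#'   division by near-zero.
#' @param probs the six percentile edges of bins A, B, C.
#' @return list with `mA`, `mB`, `mC`, `y`, `valid`, `nA`, `nB`, `nC`.
#' @examples
#' x <- runif(1000)
#' classifierScore(x, x)$y  # output == classifier: y near 1
#' @export
classifierScore <- function(classifier, output, minCells = 30L,
                            guard = 1e-6,
                            probs = c(0.05, 0.15, 0.45, 0.55, 0.85,
                                      0.95)) {
  stopifnot(length(classifier) == length(output))
  n <- length(classifier)
  q <- quantile(classifier, probs, names = FALSE, type = 7)
  inBin <- function(lo, hi) classifier >= lo & classifier <= hi
  A <- inBin(q[1], q[2]); B <- inBin(q[3], q[4]); C <- inBin(q[5], q[6])
  mA <- if (any(A)) mean(output[A]) else NA_real_
  mB <- if (any(B)) mean(output[B]) else NA_real_
  mC <- if (any(C)) mean(output[C]) else NA_real_
  denomOk <- !is.na(mB) && !is.na(mC) &&
    abs(mB - mC) > guard * max(sd(output), .Machine$double.eps)
  valid <- n >= minCells && any(A) && any(B) && any(C) && denomOk
  y <- if (valid) (mA - mB) / (mB - mC) else NA_real_
  list(mA = mA, mB = mB, mC = mC, y = y, valid = valid,
       nA = sum(A), nB = sum(B), nC = sum(C))
}

#' Delta-y matrix over candidate classifier/output feature pairs
#'
#' For every (classifier i, output j) pair, computes the per-well
#' correlation score y (percentiles taken within each well) for all
#' positive- and negative-control wells, and reports
#' \eqn{\Delta y_{ij}} = median y over positive wells minus median y over
#' negative wells. A near-zero diagonal entry \eqn{\Delta y_{ii}} flags
#' feature i as unaffected (a classifier candidate); a large off-diagonal
#' magnitude flags a state-dependent output. Cells with fewer than
#' `minWells` valid wells on either side are masked (`NA`). When
#' `nPerm > 0`, control-well labels are shuffled to obtain the
#' permutation 95th percentile of each entry's magnitude.
#'
#' @param screen a [ScreenExperiment-class].
#' @param classifiers,outputs feature names (defaults: all features).
#' @param minWells minimum valid wells per group (default 3).
#' @param nPerm permutations for the null magnitude (default 0: none).
#' @param seed RNG seed for permutations.
#' @param ... passed to [classifierScore()].
#' @return a [DeltaYMatrix-class].
#' @export
deltaYMatrix <- function(screen, classifiers = NULL, outputs = NULL,
                         minWells = 3L, nPerm = 0L, seed = 1L, ...) {
  if (is.null(classifiers)) classifiers <- rownames(screen)
  if (is.null(outputs)) outputs <- rownames(screen)
  lay <- screenLayout(screen)
  ctrl <- lay[lay$role %in% c("positive", "negative"), , drop = FALSE]
  nW <- nrow(ctrl)
  feats <- unique(c(classifiers, outputs))
  wellData <- vector("list", nW)
  for (w in seq_len(nW))
    wellData[[w]] <- lapply(stats::setNames(feats, feats), function(f)
      wellValues(screen, ctrl$slide_id[w], ctrl$well_id[w], f))
  yArr <- array(NA_real_, dim = c(nW, length(classifiers),
                                  length(outputs)),
                dimnames = list(NULL, classifiers, outputs))
  for (w in seq_len(nW))
    for (ci in classifiers)
      for (oj in outputs) {
        sc <- classifierScore(wellData[[w]][[ci]], wellData[[w]][[oj]],
                              ...)
        if (sc$valid) yArr[w, ci, oj] <- sc$y
      }
  isPos <- ctrl$role == "positive"
  summarize <- function(pos) {
    delta <- nP <- nN <- matrix(NA_real_,
                                length(classifiers), length(outputs),
                                dimnames = list(classifiers, outputs))
    for (ci in classifiers)
      for (oj in outputs) {
        yp <- yArr[pos, ci, oj]; yn <- yArr[!pos, ci, oj]
        yp <- yp[!is.na(yp)]; yn <- yn[!is.na(yn)]
        nP[ci, oj] <- length(yp); nN[ci, oj] <- length(yn)
        if (length(yp) >= minWells && length(yn) >= minWells)
          delta[ci, oj] <- median(yp) - median(yn)
      }
    list(delta = delta, nP = nP, nN = nN)
  }
  obs <- summarize(isPos)
  permQ <- NULL
  if (nPerm > 0L) {
    set.seed(seed)
    mags <- array(NA_real_, dim = c(nPerm, length(classifiers),
                                    length(outputs)))
    for (p in seq_len(nPerm))
      mags[p, , ] <- abs(summarize(sample(isPos))$delta)
    permQ <- apply(mags, c(2L, 3L), function(v)
      if (all(is.na(v))) NA_real_ else
        quantile(v, 0.95, na.rm = TRUE, names = FALSE))
    dimnames(permQ) <- list(classifiers, outputs)
  }
  .DeltaYMatrix(delta = obs$delta, nPos = obs$nP, nNeg = obs$nN,
                permQuantile = permQ, nPerm = as.integer(nPerm))
}

#' Binned response curves: mean output per classifier percentile bin
#'
#' Pools cells from perturbed and unperturbed wells, splits each pool into
#' `nBins` classifier percentile bins (quintiles by default, edges from
#' the combined pool so both pools share bins), and reports the mean
#' output per bin for each pool together with the perturbed-minus-control
#' difference, which quantifies how strongly the response depends on cell
#' state. `nBins = 1` reduces to the pooled mean difference.
#'
#' @param classifierCtrl,outputCtrl per-cell values, unperturbed pool.
#' @param classifierPert,outputPert per-cell values, perturbed pool.
#' @param nBins number of percentile bins (default 5).
#' @return `data.frame` with columns `bin`, `lo`, `hi` (classifier edge
#'   values), `n_ctrl`, `n_pert`, `mean_ctrl`, `mean_pert`, `diff`
#'   (`NA`-masked for empty bins).
#' @export
binnedResponse <- function(classifierCtrl, outputCtrl, classifierPert,
                           outputPert, nBins = 5L) {
  stopifnot(length(classifierCtrl) == length(outputCtrl),
            length(classifierPert) == length(outputPert),
            length(classifierCtrl) > 0L, length(classifierPert) > 0L)
  edges <- quantile(c(classifierCtrl, classifierPert),
                    probs = seq(0, 1, length.out = nBins + 1L),
                    names = FALSE, type = 7)
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  bC <- cut(classifierCtrl, edges, labels = FALSE,
            include.lowest = TRUE)
  bP <- cut(classifierPert, edges, labels = FALSE,
            include.lowest = TRUE)
  out <- lapply(seq_len(nBins), function(b) {
    iC <- bC == b; iP <- bP == b
    mc <- if (any(iC)) mean(outputCtrl[iC]) else NA_real_
    mp <- if (any(iP)) mean(outputPert[iP]) else NA_real_
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1L],
               n_ctrl = sum(iC), n_pert = sum(iP), mean_ctrl = mc,
               mean_pert = mp, diff = mp - mc)
  })
  do.call(rbind, out)
}
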