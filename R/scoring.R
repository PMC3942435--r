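#' Shape-based Z-scores for one slide and feature
#'
#' The central scoring procedure. Every well on the slide is preprocessed
#' according to `mode` (N: normalized to zero mean and unit variance; P:
#' partially normalized to the average mean and variance of its eight
#' nearest neighbors; U: raw). For each designated negative-control well
#' the scaled KS statistic \eqn{D^*} against all wells is computed, giving
#' one row per negative; each row is standardized to zero mean and unit
#' variance. A preliminary Z-score per well is the column mean over all
#' negative rows; the `holdout` negatives with the highest preliminary Z
#' (the "worst-scoring" negatives) are then removed, and the final Z-score
#' of every well is the column mean over the retained rows. The held-out
#' negatives never enter the final matrix, so their own Z-scores provide an
#' unbiased estimate of the false-positive rate (see [fpRateHeldout()]).
#'
#' In mode N the Z-scores are invariant to per-well affine artifacts
#' (\eqn{v \mapsto a v + b}, \eqn{a > 0}); in mode U they are not.
#'
#' @param screen a [ScreenExperiment-class].
#' @param slide slide identifier.
#' @param feature feature name.
#' @param mode `"N"`, `"P"` or `"U"`.
#' @param nNegatives number of negative wells to use (default: all
#'   negatives on the slide; the study design has 30).
#' @param holdout number of worst-scoring negatives to hold out
#'   (default 10).
#' @param excludeSelf if `TRUE`, a negative's \eqn{D^*} against itself is
#'   dropped from its row before standardization; by default the self
#'   comparison (which is 0) is retained, since the row is standardized
#'   anyway.
#' @return a [SlideScores-class].
#' @seealso [traditionalZscore()], [scoreScreen()], [scoresTable()]
#' @export
scoreSlide <- function(screen, slide, feature, mode = c("N", "P", "U"),
                       nNegatives = NULL, holdout = 10L,
                       excludeSelf = FALSE) {
  mode <- match.arg(mode)
  lay <- screenLayout(screen)
  lay <- lay[lay$slide_id == slide, , drop = FALSE]
  if (!nrow(lay)) stop(sprintf("slide '%s' not found", slide))
  wells <- .slideWellValues(screen, slide, feature)

  excluded <- names(wells)[vapply(wells, function(v)
    length(v) < 2L || .popSd(v) == 0, TRUE)]
  if (length(excluded))
    message(sprintf("slide %s, feature %s: excluding %d degenerate well(s)",
                    slide, feature, length(excluded)))
  keep <- setdiff(names(wells), excluded)

  prep <- switch(mode,
    N = lapply(wells[keep], normalizeDistribution),
    U = wells[keep],
    P = {
      pos <- lay[, c("well_id", "row", "col")]
      stats::setNames(lapply(keep, function(w)
        partialNormalize(wells, pos, w)), keep)
    })
  prepSorted <- lapply(prep, sort)
  nCells <- vapply(prep, length, 1L)

  negs <- intersect(lay$well_id[lay$role == "negative"], keep)
  if (!is.null(nNegatives)) {
    if (length(negs) < nNegatives)
      stop(sprintf("slide has %d usable negatives, %d requested",
                   length(negs), nNegatives))
    negs <- negs[seq_len(nNegatives)]
  }
  holdout <- as.integer(holdout)
  if (length(negs) < holdout + 2L)
    stop(sprintf("need at least holdout + 2 = %d negatives, have %d",
                 holdout + 2L, length(negs)))

  nw <- length(keep)
  mat <- matrix(NA_real_, nrow = length(negs), ncol = nw,
                dimnames = list(negs, keep))
  for (ng in negs) {
    a <- prepSorted[[ng]]
    ne <- nCells[ng] * nCells / (nCells[ng] + nCells)
    row <- vapply(seq_len(nw), function(j)
      .ksD(a, prepSorted[[j]]), 0) * sqrt(ne)
    if (excludeSelf) row[ng] <- NA
    mu <- mean(row, na.rm = TRUE)
    s <- sqrt(mean((row[!is.na(row)] - mu)^2))
    mat[ng, ] <- (row - mu) / s
  }
  prelimZ <- colMeans(mat, na.rm = TRUE)
  heldOut <- negs[order(prelimZ[negs], decreasing = TRUE)][seq_len(holdout)]
  retained <- mat[setdiff(negs, heldOut), , drop = FALSE]
  z <- colMeans(retained, na.rm = TRUE)

  zAll <- stats::setNames(rep(NA_real_, nrow(lay)), lay$well_id)
  zAll[names(z)] <- z
  .SlideScores(slideId = slide, feature = feature, mode = mode,
               wellIds = lay$well_id, gene = as.character(lay$gene),
               role = as.character(lay$role),
               replicate = as.integer(lay$replicate), z = zAll,
               heldOut = heldOut, excluded = excluded,
               scoreMatrix = retained)
}

#' Traditional mean-based Z-score for one slide and feature
#'
#' The comparator score that uses only the population-averaged signal: the
#' signal \eqn{s_i} of a well is its mean feature value, and the score is
#' the squared difference between \eqn{s_i} and the slide-average signal,
#' normalized by the (population) variance of all signals:
#' \eqn{(s_i - \bar s)^2 / \mathrm{Var}(s)}.
#'
#' @inheritParams scoreSlide
#' @return a [SlideScores-class] with `mode = "traditional"` (no score
#'   matrix, no held-out wells).
#' @export
traditionalZscore <- function(screen, slide, feature) {
  lay <- screenLayout(screen)
  lay <- lay[lay$slide_id == slide, , drop = FALSE]
  if (!nrow(lay)) stop(sprintf("slide '%s' not found", slide))
  wells <- .slideWellValues(screen, slide, feature)
  s <- vapply(wells, mean, 0)
  v <- mean((s - mean(s))^2)
  if (v == 0)
    .stop2("shapescreen_degenerate",
           "all well means identical: signal variance is 0")
  z <- (s - mean(s))^2 / v
  .SlideScores(slideId = slide, feature = feature, mode = "traditional",
               wellIds = lay$well_id, gene = as.character(lay$gene),
               role = as.character(lay$role),
               replicate = as.integer(lay$replicate),
               z = stats::setNames(z[lay$well_id], lay$well_id),
               heldOut = character(), excluded = character(),
               scoreMatrix = NULL)
}

#' Score every slide of a screen
#'
#' @inheritParams scoreSlide
#' @param features feature names (default: all features).
#' @param mode `"N"`, `"P"`, `"U"` or `"traditional"`.
#' @param ... passed to [scoreSlide()].
#' @return list of [SlideScores-class], one per slide x feature.
#' @export
scoreScreen <- function(screen, features = NULL, mode = "N", ...) {
  if (is.null(features)) features <- rownames(screen)
  out <- list()
  for (s in slideIds(screen)) {
    for (f in features) {
      sc <- if (mode == "traditional") traditionalZscore(screen, s, f)
            else scoreSlide(screen, s, f, mode = mode, ...)
      out[[paste(s, f, sep = ".")]] <- sc
    }
  }
  out
}

#' Tidy table of per-well scores
#'
#' @param scores a [SlideScores-class] or list of them.
#' @return `data.frame` with columns `slide_id`, `well_id`, `gene`, `role`,
#'   `replicate`, `feature`, `mode`, `z`, `held_out`.
#' @export
scoresTable <- function(scores) {
  if (is(scores, "SlideScores")) scores <- list(scores)
  do.call(rbind, lapply(scores, function(x)
    data.frame(slide_id = x@slideId, well_id = x@wellIds, gene = x@gene,
               role = x@role, replicate = x@replicate, feature = x@feature,
               mode = x@mode, z = unname(x@z),
               held_out = x@wellIds %in% x@heldOut, row.names = NULL)))
}
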