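#' Construct a ScreenExperiment from tidy per-cell tables
#'
#' @param cellData `data.frame` with columns `slide_id`, `well_id`,
#'   `cell_id` and one numeric column per feature.
#' @param layout `data.frame` with columns `slide_id`, `well_id`, `row`,
#'   `col`, `gene`, `role`, `replicate`.
#' @param featureFamily named character vector mapping every feature to
#'   `"intensity"` or `"geometry"`. Defaults to `"intensity"` for all.
#' @param truth optional per-gene ground-truth `data.frame` (simulations).
#' @return A [ScreenExperiment-class] object.
#' @examples
#' cells <- data.frame(slide_id = "S1", well_id = rep(c("A", "B"), each = 5),
#'                     cell_id = rep(1:5, 2), f1 = rnorm(10))
#' lay <- data.frame(slide_id = "S1", well_id = c("A", "B"), row = 1,
#'                   col = 1:2, gene = c("neg", "g1"),
#'                   role = c("negative", "test"), replicate = 1L)
#' se <- ScreenExperiment(cells, lay)
#' @export
ScreenExperiment <- function(cellData, layout, featureFamily = NULL,
                             truth = NULL) {
  stopifnot(is.data.frame(cellData), is.data.frame(layout))
  meta <- c("slide_id", "well_id", "cell_id")
  if (!all(meta %in% colnames(cellData)))
    stop("cellData must contain columns slide_id, well_id, cell_id")
  feats <- setdiff(colnames(cellData), meta)
  if (!length(feats)) stop("cellData has no feature columns")
  for (f in feats) {
    if (!is.numeric(cellData[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(cellData[[f]]))) &
                     !is.na(cellData[[f]]))
      stop(sprintf("feature '%s' is non-numeric (first offending row: %d)",
                   f, if (length(bad)) bad[1] else 1L))
    }
  }
  if (is.null(featureFamily))
    featureFamily <- stats::setNames(rep("intensity", length(feats)), feats)
  assay <- t(as.matrix(cellData[, feats, drop = FALSE]))
  rownames(assay) <- feats
  cd <- S4Vectors::DataFrame(slide_id = as.character(cellData$slide_id),
                             well_id = as.character(cellData$well_id),
                             cell_id = cellData$cell_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), colData = cd)
  layout$slide_id <- as.character(layout$slide_id)
  layout$well_id <- as.character(layout$well_id)
  .ScreenExperiment(se, layout = as.data.frame(layout), truth = truth,
                    featureFamily = featureFamily)
}

#' Per-cell feature table of a screen
#'
#' @param x a [ScreenExperiment-class].
#' @param ... unused.
#' @return tidy `data.frame`: `slide_id`, `well_id`, `cell_id`, features.
#' @export
setMethod("cellTable", "ScreenExperiment", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  cbind(data.frame(slide_id = cd$slide_id, well_id = cd$well_id,
                   cell_id = cd$cell_id),
        as.data.frame(t(SummarizedExperiment::assay(x, "features"))),
        row.names = NULL)
})

#' Slide layout of a screen
#'
#' @param x a [ScreenExperiment-class].
#' @param ... unused.
#' @return `data.frame` with one row per well.
#' @export
setMethod("screenLayout", "ScreenExperiment", function(x, ...) x@layout)

#' Simulation ground truth of a screen
#'
#' @param x a [ScreenExperiment-class].
#' @param ... unused.
#' @return per-gene `data.frame` or `NULL` for real data.
#' @export
setMethod("truthTable", "ScreenExperiment", function(x, ...) x@truth)

#' Feature family (intensity vs geometry) of each feature
#'
#' @param x a [ScreenExperiment-class].
#' @param ... unused.
#' @return named character vector.
#' @export
setMethod("featureFamily", "ScreenExperiment", function(x, ...)
  x@featureFamily)

setMethod("show", "ScreenExperiment", function(object) {
  lay <- object@layout
  cat("ScreenExperiment:", ncol(object), "cells,", nrow(object),
      "features\n")
  cat("  slides:", length(unique(lay$slide_id)), " wells:", nrow(lay), "\n")
  cat("  roles: ", paste(sprintf("%s=%d", names(table(lay$role)),
                                 table(lay$role)), collapse = ", "), "\n")
  cat("  families:", paste(sprintf("%s=%d", names(table(object@featureFamily)),
                                   table(object@featureFamily)),
                           collapse = ", "), "\n")
  if (!is.null(object@truth))
    cat("  truth:", sum(object@truth$is_hit), "of", nrow(object@truth),
        "genes are hits\n")
  invisible(NULL)
})

#' Slide identifiers of a screen
#' @param x a [ScreenExperiment-class].
#' @return character vector of slide ids (layout order).
#' @export
slideIds <- function(x) unique(x@layout$slide_id)

#' Values of one feature in one well
#'
#' @param x a [ScreenExperiment-class].
#' @param slide,well slide and well identifiers.
#' @param feature feature name.
#' @return numeric vector of per-cell values.
#' @export
wellValues <- function(x, slide, well, feature) {
  cd <- SummarizedExperiment::colData(x)
  sel <- cd$slide_id == slide & cd$well_id == well
  unname(SummarizedExperiment::assay(x, "features")[feature, sel])
}

# Per-well value lists for one slide/feature, in layout order.
.slideWellValues <- function(x, slide, feature) {
  cd <- SummarizedExperiment::colData(x)
  sel <- which(cd$slide_id == slide)
  if (!length(sel)) stop(sprintf("slide '%s' not found", slide))
  v <- SummarizedExperiment::assay(x, "features")[feature, sel]
  byWell <- split(unname(v), cd$well_id[sel])
  lay <- x@layout[x@layout$slide_id == slide, , drop = FALSE]
  byWell[lay$well_id]
}

setMethod("show", "KSResult", function(object) {
  cat(sprintf("KSResult: D = %.6g (n1 = %d, n2 = %d), Ne = %.4g, D* = %.6g\n",
              object@d, object@n1, object@n2, object@nEffective,
              object@dStar))
  invisible(NULL)
})

#' Per-well Z-scores of a SlideScores object
#' @param x a [SlideScores-class].
#' @param ... unused.
#' @return named numeric vector.
#' @export
setMethod("zScores", "SlideScores", function(x, ...) x@z)

#' Held-out negative wells of a SlideScores object
#' @param x a [SlideScores-class].
#' @param ... unused.
#' @return character vector of well ids.
#' @export
setMethod("heldOutWells", "SlideScores", function(x, ...) x@heldOut)

setMethod("show", "SlideScores", function(object) {
  cat(sprintf("SlideScores: slide %s, feature %s, mode %s\n",
              object@slideId, object@feature, object@mode))
  cat(sprintf("  %d wells, %d held-out negatives, %d excluded\n",
              length(object@z), length(object@heldOut),
              length(object@excluded)))
  cat(sprintf("  Z range: [%.3g, %.3g]\n", min(object@z, na.rm = TRUE),
              max(object@z, na.rm = TRUE)))
  invisible(NULL)
})

setMethod("show", "PermutationBand", function(object) {
  cat(sprintf("PermutationBand (%s): %d thresholds, %d permutations\n",
              object@feature, length(object@thresholds), object@nPerm))
  out <- sum(object@observed > object@maxCount)
  cat(sprintf("  observed exceeds band max at %d threshold(s)\n", out))
  invisible(NULL)
})

setMethod("show", "PowerFit", function(object) {
  cat(sprintf("PowerFit: h = %.4f (%s%s)\n", object@h,
              if (object@converged) "converged" else "NOT converged",
              if (object@underDetermined) ", under-determined" else ""))
  t3 <- object@table[which.min(abs(object@table$threshold - 3)), ]
  cat(sprintf("  near threshold %.2g: alpha = %.4f, beta0 = %.4f, sigma = %.4f\n",
              t3$threshold, t3$alpha, t3$beta0, t3$sigma))
  invisible(NULL)
})

setMethod("show", "DeltaYMatrix", function(object) {
  cat(sprintf("DeltaYMatrix: %d classifiers x %d outputs (%d permutations)\n",
              nrow(object@delta), ncol(object@delta), object@nPerm))
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d slide design(s) x %d replicates, %dx%d wells\n",
              object@nSlides, object@nReplicates, object@rows, object@cols))
  cat(sprintf("  %d negatives, %d positives, %d-%d cells/well, %d features\n",
              object@nNegative, object@nPositive, object@cellsPerWell[1],
              object@cellsPerWell[2], length(object@features)))
  cat(sprintf("  hit fraction %.3g, penetrance %.2g +/- %.2g, seed %d\n",
              object@hitFraction, object@penetranceMean,
              object@penetranceSd, object@seed))
  invisible(NULL)
})

# Small helpers shared across modules ---------------------------------------

.popSd <- function(v) sqrt(mean((v - mean(v))^2))

.stop2 <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
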