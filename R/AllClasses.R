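#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats anova aov approx dnorm lm median optim optimize phyper
#'   pnorm qnorm quantile rbinom rgamma rlnorm rnorm rpois runif sd var
#' @importFrom utils read.delim write.table packageVersion
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ScreenExperiment: single-cell feature data for a perturbation screen
#'
#' Container for the per-cell feature measurements of a plate-based
#' perturbation screen. Extends
#' [SummarizedExperiment::SummarizedExperiment-class]: the `"features"`
#' assay holds one row per feature and one column per cell, and `colData`
#' carries the `slide_id`, `well_id` and `cell_id` of every cell. The slide
#' layout (well positions, gene targets, roles, replicate indices) lives in
#' the `layout` slot; simulated screens additionally carry a per-gene
#' ground-truth table in `truth`.
#'
#' @slot layout `data.frame` with columns `slide_id`, `well_id`, `row`,
#'   `col`, `gene`, `role` (one of `"negative"`, `"positive"`, `"test"`)
#'   and `replicate`; one row per well.
#' @slot truth `data.frame` or `NULL`; for simulated screens, columns
#'   `gene`, `is_hit`, `penetrance`, `affected_features`.
#' @slot featureFamily named `character`; for every feature either
#'   `"intensity"` (continuous, artifact-prone) or `"geometry"`
#'   (narrow/discrete, artifact-free).
#'
#' @seealso [ScreenExperiment()] (constructor), [generateScreen()],
#'   [readScreen()], [cellTable()], [screenLayout()], [truthTable()]
#' @exportClass ScreenExperiment
.ScreenExperiment <- setClass("ScreenExperiment",
  contains = "SummarizedExperiment",
  slots = c(
    layout = "data.frame",
    truth = "data.frameOrNULL",
    featureFamily = "character"
  )
)

setValidity("ScreenExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  need <- c("slide_id", "well_id", "cell_id")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  lay <- object@layout
  needL <- c("slide_id", "well_id", "row", "col", "gene", "role", "replicate")
  if (!all(needL %in% colnames(lay)))
    msg <- c(msg, paste("layout must contain", paste(needL, collapse = ", ")))
  if (!length(msg)) {
    keyL <- paste(lay$slide_id, lay$well_id)
    if (anyDuplicated(keyL))
      msg <- c(msg, "layout has duplicated (slide_id, well_id) rows")
    keyC <- unique(paste(cd$slide_id, cd$well_id))
    miss <- setdiff(keyC, keyL)
    if (length(miss))
      msg <- c(msg, paste0("wells present in cell data but absent from ",
                           "layout: ", paste(utils::head(miss, 3),
                                             collapse = ", ")))
    bad <- setdiff(unique(lay$role), c("negative", "positive", "test"))
    if (length(bad))
      msg <- c(msg, paste("unknown roles in layout:",
                          paste(bad, collapse = ", ")))
    fam <- object@featureFamily
    feats <- rownames(object)
    if (!all(feats %in% names(fam)))
      msg <- c(msg, "featureFamily must name every feature (assay row)")
    if (!all(fam %in% c("intensity", "geometry")))
      msg <- c(msg, "featureFamily values must be 'intensity' or 'geometry'")
  }
  if (length(msg)) msg else TRUE
})

#' Two-sample Kolmogorov-Smirnov result with effective-size scaling
#'
#' Holds the two-sample KS distance `d` (sup over pooled evaluation points
#' of the absolute ECDF difference), the sample sizes, the effective sample
#' size \eqn{N_e} with \eqn{1/N_e = 1/N_1 + 1/N_2}, and the scaled statistic
#' \eqn{D^* = \sqrt{N_e}\,D} used throughout the shape-scoring machinery.
#'
#' @slot d KS distance in \[0, 1\].
#' @slot n1,n2 sample sizes.
#' @slot nEffective effective sample size \eqn{N_1 N_2 / (N_1 + N_2)}.
#' @slot dStar scaled statistic \eqn{\sqrt{N_e} D}.
#' @seealso [ksStatistic()]
#' @exportClass KSResult
.KSResult <- setClass("KSResult",
  slots = c(d = "numeric", n1 = "numeric", n2 = "numeric",
            nEffective = "numeric", dStar = "numeric"))

setValidity("KSResult", function(object) {
  if (object@d < -1e-12 || object@d > 1 + 1e-12)
    return("d must lie in [0, 1]")
  TRUE
})

#' Per-well shape (or traditional) Z-scores for one slide and feature
#'
#' Result of [scoreSlide()] or [traditionalZscore()]: the per-well score
#' vector, the retained-negatives-by-wells standardized \eqn{D^*} matrix the
#' Z-scores are column means of, and the identities of the held-out
#' (worst-scoring) negative wells reserved for false-positive estimation.
#'
#' @slot slideId slide identifier.
#' @slot feature feature name.
#' @slot mode `"N"` (normalized), `"P"` (partial), `"U"` (un-normalized) or
#'   `"traditional"`.
#' @slot wellIds,gene,role,replicate per-well metadata in slide order.
#' @slot z per-well score vector (named by well).
#' @slot heldOut well ids of the held-out negatives.
#' @slot excluded well ids excluded as degenerate (constant feature).
#' @slot scoreMatrix retained-negatives x wells matrix of row-standardized
#'   \eqn{D^*} values (`NULL` for traditional scores).
#' @seealso [scoreSlide()], [traditionalZscore()], [scoresTable()]
#' @exportClass SlideScores
.SlideScores <- setClass("SlideScores",
  slots = c(slideId = "character", feature = "character", mode = "character",
            wellIds = "character", gene = "character", role = "character",
            replicate = "integer", z = "numeric", heldOut = "character",
            excluded = "character", scoreMatrix = "matrixOrNULL"))

setValidity("SlideScores", function(object) {
  n <- length(object@wellIds)
  if (length(object@z) != n || length(object@gene) != n ||
      length(object@role) != n)
    return("per-well slots must have equal length")
  TRUE
})

#' Permutation null band for triplicate hit counts
#'
#' For a grid of Z-score thresholds, the minimum and maximum number of genes
#' called by the 2-of-3 rule over label-permuted score tables, together with
#' the observed counts.
#'
#' @slot thresholds threshold grid.
#' @slot minCount,maxCount per-threshold band limits over permutations.
#' @slot observed per-threshold observed hit counts.
#' @slot nPerm number of permutations.
#' @slot feature feature the band was computed for.
#' @seealso [permutationBand()]
#' @exportClass PermutationBand
.PermutationBand <- setClass("PermutationBand",
  slots = c(thresholds = "numeric", minCount = "numeric",
            maxCount = "numeric", observed = "numeric", nPerm = "integer",
            feature = "character"))

setValidity("PermutationBand", function(object) {
  if (any(object@minCount > object@maxCount))
    return("band minimum exceeds maximum")
  TRUE
})

#' Triplicate-bin mixture-model fit
#'
#' Result of [fitPowerModel()]: the shared hit fraction `h` and, per
#' threshold, the false-positive rate `alpha`, the mean `beta0` and spread
#' `sigma` of the (truncated) Gaussian distribution of per-gene
#' false-negative rates, with least-squares residuals.
#'
#' @slot h fitted hit fraction, shared across thresholds.
#' @slot table `data.frame` with columns `threshold`, `alpha`, `beta0`,
#'   `sigma`, `residual`, `converged`.
#' @slot converged overall convergence flag.
#' @slot underDetermined `TRUE` when fitted from a single threshold
#'   (3 degrees of freedom for 4 unknowns).
#' @slot details list of optimizer diagnostics.
#' @seealso [fitPowerModel()], [tpFpCurve()]
#' @exportClass PowerFit
.PowerFit <- setClass("PowerFit",
  slots = c(h = "numeric", table = "data.frame", converged = "logical",
            underDetermined = "logical", details = "list"))

#' Classifier/output Delta-y score matrix
#'
#' For every candidate (classifier feature i, output feature j) pair, the
#' median per-well correlation score y over positive-control wells minus the
#' median over negative-control wells, with per-cell valid-well counts and
#' (optionally) permutation 95th-percentile magnitudes.
#'
#' @slot delta classifiers x outputs matrix of Delta-y values (NA = masked).
#' @slot nPos,nNeg matrices of valid-well counts per cell.
#' @slot permQuantile matrix of permutation 95th percentiles of |Delta-y|
#'   (or `NULL` when no permutations were run).
#' @slot nPerm number of permutations.
#' @seealso [deltaYMatrix()], [classifierScore()]
#' @exportClass DeltaYMatrix
.DeltaYMatrix <- setClass("DeltaYMatrix",
  slots = c(delta = "matrix", nPos = "matrix", nNeg = "matrix",
            permQuantile = "matrixOrNULL", nPerm = "integer"))

#' Synthetic screen configuration
#'
#' Parameters of the synthetic screen generator. Defaults emulate the study
#' design: 10 x 30-well slides assayed in triplicate with scrambled
#' well-to-gene assignments, 30 negative and 8 positive control wells,
#' 200-500 cells per well, right-skewed continuous intensity features and
#' narrow/discrete geometric features, affine (additive + multiplicative)
#' row/column/slide artifacts on intensity features only, and hit genes
#' whose perturbation is expressed in a gene-specific fraction of cells
#' (penetrance).
#'
#' @seealso [simConfig()], [generateScreen()]
#' @exportClass SimConfig
.SimConfig <- setClass("SimConfig",
  slots = c(nSlides = "integer", nReplicates = "integer", rows = "integer",
            cols = "integer", nNegative = "integer", nPositive = "integer",
            cellsPerWell = "integer", features = "list",
            hitFraction = "numeric", penetranceMean = "numeric",
            penetranceSd = "numeric", artifact = "list", seed = "integer",
            stateClassifier = "character"))

setValidity("SimConfig", function(object) {
  msg <- character()
  wells <- object@rows * object@cols
  if (object@nNegative + object@nPositive > wells)
    msg <- c(msg, "control wells exceed slide capacity")
  if (length(object@cellsPerWell) != 2L ||
      any(object@cellsPerWell < 1L) ||
      object@cellsPerWell[1] > object@cellsPerWell[2])
    msg <- c(msg, "cellsPerWell must be an increasing positive range")
  if (object@hitFraction < 0 || object@hitFraction > 1)
    msg <- c(msg, "hitFraction must lie in [0, 1]")
  art <- object@artifact
  sc <- unlist(art[grepl("Scale", names(art))])
  if (length(sc) && any(sc < 0))
    msg <- c(msg, "artifact scale magnitudes must be non-negative")
  if (!length(object@features))
    msg <- c(msg, "at least one feature must be specified")
  if (length(msg)) msg else TRUE
})
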