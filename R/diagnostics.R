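#' Normalize a per-well distribution to zero mean and unit variance
#'
#' Subtracts the mean and divides by the (population) standard deviation.
#' This is the core shape-extraction step: any affine artifact
#' \eqn{v \mapsto a v + b} (with \eqn{a > 0}) applied uniformly to a well
#' cancels exactly, leaving only the shape of the distribution.
#'
#' @param values numeric vector of per-cell values (length >= 2).
#' @return numeric vector with mean 0 and population sd 1; order preserved.
#' @details The population convention (divide by n) is used; with hundreds
#'   of cells per well the n vs n-1 choice is immaterial, and it makes the
#'   normalize/moments identities exact. A constant input raises a
#'   condition of class `"shapescreen_degenerate"`; such wells are flagged
#'   and excluded from downstream scoring.
#' @examples
#' normalizeDistribution(c(2, 4, 6))
#' @export
normalizeDistribution <- function(values) {
  if (length(values) < 2L)
    .stop2("shapescreen_degenerate", "need at least 2 values, got %d",
           length(values))
  s <- .popSd(values)
  if (s == 0)
    .stop2("shapescreen_degenerate",
           "degenerate (constant) distribution: sd = 0")
  (values - mean(values)) / s
}

#' Moments of a per-well distribution
#'
#' Mean, population variance, and the two dimensionless shape measures:
#' skewness \eqn{m_3 / m_2^{3/2}} and (non-excess, Pearson) kurtosis
#' \eqn{m_4 / m_2^2}, from central moments \eqn{m_k}. Skewness and kurtosis
#' are invariant under affine maps with positive scale, which is what makes
#' them diagnostics for shape (as opposed to scale) artifacts.
#'
#' @param values numeric vector.
#' @return list with `mean`, `variance`, `skewness`, `kurtosis`, `n`, and
#'   logical `flags` naming any undefined entries (constant input, or fewer
#'   than 3/4 values for skewness/kurtosis).
#' @examples
#' distributionMoments(c(-1, 0, 1))$skewness  # 0 by symmetry
#' @export
distributionMoments <- function(values) {
  n <- length(values)
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  flags <- character()
  skew <- kurt <- NA_real_
  if (n < 3L) flags <- c(flags, "skewness")
  if (n < 4L) flags <- c(flags, "kurtosis")
  if (m2 == 0) {
    flags <- unique(c(flags, "skewness", "kurtosis"))
  } else {
    if (n >= 3L) skew <- mean(d^3) / m2^1.5
    if (n >= 4L) kurt <- mean(d^4) / m2^2
  }
  list(mean = m, variance = m2, skewness = skew, kurtosis = kurt, n = n,
       flags = flags)
}

#' One-way ANOVA F statistic for per-well summaries
#'
#' Compares the variability of a per-well moment (e.g. the well means of an
#' intensity feature) between and within groups of wells (rows, columns or
#' slides). A large F for means but not for skewness is the signature of
#' affine positional artifacts: offsets and scales move the scale-related
#' moments around while leaving the dimensionless shape moments alone.
#'
#' @param values numeric vector, one summary value per well.
#' @param groups grouping factor (same length), e.g. slide row.
#' @param measure optional label recorded in the result.
#' @return list with `fStatistic`, `dfBetween`, `dfWithin`, `nGroups`,
#'   `measure`, and `flagged` (`TRUE` when the within-group mean square is
#'   zero and F is undefined).
#' @details Groups with fewer than 2 members are dropped with a warning;
#'   fewer than 2 usable groups is an error. The F statistic is taken from
#'   a standard one-way `lm`/`anova` fit.
#' @export
anovaF <- function(values, groups, measure = NA_character_) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("dropping %d group(s) with < 2 wells: %s",
                    length(small), paste(small, collapse = ", ")))
    keep <- !(as.character(groups) %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups with >= 2 wells each")
  tab <- suppressWarnings(anova(lm(values ~ groups)))
  ssw <- tab["Residuals", "Sum Sq"]
  sst <- ssw + tab["groups", "Sum Sq"]
  flagged <- !is.finite(ssw) || ssw <= 1e-12 * max(sst, 1e-300)
  list(fStatistic = if (flagged) NA_real_ else tab["groups", "F value"],
       dfBetween = k - 1L, dfWithin = length(values) - k, nGroups = k,
       measure = measure, flagged = flagged)
}

#' Positional-artifact diagnostics for a whole screen
#'
#' For every (slide, feature, moment) computes the one-way ANOVA F
#' comparing per-well moments between and within the requested grouping
#' (slide rows by default). Reproduces the moment-vs-shape artifact
#' diagnostic: on artifact-laden intensity features, F for well means is
#' large while F for skewness stays near 1.
#'
#' @param screen a [ScreenExperiment-class].
#' @param features feature names (default: all).
#' @param measures subset of `c("mean", "variance", "skewness",
#'   "kurtosis")`.
#' @param grouping `"row"`, `"col"` or `"slide"`. With `"slide"` the groups
#'   are whole slides (one F per feature/measure, all wells pooled).
#' @return tidy `data.frame` with columns `slide_id`, `feature`, `family`,
#'   `measure`, `grouping`, `f`, `df_between`, `df_within`.
#' @export
diagnosticsReport <- function(screen, features = NULL,
                              measures = c("mean", "skewness"),
                              grouping = c("row", "col", "slide")) {
  grouping <- match.arg(grouping)
  if (is.null(features)) features <- rownames(screen)
  lay <- screenLayout(screen)
  out <- list()
  slides <- if (grouping == "slide") "(all)" else slideIds(screen)
  for (feat in features) {
    momentsBySlide <- lapply(slideIds(screen), function(s) {
      wells <- .slideWellValues(screen, s, feat)
      do.call(rbind, lapply(wells, function(v) {
        mm <- distributionMoments(v)
        data.frame(mean = mm$mean, variance = mm$variance,
                   skewness = mm$skewness, kurtosis = mm$kurtosis)
      }))
    })
    names(momentsBySlide) <- slideIds(screen)
    for (meas in measures) {
      if (grouping == "slide") {
        vals <- unlist(lapply(momentsBySlide, `[[`, meas))
        grp <- rep(names(momentsBySlide),
                   vapply(momentsBySlide, nrow, 1L))
        a <- anovaF(vals, grp, meas)
        out[[length(out) + 1L]] <- data.frame(
          slide_id = "(all)", feature = feat,
          family = unname(featureFamily(screen)[feat]), measure = meas,
          grouping = grouping, f = a$fStatistic,
          df_between = a$dfBetween, df_within = a$dfWithin)
      } else {
        for (s in slideIds(screen)) {
          laySlide <- lay[lay$slide_id == s, ]
          grp <- laySlide[[grouping]]
          a <- anovaF(momentsBySlide[[s]][[meas]], grp, meas)
          out[[length(out) + 1L]] <- data.frame(
            slide_id = s, feature = feat,
            family = unname(featureFamily(screen)[feat]), measure = meas,
            grouping = grouping, f = a$fStatistic,
            df_between = a$dfBetween, df_within = a$dfWithin)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Nonlinear-rescale convergence check
#'
#' Computes pairwise KS distances between normalized wells with and without
#' a nonlinear pre-transform (log or power). Wells that differ only by
#' affine artifacts converge to identical shapes under plain normalization
#' (D near 0) but *diverge* when log-rescaled first whenever their additive
#' offsets differ, because log breaks affine equivalence. Wells differing
#' by a multiplicative scale alone still converge under log (the scale
#' becomes a shift, removed by normalization).
#'
#' @param wells named list of per-well numeric vectors.
#' @param transform `"log"` or `"power"`.
#' @param power exponent when `transform = "power"`.
#' @return `data.frame` with columns `well_a`, `well_b`, `d_plain`
#'   (normalize only) and `d_transformed` (transform, then normalize).
#' @export
rescaleConvergenceCheck <- function(wells, transform = c("log", "power"),
                                    power = 0.5) {
  transform <- match.arg(transform)
  stopifnot(length(wells) >= 2L)
  if (is.null(names(wells))) names(wells) <- seq_along(wells)
  if (transform == "log") {
    bad <- names(wells)[vapply(wells, function(v) any(v <= 0), TRUE)]
    if (length(bad))
      stop(sprintf("log transform needs positive values; offending well(s): %s",
                   paste(bad, collapse = ", ")))
    tf <- log
  } else {
    tf <- function(v) sign(v) * abs(v)^power
  }
  plain <- lapply(wells, normalizeDistribution)
  trans <- lapply(wells, function(v) normalizeDistribution(tf(v)))
  pairs <- utils::combn(names(wells), 2L)
  data.frame(
    well_a = pairs[1, ], well_b = pairs[2, ],
    d_plain = apply(pairs, 2L, function(p)
      ksStatistic(plain[[p[1]]], plain[[p[2]]])@d),
    d_transformed = apply(pairs, 2L, function(p)
      ksStatistic(trans[[p[1]]], trans[[p[2]]])@d),
    row.names = NULL)
}

#' Partial normalization against the eight nearest neighbor wells
#'
#' Linearly transforms a target well so that its mean and variance equal
#' the averages of its neighbors' means and variances (the 8 wells of the
#' surrounding 3x3 block; edge and corner wells use their existing 5 or 3
#' neighbors). This is the intermediate between no normalization and full
#' per-well normalization: local smooth artifacts are removed while
#' slide-scale trends survive.
#'
#' @param wells named list of per-well numeric vectors for one slide.
#' @param positions `data.frame` with columns `well_id`, `row`, `col`
#'   covering every well in `wells`.
#' @param target well id of the well to transform.
#' @return numeric vector: the target well's values with mean equal to the
#'   neighbor-average mean and variance equal to the neighbor-average
#'   variance.
#' @export
partialNormalize <- function(wells, positions, target) {
  stopifnot(target %in% names(wells), target %in% positions$well_id)
  pos <- positions[match(names(wells), positions$well_id), ]
  t0 <- pos[pos$well_id == target, ]
  nb <- pos$well_id[abs(pos$row - t0$row) <= 1L &
                      abs(pos$col - t0$col) <= 1L &
                      pos$well_id != target]
  nb <- nb[vapply(wells[nb], function(v) length(v) >= 2L, TRUE)]
  if (!length(nb))
    stop(sprintf("well '%s' has no neighbors with valid statistics", target))
  nbMeans <- vapply(wells[nb], mean, 0)
  nbVars <- vapply(wells[nb], function(v) mean((v - mean(v))^2), 0)
  v <- wells[[target]]
  s <- .popSd(v)
  if (s == 0)
    .stop2("shapescreen_degenerate", "target well '%s' is degenerate", target)
  (v - mean(v)) / s * sqrt(mean(nbVars)) + mean(nbMeans)
}
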