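#' Feature specification for the synthetic screen
#'
#' Describes one single-cell feature: its family (`"intensity"` features
#' are continuous and right-skewed and receive affine artifacts;
#' `"geometry"` features are narrow or discrete and artifact-free), its
#' baseline sampling distribution, and the perturbed distribution that
#' responding cells are drawn from. Perturbations are chosen to change the
#' *shape* of the distribution (skewness and/or kurtosis), not only its
#' location and scale, so that they remain visible after normalization.
#'
#' @param name feature name.
#' @param family `"intensity"` or `"geometry"`.
#' @param dist `"gamma"`, `"poisson"`, `"norm"` or `"lnorm"`.
#' @param params named list of baseline distribution parameters
#'   (`shape`/`scale`, `lambda`, `mean`/`sd`, `meanlog`/`sdlog`).
#' @param perturb named list of perturbed-distribution parameters, or
#'   `NULL` for an unperturbable feature (e.g. a cell-size classifier
#'   candidate). For `"norm"` a two-component mixture may be given as
#'   `list(mean = c(..), sd = c(..), w = c(..))`.
#' @return a `list` of class `"FeatureSpec"`.
#' @export
featureSpec <- function(name, family = c("intensity", "geometry"),
                        dist = c("gamma", "poisson", "norm", "lnorm"),
                        params, perturb = NULL) {
  structure(list(name = name, family = match.arg(family),
                 dist = match.arg(dist), params = params,
                 perturb = perturb), class = "FeatureSpec")
}

#' Affine artifact specification
#'
#' Magnitudes of the per-row, per-column and per-slide artifacts applied to
#' intensity features: additive offsets are drawn from normal distributions
#' with the given standard deviations (expressed as fractions of the
#' feature's baseline mean) and multiplicative scales from lognormal
#' distributions with the given `sdlog` values (so scales are strictly
#' positive). Within a well the artifact is affine, `v -> a * v + b`, with
#' `a` the product of slide/row/column scales and `b` the sum of offsets.
#'
#' @param enabled logical; `FALSE` zeroes all magnitudes.
#' @param rowOffset,colOffset,slideOffset additive-offset sds (fractions of
#'   the baseline mean).
#' @param rowScale,colScale,slideScale multiplicative-scale sdlogs.
#' @return a named list.
#' @export
artifactSpec <- function(enabled = TRUE, rowOffset = 0.3, colOffset = 0.15,
                         slideOffset = 0.3, rowScale = 0.2, colScale = 0.1,
                         slideScale = 0.2) {
  if (!enabled)
    rowOffset <- colOffset <- slideOffset <- rowScale <- colScale <-
      slideScale <- 0
  list(enabled = enabled, rowOffset = rowOffset, colOffset = colOffset,
       slideOffset = slideOffset, rowScale = rowScale, colScale = colScale,
       slideScale = slideScale)
}

#' Default synthetic feature panel
#'
#' Two right-skewed continuous intensity features (gamma family; the
#' perturbation shifts the gamma shape parameter, changing skewness), two
#' geometry features (a small-count Poisson whose perturbation is an
#' overdispersed rate mixture with nearly unchanged mean, and a narrow
#' Gaussian whose perturbation is a variance-matched bimodal mixture — a
#' pure shape change invisible to mean- and variance-based scores), plus
#' an unperturbable lognormal cell-`size` feature usable as a cell-state
#' classifier.
#'
#' @return list of [featureSpec()] objects.
#' @export
defaultFeatures <- function() {
  list(
    featureSpec("I1", "intensity", "gamma",
                params = list(shape = 2, scale = 50),
                perturb = list(shape = 8, scale = 50)),
    featureSpec("I2", "intensity", "gamma",
                params = list(shape = 3, scale = 20),
                perturb = list(shape = 0.8, scale = 20)),
    featureSpec("G1", "geometry", "poisson",
                params = list(lambda = 3),
                perturb = list(lambda = c(1, 6), w = c(0.5, 0.5))),
    featureSpec("G2", "geometry", "norm",
                params = list(mean = 10, sd = 0.5),
                perturb = list(mean = c(9.53, 10.47), sd = c(0.17, 0.17),
                               w = c(0.5, 0.5))),
    featureSpec("size", "geometry", "lnorm",
                params = list(meanlog = log(150), sdlog = 0.35),
                perturb = NULL)
  )
}

#' Synthetic screen configuration
#'
#' Defaults emulate the study design: one slide design of 10 x 30 = 300
#' wells assayed in triplicate with scrambled (uniformly permuted)
#' well-to-gene assignments per replicate, 30 negative and 8 positive
#' control wells, 200-500 cells per well. Positive controls come in three
#' strengths (penetrance 0.9 / 0.6 / 0.3, mirroring the three positive
#' controls' differing true-positive rates); hit genes receive a penetrance
#' drawn from a Gaussian truncated to \[0, 1\].
#'
#' @param nSlides number of distinct slide designs (disjoint gene sets).
#' @param nReplicates replicate slides per design.
#' @param rows,cols slide grid (default 10 x 30).
#' @param nNegative,nPositive control well counts per slide.
#' @param cellsPerWell integer range; each well's population size is drawn
#'   uniformly from it.
#' @param features list of [featureSpec()] (default [defaultFeatures()]).
#' @param hitFraction fraction of test genes that are true hits.
#' @param penetranceMean,penetranceSd parameters of the truncated-Gaussian
#'   per-hit-gene penetrance (fraction of responding cells).
#' @param artifact an [artifactSpec()].
#' @param seed RNG seed.
#' @param stateClassifier optional feature name; when set, a perturbed
#'   well's cells respond with probability proportional to their
#'   within-well percentile of this (unperturbable) feature, so the
#'   response becomes predictable from cell state.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nSlides = 1L, nReplicates = 3L, rows = 10L,
                      cols = 30L, nNegative = 30L, nPositive = 8L,
                      cellsPerWell = c(200L, 500L),
                      features = defaultFeatures(), hitFraction = 0.1,
                      penetranceMean = 0.5, penetranceSd = 0.2,
                      artifact = artifactSpec(), seed = 1L,
                      stateClassifier = NA_character_) {
  .SimConfig(nSlides = as.integer(nSlides),
             nReplicates = as.integer(nReplicates), rows = as.integer(rows),
             cols = as.integer(cols), nNegative = as.integer(nNegative),
             nPositive = as.integer(nPositive),
             cellsPerWell = as.integer(cellsPerWell), features = features,
             hitFraction = hitFraction, penetranceMean = penetranceMean,
             penetranceSd = penetranceSd, artifact = artifact,
             seed = as.integer(seed),
             stateClassifier = as.character(stateClassifier))
}

#' Apply an affine artifact to per-cell values
#'
#' @param values numeric vector.
#' @param scale multiplicative scale (strictly positive).
#' @param offset additive offset.
#' @return `scale * values + offset`, order preserved.
#' @examples
#' applyAffineArtifact(c(1, 2, 3), scale = 2, offset = 5)  # 7 9 11
#' @export
applyAffineArtifact <- function(values, scale, offset) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    .stop2("shapescreen_domain",
           "multiplicative scale must be strictly positive, got %s",
           format(scale))
  scale * values + offset
}

.rtrunc01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(max(mean, 0), 1), n))
  lo <- pnorm((0 - mean) / sd)
  hi <- pnorm((1 - mean) / sd)
  mean + sd * qnorm(runif(n, lo, hi))
}

.baselineMean <- function(spec) {
  p <- spec$params
  switch(spec$dist,
         gamma = p$shape * p$scale,
         poisson = p$lambda,
         norm = p$mean,
         lnorm = exp(p$meanlog + p$sdlog^2 / 2))
}

.drawFeature <- function(spec, n, perturbed = FALSE) {
  p <- if (perturbed) spec$perturb else spec$params
  switch(spec$dist,
    gamma = rgamma(n, shape = p$shape, scale = p$scale),
    poisson = {
      if (!is.null(p$w)) {
        comp <- sample.int(length(p$w), n, replace = TRUE, prob = p$w)
        rpois(n, lambda = p$lambda[comp])
      } else rpois(n, lambda = p$lambda)
    },
    lnorm = rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    norm = {
      if (!is.null(p$w)) {
        comp <- sample.int(length(p$w), n, replace = TRUE, prob = p$w)
        rnorm(n, mean = p$mean[comp], sd = p$sd[comp])
      } else rnorm(n, mean = p$mean, sd = p$sd)
    })
}

#' Generate a synthetic screen
#'
#' Simulates a full screen (cells in wells on replicated slides) under a
#' [simConfig()]: hit genes are assigned a gene-specific penetrance; in
#' each well of a perturbed gene that fraction of cells is drawn from the
#' perturbed distribution of every affected feature and the rest from
#' baseline; replicate slides carry the same genes at uniformly permuted
#' well positions; affine row/column/slide artifacts are applied to
#' intensity features. Deterministic given the config seed.
#'
#' @param config a [SimConfig-class].
#' @return a [ScreenExperiment-class] whose [truthTable()] records, for
#'   every non-negative-control gene, `is_hit`, `penetrance` and the
#'   affected features.
#' @examples
#' cfg <- simConfig(rows = 4L, cols = 6L, nNegative = 8L, nPositive = 2L,
#'                  cellsPerWell = c(50L, 80L), seed = 7L)
#' scr <- generateScreen(cfg)
#' @export
generateScreen <- function(config) {
  validObject(config)
  set.seed(config@seed)
  specs <- config@features
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (!is.na(config@stateClassifier)) {
    cls <- config@stateClassifier
    if (!cls %in% names(specs))
      stop(sprintf("stateClassifier '%s' is not a feature", cls))
    if (!is.null(specs[[cls]]$perturb))
      stop(sprintf("stateClassifier '%s' must be unperturbable", cls))
  }
  perturbable <- names(specs)[!vapply(specs, function(s)
    is.null(s$perturb), TRUE)]
  affectedStr <- paste(perturbable, collapse = ",")
  wellsPerSlide <- config@rows * config@cols
  nTest <- wellsPerSlide - config@nNegative - config@nPositive
  posTiers <- rep(c("strong", "medium", "weak"),
                  length.out = config@nPositive)
  posPen <- c(strong = 0.9, medium = 0.6, weak = 0.3)
  paste0v <- function(pre, x)  # zero-length-safe paste0
    if (length(x)) paste0(pre, x) else character(0)

  truth <- list()
  cellChunks <- list()
  layChunks <- list()
  for (d in seq_len(config@nSlides)) {
    genes <- sprintf("g%05d", (d - 1L) * nTest + seq_len(nTest))
    isHit <- runif(nTest) < config@hitFraction
    pen <- numeric(nTest)
    pen[isHit] <- .rtrunc01(sum(isHit), config@penetranceMean,
                            config@penetranceSd)
    truth[[d]] <- data.frame(
      gene = c(genes, paste0v("pos_", unique(posTiers))),
      is_hit = c(isHit, rep(TRUE, length(unique(posTiers)))),
      penetrance = c(pen, posPen[unique(posTiers)]),
      affected_features = ifelse(
        c(isHit, rep(TRUE, length(unique(posTiers)))), affectedStr, ""),
      row.names = NULL)
    contents <- c(rep("neg_ctrl", config@nNegative),
                  paste0v("pos_", posTiers), genes)
    penByGene <- stats::setNames(c(pen, posPen[posTiers]),
                                 c(genes, paste0v("pos_", posTiers)))
    for (r in seq_len(config@nReplicates)) {
      slide <- sprintf("D%02dR%d", d, r)
      assign <- sample(contents)
      rowIdx <- rep(seq_len(config@rows), each = config@cols)
      colIdx <- rep(seq_len(config@cols), times = config@rows)
      wellIds <- sprintf("r%02dc%02d", rowIdx, colIdx)
      role <- ifelse(startsWith(assign, "neg"), "negative",
                     ifelse(startsWith(assign, "pos"), "positive", "test"))
      layChunks[[slide]] <- data.frame(
        slide_id = slide, well_id = wellIds, row = rowIdx, col = colIdx,
        gene = assign, role = role, replicate = r)
      # artifact fields per (slide, intensity feature)
      art <- config@artifact
      # standard normals are drawn unconditionally and scaled afterwards,
      # so screens generated with artifacts on and off from the same seed
      # share the identical cell population
      artFields <- lapply(specs, function(sp) {
        if (sp$family != "intensity") return(NULL)
        ref <- .baselineMean(sp)
        list(a = exp(rnorm(1) * art$slideScale) *
               exp(rnorm(config@rows) * art$rowScale)[rowIdx] *
               exp(rnorm(config@cols) * art$colScale)[colIdx],
             b = ref * (rnorm(1) * art$slideOffset +
                          (rnorm(config@rows) * art$rowOffset)[rowIdx] +
                          (rnorm(config@cols) * art$colOffset)[colIdx]))
      })
      nCells <- sample(seq(config@cellsPerWell[1], config@cellsPerWell[2]),
                       wellsPerSlide, replace = TRUE)
      total <- sum(nCells)
      ends <- cumsum(nCells)
      starts <- ends - nCells + 1L
      mat <- matrix(NA_real_, nrow = total, ncol = length(specs),
                    dimnames = list(NULL, names(specs)))
      for (w in seq_len(wellsPerSlide)) {
        n <- nCells[w]
        idx <- starts[w]:ends[w]
        g <- assign[w]
        penW <- if (g %in% names(penByGene)) penByGene[[g]] else 0
        vals <- lapply(specs, .drawFeature, n = n)
        if (penW > 0) {
          if (!is.na(config@stateClassifier)) {
            rk <- (rank(vals[[config@stateClassifier]],
                        ties.method = "average") - 0.5) / n
            respond <- runif(n) < pmin(1, 2 * penW * rk)
          } else {
            respond <- runif(n) < penW
          }
          if (any(respond)) {
            for (f in perturbable)
              vals[[f]][respond] <- .drawFeature(specs[[f]], sum(respond),
                                                 perturbed = TRUE)
          }
        }
        for (f in names(specs)) {
          v <- vals[[f]]
          af <- artFields[[f]]
          if (!is.null(af))
            v <- applyAffineArtifact(v, max(af$a[w], 1e-12), af$b[w])
          mat[idx, f] <- v
        }
      }
      cellChunks[[slide]] <- cbind(
        data.frame(slide_id = slide,
                   well_id = rep(wellIds, nCells),
                   cell_id = sequence(nCells)),
        as.data.frame(mat))
    }
  }
  fam <- vapply(specs, `[[`, "", "family")
  ScreenExperiment(do.call(rbind, cellChunks), do.call(rbind, layChunks),
                   featureFamily = fam,
                   truth = do.call(rbind, truth))
}

#' Apply per-well affine maps to a feature of a screen
#'
#' Utility for artifact experiments: replaces the values of `feature` in
#' the given wells of one slide by `scale * v + offset` (well-specific
#' scale and offset). Used to verify the affine invariance of mode-N
#' scores.
#'
#' @param screen a [ScreenExperiment-class].
#' @param slide slide id.
#' @param wells character vector of well ids.
#' @param feature feature name.
#' @param scales,offsets numeric vectors (recycled to `length(wells)`);
#'   scales must be strictly positive.
#' @return the modified [ScreenExperiment-class].
#' @export
applyWellAffine <- function(screen, slide, wells, feature, scales,
                            offsets) {
  scales <- rep_len(scales, length(wells))
  offsets <- rep_len(offsets, length(wells))
  cd <- SummarizedExperiment::colData(screen)
  a <- SummarizedExperiment::assay(screen, "features")
  for (i in seq_along(wells)) {
    sel <- cd$slide_id == slide & cd$well_id == wells[i]
    a[feature, sel] <- applyAffineArtifact(a[feature, sel], scales[i],
                                           offsets[i])
  }
  SummarizedExperiment::assay(screen, "features") <- a
  screen
}

#' Simulate triplicate gene Z-scores from the screening error model
#'
#' Score-level generative process matching the triplicate mixture model:
#' a fraction `h` of genes are hits; each hit gene's false-negative rate
#' `beta_g` is drawn from a Gaussian with mean `beta0` and sd `sigma`
#' truncated to \[0, 1\]; each of its replicate scores comes from a shifted
#' signal distribution with probability `1 - beta_g` and from the null
#' otherwise; negative genes draw all three scores from the null, whose
#' spread is set so that the per-replicate false-positive rate at
#' `threshold` equals `alpha`.
#'
#' @param nGenes number of genes.
#' @param h hit fraction.
#' @param alpha per-replicate false-positive rate at `threshold`.
#' @param threshold the Z-score threshold the rates refer to.
#' @param beta0,sigma mean and sd of the per-gene false-negative rate.
#' @param seed RNG seed.
#' @return `data.frame` with columns `gene`, `feature`, `z1`, `z2`, `z3`
#'   and attribute `"truth"` (a `data.frame` with `gene`, `is_hit`,
#'   `beta`).
#' @export
simulateGeneScores <- function(nGenes = 10000L, h = 0.15, alpha = 0.05,
                               threshold = 3, beta0 = 0.4, sigma = 0.15,
                               seed = 1L) {
  set.seed(seed)
  nullSd <- threshold / qnorm(1 - alpha)
  isHit <- runif(nGenes) < h
  beta <- rep(NA_real_, nGenes)
  beta[isHit] <- .rtrunc01(sum(isHit), beta0, sigma)
  z <- matrix(rnorm(3L * nGenes, 0, nullSd), ncol = 3L)
  hitIdx <- which(isHit)
  if (length(hitIdx)) {
    respond <- matrix(runif(3L * length(hitIdx)) >= beta[hitIdx],
                      ncol = 3L)
    sig <- matrix(rnorm(3L * length(hitIdx), threshold + 4, 1), ncol = 3L)
    z[hitIdx, ][respond] <- sig[respond]
  }
  out <- data.frame(gene = sprintf("g%05d", seq_len(nGenes)),
                    feature = "sim", z1 = z[, 1], z2 = z[, 2], z3 = z[, 3])
  attr(out, "truth") <- data.frame(gene = out$gene, is_hit = isHit,
                                   beta = beta)
  out
}
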