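#' Build the per-gene triplicate Z-score table
#'
#' Collects, for every test gene and feature, the Z-scores from the three
#' replicate slides into a wide table. Genes with missing replicates keep
#' `NA` entries; downstream the 2-of-3 rule requires at least two
#' available scores.
#'
#' @param scores a [scoresTable()] `data.frame` or list of
#'   [SlideScores-class].
#' @return `data.frame` with columns `gene`, `feature`, `z1`, `z2`, `z3`.
#' @export
geneScoreTable <- function(scores) {
  if (!is.data.frame(scores)) scores <- scoresTable(scores)
  tst <- scores[scores$role == "test" & !is.na(scores$z), , drop = FALSE]
  key <- interaction(tst$gene, tst$feature, drop = TRUE)
  rows <- lapply(split(tst, key), function(g) {
    z <- rep(NA_real_, 3L)
    ord <- order(g$replicate)
    z[seq_len(min(3L, nrow(g)))] <- g$z[ord][seq_len(min(3L, nrow(g)))]
    data.frame(gene = g$gene[1], feature = g$feature[1],
               z1 = z[1], z2 = z[2], z3 = z[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$feature, out$gene), ]
}

#' Call hits by the triplicate 2-of-3 rule
#'
#' A gene (for a feature) is a hit when two or more of its replicate
#' Z-scores lie strictly above the threshold. Genes with fewer than two
#' usable replicate scores are excluded (with a message).
#'
#' @param geneScores a [geneScoreTable()] `data.frame`.
#' @param threshold Z-score cutoff (default 3, where the deviation of
#'   observed from permuted hit counts is maximal).
#' @return `data.frame` with columns `gene`, `feature`, `times_above`,
#'   `n_avail`, `is_hit`, `threshold`.
#' @examples
#' gs <- data.frame(gene = "g1", feature = "f", z1 = 3.5, z2 = 3.2,
#'                  z3 = 1.0)
#' callHits(gs, threshold = 3)
#' @export
callHits <- function(geneScores, threshold = 3) {
  z <- as.matrix(geneScores[, c("z1", "z2", "z3")])
  nAvail <- rowSums(!is.na(z))
  drop <- nAvail < 2L
  if (any(drop))
    message(sprintf("excluding %d gene(s) with < 2 usable replicates",
                    sum(drop)))
  ta <- rowSums(z > threshold, na.rm = TRUE)
  out <- data.frame(gene = geneScores$gene, feature = geneScores$feature,
                    times_above = as.integer(ta), n_avail = nAvail,
                    is_hit = ta >= 2L, threshold = threshold)
  out[!drop, , drop = FALSE]
}

#' Union of per-feature hits at the screen level
#'
#' A gene is a screen hit when it is a hit for at least one feature.
#'
#' @param hitCalls a [callHits()] result (possibly several features).
#' @return character vector of unique hit genes.
#' @export
screenHits <- function(hitCalls) {
  sort(unique(hitCalls$gene[hitCalls$is_hit]))
}

# counts of genes whose 2nd-largest z exceeds each threshold (2/3 rule)
.hitCounts <- function(secondMax, thresholds) {
  s <- sort(secondMax)
  length(s) - findInterval(thresholds, s)
}

.secondMax <- function(zmat) {
  apply(zmat, 1L, function(r) sort(r, decreasing = TRUE)[2L])
}

#' Permutation null band for hit counts across thresholds
#'
#' For each of `nPerm` permutations the gene labels are shuffled
#' independently within each replicate, which preserves every replicate's
#' Z-score multiset but destroys gene-level reproducibility; the 2-of-3
#' hit count is recomputed over the threshold grid, and the band is the
#' per-threshold minimum and maximum over permutations. A real screen's
#' observed counts rising above the band maximum is the signature of
#' reproducible hits.
#'
#' @param geneScores a [geneScoreTable()] for a single feature.
#' @param thresholds threshold grid (default `seq(0.5, 6, 0.25)`).
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return a [PermutationBand-class].
#' @export
permutationBand <- function(geneScores, thresholds = seq(0.5, 6, 0.25),
                            nPerm = 1000L, seed = 1L) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  feat <- unique(geneScores$feature)
  if (length(feat) > 1L)
    stop("permutationBand expects a single feature; filter first")
  z <- as.matrix(geneScores[, c("z1", "z2", "z3")])
  z <- z[rowSums(!is.na(z)) == 3L, , drop = FALSE]
  if (nrow(z) < 2L) stop("need at least 2 genes with full triplicates")
  set.seed(seed)
  obs <- .hitCounts(.secondMax(z), thresholds)
  lo <- rep(Inf, length(thresholds))
  hi <- rep(-Inf, length(thresholds))
  n <- nrow(z)
  for (p in seq_len(nPerm)) {
    zp <- cbind(z[sample.int(n), 1L], z[sample.int(n), 2L],
                z[sample.int(n), 3L])
    cnt <- .hitCounts(.secondMax(zp), thresholds)
    lo <- pmin(lo, cnt)
    hi <- pmax(hi, cnt)
  }
  .PermutationBand(thresholds = thresholds, minCount = lo, maxCount = hi,
                   observed = obs, nPerm = nPerm,
                   feature = if (length(feat)) feat else NA_character_)
}

#' False-positive rate from held-out negative wells
#'
#' The held-out "worst-scoring" negatives never enter the score matrix, so
#' the fraction of their Z-scores above the threshold (pooled across
#' slides) is an unbiased measurement of the per-replicate false-positive
#' rate, directly comparable to the model-inferred `alpha` of
#' [fitPowerModel()].
#'
#' @param scores a [scoresTable()] `data.frame` or list of
#'   [SlideScores-class].
#' @param threshold Z-score cutoff.
#' @return fraction of held-out negative scores strictly above
#'   `threshold`.
#' @export
fpRateHeldout <- function(scores, threshold = 3) {
  if (!is.data.frame(scores)) scores <- scoresTable(scores)
  ho <- scores$z[scores$held_out & !is.na(scores$z)]
  if (!length(ho)) stop("no held-out negative scores present")
  mean(ho > threshold)
}

#' Observed vs chance-expected overlap of two gene sets
#'
#' @param setA,setB gene sets (subsets of `universe`).
#' @param universe the gene universe.
#' @return list with `observed` (`|A` intersect `B|`) and `expected`
#'   (`|A| |B| / |U|`, the hypergeometric mean under independent draws).
#' @examples
#' overlapExpected(paste0("g", 1:470), paste0("g", 300:901),
#'                 paste0("g", 1:7131))
#' @export
overlapExpected <- function(setA, setB, universe) {
  if (!length(universe)) stop("empty universe")
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  list(observed = length(intersect(setA, setB)),
       expected = length(setA) * length(setB) / length(universe))
}

#' Term enrichment among hits with permutation-corrected p-values
#'
#' For each annotation term, the one-tailed Fisher exact p-value of the
#' 2x2 table (hit / non-hit vs in-term / not-in-term), computed as the
#' hypergeometric upper tail. Multiplicity correction uses permutations of
#' the gene-to-term assignment: by default the family-wise corrected
#' p-value of a term is the fraction of permutations in which *any* term
#' attains a raw p-value at or below the term's observed one
#' (`method = "fwer"`); `method = "per-term"` calibrates each term against
#' its own permutation distribution instead.
#'
#' @param hits hit gene set.
#' @param annotations named character vector: gene -> term (one, most
#'   specific, term per gene). Genes outside `universe` are dropped with a
#'   message.
#' @param universe the gene universe.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param method `"fwer"` or `"per-term"`.
#' @return `data.frame` with columns `term`, `n_term`, `n_hit_term`,
#'   `expected`, `p_raw`, `p_corrected`, sorted by `p_raw`.
#' @export
enrichment <- function(hits, annotations, universe, nPerm = 1000L,
                       seed = 1L, method = c("fwer", "per-term")) {
  method <- match.arg(method)
  universe <- unique(universe)
  drop <- !(names(annotations) %in% universe)
  if (any(drop)) {
    message(sprintf("dropping %d annotation(s) outside the universe",
                    sum(drop)))
    annotations <- annotations[!drop]
  }
  hits <- intersect(unique(hits), universe)
  genes <- names(annotations)
  terms <- sort(unique(annotations))
  nU <- length(universe)
  nH <- length(hits)
  isHit <- genes %in% hits

  termP <- function(ann) {
    nTerm <- table(factor(ann, levels = terms))
    nHitTerm <- table(factor(ann[isHit], levels = terms))
    p <- phyper(as.numeric(nHitTerm) - 1, m = as.numeric(nTerm),
                n = nU - as.numeric(nTerm), k = nH, lower.tail = FALSE)
    list(p = p, nTerm = as.numeric(nTerm),
         nHitTerm = as.numeric(nHitTerm))
  }
  obs <- termP(annotations)
  set.seed(seed)
  permP <- matrix(NA_real_, nrow = nPerm, ncol = length(terms))
  for (i in seq_len(nPerm))
    permP[i, ] <- termP(stats::setNames(sample(unname(annotations)),
                                        genes))$p
  pCorr <- if (method == "fwer") {
    minP <- apply(permP, 1L, min)
    vapply(obs$p, function(p) (1 + sum(minP <= p)) / (nPerm + 1), 0)
  } else {
    vapply(seq_along(terms), function(j)
      (1 + sum(permP[, j] <= obs$p[j])) / (nPerm + 1), 0)
  }
  out <- data.frame(term = terms, n_term = obs$nTerm,
                    n_hit_term = obs$nHitTerm,
                    expected = obs$nTerm * nH / nU, p_raw = obs$p,
                    p_corrected = pCorr)
  out[order(out$p_raw), ]
}
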