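test_that("applyAffineArtifact is exact arithmetic and rejects bad scales", {
  expect_identical(applyAffineArtifact(c(1, 2, 3), 1, 0), c(1, 2, 3))
  expect_identical(applyAffineArtifact(c(1, 2, 3), 2, 5), c(7, 9, 11))
  expect_error(applyAffineArtifact(1:3, 0, 1), class = "shapescreen_domain")
  expect_error(applyAffineArtifact(1:3, -2, 1),
               class = "shapescreen_domain")
})

test_that("identical config and seed give bit-identical screens", {
  s1 <- generateScreen(smallConfig(seed = 5))
  s2 <- generateScreen(smallConfig(seed = 5))
  expect_identical(SummarizedExperiment::assay(s1),
                   SummarizedExperiment::assay(s2))
  expect_identical(screenLayout(s1), screenLayout(s2))
  expect_identical(truthTable(s1), truthTable(s2))
  s3 <- generateScreen(smallConfig(seed = 6))
  expect_false(identical(SummarizedExperiment::assay(s1),
                         SummarizedExperiment::assay(s3)))
})

test_that("hit_fraction 0 yields a null screen by construction", {
  scr <- generateScreen(smallConfig(seed = 8, hitFraction = 0))
  tr <- truthTable(scr)
  expect_false(any(tr$is_hit[grepl("^g", tr$gene)]))
  expect_true(all(tr$penetrance[grepl("^g", tr$gene)] == 0))
})

test_that("replicate slides carry the same genes at permuted positions", {
  scr <- generateScreen(smallConfig(seed = 9))
  lay <- screenLayout(scr)
  byRep <- split(lay, lay$slide_id)
  expect_length(byRep, 3L)
  g1 <- byRep[[1]][order(byRep[[1]]$well_id), ]
  g2 <- byRep[[2]][order(byRep[[2]]$well_id), ]
  expect_setequal(g1$gene, g2$gene)
  expect_false(all(g1$gene == g2$gene))  # scrambled assignment
  # every well in the cell table appears exactly once in the layout
  ct <- cellTable(scr)
  expect_setequal(unique(paste(ct$slide_id, ct$well_id)),
                  paste(lay$slide_id, lay$well_id))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(rows = 2L, cols = 3L, nNegative = 5L,
                         nPositive = 2L), "capacity")
  expect_error(simConfig(hitFraction = 1.2), "hitFraction")
  expect_error(simConfig(cellsPerWell = c(100L, 50L)), "cellsPerWell")
})

test_that("a fully penetrant strong perturbation exceeds the negative-pair null", {
  # a drastic skew change (gamma shape 2 -> 0.5) so a single well pair,
  # not only the averaged Z, separates from the null
  strongFeat <- list(featureSpec("I1", "intensity", "gamma",
                                 params = list(shape = 2, scale = 50),
                                 perturb = list(shape = 0.5, scale = 50)))
  cfg <- simConfig(rows = 4L, cols = 6L, nNegative = 8L, nPositive = 2L,
                   cellsPerWell = c(200L, 300L), features = strongFeat,
                   hitFraction = 0.3, penetranceMean = 1,
                   penetranceSd = 0, artifact = artifactSpec(FALSE),
                   seed = 12L)
  scr <- generateScreen(cfg)
  lay <- screenLayout(scr)
  lay1 <- lay[lay$slide_id == lay$slide_id[1], ]
  tr <- truthTable(scr)
  hitGene <- tr$gene[tr$is_hit & grepl("^g", tr$gene)][1]
  hitWell <- lay1$well_id[lay1$gene == hitGene]
  negWells <- lay1$well_id[lay1$role == "negative"]
  val <- function(w) normalizeDistribution(
    wellValues(scr, lay1$slide_id[1], w, "I1"))
  # empirical null: D from resampled negative-vs-negative comparisons
  set.seed(99)
  nullD <- replicate(1000, {
    p <- sample(negWells, 2)
    ksStatistic(val(p[1]), val(p[2]))@d
  })
  dHit <- ksStatistic(val(hitWell), val(negWells[1]))@d
  expect_gt(dHit, quantile(nullD, 0.99))
})

test_that("artifacts shift well means but not normalized shapes", {
  cfgOn <- smallConfig(seed = 14, hitFraction = 0,
                       artifact = artifactSpec(TRUE))
  cfgOff <- smallConfig(seed = 14, hitFraction = 0,
                        artifact = artifactSpec(FALSE))
  on <- generateScreen(cfgOn)
  off <- generateScreen(cfgOff)
  s <- slideIds(on)[1]
  lay <- screenLayout(on)
  wells <- lay$well_id[lay$slide_id == s][1:5]
  for (w in wells) {
    vOn <- wellValues(on, s, w, "I1")
    vOff <- wellValues(off, s, w, "I1")
    # same seed, same cells: artifact is affine within the well
    expect_lt(max(abs(normalizeDistribution(vOn) -
                        normalizeDistribution(vOff))), 1e-9)
  }
  # geometry features receive no artifacts at all
  expect_identical(wellValues(on, s, wells[1], "G2"),
                   wellValues(off, s, wells[1], "G2"))
})

test_that("null screens with artifacts have calibrated test-vs-negative D*", {
  # normalized-shape D* between test and negative wells should be
  # indistinguishable from negative-pair D* when nothing is perturbed
  pvals <- vapply(1:10, function(seed) {
    scr <- generateScreen(smallConfig(seed = 100 + seed, hitFraction = 0))
    s <- slideIds(scr)[1]
    lay <- screenLayout(scr)
    lay1 <- lay[lay$slide_id == s, ]
    wells <- lapply(stats::setNames(lay1$well_id, lay1$well_id),
                    function(w) normalizeDistribution(
                      wellValues(scr, s, w, "I1")))
    negs <- lay1$well_id[lay1$role == "negative"]
    tst <- lay1$well_id[lay1$role == "test"]
    negPairs <- combn(negs, 2)
    dNeg <- apply(negPairs, 2, function(p)
      ksStatistic(wells[[p[1]]], wells[[p[2]]])@dStar)
    dTest <- as.vector(vapply(tst[1:8], function(tw)
      vapply(negs[1:4], function(nw)
        ksStatistic(wells[[tw]], wells[[nw]])@dStar, 0), numeric(4)))
    suppressWarnings(ks.test(dNeg, dTest)$p.value)
  }, 0)
  expect_gte(sum(pvals > 0.01), 9)
})

test_that("screens round-trip losslessly through text files", {
  scr <- generateScreen(smallConfig(seed = 17))
  dir <- withr::local_tempdir()
  writeScreen(scr, dir)
  back <- readScreen(dir)
  expect_equal(cellTable(back), cellTable(scr), tolerance = 0)
  expect_equal(screenLayout(back)$gene, screenLayout(scr)$gene)
  expect_equal(truthTable(back)$penetrance, truthTable(scr)$penetrance,
               tolerance = 0)
  expect_identical(featureFamily(back), featureFamily(scr))
})

test_that("schema violations are reported with the offending entity", {
  scr <- generateScreen(smallConfig(seed = 18))
  dir <- withr::local_tempdir()
  writeScreen(scr, dir)
  lay <- read.delim(file.path(dir, "layout.tsv"))
  write.table(lay[-1, ], file.path(dir, "layout.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readScreen(dir), class = "shapescreen_format")

  dir2 <- withr::local_tempdir()
  writeScreen(scr, dir2)
  cells <- readLines(file.path(dir2, "cells.tsv"))
  cells[3] <- sub("\t[0-9.e+-]+$", "\toops", cells[3])
  writeLines(cells, file.path(dir2, "cells.tsv"))
  err <- tryCatch(readScreen(dir2), error = identity)
  expect_s3_class(err, "shapescreen_format")
  expect_match(conditionMessage(err), "row 2")
})
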