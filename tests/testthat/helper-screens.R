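# Small screen configurations used throughout the unit tests: a 4 x 6
# slide keeps generation and scoring fast while preserving the full
# design (negatives, tiered positives, triplicates, artifacts).
smallConfig <- function(seed = 1L, hitFraction = 0.1,
                        cellsPerWell = c(60L, 100L), nPositive = 2L,
                        ...) {
  simConfig(rows = 4L, cols = 6L, nNegative = 8L, nPositive = nPositive,
            cellsPerWell = cellsPerWell,
            features = defaultFeatures()[c(1, 4, 5)],  # I1, G2, size
            hitFraction = hitFraction, seed = seed, ...)
}

# Tiny hand-built screen: one slide, explicit well values.
toyScreen <- function(wellValuesList, roles = NULL, rows = 1L,
                      cols = length(wellValuesList)) {
  wells <- sprintf("W%02d", seq_along(wellValuesList))
  if (is.null(roles)) roles <- rep("test", length(wells))
  cells <- do.call(rbind, lapply(seq_along(wells), function(i)
    data.frame(slide_id = "S1", well_id = wells[i],
               cell_id = seq_along(wellValuesList[[i]]),
               f1 = wellValuesList[[i]])))
  lay <- data.frame(slide_id = "S1", well_id = wells,
                    row = rep(seq_len(rows), each = cols,
                              length.out = length(wells)),
                    col = rep(seq_len(cols), times = rows,
                              length.out = length(wells)),
                    gene = paste0("g", seq_along(wells)), role = roles,
                    replicate = 1L)
  ScreenExperiment(cells, lay)
}

# Brute-force two-sample KS distance: O(n1 * n2) sup over pooled points.
bruteKsD <- function(a, b) {
  pts <- c(a, b)
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}
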