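.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a screen to a directory of delimited text files
#'
#' Writes `cells.tsv` (slide_id, well_id, cell_id, one column per
#' feature), `layout.tsv`, `features.tsv` (name, family) and, for
#' simulated screens, `truth.tsv`. Floating-point values are written with
#' 17 significant digits so the round trip through [readScreen()] is
#' lossless.
#'
#' @param screen a [ScreenExperiment-class].
#' @param dir destination directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeScreen <- function(screen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeTsv(cellTable(screen), file.path(dir, "cells.tsv"))
  .writeTsv(screenLayout(screen), file.path(dir, "layout.tsv"))
  fam <- featureFamily(screen)
  .writeTsv(data.frame(name = names(fam), family = unname(fam)),
            file.path(dir, "features.tsv"))
  if (!is.null(truthTable(screen)))
    .writeTsv(truthTable(screen), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a screen from a directory of delimited text files
#'
#' Inverse of [writeScreen()]. Schema violations are reported as format
#' errors naming the offending entity: a duplicated (slide, well, gene)
#' layout row, a well present in the cell table but missing from the
#' layout, or a non-numeric feature value (with its row index).
#'
#' @param dir directory containing `cells.tsv`, `layout.tsv`,
#'   `features.tsv` and optionally `truth.tsv`.
#' @return a [ScreenExperiment-class].
#' @export
readScreen <- function(dir) {
  pCells <- file.path(dir, "cells.tsv")
  pLay <- file.path(dir, "layout.tsv")
  pFeat <- file.path(dir, "features.tsv")
  for (p in c(pCells, pLay, pFeat))
    if (!file.exists(p)) .stop2("shapescreen_format", "missing file: %s", p)
  cells <- read.delim(pCells, colClasses = "character",
                      check.names = FALSE)
  lay <- read.delim(pLay)
  featTab <- read.delim(pFeat, colClasses = "character")
  meta <- c("slide_id", "well_id", "cell_id")
  if (!all(meta %in% colnames(cells)))
    .stop2("shapescreen_format",
           "cells.tsv must contain slide_id, well_id, cell_id")
  feats <- setdiff(colnames(cells), meta)
  for (f in feats) {
    num <- suppressWarnings(as.numeric(cells[[f]]))
    bad <- which(is.na(num) & !is.na(cells[[f]]) & cells[[f]] != "NA")
    if (length(bad))
      .stop2("shapescreen_format",
             "non-numeric value '%s' for feature '%s' at cells.tsv row %d",
             cells[[f]][bad[1]], f, bad[1])
    cells[[f]] <- num
  }
  cells$cell_id <- as.integer(cells$cell_id)
  keyL <- paste(lay$slide_id, lay$well_id)
  dup <- which(duplicated(keyL))
  if (length(dup))
    .stop2("shapescreen_format",
           "duplicate layout row %d for well (%s, %s)", dup[1],
           lay$slide_id[dup[1]], lay$well_id[dup[1]])
  keyC <- unique(paste(cells$slide_id, cells$well_id))
  miss <- setdiff(keyC, keyL)
  if (length(miss))
    .stop2("shapescreen_format",
           "well(s) in cells.tsv missing from layout.tsv: %s",
           paste(utils::head(miss, 3), collapse = ", "))
  fam <- stats::setNames(featTab$family, featTab$name)
  if (!all(feats %in% names(fam)))
    .stop2("shapescreen_format",
           "features.tsv does not cover all cell-table features")
  truth <- NULL
  if (file.exists(file.path(dir, "truth.tsv")))
    truth <- read.delim(file.path(dir, "truth.tsv"))
  ScreenExperiment(cells, lay, featureFamily = fam[feats], truth = truth)
}
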