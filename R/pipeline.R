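# End-to-end orchestration: occurrence text file in, Newick + region table
# + overlap report + Gi* table out.

#' Run the full bioregionalization pipeline
#'
#' Reads (or accepts) occurrence records, normalizes taxon names, cleans
#' coordinates, projects to the Albers plane when the records are
#' geographic, aggregates to grid cells, computes the Simpson's beta
#' turnover matrix, clusters with CWE-tie-broken WPGMA, cuts regions, and
#' optionally compares against a reference classification and scores
#' environmental correlates with Gi*. All outputs are plain text.
#'
#' @param occurrences path to an occurrence file, or a records data.frame.
#' @param grid a [GridSpec-class]; inferred from the records when NULL.
#' @param cellSize cell size (m) used when inferring the grid.
#' @param k number of regions to cut; exclusive with \code{minBranch}.
#' @param minBranch branch-length separation threshold (alternative to k).
#' @param reference optional reference classification: path to a
#'   cell-label table / polygon table, a [RegionClassification-class], or
#'   a \code{phytoPolygons} set.
#' @param env optional environmental table: path or data.frame (cell table
#'   or point-value table; see [aggregateEnv()]).
#' @param mask optional land-mask polygons (geographic) for cleaning.
#' @param outlierSd optional spatial-outlier multiplier (see
#'   [cleanRecords()]); off by default.
#' @param redundancyThreshold threshold for the redundancy report.
#' @param outDir optional output directory; when given, writes
#'   \code{regions.csv}, \code{dendrogram.nwk}, \code{matrix_triplets.csv},
#'   \code{redundancy.csv}, \code{turnover_pairs.csv}, and (when inputs
#'   allow) \code{overlap.csv} + \code{confusion.csv} and
#'   \code{gi_star.csv}.
#' @param overlapMode "plurality" or "strict" (see [overlapAgreement()]).
#' @return invisibly, a list with every intermediate object: records,
#'   cleaning log, matrix, redundancy, turnover, dendrogram,
#'   classification, diagnostics, overlap, giProfile.
#' @export
runPipeline <- function(occurrences, grid = NULL, cellSize = 100000,
                        k = NULL, minBranch = NULL,
                        reference = NULL, env = NULL, mask = NULL,
                        outlierSd = NULL, redundancyThreshold = 0.6,
                        outDir = NULL, overlapMode = "plurality") {
  records <- if (is.character(occurrences)) readOccurrences(occurrences)
             else occurrences
  records$species <- normalizeName(records$species)
  nameRejected <- which(is.na(records$species))
  records <- records[!is.na(records$species), , drop = FALSE]

  cleaned <- cleanRecords(records, mask = mask, outlierSd = outlierSd)
  records <- cleaned$records

  if (!all(c("x", "y") %in% names(records))) {
    params <- if (!is.null(grid)) grid@projection else albersParams()
    records <- projectRecords(records, params)
  }
  if (is.null(grid)) grid <- inferGrid(records, cellSize)

  mat <- gridRecords(records, grid)
  red <- redundancy(mat, threshold = redundancyThreshold)
  turn <- turnoverMatrix(mat)
  dend <- wpgma(turn, mat)
  cut <- cutRegions(dend, k = k, minBranch = minBranch)

  overlap <- NULL
  if (!is.null(reference)) {
    refClass <- if (is.character(reference)) {
      df <- utils::read.table(reference, header = TRUE,
                              sep = .sniffSep(reference),
                              stringsAsFactors = FALSE)
      if (all(c("cell", "label") %in% names(df))) readCellLabels(reference)
      else rasterizeReference(readPolygons(reference), grid)
    } else if (inherits(reference, "phytoPolygons")) {
      rasterizeReference(reference, grid)
    } else reference
    overlap <- overlapAgreement(cut$classification, refClass,
                                mode = overlapMode)
  }

  giProfile <- NULL
  if (!is.null(env)) {
    envTab <- if (is.character(env)) readEnvTable(env) else env
    envCells <- if (is(envTab, "EnvCellTable")) envTab
                else aggregateEnv(envTab, grid)
    giProfile <- regionEnvProfile(envCells, cut$classification)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCellLabels(cut$classification, file.path(outDir, "regions.csv"))
    writeLines(toNewick(dend), file.path(outDir, "dendrogram.nwk"))
    writeMatrixTriplet(mat, file.path(outDir, "matrix_triplets.csv"))
    utils::write.csv(red@perCell, file.path(outDir, "redundancy.csv"),
                     row.names = FALSE, quote = FALSE)
    writeTurnover(turn, pairsPath = file.path(outDir, "turnover_pairs.csv"))
    utils::write.csv(cut$diagnostics, file.path(outDir, "diagnostics.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(overlap)) {
      utils::write.csv(overlap@perRegion, file.path(outDir, "overlap.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(
        data.frame(reference = rownames(overlap@confusion),
                   overlap@confusion, check.names = FALSE),
        file.path(outDir, "confusion.csv"), row.names = FALSE, quote = FALSE)
      writeLines(sprintf("overall_agreement,%.6f", overlap@overallAgreement),
                 file.path(outDir, "overall_agreement.csv"))
    }
    if (!is.null(giProfile)) {
      writeGiTable(giProfile, file.path(outDir, "gi_star.csv"))
    }
  }

  invisible(list(records = records, nameRejected = nameRejected,
                 cleaningLog = cleaned$rejected, grid = grid, matrix = mat,
                 redundancy = red, turnover = turn, dendrogram = dend,
                 classification = cut$classification,
                 diagnostics = cut$diagnostics, overlap = overlap,
                 giProfile = giProfile))
}
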