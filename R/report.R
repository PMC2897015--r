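## Spreadsheet-style reporting: per-plan, per-structure DVH statistics laid
## out as four CSV sections (targets; normalized and absolute coverage of
## normal structures; Vx/min/max/mean/median statistics).

targetCoverageTokens <- c("<0.93PD", "<0.95PD", ">1.05PD", ">1.10PD",
                          ">1.15PD", ">1.20PD")
normalCoverageTokens <- c(">0.25PD", ">0.50PD", ">0.75PD", ">1.00PD")
normalVxTokens <- c("V40", "V50", "V65", "V75")

#' Compute DVH statistics for every plan/structure pair of a bundle
#'
#' Rasterizes each structure once, then for every plan builds its
#' differential and cumulative DVHs against that plan's dose grid and
#' answers the report's standard query sets: prescription-dose-fraction
#' coverages for targets, and PD-fraction coverages, Vx points and scalar
#' statistics for normal structures. Additional user queries can be merged
#' in via \code{poi}.
#'
#' @param bundle a \linkS4class{PlanBundle}.
#' @param targets regular expression selecting target structures by name.
#' @param supersample rasterization sub-sampling factor (1..4).
#' @param binWidth DVH bin width in cGy (default per-grid max/500).
#' @param poi optional extra queries (data.frame from
#'   \code{\link{parsePoiQueries}}).
#' @param patient patient label used in the report.
#' @return list of per-(plan, structure) records, each holding the labels,
#'   prescription dose, target flag, structure volume and a
#'   \linkS4class{DVHStatistics}.
#' @export
analyzeBundle <- function(bundle, targets = "^PTV", supersample = 1L,
                          binWidth = NULL, poi = NULL, patient = "CASE") {
  stopifnot(is(bundle, "PlanBundle"))
  masks <- lapply(bundle@structures, function(s)
    rasterizeStructure(s, bundle@grids[[1]], supersample))
  records <- list()
  for (p in bundle@plans) {
    grid <- bundle@grids[[p@planId]]
    pd <- p@prescriptionDose
    for (nm in names(masks)) {
      isTarget <- grepl(targets, nm)
      tokens <- if (isTarget) targetCoverageTokens
                else c(normalCoverageTokens, normalVxTokens,
                       "min", "max", "mean", "median")
      q <- parsePoiQueries(tokens, pd)
      if (!is.null(poi) && nrow(poi)) q <- rbind(q, poi)
      ddvh <- computeDDVH(grid, masks[[nm]], binWidth)
      cdvh <- cumulate(ddvh)
      stats <- suppressWarnings(dvhStatistics(cdvh, ddvh, q, pd))
      records[[length(records) + 1L]] <- list(
        patient = patient, plan = p@planId, pd = pd, structure = nm,
        isTarget = isTarget, volume = cdvh@totalVolume, stats = stats)
    }
  }
  records
}

pctCell <- function(frac) sprintf("%d%%", percentHalfUp(frac))
numCell <- function(x) sprintf("%.1f", x)

queryRow <- function(stats, token) {
  q <- stats@queries
  i <- match(token, q$token)
  if (is.na(i)) stop(sprintf("report needs query '%s' but it was not computed", token))
  q[i, ]
}

#' Write the four-section spreadsheet report
#'
#' Section A: target min/max/mean/volume plus absolute and normalized
#' coverage at prescription-dose fractions. Sections B and C: normalized and
#' absolute coverage of normal structures at PD fractions. Section D: Vx
#' points and min/max/mean/median per normal structure per plan. Percent
#' cells are rounded half-up to whole percents; the output is
#' byte-deterministic for identical inputs.
#'
#' @param results record list from \code{\link{analyzeBundle}}.
#' @param path output directory (created if missing).
#' @return invisible character vector of the files written.
#' @export
writeReport <- function(results, path) {
  if (!length(results)) stop("no results to report")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tg <- Filter(function(r) r$isTarget, results)
  nr <- Filter(function(r) !r$isTarget, results)
  files <- character()

  ## Section A — targets
  fa <- file.path(path, "report_A_targets.csv")
  rows <- c(paste(c("Patient", "Trial", "PD_cGy", "Min_cGy", "Max_cGy",
                    "Mean_cGy", "Volume_cc",
                    paste0("cc:", targetCoverageTokens),
                    paste0("pct:", targetCoverageTokens)), collapse = ","))
  for (r in tg) {
    s <- r$stats
    cc <- vapply(targetCoverageTokens,
                 function(tk) queryRow(s, tk)$volume_cc, numeric(1))
    rows <- c(rows, paste(c(r$patient, r$plan, numCell(r$pd), numCell(s@minDose),
                            numCell(s@maxDose), numCell(s@meanDose),
                            numCell(r$volume), numCell(cc),
                            pctCell(cc / r$volume)), collapse = ","))
  }
  writeLines(rows, fa); files <- c(files, fa)

  ## Sections B (normalized %) and C (absolute cc) — normal structures
  for (sec in c("B", "C")) {
    f <- file.path(path, sprintf("report_%s_%s.csv", sec,
                                 if (sec == "B") "normalized" else "absolute"))
    rows <- c(paste(c("Patient", "Structure", "Trial", normalCoverageTokens),
                    collapse = ","))
    for (r in nr) {
      cells <- vapply(normalCoverageTokens, function(tk) {
        q <- queryRow(r$stats, tk)
        if (sec == "B") pctCell(q$volume_pct / 100) else numCell(q$volume_cc)
      }, character(1))
      rows <- c(rows, paste(c(r$patient, r$structure, r$plan, cells),
                            collapse = ","))
    }
    writeLines(rows, f); files <- c(files, f)
  }

  ## Section D — Vx and scalar statistics for normal structures
  fd <- file.path(path, "report_D_statistics.csv")
  rows <- c(paste(c("Patient", "Structure", "Trial", normalVxTokens,
                    "MIN", "MAX", "MEAN", "MEDIAN"), collapse = ","))
  for (r in nr) {
    s <- r$stats
    vx <- vapply(normalVxTokens,
                 function(tk) pctCell(queryRow(s, tk)$volume_pct / 100),
                 character(1))
    rows <- c(rows, paste(c(r$patient, r$structure, r$plan, vx,
                            numCell(s@minDose), numCell(s@maxDose),
                            numCell(s@meanDose), numCell(s@medianDose)),
                          collapse = ","))
  }
  writeLines(rows, fd); files <- c(files, fd)
  invisible(files)
}
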