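## Plan-bundle exchange dialect (plain text).
##
## A bundle is a directory holding:
##   header.txt            plans + prescription doses, structure roster,
##                         grid geometry, file cross-references
##   dose_<planid>.txt     ASCII dose values in cGy, x fastest then y then z
##                         (slice-major), one value per whitespace token
##   contour_<name>.txt    per-slice closed rings: z position, then x,y pairs
##
## All floating point values are written with 17 significant digits so a
## write/read round trip reproduces the numbers bit-for-bit.

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a plan bundle to a directory
#'
#' @param bundle a \linkS4class{PlanBundle}.
#' @param path directory (created if missing).
#' @return the path, invisibly.
#' @export
writePlanBundle <- function(bundle, path) {
  stopifnot(is(bundle, "PlanBundle"))
  validObject(bundle)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- bundle@grids[[1]]
  hdr <- c("PLANDVH-BUNDLE 1",
           paste("GRID ORIGIN", paste(fmtNum(g@origin), collapse = " ")),
           paste("GRID SPACING", paste(fmtNum(g@spacing), collapse = " ")),
           paste("GRID DIMS", paste(g@dims, collapse = " ")))
  for (p in bundle@plans) {
    line <- sprintf("PLAN %s PD %s DOSEFILE dose_%s.txt", p@planId,
                    fmtNum(p@prescriptionDose), p@planId)
    if (length(p@components))
      line <- paste0(line, " COMPONENTS ", paste(p@components, collapse = ","))
    hdr <- c(hdr, line)
  }
  for (s in bundle@structures)
    hdr <- c(hdr, sprintf("STRUCTURE %s FILE contour_%s.txt", s@name, s@name))
  writeLines(hdr, file.path(path, "header.txt"))

  for (p in bundle@plans) {
    gp <- bundle@grids[[p@planId]]
    con <- file(file.path(path, sprintf("dose_%s.txt", p@planId)), "w")
    writeLines(fmtNum(as.vector(gp@dose)), con)
    close(con)
  }
  for (s in bundle@structures) {
    lines <- character()
    for (sl in s@slices) {
      lines <- c(lines, sprintf("SLICE %s %d", fmtNum(sl$z), length(sl$rings)))
      for (r in sl$rings) {
        lines <- c(lines, sprintf("RING %d", nrow(r)),
                   paste(fmtNum(r[, 1]), fmtNum(r[, 2])))
      }
    }
    writeLines(lines, file.path(path, sprintf("contour_%s.txt", s@name)))
  }
  invisible(path)
}

#' Read a plan bundle from a directory
#'
#' Validates the header, resolves every cross-reference (plan to dose file,
#' structure to contour file), checks the dose grids against the declared
#' dimensions and returns a validated \linkS4class{PlanBundle}.
#'
#' @param path bundle directory.
#' @return A \linkS4class{PlanBundle}.
#' @export
readPlanBundle <- function(path) {
  hf <- file.path(path, "header.txt")
  if (!dir.exists(path) || !file.exists(hf))
    stop("bundle malformed: missing header.txt under ", path)
  lines <- readLines(hf, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "PLANDVH-BUNDLE"))
    stop("bundle malformed: bad magic line")

  origin <- spacing <- NULL; dims <- NULL
  plans <- list(); doseFiles <- character()
  structs <- character(); structFiles <- character()
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || !nzchar(tok[1])) next
    if (tok[1] == "GRID") {
      val <- as.numeric(tok[-(1:2)])
      if (tok[2] == "ORIGIN") origin <- val
      else if (tok[2] == "SPACING") spacing <- val
      else if (tok[2] == "DIMS") dims <- as.integer(val)
    } else if (tok[1] == "PLAN") {
      if (length(tok) < 6L || tok[3] != "PD" || tok[5] != "DOSEFILE")
        stop("bundle malformed: bad PLAN line: ", ln)
      comp <- character()
      if (length(tok) >= 8L && tok[7] == "COMPONENTS")
        comp <- strsplit(tok[8], ",")[[1]]
      plans[[length(plans) + 1L]] <- PlanRecord(tok[2], as.numeric(tok[4]), comp)
      doseFiles[tok[2]] <- tok[6]
    } else if (tok[1] == "STRUCTURE") {
      if (length(tok) < 4L || tok[3] != "FILE")
        stop("bundle malformed: bad STRUCTURE line: ", ln)
      structs <- c(structs, tok[2]); structFiles[tok[2]] <- tok[4]
    } else stop("bundle malformed: unknown header record: ", tok[1])
  }
  if (is.null(origin) || is.null(spacing) || is.null(dims) || !length(plans))
    stop("bundle malformed: header incomplete")

  grids <- list()
  for (p in plans) {
    df <- file.path(path, doseFiles[p@planId])
    if (!file.exists(df))
      stop("grid inconsistent: missing dose file ", doseFiles[p@planId])
    vals <- scan(df, what = double(), quiet = TRUE)
    if (length(vals) != prod(dims))
      stop(sprintf("grid inconsistent: %d dose values, header declares %d",
                   length(vals), prod(dims)))
    grids[[p@planId]] <- DoseGrid(array(vals, dims), origin, spacing)
  }

  structures <- list()
  for (nm in structs) {
    cf <- file.path(path, structFiles[nm])
    if (!file.exists(cf))
      stop("dangling structure: missing contour file for ", nm)
    structures[[length(structures) + 1L]] <- readContourFile(cf, nm)
  }

  PlanBundle(plans = plans, structures = structures, grids = grids)
}

readContourFile <- function(cf, name) {
  lines <- readLines(cf, warn = FALSE)
  slices <- list(); i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(tok) || !nzchar(tok[1])) { i <- i + 1L; next }
    if (tok[1] != "SLICE") stop("bundle malformed: expected SLICE in ", cf)
    z <- as.numeric(tok[2]); nr <- as.integer(tok[3])
    i <- i + 1L
    rings <- vector("list", nr)
    for (r in seq_len(nr)) {
      rtok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (rtok[1] != "RING") stop("bundle malformed: expected RING in ", cf)
      np <- as.integer(rtok[2])
      pts <- matrix(NA_real_, np, 2)
      for (k in seq_len(np)) {
        xy <- as.numeric(strsplit(trimws(lines[i + k]), "\\s+")[[1]])
        pts[k, ] <- xy[1:2]
      }
      rings[[r]] <- pts
      i <- i + np + 1L
    }
    slices[[length(slices) + 1L]] <- list(z = z, rings = rings)
  }
  StructureContours(name, slices)
}

#' Parse a point-of-interest query configuration
#'
#' One query token per line or comma-separated. Grammar:
#' \itemize{
#'   \item \code{V<x>} — volume receiving at least x Gy (e.g. \code{V40});
#'   \item \code{D<x>} — dose received by x\% of the volume (e.g. \code{D95});
#'   \item \code{><f>PD} / \code{<<f>PD} — volume above/below the fraction f
#'     of the prescription dose (e.g. \code{>0.25PD}, \code{<0.95PD});
#'   \item \code{min}, \code{max}, \code{mean}, \code{median}.
#' }
#'
#' @param path config file, or a character vector of tokens.
#' @param pd optional prescription dose (cGy); when given, PD-relative
#'   thresholds are also resolved to absolute cGy in \code{dose_cGy}.
#' @return data.frame with columns token, type, value, dose_cGy.
#' @examples
#' parsePoiQueries(c("V40", "D95", ">0.25PD"), pd = 3900)
#' @export
readPoiConfig <- function(path, pd = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  tokens <- unlist(strsplit(lines, "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  parsePoiQueries(tokens, pd)
}

#' @rdname readPoiConfig
#' @param tokens character vector of query tokens.
#' @export
parsePoiQueries <- function(tokens, pd = NA_real_) {
  if (!length(tokens))
    return(data.frame(token = character(), type = character(),
                      value = numeric(), dose_cGy = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(tokens, function(tk) {
    low <- tolower(tk)
    if (low %in% c("min", "max", "mean", "median"))
      return(data.frame(token = low, type = "scalar", value = NA_real_,
                        dose_cGy = NA_real_, stringsAsFactors = FALSE))
    if (grepl("^V[0-9.]+$", tk)) {
      gy <- as.numeric(sub("^V", "", tk))
      return(data.frame(token = tk, type = "volume_at_dose", value = 100 * gy,
                        dose_cGy = 100 * gy, stringsAsFactors = FALSE))
    }
    if (grepl("^D[0-9.]+$", tk)) {
      pct <- as.numeric(sub("^D", "", tk))
      return(data.frame(token = tk, type = "dose_at_volume", value = pct,
                        dose_cGy = NA_real_, stringsAsFactors = FALSE))
    }
    if (grepl("^[<>][0-9.]+PD$", tk)) {
      f <- as.numeric(sub("PD$", "", substring(tk, 2)))
      type <- if (startsWith(tk, ">")) "coverage_above" else "coverage_below"
      return(data.frame(token = tk, type = type, value = f,
                        dose_cGy = if (is.na(pd)) NA_real_ else f * pd,
                        stringsAsFactors = FALSE))
    }
    stop(sprintf("cannot parse query token '%s'", tk))
  })
  do.call(rbind, rows)
}
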