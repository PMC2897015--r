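## Differential / cumulative DVH construction and statistics extraction.
##
## Binning model: uniform half-open bins [lo, hi); a voxel's (possibly
## fractional) volume is accumulated into the bin containing its dose, and
## the exact dose moment (dose x volume) is accumulated alongside, so mean,
## minimum and maximum dose are independent of the bin width. The cumulative
## curve treats each bin's volume as uniformly spread across the bin, giving
## an exact value at every bin edge and linear behavior inside a bin.

#' Build a differential DVH
#'
#' Accumulates each member voxel's (fractional) volume into the dose bin
#' containing its dose. The default bin width is (max grid dose)/500, the
#' convention that yields 501 cumulative sampling points.
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @param mask a \linkS4class{StructureMask} on the same lattice.
#' @param binWidth bin width in cGy; default \code{max(dose)/500}.
#' @return A \linkS4class{DifferentialDVH}.
#' @examples
#' g <- DoseGrid(array(5000, c(5, 5, 8)))
#' d <- computeDDVH(g, wholeGridMask(g))
#' sum(binVolumes(d)) - maskVolume(wholeGridMask(g))  # conserved
#' @export
computeDDVH <- function(grid, mask, binWidth = NULL) {
  stopifnot(is(grid, "DoseGrid"), is(mask, "StructureMask"))
  if (!identical(dim(mask@weight), dim(grid@dose)))
    stop("mask and grid lattices differ")
  sel <- mask@weight > 0
  if (!any(sel)) stop("empty structure")
  d <- grid@dose[sel]
  wv <- mask@weight[sel] * mask@voxelVolume
  if (is.null(binWidth)) {
    gmax <- max(grid@dose)
    if (gmax <= 0) gmax <- 1
    binWidth <- gmax / 500
  }
  if (binWidth <= 0) stop("bin width must be positive")
  idx <- floor(d / binWidth) + 1L
  nb <- max(idx)
  vol <- numeric(nb); mom <- numeric(nb)
  agg <- rowsum(cbind(wv, wv * d), idx)
  at <- as.integer(rownames(agg))
  vol[at] <- agg[, 1]; mom[at] <- agg[, 2]
  new("DifferentialDVH", breaks = (0:nb) * binWidth, volume = vol,
      moment = mom, doseRange = range(d))
}

#' Cumulative DVH from a differential DVH
#'
#' V(d) is the volume receiving at least dose d, with each bin's volume
#' spread uniformly across the bin; the curve is exact at every bin edge and
#' piecewise linear in between. By default it is resampled onto 501 evenly
#' spaced dose points spanning [0, max dose].
#'
#' @param ddvh a \linkS4class{DifferentialDVH}.
#' @param nPoints number of evenly spaced dose samples (default 501).
#' @return A \linkS4class{CumulativeDVH}.
#' @export
cumulate <- function(ddvh, nPoints = 501L) {
  stopifnot(is(ddvh, "DifferentialDVH"))
  edges <- ddvh@breaks
  # exact cumulative volume at each bin edge
  vAtEdge <- c(rev(cumsum(rev(ddvh@volume))), 0)
  dq <- seq(0, edges[length(edges)], length.out = as.integer(nPoints))
  vq <- stats::approx(edges, vAtEdge, xout = dq, rule = 2)$y
  new("CumulativeDVH", dose = dq, volume = vq, totalVolume = sum(ddvh@volume))
}

#' Evaluate a cumulative DVH at arbitrary doses
#'
#' Linear interpolation between the stored samples; doses below the first
#' sample return the total volume, doses beyond the last return 0.
#'
#' @param cdvh a \linkS4class{CumulativeDVH}.
#' @param dose doses in cGy.
#' @param relative if TRUE return the fraction of total volume instead of cc.
#' @return volumes (cc, or fraction of total).
#' @export
volumeAtDose <- function(cdvh, dose, relative = FALSE) {
  stopifnot(is(cdvh, "CumulativeDVH"))
  v <- stats::approx(cdvh@dose, cdvh@volume, xout = dose, rule = 2)$y
  v[dose > max(cdvh@dose)] <- 0
  v[dose < min(cdvh@dose)] <- cdvh@totalVolume
  if (relative) v / cdvh@totalVolume else v
}

#' Fraction-of-total view of a cumulative DVH
#' @param cdvh a \linkS4class{CumulativeDVH}.
#' @return numeric vector of volume fractions parallel to \code{dosePoints(cdvh)}.
#' @export
relativeVolume <- function(cdvh) cdvh@volume / cdvh@totalVolume

#' Extract DVH statistics
#'
#' Minimum, maximum and mean dose come from the differential DVH's exact
#' dose range and first moment. The median is D50 obtained by inverse lookup
#' on the smoothed cumulative curve (falling back to linear interpolation
#' when the curve is too short to smooth). Point-of-interest queries follow
#' the grammar of \code{\link{readPoiConfig}}: volume at an absolute dose
#' (Vx), dose at a volume level (Dx), and coverage above/below a fraction of
#' the prescription dose. Queries outside the curve range are clamped and
#' flagged, never extrapolated.
#'
#' @param cdvh a \linkS4class{CumulativeDVH}.
#' @param ddvh the matching \linkS4class{DifferentialDVH}.
#' @param queries data.frame as returned by \code{\link{readPoiConfig}}, or NULL.
#' @param pd prescription dose in cGy (needed for PD-relative queries).
#' @return A \linkS4class{DVHStatistics}.
#' @export
dvhStatistics <- function(cdvh, ddvh, queries = NULL, pd = NA_real_) {
  stopifnot(is(cdvh, "CumulativeDVH"), is(ddvh, "DifferentialDVH"))
  total <- cdvh@totalVolume
  mn <- ddvh@doseRange[1]; mx <- ddvh@doseRange[2]
  mean_ <- sum(ddvh@moment) / sum(ddvh@volume)

  sm <- if (length(cdvh@dose) >= 7L) smoothCDVH(cdvh) else NULL
  # inverse lookups carry half-a-bin resolution; clamp them to the exact
  # observed dose range so Dx can never leave [min, max]
  invDose <- function(frac) min(max(invDoseRaw(frac), mn), mx)
  invDoseRaw <- function(frac) {
    if (!is.null(sm)) doseAtVolume(sm, frac)
    else {
      # short-curve fallback: invert the piecewise-linear sampled curve
      target <- frac * total
      i <- which(cdvh@volume <= target)[1]
      if (is.na(i)) return(max(cdvh@dose))
      if (i == 1L) return(cdvh@dose[1])
      v1 <- cdvh@volume[i - 1L]; v2 <- cdvh@volume[i]
      if (v1 == v2) return(cdvh@dose[i])
      cdvh@dose[i - 1L] + (v1 - target) / (v1 - v2) * diff(cdvh@dose[(i - 1L):i])
    }
  }
  med <- invDose(0.5)

  clamped <- FALSE
  qdf <- data.frame(token = character(), kind = character(),
                    dose_cGy = numeric(), volume_cc = numeric(),
                    volume_pct = numeric(), value = numeric(),
                    stringsAsFactors = FALSE)
  if (!is.null(queries) && nrow(queries)) {
    rows <- vector("list", nrow(queries))
    for (q in seq_len(nrow(queries))) {
      type <- queries$type[q]; val <- queries$value[q]
      token <- queries$token[q]
      dose <- vol <- pct <- ans <- NA_real_
      if (type == "volume_at_dose") {
        dose <- val
        if (dose > max(cdvh@dose)) clamped <- TRUE
        vol <- volumeAtDose(cdvh, dose)
        pct <- 100 * vol / total
        ans <- pct
      } else if (type == "dose_at_volume") {
        frac <- val / 100
        if (frac <= 0 || frac > 1) { clamped <- TRUE; frac <- min(max(frac, 1e-9), 1) }
        dose <- invDose(frac)
        ans <- dose
      } else if (type %in% c("coverage_above", "coverage_below")) {
        if (is.na(pd)) stop(sprintf("query '%s' needs a prescription dose", token))
        dose <- val * pd
        if (dose > max(cdvh@dose)) clamped <- TRUE
        vabove <- volumeAtDose(cdvh, dose)
        vol <- if (type == "coverage_above") vabove else total - vabove
        pct <- 100 * vol / total
        ans <- pct
      } else if (type == "scalar") {
        ans <- switch(token, min = mn, max = mx, mean = mean_, median = med)
        dose <- ans
      } else stop(sprintf("unknown query type '%s'", type))
      rows[[q]] <- data.frame(token = token, kind = type, dose_cGy = dose,
                              volume_cc = vol, volume_pct = pct, value = ans,
                              stringsAsFactors = FALSE)
    }
    qdf <- do.call(rbind, rows)
  }
  if (clamped)
    warning("one or more queries fell outside the DVH range and were clamped")
  new("DVHStatistics", minDose = mn, maxDose = mx, meanDose = mean_,
      medianDose = med, totalVolume = total, queries = qdf, clamped = clamped)
}

#' Convert a differential DVH to the fractional form used by TCP/NTCP models
#'
#' Nonzero bins become (Di, vi) pairs with Di the bin midpoint dose and vi
#' the bin's fraction of total volume.
#'
#' @param ddvh a \linkS4class{DifferentialDVH}.
#' @return A \linkS4class{FractionalDVH}.
#' @export
asFractionalDVH <- function(ddvh) {
  stopifnot(is(ddvh, "DifferentialDVH"))
  keep <- ddvh@volume > 0
  FractionalDVH(binMidpoints(ddvh)[keep], ddvh@volume[keep] / sum(ddvh@volume))
}

#' Round a fraction to a whole percent, half away from zero
#'
#' Display rule for percent cells in spreadsheet reports: 0.469 becomes 47.
#'
#' @param frac fraction(s) in [0, 1].
#' @return integer percent value(s).
#' @export
percentHalfUp <- function(frac) as.integer(floor(100 * frac + 0.5))
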