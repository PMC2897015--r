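#' @import methods
NULL

## Units used throughout: dose in cGy, lengths in mm, volumes in cc.
## Voxel indexing is 0-based in the coordinate convention: the center of
## voxel (0,0,0) sits at `origin`, and voxel (i,j,k) at origin + (i,j,k)*spacing.

#' Regular 3D dose lattice
#'
#' A rectilinear voxel grid of absorbed dose. Dose values are stored in a
#' 3D array indexed \code{[x, y, z]}; the grid geometry (origin, spacing)
#' is in patient millimeters and the origin is the center of the first voxel.
#'
#' @slot origin numeric(3), mm; center of voxel (0,0,0).
#' @slot spacing numeric(3), mm; all components strictly positive.
#' @slot dims integer(3), voxel counts per axis.
#' @slot dose 3D numeric array of dose in cGy, dimensions equal to \code{dims}.
#' @export
setClass("DoseGrid", representation(
  origin = "numeric", spacing = "numeric", dims = "integer", dose = "array"
))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be 3 positive voxel counts")
  if (!identical(dim(object@dose), as.integer(object@dims)))
    msg <- c(msg, "dose array dimensions do not match dims")
  if (any(!is.finite(object@dose)) || any(object@dose < 0))
    msg <- c(msg, "dose values must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseGrid
#'
#' @param dose 3D array of dose values (cGy), dimension \code{[nx, ny, nz]}.
#' @param origin numeric(3) mm, center of the first voxel.
#' @param spacing numeric(3) mm.
#' @return A \linkS4class{DoseGrid}.
#' @examples
#' g <- DoseGrid(array(100, c(4, 4, 2)), origin = c(0, 0, 0), spacing = c(2, 2, 3))
#' voxelVolume(g)  # 2*2*3 mm^3 = 0.012 cc
#' @export
DoseGrid <- function(dose, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  new("DoseGrid", origin = as.numeric(origin), spacing = as.numeric(spacing),
      dims = as.integer(dim(dose)), dose = dose)
}

#' Named structure as closed planar contours
#'
#' One region of interest given as closed polygon rings per axial (CT) slice.
#' Each slice is a list with elements \code{z} (mm) and \code{rings}, a list
#' of n-by-2 matrices of (x, y) vertices in mm. Rings are implicitly closed
#' (last vertex connects back to the first); nested rings produce holes under
#' the even-odd rasterization rule.
#'
#' @slot name character scalar, unique within a bundle.
#' @slot slices list of \code{list(z =, rings =)} entries.
#' @export
setClass("StructureContours", representation(name = "character", slices = "list"))

setValidity("StructureContours", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a non-empty string")
  for (sl in object@slices) {
    if (!is.list(sl) || is.null(sl$z) || is.null(sl$rings))
      return("each slice must be list(z=, rings=)")
    for (r in sl$rings) {
      if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L)
        return("each ring must be an n-by-2 matrix with >= 3 vertices")
    }
  }
  TRUE
})

#' @rdname StructureContours-class
#' @param name structure name.
#' @param slices list of \code{list(z =, rings =)} entries.
#' @export
StructureContours <- function(name, slices) {
  new("StructureContours", name = name, slices = slices)
}

#' Voxel-membership rasterization of a structure
#'
#' Fractional membership weights per voxel of a \linkS4class{DoseGrid}.
#' With supersampling the weight is the fraction of sub-voxel sample points
#' inside the contour polygons; with \code{supersample = 1} weights are 0/1.
#'
#' @slot weight 3D numeric array in [0, 1], same dimensions as the grid.
#' @slot voxelVolume voxel volume in cc.
#' @slot name structure name the mask was built from.
#' @export
setClass("StructureMask", representation(
  weight = "array", voxelVolume = "numeric", name = "character"
))

setValidity("StructureMask", function(object) {
  if (any(object@weight < 0) || any(object@weight > 1))
    return("membership weights must lie in [0, 1]")
  if (object@voxelVolume <= 0) return("voxel volume must be positive")
  TRUE
})

#' Differential dose-volume histogram
#'
#' Volume binned by dose on a uniform grid of bin edges. In addition to the
#' per-bin volumes, the exact per-bin first dose moments and the observed
#' dose range are retained, so mean, minimum and maximum dose are recovered
#' exactly regardless of bin width.
#'
#' @slot breaks bin edges in cGy, uniform width, length nbins + 1.
#' @slot volume cc per bin, length nbins.
#' @slot moment per-bin sum of dose x volume (cGy cc), length nbins.
#' @slot doseRange observed (min, max) voxel dose in cGy.
#' @export
setClass("DifferentialDVH", representation(
  breaks = "numeric", volume = "numeric", moment = "numeric", doseRange = "numeric"
))

setValidity("DifferentialDVH", function(object) {
  nb <- length(object@breaks) - 1L
  if (nb < 1L) return("need at least one bin")
  w <- diff(object@breaks)
  if (any(w <= 0) || diff(range(w)) > 1e-9 * mean(w))
    return("bin edges must be ascending with uniform width")
  if (length(object@volume) != nb || length(object@moment) != nb)
    return("volume and moment must have one value per bin")
  if (any(object@volume < -1e-12)) return("bin volumes must be non-negative")
  TRUE
})

#' Cumulative dose-volume histogram
#'
#' Volume receiving at least a given dose, sampled at ascending dose points.
#'
#' @slot dose ascending dose points in cGy.
#' @slot volume cc at or above each dose point; non-increasing.
#' @slot totalVolume structure volume in cc (value of the curve at dose 0).
#' @export
setClass("CumulativeDVH", representation(
  dose = "numeric", volume = "numeric", totalVolume = "numeric"
))

setValidity("CumulativeDVH", function(object) {
  if (length(object@dose) != length(object@volume))
    return("dose and volume must have equal length")
  if (is.unsorted(object@dose, strictly = TRUE))
    return("dose points must be strictly ascending")
  if (any(diff(object@volume) > 1e-9 * max(object@totalVolume, 1)))
    return("cumulative volume must be non-increasing in dose")
  TRUE
})

#' Piecewise-polynomial smoothed cDVH
#'
#' Continuous model of a cumulative DVH: between each pair of adjacent
#' samples a cosine-interpolated midpoint is synthesized and a least-squares
#' polynomial is fit over that midpoint plus the six nearest samples. The
#' per-window coefficients are retained together with a dense monotone
#' evaluation table used for fast queries and inverse lookup.
#'
#' @slot dose,volume the original cDVH samples.
#' @slot totalVolume structure volume (cc).
#' @slot windows per-interval list of \code{list(center, coef, degree)}.
#' @slot tableDose,tableVolume dense monotone evaluation table.
#' @export
setClass("SmoothedCDVH", representation(
  dose = "numeric", volume = "numeric", totalVolume = "numeric",
  windows = "list", tableDose = "numeric", tableVolume = "numeric"
))

#' DVH summary statistics
#'
#' @slot minDose,maxDose,meanDose,medianDose cGy.
#' @slot totalVolume cc.
#' @slot queries data.frame of answered point-of-interest queries.
#' @slot clamped logical; TRUE if any query fell outside the curve range and
#'   was clamped rather than extrapolated.
#' @export
setClass("DVHStatistics", representation(
  minDose = "numeric", maxDose = "numeric", meanDose = "numeric",
  medianDose = "numeric", totalVolume = "numeric",
  queries = "data.frame", clamped = "logical"
))

setValidity("DVHStatistics", function(object) {
  eps <- 1e-6 * max(object@maxDose, 1)
  if (object@minDose > object@medianDose + eps ||
      object@medianDose > object@maxDose + eps)
    return("min <= median <= max violated")
  if (object@meanDose < object@minDose - eps ||
      object@meanDose > object@maxDose + eps)
    return("mean must lie within [min, max]")
  TRUE
})

#' Spatial (per-slice) differential DVH
#'
#' One differential DVH per axial slice containing member voxels, all sharing
#' the same bin edges. Summing the entries bin-by-bin over z reproduces the
#' whole-structure differential DVH exactly.
#'
#' @slot z slice positions in mm (slices with member voxels only).
#' @slot entries list of \linkS4class{DifferentialDVH}, parallel to \code{z}.
#' @export
setClass("ZDVH", representation(z = "numeric", entries = "list"))

#' Dose-surface histogram
#'
#' Differential DVH restricted to the structure's boundary voxels (member
#' voxels with at least one of their six face neighbors outside the mask or
#' outside the grid).
#'
#' @slot ddvh the surface \linkS4class{DifferentialDVH}.
#' @slot surfaceVoxels number of boundary voxels.
#' @export
setClass("DSH", representation(ddvh = "DifferentialDVH", surfaceVoxels = "integer"))

#' Plan record
#'
#' @slot planId text label, e.g. "PTV1" or "COMPOSITE".
#' @slot prescriptionDose prescription dose in cGy, > 0.
#' @slot components for a composite plan, the component plan ids (else empty).
#' @export
setClass("PlanRecord", representation(
  planId = "character", prescriptionDose = "numeric", components = "character"
))

setValidity("PlanRecord", function(object) {
  if (length(object@prescriptionDose) != 1L || object@prescriptionDose <= 0)
    return("prescription dose must be a single positive value (cGy)")
  TRUE
})

#' @rdname PlanRecord-class
#' @param planId plan label.
#' @param prescriptionDose cGy.
#' @param components component plan ids for a composite plan.
#' @export
PlanRecord <- function(planId, prescriptionDose, components = character()) {
  new("PlanRecord", planId = planId, prescriptionDose = as.numeric(prescriptionDose),
      components = components)
}

#' A complete plan bundle
#'
#' Plans with prescription doses, named structures as contours, and one dose
#' grid per plan.
#'
#' @slot plans list of \linkS4class{PlanRecord}.
#' @slot structures named list of \linkS4class{StructureContours}.
#' @slot grids named list of \linkS4class{DoseGrid}, one per plan id.
#' @export
setClass("PlanBundle", representation(
  plans = "list", structures = "list", grids = "list"
))

setValidity("PlanBundle", function(object) {
  ids <- vapply(object@plans, function(p) p@planId, character(1))
  if (anyDuplicated(ids)) return("plan ids must be unique")
  snames <- vapply(object@structures, function(s) s@name, character(1))
  if (anyDuplicated(snames)) return("structure names must be unique")
  if (!all(ids %in% names(object@grids)))
    return("every plan needs a dose grid keyed by its plan id")
  for (p in object@plans) {
    if (length(p@components)) {
      if (!all(p@components %in% ids))
        return(sprintf("composite plan %s references unknown components", p@planId))
      pd <- sum(vapply(object@plans[match(p@components, ids)],
                       function(q) q@prescriptionDose, numeric(1)))
      if (abs(pd - p@prescriptionDose) > 1e-6 * pd)
        return(sprintf("composite %s prescription must equal sum of components", p@planId))
    }
  }
  TRUE
})

#' @rdname PlanBundle-class
#' @param plans list of \linkS4class{PlanRecord}.
#' @param structures list of \linkS4class{StructureContours}.
#' @param grids named list of \linkS4class{DoseGrid} keyed by plan id.
#' @export
PlanBundle <- function(plans, structures, grids) {
  names(structures) <- vapply(structures, function(s) s@name, character(1))
  new("PlanBundle", plans = plans, structures = structures, grids = grids)
}

#' Fractional differential DVH for radiobiological models
#'
#' Pairs (Di, vi) with volume fractions summing to one.
#'
#' @slot dose bin doses Di in cGy.
#' @slot volfrac fractional volumes vi, non-negative, sum to 1 within 1e-9.
#' @export
setClass("FractionalDVH", representation(dose = "numeric", volfrac = "numeric"))

setValidity("FractionalDVH", function(object) {
  if (length(object@dose) != length(object@volfrac))
    return("dose and volfrac must have equal length")
  if (any(object@volfrac < 0)) return("volume fractions must be non-negative")
  if (any(object@dose < 0)) return("doses must be non-negative")
  if (abs(sum(object@volfrac) - 1) > 1e-9)
    return("volume fractions must sum to 1 (within 1e-9)")
  TRUE
})

#' @rdname FractionalDVH-class
#' @param dose bin doses in cGy.
#' @param volfrac fractional volumes.
#' @export
FractionalDVH <- function(dose, volfrac) {
  new("FractionalDVH", dose = as.numeric(dose), volfrac = as.numeric(volfrac))
}

#' Poisson TCP model parameters
#'
#' @slot tcd50 dose at 50\% tumor control, cGy.
#' @slot gamma50 normalized dose-response slope at 50\% control.
#' @export
setClass("TCPParams", representation(tcd50 = "numeric", gamma50 = "numeric"))

setValidity("TCPParams", function(object) {
  if (object@tcd50 <= 0) return("TCD50 must be positive")
  if (object@gamma50 <= 0) return("gamma50 must be positive")
  TRUE
})

#' @rdname TCPParams-class
#' @param tcd50 cGy.
#' @param gamma50 dimensionless slope.
#' @export
TCPParams <- function(tcd50, gamma50) new("TCPParams", tcd50 = tcd50, gamma50 = gamma50)

#' Lyman NTCP model parameters
#'
#' @slot td50 dose at 50\% complication, cGy.
#' @slot m slope parameter of the sigmoid dose response.
#' @slot n volume-dependence exponent in (0, 1].
#' @export
setClass("NTCPParams", representation(td50 = "numeric", m = "numeric", n = "numeric"))

setValidity("NTCPParams", function(object) {
  if (object@td50 <= 0) return("TD50 must be positive")
  if (object@m <= 0) return("m must be positive")
  if (object@n <= 0 || object@n > 1) return("n must lie in (0, 1]")
  TRUE
})

#' @rdname NTCPParams-class
#' @param td50 cGy.
#' @param m slope parameter.
#' @param n volume-dependence exponent.
#' @export
NTCPParams <- function(td50, m, n) new("NTCPParams", td50 = td50, m = m, n = n)

#' Dose/volume quantities feeding the plan-index set
#'
#' @slot ptv planning target volume, cc.
#' @slot ptvPD,ptv95PD,ptv50PD target volume covered at PD, 0.95 PD, 0.50 PD (cc).
#' @slot piv prescription isodose volume over the whole grid, cc.
#' @slot dmax,d95,d5 maximum dose and dose at 95\%/5\% target volume, cGy.
#' @slot pd prescription dose, cGy.
#' @slot oarFractions fractional OAR volumes at or above their tolerance doses.
#' @slot oarWeights per-OAR weights (default 1/N each).
#' @export
setClass("UPIInputs", representation(
  ptv = "numeric", ptvPD = "numeric", ptv95PD = "numeric", ptv50PD = "numeric",
  piv = "numeric", dmax = "numeric", d95 = "numeric", d5 = "numeric",
  pd = "numeric", oarFractions = "numeric", oarWeights = "numeric"
))

setValidity("UPIInputs", function(object) {
  eps <- 1e-9 * max(object@ptv, 1)
  if (any(c(object@ptv, object@ptvPD, object@ptv95PD, object@ptv50PD, object@piv) < 0))
    return("volumes must be non-negative")
  if (object@ptvPD > object@ptv95PD + eps || object@ptv95PD > object@ptv + eps)
    return("coverage ordering PTV_PD <= PTV_0.95PD <= PTV violated")
  if (length(object@oarFractions) &&
      (any(object@oarFractions < 0) || any(object@oarFractions > 1)))
    return("fractional OAR volumes must lie in [0, 1]")
  TRUE
})

#' Plan-index set result
#'
#' @slot indices named numeric vector of the ten scored indices
#'   (TCI, COSI, RCI, PITV, HI, MHI, CN, TVR, DGI, NCI); NA when undefined.
#' @slot auxiliary named numeric vector with CI and TR.
#' @slot undefined named character vector of reasons for undefined indices.
#' @export
setClass("UPIResult", representation(
  indices = "numeric", auxiliary = "numeric", undefined = "character"
))

## ---- show methods -------------------------------------------------------

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid: %d x %d x %d voxels, spacing %s mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  dose range [%.1f, %.1f] cGy, origin (%s) mm\n",
              min(object@dose), max(object@dose),
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "StructureContours", function(object) {
  nr <- sum(vapply(object@slices, function(s) length(s$rings), integer(1)))
  cat(sprintf("StructureContours '%s': %d slice(s), %d ring(s)\n",
              object@name, length(object@slices), nr))
})

setMethod("show", "StructureMask", function(object) {
  cat(sprintf("StructureMask '%s': %.3f cc in %d voxels (voxel %.4f cc)\n",
              object@name, maskVolume(object), sum(object@weight > 0),
              object@voxelVolume))
})

setMethod("show", "DifferentialDVH", function(object) {
  cat(sprintf("DifferentialDVH: %d bins of %.2f cGy, total %.3f cc, dose [%.1f, %.1f] cGy\n",
              length(object@volume), diff(object@breaks[1:2]),
              sum(object@volume), object@doseRange[1], object@doseRange[2]))
})

setMethod("show", "CumulativeDVH", function(object) {
  cat(sprintf("CumulativeDVH: %d dose points on [%.1f, %.1f] cGy, total %.3f cc\n",
              length(object@dose), min(object@dose), max(object@dose),
              object@totalVolume))
})

setMethod("show", "PlanBundle", function(object) {
  cat(sprintf("PlanBundle: %d plan(s), %d structure(s)\n",
              length(object@plans), length(object@structures)))
  for (p in object@plans)
    cat(sprintf("  plan %-12s PD %.0f cGy\n", p@planId, p@prescriptionDose))
  cat(sprintf("  structures: %s\n", paste(names(object@structures), collapse = ", ")))
})

setMethod("show", "UPIResult", function(object) {
  cat("UPI indices:\n")
  print(round(object@indices, 4))
  cat("auxiliary:\n")
  print(round(object@auxiliary, 4))
  if (length(object@undefined)) {
    cat("undefined:\n")
    for (nm in names(object@undefined))
      cat(sprintf("  %s: %s\n", nm, object@undefined[[nm]]))
  }
})
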