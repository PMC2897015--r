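## Generics and accessors. Slot access from user code should go through these.

#' Voxel volume in cc
#' @param x a \linkS4class{DoseGrid} or \linkS4class{StructureMask}.
#' @return scalar volume of one voxel in cc.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "DoseGrid", function(x) prod(x@spacing) / 1000)

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "StructureMask", function(x) x@voxelVolume)

#' Total volume of a structure or histogram, in cc
#' @param x a mask or DVH object.
#' @return scalar volume in cc.
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))

#' @rdname totalVolume
#' @export
setMethod("totalVolume", "DifferentialDVH", function(x) sum(x@volume))

#' @rdname totalVolume
#' @export
setMethod("totalVolume", "CumulativeDVH", function(x) x@totalVolume)

#' @rdname totalVolume
#' @export
setMethod("totalVolume", "SmoothedCDVH", function(x) x@totalVolume)

#' Mask volume (sum of fractional voxel memberships times voxel volume)
#' @param mask a \linkS4class{StructureMask}.
#' @return volume in cc.
#' @export
maskVolume <- function(mask) sum(mask@weight) * mask@voxelVolume

#' Membership weight array of a mask
#' @param mask a \linkS4class{StructureMask}.
#' @export
maskWeights <- function(mask) mask@weight

#' Dose array of a grid (cGy)
#' @param grid a \linkS4class{DoseGrid}.
#' @export
doseArray <- function(grid) grid@dose

#' Grid geometry accessors
#' @param grid a \linkS4class{DoseGrid}.
#' @return numeric(3): origin / spacing in mm, or integer(3) dims.
#' @export
gridOrigin <- function(grid) grid@origin

#' @rdname gridOrigin
#' @export
gridSpacing <- function(grid) grid@spacing

#' @rdname gridOrigin
#' @export
gridDims <- function(grid) grid@dims

#' Axial slice z-positions of a grid (mm)
#' @param grid a \linkS4class{DoseGrid}.
#' @export
slicePositions <- function(grid) grid@origin[3] + (seq_len(grid@dims[3]) - 1) * grid@spacing[3]

#' Bin edges / midpoints / widths of a differential DVH
#' @param ddvh a \linkS4class{DifferentialDVH}.
#' @export
binEdges <- function(ddvh) ddvh@breaks

#' @rdname binEdges
#' @export
binMidpoints <- function(ddvh) (ddvh@breaks[-1] + ddvh@breaks[-length(ddvh@breaks)]) / 2

#' @rdname binEdges
#' @export
binVolumes <- function(ddvh) ddvh@volume

#' Observed dose range of a differential DVH (cGy)
#' @param ddvh a \linkS4class{DifferentialDVH}.
#' @return numeric(2): (min, max) voxel dose.
#' @export
doseRange <- function(ddvh) ddvh@doseRange

#' Dose points / volumes of a cumulative DVH
#' @param cdvh a \linkS4class{CumulativeDVH}.
#' @export
dosePoints <- function(cdvh) cdvh@dose

#' @rdname dosePoints
#' @export
volumeAtOrAbove <- function(cdvh) cdvh@volume

#' Plan ids of a bundle
#' @param bundle a \linkS4class{PlanBundle}.
#' @export
planIds <- function(bundle) vapply(bundle@plans, function(p) p@planId, character(1))

#' Prescription dose of a plan in a bundle (cGy)
#' @param bundle a \linkS4class{PlanBundle}.
#' @param planId plan label.
#' @export
prescriptionDose <- function(bundle, planId) {
  ids <- planIds(bundle)
  i <- match(planId, ids)
  if (is.na(i)) stop(sprintf("unknown plan '%s'", planId))
  bundle@plans[[i]]@prescriptionDose
}

#' Structure names of a bundle
#' @param bundle a \linkS4class{PlanBundle}.
#' @export
structureNames <- function(bundle) names(bundle@structures)

#' Fetch a structure's contours from a bundle
#' @param bundle a \linkS4class{PlanBundle}.
#' @param name structure name.
#' @export
getStructure <- function(bundle, name) {
  if (!name %in% names(bundle@structures))
    stop(sprintf("dangling structure: '%s' not in bundle", name))
  bundle@structures[[name]]
}

#' Fetch a plan's dose grid from a bundle
#' @param bundle a \linkS4class{PlanBundle}.
#' @param planId plan label.
#' @export
getGrid <- function(bundle, planId) {
  if (!planId %in% names(bundle@grids))
    stop(sprintf("unknown plan '%s'", planId))
  bundle@grids[[planId]]
}

#' UPI accessors
#' @param x a \linkS4class{UPIResult}.
#' @return named numeric vector of index values (scored set or auxiliaries).
#' @export
upiIndices <- function(x) x@indices

#' @rdname upiIndices
#' @export
upiAuxiliary <- function(x) x@auxiliary
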