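## Spatial DVH derivatives: per-slice (z) differential DVHs and the
## dose-surface histogram over 6-connectivity boundary voxels.

#' Per-slice spatial DVH (zDVH)
#'
#' One differential DVH per axial slice containing member voxels, all built
#' on the bin edges of the whole-structure differential DVH so that summing
#' the slice histograms bin-by-bin reproduces the structure DVH exactly.
#' Slices with no member voxels are omitted.
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @param mask a \linkS4class{StructureMask}.
#' @param binWidth bin width in cGy (default as in \code{\link{computeDDVH}}).
#' @return A \linkS4class{ZDVH}.
#' @export
computeZDVH <- function(grid, mask, binWidth = NULL) {
  stopifnot(is(grid, "DoseGrid"), is(mask, "StructureMask"))
  full <- computeDDVH(grid, mask, binWidth)
  breaks <- full@breaks
  bw <- breaks[2] - breaks[1]
  nb <- length(breaks) - 1L
  zpos <- slicePositions(grid)
  keep <- which(apply(mask@weight, 3, function(w) any(w > 0)))
  entries <- vector("list", length(keep))
  for (e in seq_along(keep)) {
    k <- keep[e]
    w <- mask@weight[, , k]
    sel <- w > 0
    d <- grid@dose[, , k][sel]
    wv <- w[sel] * mask@voxelVolume
    idx <- pmin(floor(d / bw) + 1L, nb)
    vol <- numeric(nb); mom <- numeric(nb)
    agg <- rowsum(cbind(wv, wv * d), idx)
    at <- as.integer(rownames(agg))
    vol[at] <- agg[, 1]; mom[at] <- agg[, 2]
    entries[[e]] <- new("DifferentialDVH", breaks = breaks, volume = vol,
                        moment = mom, doseRange = range(d))
  }
  new("ZDVH", z = zpos[keep], entries = entries)
}

#' Sum a zDVH over slices
#'
#' Bin-by-bin sum of the per-slice histograms; equals the whole-structure
#' differential DVH (the slice-sum identity).
#'
#' @param zdvh a \linkS4class{ZDVH}.
#' @return A \linkS4class{DifferentialDVH}.
#' @export
sumZDVH <- function(zdvh) {
  stopifnot(is(zdvh, "ZDVH"), length(zdvh@entries) > 0)
  vol <- Reduce(`+`, lapply(zdvh@entries, function(d) d@volume))
  mom <- Reduce(`+`, lapply(zdvh@entries, function(d) d@moment))
  rng <- range(unlist(lapply(zdvh@entries, function(d) d@doseRange)))
  new("DifferentialDVH", breaks = zdvh@entries[[1]]@breaks, volume = vol,
      moment = mom, doseRange = rng)
}

#' Flag hot and cold slices of a structure
#'
#' Reporting convenience: a slice is "hot" when its maximum member-voxel
#' dose exceeds 1.05 PD and "cold" when its minimum falls below 0.95 PD.
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @param mask a \linkS4class{StructureMask}.
#' @param pd prescription dose in cGy.
#' @return data.frame with columns z, minDose, maxDose, hot, cold.
#' @export
hotColdSlices <- function(grid, mask, pd) {
  zpos <- slicePositions(grid)
  keep <- which(apply(mask@weight, 3, function(w) any(w > 0)))
  rows <- lapply(keep, function(k) {
    sel <- mask@weight[, , k] > 0
    d <- grid@dose[, , k][sel]
    data.frame(z = zpos[k], minDose = min(d), maxDose = max(d),
               hot = max(d) > 1.05 * pd, cold = min(d) < 0.95 * pd)
  })
  do.call(rbind, rows)
}

# 6-connectivity boundary of a logical membership array
surfaceVoxelFlags <- function(member) {
  dims <- dim(member)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, dims)
    n <- dims[ax]
    if (n <= abs(by)) return(out)
    src <- seq_len(n - abs(by))
    if (by > 0) {
      if (ax == 1) out[src + by, , ] <- arr[src, , ]
      if (ax == 2) out[, src + by, ] <- arr[, src, ]
      if (ax == 3) out[, , src + by] <- arr[, , src]
    } else {
      if (ax == 1) out[src, , ] <- arr[src - by, , ]
      if (ax == 2) out[, src, ] <- arr[, src - by, ]
      if (ax == 3) out[, , src] <- arr[, , src - by]
    }
    out
  }
  interior <- member
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift(member, ax, by)
  member & !interior
}

#' Dose-surface histogram
#'
#' Differential DVH restricted to the structure's boundary voxels: member
#' voxels with at least one of their six face neighbors outside the mask or
#' outside the grid. The surface voxels keep their fractional membership
#' volumes.
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @param mask a \linkS4class{StructureMask}.
#' @param binWidth bin width in cGy (default as in \code{\link{computeDDVH}}).
#' @return A \linkS4class{DSH}.
#' @export
computeDSH <- function(grid, mask, binWidth = NULL) {
  stopifnot(is(grid, "DoseGrid"), is(mask, "StructureMask"))
  member <- mask@weight > 0
  if (!any(member)) stop("empty structure")
  surf <- surfaceVoxelFlags(member)
  w <- mask@weight
  w[!surf] <- 0
  smask <- new("StructureMask", weight = w, voxelVolume = mask@voxelVolume,
               name = paste0(mask@name, ".surface"))
  new("DSH", ddvh = computeDDVH(grid, smask, binWidth),
      surfaceVoxels = sum(surf))
}
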