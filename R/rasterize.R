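## Contour-to-voxel rasterization.
##
## Membership rule: even-odd (ray crossing parity) over all rings of a slice,
## with points exactly on a ring boundary counted inside. Nested rings thus
## carve holes, which is how annular (shell) cross-sections are encoded.

# Even-odd point-in-polygon for one slice's rings, vectorized over points.
# px, py: coordinates (mm); rings: list of n-by-2 vertex matrices.
pointsInRings <- function(px, py, rings, tol = 1e-9) {
  inside <- logical(length(px))
  onedge <- logical(length(px))
  for (ring in rings) {
    nv <- nrow(ring)
    xs <- ring[, 1]; ys <- ring[, 2]
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j]; y2 <- ys[j]
      # boundary test: collinear and within the segment's bounding box
      cr <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
      seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
      on <- abs(cr) <= tol * max(1, sqrt(seglen2)) &
        px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
        py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
      onedge <- onedge | on
      # half-open edge rule for the crossing parity (robust at shared vertices)
      crosses <- ((y1 > py) != (y2 > py))
      if (any(crosses)) {
        xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        crosses <- crosses & (px < xi)
        inside <- xor(inside, crosses)
      }
    }
  }
  inside | onedge
}

#' Rasterize structure contours onto a dose grid
#'
#' Converts per-slice closed polygon rings into fractional voxel membership
#' on the lattice of a \linkS4class{DoseGrid}. A voxel belongs to the
#' structure according to an even-odd point-in-polygon test of its sample
#' points: the voxel center when \code{supersample = 1}, or a stratified
#' \code{k x k} in-plane sub-grid of sample points when \code{supersample = k},
#' in which case the membership weight is the fraction of sample points
#' inside (partial-volume handling). Points exactly on a contour edge count
#' as inside. Contour slices are matched to the nearest grid slice; a
#' contour slice farther than half a slice spacing from every grid slice is
#' rejected.
#'
#' @param contours a \linkS4class{StructureContours}.
#' @param grid a \linkS4class{DoseGrid} supplying the lattice.
#' @param supersample integer in 1..4; in-plane sub-sampling factor per axis.
#' @return A \linkS4class{StructureMask}.
#' @examples
#' g <- DoseGrid(array(0, c(20, 20, 3)), origin = c(0, 0, 0), spacing = c(1, 1, 3))
#' sq <- rbind(c(4, 4), c(14, 4), c(14, 14), c(4, 14))
#' sc <- StructureContours("box", list(list(z = 3, rings = list(sq))))
#' maskVolume(rasterizeStructure(sc, g))  # 100 voxels of 3 mm^3
#' @export
rasterizeStructure <- function(contours, grid, supersample = 1L) {
  stopifnot(is(contours, "StructureContours"), is(grid, "DoseGrid"))
  supersample <- as.integer(supersample)
  if (!supersample %in% 1:4) stop("supersample must be an integer in 1..4")
  if (length(contours@slices) == 0L) stop("degenerate contour: no slices")
  for (sl in contours@slices) for (r in sl$rings)
    if (nrow(r) < 3L) stop("degenerate contour: ring with fewer than 3 points")

  dims <- grid@dims; sp <- grid@spacing; org <- grid@origin
  zpos <- slicePositions(grid)
  weight <- array(0, dims)

  # in-plane stratified sub-centers, in voxel units relative to the center
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  subx <- rep(off, times = supersample)
  suby <- rep(off, each = supersample)
  nsub <- supersample^2

  matched <- FALSE
  for (sl in contours@slices) {
    k <- which.min(abs(zpos - sl$z))
    if (abs(zpos[k] - sl$z) > sp[3] / 2 + 1e-9) next
    matched <- TRUE

    allxy <- do.call(rbind, sl$rings)
    # candidate voxel index ranges from the ring bounding box (0-based indices)
    i0 <- max(0L, floor((min(allxy[, 1]) - org[1]) / sp[1] - 1))
    i1 <- min(dims[1] - 1L, ceiling((max(allxy[, 1]) - org[1]) / sp[1] + 1))
    j0 <- max(0L, floor((min(allxy[, 2]) - org[2]) / sp[2] - 1))
    j1 <- min(dims[2] - 1L, ceiling((max(allxy[, 2]) - org[2]) / sp[2] + 1))
    if (i1 < i0 || j1 < j0) next

    ii <- i0:i1; jj <- j0:j1
    cx <- org[1] + ii * sp[1]
    cy <- org[2] + jj * sp[2]
    px0 <- rep(cx, times = length(cy))
    py0 <- rep(cy, each = length(cx))

    frac <- numeric(length(px0))
    for (s in seq_len(nsub)) {
      frac <- frac + pointsInRings(px0 + subx[s] * sp[1],
                                   py0 + suby[s] * sp[2], sl$rings)
    }
    frac <- frac / nsub
    sub <- matrix(frac, nrow = length(ii), ncol = length(jj))
    # union when several contour slices map to one grid slice
    weight[ii + 1L, jj + 1L, k] <- pmax(weight[ii + 1L, jj + 1L, k], sub)
  }
  if (!matched) stop("structure outside grid: no contour slice overlaps the lattice")

  new("StructureMask", weight = weight, voxelVolume = voxelVolume(grid),
      name = contours@name)
}

#' Whole-grid mask
#'
#' Mask covering every voxel of the grid; used as the "body" region when the
#' prescription isodose volume must be measured over the full dose matrix.
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @return A \linkS4class{StructureMask} with all weights equal to 1.
#' @export
wholeGridMask <- function(grid) {
  new("StructureMask", weight = array(1, grid@dims),
      voxelVolume = voxelVolume(grid), name = "BODY")
}
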