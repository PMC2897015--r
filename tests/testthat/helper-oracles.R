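# Shared fixtures and independent oracles used across the suite.
# Everything here is deliberately written as plain scalar code, separate from
# the package's vectorized implementations, so the two can disagree.

# Classic per-point crossing-parity test (pnpoly) with an explicit
# on-segment check; combines multiple rings by parity, boundary := inside.
oraclePointInRings <- function(x, y, rings, tol = 1e-9) {
  inside <- FALSE
  for (ring in rings) {
    nv <- nrow(ring)
    j <- nv
    for (i in seq_len(nv)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      # on-segment: zero cross product and inside the bounding box
      cross <- (x - xi) * (yj - yi) - (y - yi) * (xj - xi)
      if (abs(cross) <= tol * max(1, abs(xj - xi) + abs(yj - yi)) &&
          x >= min(xi, xj) - tol && x <= max(xi, xj) + tol &&
          y >= min(yi, yj) - tol && y <= max(yi, yj) + tol)
        return(TRUE)
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
  }
  inside
}

# Exhaustive rasterization oracle: test every voxel center of the grid.
oracleRasterize <- function(contours, grid) {
  dims <- gridDims(grid); org <- gridOrigin(grid); sp <- gridSpacing(grid)
  zpos <- slicePositions(grid)
  out <- array(0, dims)
  for (sl in contours@slices) {
    k <- which.min(abs(zpos - sl$z))
    if (abs(zpos[k] - sl$z) > sp[3] / 2 + 1e-9) next
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      x <- org[1] + (i - 1) * sp[1]
      y <- org[2] + (j - 1) * sp[2]
      if (oraclePointInRings(x, y, sl$rings)) out[i, j, k] <- 1
    }
  }
  out
}

# Exact voxel-level cumulative curve (no binning): volume with dose >= d.
oracleCumulative <- function(grid, mask) {
  w <- maskWeights(mask)
  sel <- w > 0
  d <- doseArray(grid)[sel]
  wv <- w[sel] * voxelVolume(mask)
  f <- function(q) vapply(q, function(qq) sum(wv[d >= qq]), numeric(1))
  attr(f, "totalVolume") <- sum(wv)
  attr(f, "maxDose") <- max(d)
  f
}

# Small fast phantoms used across tests (2 mm lattice keeps them < 1 s).
coarseFalloffSpec <- function(seed = 1L)
  phantomSpec(dims = c(34, 34, 34), spacing = c(2, 2, 2), targetRadius = 12,
              falloffLength = 8, oarInner = 12, oarOuter = 20, seed = seed)

coarsePlateauSpec <- function(seed = 1L)
  phantomSpec(dims = c(30, 30, 30), spacing = c(2, 2, 2), targetRadius = 10,
              doseModel = "plateau", oarInner = 12, oarOuter = 20,
              d0 = 5000, pd = 5000, seed = seed)

# square ring with edges on integer mm; on the half-offset lattice below all
# 100 interior voxel centers fall strictly inside
unitSquareGrid <- function(dose = 100) {
  DoseGrid(array(dose, c(20, 20, 1)), origin = c(0.5, 0.5, 0), spacing = c(1, 1, 1))
}
unitSquareContours <- function() {
  ring <- rbind(c(4, 4), c(14, 4), c(14, 14), c(4, 14))
  StructureContours("SQ", list(list(z = 0, rings = list(ring))))
}
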