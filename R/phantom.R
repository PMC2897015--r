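## Synthetic phantom plan bundles with closed-form DVHs.
##
## Geometric targets (sphere or box) and a concentric shell or offset
## spherical organ at risk, irradiated with an idealized conformal field:
## a uniform plateau D0 inside the target with, optionally, a linear radial
## falloff D(r) = D0 max(0, 1 - (r - R)/L) outside, or a two-level field.
## Contours are 64-gon approximations of the circular cross-sections, so
## the rasterization and the contour files describe exactly the same
## polygons the closed forms idealize.

#' Phantom specification
#'
#' @slot dims,spacing,origin grid geometry (voxels, mm, mm).
#' @slot targetType "sphere" or "box".
#' @slot targetCenter center in mm.
#' @slot targetRadius sphere radius R in mm.
#' @slot targetHalfSize box half-extents in mm (box target only).
#' @slot oarType "none", "shell" (concentric spherical shell) or "sphere"
#'   (offset sphere).
#' @slot oarInner,oarOuter shell radii in mm.
#' @slot oarCenter,oarRadius offset-sphere geometry in mm.
#' @slot doseModel "plateau", "falloff" or "twolevel".
#' @slot d0 plateau dose in cGy.
#' @slot pd prescription dose in cGy.
#' @slot falloffLength linear falloff length L in mm (falloff model).
#' @slot lowDose background dose level in cGy (twolevel model).
#' @slot noiseSd additive Gaussian dose noise sd in cGy (clipped at 0).
#' @slot seed integer seed driving all randomness.
#' @slot nGon number of polygon vertices approximating circles.
#' @export
setClass("PhantomSpec", representation(
  dims = "integer", spacing = "numeric", origin = "numeric",
  targetType = "character", targetCenter = "numeric",
  targetRadius = "numeric", targetHalfSize = "numeric",
  oarType = "character", oarInner = "numeric", oarOuter = "numeric",
  oarCenter = "numeric", oarRadius = "numeric",
  doseModel = "character", d0 = "numeric", pd = "numeric",
  falloffLength = "numeric", lowDose = "numeric",
  noiseSd = "numeric", seed = "integer", nGon = "integer"
))

setValidity("PhantomSpec", function(object) {
  if (!object@targetType %in% c("sphere", "box")) return("unknown target type")
  if (!object@oarType %in% c("none", "shell", "sphere")) return("unknown OAR type")
  if (!object@doseModel %in% c("plateau", "falloff", "twolevel"))
    return("unknown dose model")
  if (object@d0 <= 0 || object@pd <= 0) return("D0 and PD must be positive")
  if (object@doseModel == "falloff" && object@falloffLength <= 0)
    return("falloff length L must be positive")
  # geometry must fit inside the grid
  ext <- object@origin + (object@dims - 1) * object@spacing
  reach <- switch(object@targetType,
                  sphere = object@targetRadius +
                    if (object@doseModel == "falloff") object@falloffLength else 0,
                  box = max(object@targetHalfSize))
  if (object@oarType == "shell") reach <- max(reach, object@oarOuter)
  if (any(object@targetCenter - reach < object@origin - 1e-9) ||
      any(object@targetCenter + reach > ext + 1e-9))
    return("phantom geometry exceeds the grid")
  TRUE
})

#' Create a phantom specification
#'
#' Defaults describe the reference validation phantom: a 20 mm radius
#' spherical target centered in a 66 mm cube at 1 mm isotropic spacing,
#' plateau dose D0 = PD = 6000 cGy with a 10 mm linear radial falloff, and a
#' concentric 20-30 mm spherical-shell organ at risk lying in the falloff
#' region. Contours are 64-gons; noise defaults to zero.
#'
#' @param dims,spacing,origin grid geometry.
#' @param targetType,targetCenter,targetRadius,targetHalfSize target geometry.
#' @param oarType,oarInner,oarOuter,oarCenter,oarRadius OAR geometry.
#' @param doseModel,d0,pd,falloffLength,lowDose dose field model.
#' @param noiseSd,seed,nGon noise level, seed, circle polygonization.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(dims = c(66, 66, 66), spacing = c(1, 1, 1),
                        origin = NULL,
                        targetType = "sphere", targetCenter = NULL,
                        targetRadius = 20, targetHalfSize = c(15, 12, 10),
                        oarType = "shell", oarInner = 20, oarOuter = 30,
                        oarCenter = NULL, oarRadius = 8,
                        doseModel = "falloff", d0 = 6000, pd = 6000,
                        falloffLength = 10, lowDose = 1000,
                        noiseSd = 0, seed = 1L, nGon = 64L) {
  dims <- as.integer(dims)
  if (is.null(origin)) origin <- -(dims - 1) * spacing / 2
  if (is.null(targetCenter)) targetCenter <- origin + (dims - 1) * spacing / 2
  if (is.null(oarCenter)) oarCenter <- targetCenter
  new("PhantomSpec", dims = dims, spacing = as.numeric(spacing),
      origin = as.numeric(origin), targetType = targetType,
      targetCenter = as.numeric(targetCenter),
      targetRadius = as.numeric(targetRadius),
      targetHalfSize = as.numeric(targetHalfSize),
      oarType = oarType, oarInner = as.numeric(oarInner),
      oarOuter = as.numeric(oarOuter), oarCenter = as.numeric(oarCenter),
      oarRadius = as.numeric(oarRadius), doseModel = doseModel,
      d0 = as.numeric(d0), pd = as.numeric(pd),
      falloffLength = as.numeric(falloffLength), lowDose = as.numeric(lowDose),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
      nGon = as.integer(nGon))
}

# regular n-gon ring (inscribed in the circle of radius r)
circleRing <- function(cx, cy, r, n) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(a), cy + r * sin(a))
}

sphereContours <- function(name, center, R, zpos, nGon) {
  slices <- list()
  for (z in zpos) {
    dz <- z - center[3]
    if (abs(dz) >= R) next
    rs <- sqrt(R^2 - dz^2)
    if (rs < 1e-6) next
    slices[[length(slices) + 1L]] <-
      list(z = z, rings = list(circleRing(center[1], center[2], rs, nGon)))
  }
  if (!length(slices)) stop("phantom geometry produces no contour slices")
  StructureContours(name, slices)
}

shellContours <- function(name, center, R1, R2, zpos, nGon) {
  slices <- list()
  for (z in zpos) {
    dz <- z - center[3]
    if (abs(dz) >= R2) next
    rOut <- sqrt(R2^2 - dz^2)
    if (rOut < 1e-6) next
    rings <- list(circleRing(center[1], center[2], rOut, nGon))
    if (abs(dz) < R1) {
      rIn <- sqrt(R1^2 - dz^2)
      if (rIn > 1e-6)
        rings[[2]] <- circleRing(center[1], center[2], rIn, nGon)
    }
    slices[[length(slices) + 1L]] <- list(z = z, rings = rings)
  }
  StructureContours(name, slices)
}

boxContours <- function(name, center, half, zpos) {
  slices <- list()
  for (z in zpos) {
    if (abs(z - center[3]) > half[3]) next
    ring <- rbind(c(center[1] - half[1], center[2] - half[2]),
                  c(center[1] + half[1], center[2] - half[2]),
                  c(center[1] + half[1], center[2] + half[2]),
                  c(center[1] - half[1], center[2] + half[2]))
    slices[[length(slices) + 1L]] <- list(z = z, rings = list(ring))
  }
  StructureContours(name, slices)
}

#' Generate a phantom plan bundle
#'
#' Builds the dose grid from the spec's analytic dose model evaluated at
#' voxel centers (plus seeded Gaussian noise, clipped at 0 cGy, when
#' \code{noiseSd > 0}), the target and OAR contours as per-slice polygons,
#' and packages everything as a single-plan \linkS4class{PlanBundle}.
#' Identical specs (including seed) produce identical bundles; if
#' \code{dir} is given the bundle is also written in the plan-bundle
#' dialect.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param dir optional directory to write the bundle to.
#' @return A \linkS4class{PlanBundle} (invisibly if written to disk).
#' @export
makePhantomPlan <- function(spec, dir = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  dims <- spec@dims; sp <- spec@spacing; org <- spec@origin
  cx <- org[1] + (seq_len(dims[1]) - 1) * sp[1]
  cy <- org[2] + (seq_len(dims[2]) - 1) * sp[2]
  cz <- org[3] + (seq_len(dims[3]) - 1) * sp[3]

  tc <- spec@targetCenter
  if (spec@targetType == "sphere") {
    r2 <- outer(outer((cx - tc[1])^2, (cy - tc[2])^2, `+`), (cz - tc[3])^2, `+`)
    r <- sqrt(r2)
    insideTarget <- r <= spec@targetRadius
  } else {
    inx <- abs(cx - tc[1]) <= spec@targetHalfSize[1]
    iny <- abs(cy - tc[2]) <= spec@targetHalfSize[2]
    inz <- abs(cz - tc[3]) <= spec@targetHalfSize[3]
    insideTarget <- outer(outer(inx, iny, `&`), inz, `&`)
    r <- NULL
  }

  dose <- array(0, dims)
  if (spec@doseModel == "plateau") {
    dose[insideTarget] <- spec@d0
  } else if (spec@doseModel == "falloff") {
    if (spec@targetType != "sphere")
      stop("linear radial falloff requires a spherical target")
    dose <- spec@d0 * pmax(0, 1 - (r - spec@targetRadius) / spec@falloffLength)
    dose[insideTarget] <- spec@d0
    dim(dose) <- dims
  } else {                                # twolevel
    dose <- array(spec@lowDose, dims)
    dose[insideTarget] <- spec@d0
  }

  if (spec@noiseSd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec@seed)
    dose <- pmax(0, dose + stats::rnorm(length(dose), sd = spec@noiseSd))
    dim(dose) <- dims
  }

  grid <- DoseGrid(dose, origin = org, spacing = sp)
  target <- if (spec@targetType == "sphere")
    sphereContours("PTV", tc, spec@targetRadius, cz, spec@nGon)
  else boxContours("PTV", tc, spec@targetHalfSize, cz)

  structures <- list(target)
  if (spec@oarType == "shell")
    structures[[2]] <- shellContours("OAR", spec@oarCenter, spec@oarInner,
                                     spec@oarOuter, cz, spec@nGon)
  else if (spec@oarType == "sphere")
    structures[[2]] <- sphereContours("OAR", spec@oarCenter, spec@oarRadius,
                                      cz, spec@nGon)

  bundle <- PlanBundle(
    plans = list(PlanRecord("PTV1", spec@pd)),
    structures = structures,
    grids = list(PTV1 = grid))
  if (!is.null(dir)) {
    writePlanBundle(bundle, dir)
    return(invisible(bundle))
  }
  bundle
}

#' Closed-form cumulative DVH of a phantom structure
#'
#' Returns the exact volume-at-or-above-dose curve implied by the phantom's
#' analytic dose model, as a vectorized function of dose (cGy) returning cc,
#' with attributes \code{totalVolume} and \code{maxDose}. Available for the
#' noiseless plateau, linear-falloff and two-level models; \code{structure}
#' may be "PTV", "OAR" (concentric shell only) or "BODY" (the whole grid;
#' falloff requires the dosed ball to fit inside it).
#'
#' @param spec a \linkS4class{PhantomSpec} with \code{noiseSd = 0}.
#' @param structure "PTV", "OAR" or "BODY".
#' @return function(d) -> cc, with totalVolume/maxDose attributes.
#' @export
analyticCDVH <- function(spec, structure = "PTV") {
  stopifnot(is(spec, "PhantomSpec"))
  if (spec@noiseSd > 0) stop("no closed form: phantom has dose noise")
  ballcc <- function(r) 4 / 3 * pi * r^3 / 1000
  gridcc <- prod(spec@dims) * prod(spec@spacing) / 1000
  D0 <- spec@d0; R <- spec@targetRadius; L <- spec@falloffLength

  if (spec@targetType == "box" && structure != "PTV")
    stop("no closed form for this structure with a box target")
  vt <- if (spec@targetType == "sphere") ballcc(R)
        else prod(2 * spec@targetHalfSize) / 1000

  stepCurve <- function(total, at) {
    f <- function(d) ifelse(d <= at, total, 0)
    attr(f, "totalVolume") <- total; attr(f, "maxDose") <- at
    f
  }

  if (structure == "PTV") {
    # dose is exactly D0 throughout the target under all three models
    return(stepCurve(vt, D0))
  }

  if (structure == "OAR") {
    if (spec@oarType != "shell")
      stop("no closed form: analytic OAR curve requires the concentric shell")
    if (any(spec@oarCenter != spec@targetCenter))
      stop("no closed form: shell must be concentric with the target")
    R1 <- spec@oarInner; R2 <- spec@oarOuter
    vs <- ballcc(R2) - ballcc(R1)
    if (spec@doseModel == "plateau") {
      # dose outside the target is zero; shell overlap with the target ball
      vin <- ballcc(min(max(R1, R), R2)) - ballcc(R1)
      f <- function(d) ifelse(d <= 0, vs, ifelse(d <= D0, vin, 0))
    } else if (spec@doseModel == "twolevel") {
      vin <- ballcc(min(max(R1, R), R2)) - ballcc(R1)
      f <- function(d) ifelse(d <= spec@lowDose, vs, ifelse(d <= D0, vin, 0))
    } else {
      f <- function(d) {
        rd <- R + L * (1 - d / D0)
        v <- ballcc(pmin(pmax(rd, R1), R2)) - ballcc(R1)
        ifelse(d <= 0, vs, ifelse(d <= D0, v, 0))
      }
    }
    attr(f, "totalVolume") <- vs; attr(f, "maxDose") <- D0
    return(f)
  }

  if (structure == "BODY") {
    if (spec@doseModel == "plateau") {
      f <- function(d) ifelse(d <= 0, gridcc, ifelse(d <= D0, vt, 0))
    } else if (spec@doseModel == "twolevel") {
      f <- function(d) ifelse(d <= spec@lowDose, gridcc, ifelse(d <= D0, vt, 0))
    } else {
      f <- function(d) {
        rd <- R + L * (1 - d / D0)
        ifelse(d <= 0, gridcc, ifelse(d <= D0, ballcc(pmax(rd, R)), 0))
      }
    }
    attr(f, "totalVolume") <- gridcc; attr(f, "maxDose") <- D0
    return(f)
  }
  stop(sprintf("unknown phantom structure '%s'", structure))
}

#' Named phantom presets for the command line
#'
#' "sphere": spherical target with linear falloff and shell OAR (the
#' reference validation phantom); "box": box target with a uniform plateau;
#' "shell": plateau target with a wider shell OAR.
#'
#' @param preset "sphere", "box" or "shell".
#' @param seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
presetPhantom <- function(preset = c("sphere", "box", "shell"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    sphere = phantomSpec(seed = seed),
    box = phantomSpec(targetType = "box", doseModel = "plateau",
                      oarType = "none", seed = seed),
    shell = phantomSpec(targetRadius = 15, doseModel = "plateau",
                        oarInner = 18, oarOuter = 25, seed = seed))
}
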