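## Universal plan-index (UPI) set and quality factor.
##
## Ten scored indices: TCI, COSI, RCI, PITV, HI, MHI, CN, TVR, DGI, NCI,
## with CI and TR as auxiliaries. Every index equals 1 for the ideal plan
## (perfect coverage, perfect conformity, no hot spots, no OAR overdose).

upiNames <- c("TCI", "COSI", "RCI", "PITV", "HI", "MHI", "CN", "TVR", "DGI", "NCI")

#' Assemble the dose/volume inputs for the plan-index set
#'
#' Evaluates the target coverages at PD, 0.95 PD and 0.50 PD from the PTV
#' cumulative DVH, the prescription isodose volume (PIV) from the whole-grid
#' ("body") cumulative DVH, Dmax/D95/D5 from the target curve, and the
#' fractional OAR volumes at or above their tolerance doses.
#'
#' @param cdvhPtv target \linkS4class{CumulativeDVH}.
#' @param ddvhPtv target \linkS4class{DifferentialDVH} (exact Dmax).
#' @param cdvhBody whole-grid \linkS4class{CumulativeDVH}; required because
#'   PIV is measured over the entire dose matrix, not the target.
#' @param pd prescription dose in cGy.
#' @param oarCdvhs named list of OAR \linkS4class{CumulativeDVH} objects.
#' @param oarTolerances named numeric vector of tolerance doses (cGy), one
#'   per OAR in \code{oarCdvhs}.
#' @param oarWeights per-OAR weights; default 1/N each.
#' @return A \linkS4class{UPIInputs}.
#' @export
computeUpiInputs <- function(cdvhPtv, ddvhPtv, cdvhBody, pd,
                             oarCdvhs = list(), oarTolerances = numeric(),
                             oarWeights = NULL) {
  stopifnot(is(cdvhPtv, "CumulativeDVH"), is(ddvhPtv, "DifferentialDVH"))
  if (is.null(cdvhBody))
    stop("whole-grid cumulative DVH required: PIV-dependent indices need it")
  stopifnot(is(cdvhBody, "CumulativeDVH"))
  if (length(oarCdvhs)) {
    if (is.null(names(oarCdvhs)) || !all(names(oarCdvhs) %in% names(oarTolerances)))
      stop("every OAR curve needs a named tolerance dose")
  }
  N <- length(oarCdvhs)
  if (is.null(oarWeights)) oarWeights <- rep(1 / max(N, 1), N)
  fr <- vapply(seq_len(N), function(i) {
    volumeAtDose(oarCdvhs[[i]], oarTolerances[[names(oarCdvhs)[i]]], relative = TRUE)
  }, numeric(1))
  names(fr) <- names(oarCdvhs)

  sm <- if (length(cdvhPtv@dose) >= 7L) smoothCDVH(cdvhPtv) else NULL
  rng <- ddvhPtv@doseRange
  # clamp Dx to the exact observed dose range (binned-curve resolution)
  dx <- function(f) if (is.null(sm)) NA_real_
        else min(max(doseAtVolume(sm, f), rng[1]), rng[2])

  new("UPIInputs",
      ptv = cdvhPtv@totalVolume,
      ptvPD = volumeAtDose(cdvhPtv, pd),
      ptv95PD = volumeAtDose(cdvhPtv, 0.95 * pd),
      ptv50PD = volumeAtDose(cdvhPtv, 0.50 * pd),
      piv = volumeAtDose(cdvhBody, pd),
      dmax = ddvhPtv@doseRange[2],
      d95 = dx(0.95), d5 = dx(0.05),
      pd = pd, oarFractions = fr,
      oarWeights = if (N) oarWeights else numeric())
}

#' Construct UPIInputs directly from known quantities
#'
#' @param ptv,ptvPD,ptv95PD,ptv50PD,piv volumes in cc.
#' @param dmax,d95,d5,pd doses in cGy.
#' @param oarFractions fractional OAR volumes at/above tolerance.
#' @param oarWeights per-OAR weights (default 1/N).
#' @return A \linkS4class{UPIInputs}.
#' @export
UPIInputs <- function(ptv, ptvPD, ptv95PD, ptv50PD, piv, dmax, d95, d5, pd,
                      oarFractions = numeric(), oarWeights = NULL) {
  N <- length(oarFractions)
  if (is.null(oarWeights)) oarWeights <- rep(1 / max(N, 1), N)
  new("UPIInputs", ptv = ptv, ptvPD = ptvPD, ptv95PD = ptv95PD,
      ptv50PD = ptv50PD, piv = piv, dmax = dmax, d95 = d95, d5 = d5, pd = pd,
      oarFractions = oarFractions,
      oarWeights = if (N) oarWeights else numeric())
}

#' Compute the ten-index plan score set
#'
#' TCI = PTV_PD/PTV; COSI = 1 - (sum wi V(OARi >= TOLi))/TCI;
#' RCI = PTV_PD/PTV_0.95PD; PITV = PIV/PTV; HI = Dmax/PD; MHI = D95/D5;
#' TR = PIV/PTV_PD; CI = 1/TR; CN = TCI/TR; TVR = PTV/PIV;
#' DGI = PTV_PD/PTV_0.50PD; NCI = PIV*PTV/PTV_PD^2. An index whose
#' denominator vanishes is reported as NA together with the reason, never
#' as an infinity.
#'
#' @param inputs a \linkS4class{UPIInputs}.
#' @return A \linkS4class{UPIResult}.
#' @examples
#' ideal <- UPIInputs(ptv = 100, ptvPD = 100, ptv95PD = 100, ptv50PD = 100,
#'                    piv = 100, dmax = 6000, d95 = 6000, d5 = 6000, pd = 6000)
#' upiIndices(computeUPI(ideal))  # all ten equal 1
#' @export
computeUPI <- function(inputs) {
  stopifnot(is(inputs, "UPIInputs"))
  idx <- setNames(rep(NA_real_, 10L), upiNames)
  aux <- c(CI = NA_real_, TR = NA_real_)
  why <- character()
  note <- function(nm, reason) {
    why[[nm]] <<- reason
  }

  if (inputs@ptv > 0) idx["TCI"] <- inputs@ptvPD / inputs@ptv
  else note("TCI", "zero PTV volume")

  if (!is.na(idx["TCI"]) && idx["TCI"] > 0) {
    s <- if (length(inputs@oarFractions))
      sum(inputs@oarWeights * inputs@oarFractions) else 0
    idx["COSI"] <- 1 - s / idx["TCI"]
  } else note("COSI", "zero target coverage index")

  if (inputs@ptv95PD > 0) idx["RCI"] <- inputs@ptvPD / inputs@ptv95PD
  else note("RCI", "zero PTV coverage at 0.95 PD")

  if (inputs@ptv > 0) idx["PITV"] <- inputs@piv / inputs@ptv
  else note("PITV", "zero PTV volume")

  if (inputs@pd > 0) idx["HI"] <- inputs@dmax / inputs@pd
  else note("HI", "zero prescription dose")

  if (!is.na(inputs@d5) && inputs@d5 > 0) idx["MHI"] <- inputs@d95 / inputs@d5
  else note("MHI", "zero or unavailable D5")

  if (inputs@ptvPD > 0) {
    tr <- inputs@piv / inputs@ptvPD
    aux["TR"] <- tr
    if (tr > 0) {
      aux["CI"] <- 1 / tr
      idx["CN"] <- idx["TCI"] / tr
    } else note("CN", "zero treatment volume ratio")
  } else {
    note("CN", "zero PTV coverage at PD")
  }

  if (inputs@piv > 0) idx["TVR"] <- inputs@ptv / inputs@piv
  else note("TVR", "zero prescription isodose volume")

  if (inputs@ptv50PD > 0) idx["DGI"] <- inputs@ptvPD / inputs@ptv50PD
  else note("DGI", "zero PTV coverage at 0.50 PD")

  if (inputs@ptvPD > 0) idx["NCI"] <- inputs@piv * inputs@ptv / inputs@ptvPD^2
  else note("NCI", "zero PTV coverage at PD")

  new("UPIResult", indices = idx, auxiliary = aux,
      undefined = if (length(why)) unlist(why) else character())
}

#' Quality factor of a plan
#'
#' QF = 2.718 exp(-sum Wi Xi) over the selected indices of the UPI set.
#' The printed constant 2.718 is used literally (not exp(1)); for the ideal
#' plan with all ten indices 1 and equal weights 0.1 the factor is
#' 2.718/e = 0.99990.
#'
#' @param result a \linkS4class{UPIResult}.
#' @param weights weights Wi in [0, 1]; a single value is recycled.
#' @param select names of indices to include; default all ten.
#' @return the quality factor (dimensionless).
#' @export
computeQF <- function(result, weights = 0.1, select = upiNames) {
  stopifnot(is(result, "UPIResult"))
  if (!all(select %in% names(result@indices)))
    stop("unknown index selected: ",
         paste(setdiff(select, names(result@indices)), collapse = ", "))
  xi <- result@indices[select]
  if (anyNA(xi))
    stop("undefined index selected: ", paste(select[is.na(xi)], collapse = ", "))
  if (length(weights) == 1L) weights <- rep(weights, length(select))
  if (length(weights) != length(select))
    stop("need one weight per selected index")
  if (any(weights < 0 | weights > 1))
    stop("weights must lie in [0, 1]")
  2.718 * exp(-sum(weights * xi))
}
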