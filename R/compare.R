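## Curve comparison metrics: NRMSD and distance-to-agreement.
##
## Both metrics accept any mixture of CumulativeDVH, SmoothedCDVH, or a
## plain function(dose) -> volume_cc carrying "totalVolume" and "maxDose"
## attributes (the form returned by analyticCDVH). Curves are compared on
## the fraction-of-own-total scale, i.e. normalized by each curve's total
## structure volume.

# adapter: list(eval = function(d) cc, total = cc, dmax = cGy)
asDvhCurve <- function(x) {
  if (is(x, "CumulativeDVH"))
    list(eval = function(d) volumeAtDose(x, d), total = x@totalVolume,
         dmax = max(x@dose))
  else if (is(x, "SmoothedCDVH"))
    list(eval = function(d) evaluateSmoothed(x, d), total = x@totalVolume,
         dmax = max(x@tableDose))
  else if (is.function(x)) {
    total <- attr(x, "totalVolume"); dmax <- attr(x, "maxDose")
    if (is.null(total)) total <- x(0)
    if (is.null(dmax)) stop("function curves need a 'maxDose' attribute")
    list(eval = x, total = total, dmax = dmax)
  } else stop("not a DVH curve: expected CumulativeDVH, SmoothedCDVH or function")
}

#' Normalized root-mean-square difference between two cumulative DVH curves
#'
#' RMS of the pointwise difference of the two curves at the probe doses,
#' with each curve normalized by its own total structure volume, expressed
#' in percent. Symmetric in its curve arguments.
#'
#' @param curveA,curveB cumulative DVH curves (see Details above).
#' @param probeDoses doses (cGy) at which the curves are compared; default
#'   501 evenly spaced points spanning the common dose range.
#' @return NRMSD in percent of total volume.
#' @export
nrmsd <- function(curveA, curveB, probeDoses = NULL) {
  a <- asDvhCurve(curveA); b <- asDvhCurve(curveB)
  if (is.null(probeDoses))
    probeDoses <- seq(0, max(a$dmax, b$dmax), length.out = 501L)
  if (length(probeDoses) < 1L) stop("need at least one probe dose")
  fa <- a$eval(probeDoses) / a$total
  fb <- b$eval(probeDoses) / b$total
  100 * sqrt(mean((fa - fb)^2))
}

#' Dose-axis distance-to-agreement at a volume level
#'
#' The absolute difference between the doses at which the two curves attain
#' the given fraction of their own total volume, normalized to the
#' prescription dose and expressed in percent. The default level is 50% of
#' the structure volume.
#'
#' @param curveA,curveB cumulative DVH curves (see \code{\link{nrmsd}}).
#' @param pd prescription dose in cGy (normalization).
#' @param volumeFraction volume level in (0, 1); default 0.5.
#' @return DTA in percent of the prescription dose.
#' @export
dta <- function(curveA, curveB, pd, volumeFraction = 0.5) {
  if (volumeFraction <= 0 || volumeFraction >= 1)
    stop("volumeFraction must lie strictly between 0 and 1")
  a <- asDvhCurve(curveA); b <- asDvhCurve(curveB)
  da <- curveInverse(a, volumeFraction)
  db <- curveInverse(b, volumeFraction)
  100 * abs(da - db) / pd
}

# dose at which a (non-increasing) curve reaches the given fraction of its
# own total; bisection on the adapter's eval.
curveInverse <- function(cv, frac) {
  target <- frac * cv$total
  lo <- 0; hi <- cv$dmax
  flo <- cv$eval(lo); fhi <- cv$eval(hi)
  if (flo < target - 1e-9 * cv$total)
    stop(sprintf("volume fraction %.3f unattained by curve", frac))
  if (fhi >= target) return(hi)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (cv$eval(mid) >= target) lo <- mid else hi <- mid
    if (hi - lo < 1e-10 * max(1, cv$dmax)) break
  }
  (lo + hi) / 2
}
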