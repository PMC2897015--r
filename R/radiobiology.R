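## Radiobiological outcome models on fractional DVHs.
##
## Poisson tumor control: TCP = (1/2)^(sum_i vi exp[2 gamma50 (1 - Di/TCD50) ln 2]).
## Lyman sigmoidal dose response: NTCP = Phi[(EUD - TD50)/(m TD50)], with the
## equivalent uniform dose taken as the generalized mean dose
## GMD = (sum_i vi Di^(1/n))^n.

#' Poisson tumor control probability
#'
#' Probability of killing every clonogen under heterogeneous irradiation:
#' each volume element vi at dose Di contributes a survival exponent, and a
#' uniform dose equal to TCD50 yields exactly 50% control.
#'
#' @param dvh a \linkS4class{FractionalDVH} (volume fractions sum to 1).
#' @param params a \linkS4class{TCPParams}.
#' @return tumor control probability in (0, 1].
#' @examples
#' tcpPoisson(FractionalDVH(4180, 1), TCPParams(tcd50 = 4180, gamma50 = 0.6))  # 0.5
#' @export
tcpPoisson <- function(dvh, params) {
  stopifnot(is(dvh, "FractionalDVH"), is(params, "TCPParams"))
  expo <- sum(dvh@volfrac *
                exp(2 * params@gamma50 * (1 - dvh@dose / params@tcd50) * log(2)))
  0.5^expo
}

#' Generalized mean dose (equivalent uniform dose)
#'
#' GMD = (sum vi Di^(1/n))^n. Equals the arithmetic mean dose at n = 1 and
#' approaches the maximum dose as n tends to 0. Computed on the scale of the
#' maximum dose to avoid overflow for small n.
#'
#' @param dvh a \linkS4class{FractionalDVH}.
#' @param n volume-dependence exponent in (0, 1]; small n makes the organ
#'   behave serially (max-dose driven), n = 1 parallel (mean-dose driven).
#' @return generalized mean dose in cGy.
#' @export
gmd <- function(dvh, n) {
  stopifnot(is(dvh, "FractionalDVH"))
  if (length(n) != 1L || !is.finite(n) || n <= 0 || n > 1)
    stop("volume-dependence exponent n must lie in (0, 1]")
  M <- max(dvh@dose)
  if (M == 0) return(0)
  M * sum(dvh@volfrac * (dvh@dose / M)^(1 / n))^n
}

#' Lyman sigmoidal dose-response NTCP
#'
#' NTCP = Phi[(EUD - TD50)/(m TD50)] with Phi the standard normal CDF and
#' EUD the generalized mean dose \code{\link{gmd}} at the model's n. A
#' structure at EUD = TD50 has exactly 50% complication probability.
#'
#' @param dvh a \linkS4class{FractionalDVH}.
#' @param params an \linkS4class{NTCPParams}.
#' @return complication probability in (0, 1).
#' @examples
#' p <- NTCPParams(td50 = 8190, m = 0.19, n = 0.23)
#' ntcpLyman(FractionalDVH(8190, 1), p)  # 0.5
#' @export
ntcpLyman <- function(dvh, params) {
  stopifnot(is(dvh, "FractionalDVH"), is(params, "NTCPParams"))
  eudVal <- gmd(dvh, params@n)
  stats::pnorm((eudVal - params@td50) / (params@m * params@td50))
}

#' Equivalent uniform dose of a fractional DVH under a Lyman model
#'
#' @param dvh a \linkS4class{FractionalDVH}.
#' @param params an \linkS4class{NTCPParams} (supplies n).
#' @return EUD in cGy.
#' @export
eud <- function(dvh, params) {
  stopifnot(is(params, "NTCPParams"))
  gmd(dvh, params@n)
}

#' Example radiobiological parameter sets
#'
#' Illustrative parameter values for a prostate target (Poisson model) and
#' rectum (Lyman model): TCD50 = 4180 cGy, gamma50 = 0.6; TD50 = 8190 cGy,
#' m = 0.19, n = 0.23. Shipped as worked-example defaults only, not as
#' clinical recommendations.
#'
#' @return list with elements \code{tcp} (\linkS4class{TCPParams}) and
#'   \code{ntcp} (\linkS4class{NTCPParams}).
#' @export
exampleOutcomeParams <- function() {
  list(tcp = TCPParams(tcd50 = 4180, gamma50 = 0.6),
       ntcp = NTCPParams(td50 = 8190, m = 0.19, n = 0.23))
}
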