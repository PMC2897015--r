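## Cosine-interpolated piecewise-polynomial smoothing of cumulative DVHs.
##
## Between each pair of adjacent cDVH samples a transition point is
## synthesized by cosine interpolation with weight 0.5: at fraction t the
## cosine blend is g(t) = (1 - cos(pi t))/2, and at the midpoint t = 0.5
## g = 0.5, i.e. the synthesized point is the equal-weight blend of its two
## neighbors. A least-squares polynomial is then fit over that midpoint plus
## the six nearest samples; the polynomial degree (2..5) is chosen per
## window by minimal leave-one-out RMSE with ties broken toward the lowest
## degree. Fitted values are clipped to the bracketing samples, which also
## pins the curve to the data at every original sample dose.

# leave-one-out RMSE of a polynomial LS fit, via the hat-matrix identity
# e_loo = e / (1 - h); degenerate leverages (h ~ 1) disqualify the degree.
polyLooRmse <- function(u, y, degree) {
  X <- outer(u, 0:degree, `^`)
  qrx <- qr(X)
  if (qrx$rank < degree + 1L) return(list(rmse = Inf, coef = NULL))
  coef <- qr.coef(qrx, y)
  fit <- drop(X %*% coef)
  h <- rowSums(qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-8)) return(list(rmse = Inf, coef = coef))
  r <- (y - fit) / (1 - h)
  list(rmse = sqrt(mean(r^2)), coef = coef)
}

#' Smooth a cumulative DVH by cosine interpolation + piecewise polynomials
#'
#' Builds the continuous model described above and a dense monotone
#' evaluation table (fitted values on a per-interval sub-grid, clipped to
#' the bracketing samples and passed through a running minimum so the curve
#' is non-increasing by construction and reproduces every original sample).
#'
#' @param cdvh a \linkS4class{CumulativeDVH} with at least 7 dose points.
#' @param subdivisions fitted evaluation points per interval in the dense
#'   table (default 8).
#' @return A \linkS4class{SmoothedCDVH}.
#' @export
smoothCDVH <- function(cdvh, subdivisions = 8L) {
  stopifnot(is(cdvh, "CumulativeDVH"))
  x <- cdvh@dose; y <- cdvh@volume
  n <- length(x)
  if (n < 7L) stop("curve too short: need at least 7 cDVH points to smooth")

  windows <- vector("list", n - 1L)
  K <- as.integer(subdivisions)
  tabx <- taby <- vector("list", n - 1L)
  degrees <- 2:5
  for (i in seq_len(n - 1L)) {
    xm <- (x[i] + x[i + 1L]) / 2
    ym <- (y[i] + y[i + 1L]) / 2          # cosine blend, weight 0.5
    # six nearest samples to the midpoint: three on each side where possible
    lo <- max(1L, min(i - 2L, n - 5L))
    hi <- min(n, lo + 5L)
    lo <- hi - 5L
    xw <- c(x[lo:hi], xm); yw <- c(y[lo:hi], ym)
    h <- max(xw) - min(xw)
    u <- (xw - xm) / h                     # centered + scaled for conditioning
    best <- NULL; bestRmse <- Inf; bestDeg <- NA_integer_
    for (dg in degrees) {
      f <- polyLooRmse(u, yw, dg)
      if (f$rmse < bestRmse * (1 - 1e-12)) {
        bestRmse <- f$rmse; best <- f$coef; bestDeg <- dg
      }
    }
    if (is.null(best)) {                   # all degrees degenerate: fall back
      best <- c(ym, rep(0, 2)); bestDeg <- 2L; h <- max(h, 1)
    }
    windows[[i]] <- list(center = xm, scale = h, coef = best, degree = bestDeg)
    # dense in-interval evaluation, clipped to the bracketing samples
    xs <- seq(x[i], x[i + 1L], length.out = K + 2L)
    us <- (xs - xm) / h
    ys <- drop(outer(us, seq_along(best) - 1L, `^`) %*% best)
    ys <- pmin(pmax(ys, y[i + 1L]), y[i])
    ys[1] <- y[i]; ys[K + 2L] <- y[i + 1L]
    keep <- seq_len(K + 1L)                # drop right endpoint, next interval owns it
    tabx[[i]] <- xs[keep]; taby[[i]] <- ys[keep]
  }
  tx <- c(unlist(tabx), x[n])
  ty <- cummin(c(unlist(taby), y[n]))      # global monotonicity enforcement

  new("SmoothedCDVH", dose = x, volume = y, totalVolume = cdvh@totalVolume,
      windows = windows, tableDose = tx, tableVolume = ty)
}

#' Evaluate a smoothed cDVH
#'
#' @param sm a \linkS4class{SmoothedCDVH}.
#' @param dose doses in cGy; values outside the modeled range are clamped to
#'   the curve endpoints.
#' @param relative if TRUE return fraction of total volume.
#' @return volumes (cc, or fraction of total).
#' @export
evaluateSmoothed <- function(sm, dose, relative = FALSE) {
  stopifnot(is(sm, "SmoothedCDVH"))
  v <- stats::approx(sm@tableDose, sm@tableVolume, xout = dose, rule = 2)$y
  if (relative) v / sm@totalVolume else v
}

#' Inverse lookup: dose at a volume level (Dx)
#'
#' Returns the dose at which the smoothed cumulative curve crosses the given
#' volume fraction, by linear inversion of the monotone evaluation table.
#' Levels above the curve start (or below its end) clamp to the first (last)
#' modeled dose.
#'
#' @param sm a \linkS4class{SmoothedCDVH}.
#' @param volumeFraction fraction(s) of total volume in (0, 1].
#' @return dose(s) in cGy.
#' @export
doseAtVolume <- function(sm, volumeFraction) {
  stopifnot(is(sm, "SmoothedCDVH"))
  vapply(volumeFraction, function(f) {
    target <- f * sm@totalVolume
    v <- sm@tableVolume; d <- sm@tableDose
    i <- which(v <= target)[1]
    if (is.na(i)) return(d[length(d)])
    if (i == 1L) return(d[1])
    v1 <- v[i - 1L]; v2 <- v[i]
    if (v1 == v2) return(d[i])
    d[i - 1L] + (v1 - target) / (v1 - v2) * (d[i] - d[i - 1L])
  }, numeric(1))
}
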