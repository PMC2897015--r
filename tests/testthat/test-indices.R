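idealInputs <- function() {
  UPIInputs(ptv = 100, ptvPD = 100, ptv95PD = 100, ptv50PD = 100, piv = 100,
            dmax = 6000, d95 = 6000, d5 = 6000, pd = 6000,
            oarFractions = c(OAR = 0))
}

test_that("the ideal plan scores unity on every index, exactly", {
  res <- computeUPI(idealInputs())
  expect_equal(unname(upiIndices(res)), rep(1, 10), tolerance = 1e-12)
  expect_equal(unname(upiAuxiliary(res)), c(1, 1), tolerance = 1e-12)
  expect_length(res@undefined, 0)
})

test_that("index formulas evaluate correctly on a non-ideal plan", {
  inp <- UPIInputs(ptv = 100, ptvPD = 95, ptv95PD = 99, ptv50PD = 100,
                   piv = 120, dmax = 6300, d95 = 5700, d5 = 6200, pd = 6000)
  x <- upiIndices(computeUPI(inp))
  expect_equal(unname(x["TCI"]), 0.95)
  expect_equal(unname(x["RCI"]), 95 / 99, tolerance = 1e-12)
  expect_equal(unname(x["PITV"]), 1.2)
  expect_equal(unname(x["HI"]), 1.05)
  expect_equal(unname(x["MHI"]), 5700 / 6200, tolerance = 1e-12)
  expect_equal(unname(x["CN"]), 0.95 / (120 / 95), tolerance = 1e-12)
  expect_equal(unname(x["TVR"]), 100 / 120, tolerance = 1e-12)
  expect_equal(unname(x["DGI"]), 0.95)
  expect_equal(unname(x["NCI"]), 120 * 100 / 95^2, tolerance = 1e-12)
  aux <- upiAuxiliary(computeUPI(inp))
  expect_equal(unname(aux["TR"]), 120 / 95, tolerance = 1e-12)
  expect_equal(unname(aux["CI"]), 95 / 120, tolerance = 1e-12)
})

test_that("TVR is the reciprocal of PITV and CN = TCI * CI, identically", {
  set.seed(42)
  for (i in 1:25) {
    ptv <- runif(1, 10, 500)
    cov <- sort(runif(3, 0.3, 1)) * ptv  # ptvPD <= ptv95 <= ptv50
    inp <- UPIInputs(ptv = ptv, ptvPD = cov[1], ptv95PD = cov[2],
                     ptv50PD = min(ptv, cov[3] * 1.01), piv = runif(1, 5, 600),
                     dmax = 6200, d95 = 5800, d5 = 6100, pd = 6000)
    x <- upiIndices(computeUPI(inp))
    aux <- upiAuxiliary(computeUPI(inp))
    expect_equal(unname(x["TVR"] * x["PITV"]), 1, tolerance = 1e-12)
    expect_equal(unname(x["CN"]), unname(x["TCI"] * aux["CI"]), tolerance = 1e-12)
    # dimensionless: simultaneous volume rescaling leaves every index fixed
    inp2 <- UPIInputs(ptv = ptv / 1000, ptvPD = cov[1] / 1000,
                      ptv95PD = cov[2] / 1000,
                      ptv50PD = min(ptv, cov[3] * 1.01) / 1000,
                      piv = upiAuxiliary(computeUPI(inp))["TR"] * cov[1] / 1000,
                      dmax = 6200, d95 = 5800, d5 = 6100, pd = 6000)
    expect_equal(upiIndices(computeUPI(inp2)), x, tolerance = 1e-9)
  }
})

test_that("COSI penalizes OAR overdose fractions weighted 1/N", {
  inp <- UPIInputs(ptv = 100, ptvPD = 95, ptv95PD = 100, ptv50PD = 100,
                   piv = 100, dmax = 6000, d95 = 5900, d5 = 6000, pd = 6000,
                   oarFractions = c(A = 0.2, B = 0.4))
  x <- upiIndices(computeUPI(inp))
  expect_equal(unname(x["COSI"]), 1 - (0.5 * 0.2 + 0.5 * 0.4) / 0.95,
               tolerance = 1e-12)
})

test_that("vanishing denominators yield NA with a reason, never infinities", {
  inp <- UPIInputs(ptv = 100, ptvPD = 0, ptv95PD = 0, ptv50PD = 0, piv = 0,
                   dmax = 6000, d95 = 5000, d5 = 6000, pd = 6000)
  res <- computeUPI(inp)
  x <- upiIndices(res)
  expect_true(all(is.na(x[c("RCI", "CN", "TVR", "DGI", "NCI")])))
  expect_false(any(is.infinite(x), na.rm = TRUE))
  expect_true(all(c("RCI", "TVR") %in% names(res@undefined)))
  expect_error(computeQF(res), "undefined index")
})

test_that("quality factor follows 2.718 exp(-sum WiXi)", {
  res <- computeUPI(idealInputs())
  expect_equal(computeQF(res, weights = 0.1), 1, tolerance = 1e-3)
  expect_equal(computeQF(res, weights = 0), 2.718)
  # strictly decreasing in the weighted index sum
  qf <- vapply(c(0.02, 0.05, 0.1), function(w) computeQF(res, w), numeric(1))
  expect_true(all(diff(qf) < 0))
  expect_error(computeQF(res, weights = 2), "\\[0, 1\\]")
  expect_error(computeQF(res, select = "XYZ"), "unknown index")
})

test_that("UPI inputs extract coverages, PIV and Dx from the curves", {
  spec <- coarsePlateauSpec()
  b <- makePhantomPlan(spec)
  g <- getGrid(b, "PTV1")
  m <- rasterizeStructure(getStructure(b, "PTV"), g)
  dd <- computeDDVH(g, m); cc <- cumulate(dd)
  body <- cumulate(computeDDVH(g, wholeGridMask(g)))
  inp <- computeUpiInputs(cc, dd, body, pd = spec@pd)
  expect_equal(inp@ptvPD, inp@ptv, tolerance = 0.01)   # uniform PD coverage
  expect_equal(inp@piv, inp@ptv, tolerance = 0.01)     # PIV = PTV
  expect_error(computeUpiInputs(cc, dd, NULL, spec@pd), "whole-grid")
  # PD above the global maximum: empty prescription isodose volume
  inp0 <- computeUpiInputs(cc, dd, body, pd = 2 * spec@d0)
  expect_equal(inp0@piv, 0)

  # falloff phantom: PIV against the analytic isodose ball at 0.8 D0
  fs <- coarseFalloffSpec()
  fb <- makePhantomPlan(fs)
  fg <- getGrid(fb, "PTV1")
  fbody <- cumulate(computeDDVH(fg, wholeGridMask(fg), binWidth = fs@d0 / 2000))
  an <- analyticCDVH(fs, "BODY")
  expect_equal(volumeAtDose(fbody, 0.8 * fs@d0), an(0.8 * fs@d0),
               tolerance = 0.01)
})
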