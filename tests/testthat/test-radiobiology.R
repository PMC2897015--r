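test_that("Poisson TCP hits its anchors and limits", {
  p <- TCPParams(tcd50 = 4180, gamma50 = 0.6)
  expect_equal(tcpPoisson(FractionalDVH(4180, 1), p), 0.5)
  expect_gt(tcpPoisson(FractionalDVH(41800, 1), p), 0.999)
  # zero dose: 0.5^(2^(2*gamma50*log2(e)... )) evaluated independently at
  # 30-digit precision: 0.5^exp(1.2 ln 2) = 0.203429849758
  expect_equal(tcpPoisson(FractionalDVH(0, 1), p), 0.2034298497585,
               tolerance = 1e-10)
  bad <- new("FractionalDVH", dose = 100, volfrac = 1)
  bad@volfrac <- 0.7
  expect_error(validObject(bad), "sum to 1")
})

test_that("generalized mean dose recovers mean, uniform and serial limits", {
  halves <- FractionalDVH(c(1000, 3000), c(0.5, 0.5))
  expect_equal(gmd(halves, 1), 2000)
  expect_equal(gmd(FractionalDVH(1234, 1), 0.37), 1234)
  # direct 30-digit evaluation of (0.5*1000^(1/0.23) + 0.5*3000^(1/0.23))^0.23
  expect_equal(gmd(halves, 0.23), 2562.84514218991, tolerance = 1e-10)
  # n -> 0: approaches the maximum dose (3000 * 0.5^n for this two-bin case)
  expect_equal(gmd(halves, 0.01), 3000 * 0.5^0.01, tolerance = 1e-10)
  expect_gt(gmd(halves, 0.001), 2995)
  expect_error(gmd(halves, 0), "n must lie")
  expect_error(gmd(halves, -1), "n must lie")
  # bounded by [min, max] and monotone in every dose
  expect_true(gmd(halves, 0.4) >= 1000 && gmd(halves, 0.4) <= 3000)
  expect_gt(gmd(FractionalDVH(c(1100, 3000), c(0.5, 0.5)), 0.4),
            gmd(halves, 0.4))
})

test_that("Lyman NTCP hits its probit anchors", {
  p <- NTCPParams(td50 = 8190, m = 0.19, n = 0.23)
  expect_equal(ntcpLyman(FractionalDVH(8190, 1), p), 0.5)
  # EUD = TD50 (1 + m) sits one probit unit above threshold
  expect_equal(ntcpLyman(FractionalDVH(8190 * 1.19, 1), p), pnorm(1))
  expect_lt(ntcpLyman(FractionalDVH(1e-6, 1), p), 1e-6)
  expect_equal(eud(FractionalDVH(8190, 1), p), 8190)
})

test_that("TCP and NTCP respond monotonically to dose escalation", {
  p <- TCPParams(4180, 0.6); q <- NTCPParams(8190, 0.19, 0.23)
  doses <- seq(2000, 9000, by = 1000)
  tcp <- vapply(doses, function(d)
    tcpPoisson(FractionalDVH(c(d, d * 1.1), c(0.5, 0.5)), p), numeric(1))
  ntcp <- vapply(doses, function(d)
    ntcpLyman(FractionalDVH(c(d, d * 1.1), c(0.5, 0.5)), q), numeric(1))
  expect_true(all(diff(tcp) > 0))
  expect_true(all(diff(ntcp) > 0))
})

test_that("splitting DVH bins in half changes nothing (refinement invariance)", {
  d <- c(1200, 2500, 4100); v <- c(0.25, 0.5, 0.25)
  orig <- FractionalDVH(d, v)
  split <- FractionalDVH(rep(d, each = 2), rep(v / 2, each = 2))
  p <- TCPParams(4180, 0.6); q <- NTCPParams(8190, 0.19, 0.23)
  expect_equal(tcpPoisson(split, p), tcpPoisson(orig, p), tolerance = 1e-14)
  expect_equal(gmd(split, 0.23), gmd(orig, 0.23), tolerance = 1e-14)
  expect_equal(ntcpLyman(split, q), ntcpLyman(orig, q), tolerance = 1e-14)
})

test_that("zero-dose bins keep their volume in the models", {
  p <- TCPParams(4180, 0.6)
  withz <- FractionalDVH(c(0, 4180), c(0.3, 0.7))
  # the zero-dose element contributes exp(2 gamma50 ln 2) to the exponent
  expo <- 0.3 * exp(1.2 * log(2)) + 0.7
  expect_equal(tcpPoisson(withz, p), 0.5^expo, tolerance = 1e-14)
  expect_equal(gmd(withz, 0.5), 4180 * 0.7^0.5, tolerance = 1e-12)
})

test_that("differential DVHs convert to normalized fractional form", {
  g <- DoseGrid(array(rep(c(1000, 2000), each = 100), c(200, 1, 1)))
  fd <- asFractionalDVH(computeDDVH(g, wholeGridMask(g), binWidth = 100))
  expect_equal(sum(fd@volfrac), 1, tolerance = 1e-12)
  expect_length(fd@dose, 2)
  ex <- exampleOutcomeParams()
  expect_s4_class(ex$tcp, "TCPParams")
  expect_s4_class(ex$ntcp, "NTCPParams")
})
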