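test_that("plateau phantoms deliver exactly D0 to every target voxel", {
  spec <- coarsePlateauSpec()
  b <- makePhantomPlan(spec)
  g <- getGrid(b, "PTV1")
  m <- rasterizeStructure(getStructure(b, "PTV"), g)
  doses <- doseArray(g)[maskWeights(m) > 0]
  expect_true(all(doses == spec@d0))
})

test_that("identical seeds give byte-identical bundles on disk", {
  spec <- phantomSpec(dims = c(24, 24, 24), spacing = c(2, 2, 2),
                      targetRadius = 8, falloffLength = 5, oarInner = 8,
                      oarOuter = 14, noiseSd = 40, seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  makePhantomPlan(spec, d1); makePhantomPlan(spec, d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]), label = basename(f1[k]))
  # different seed: different noise
  spec2 <- spec; spec2@seed <- 43L
  b42 <- makePhantomPlan(spec); b43 <- makePhantomPlan(spec2)
  expect_false(identical(doseArray(getGrid(b42, "PTV1")),
                         doseArray(getGrid(b43, "PTV1"))))
})

test_that("a 20 mm sphere on a 1 mm grid rasterizes to within 2% of 4/3 pi R^3", {
  spec <- phantomSpec(dims = c(46, 46, 46), targetRadius = 20,
                      doseModel = "plateau", oarType = "none")
  b <- makePhantomPlan(spec)
  m <- rasterizeStructure(getStructure(b, "PTV"), getGrid(b, "PTV1"))
  vref <- 4 / 3 * pi * 20^3 / 1000
  expect_lt(abs(maskVolume(m) - vref) / vref, 0.02)
})

test_that("geometry that exceeds the grid is rejected", {
  expect_error(phantomSpec(dims = c(20, 20, 20), targetRadius = 15,
                           doseModel = "plateau", oarType = "none"),
               "exceeds the grid")
})

test_that("analytic curves give the closed forms of the three dose models", {
  pl <- coarsePlateauSpec()
  f <- analyticCDVH(pl, "PTV")
  vt <- 4 / 3 * pi * pl@targetRadius^3 / 1000
  expect_equal(f(c(0, pl@d0 / 2, pl@d0)), rep(vt, 3))
  expect_equal(f(pl@d0 + 1), 0)

  fo <- coarseFalloffSpec()   # R = 12, L = 8, shell [12, 20]
  oar <- analyticCDVH(fo, "OAR")
  R <- fo@targetRadius; L <- fo@falloffLength
  # boundary: at D = D0 the isodose ball shrinks to the target sphere
  expect_equal(oar(fo@d0), 0, tolerance = 1e-12)
  expect_equal(oar(0), 4 / 3 * pi * (20^3 - 12^3) / 1000)
  # half dose: r = R + L/2
  body <- analyticCDVH(fo, "BODY")
  expect_equal(body(fo@d0 / 2), 4 / 3 * pi * (R + L / 2)^3 / 1000)
  expect_equal(oar(fo@d0 / 2),
               4 / 3 * pi * ((R + L / 2)^3 - R^3) / 1000)

  noisy <- coarseFalloffSpec(); noisy@noiseSd <- 50
  expect_error(analyticCDVH(noisy, "PTV"), "no closed form")
})

test_that("computed cumulative curves converge to the analytic oracle", {
  fo <- coarseFalloffSpec()
  b <- makePhantomPlan(fo)
  g <- getGrid(b, "PTV1")
  m <- rasterizeStructure(getStructure(b, "OAR"), g, supersample = 2L)
  cc <- cumulate(computeDDVH(g, m))
  an <- analyticCDVH(fo, "OAR")
  expect_lt(nrmsd(cc, an), 2)            # 2 mm lattice; the 1 mm envelope is tested in acceptance
  expect_lt(dta(cc, an, pd = fo@pd), 2)
})

test_that("presets cover the three phantom families", {
  expect_s4_class(presetPhantom("sphere"), "PhantomSpec")
  expect_equal(presetPhantom("box")@targetType, "box")
  expect_equal(presetPhantom("shell")@oarType, "shell")
})
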