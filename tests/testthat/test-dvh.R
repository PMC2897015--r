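uniformGridMask <- function(dose, nvox = 200, voxmm = c(1, 1, 1)) {
  dims <- c(nvox, 1L, 1L)
  g <- DoseGrid(array(dose, dims), spacing = voxmm)
  list(grid = g, mask = wholeGridMask(g))
}

test_that("differential DVH conserves volume and locates uniform dose", {
  gm <- uniformGridMask(5000)
  dd <- computeDDVH(gm$grid, gm$mask, binWidth = 10)
  expect_equal(sum(binVolumes(dd)), maskVolume(gm$mask))
  expect_equal(sum(binVolumes(dd) > 0), 1)
  expect_equal(binVolumes(dd)[binVolumes(dd) > 0], 0.200)

  # half at 1000, half at 2000 -> two equal bins
  g2 <- DoseGrid(array(rep(c(1000, 2000), each = 100), c(200, 1, 1)))
  dd2 <- computeDDVH(g2, wholeGridMask(g2), binWidth = 100)
  nz <- which(binVolumes(dd2) > 0)
  expect_length(nz, 2)
  expect_equal(binVolumes(dd2)[nz[1]], binVolumes(dd2)[nz[2]])
  expect_error(computeDDVH(g2, new("StructureMask", weight = array(0, c(200, 1, 1)),
                                   voxelVolume = 0.001, name = "E")),
               "empty structure")
})

test_that("fractional supersampled volumes propagate into the bins", {
  g <- unitSquareGrid(3000)
  a <- 2 * pi * (0:63) / 64
  sc <- StructureContours("C", list(list(z = 0, rings = list(
    cbind(10 + 6.3 * cos(a), 10 + 6.3 * sin(a))))))
  m <- rasterizeStructure(sc, g, supersample = 3L)
  dd <- computeDDVH(g, m, binWidth = 50)
  expect_equal(sum(binVolumes(dd)), maskVolume(m), tolerance = 1e-12)
  expect_false(all(maskWeights(m) %in% c(0, 1)))  # genuinely fractional
})

test_that("cumulative DVH matches the step construction and is monotone", {
  g2 <- DoseGrid(array(rep(c(1000, 2000), each = 100), c(200, 1, 1)))
  dd <- computeDDVH(g2, wholeGridMask(g2), binWidth = 100)
  cc <- cumulate(dd)
  expect_length(dosePoints(cc), 501)
  expect_equal(volumeAtDose(cc, 0, relative = TRUE), 1)
  expect_equal(volumeAtDose(cc, 1500, relative = TRUE), 0.5)
  expect_equal(volumeAtDose(cc, 2500, relative = TRUE), 0)
  expect_true(all(diff(volumeAtOrAbove(cc)) <= 1e-12))
  expect_equal(volumeAtOrAbove(cc)[1], totalVolume(cc))
})

test_that("cumulative curve tracks the exact voxel-level oracle on a phantom", {
  spec <- coarseFalloffSpec()
  b <- makePhantomPlan(spec)
  g <- getGrid(b, "PTV1")
  m <- rasterizeStructure(getStructure(b, "OAR"), g)
  cc <- cumulate(computeDDVH(g, m))
  orc <- oracleCumulative(g, m)
  expect_lt(nrmsd(cc, orc), 1)
})

test_that("statistics are exact for uniform dose and correct on a linear curve", {
  gm <- uniformGridMask(4000)
  dd <- computeDDVH(gm$grid, gm$mask)
  cc <- cumulate(dd)
  st <- dvhStatistics(cc, dd, NULL, pd = 4000)
  expect_equal(st@minDose, 4000)
  expect_equal(st@maxDose, 4000)
  expect_equal(st@meanDose, 4000)
  expect_equal(st@medianDose, 4000)

  # linear cDVH from (0, 100%) to (100 cGy, 0%): D50 = 50 cGy
  lin <- new("CumulativeDVH", dose = seq(0, 100, length.out = 101),
             volume = seq(10, 0, length.out = 101), totalVolume = 10)
  lind <- new("DifferentialDVH", breaks = seq(0, 100, by = 1),
              volume = rep(0.1, 100), moment = rep(0.1, 100) * seq(0.5, 99.5),
              doseRange = c(0, 100))
  st2 <- dvhStatistics(lin, lind)
  expect_equal(st2@medianDose, 50, tolerance = 1e-6)
})

test_that("coverage percent cells reproduce the whole-percent rounding rule", {
  expect_equal(percentHalfUp(652.7 / 1391.5), 47)
  expect_equal(percentHalfUp(241.0 / 624.4), 39)
  expect_equal(percentHalfUp(124.7 / 308.6), 40)
  expect_equal(percentHalfUp(0.005), 1)   # half rounds up
  expect_equal(percentHalfUp(0.0049), 0)
})

test_that("PD-relative and Vx/Dx queries resolve and clamp correctly", {
  q <- parsePoiQueries(c("V40", "V50", "V65", "V75"), pd = 3900)
  expect_equal(q$dose_cGy, c(4000, 5000, 6500, 7500))
  q2 <- parsePoiQueries(">0.25PD", pd = 3900)
  expect_equal(q2$dose_cGy, 975)

  gm <- uniformGridMask(2000)
  dd <- computeDDVH(gm$grid, gm$mask)
  cc <- cumulate(dd)
  qq <- parsePoiQueries(c("V40", ">0.25PD", "<0.95PD", "D95"), pd = 2000)
  expect_warning(st <- dvhStatistics(cc, dd, qq, pd = 2000), "clamped")
  a <- st@queries
  expect_equal(a$volume_pct[a$token == "V40"], 0)       # 4000 cGy beyond curve
  expect_equal(a$volume_pct[a$token == ">0.25PD"], 100)
  expect_equal(a$volume_pct[a$token == "<0.95PD"], 0)
  expect_equal(a$value[a$token == "D95"], 2000)
  expect_true(st@clamped)
})
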