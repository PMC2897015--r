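test_that("write/read round trip is the identity on valid bundles", {
  spec <- coarseFalloffSpec()
  b <- makePhantomPlan(spec)
  d <- withr::local_tempdir()
  writePlanBundle(b, d)
  b2 <- readPlanBundle(d)
  expect_equal(planIds(b2), planIds(b))
  expect_equal(prescriptionDose(b2, "PTV1"), prescriptionDose(b, "PTV1"))
  expect_identical(doseArray(getGrid(b2, "PTV1")), doseArray(getGrid(b, "PTV1")))
  expect_identical(gridOrigin(getGrid(b2, "PTV1")), gridOrigin(getGrid(b, "PTV1")))
  expect_equal(structureNames(b2), structureNames(b))
  for (nm in structureNames(b))
    expect_equal(getStructure(b2, nm)@slices, getStructure(b, nm)@slices)
})

test_that("malformed bundles fail with the documented error classes", {
  spec <- coarsePlateauSpec()
  b <- makePhantomPlan(spec)
  d <- withr::local_tempdir()
  writePlanBundle(b, d)

  expect_error(readPlanBundle(file.path(d, "nope")), "bundle malformed")

  file.remove(file.path(d, "dose_PTV1.txt"))
  expect_error(readPlanBundle(d), "grid inconsistent")

  writePlanBundle(b, d)
  # truncate the dose file: length no longer matches the declared dims
  v <- readLines(file.path(d, "dose_PTV1.txt"))
  writeLines(v[-(1:10)], file.path(d, "dose_PTV1.txt"))
  expect_error(readPlanBundle(d), "grid inconsistent")

  writePlanBundle(b, d)
  file.remove(file.path(d, "contour_OAR.txt"))
  expect_error(readPlanBundle(d), "dangling structure")
})

test_that("phantom bundles parse back with their declared plans and structures", {
  spec <- phantomSpec(dims = c(24, 24, 24), spacing = c(2, 2, 2),
                      targetRadius = 8, falloffLength = 5, oarInner = 8,
                      oarOuter = 14, seed = 42L)
  d <- withr::local_tempdir()
  makePhantomPlan(spec, d)
  b <- readPlanBundle(d)
  expect_length(b@plans, 1)
  expect_length(b@structures, 2)
})

test_that("composite plans must carry the sum of component prescriptions", {
  g <- DoseGrid(array(100, c(3, 3, 3)))
  mk <- function(pdComp) {
    PlanBundle(plans = list(PlanRecord("P1", 3900), PlanRecord("P2", 1500),
                            PlanRecord("COMP", pdComp, c("P1", "P2"))),
               structures = list(StructureContours("S", list(list(z = 0, rings =
                 list(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))))))),
               grids = list(P1 = g, P2 = g, COMP = g))
  }
  expect_s4_class(mk(5400), "PlanBundle")
  expect_error(mk(6000), "sum of components")
})

test_that("the POI grammar parses, resolves units and rejects junk", {
  f <- withr::local_tempfile(lines = "V40, V50\nV65 V75\nD95\n>0.25PD\nmin")
  q <- readPoiConfig(f, pd = 3900)
  expect_equal(nrow(q), 7)
  expect_equal(q$dose_cGy[q$token == "V40"], 4000)
  expect_equal(q$dose_cGy[q$token == ">0.25PD"], 975)
  expect_equal(q$type[q$token == "D95"], "dose_at_volume")
  expect_equal(q$type[q$token == "min"], "scalar")

  empty <- withr::local_tempfile(lines = "")
  expect_equal(nrow(readPoiConfig(empty)), 0)
  expect_error(parsePoiQueries("Q77"), "cannot parse query token 'Q77'")
})

test_that("reports carry exact uniform-dose rows and are byte-deterministic", {
  spec <- coarsePlateauSpec()
  b <- makePhantomPlan(spec)
  rec <- analyzeBundle(b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeReport(rec, d1)
  writeReport(analyzeBundle(b), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  a <- read.csv(file.path(d1, "report_A_targets.csv"), check.names = FALSE)
  expect_equal(a$Min_cGy, spec@pd)
  expect_equal(a$Max_cGy, spec@pd)
  expect_equal(a$Mean_cGy, spec@pd)
  expect_equal(a[["pct:>1.05PD"]], "0%")
  dsec <- read.csv(file.path(d1, "report_D_statistics.csv"), check.names = FALSE)
  expect_equal(dsec$Structure, "OAR")
  expect_error(writeReport(list(), d1), "no results")
})
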