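test_that("expression TSVs read, validate and round-trip", {
  path <- writeTsv(c("gene\ts1\ts2", "A\t1.5\t2", "B\t0\t4.25", "C\t3\t0.5"))
  m <- readExpressionMatrix(path, scale = "log2")
  expect_s4_class(m, "ExpressionMatrix")
  expect_equal(dim(exprValues(m)), c(3L, 2L))
  expect_equal(exprValues(m)["B", "s2"], 4.25)
  expect_equal(sampleNames(m), c("s1", "s2"))

  dup <- writeTsv(c("gene\ts1", "A\t1", "A\t2"))
  expect_error(readExpressionMatrix(dup), "duplicate")
  bad <- writeTsv(c("gene\ts1", "A\tx"))
  expect_error(readExpressionMatrix(bad), "non-numeric")
  expect_error(readExpressionMatrix(writeTsv("gene\ts1")), "at least one")

  out <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(m, out)
  expect_equal(exprValues(readExpressionMatrix(out)), exprValues(m))

  # generator output survives the TSV cycle
  sim <- simulateExpression(syntheticConfig(nActive = 3, nInactive = 2, seed = 5))
  writeExpressionMatrix(sim$matrix, out)
  back <- readExpressionMatrix(out, scale = "log2")
  expect_equal(exprValues(back), exprValues(sim$matrix), tolerance = 1e-12)
})

test_that("log transform applies log2(RPKM + pseudocount) exactly once", {
  path <- writeTsv(c("gene\ts1\ts2", "A\t0\t7", "B\t15\t1"))
  raw <- readExpressionMatrix(path, scale = "rpkm")
  lg <- logTransform(raw, pseudocount = 1)
  expect_equal(exprScale(lg), "log2")
  expect_equal(exprValues(lg)["A", "s1"], 0)
  expect_equal(exprValues(lg)["A", "s2"], 3)
  expect_equal(exprValues(lg)["B", "s1"], 4)
  expect_error(logTransform(lg), "twice")
  expect_error(logTransform(raw, pseudocount = 0), "positive")
  neg <- writeTsv(c("gene\ts1", "A\t-2"))
  expect_error(readExpressionMatrix(neg, scale = "rpkm"), "negative")
})

test_that("thresholds are midpoints of class means and flag discordant genes", {
  path <- writeTsv(c("gene\ta1\ta2\ti1\ti2",
                     "UP\t4\t6\t0\t2",
                     "FLAT\t1\t1\t1\t1"))
  m <- readExpressionMatrix(path, scale = "log2")
  labels <- c(a1 = "active", a2 = "active", i1 = "inactive", i2 = "inactive")
  expect_warning(th <- fitThresholds(m, labels), "discordant")
  expect_equal(th$threshold[th$gene == "UP"], 3.0)
  expect_true(th$direction_ok[th$gene == "UP"])
  expect_equal(th$threshold[th$gene == "FLAT"], 1.0)
  expect_false(th$direction_ok[th$gene == "FLAT"])
  expect_equal(nrow(th), 2)  # discordant gene kept

  expect_error(fitThresholds(m, c(a1 = "active", a2 = "active")),
               "at least one")
  expect_error(fitThresholds(m, c(a1 = "on", i1 = "inactive")), "active")
})

test_that("thresholds are equivariant under per-gene affine shifts", {
  set.seed(81)
  v <- matrix(rnorm(5 * 6, mean = 3), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  labels <- setNames(rep(c("active", "inactive"), each = 3), paste0("s", 1:6))
  m <- new("ExpressionMatrix", values = v, scale = "log2")
  th <- suppressWarnings(fitThresholds(m, labels))
  shift <- c(2.5, -1, 0, 10, 0.125)
  m2 <- new("ExpressionMatrix", values = v + shift, scale = "log2")
  th2 <- suppressWarnings(fitThresholds(m2, labels))
  expect_equal(th2$threshold, th$threshold + shift)
  expect_equal(th2$direction_ok, th$direction_ok)
})

test_that("softCall is a logistic ramp with a hard-call limit", {
  expect_equal(softCall(2, 2, 0.25), 0.5)
  expect_equal(softCall(2, 2, 0), 0.5)
  expect_equal(softCall(2.1, 2, 0), 1)
  expect_equal(softCall(1.9, 2, 0), 0)
  expect_equal(softCall(2.25, 2, 0.25), 1 / (1 + exp(-1)))
  expect_equal(softCall(2.25, 2, 0.25), 0.73106, tolerance = 1e-5)

  x <- seq(-3, 3, by = 0.05)
  q <- softCall(x, 0, 0.5)
  expect_true(all(diff(q) > 0))          # strictly increasing
  expect_true(all(q > 0 & q < 1))        # bounded away from the hard calls
  # hard and soft calls agree in the softness -> 0 limit away from threshold
  expect_equal(round(softCall(c(-0.2, 0.3), 0, 1e-9)), softCall(c(-0.2, 0.3), 0, 0))
  expect_error(softCall(1, 0, -0.1), "non-negative")
})

test_that("evidence vectors carry soft calls and mark absent genes missing", {
  path <- writeTsv(c("gene\ta1\ti1", "UP\t6\t0", "Up2\t5\t1"))
  m <- readExpressionMatrix(path, scale = "log2")
  th <- fitThresholds(m, c(a1 = "active", i1 = "inactive"))
  th <- rbind(th, data.frame(gene = "GONE", threshold = 2, direction_ok = TRUE,
                             mean_active = NA, mean_inactive = NA))

  q <- evidenceFromSample(m, "i1", th, softness = 0)
  expect_equal(unname(q[c("UP", "Up2")]), c(0, 0))  # inactive profile below thresholds
  expect_true(is.na(q[["GONE"]]))
  qa <- evidenceFromSample(m, "a1", th, softness = 0)
  expect_equal(unname(qa[c("UP", "Up2")]), c(1, 1))
  expect_error(evidenceFromSample(m, "nope", th), "unknown sample")

  # gene matching is case-insensitive after trimming
  th2 <- th; th2$gene <- c(" up ", "UP2", "gone")
  q2 <- evidenceFromSample(m, "a1", th2, softness = 0)
  expect_equal(unname(q2[1:2]), c(1, 1))

  qm <- evidenceMatrix(m, th, softness = 0)
  expect_equal(dim(qm), c(3L, 2L))
  expect_equal(qm["UP", "i1"], 0)
})

test_that("cluster matrices export at 4 decimals with NA for missing", {
  q <- matrix(0.5, 1, 1, dimnames = list("g1", "s1"))
  path <- tempfile(fileext = ".tsv")
  exportClusterMatrix(q, path)
  lines <- readLines(path)
  expect_equal(lines[2], "g1\t0.5000")

  q2 <- matrix(c(0.1234, NA, 1, 0.7311), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  exportClusterMatrix(q2, path)
  back <- as.matrix(read.delim(path, row.names = 1))
  expect_equal(unname(back), unname(q2))
  expect_true(is.na(back["g2", "s1"]))

  expect_error(exportClusterMatrix(matrix(1.5, 1, 1,
                                          dimnames = list("g", "s")), path),
               "\\[0, 1\\]")
})

test_that("the calibrate-evidence-infer chain recovers the calibration labels", {
  cfg <- syntheticConfig(nActive = 2, nInactive = 2, seed = 91)
  sim <- simulateExpression(cfg)
  th <- fitThresholds(sim$matrix, sim$labels)
  model <- readModelPanel(wntTargetPanel())
  for (s in sampleNames(sim$matrix)) {
    q <- evidenceFromSample(sim$matrix, s, th, softness = 0.25)
    pred <- classifyActivity(inferLogOdds(model, q))
    expect_equal(pred, unname(sim$labels[s]))
  }
})
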