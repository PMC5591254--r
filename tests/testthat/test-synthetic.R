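test_that("generator configs validate their parameters", {
  expect_s4_class(syntheticConfig(), "SyntheticConfig")
  expect_equal(length(syntheticConfig()@genes), 34)  # bundled panel default
  expect_error(syntheticConfig(noiseSd = 0), "noiseSd")
  expect_error(syntheticConfig(zeroInflation = 1.5), "zeroInflation")
  expect_error(syntheticConfig(genomeBins = 0), "genomeBins")
  expect_error(syntheticConfig(genes = c("A", "B"), mu = 1), "per gene")
  expect_error(syntheticConfig(depthDispersion = -1), "depthDispersion")
})

test_that("expression simulation is deterministic and honours sample counts", {
  cfg <- syntheticConfig(nActive = 3, nInactive = 2, mode = "single_cell",
                         seed = 21)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(exprValues(a$matrix), exprValues(b$matrix))
  expect_identical(a$labels, b$labels)
  expect_identical(attr(a$manifest, "dropout"), attr(b$manifest, "dropout"))
  expect_equal(sum(a$labels == "active"), 3)
  expect_equal(sum(a$labels == "inactive"), 2)
  expect_equal(exprScale(a$matrix), "log2")

  # a different seed moves the draws
  c2 <- simulateExpression(syntheticConfig(nActive = 3, nInactive = 2,
                                           mode = "single_cell", seed = 22))
  expect_false(identical(exprValues(a$matrix), exprValues(c2$matrix)))

  empty <- simulateExpression(syntheticConfig(nActive = 0, nInactive = 0))
  expect_equal(ncol(exprValues(empty$matrix)), 0)
  expect_equal(length(empty$labels), 0)
})

test_that("a zero effect size leaves active and inactive distributions identical", {
  cfg <- syntheticConfig(genes = paste0("g", 1:20), delta = 0,
                         nActive = 150, nInactive = 150, seed = 23)
  sim <- simulateExpression(cfg)
  v <- exprValues(sim$matrix)
  act <- v[, sim$labels == "active"]; inact <- v[, sim$labels == "inactive"]
  p <- vapply(seq_len(nrow(v)), function(g)
    t.test(act[g, ], inact[g, ])$p.value, numeric(1))
  # gene-wise tests find differences only at the nominal rate
  expect_lt(mean(p < 0.05), 0.15)
  expect_gt(min(p), 1e-4)
})

test_that("single-cell dropout hits lowly expressed genes hardest", {
  genes <- paste0("g", 1:10)
  mu <- seq(0.5, 8, length.out = 10)
  mkCfg <- function(mode) syntheticConfig(
    genes = genes, mu = mu, delta = 2, nActive = 120, nInactive = 0,
    mode = mode, dropoutBase = 0.05, dropoutSlope = 0.2, seed = 24)
  sc <- simulateExpression(mkCfg("single_cell"))
  blk <- simulateExpression(mkCfg("bulk"))
  drop <- attr(sc$manifest, "dropout")
  rate <- rowMeans(drop)
  expect_gt(rate[["g1"]], rate[["g10"]] + 0.3)    # low baseline drops out more
  expect_false(any(attr(blk$manifest, "dropout")))

  # dropout lowers the soft calls of low-baseline genes relative to bulk
  th <- data.frame(gene = genes, threshold = mu + 1)
  qSc <- rowMeans(evidenceMatrix(sc$matrix, th, softness = 0.25))
  qBlk <- rowMeans(evidenceMatrix(blk$matrix, th, softness = 0.25))
  expect_lt(qSc[["g1"]], qBlk[["g1"]] - 0.1)
  expect_lt(abs(qSc[["g10"]] - qBlk[["g10"]]), 0.1)
})

test_that("depth simulation matches its configured moments and limits", {
  # all-dropout limit: nothing covered
  h0 <- simulateDepth(syntheticConfig(zeroInflation = 1, genomeBins = 2000,
                                      seed = 25))
  expect_equal(depths(h0), 0L)
  expect_equal(coverageSummary(h0)$breadth, 0)

  # law of large numbers on the mean
  cfg <- syntheticConfig(depthMean = 16, depthDispersion = 0.5,
                         zeroInflation = 0, genomeBins = 100000L, seed = 26)
  h <- simulateDepth(cfg)
  expect_equal(totalBases(h), 100000)
  expect_lt(abs(coverageSummary(h)$mean_depth - 16) / 16, 0.02)

  # Poisson branch at high mean is nearly uniform
  hp <- simulateDepth(syntheticConfig(depthMean = 30, depthDispersion = 0,
                                      zeroInflation = 0, genomeBins = 100000L,
                                      seed = 27))
  expect_lt(coverageSummary(hp)$gini, 0.2)

  # determinism
  expect_identical(depths(simulateDepth(cfg)), depths(h))
  expect_identical(baseCounts(simulateDepth(cfg)), baseCounts(h))
})

test_that("coverage bias metrics respond monotonically to the generator knobs", {
  ginis <- vapply(c(0.2, 1, 3), function(a)
    giniCoefficient(simulateDepth(syntheticConfig(
      depthDispersion = a, zeroInflation = 0.05, genomeBins = 20000L,
      seed = 28))), numeric(1))
  expect_true(all(diff(ginis) > 0))

  uncov <- vapply(c(0.05, 0.2, 0.5), function(z)
    coverageSummary(simulateDepth(syntheticConfig(
      zeroInflation = z, genomeBins = 20000L, seed = 29)))$frac_uncovered,
    numeric(1))
  expect_true(all(diff(uncov) > 0))
})

test_that("synthetic variant files are valid, deterministic and complete", {
  panel <- loadPanel(driverPanel())
  d <- withr::local_tempdir()
  gen <- writeVariantCalls(list(s1 = panel$variant_id), panel,
                           file.path(d, "v1"))
  lines <- readLines(gen$vcf[["s1"]])
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_equal(sum(!startsWith(lines, "#")), 3)

  # identical inputs give byte-identical files
  gen2 <- writeVariantCalls(list(s1 = panel$variant_id), panel,
                            file.path(d, "v2"))
  expect_identical(readLines(gen$vcf[["s1"]]), readLines(gen2$vcf[["s1"]]))
  expect_identical(readLines(gen$bed[["s1"]]), readLines(gen2$bed[["s1"]]))

  expect_error(writeVariantCalls(list(s1 = "NOPE:c.1A>G"), panel, d),
               "unknown variant")

  # empty plant with full callable evidence screens all wild-type
  gWt <- writeVariantCalls(list(wt = character(0)), panel, file.path(d, "v3"))
  rep <- screenSample(gWt$vcf[["wt"]], panel, gWt$bed[["wt"]], breadth = 0.95,
                      sample = "wt")
  expect_true(all(rep$status == "wild_type"))
})
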