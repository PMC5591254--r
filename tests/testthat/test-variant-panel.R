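test_that("the bundled driver panel loads and validates", {
  panel <- loadPanel(driverPanel())
  expect_equal(nrow(panel), 3)
  expect_setequal(panel$gene, c("CTNNB1", "KRAS", "PIK3CA"))
  expect_true(all(c("c.134C>T", "c.35G>A", "c.3140A>G") %in% panel$cdna))
  expect_true(all(panel$ref != panel$alt))
  expect_type(panel$pos, "integer")

  empty <- writeTsv("gene\tchrom\tpos\tref\talt\tcdna\tprotein")
  expect_warning(p0 <- loadPanel(empty), "empty")
  expect_equal(nrow(p0), 0)

  expect_error(loadPanel(writeTsv(c(
    "gene\tchrom\tpos\tref\talt\tcdna\tprotein",
    "X\tchr1\t100\tA\tA\tc.1A>A\tp"))), "ref == alt")
  expect_error(loadPanel(writeTsv(c(
    "gene\tchrom\tpos\tref\talt\tcdna\tprotein",
    "X\tchr1\t100\tA\tn\tc.1A>N\tp"))), "ACGT")
  expect_error(loadPanel(writeTsv(c(
    "gene\tchrom\tpos\tref\talt\tcdna\tprotein",
    "X\tchr1\t1.5\tA\tG\tc.1A>G\tp"))), "integer")
})

test_that("screening assigns mutant, wild_type, insufficient and excluded", {
  panel <- loadPanel(driverPanel())
  d <- withr::local_tempdir()
  gen <- writeVariantCalls(
    plant = list(cellMut = panel$variant_id[c(1, 3)], cellWt = character(0)),
    panel = panel, dir = d,
    uncallable = list(cellWt = panel$variant_id[2]))

  repMut <- screenSample(gen$vcf[["cellMut"]], panel, gen$bed[["cellMut"]],
                         breadth = 0.85, sample = "cellMut")
  expect_equal(repMut$status[repMut$gene == "CTNNB1"], "mutant")
  expect_equal(repMut$status[repMut$gene == "PIK3CA"], "mutant")
  expect_equal(repMut$status[repMut$gene == "KRAS"], "wild_type")

  repWt <- screenSample(gen$vcf[["cellWt"]], panel, gen$bed[["cellWt"]],
                        breadth = 0.9, sample = "cellWt")
  expect_equal(repWt$status[repWt$gene == "KRAS"], "insufficient_coverage")
  expect_equal(sum(repWt$status == "wild_type"), 2)

  # every (sample, variant) pair gets exactly one status
  expect_true(all(repMut$status %in% c("mutant", "wild_type",
                                       "insufficient_coverage",
                                       "sample_excluded")))
  expect_equal(nrow(repMut), nrow(panel))

  # the breadth gate excludes the whole sample
  repEx <- screenSample(gen$vcf[["cellMut"]], panel, gen$bed[["cellMut"]],
                        breadth = 0.65, sample = "cellMut")
  expect_true(all(repEx$status == "sample_excluded"))
  expect_error(screenSample(gen$vcf[["cellMut"]], panel, gen$bed[["cellMut"]],
                            breadth = 1.2), "\\[0, 1\\]")
})

test_that("raising the breadth gate only ever flips statuses to excluded", {
  panel <- loadPanel(driverPanel())
  d <- withr::local_tempdir()
  gen <- writeVariantCalls(list(c1 = panel$variant_id[1]), panel, d)
  breadth <- 0.75
  lo <- screenSample(gen$vcf[["c1"]], panel, gen$bed[["c1"]], breadth,
                     breadthGate = 0.5)
  hi <- screenSample(gen$vcf[["c1"]], panel, gen$bed[["c1"]], breadth,
                     breadthGate = 0.8)
  changed <- lo$status != hi$status
  expect_true(all(hi$status[changed] == "sample_excluded"))
  same <- screenSample(gen$vcf[["c1"]], panel, gen$bed[["c1"]], breadth,
                       breadthGate = 0.7)
  expect_equal(same$status, lo$status)
})

test_that("VCF matching is exact on alleles, decomposes multi-allelics and honours FILTER/GT", {
  panel <- loadPanel(driverPanel())
  d <- withr::local_tempdir()
  vcf <- file.path(d, "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr3>", "##contig=<ID=chr12>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s", sep = "\t"),
    "chr3\t41266113\t.\tC\tT,G\t50\tPASS\t.\tGT\t0/1",       # multi-allelic hit
    "chr12\t25398284\t.\tC\tT\t50\tq10\t.\tGT\t0/1",         # filtered out
    "chr3\t178952085\t.\tA\tG\t50\tPASS\t.\tGT\t0/0"),       # no alt allele
    vcf)
  bed <- file.path(d, "all.bed")
  writeLines(paste(panel$chrom, panel$pos - 1L, panel$pos, sep = "\t"), bed)

  rep <- screenSample(vcf, panel, bed, breadth = 0.9, sample = "s")
  expect_equal(rep$status[rep$gene == "CTNNB1"], "mutant")
  expect_equal(rep$status[rep$gene == "KRAS"], "wild_type")     # non-PASS record
  expect_equal(rep$status[rep$gene == "PIK3CA"], "wild_type")   # hom-ref GT
})

test_that("aggregation reproduces cohort tallies and rejects mixed panels", {
  panel <- loadPanel(driverPanel())
  d <- withr::local_tempdir()
  # an RKO-like cohort: 6 cells, 5 wild-type at CTNNB1, one below the gate
  plant <- setNames(rep(list(character(0)), 6), paste0("rko", 1:6))
  gen <- writeVariantCalls(plant, panel, d)
  reports <- lapply(paste0("rko", 1:5), function(s)
    screenSample(gen$vcf[[s]], panel, gen$bed[[s]], breadth = 0.85, sample = s))
  reports$excluded <- screenSample(gen$vcf[["rko6"]], panel, gen$bed[["rko6"]],
                                   breadth = 0.5, sample = "rko6")
  agg <- aggregateReports(reports)
  expect_equal(nrow(agg$grid), 6)
  ct <- agg$tallies[agg$tallies$gene == "CTNNB1", ]
  expect_equal(ct$n_wild_type, 5)
  expect_equal(ct$n_callable, 5)
  expect_equal(ct$n_excluded, 1)
  expect_match(ct$summary, "5 of 5 callable cells wild_type")

  expect_equal(nrow(aggregateReports(list())$grid), 0)

  other <- panel[1:2, ]
  other$variant_id <- NULL
  rep2 <- screenSample(gen$vcf[["rko1"]], other, gen$bed[["rko1"]],
                       breadth = 0.9, sample = "x")
  expect_error(aggregateReports(list(reports[[1]], rep2)), "different panels")
})

test_that("screening recovers the generator's planted truth exactly", {
  panel <- loadPanel(driverPanel())
  d <- withr::local_tempdir()
  set.seed(110)
  samples <- sprintf("cell%02d", 1:8)
  plant <- lapply(samples, function(s)
    sample(panel$variant_id, sample(0:3, 1)))
  names(plant) <- samples
  uncall <- list(cell03 = panel$variant_id[2], cell07 = panel$variant_id[1:2])
  # a planted variant is reported from the VCF even if its site is uncallable
  uncall$cell07 <- setdiff(uncall$cell07, plant$cell07)
  uncall$cell03 <- setdiff(uncall$cell03, plant$cell03)
  gen <- writeVariantCalls(plant, panel, d, uncallable = uncall)

  got <- do.call(rbind, lapply(samples, function(s)
    screenSample(gen$vcf[[s]], panel, gen$bed[[s]], breadth = 0.9, sample = s)))
  key <- paste(got$sample, got$variant_id)
  mkey <- paste(gen$manifest$sample, gen$manifest$variant_id)
  expect_equal(got$status[match(mkey, key)], gen$manifest$expected_status)
})
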