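#' @include AllClasses.R utils.R coverage.R
NULL

#' Build a synthetic-data generator configuration
#'
#' Defaults emulate the structure the analysis assumes: target genes
#' up-regulated by \code{delta = 2} log2 units in pathway-active samples over
#' baselines spread across 2--8 log2 RPKM, Gaussian measurement noise of 0.5
#' log2 units, optional single-cell dropout that rises linearly as a gene's
#' baseline falls below 4 log2 RPKM, and zero-inflated negative-binomial
#' per-bin sequencing depth mimicking whole-genome-amplification bias.
#'
#' @param genes gene names; default the bundled 34-gene Wnt target panel.
#' @param mu per-gene baseline means (log2 RPKM); default evenly spread over
#'   \[2, 8\].
#' @param delta per-gene activation effects (log2 units); scalar recycled.
#' @param noiseSd expression noise SD (log2 units).
#' @param nActive,nInactive numbers of active/inactive samples.
#' @param mode \code{"bulk"} or \code{"single_cell"}.
#' @param dropoutBase,dropoutSlope,dropoutRef dropout model: a value drops to
#'   log2-pseudocount level with probability
#'   \code{min(1, dropoutBase + dropoutSlope * max(0, dropoutRef - mu))}.
#' @param depthMean mean per-bin depth.
#' @param depthDispersion negative-binomial overdispersion \eqn{\alpha}
#'   (variance \eqn{\mu(1+\alpha\mu)}); 0 gives exact Poisson depth.
#' @param zeroInflation probability a bin is zeroed outright (allelic/locus
#'   dropout of the amplification).
#' @param genomeBins number of simulated genome bins.
#' @param seed integer seed; all draws are reproducible from it.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(genes = NULL, mu = NULL, delta = 2,
                            noiseSd = 0.5, nActive = 2L, nInactive = 2L,
                            mode = c("bulk", "single_cell"),
                            dropoutBase = 0.05, dropoutSlope = 0.15,
                            dropoutRef = 4, depthMean = 16,
                            depthDispersion = 0.5, zeroInflation = 0.1,
                            genomeBins = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(genes))
    genes <- utils::read.delim(wntTargetPanel(), stringsAsFactors = FALSE)$gene
  n <- length(genes)
  if (is.null(mu)) mu <- seq(2, 8, length.out = n)
  stopIfNot(length(mu) == n, "mu must have one value per gene")
  delta <- rep_len(delta, n)
  new("SyntheticConfig", genes = as.character(genes), mu = as.numeric(mu),
      delta = as.numeric(delta), noiseSd = as.numeric(noiseSd),
      nActive = as.integer(nActive), nInactive = as.integer(nInactive),
      mode = mode, dropoutBase = as.numeric(dropoutBase),
      dropoutSlope = as.numeric(dropoutSlope),
      dropoutRef = as.numeric(dropoutRef), depthMean = as.numeric(depthMean),
      depthDispersion = as.numeric(depthDispersion),
      zeroInflation = as.numeric(zeroInflation),
      genomeBins = as.integer(genomeBins), seed = as.integer(seed))
}

#' Simulate a log2 expression matrix with known pathway activity
#'
#' Active samples draw gene g from Normal(mu_g + delta_g, noiseSd), inactive
#' samples from Normal(mu_g, noiseSd). In \code{single_cell} mode a value
#' additionally drops out (is set to 0, the log2-pseudocount level of an
#' unobserved transcript) with probability
#' \code{min(1, dropoutBase + dropoutSlope * max(0, dropoutRef - mu_g))},
#' so lowly expressed genes drop out more often. Deterministic given the
#' config seed.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return list with \code{matrix} (an \linkS4class{ExpressionMatrix}, log2
#'   scale), \code{labels} (named character, \code{"active"}/\code{"inactive"})
#'   and \code{manifest} (per-cell truth: a data.frame of sample, label, and
#'   per-value dropout indicators as a gene-by-sample logical matrix in
#'   \code{attr(manifest, "dropout")}).
#' @export
simulateExpression <- function(cfg) {
  stopIfNot(is(cfg, "SyntheticConfig"), "cfg must be a SyntheticConfig")
  nG <- length(cfg@genes)
  nS <- cfg@nActive + cfg@nInactive
  labels <- rep(c("active", "inactive"), c(cfg@nActive, cfg@nInactive))
  samples <- c(sprintf("active_%02d", seq_len(cfg@nActive)),
               sprintf("inactive_%02d", seq_len(cfg@nInactive)))
  names(labels) <- samples

  set.seed(deriveSeed(cfg@seed, 101L))
  if (nS == 0) {
    values <- matrix(numeric(0), nG, 0, dimnames = list(cfg@genes, NULL))
  } else {
    means <- outer(cfg@mu, rep(1, nS)) +
      outer(cfg@delta, as.numeric(labels == "active"))
    values <- matrix(stats::rnorm(nG * nS, mean = means, sd = cfg@noiseSd),
                     nrow = nG, ncol = nS,
                     dimnames = list(cfg@genes, samples))
  }
  dropout <- matrix(FALSE, nG, nS, dimnames = list(cfg@genes, samples))
  if (cfg@mode == "single_cell" && nS > 0) {
    pDrop <- pmin(1, cfg@dropoutBase +
                    cfg@dropoutSlope * pmax(0, cfg@dropoutRef - cfg@mu))
    dropout <- matrix(stats::runif(nG * nS) < pDrop, nG, nS,
                      dimnames = list(cfg@genes, samples))
    values[dropout] <- 0
  }
  manifest <- data.frame(sample = samples, label = unname(labels),
                         stringsAsFactors = FALSE)
  attr(manifest, "dropout") <- dropout
  list(matrix = new("ExpressionMatrix", values = values, scale = "log2"),
       labels = labels, manifest = manifest)
}

#' Simulate per-bin sequencing depth of an amplified single-cell genome
#'
#' Each genome bin yields depth 0 with probability \code{zeroInflation}
#' (amplification dropout) and otherwise a negative-binomial draw with mean
#' \code{depthMean} and overdispersion \code{depthDispersion} (variance
#' \eqn{\mu(1+\alpha\mu)}); \code{depthDispersion = 0} takes an exact Poisson
#' branch. Deterministic given the config seed.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{DepthHistogram} over \code{genomeBins} bins.
#' @export
simulateDepth <- function(cfg) {
  stopIfNot(is(cfg, "SyntheticConfig"), "cfg must be a SyntheticConfig")
  set.seed(deriveSeed(cfg@seed, 202L))
  n <- cfg@genomeBins
  d <- if (cfg@depthDispersion == 0) {
    stats::rpois(n, lambda = cfg@depthMean)
  } else {
    stats::rnbinom(n, mu = cfg@depthMean, size = 1 / cfg@depthDispersion)
  }
  zero <- stats::runif(n) < cfg@zeroInflation
  d[zero] <- 0L
  tab <- table(d)
  depthHistogram(as.integer(names(tab)), as.numeric(tab))
}

#' Write a depth histogram in the genomecov genome-summary dialect
#'
#' @param h a \linkS4class{DepthHistogram}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeDepthHistogram <- function(h, path) {
  stopIfNot(is(h, "DepthHistogram"), "h must be a DepthHistogram")
  tab <- data.frame(label = "genome", depth = h@depth,
                    bases = format(h@bases, scientific = FALSE, trim = TRUE),
                    total = format(totalBases(h), scientific = FALSE, trim = TRUE),
                    fraction = sprintf("%.7g", h@bases / totalBases(h)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write synthetic per-sample variant calls, callable regions and truth
#'
#' For each sample in \code{plant}, writes a minimal valid VCF 4.2 containing
#' exactly the planted panel records (FILTER PASS, genotype 0/1) and a
#' callable-region BED covering every panel site except those listed in
#' \code{uncallable} for that sample. The returned manifest records the truth
#' each (sample, variant) pair should screen to: \code{mutant} when planted,
#' \code{insufficient_coverage} when uncallable, \code{wild_type} otherwise.
#'
#' @param plant named list: sample name -> character vector of planted
#'   \code{variant_id}s (subset of the panel; empty vectors allowed).
#' @param panel validated panel table from [loadPanel()].
#' @param dir output directory (created if needed).
#' @param uncallable optional named list: sample -> \code{variant_id}s whose
#'   sites are left out of the callable BED.
#' @return list with \code{vcf} and \code{bed} (named file paths per sample)
#'   and \code{manifest} (data.frame sample, variant_id, expected_status).
#' @export
writeVariantCalls <- function(plant, panel, dir, uncallable = list()) {
  panel <- validatePanel(panel)
  stopIfNot(is.list(plant) && !is.null(names(plant)) && all(nzchar(names(plant))),
            "plant must be a named list (sample -> variant ids)")
  allIds <- unlist(c(plant, uncallable), use.names = FALSE)
  unknown <- setdiff(allIds, panel$variant_id)
  stopIfNot(length(unknown) == 0, "plant references unknown variant(s): %s",
            paste(unknown, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  contigs <- unique(panel$chrom)
  vcfPaths <- bedPaths <- character(0)
  manifest <- NULL
  for (s in names(plant)) {
    planted <- panel$variant_id %in% plant[[s]]
    uncall <- panel$variant_id %in% uncallable[[s]]
    vcfPath <- file.path(dir, paste0(s, ".vcf"))
    bedPath <- file.path(dir, paste0(s, ".callable.bed"))

    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s>", contigs),
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", s, sep = "\t"))
    body <- if (any(planted)) {
      p <- panel[planted, , drop = FALSE]
      p <- p[order(p$chrom, p$pos), , drop = FALSE]
      paste(p$chrom, p$pos, ".", p$ref, p$alt, "100", "PASS", ".", "GT", "0/1",
            sep = "\t")
    } else character(0)
    writeLines(c(header, body), vcfPath)

    callable <- panel[!uncall, , drop = FALSE]
    callable <- callable[order(callable$chrom, callable$pos), , drop = FALSE]
    bedLines <- if (nrow(callable)) {
      paste(callable$chrom, callable$pos - 1L, callable$pos, sep = "\t")
    } else character(0)
    writeLines(bedLines, bedPath)

    vcfPaths[s] <- vcfPath; bedPaths[s] <- bedPath
    manifest <- rbind(manifest, data.frame(
      sample = s, variant_id = panel$variant_id,
      expected_status = ifelse(planted, "mutant",
                               ifelse(uncall, "insufficient_coverage",
                                      "wild_type")),
      stringsAsFactors = FALSE))
  }
  manifestPath <- file.path(dir, "variant_manifest.tsv")
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcfPaths, bed = bedPaths, manifest = manifest,
       manifest_path = manifestPath)
}
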