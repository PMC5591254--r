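#' @include utils.R
NULL

PANEL_COLS <- c("gene", "chrom", "pos", "ref", "alt", "cdna", "protein")
PANEL_STATUSES <- c("mutant", "wild_type", "insufficient_coverage",
                    "sample_excluded")

validatePanel <- function(panel) {
  stopIfNot(is.data.frame(panel) && all(PANEL_COLS %in% names(panel)),
            "panel must have columns: %s", paste(PANEL_COLS, collapse = ", "))
  if (nrow(panel) == 0) return(panel)
  stopIfNot(all(grepl("^[ACGT]+$", panel$ref)) && all(grepl("^[ACGT]+$", panel$alt)),
            "alleles must be uppercase ACGT strings")
  stopIfNot(all(panel$ref != panel$alt), "panel row with ref == alt")
  stopIfNot(is.numeric(panel$pos) && all(panel$pos == round(panel$pos)) &&
              all(panel$pos >= 1), "pos must be 1-based positive integers")
  panel$pos <- as.integer(panel$pos)
  panel$variant_id <- paste0(panel$gene, ":", panel$cdna)
  stopIfNot(!anyDuplicated(panel$variant_id), "duplicate panel entries")
  panel
}

#' Load a driver-mutation panel
#'
#' Reads a TSV with columns \code{gene, chrom, pos, ref, alt, cdna, protein}
#' (1-based positions, uppercase ACGT alleles; HGVS labels are metadata and
#' never mapped to coordinates — the genome build is the panel file's
#' responsibility). The package bundles an example panel with the three
#' colorectal hotspots CTNNB1 c.134C>T (S45F), KRAS c.35G>A (G12D) and
#' PIK3CA c.3140A>G (H1047R); see [driverPanel()].
#'
#' @param path panel TSV path.
#' @return \code{data.frame} of validated panel entries plus a derived
#'   \code{variant_id} column (\code{gene:cdna}); empty with a warning if the
#'   file holds no rows.
#' @export
loadPanel <- function(path) {
  stopIfNot(file.exists(path), "panel file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  if (nrow(tab) == 0) {
    warning("driver panel is empty: ", path, call. = FALSE)
    tab$variant_id <- character(0)
    return(tab)
  }
  validatePanel(tab)
}

#' Path to the bundled driver-mutation panel
#'
#' @return file path of the bundled three-entry colorectal driver panel TSV.
#' @export
driverPanel <- function() {
  system.file("extdata", "driver_panel.tsv", package = "wntscreen",
              mustWork = TRUE)
}

# read a VCF into a flat record table (chrom, pos, ref, alt, filter, has_alt),
# multi-allelic records decomposed into one row per alternate allele
readVcfRecords <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "panel")
  if (nrow(vcf) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      filter = character(0), has_alt = logical(0)))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  hasAlt <- if (is.null(gt)) rep(TRUE, nrow(vcf)) else
    apply(gt, 1, function(g) any(grepl("[1-9]", g)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(rr$REF),
             alt = as.character(rr$ALT),
             filter = as.character(rr$FILTER),
             has_alt = hasAlt,
             stringsAsFactors = FALSE)
}

# callable evidence as a GRanges, from a BED path or a ready-made GRanges
asCallable <- function(callable) {
  if (is(callable, "GRanges")) return(callable)
  stopIfNot(is.character(callable) && file.exists(callable),
            "callable must be a GRanges or an existing BED path")
  rtracklayer::import(callable, format = "BED")
}

#' Screen one sample's variant calls against a driver panel
#'
#' Applies the genome-breadth gate first: samples whose coverage breadth is
#' below \code{breadthGate} (default 0.70 of the genome covered at least
#' once) receive \code{sample_excluded} for every panel entry. Otherwise each
#' panel variant is \code{mutant} when the VCF carries a matching record
#' (exact chrom/pos/ref/alt after multi-allelic decomposition, FILTER PASS or
#' ".", and at least one alternate allele in GT when genotypes are present);
#' \code{wild_type} when no record matches but the site lies inside the
#' callable evidence; and \code{insufficient_coverage} otherwise — absence
#' from a variants-only VCF is not evidence of reference under single-cell
#' amplification dropout.
#'
#' @param vcf path to a VCF 4.x file of the sample's calls (1-based).
#' @param panel validated panel table from [loadPanel()].
#' @param callable callable-region evidence: a BED path (0-based half-open)
#'   or a \code{GRanges}.
#' @param breadth the sample's genome coverage breadth, in \[0, 1\].
#' @param sample sample name recorded in the report.
#' @param breadthGate minimum breadth for inclusion; default 0.70.
#' @return \code{data.frame} with one row per panel entry: \code{sample},
#'   \code{gene}, \code{variant_id}, \code{cdna}, \code{protein},
#'   \code{chrom}, \code{pos}, \code{breadth}, \code{status}.
#' @export
screenSample <- function(vcf, panel, callable, breadth,
                         sample = "sample", breadthGate = 0.70) {
  panel <- validatePanel(panel)
  stopIfNot(is.numeric(breadth) && length(breadth) == 1 &&
              breadth >= 0 && breadth <= 1, "breadth must lie in [0, 1]")
  out <- data.frame(sample = sample, gene = panel$gene,
                    variant_id = panel$variant_id, cdna = panel$cdna,
                    protein = panel$protein, chrom = panel$chrom,
                    pos = panel$pos, breadth = breadth,
                    status = NA_character_, stringsAsFactors = FALSE)
  if (nrow(panel) == 0) return(out)

  if (breadth < breadthGate) {
    out$status <- "sample_excluded"
    return(out)
  }
  recs <- readVcfRecords(vcf)
  recs <- recs[recs$filter %in% c("PASS", ".") & recs$has_alt, , drop = FALSE]
  callableGr <- asCallable(callable)
  sites <- GenomicRanges::GRanges(panel$chrom,
                                  IRanges::IRanges(panel$pos, panel$pos))
  inCallable <- IRanges::overlapsAny(sites, callableGr)

  for (i in seq_len(nrow(panel))) {
    hit <- recs$chrom == panel$chrom[i] & recs$pos == panel$pos[i] &
      recs$ref == panel$ref[i] & recs$alt == panel$alt[i]
    out$status[i] <- if (any(hit)) "mutant"
      else if (inCallable[i]) "wild_type"
      else "insufficient_coverage"
  }
  out
}

#' Aggregate per-sample screening reports
#'
#' Combines [screenSample()] outputs across samples into a samples-by-variants
#' status grid and per-variant tallies of the kind printed in cohort reports,
#' e.g. "5 of 5 callable cells wild_type, 1 insufficient_coverage".
#'
#' @param reports a list of (or single row-bound) screening data.frames over
#'   the same panel.
#' @return list with elements \code{rows} (all report rows), \code{grid}
#'   (samples x variants status data.frame), and \code{tallies} (per variant:
#'   counts of each status, the number of callable cells — mutant plus
#'   wild-type — and a human-readable \code{summary} string).
#' @export
aggregateReports <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  rows <- do.call(rbind, reports)
  if (is.null(rows) || nrow(rows) == 0) {
    return(list(rows = rows,
                grid = data.frame(sample = character(0)),
                tallies = data.frame(variant_id = character(0))))
  }
  panels <- unique(vapply(reports, function(r)
    paste(sort(r$variant_id), collapse = "|"), character(1)))
  stopIfNot(length(panels) == 1, "reports use different panels")

  samples <- unique(rows$sample)
  variants <- unique(rows$variant_id)
  grid <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (v in variants)
    grid[[v]] <- rows$status[match(paste(samples, v),
                                   paste(rows$sample, rows$variant_id))]

  tallies <- do.call(rbind, lapply(variants, function(v) {
    st <- rows$status[rows$variant_id == v]
    counts <- vapply(PANEL_STATUSES, function(s) sum(st == s), integer(1))
    callable <- counts[["mutant"]] + counts[["wild_type"]]
    parts <- character(0)
    if (counts[["mutant"]] > 0)
      parts <- c(parts, sprintf("%d of %d callable cells mutant",
                                counts[["mutant"]], callable))
    if (counts[["wild_type"]] > 0)
      parts <- c(parts, sprintf("%d of %d callable cells wild_type",
                                counts[["wild_type"]], callable))
    if (counts[["insufficient_coverage"]] > 0)
      parts <- c(parts, sprintf("%d insufficient_coverage",
                                counts[["insufficient_coverage"]]))
    if (counts[["sample_excluded"]] > 0)
      parts <- c(parts, sprintf("%d sample_excluded", counts[["sample_excluded"]]))
    data.frame(variant_id = v, gene = rows$gene[match(v, rows$variant_id)],
               n_mutant = counts[["mutant"]],
               n_wild_type = counts[["wild_type"]],
               n_insufficient = counts[["insufficient_coverage"]],
               n_excluded = counts[["sample_excluded"]],
               n_callable = callable,
               summary = paste(parts, collapse = ", "),
               stringsAsFactors = FALSE)
  }))
  list(rows = rows, grid = grid, tallies = tallies)
}
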