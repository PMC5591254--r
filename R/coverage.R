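#' @include AllClasses.R utils.R
NULL

#' Construct a depth histogram
#'
#' @param depth non-negative integer depth classes (duplicates are pooled).
#' @param bases base counts per class (non-negative; zero-count classes are
#'   dropped).
#' @return a \linkS4class{DepthHistogram}.
#' @export
depthHistogram <- function(depth, bases) {
  stopIfNot(length(depth) == length(bases), "depth and bases lengths differ")
  stopIfNot(all(depth >= 0) && all(depth == round(depth)),
            "depths must be non-negative integers")
  stopIfNot(all(is.finite(bases)) && all(bases >= 0) && all(bases == round(bases)),
            "bases must be non-negative integer counts")
  keep <- bases > 0
  depth <- as.integer(depth[keep]); bases <- as.numeric(bases[keep])
  agg <- rowsum(bases, depth)
  d <- as.integer(rownames(agg))
  o <- order(d)
  new("DepthHistogram", depth = d[o], bases = as.numeric(agg[o, 1]))
}

#' Read per-sample depth data
#'
#' Two dialects are supported. \code{"histogram"} is the genome-summary
#' output of \code{bedtools genomecov}: rows
#' \code{(label, depth, bases_at_depth, total_bases, fraction)}, no header;
#' if any rows carry the label \code{genome} only those are used, otherwise
#' per-chromosome rows are aggregated. \code{"bed_intervals"} is a BED4-like
#' TSV \code{(chrom, start, end, depth)} with 0-based half-open intervals;
#' interval lengths accumulate into base counts and overlapping intervals are
#' rejected.
#'
#' @param path TSV file path.
#' @param dialect \code{"histogram"} or \code{"bed_intervals"}.
#' @return a \linkS4class{DepthHistogram} aggregated over all
#'   chromosomes/intervals.
#' @export
readDepthHistogram <- function(path, dialect = c("histogram", "bed_intervals")) {
  dialect <- match.arg(dialect)
  stopIfNot(file.exists(path), "depth file not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopIfNot(nrow(tab) > 0, "depth file is empty: %s", path)

  if (dialect == "histogram") {
    stopIfNot(ncol(tab) >= 4, "histogram dialect needs columns label, depth, bases, total")
    names(tab)[1:4] <- c("label", "depth", "bases", "total")
    if (any(tab$label == "genome")) tab <- tab[tab$label == "genome", ]
    stopIfNot(is.numeric(tab$depth) && all(tab$depth >= 0), "negative or non-numeric depth")
    stopIfNot(is.numeric(tab$bases) && all(tab$bases >= 0), "invalid base count")
    for (lab in unique(tab$label)) {
      rows <- tab[tab$label == lab, ]
      stopIfNot(length(unique(rows$total)) == 1 &&
                  sum(rows$bases) == rows$total[1],
                "inconsistent totals for label %s: bases sum to %.0f, total column says %.0f",
                lab, sum(rows$bases), rows$total[1])
    }
    depthHistogram(tab$depth, tab$bases)
  } else {
    stopIfNot(ncol(tab) >= 4, "bed_intervals dialect needs columns chrom, start, end, depth")
    names(tab)[1:4] <- c("chrom", "start", "end", "depth")
    stopIfNot(is.numeric(tab$start) && is.numeric(tab$end) && is.numeric(tab$depth),
              "non-numeric BED coordinates or depth")
    stopIfNot(all(tab$depth >= 0), "negative depth in BED input")
    stopIfNot(all(tab$end > tab$start), "BED interval with end <= start")
    o <- order(tab$chrom, tab$start)
    tab <- tab[o, ]
    prevEnd <- c(-Inf, tab$end[-nrow(tab)])
    sameChrom <- c(FALSE, tab$chrom[-1] == tab$chrom[-nrow(tab)])
    stopIfNot(!any(sameChrom & tab$start < prevEnd),
              "overlapping BED intervals")
    depthHistogram(tab$depth, tab$end - tab$start)
  }
}

#' Lorenz curve of coverage uniformity
#'
#' Sorts depth classes by increasing depth and returns the cumulative
#' fraction of total reads (y) against the cumulative fraction of genome
#' bases (x), starting at (0, 0). Perfectly uniform coverage gives the
#' diagonal; amplification bias bows the curve below it, with uncovered bases
#' visible as the initial flat segment.
#'
#' @param h a \linkS4class{DepthHistogram} with positive total reads.
#' @return \code{data.frame} with columns \code{x} (genome fraction) and
#'   \code{y} (read fraction), convex, non-decreasing, ending at (1, 1).
#' @export
lorenzCurve <- function(h) {
  stopIfNot(is(h, "DepthHistogram"), "h must be a DepthHistogram")
  reads <- as.numeric(h@depth) * h@bases
  stopIfNot(sum(reads) > 0, "no reads: Lorenz curve undefined")
  data.frame(x = c(0, cumsum(h@bases) / sum(h@bases)),
             y = c(0, cumsum(reads) / sum(reads)))
}

#' Coverage-depth profile
#'
#' Fraction of genome bases covered at or above each depth \code{d}, for
#' \code{d = 1 .. maxDepth} — the coverage graph used to read off how much of
#' the genome reaches the 20x or 30x depth typically required for SNP
#' calling.
#'
#' @param h a \linkS4class{DepthHistogram}.
#' @param maxDepth largest depth evaluated (>= 1); default covers the
#'   histogram's own range.
#' @return \code{data.frame} with columns \code{depth}, \code{fraction}
#'   (non-increasing; the value at depth 1 is the breadth of coverage).
#' @export
coverageProfile <- function(h, maxDepth = max(depths(h))) {
  stopIfNot(is(h, "DepthHistogram"), "h must be a DepthHistogram")
  stopIfNot(length(maxDepth) == 1 && maxDepth >= 1, "maxDepth must be >= 1")
  maxDepth <- as.integer(maxDepth)
  d <- seq_len(maxDepth)
  frac <- vapply(d, function(k) sum(h@bases[h@depth >= k]), numeric(1)) /
    totalBases(h)
  data.frame(depth = d, fraction = frac)
}

#' Fraction of bases at or above a depth
#'
#' @param h a \linkS4class{DepthHistogram}.
#' @param minDepth depth cutoff.
#' @return numeric fraction in \[0, 1\]; \code{minDepth = 1} gives breadth.
#' @export
fractionAtLeast <- function(h, minDepth) {
  stopIfNot(is(h, "DepthHistogram"), "h must be a DepthHistogram")
  sum(h@bases[h@depth >= minDepth]) / totalBases(h)
}

#' Gini coefficient of coverage uniformity
#'
#' One minus twice the trapezoidal area under the Lorenz curve: 0 for
#' perfectly uniform depth, approaching 1 under extreme amplification bias.
#'
#' @param h a \linkS4class{DepthHistogram}.
#' @return numeric in \[0, 1\].
#' @export
giniCoefficient <- function(h) {
  lc <- lorenzCurve(h)
  area <- sum(diff(lc$x) * (utils::head(lc$y, -1) + utils::tail(lc$y, -1)) / 2)
  1 - 2 * area
}

#' Coverage summary statistics
#'
#' One-row summary of a sample's whole-genome-amplification coverage: mean
#' depth, breadth (fraction of bases covered at least once), its complement,
#' the fractions reaching 20x and 30x, and the Gini coefficient of the Lorenz
#' curve.
#'
#' @param h a \linkS4class{DepthHistogram}.
#' @return \code{data.frame} with columns \code{mean_depth}, \code{breadth},
#'   \code{frac_uncovered}, \code{frac_ge_20x}, \code{frac_ge_30x},
#'   \code{gini}.
#' @export
coverageSummary <- function(h) {
  stopIfNot(is(h, "DepthHistogram"), "h must be a DepthHistogram")
  stopIfNot(totalBases(h) > 0, "empty genome")
  breadth <- fractionAtLeast(h, 1)
  data.frame(mean_depth = totalReads(h) / totalBases(h),
             breadth = breadth,
             frac_uncovered = 1 - breadth,
             frac_ge_20x = fractionAtLeast(h, 20),
             frac_ge_30x = fractionAtLeast(h, 30),
             gini = if (totalReads(h) > 0) giniCoefficient(h) else NA_real_)
}

#' Write Lorenz curve or coverage profile as TSV
#'
#' @param curve data.frame from [lorenzCurve()] or [coverageProfile()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCurve <- function(curve, path) {
  stopIfNot(is.data.frame(curve), "curve must be a data.frame")
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
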