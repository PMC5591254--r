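#' @include AllClasses.R utils.R
NULL

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects gene names in the first column, sample names in the header row and
#' a numeric body. Values are RPKM, raw or already log2-transformed, declared
#' via \code{scale}.
#'
#' @param path TSV file path.
#' @param scale \code{"rpkm"} (raw) or \code{"log2"}.
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, scale = c("log2", "rpkm")) {
  scale <- match.arg(scale)
  stopIfNot(file.exists(path), "expression file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfNot(nrow(tab) > 0 && ncol(tab) >= 2,
            "expression file must have a gene column and at least one sample: %s", path)
  genes <- trimws(as.character(tab[[1]]))
  stopIfNot(!anyDuplicated(canonicalGene(genes)),
            "duplicate gene row(s): %s",
            paste(unique(genes[duplicated(canonicalGene(genes))]), collapse = ", "))
  body <- tab[, -1, drop = FALSE]
  nonnum <- !vapply(body, is.numeric, logical(1))
  stopIfNot(!any(nonnum), "non-numeric expression column(s): %s",
            paste(names(body)[nonnum], collapse = ", "))
  values <- as.matrix(body)
  rownames(values) <- genes
  new("ExpressionMatrix", values = values, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(m, path) {
  stopIfNot(is(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  tab <- data.frame(gene = rownames(m@values), m@values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform an RPKM expression matrix
#'
#' Applies \code{log2(RPKM + pseudocount)}. The pseudocount keeps the exact
#' zeros produced by single-cell dropout finite; the default of 1 maps
#' dropout to log2 expression 0.
#'
#' @param m an \linkS4class{ExpressionMatrix} on the RPKM scale.
#' @param pseudocount positive offset added before the log (RPKM units).
#' @return an \linkS4class{ExpressionMatrix} on the log2 scale.
#' @export
logTransform <- function(m, pseudocount = 1) {
  stopIfNot(is(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  stopIfNot(identical(m@scale, "rpkm"),
            "matrix is already on the log2 scale; refusing to transform twice")
  stopIfNot(is.numeric(pseudocount) && pseudocount > 0,
            "pseudocount must be positive")
  new("ExpressionMatrix", values = log2(m@values + pseudocount), scale = "log2")
}

#' Calibrate per-gene expression thresholds on labelled samples
#'
#' For every gene the threshold is the midpoint between the mean log2
#' expression of the active-labelled and the inactive-labelled calibration
#' samples — the value that separates the two classes when they are
#' separable. Genes whose inactive mean is not below their active mean are
#' flagged (\code{direction_ok = FALSE}) and kept with a warning: the
#' Bayesian combination across the panel tolerates individual noisy genes.
#'
#' @param m an \linkS4class{ExpressionMatrix} on the log2 scale.
#' @param labels named character vector (or factor) mapping every calibration
#'   sample to \code{"active"} or \code{"inactive"}; both classes must occur.
#' @return \code{data.frame} with columns \code{gene}, \code{threshold}
#'   (log2 RPKM), \code{direction_ok}, \code{mean_active}, \code{mean_inactive}.
#' @export
fitThresholds <- function(m, labels) {
  stopIfNot(is(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  stopIfNot(identical(m@scale, "log2"), "thresholds are fit on the log2 scale")
  labels <- vapply(labels, as.character, character(1))
  stopIfNot(!is.null(names(labels)) && all(nzchar(names(labels))),
            "labels must be named by sample")
  stopIfNot(all(labels %in% c("active", "inactive")),
            'labels must be "active" or "inactive"')
  missing <- setdiff(names(labels), colnames(m@values))
  stopIfNot(length(missing) == 0, "labelled sample(s) not in matrix: %s",
            paste(missing, collapse = ", "))
  act <- names(labels)[labels == "active"]
  inact <- names(labels)[labels == "inactive"]
  stopIfNot(length(act) >= 1 && length(inact) >= 1,
            "need at least one active and one inactive calibration sample")

  meanA <- rowMeans(m@values[, act, drop = FALSE], na.rm = TRUE)
  meanI <- rowMeans(m@values[, inact, drop = FALSE], na.rm = TRUE)
  allNA <- !is.finite(meanA) | !is.finite(meanI)
  stopIfNot(!any(allNA), "gene(s) with no usable calibration values: %s",
            paste(rownames(m@values)[allNA], collapse = ", "))

  out <- data.frame(gene = rownames(m@values),
                    threshold = (meanA + meanI) / 2,
                    direction_ok = meanA > meanI,
                    mean_active = meanA, mean_inactive = meanI,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(!out$direction_ok))
    warning(sprintf(
      "%d gene(s) discordant in calibration (inactive mean >= active mean), kept: %s",
      sum(!out$direction_ok),
      paste(out$gene[!out$direction_ok], collapse = ", ")), call. = FALSE)
  out
}

#' Soft threshold call
#'
#' Converts a log2 expression value into the probability \code{q} that the
#' measurement lies above its calibrated threshold, via a logistic ramp of
#' width \code{softness} (log2 units):
#' \code{q = logistic((x - threshold) / softness)}. \code{softness = 0}
#' degenerates to the hard call (1 above, 0 below, 0.5 at equality).
#'
#' @param x log2 expression value(s).
#' @param threshold calibrated threshold(s), log2 scale.
#' @param softness non-negative logistic width; default 0.25 log2 units.
#' @return probabilities in \[0, 1\] (vectorised).
#' @export
softCall <- function(x, threshold, softness = 0.25) {
  stopIfNot(is.numeric(softness) && length(softness) == 1 && softness >= 0,
            "softness must be a single non-negative number")
  if (softness == 0) {
    (x > threshold) + 0.5 * (x == threshold)
  } else {
    stats::plogis((x - threshold) / softness)
  }
}

#' Convert one sample's expression into soft evidence
#'
#' Looks up each calibrated gene in the matrix (case-insensitive after
#' trimming) and applies [softCall()]; genes absent from the matrix come back
#' as \code{NA} (missing evidence, ignored by [inferLogOdds()]).
#'
#' @param m an \linkS4class{ExpressionMatrix} on the log2 scale.
#' @param sample a sample (column) name present in \code{m}.
#' @param thresholds threshold table from [fitThresholds()].
#' @param softness passed to [softCall()].
#' @return named numeric evidence vector (one entry per threshold gene).
#' @export
evidenceFromSample <- function(m, sample, thresholds, softness = 0.25) {
  stopIfNot(is(m, "ExpressionMatrix"), "m must be an ExpressionMatrix")
  stopIfNot(identical(m@scale, "log2"), "evidence is computed on the log2 scale")
  stopIfNot(length(sample) == 1 && sample %in% colnames(m@values),
            "unknown sample: %s", paste(sample, collapse = ", "))
  stopIfNot(is.data.frame(thresholds) &&
              all(c("gene", "threshold") %in% names(thresholds)),
            "thresholds must be a data.frame with gene and threshold columns")
  idx <- matchGenes(thresholds$gene, rownames(m@values))
  q <- rep(NA_real_, nrow(thresholds))
  found <- !is.na(idx)
  q[found] <- softCall(m@values[idx[found], sample],
                       thresholds$threshold[found], softness)
  names(q) <- thresholds$gene
  q
}

#' Soft-evidence matrix over many samples
#'
#' Convenience wrapper applying [evidenceFromSample()] to every requested
#' sample; this gene-by-sample matrix of q values is what the cluster-plot
#' export displays.
#'
#' @inheritParams evidenceFromSample
#' @param samples sample names; default all samples of \code{m}.
#' @return numeric matrix (threshold genes x samples) of q values, \code{NA}
#'   where a gene is unmeasured.
#' @export
evidenceMatrix <- function(m, thresholds, samples = sampleNames(m),
                           softness = 0.25) {
  qs <- vapply(samples,
               function(s) evidenceFromSample(m, s, thresholds, softness),
               numeric(nrow(thresholds)))
  qs <- matrix(qs, nrow = nrow(thresholds),
               dimnames = list(thresholds$gene, samples))
  qs
}

#' Export a cluster matrix of soft calls
#'
#' Writes the gene-by-sample matrix of threshold probabilities (q) as TSV,
#' genes as rows, 4 decimal places, missing values as \code{NA} — the tabular
#' form of the red/blue cluster plot of per-gene up/down calls.
#'
#' @param q numeric matrix with values in \[0, 1\] or \code{NA}; row and
#'   column names required.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
exportClusterMatrix <- function(q, path) {
  stopIfNot(is.matrix(q) && is.numeric(q), "q must be a numeric matrix")
  stopIfNot(!is.null(rownames(q)) && !is.null(colnames(q)),
            "q must have gene row names and sample column names")
  bad <- !is.na(q) & (q < 0 | q > 1)
  stopIfNot(!any(bad), "q values outside [0, 1]")
  fmt <- ifelse(is.na(q), "NA", sprintf("%.4f", q))
  fmt <- matrix(fmt, nrow = nrow(q), dimnames = dimnames(q))
  tab <- data.frame(gene = rownames(q), fmt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
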