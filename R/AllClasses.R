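#' @import methods
NULL

REQUIRED_CPT_COLS <- c("gene", "p_up_given_active", "p_up_given_inactive",
                       "p_high_given_up", "p_high_given_down")

#' PathwayModel: a three-layer Bayesian network of transcriptional activity
#'
#' The model has a single latent binary root node (the transcription complex,
#' TC), one binary node per target gene (transcriptionally up or down), and one
#' binary measurement node per gene (expression above or below its calibrated
#' threshold). Gene nodes are conditionally independent given the TC, and each
#' measurement depends only on its gene, so posterior odds factorise into a
#' product of per-gene likelihood ratios.
#'
#' @slot tcPriorOdds prior odds (active : inactive) on the transcription
#'   complex; strictly positive.
#' @slot genes a \code{data.frame} with one row per target gene and columns
#'   \code{gene}, \code{p_up_given_active}, \code{p_up_given_inactive},
#'   \code{p_high_given_up}, \code{p_high_given_down}, all conditional
#'   probabilities strictly inside (0, 1).
#'
#' @seealso [buildModel()], [inferLogOdds()], [compositeLR()]
#' @export
setClass("PathwayModel",
         representation(tcPriorOdds = "numeric", genes = "data.frame"))

setValidity("PathwayModel", function(object) {
  msgs <- character()
  if (length(object@tcPriorOdds) != 1L || !is.finite(object@tcPriorOdds) ||
      object@tcPriorOdds <= 0)
    msgs <- c(msgs, "tcPriorOdds must be a single positive finite number")
  g <- object@genes
  if (!all(REQUIRED_CPT_COLS %in% names(g))) {
    msgs <- c(msgs, paste("genes must have columns:",
                          paste(REQUIRED_CPT_COLS, collapse = ", ")))
    return(msgs)
  }
  if (nrow(g) == 0L)
    msgs <- c(msgs, "model must contain at least one target gene")
  if (anyDuplicated(canonicalGene(g$gene)))
    msgs <- c(msgs, "gene names must be unique")
  for (col in REQUIRED_CPT_COLS[-1]) {
    p <- g[[col]]
    if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
      msgs <- c(msgs, sprintf("%s must lie strictly in (0, 1)", col))
  }
  if (length(msgs) == 0L) {
    if (any(g$p_up_given_active <= g$p_up_given_inactive))
      msgs <- c(msgs,
        "p_up_given_active must exceed p_up_given_inactive (positively regulated targets only)")
    if (any(g$p_high_given_up <= g$p_high_given_down))
      msgs <- c(msgs, "p_high_given_up must exceed p_high_given_down")
  }
  if (length(msgs)) msgs else TRUE
})

#' InferenceResult: posterior odds of pathway activity for one sample
#'
#' @slot logOdds natural-log posterior odds (active : inactive) of the
#'   transcription complex.
#' @slot perGeneLogLR named numeric vector of per-gene log likelihood-ratio
#'   contributions; genes with missing evidence contribute exactly 0.
#' @slot nGenesUsed number of genes with non-missing evidence.
#'
#' @export
setClass("InferenceResult",
         representation(logOdds = "numeric", perGeneLogLR = "numeric",
                        nGenesUsed = "integer"))

setValidity("InferenceResult", function(object) {
  if (length(object@logOdds) != 1L || is.na(object@logOdds))
    return("logOdds must be a single non-missing number")
  TRUE
})

#' ExpressionMatrix: a gene-by-sample expression matrix with a declared scale
#'
#' Expression values are RPKM (reads per kilobase of transcript per million
#' mapped reads) either raw (\code{scale = "rpkm"}) or log2-transformed with a
#' pseudocount (\code{scale = "log2"}).
#'
#' @slot values numeric matrix, genes as rows, samples as columns, both
#'   uniquely named.
#' @slot scale either \code{"rpkm"} or \code{"log2"}.
#'
#' @seealso [readExpressionMatrix()], [logTransform()]
#' @export
setClass("ExpressionMatrix",
         representation(values = "matrix", scale = "character"))

setValidity("ExpressionMatrix", function(object) {
  msgs <- character()
  v <- object@values
  if (!is.numeric(v))
    msgs <- c(msgs, "values must be a numeric matrix")
  if (length(object@scale) != 1L || !object@scale %in% c("rpkm", "log2"))
    msgs <- c(msgs, 'scale must be "rpkm" or "log2"')
  if (is.null(rownames(v)) && nrow(v) > 0)
    msgs <- c(msgs, "gene (row) names are required")
  if (is.null(colnames(v)) && ncol(v) > 0)
    msgs <- c(msgs, "sample (column) names are required")
  if (!is.null(rownames(v)) && anyDuplicated(canonicalGene(rownames(v))))
    msgs <- c(msgs, "gene names must be unique")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msgs <- c(msgs, "sample names must be unique")
  if (length(msgs) == 0L && identical(object@scale, "rpkm") &&
      length(v) && any(v < 0, na.rm = TRUE))
    msgs <- c(msgs, "RPKM values cannot be negative")
  if (length(msgs)) msgs else TRUE
})

#' DepthHistogram: per-base sequencing depth distribution for one sample
#'
#' Maps each observed depth class to the number of genome bases at that depth.
#' This is the unit of input for Lorenz-curve and coverage-profile QC of
#' whole-genome-amplified single-cell DNA.
#'
#' @slot depth integer vector of unique non-negative depth classes, ascending.
#' @slot bases numeric vector (same length) of positive base counts per class.
#'
#' @seealso [readDepthHistogram()], [lorenzCurve()], [coverageSummary()]
#' @export
setClass("DepthHistogram",
         representation(depth = "integer", bases = "numeric"))

setValidity("DepthHistogram", function(object) {
  msgs <- character()
  d <- object@depth; b <- object@bases
  if (length(d) != length(b))
    msgs <- c(msgs, "depth and bases must have equal length")
  if (length(d) == 0L)
    msgs <- c(msgs, "histogram must contain at least one depth class")
  if (length(d) && (any(d < 0L) || anyDuplicated(d) || is.unsorted(d, strictly = TRUE)))
    msgs <- c(msgs, "depths must be unique, non-negative and ascending")
  if (length(b) && (any(!is.finite(b)) || any(b <= 0) || any(b != round(b))))
    msgs <- c(msgs, "bases must be positive integer counts")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: parameters of the synthetic-data generator
#'
#' Holds every knob of the simulator: per-gene baseline means and activation
#' effects for expression, measurement noise, sample counts, single-cell
#' dropout parameters, and the zero-inflated negative-binomial depth model
#' emulating whole-genome-amplification bias.
#'
#' @slot genes gene names.
#' @slot mu per-gene baseline mean expression (log2 RPKM).
#' @slot delta per-gene activation effect (log2 units), added in active samples.
#' @slot noiseSd measurement noise standard deviation (log2 units).
#' @slot nActive,nInactive sample counts per class.
#' @slot mode \code{"bulk"} or \code{"single_cell"} (the latter adds dropout).
#' @slot dropoutBase baseline dropout probability.
#' @slot dropoutSlope extra dropout probability per log2 unit that a gene's
#'   baseline falls below \code{dropoutRef}.
#' @slot dropoutRef reference expression level below which dropout rises.
#' @slot depthMean mean sequencing depth per genome bin.
#' @slot depthDispersion negative-binomial overdispersion \eqn{\alpha}
#'   (variance \eqn{\mu(1+\alpha\mu)}); 0 selects an exact Poisson branch.
#' @slot zeroInflation probability that a bin yields zero depth outright.
#' @slot genomeBins number of genome bins simulated.
#' @slot seed integer RNG seed; identical seeds give bit-identical output.
#'
#' @seealso [syntheticConfig()], [simulateExpression()], [simulateDepth()]
#' @export
setClass("SyntheticConfig",
         representation(genes = "character", mu = "numeric", delta = "numeric",
                        noiseSd = "numeric", nActive = "integer",
                        nInactive = "integer", mode = "character",
                        dropoutBase = "numeric", dropoutSlope = "numeric",
                        dropoutRef = "numeric", depthMean = "numeric",
                        depthDispersion = "numeric", zeroInflation = "numeric",
                        genomeBins = "integer", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  n <- length(object@genes)
  if (n == 0L || anyDuplicated(canonicalGene(object@genes)))
    msgs <- c(msgs, "genes must be non-empty and unique")
  if (length(object@mu) != n || length(object@delta) != n)
    msgs <- c(msgs, "mu and delta must have one value per gene")
  if (object@noiseSd <= 0) msgs <- c(msgs, "noiseSd must be positive")
  if (object@nActive < 0L || object@nInactive < 0L)
    msgs <- c(msgs, "sample counts must be non-negative")
  if (!object@mode %in% c("bulk", "single_cell"))
    msgs <- c(msgs, 'mode must be "bulk" or "single_cell"')
  for (p in c("dropoutBase", "zeroInflation")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msgs <- c(msgs, sprintf("%s must lie in [0, 1]", p))
  }
  if (object@dropoutSlope < 0) msgs <- c(msgs, "dropoutSlope must be >= 0")
  if (object@depthMean <= 0) msgs <- c(msgs, "depthMean must be positive")
  if (object@depthDispersion < 0)
    msgs <- c(msgs, "depthDispersion must be >= 0")
  if (object@genomeBins < 1L) msgs <- c(msgs, "genomeBins must be >= 1")
  if (length(msgs)) msgs else TRUE
})
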