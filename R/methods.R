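#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname model-accessors
setMethod("geneNames", "PathwayModel", function(x) x@genes$gene)

#' @rdname model-accessors
setMethod("nGenes", "PathwayModel", function(x) nrow(x@genes))

#' @rdname model-accessors
setMethod("tcPriorOdds", "PathwayModel", function(x) x@tcPriorOdds)

#' @rdname model-accessors
setMethod("geneTable", "PathwayModel", function(x) x@genes)

#' @rdname model-accessors
setMethod("geneNames", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname model-accessors
setMethod("nGenes", "ExpressionMatrix", function(x) nrow(x@values))

#' @rdname expression-accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname expression-accessors
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' @rdname expression-accessors
setMethod("sampleNames", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname depth-accessors
setMethod("depths", "DepthHistogram", function(x) x@depth)

#' @rdname depth-accessors
setMethod("baseCounts", "DepthHistogram", function(x) x@bases)

#' @rdname depth-accessors
setMethod("totalBases", "DepthHistogram", function(x) sum(x@bases))

#' @rdname depth-accessors
setMethod("totalReads", "DepthHistogram",
          function(x) sum(as.numeric(x@depth) * x@bases))

#' Log-odds accessors for inference results
#'
#' @param x an \linkS4class{InferenceResult}.
#' @return \code{logOdds}: numeric scalar (natural log);
#'   \code{perGeneLogLR}: named numeric vector.
#' @name inference-accessors
#' @aliases logOdds perGeneLogLR
#' @export
logOdds <- function(x) {
  stopIfNot(is(x, "InferenceResult"), "x must be an InferenceResult")
  x@logOdds
}

#' @rdname inference-accessors
#' @export
perGeneLogLR <- function(x) {
  stopIfNot(is(x, "InferenceResult"), "x must be an InferenceResult")
  x@perGeneLogLR
}

setMethod("show", "PathwayModel", function(object) {
  cat(sprintf("PathwayModel: %d target gene(s), TC prior odds %.4g\n",
              nrow(object@genes), object@tcPriorOdds))
  lr <- compositeLR(object)
  cat(sprintf("  composite LR range: high [%.4g, %.4g], low [%.4g, %.4g]\n",
              min(lr$lr_high), max(lr$lr_high), min(lr$lr_low), max(lr$lr_low)))
  cat("  genes:", paste(utils::head(object@genes$gene, 8), collapse = ", "),
      if (nrow(object@genes) > 8) "..." else "", "\n")
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult: log-odds %.4f (log10 %.4f), %d gene(s) used\n",
              object@logOdds, object@logOdds / log(10), object@nGenesUsed))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d gene(s) x %d sample(s), scale %s\n",
              nrow(object@values), ncol(object@values), object@scale))
})

setMethod("show", "DepthHistogram", function(object) {
  cat(sprintf(
    "DepthHistogram: %d depth class(es), %.0f bases, mean depth %.2fx\n",
    length(object@depth), totalBases(object),
    totalReads(object) / totalBases(object)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d gene(s), %d active + %d inactive sample(s), mode %s\n",
    length(object@genes), object@nActive, object@nInactive, object@mode))
  cat(sprintf("  depth: mean %.1fx, dispersion %.3g, zero-inflation %.3g, %d bins, seed %d\n",
              object@depthMean, object@depthDispersion, object@zeroInflation,
              object@genomeBins, object@seed))
})
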