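#' @include AllClasses.R
NULL

#' Accessors for pathway models and related objects
#'
#' \code{geneNames} returns the gene identifiers carried by an object;
#' \code{nGenes} the number of genes; \code{tcPriorOdds} the prior odds on the
#' transcription-complex node of a \linkS4class{PathwayModel};
#' \code{geneTable} the per-gene conditional-probability table.
#'
#' @param x an object.
#' @return \code{geneNames}: character vector; \code{nGenes}: integer;
#'   \code{tcPriorOdds}: numeric scalar; \code{geneTable}: \code{data.frame}.
#' @name model-accessors
#' @aliases geneNames nGenes tcPriorOdds geneTable
#' @examples
#' m <- buildModel(c("AXIN2", "LGR5"))
#' geneNames(m)
#' tcPriorOdds(m)
NULL

#' @rdname model-accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname model-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname model-accessors
#' @export
setGeneric("tcPriorOdds", function(x) standardGeneric("tcPriorOdds"))

#' @rdname model-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' Accessors for expression matrices
#'
#' \code{exprValues} returns the numeric gene-by-sample matrix,
#' \code{exprScale} the declared scale (\code{"rpkm"} or \code{"log2"}), and
#' \code{sampleNames} the sample (column) names.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @name expression-accessors
#' @aliases exprValues exprScale sampleNames
NULL

#' @rdname expression-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname expression-accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname expression-accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' Accessors for depth histograms
#'
#' \code{depths} and \code{baseCounts} return the parallel vectors of depth
#' classes and base counts; \code{totalBases} their total genome size;
#' \code{totalReads} the total read mass \eqn{\sum_d d \cdot b_d}.
#'
#' @param x a \linkS4class{DepthHistogram}.
#' @name depth-accessors
#' @aliases depths baseCounts totalBases totalReads
NULL

#' @rdname depth-accessors
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname depth-accessors
#' @export
setGeneric("baseCounts", function(x) standardGeneric("baseCounts"))

#' @rdname depth-accessors
#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))

#' @rdname depth-accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
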