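#' @include pathway-model.R calibration.R coverage.R variant-panel.R synthetic.R
NULL

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood rule: with the margins
#' fixed, the hypergeometric probability of every realisable table is
#' computed and those no more probable than the observed table (up to a
#' relative tie tolerance of 1e-7) are summed. This is the convention under
#' which a perfectly separated 7-vs-6 confusion table gives
#' p = 1/1716 ~ 0.0006.
#'
#' @param tab 2x2 matrix of non-negative integer counts with at least one
#'   positive margin.
#' @return the p-value, in (0, 1\].
#' @examples
#' fisherExactTwoSided(matrix(c(7, 0, 0, 6), 2))  # 1/1716
#' @export
fisherExactTwoSided <- function(tab) {
  tab <- as.matrix(tab)
  stopIfNot(all(dim(tab) == c(2, 2)), "tab must be 2x2")
  stopIfNot(is.numeric(tab) && all(tab >= 0) && all(tab == round(tab)),
            "tab must hold non-negative integer counts")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  stopIfNot(m + n > 0, "all margins are zero")
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(tab[1, 1], m, n, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Classify a sample from its inferred log-odds
#'
#' The decision boundary sits at odds 1 (log-odds 0), the visual boundary of
#' the log-scale odds plot; exact ties go conservatively to
#' \code{"inactive"}.
#'
#' @param logOdds finite numeric log-odds value(s), or an
#'   \linkS4class{InferenceResult}.
#' @return character vector of \code{"active"}/\code{"inactive"}.
#' @export
classifyActivity <- function(logOdds) {
  if (is(logOdds, "InferenceResult")) logOdds <- logOdds@logOdds
  stopIfNot(is.numeric(logOdds) && all(is.finite(logOdds)),
            "log-odds must be finite")
  ifelse(logOdds > 0, "active", "inactive")
}

#' Evaluate classifications against known labels
#'
#' Builds the truth-by-prediction confusion table and tests the association
#' between truth and prediction with the two-sided Fisher exact test.
#'
#' @param logOdds named numeric vector of per-sample log-odds.
#' @param truth named character vector (\code{"active"}/\code{"inactive"})
#'   covering the same samples.
#' @return list with \code{predicted} (named character), \code{confusion}
#'   (2x2 integer matrix, truth x prediction), \code{accuracy} and
#'   \code{fisher_p}.
#' @export
evaluateClassification <- function(logOdds, truth) {
  stopIfNot(!is.null(names(logOdds)) && !is.null(names(truth)),
            "logOdds and truth must be named by sample")
  common <- intersect(names(logOdds), names(truth))
  stopIfNot(length(common) > 0, "no samples shared between logOdds and truth")
  predicted <- classifyActivity(logOdds[common])
  names(predicted) <- common
  lev <- c("active", "inactive")
  confusion <- table(factor(truth[common], lev), factor(predicted, lev))
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(truth = lev, predicted = lev))
  list(predicted = predicted,
       confusion = confusion,
       accuracy = mean(predicted == truth[common]),
       fisher_p = fisherExactTwoSided(confusion))
}

readLabels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopIfNot(ncol(tab) >= 2, "labels file needs columns sample, label: %s", path)
  labels <- tab[[2]]
  names(labels) <- tab[[1]]
  labels
}

#' Write sample labels as TSV
#'
#' @param labels named character vector (sample -> label).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(labels, path) {
  utils::write.table(data.frame(sample = names(labels), label = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

loadExprInput <- function(node, pseudocount) {
  m <- readExpressionMatrix(node$expression,
                            scale = if (is.null(node$scale)) "log2" else node$scale)
  if (identical(exprScale(m), "rpkm")) m <- logTransform(m, pseudocount)
  m
}

checkPipelineInputs <- function(config) {
  stopIfNot(!is.null(config$calibration$expression) &&
              !is.null(config$calibration$labels),
            "config must name calibration$expression and calibration$labels")
  paths <- c(config$calibration$expression, config$calibration$labels,
             config$test$expression, config$test$labels,
             config$model$panel, config$variants$panel)
  for (s in config$coverage$samples) paths <- c(paths, s)
  for (s in config$variants$samples) paths <- c(paths, s$vcf, s$callable)
  paths <- unlist(Filter(is.character, paths))
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  stopIfNot(length(missing) == 0, "input file(s) not found: %s",
            paste(missing, collapse = ", "))
}

#' Run the full calibrate/score/QC/screen pipeline
#'
#' Orchestrates the whole analysis from a YAML (or list) configuration:
#' calibrates per-gene thresholds on the labelled calibration matrix, scores
#' any test samples into per-sample log-odds of pathway activity, exports the
#' soft-call cluster matrix, evaluates classification against test labels
#' (confusion table and Fisher exact p), summarises per-sample coverage
#' histograms, and screens per-sample VCFs against the driver panel. All
#' outputs are TSV files in \code{outDir}; every decision (discordant genes,
#' excluded samples) is surfaced as a message or warning.
#'
#' Config keys: \code{calibration: {expression, labels, scale}} (required),
#' \code{test: {expression, labels}}, \code{model: {panel, tc_prior_odds}},
#' \code{pseudocount}, \code{softness}, \code{coverage: {dialect, samples}}
#' (named map sample -> depth file), \code{variants: {panel, breadth_gate,
#' samples}} (named map sample -> \code{{vcf, callable, breadth}}; breadth
#' defaults to the sample's coverage summary).
#'
#' @param config path to a YAML config file, or an equivalent nested list.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the computed thresholds, odds table,
#'   classification evaluation, coverage summaries and panel report.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    stopIfNot(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopIfNot(is.list(config), "config must be a list or a YAML path")
  checkPipelineInputs(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  pseudocount <- if (is.null(config$pseudocount)) 1 else config$pseudocount
  softness <- if (is.null(config$softness)) 0.25 else config$softness
  panelPath <- if (is.null(config$model$panel)) wntTargetPanel() else config$model$panel
  priorOdds <- if (is.null(config$model$tc_prior_odds)) 1 else config$model$tc_prior_odds
  model <- readModelPanel(panelPath, tcPriorOdds = priorOdds)
  message(sprintf("pathway model: %d target genes, prior odds %g",
                  nGenes(model), tcPriorOdds(model)))

  calM <- loadExprInput(config$calibration, pseudocount)
  calLabels <- readLabels(config$calibration$labels)
  thresholds <- fitThresholds(calM, calLabels)
  modelThresholds <- thresholds[!is.na(matchGenes(thresholds$gene,
                                                  geneNames(model))), ]
  stopIfNot(nrow(modelThresholds) > 0,
            "no calibrated gene overlaps the pathway model panel")
  utils::write.table(thresholds, file.path(outDir, "thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$thresholds <- thresholds

  qCal <- evidenceMatrix(calM, modelThresholds, softness = softness)
  qAll <- qCal
  if (!is.null(config$test$expression)) {
    testM <- loadExprInput(config$test, pseudocount)
    qTest <- evidenceMatrix(testM, modelThresholds, softness = softness)
    qAll <- cbind(qCal, qTest)

    res <- lapply(sampleNames(testM), function(s)
      inferLogOdds(model, qTest[, s]))
    lo <- vapply(res, logOdds, numeric(1))
    names(lo) <- sampleNames(testM)
    odds <- data.frame(sample = names(lo), log_odds = unname(lo),
                       log10_odds = unname(lo) / log(10),
                       predicted = classifyActivity(lo),
                       n_genes_used = vapply(res, function(r) r@nGenesUsed,
                                             integer(1)),
                       stringsAsFactors = FALSE)
    utils::write.table(odds, file.path(outDir, "odds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$odds <- odds

    if (!is.null(config$test$labels)) {
      truth <- readLabels(config$test$labels)
      eval <- evaluateClassification(lo, truth)
      summary <- data.frame(
        n = length(eval$predicted), accuracy = eval$accuracy,
        fisher_p = eval$fisher_p,
        tp = eval$confusion["active", "active"],
        fn = eval$confusion["active", "inactive"],
        fp = eval$confusion["inactive", "active"],
        tn = eval$confusion["inactive", "inactive"])
      utils::write.table(summary, file.path(outDir, "classification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message(sprintf("classification: accuracy %.3f, Fisher p %.3g",
                      eval$accuracy, eval$fisher_p))
      out$evaluation <- eval
    }
  }
  exportClusterMatrix(qAll, file.path(outDir, "cluster_matrix.tsv"))

  covSummaries <- NULL
  if (!is.null(config$coverage$samples)) {
    dialect <- if (is.null(config$coverage$dialect)) "histogram" else config$coverage$dialect
    for (s in names(config$coverage$samples)) {
      h <- readDepthHistogram(config$coverage$samples[[s]], dialect)
      covSummaries <- rbind(covSummaries,
                            cbind(data.frame(sample = s), coverageSummary(h)))
      writeCurve(lorenzCurve(h),
                 file.path(outDir, paste0("lorenz_", s, ".tsv")))
      writeCurve(coverageProfile(h, max(30, max(depths(h)))),
                 file.path(outDir, paste0("coverage_profile_", s, ".tsv")))
    }
    utils::write.table(covSummaries, file.path(outDir, "coverage_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$coverage <- covSummaries
  }

  if (!is.null(config$variants$samples)) {
    panel <- loadPanel(if (is.null(config$variants$panel)) driverPanel()
                       else config$variants$panel)
    gate <- if (is.null(config$variants$breadth_gate)) 0.70 else config$variants$breadth_gate
    reports <- lapply(names(config$variants$samples), function(s) {
      node <- config$variants$samples[[s]]
      breadth <- node$breadth
      if (is.null(breadth)) {
        stopIfNot(!is.null(covSummaries) && s %in% covSummaries$sample,
                  "no breadth given and no coverage summary for sample %s", s)
        breadth <- covSummaries$breadth[covSummaries$sample == s]
      }
      rep <- screenSample(node$vcf, panel, node$callable, breadth,
                          sample = s, breadthGate = gate)
      if (any(rep$status == "sample_excluded"))
        message(sprintf("sample %s excluded: breadth %.3f < gate %.2f",
                        s, breadth, gate))
      rep
    })
    agg <- aggregateReports(reports)
    utils::write.table(agg$rows, file.path(outDir, "panel_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(agg$tallies, file.path(outDir, "panel_tallies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$panel <- agg
  }
  invisible(out)
}
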