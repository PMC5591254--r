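#' @include AllClasses.R AllGenerics.R
NULL

# Default gene-layer CPT: a target gene is transcriptionally up with
# probability 0.95 when the transcription complex is active and 0.05 when not.
DEFAULT_P_UP_ACTIVE <- 0.95
DEFAULT_P_UP_INACTIVE <- 0.05
# Default composite likelihood ratios of the measurement evidence: an
# above-threshold call multiplies the active odds by 5, while a
# below-threshold call divides them only by 5^(1/5), so up-regulated genes
# carry five times the log-odds weight of non-up-regulated ones.
DEFAULT_LR_HIGH <- 5.0
DEFAULT_LR_LOW <- 5.0^(-1 / 5)

# Solve the measurement-layer CPT (p_high_given_up, p_high_given_down) so the
# composite likelihood ratios hit the requested targets, given the gene-layer
# CPT. Both constraints are linear in the two unknowns:
#   P(high|TC)  = pUp(TC) * a + (1 - pUp(TC)) * b        (a, b the unknowns)
#   lr_high = P(high|active)/P(high|inactive),  lr_low analogous on "low".
solveMeasurementCPT <- function(pUpActive, pUpInactive,
                                lrHigh = DEFAULT_LR_HIGH,
                                lrLow = DEFAULT_LR_LOW) {
  A <- rbind(
    c(pUpActive - lrHigh * pUpInactive,
      (1 - pUpActive) - lrHigh * (1 - pUpInactive)),
    c(lrLow * pUpInactive - pUpActive,
      lrLow * (1 - pUpInactive) - (1 - pUpActive)))
  ab <- solve(A, c(0, lrLow - 1))
  stopIfNot(all(ab > 0 & ab < 1) && ab[1] > ab[2],
            "no valid measurement CPT reaches lr_high=%g, lr_low=%g under this gene-layer CPT",
            lrHigh, lrLow)
  c(p_high_given_up = ab[[1]], p_high_given_down = ab[[2]])
}

#' Build a pathway activity model over a target-gene panel
#'
#' Constructs the three-layer Bayesian network (transcription complex, target
#' genes, threshold measurements). By default every gene gets the same
#' conditional probability tables, chosen so that an above-threshold
#' measurement shifts the log-odds of pathway activity five times as far up as
#' a below-threshold measurement shifts them down (composite likelihood ratios
#' 5 and 5^(-1/5)); any of the four CPT entries can be overridden globally via
#' \code{cpt} or per gene via the panel columns of [readModelPanel()].
#'
#' @param panel character vector of target gene names (non-empty, unique), or
#'   a \code{data.frame} with a \code{gene} column and optional per-gene CPT
#'   columns \code{p_up_given_active}, \code{p_up_given_inactive},
#'   \code{p_high_given_up}, \code{p_high_given_down} (\code{NA} cells fall
#'   back to defaults).
#' @param cpt optional named list of global CPT overrides (same four names).
#' @param tcPriorOdds prior odds on the transcription complex; default 1
#'   (uninformative, the decision boundary of the log-odds plot).
#'
#' @return a \linkS4class{PathwayModel}.
#' @examples
#' m <- buildModel(c("AXIN2", "LGR5", "MYC"))
#' compositeLR(m)
#' @export
buildModel <- function(panel, cpt = list(), tcPriorOdds = 1) {
  if (is.data.frame(panel)) {
    stopIfNot("gene" %in% names(panel), "panel data.frame needs a 'gene' column")
    tab <- panel
  } else {
    tab <- data.frame(gene = as.character(panel), stringsAsFactors = FALSE)
  }
  stopIfNot(nrow(tab) > 0, "panel must be non-empty")
  tab$gene <- trimws(tab$gene)
  stopIfNot(!anyDuplicated(canonicalGene(tab$gene)),
            "duplicate gene name(s) in panel: %s",
            paste(unique(tab$gene[duplicated(canonicalGene(tab$gene))]), collapse = ", "))

  unknown <- setdiff(names(cpt), REQUIRED_CPT_COLS[-1])
  stopIfNot(length(unknown) == 0, "unknown cpt entries: %s",
            paste(unknown, collapse = ", "))
  for (nm in names(cpt))
    stopIfNot(is.numeric(cpt[[nm]]) && length(cpt[[nm]]) == 1 &&
                is.finite(cpt[[nm]]) && cpt[[nm]] > 0 && cpt[[nm]] < 1,
              "%s must lie strictly in (0, 1)", nm)
  pUpA <- if (is.null(cpt$p_up_given_active)) DEFAULT_P_UP_ACTIVE else cpt$p_up_given_active
  pUpI <- if (is.null(cpt$p_up_given_inactive)) DEFAULT_P_UP_INACTIVE else cpt$p_up_given_inactive
  stopIfNot(pUpA > pUpI,
            "p_up_given_active (%g) must exceed p_up_given_inactive (%g)",
            pUpA, pUpI)
  meas <- c(cpt$p_high_given_up, cpt$p_high_given_down)
  if (length(meas) == 2) {
    pHU <- cpt$p_high_given_up; pHD <- cpt$p_high_given_down
  } else if (length(meas) == 0) {
    m <- solveMeasurementCPT(pUpA, pUpI)
    pHU <- m[["p_high_given_up"]]; pHD <- m[["p_high_given_down"]]
  } else {
    stop("p_high_given_up and p_high_given_down must be overridden together",
         call. = FALSE)
  }

  defaults <- c(p_up_given_active = pUpA, p_up_given_inactive = pUpI,
                p_high_given_up = pHU, p_high_given_down = pHD)
  for (col in names(defaults)) {
    if (is.null(tab[[col]])) tab[[col]] <- defaults[[col]]
    tab[[col]] <- ifelse(is.na(tab[[col]]), defaults[[col]], tab[[col]])
  }
  new("PathwayModel", tcPriorOdds = as.numeric(tcPriorOdds),
      genes = tab[, REQUIRED_CPT_COLS])
}

# composite measurement likelihoods with the gene layer marginalised out:
# P(high | TC) for both TC states, per gene
.measurement_given_tc <- function(genes) {
  pHighOn <- genes$p_up_given_active * genes$p_high_given_up +
    (1 - genes$p_up_given_active) * genes$p_high_given_down
  pHighOff <- genes$p_up_given_inactive * genes$p_high_given_up +
    (1 - genes$p_up_given_inactive) * genes$p_high_given_down
  list(on = pHighOn, off = pHighOff)
}

.composite_lr <- function(p_up_given_active, p_up_given_inactive,
                          p_high_given_up, p_high_given_down) {
  m <- .measurement_given_tc(data.frame(
    p_up_given_active = p_up_given_active,
    p_up_given_inactive = p_up_given_inactive,
    p_high_given_up = p_high_given_up,
    p_high_given_down = p_high_given_down))
  data.frame(lr_high = m$on / m$off, lr_low = (1 - m$on) / (1 - m$off))
}

#' Composite per-gene likelihood ratios
#'
#' Marginalises the hidden gene layer out of each gene's two conditional
#' probability tables and returns, per gene, the likelihood ratio that an
#' above-threshold (\code{lr_high}) or below-threshold (\code{lr_low})
#' measurement contributes to the active:inactive odds of the transcription
#' complex. The model invariants guarantee \code{lr_high > 1 > lr_low}.
#'
#' @param model a \linkS4class{PathwayModel}.
#' @return \code{data.frame} with columns \code{gene}, \code{lr_high},
#'   \code{lr_low}.
#' @export
compositeLR <- function(model) {
  stopIfNot(is(model, "PathwayModel"), "model must be a PathwayModel")
  lr <- .composite_lr(model@genes$p_up_given_active,
                      model@genes$p_up_given_inactive,
                      model@genes$p_high_given_up,
                      model@genes$p_high_given_down)
  cbind(data.frame(gene = model@genes$gene, stringsAsFactors = FALSE), lr)
}

#' Create a soft-evidence vector
#'
#' Evidence for inference is a named vector of probabilities \code{q}, one per
#' gene, that the gene's measured expression lies above its calibrated
#' threshold. \code{NA} marks missing evidence (gene not measured), which
#' contributes nothing to the inferred odds.
#'
#' @param q named numeric vector in \[0, 1\], \code{NA} allowed.
#' @return the validated vector.
#' @export
evidenceVector <- function(q) {
  stopIfNot(is.numeric(q) && !is.null(names(q)) && all(nzchar(names(q))),
            "evidence must be a named numeric vector")
  stopIfNot(!anyDuplicated(canonicalGene(names(q))), "duplicate gene in evidence")
  bad <- !is.na(q) & (q < 0 | q > 1)
  stopIfNot(!any(bad), "evidence probabilities must lie in [0, 1]: %s",
            paste(names(q)[bad], collapse = ", "))
  q
}

#' Infer the posterior log-odds of pathway activity
#'
#' Exact inference in the three-layer network under virtual (soft) evidence:
#' each measurement node receives likelihood weights \code{q : 1 - q} for its
#' high/low states rather than being clamped. Because genes are conditionally
#' independent given the transcription complex, the posterior log-odds is the
#' log prior odds plus a sum of per-gene log likelihood ratios
#' \deqn{\log \frac{q\,P(\mathrm{high}\mid \mathrm{on}) + (1-q)\,P(\mathrm{low}\mid \mathrm{on})}
#'                {q\,P(\mathrm{high}\mid \mathrm{off}) + (1-q)\,P(\mathrm{low}\mid \mathrm{off})}.}
#' Genes with missing (\code{NA}) or absent evidence contribute exactly 0.
#'
#' @param model a \linkS4class{PathwayModel}.
#' @param evidence named numeric vector as produced by [evidenceVector()] or
#'   [evidenceFromSample()]; names must be model genes (case-insensitive).
#' @return an \linkS4class{InferenceResult}; natural-log scale.
#' @examples
#' m <- buildModel("AXIN2")
#' inferLogOdds(m, c(AXIN2 = 1))  # log 5
#' @export
inferLogOdds <- function(model, evidence) {
  stopIfNot(is(model, "PathwayModel"), "model must be a PathwayModel")
  evidence <- evidenceVector(evidence)
  idx <- matchGenes(names(evidence), model@genes$gene)
  stopIfNot(!anyNA(idx), "evidence contains gene(s) not in the model: %s",
            paste(names(evidence)[is.na(idx)], collapse = ", "))

  m <- .measurement_given_tc(model@genes)
  q <- rep(NA_real_, nrow(model@genes))
  q[idx] <- evidence
  used <- !is.na(q)
  llr <- numeric(nrow(model@genes))
  llr[used] <- log(q[used] * m$on[used] + (1 - q[used]) * (1 - m$on[used])) -
    log(q[used] * m$off[used] + (1 - q[used]) * (1 - m$off[used]))
  names(llr) <- model@genes$gene
  new("InferenceResult",
      logOdds = log(model@tcPriorOdds) + sum(llr),
      perGeneLogLR = llr,
      nGenesUsed = sum(used))
}

#' Brute-force inference oracle by joint enumeration
#'
#' Recomputes the posterior log-odds of [inferLogOdds()] without using the
#' factorised form: it enumerates every configuration of the transcription
#' complex and all gene states, and for each configuration sums over both
#' measurement states of every gene with the virtual-evidence weights
#' \code{(q, 1 - q)} applied. Intended as an independent correctness check;
#' guarded to small models.
#'
#' @inheritParams inferLogOdds
#' @return the posterior log-odds (numeric scalar, natural log).
#' @export
inferLogOddsBruteforce <- function(model, evidence) {
  stopIfNot(is(model, "PathwayModel"), "model must be a PathwayModel")
  n <- nrow(model@genes)
  stopIfNot(n <= 15L, "enumeration oracle is limited to 15 genes (got %d)", n)
  evidence <- evidenceVector(evidence)
  idx <- matchGenes(names(evidence), model@genes$gene)
  stopIfNot(!anyNA(idx), "evidence contains gene(s) not in the model: %s",
            paste(names(evidence)[is.na(idx)], collapse = ", "))
  q <- rep(NA_real_, n)
  q[idx] <- evidence

  # virtual-evidence weight of each gene state, summed over its two
  # measurement states: w(state) = q * P(high|state) + (1-q) * P(low|state);
  # a missing measurement weighs both states 1
  wUp <- ifelse(is.na(q), 1,
                q * model@genes$p_high_given_up +
                  (1 - q) * (1 - model@genes$p_high_given_up))
  wDown <- ifelse(is.na(q), 1,
                  q * model@genes$p_high_given_down +
                    (1 - q) * (1 - model@genes$p_high_given_down))

  configs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))  # gene states, 1 = up
  stateWeight <- exp(configs %*% log(wUp) + (1 - configs) %*% log(wDown))

  total <- function(pUp) {
    prior <- exp(configs %*% log(pUp) + (1 - configs) %*% log(1 - pUp))
    sum(prior * stateWeight)
  }
  log(model@tcPriorOdds) +
    log(total(model@genes$p_up_given_active)) -
    log(total(model@genes$p_up_given_inactive))
}

#' Read and write pathway model panels
#'
#' The on-disk panel format is a TSV with a \code{gene} column and optional
#' CPT columns \code{p_up_given_active}, \code{p_up_given_inactive},
#' \code{p_high_given_up}, \code{p_high_given_down}; empty cells fall back to
#' the defaults of [buildModel()]. \code{writeModelPanel} serialises with full
#' double precision so a write/read cycle reproduces the model exactly.
#'
#' @param path TSV file path.
#' @param cpt,tcPriorOdds passed to [buildModel()].
#' @param model a \linkS4class{PathwayModel}.
#' @return \code{readModelPanel}: a \linkS4class{PathwayModel};
#'   \code{writeModelPanel}: \code{path}, invisibly.
#' @export
readModelPanel <- function(path, cpt = list(), tcPriorOdds = 1) {
  stopIfNot(file.exists(path), "panel file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfNot(nrow(tab) > 0, "panel file is empty: %s", path)
  buildModel(tab, cpt = cpt, tcPriorOdds = tcPriorOdds)
}

#' @rdname readModelPanel
#' @export
writeModelPanel <- function(model, path) {
  stopIfNot(is(model, "PathwayModel"), "model must be a PathwayModel")
  tab <- model@genes
  for (col in REQUIRED_CPT_COLS[-1]) tab[[col]] <- sprintf("%.17g", tab[[col]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled Wnt target-gene panel
#'
#' Returns the path to the package's representative 34-gene panel of canonical
#' TCF4/beta-catenin (Wnt) transcriptional targets used as the default
#' pathway profile.
#'
#' @return file path of the bundled panel TSV.
#' @export
wntTargetPanel <- function() {
  system.file("extdata", "wnt_target_panel.tsv", package = "wntscreen",
              mustWork = TRUE)
}
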