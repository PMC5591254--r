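# random valid model/evidence generators shared by property-style tests

randomGeneCPT <- function(n) {
  pUpI <- runif(n, 0.05, 0.45)
  pUpA <- runif(n, pUpI + 0.1, 0.95)
  pHD <- runif(n, 0.05, 0.45)
  pHU <- runif(n, pHD + 0.1, 0.95)
  data.frame(gene = sprintf("G%02d", seq_len(n)),
             p_up_given_active = pUpA, p_up_given_inactive = pUpI,
             p_high_given_up = pHU, p_high_given_down = pHD,
             stringsAsFactors = FALSE)
}

randomModel <- function(n) {
  buildModel(randomGeneCPT(n), tcPriorOdds = exp(runif(1, -2, 2)))
}

randomEvidence <- function(model, pMissing = 0.25) {
  n <- nGenes(model)
  q <- runif(n)
  q[runif(n) < pMissing] <- NA
  names(q) <- geneNames(model)
  q
}

randomDepthHistogram <- function(maxClasses = 12, maxDepth = 60) {
  k <- sample(2:maxClasses, 1)
  d <- sort(sample(0:maxDepth, k))
  if (!any(d > 0)) d[k] <- maxDepth  # ensure some reads exist
  depthHistogram(d, sample(1:500, k, replace = TRUE))
}

# enumeration oracle for the two-sided Fisher test: walks every table with
# the observed margins, computing probabilities from binomial coefficients
fisherOracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  pObs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

writeTsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
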