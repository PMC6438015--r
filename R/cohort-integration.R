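#' @importFrom stats complete.cases
NULL

#' Select the low-anchor tumor subset
#'
#' Returns the tumors in the bottom `quantile` of anchor-gene expression
#' (e.g. the bottom 10th percentile of TET2 expression). The subset size is
#' `ceiling(quantile * nTumors)`; ties at the boundary are resolved by
#' expression rank and then by sample id, so the subset size is exact.
#'
#' @param cohort a [CohortData-class].
#' @param anchorGene anchor gene id (default `"TET2"`).
#' @param quantile expression quantile defining "low" (default 0.10).
#' @return character vector of tumor sample ids, ordered by anchor
#'   expression.
#' @export
selectLowAnchorSubset <- function(cohort, anchorGene = "TET2",
                                  quantile = 0.10) {
  expr <- cohortExpr(cohort)
  if (!anchorGene %in% rownames(expr))
    stop("anchor gene not in expression matrix: ", anchorGene)
  tumors <- tissueSamples(cohort, "tumor")
  if (length(tumors) < 1L) stop("no tumors in cohort")
  v <- expr[anchorGene, tumors]
  k <- ceiling(quantile * length(tumors))
  ord <- order(v, tumors)
  tumors[ord][seq_len(min(k, length(tumors)))]
}

#' Cohort expression concordance with knockout down-regulation
#'
#' For each knockout-down gene, a two-sided Mann-Whitney test of the
#' low-anchor tumor subset against the normals, gated on the tumor-down
#' direction, against the Bonferroni threshold `alpha / |koDownGenes|`.
#'
#' @param cohort a [CohortData-class].
#' @param koDownGenes character vector of genes down-regulated in either
#'   knockout (the Bonferroni family).
#' @param subsetSamples tumor sample ids from [selectLowAnchorSubset()].
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with `geneId`, `p.value`, `downInTumor`, `pass`; the
#'   Bonferroni threshold is attached as attribute `threshold`.
#' @export
cohortExpressionConcordance <- function(cohort, koDownGenes, subsetSamples,
                                        alpha = 0.05) {
  if (length(koDownGenes) == 0L) {
    out <- data.frame(geneId = character(), p.value = numeric(),
                      downInTumor = logical(), pass = logical())
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  expr <- cohortExpr(cohort)
  normals <- tissueSamples(cohort, "normal")
  thr <- bonferroniThreshold(alpha, length(koDownGenes))
  genes <- intersect(koDownGenes, rownames(expr))
  p <- dn <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    x <- expr[genes[i], subsetSamples]
    y <- expr[genes[i], normals]
    p[i] <- mannWhitneyU(x, y, mode = "approximate")$p.value
    ## direction: tumors ranked lower than normals
    dn[i] <- mean(rank(c(x, y))[seq_along(x)]) <
      mean(rank(c(x, y))[-seq_along(x)])
  }
  out <- data.frame(geneId = genes, p.value = p,
                    downInTumor = as.logical(dn),
                    pass = p < thr & as.logical(dn),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}

#' Assemble the tiered candidate panel
#'
#' Applies the candidate cascade in order: (1) significant expression loss in
#' either knockout (p < alpha, FC < `downFc`); (2) concordant expression loss
#' in the low-anchor cohort subset below the Bonferroni threshold;
#' (3) significant promoter methylation gain in either knockout;
#' (4) membership in the prior evidence list (e.g. genes with prior 5hmC
#' loss), skipped when `priorList` is `NULL`; (5) concordant probe
#' hypermethylation near the knockout gain-DMRs (Bonferroni over the tested
#' genes); then the tumor/normal discriminant flags: expression loss in
#' (6) all tumors and (7) matched tumors vs normals, Bonferroni-corrected
#' over the tests run at that stage. The tier is the number of consecutive
#' stages passed; with `strictCascade = FALSE` every flag is evaluated
#' independently and recorded.
#'
#' @param deResults named list of [nbExactTest()] + [classifyDe()] results,
#'   one per knockout line, all on the same gene universe.
#' @param dmrs GRanges of knockout differential-methylation records (one
#'   element of a named list per knockout line), classified by
#'   [classifyRegion()].
#' @param cohort a [CohortData-class].
#' @param priorList character vector of prior-evidence genes, or `NULL` to
#'   drop that stage.
#' @param anchorGene,quantile low-anchor subset definition.
#' @param alpha significance level used throughout (default 0.05).
#' @param downFc cascade down-call fold-change bound (default 0.75).
#' @param probeWindow probe-to-DMR proximity window in bp (default 500).
#' @param strictCascade when `TRUE` (default) a stage is only evaluated for
#'   genes that passed all upstream stages.
#' @return a [CandidatePanel-class].
#' @export
assemblePanel <- function(deResults, dmrs, cohort, priorList = NULL,
                          anchorGene = "TET2", quantile = 0.10,
                          alpha = 0.05, downFc = 0.75, probeWindow = 500L,
                          strictCascade = TRUE) {
  universe <- unique(unlist(lapply(deResults, function(d) d$geneId)))
  for (nm in names(deResults))
    if (!setequal(deResults[[nm]]$geneId, universe))
      stop("gene-universe mismatch in DE results: ", nm)
  nGenes <- length(universe)

  ## stage 1: KO expression down in either line (p < alpha, FC < downFc)
  koDown <- rep(FALSE, nGenes)
  for (d in deResults) {
    idx <- match(d$geneId, universe)
    koDown[idx] <- koDown[idx] |
      (d$p.value < alpha & d$foldChange < downFc)
  }
  koDownGenes <- universe[koDown]

  ## stage 2: cohort concordance (Bonferroni over the KO-down family)
  subset <- selectLowAnchorSubset(cohort, anchorGene, quantile)
  conc <- cohortExpressionConcordance(cohort, koDownGenes, subset, alpha)
  cohortDown <- universe %in% conc$geneId[conc$pass]

  ## stage 3: promoter hypermethylation in either KO
  promoGain <- rep(FALSE, nGenes)
  dmrByGene <- list()
  for (nm in names(dmrs)) {
    g <- dmrs[[nm]]
    sig <- mcols(g)$significant & mcols(g)$direction == "gain" &
      mcols(g)$featureClass == "promoter" & !is.na(mcols(g)$geneId)
    gs <- mcols(g)$geneId[sig]
    promoGain[match(intersect(gs, universe), universe)] <- TRUE
    for (i in which(sig)) {
      gid <- mcols(g)$geneId[i]
      dmrByGene[[gid]] <- c(dmrByGene[[gid]],
                            sprintf("%s:%d-%d", seqnames(g)[i],
                                    start(g)[i] - 1L, end(g)[i]))
    }
  }

  ## stage 4: prior evidence list
  priorFlag <- if (is.null(priorList)) rep(NA, nGenes) else
    universe %in% priorList

  ## stage 5: probe concordance near gain-DMRs, low-anchor tumors vs normals
  gainDmrs <- do.call(c, unname(lapply(dmrs, function(g) {
    GenomicRanges::strand(g) <- "*"
    g[mcols(g)$significant & mcols(g)$direction == "gain"]
  })))
  probes <- cohortProbes(cohort)
  betas <- cohortBetas(cohort)
  normals <- tissueSamples(cohort, "normal")
  probeFlag <- rep(FALSE, nGenes)
  probeIds <- rep("", nGenes)
  upTo4 <- koDown & cohortDown & promoGain &
    (if (is.null(priorList)) TRUE else priorFlag)
  candidates5 <- if (strictCascade) universe[upTo4] else universe
  asg <- mapProbesToRegions(probes, gainDmrs, window = probeWindow)
  if (nrow(asg) && length(candidates5)) {
    dmrGene <- mcols(gainDmrs)$geneId[asg$regionIndex]
    keep <- !is.na(dmrGene) & dmrGene %in% candidates5
    probeGene <- split(asg$probeId[keep], dmrGene[keep])
    mProbe <- length(unlist(probeGene))
    testedGenes <- names(probeGene)
    if (length(testedGenes)) {
      thr5 <- bonferroniThreshold(alpha, length(testedGenes))
      for (gid in testedGenes) {
        ps <- unique(probeGene[[gid]])
        hyper <- FALSE
        for (pid in ps) {
          ri <- match(pid, mcols(probes)$probeId)
          bT <- betas[ri, subset]
          bN <- betas[ri, normals]
          pv <- mannWhitneyU(bT, bN, mode = "approximate")$p.value
          up <- mean(rank(c(bT, bN))[seq_along(bT)]) >
            mean(rank(c(bT, bN))[-seq_along(bT)])
          if (pv < thr5 && up) hyper <- TRUE
        }
        i <- match(gid, universe)
        probeFlag[i] <- hyper
        probeIds[i] <- paste(ps, collapse = ",")
      }
    }
  }

  ## stages 6-7: tumor/normal expression discriminant, all and matched
  expr <- cohortExpr(cohort)
  cl <- as.data.frame(cohortClinical(cohort))
  tumors <- tissueSamples(cohort, "tumor")
  matchedT <- cl$sampleId[cl$tissue == "tumor" & !is.na(cl$matchedPairId)]
  discAll <- discMatched <- rep(FALSE, nGenes)
  candidates6 <- if (strictCascade) universe[upTo4 & probeFlag] else universe
  candidates6 <- intersect(candidates6, rownames(expr))
  if (length(candidates6)) {
    thr6 <- bonferroniThreshold(alpha, 2L * length(candidates6))
    for (gid in candidates6) {
      i <- match(gid, universe)
      xA <- expr[gid, tumors]; yN <- expr[gid, normals]
      pA <- mannWhitneyU(xA, yN, mode = "approximate")$p.value
      dA <- mean(rank(c(xA, yN))[seq_along(xA)]) <
        mean(rank(c(xA, yN))[-seq_along(xA)])
      discAll[i] <- pA < thr6 && dA
      if (length(matchedT)) {
        xM <- expr[gid, matchedT]
        pM <- mannWhitneyU(xM, yN, mode = "approximate")$p.value
        dM <- mean(rank(c(xM, yN))[seq_along(xM)]) <
          mean(rank(c(xM, yN))[-seq_along(xM)])
        discMatched[i] <- pM < thr6 && dM
      }
    }
  }

  flags <- DataFrame(
    geneId = universe,
    koDownEither = koDown,
    cohortExprDown = cohortDown,
    koPromoterHypermethEither = promoGain,
    priorListMember = priorFlag,
    cohortProbeConcordant = probeFlag,
    tumorNormalDiscriminantAll = discAll,
    tumorNormalDiscriminantMatched = discMatched)
  stageCols <- c("koDownEither", "cohortExprDown",
                 "koPromoterHypermethEither",
                 if (!is.null(priorList)) "priorListMember",
                 "cohortProbeConcordant", "tumorNormalDiscriminantAll",
                 "tumorNormalDiscriminantMatched")
  fm <- as.matrix(as.data.frame(flags[, stageCols]))
  tier <- apply(fm, 1, function(r) {
    f <- which(!r)
    if (length(f)) f[1] - 1L else length(r)
  })
  flags$tier <- as.integer(tier)
  flags$dmrCoords <- vapply(universe, function(g)
    paste(dmrByGene[[g]], collapse = ";"), character(1), USE.NAMES = FALSE)
  flags$probeIds <- probeIds

  new("CandidatePanel", table = flags,
      metadata = list(alpha = alpha, downFc = downFc,
                      anchorGene = anchorGene, quantile = quantile,
                      probeWindow = probeWindow,
                      strictCascade = strictCascade,
                      bonferroniCohort = attr(conc, "threshold"),
                      nKoDown = length(koDownGenes),
                      subsetSize = length(subset),
                      stageOrder = stageCols))
}
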