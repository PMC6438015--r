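#' @importFrom stats rnbinom rpois rnorm runif rexp plogis qlogis rbinom
#'   uniroot
#' @importFrom withr with_seed
NULL

## The generator plants "driver" genes jointly: lowered expression and gained
## promoter methylation in the knockouts, and in the cohort a TET2-expression
## gradient across tumors with driver expression loss, probe
## hypermethylation, and recurrence hazard all scaling with the TET2
## deficit. Everything is drawn under withr::with_seed so a fixed
## configuration is byte-reproducible.

rnbinomSafe <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate the knockout experiment (methylation + expression)
#'
#' Generates a synthetic gene model, windowed methyl-capture counts for
#' parental, two knockout lines and an input control, and a gene-level
#' RNA count matrix. Planted drivers have their KO expression mean
#' multiplied by `driverExprFc` and their promoter methylation signal
#' multiplied by `driverMethFc`, in both KO lines; all other genes are null.
#' Gene 1 is reserved as the `TET2` anchor (never a driver).
#'
#' @param config a [SimulationConfig-class].
#' @param windowWidth tiling window width in bp (default 200).
#' @return list with `methWindows` (a [RegionCountSet-class]), `exprCounts`
#'   (gene x sample integer matrix), `genes` (gene model GRanges) and
#'   `truth` (a [SyntheticTruth-class]).
#' @export
simulateKoExperiment <- function(config, windowWidth = 200L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nG <- config@nGenes
  k <- config@koReplicates
  withr::with_seed(config@seed, {
    ## gene model: genes every 20 kb on 4 chromosomes, 5 kb span,
    ## alternating strand
    perChrom <- ceiling(nG / 4)
    chrom <- paste0("chr", rep(1:4, each = perChrom)[seq_len(nG)])
    posInChrom <- (seq_len(nG) - 1L) %% perChrom
    gStart <- 10000L + posInChrom * 20000L
    strand <- rep(c("+", "-"), length.out = nG)
    geneId <- c("TET2", sprintf("G%04d", seq_len(nG - 1L)))
    genes <- geneModel(geneId, chrom, gStart, gStart + 5000L, strand)
    tss <- mcols(genes)$tss

    drivers <- sample(geneId[-1], config@nPlantedDrivers)
    isDriver <- geneId %in% drivers

    ## expression: NB counts with library-size factors
    lambda <- exp(rnorm(nG, config@exprBaselineLogmean,
                        config@exprBaselineLogsd))
    conds <- c(rep("parental", k), rep("KO1", k), rep("KO2", k))
    sampleNames <- paste0(conds, "_",
                          stats::ave(seq_along(conds), conds, FUN = seq_along))
    libf <- runif(length(conds), 0.8, 1.2)
    fcMat <- matrix(1, nG, length(conds))
    fcMat[isDriver, conds != "parental"] <- config@driverExprFc
    exprCounts <- matrix(0L, nG, length(conds),
                         dimnames = list(geneId, sampleNames))
    for (j in seq_along(conds))
      exprCounts[, j] <- rnbinomSafe(nG, lambda * fcMat[, j] * libf[j],
                                     config@nbDispersion)

    ## methylation: 20 windows of `windowWidth` bp around each TSS; a
    ## 3-window signal block at the TSS carries the capture enrichment
    nWin <- 20L
    winPerGene <- lapply(seq_len(nG), function(i) {
      s0 <- tss[i] - (nWin / 2) * windowWidth
      s0 <- max(s0, 0L)
      s0 + (0:(nWin - 1L)) * windowWidth
    })
    winStart <- unlist(winPerGene)
    winChrom <- rep(chrom, each = nWin)
    winGene <- rep(seq_len(nG), each = nWin)
    offset <- rep(0:(nWin - 1L), nG) - nWin / 2
    signalWin <- offset %in% c(-1L, 0L, 1L)   # 3 windows straddling the TSS
    regions <- bedToGRanges(winChrom, winStart, winStart + windowWidth)

    bg <- 5                 # background capture noise per window
    sigParental <- 30       # parental promoter enrichment per signal window
    methConds <- c(conds, "input")
    methNames <- c(sampleNames, "input_1")
    methLibf <- c(libf, 1)
    nWinTot <- length(winStart)
    methCounts <- matrix(0L, nWinTot, length(methConds),
                         dimnames = list(NULL, methNames))
    for (j in seq_along(methConds)) {
      mu <- rep(bg, nWinTot)
      if (methConds[j] != "input") {
        sigFc <- ifelse(isDriver[winGene] & methConds[j] != "parental",
                        config@driverMethFc, 1)
        mu <- mu + ifelse(signalWin, sigParental * sigFc, 0)
      }
      methCounts[, j] <- rnbinomSafe(nWinTot, mu * methLibf[j],
                                     config@nbDispersion)
    }
    methWindows <- regionCountSet(methCounts, regions,
                                  condition = methConds)

    effects <- DataFrame(
      geneId = geneId,
      isDriver = isDriver,
      exprFc = ifelse(isDriver, config@driverExprFc, 1),
      methFc = ifelse(isDriver, config@driverMethFc, 1),
      betaShift = ifelse(isDriver,
                         config@probeBetaTumor - config@probeBetaNormal, 0),
      baselineMean = lambda)
    truth <- new("SyntheticTruth", driverGenes = drivers, effects = effects)
    list(methWindows = methWindows, exprCounts = exprCounts, genes = genes,
         truth = truth)
  })
}

#' Simulate the cohort (expression, probe betas, clinical table)
#'
#' Tumors carry a continuous TET2-expression gradient; the planted drivers
#' are down-regulated and their promoter probes hypermethylated in
#' proportion to each tumor's TET2 deficit; recurrence hazard is log-linear
#' in the mean driver expression. Follow-up is exponential with uniform
#' censoring calibrated to the configured censoring fraction; Gleason grades
#' and a binary stage group scale with the deficit.
#'
#' @param config a [SimulationConfig-class].
#' @param truth the [SyntheticTruth-class] from [simulateKoExperiment()].
#' @param genes the gene model GRanges from [simulateKoExperiment()].
#' @param exprNoiseSd residual log-normal sd of cohort expression (default
#'   0.35).
#' @param betaLogitSd logit-scale sd of probe betas (default 0.5).
#' @return a [CohortData-class].
#' @export
simulateCohort <- function(config, truth, genes, exprNoiseSd = 0.3,
                           betaLogitSd = 0.5) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "SyntheticTruth"))
  nT <- config@cohortNTumor
  nN <- config@cohortNNormal
  if (nT < 2L || nN < 2L) stop("cohort sizes must be >= 2 per group")
  eff <- truth@effects
  geneId <- eff$geneId
  nG <- length(geneId)
  isDriver <- eff$isDriver
  baseline <- eff$baselineMean

  withr::with_seed(config@seed + 1L, {
    tumorId <- sprintf("T%04d", seq_len(nT))
    normalId <- sprintf("N%04d", seq_len(nN))
    tet2Level <- runif(nT)          # relative TET2 activity, 0 = deficient
    deficit <- 1 - tet2Level

    ## expression (linear scale, normalized-abundance-like)
    mult <- matrix(1, nG, nT + nN)
    mult[match("TET2", geneId), seq_len(nT)] <- 0.2 + 0.8 * tet2Level
    ## drivers are down in every tumor (half the KO log-fold change) and
    ## further down in proportion to the TET2 deficit, mirroring a cohort
    ## where candidate loss marks tumors generally and TET2-low most
    for (i in which(isDriver))
      mult[i, seq_len(nT)] <- config@driverExprFc^(0.5 + deficit)
    expr <- baseline * mult *
      exp(matrix(rnorm(nG * (nT + nN), 0, exprNoiseSd), nG))
    dimnames(expr) <- list(geneId, c(tumorId, normalId))

    ## probes: two per gene inside the promoter (TSS -100 / +100)
    tss <- mcols(genes)$tss
    probeId <- paste0("cg", sprintf("%07d", seq_len(2L * nG)))
    pPos <- as.vector(rbind(pmax(tss - 100L, 0L), tss + 100L))
    probes <- probeManifest(probeId,
                            rep(as.character(seqnames(genes)), each = 2L),
                            pPos, geneId = rep(geneId, each = 2L))
    muN <- qlogis(config@probeBetaNormal)
    betaMeanLogit <- matrix(muN, 2L * nG, nT + nN)
    for (i in which(isDriver)) {
      bT <- config@probeBetaNormal +
        (config@probeBetaTumor - config@probeBetaNormal) *
          (0.25 + 0.75 * deficit)
      betaMeanLogit[2L * i - 1L, seq_len(nT)] <- qlogis(bT)
      betaMeanLogit[2L * i, seq_len(nT)] <- qlogis(bT)
    }
    betas <- plogis(betaMeanLogit +
                    matrix(rnorm(length(betaMeanLogit), 0, betaLogitSd),
                           nrow(betaMeanLogit)))
    dimnames(betas) <- list(probeId, c(tumorId, normalId))

    ## clinical: Gleason/stage scale with deficit; hazard log-linear in the
    ## mean driver expression
    sev <- deficit + rnorm(nT, 0, 0.3)
    q <- stats::quantile(sev, c(0.3, 0.6, 0.8))
    gPrim <- ifelse(sev <= q[1], 3L, ifelse(sev <= q[2], 3L,
             ifelse(sev <= q[3], 4L, 4L)))
    gSec <- ifelse(sev <= q[1], 3L, ifelse(sev <= q[2], 4L,
            ifelse(sev <= q[3], 3L, 4L)))
    stage <- ifelse(runif(nT) < plogis(-1 + 2 * deficit),
                    "advanced", "organ_confined")
    marker <- colMeans(log2(expr[isDriver, seq_len(nT), drop = FALSE]))
    z <- as.numeric(scale(marker))
    lambda0 <- 0.15
    rate <- lambda0 * config@hazardRatioMarker^(-z)
    tEvent <- rexp(nT, rate)
    cr <- max(config@censorRate, 0.01)
    ## Unif(0, cMax) censoring: mean censored fraction (1 - e^-x)/x = cr
    x <- uniroot(function(u) (1 - exp(-u)) / u - cr, c(1e-6, 1e3))$root
    cMax <- x / lambda0
    tCens <- runif(nT, 0, cMax)
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)

    nPairs <- min(nN, nT)
    pairT <- c(sprintf("P%03d", seq_len(nPairs)),
               rep(NA_character_, nT - nPairs))
    pairN <- c(sprintf("P%03d", seq_len(nPairs)),
               rep(NA_character_, nN - nPairs))
    clinical <- DataFrame(
      sampleId = c(tumorId, normalId),
      tissue = rep(c("tumor", "normal"), c(nT, nN)),
      matchedPairId = c(pairT, pairN),
      gleasonPrimary = c(gPrim, rep(NA_integer_, nN)),
      gleasonSecondary = c(gSec, rep(NA_integer_, nN)),
      stageGroup = c(stage, rep(NA_character_, nN)),
      recurrence = c(ifelse(event == 1, "yes", "no"),
                     rep(NA_character_, nN)),
      followupTime = c(time, rep(NA_real_, nN)),
      event = c(event, rep(NA_integer_, nN)))
    cohortData(expr, probes, betas, clinical)
  })
}

#' Simulate a prior-evidence gene list
#'
#' The cascade's prior list (e.g. genes with 5hmC loss in an earlier study)
#' is an input, not a computation; synthetically it contains every planted
#' driver plus a fraction of random non-drivers.
#'
#' @param config a [SimulationConfig-class].
#' @param truth a [SyntheticTruth-class].
#' @param extraFraction fraction of non-drivers included (default 0.1).
#' @return character vector of gene ids.
#' @export
simulatePriorList <- function(config, truth, extraFraction = 0.1) {
  withr::with_seed(config@seed + 2L, {
    nonDrivers <- setdiff(truth@effects$geneId, c(truth@driverGenes, "TET2"))
    extra <- sample(nonDrivers, round(extraFraction * length(nonDrivers)))
    sort(c(truth@driverGenes, extra))
  })
}

#' Simulate a MethyLight qPCR plate
#'
#' Generates Ct values under the standard-curve model
#' `Ct = intercept - slope * log2(template quantity) + noise` for a gene
#' target and the ALU reference, in duplicate, for a supermethylated control
#' (`CH3`, relative methylation 1) and matched tumor/normal pairs with a
#' planted methylation difference. With `noiseSd = 0`, delta-delta-Ct
#' quantification recovers `100 * methylation` exactly.
#'
#' @param config a [SimulationConfig-class] (its seed is used, offset so the
#'   plate is independent of the other simulations).
#' @param nPairs number of tumor/normal pairs (default 19).
#' @param gene gene target name (default `"ASB2"`).
#' @param tumorMethylation,normalMethylation planted relative methylation of
#'   tumors and normals (defaults 0.4 / 0.1: a 4-fold difference).
#' @param slope,intercept standard-curve parameters (defaults 1 / 38).
#' @param noiseSd Gaussian Ct noise, cycles (default 0.15).
#' @param nReplicates qPCR replicates per well (default 2).
#' @param aluCtOverride named numeric vector forcing the ALU Ct of given
#'   samples (e.g. `c(N007_N = 31)` to plant a QC failure).
#' @return data.frame with `sampleId`, `target`, `replicate`, `ct`.
#' @export
simulateMethylightPlate <- function(config, nPairs = 19L, gene = "ASB2",
                                    tumorMethylation = 0.4,
                                    normalMethylation = 0.1,
                                    slope = 1, intercept = 38,
                                    noiseSd = 0.15, nReplicates = 2L,
                                    aluCtOverride = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  withr::with_seed(config@seed + 3L, {
    aluQuantity <- 2^13   # abundant repeat reference
    sampleId <- c("CH3",
                  as.vector(rbind(sprintf("P%03d_T", seq_len(nPairs)),
                                  sprintf("P%03d_N", seq_len(nPairs)))))
    meth <- c(1, as.vector(rbind(rep(tumorMethylation, nPairs),
                                 rep(normalMethylation, nPairs))))
    rows <- list()
    for (i in seq_along(sampleId)) {
      for (tg in c(gene, "ALU")) {
        qty <- if (tg == "ALU") aluQuantity else aluQuantity * meth[i]
        ctMean <- intercept - slope * log2(qty)
        if (!is.null(aluCtOverride) && tg == "ALU" &&
            sampleId[i] %in% names(aluCtOverride))
          ctMean <- unname(aluCtOverride[sampleId[i]])
        for (r in seq_len(nReplicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sampleId = sampleId[i], target = tg, replicate = r,
            ct = ctMean + rnorm(1, 0, noiseSd), stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
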