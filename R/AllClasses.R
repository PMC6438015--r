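#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Simulation configuration for the synthetic cascade
#'
#' Holds every tunable of the synthetic-data generator: the knockout (KO)
#' experiment design, the cohort design, and the planted effect sizes for
#' driver genes. Defaults correspond to the study conditions the pipeline is
#' validated under: two replicates per condition, 200 tumors / 40 normals,
#' planted expression fold change 0.5 and promoter methylation fold change 3.
#'
#' @slot seed integer RNG seed (mandatory).
#' @slot nGenes number of simulated genes.
#' @slot nPlantedDrivers number of planted driver genes.
#' @slot koReplicates replicates per condition in the KO experiment.
#' @slot cohortNTumor,cohortNNormal cohort group sizes.
#' @slot exprBaselineLogmean,exprBaselineLogsd log-normal baseline for
#'   per-gene expression means.
#' @slot nbDispersion negative-binomial dispersion phi (variance mu + phi mu^2).
#' @slot driverExprFc planted KO/parental expression fold change, in (0, 1).
#' @slot driverMethFc planted KO/parental promoter methylation fold change, > 1.
#' @slot probeBetaNormal,probeBetaTumor array beta means for driver probes in
#'   normal tissue and in fully TET2-deficient tumors.
#' @slot censorRate fraction of follow-up lost to censoring (approximate).
#' @slot hazardRatioMarker hazard ratio per standard deviation of the planted
#'   risk marker (low driver expression raises hazard).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nGenes = "integer",
    nPlantedDrivers = "integer",
    koReplicates = "integer",
    cohortNTumor = "integer",
    cohortNNormal = "integer",
    exprBaselineLogmean = "numeric",
    exprBaselineLogsd = "numeric",
    nbDispersion = "numeric",
    driverExprFc = "numeric",
    driverMethFc = "numeric",
    probeBetaNormal = "numeric",
    probeBetaTumor = "numeric",
    censorRate = "numeric",
    hazardRatioMarker = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(nGenes = object@nGenes, nPlantedDrivers = object@nPlantedDrivers,
           koReplicates = object@koReplicates,
           cohortNTumor = object@cohortNTumor,
           cohortNNormal = object@cohortNNormal)
  if (any(is.na(cnt)) || any(cnt <= 0L))
    msg <- c(msg, "all counts must be positive integers")
  if (!is.na(object@nPlantedDrivers) && !is.na(object@nGenes) &&
      object@nPlantedDrivers > object@nGenes)
    msg <- c(msg, "nPlantedDrivers must not exceed nGenes")
  if (object@nbDispersion < 0)
    msg <- c(msg, "nbDispersion must be >= 0")
  if (!(object@driverExprFc > 0 && object@driverExprFc <= 1))
    msg <- c(msg, "driverExprFc must be in (0, 1]")
  if (object@driverMethFc < 1)
    msg <- c(msg, "driverMethFc must be >= 1")
  for (nm in c("probeBetaNormal", "probeBetaTumor", "censorRate")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, paste(nm, "must be in [0, 1]"))
  }
  if (object@hazardRatioMarker <= 0)
    msg <- c(msg, "hazardRatioMarker must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed integer RNG seed; mandatory so every downstream draw is
#'   reproducible.
#' @param nGenes,nPlantedDrivers,koReplicates,cohortNTumor,cohortNNormal
#'   design counts; see the class documentation.
#' @param exprBaselineLogmean,exprBaselineLogsd,nbDispersion expression
#'   baseline and dispersion.
#' @param driverExprFc,driverMethFc planted knockout effect sizes.
#' @param probeBetaNormal,probeBetaTumor planted array beta means.
#' @param censorRate,hazardRatioMarker survival generator settings.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, nGenes = 100, nPlantedDrivers = 5)
#' @export
simulationConfig <- function(seed,
                             nGenes = 500L,
                             nPlantedDrivers = 20L,
                             koReplicates = 2L,
                             cohortNTumor = 200L,
                             cohortNNormal = 40L,
                             exprBaselineLogmean = log(150),
                             exprBaselineLogsd = 1,
                             nbDispersion = 0.01,
                             driverExprFc = 0.5,
                             driverMethFc = 3,
                             probeBetaNormal = 0.2,
                             probeBetaTumor = 0.6,
                             censorRate = 0.3,
                             hazardRatioMarker = 3) {
  if (missing(seed)) stop("'seed' is mandatory")
  new("SimulationConfig",
      seed = as.integer(seed),
      nGenes = as.integer(nGenes),
      nPlantedDrivers = as.integer(nPlantedDrivers),
      koReplicates = as.integer(koReplicates),
      cohortNTumor = as.integer(cohortNTumor),
      cohortNNormal = as.integer(cohortNNormal),
      exprBaselineLogmean = as.numeric(exprBaselineLogmean),
      exprBaselineLogsd = as.numeric(exprBaselineLogsd),
      nbDispersion = as.numeric(nbDispersion),
      driverExprFc = as.numeric(driverExprFc),
      driverMethFc = as.numeric(driverMethFc),
      probeBetaNormal = as.numeric(probeBetaNormal),
      probeBetaTumor = as.numeric(probeBetaTumor),
      censorRate = as.numeric(censorRate),
      hazardRatioMarker = as.numeric(hazardRatioMarker))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n",
      "  seed: ", object@seed, "\n",
      "  genes: ", object@nGenes, " (", object@nPlantedDrivers,
      " planted drivers)\n",
      "  KO design: ", object@koReplicates, " replicates/condition\n",
      "  cohort: ", object@cohortNTumor, " tumors / ",
      object@cohortNNormal, " normals\n",
      "  planted effects: expression FC ", object@driverExprFc,
      ", promoter methylation FC ", object@driverMethFc, "\n", sep = "")
})

#' Ground truth of a synthetic simulation
#'
#' Records which genes carry planted knockout/cohort effects and their
#' per-gene effect sizes, so recovery and false-discovery proportions can be
#' scored exactly.
#'
#' @slot driverGenes character vector of planted driver gene ids.
#' @slot effects DataFrame with one row per gene: `geneId`, `isDriver`,
#'   `exprFc`, `methFc`, `betaShift`.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(driverGenes = "character", effects = "DataFrame"))

setValidity("SyntheticTruth", function(object) {
  if (!all(object@driverGenes %in% object@effects$geneId))
    return("driverGenes must be a subset of the simulated gene universe")
  TRUE
})

#' @describeIn SyntheticTruth-class planted driver gene ids.
#' @param x a SyntheticTruth.
#' @export
driverGenes <- function(x) {
  stopifnot(is(x, "SyntheticTruth"))
  x@driverGenes
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth with", length(object@driverGenes), "planted drivers in",
      nrow(object@effects), "genes\n")
})

#' Region-by-sample capture-seq count container
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] specialisation holding
#' non-negative read counts over genomic windows or regions, with per-sample
#' `condition` (e.g. parental, KO1, KO2, input) and `replicate` labels and
#' library sizes.
#'
#' @exportClass RegionCountSet
setClass("RegionCountSet", contains = "RangedSummarizedExperiment")

setValidity("RegionCountSet", function(object) {
  msg <- character()
  cnt <- assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  cd <- colData(object)
  for (nm in c("condition", "replicate", "libSize"))
    if (!nm %in% colnames(cd)) msg <- c(msg, paste0("colData lacks '", nm, "'"))
  if ("libSize" %in% colnames(cd) && any(cd$libSize < 0))
    msg <- c(msg, "library sizes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionCountSet
#'
#' @param counts region x sample matrix of non-negative integer counts.
#' @param regions [GenomicRanges::GRanges] of the counted regions (same length
#'   as `nrow(counts)`).
#' @param condition per-sample condition labels.
#' @param replicate per-sample replicate indices (default 1..k within
#'   condition).
#' @param libSize per-sample library sizes; defaults to column sums.
#' @return A [RegionCountSet-class].
#' @export
regionCountSet <- function(counts, regions, condition,
                           replicate = NULL, libSize = NULL) {
  counts <- as.matrix(counts)
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  if (is.null(libSize)) libSize <- colSums(counts)
  cd <- DataFrame(condition = as.character(condition),
                  replicate = as.integer(replicate),
                  libSize = as.numeric(libSize))
  if (!is.null(colnames(counts))) rownames(cd) <- colnames(counts)
  new("RegionCountSet",
      SummarizedExperiment(assays = list(counts = counts),
                           rowRanges = regions, colData = cd))
}

#' @describeIn RegionCountSet-class per-sample condition labels.
#' @param x a RegionCountSet.
#' @export
sampleCondition <- function(x) colData(x)$condition

#' @describeIn RegionCountSet-class per-sample library sizes.
#' @export
librarySizes <- function(x) colData(x)$libSize

#' Cohort container: expression, probe betas, clinical table
#'
#' Bundles the three cohort-level assays the cascade consumes: a gene x sample
#' continuous expression matrix, a probe manifest ([GenomicRanges::GRanges]
#' with a `probeId` column) with its probe x sample beta matrix, and the
#' clinical table (tissue status, matched pair id, Gleason primary/secondary,
#' binary stage group, recurrence, follow-up time and event).
#'
#' @slot expr numeric matrix, genes x samples.
#' @slot probes GRanges of single-CpG probe positions with `probeId` and
#'   `geneId` metadata columns.
#' @slot betas numeric matrix in [0,1], probes x samples (tumors and normals).
#' @slot clinical DataFrame keyed by `sampleId`.
#' @exportClass CohortData
setClass("CohortData",
  representation(expr = "matrix", probes = "GRanges", betas = "matrix",
                 clinical = "DataFrame"))

setValidity("CohortData", function(object) {
  msg <- character()
  cl <- object@clinical
  need <- c("sampleId", "tissue", "matchedPairId", "gleasonPrimary",
            "gleasonSecondary", "stageGroup", "recurrence",
            "followupTime", "event")
  miss <- setdiff(need, colnames(cl))
  if (length(miss))
    msg <- c(msg, paste("clinical table lacks:", paste(miss, collapse = ", ")))
  if (!all(colnames(object@expr) %in% cl$sampleId))
    msg <- c(msg, "expression samples absent from clinical table")
  b <- object@betas
  if (length(b) && (any(!is.finite(b)) || any(b < 0) || any(b > 1)))
    msg <- c(msg, "betas must be finite and in [0, 1]")
  if (length(b) && nrow(b) != length(object@probes))
    msg <- c(msg, "betas rows must match probe manifest")
  if ("followupTime" %in% colnames(cl) &&
      any(stats::na.omit(cl$followupTime) < 0))
    msg <- c(msg, "followupTime must be >= 0")
  if ("tissue" %in% colnames(cl) &&
      !all(cl$tissue %in% c("tumor", "normal")))
    msg <- c(msg, "tissue must be 'tumor' or 'normal'")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortData object
#'
#' @param expr genes x samples numeric matrix (normalized expression).
#' @param probes GRanges with `probeId` (and optionally `geneId`) columns.
#' @param betas probes x samples beta matrix in [0,1].
#' @param clinical data.frame/DataFrame with the clinical schema (see
#'   [CohortData-class]).
#' @return A [CohortData-class].
#' @export
cohortData <- function(expr, probes, betas, clinical) {
  new("CohortData", expr = as.matrix(expr), probes = probes,
      betas = as.matrix(betas), clinical = DataFrame(clinical))
}

#' @describeIn CohortData-class expression matrix accessor.
#' @param x a CohortData.
#' @export
cohortExpr <- function(x) x@expr

#' @describeIn CohortData-class clinical table accessor.
#' @export
cohortClinical <- function(x) x@clinical

#' @describeIn CohortData-class probe manifest accessor.
#' @export
cohortProbes <- function(x) x@probes

#' @describeIn CohortData-class beta matrix accessor.
#' @export
cohortBetas <- function(x) x@betas

#' @describeIn CohortData-class sample ids of one tissue.
#' @param tissue `"tumor"` or `"normal"`.
#' @export
tissueSamples <- function(x, tissue) {
  cl <- x@clinical
  as.character(cl$sampleId[cl$tissue == tissue])
}

setMethod("show", "CohortData", function(object) {
  cl <- object@clinical
  cat("CohortData: ", sum(cl$tissue == "tumor"), " tumors / ",
      sum(cl$tissue == "normal"), " normals; ",
      nrow(object@expr), " genes; ", length(object@probes),
      " probes\n", sep = "")
})

#' Candidate panel with cascade provenance
#'
#' One row per gene in the shared universe, with a boolean flag per cascade
#' tier (`koDownEither`, `cohortExprDown`, `koPromoterHypermethEither`,
#' `priorListMember`, `cohortProbeConcordant`, `tumorNormalDiscriminantAll`,
#' `tumorNormalDiscriminantMatched`), the tier reached (number of consecutive
#' cascade stages passed), and per-gene provenance (DMR coordinates, mapped
#' probe ids). Thresholds and derived Bonferroni cutoffs live in `metadata()`.
#'
#' @slot table DataFrame of flags, tier and provenance.
#' @slot metadata list of thresholds and stage bookkeeping.
#' @exportClass CandidatePanel
setClass("CandidatePanel",
  representation(table = "DataFrame", metadata = "list"))

#' @describeIn CandidatePanel-class the panel table.
#' @param x a CandidatePanel.
#' @export
panelTable <- function(x) x@table

#' @describeIn CandidatePanel-class thresholds and bookkeeping.
#' @export
panelMetadata <- function(x) x@metadata

#' @describeIn CandidatePanel-class gene ids that reached at least `tier`.
#' @param tier minimum tier (number of consecutive cascade stages passed).
#' @export
panelGenes <- function(x, tier = max(x@table$tier)) {
  as.character(x@table$geneId[x@table$tier >= tier])
}

setMethod("show", "CandidatePanel", function(object) {
  tb <- object@table
  cat("CandidatePanel:", nrow(tb), "genes\n")
  if (nrow(tb)) {
    tt <- table(factor(tb$tier, levels = 0:max(tb$tier)))
    funnel <- rev(cumsum(rev(tt)))
    cat("  funnel (>= tier):",
        paste(sprintf("%s:%d", names(funnel), funnel), collapse = " "), "\n")
  }
})
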