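#' @importFrom stats aggregate
NULL

## MethyLight delta-delta-Ct quantification against an ALU repeat reference
## and a supermethylated (CH3) control. Replicates are averaged on the Ct
## scale before differencing, the standard convention for ddCt.

#' Quantify methylation by the delta-delta-Ct method
#'
#' For each sample s and gene target:
#' `dCt_s = Ct_gene,s - Ct_ALU,s`, `dCt_M` likewise for the supermethylated
#' control, and the reported value is `100 * 2^-(dCt_s - dCt_M)` — percent
#' methylation relative to the fully methylated reference. Values above 100
#' are permitted and flagged. A sample with no gene amplification (missing
#' gene Ct) is reported as 0 with a flag; a missing ALU reference fails QC.
#'
#' @param ct data.frame with columns `sampleId`, `target` (gene name or
#'   `"ALU"`), `replicate`, `ct` (NA = no amplification).
#' @param controlSample sample id of the supermethylated control (default
#'   `"CH3"`).
#' @param gene gene target name; default: the single non-ALU target present.
#' @return data.frame with one row per non-control sample: `sampleId`,
#'   `gene`, `value`, `aluCt` (replicate-mean), `qcPass`, `flag`
#'   (`""`, `"no_gene_amplification"`, `"above_reference"`, `"missing_alu"`).
#' @export
quantifyDdct <- function(ct, controlSample = "CH3", gene = NULL) {
  need <- c("sampleId", "target", "replicate", "ct")
  if (!all(need %in% colnames(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (any(stats::na.omit(ct$ct) <= 0)) stop("Ct values must be positive")
  if (is.null(gene)) {
    gene <- setdiff(unique(ct$target), "ALU")
    if (length(gene) != 1L)
      stop("specify 'gene': found targets ", paste(gene, collapse = ", "))
  }
  meanCt <- function(sample, target) {
    v <- ct$ct[ct$sampleId == sample & ct$target == target]
    if (length(v) == 0L || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  gM <- meanCt(controlSample, gene)
  aM <- meanCt(controlSample, "ALU")
  if (is.na(gM) || is.na(aM))
    stop("supermethylated control lacks gene or ALU Ct")
  dCtM <- gM - aM
  samples <- setdiff(unique(ct$sampleId), controlSample)
  rows <- lapply(samples, function(s) {
    gS <- meanCt(s, gene)
    aS <- meanCt(s, "ALU")
    if (is.na(aS))
      return(data.frame(sampleId = s, gene = gene, value = NA_real_,
                        aluCt = NA_real_, qcPass = FALSE,
                        flag = "missing_alu", stringsAsFactors = FALSE))
    if (is.na(gS))
      return(data.frame(sampleId = s, gene = gene, value = 0,
                        aluCt = aS, qcPass = TRUE,
                        flag = "no_gene_amplification",
                        stringsAsFactors = FALSE))
    val <- 100 * 2^(-((gS - aS) - dCtM))
    data.frame(sampleId = s, gene = gene, value = val, aluCt = aS,
               qcPass = TRUE,
               flag = if (val > 100) "above_reference" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' QC-filter MethyLight quantifications on the ALU reference
#'
#' Excludes samples whose replicate-mean ALU Ct exceeds `aluCtMax`
#' (strictly: Ct 30.0 is retained, 30.01 is excluded), and samples already
#' failing QC upstream.
#'
#' @param quants data.frame from [quantifyDdct()].
#' @param aluCtMax maximum acceptable ALU Ct (default 30).
#' @return list with `retained` (data.frame) and `excluded` (data.frame with
#'   an `exclusionReason` column).
#' @export
qcFilter <- function(quants, aluCtMax = 30) {
  bad <- !quants$qcPass | (!is.na(quants$aluCt) & quants$aluCt > aluCtMax)
  excluded <- quants[bad, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$exclusionReason <- ifelse(
      !excluded$qcPass, excluded$flag,
      sprintf("ALU Ct %.2f exceeds %g", excluded$aluCt, aluCtMax))
  } else {
    excluded$exclusionReason <- character(0)
  }
  list(retained = quants[!bad, , drop = FALSE], excluded = excluded)
}

#' Paired tumor-normal comparison of MethyLight values
#'
#' Pairs QC-passed tumor and normal quantifications by patient id and runs
#' the paired Wilcoxon signed-rank test with continuity correction
#' ([wilcoxonSignedRankPaired()]). Pairs lost to QC reduce the effective n
#' and are reported.
#'
#' @param quants QC-filtered quantifications (the `retained` part of
#'   [qcFilter()]), with sample ids of the form `<patient>_T` / `<patient>_N`
#'   or explicit `patientId`/`tissue` columns.
#' @param patientId,tissue optional explicit vectors aligned with `quants`.
#' @return list with `W`, `p.value`, `nEffective`, `nPairsDropped`,
#'   `droppedPatients`.
#' @export
pairedComparison <- function(quants, patientId = NULL, tissue = NULL) {
  if (is.null(patientId)) {
    patientId <- sub("_[TN]$", "", quants$sampleId)
    tissue <- ifelse(grepl("_T$", quants$sampleId), "tumor", "normal")
  }
  tum <- quants$value[tissue == "tumor"]
  names(tum) <- patientId[tissue == "tumor"]
  nor <- quants$value[tissue == "normal"]
  names(nor) <- patientId[tissue == "normal"]
  common <- intersect(names(tum), names(nor))
  dropped <- setdiff(union(names(tum), names(nor)), common)
  if (length(common) < 3L)
    stop("fewer than 3 effective tumor-normal pairs after QC")
  ht <- wilcoxonSignedRankPaired(tum[common], nor[common])
  list(W = ht$W, p.value = ht$p.value,
       nEffective = length(common) - ht$nZeroDropped,
       nPairsDropped = length(dropped), droppedPatients = dropped)
}
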