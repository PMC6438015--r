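#' @importFrom stats ppois
#' @importFrom GenomicRanges reduce findOverlaps
NULL

## Simplified re-implementation of the enrichment-peak / differential-binding
## stage: a windowed Poisson caller against the input control, union-merge
## consensus regions, and the shared NB exact test on region counts. The
## cascade logic downstream is what matters; this caller trades the
## multi-scale background model of full peak callers for transparency at
## desk scale.

#' Call enrichment peaks from windowed counts
#'
#' Per fixed-width window, a Poisson upper-tail p-value for the treatment
#' count against an expectation `max(scaled input count, global background
#' rate) + 0.5`, where the input count is scaled by the treatment/input depth
#' ratio and the global background is the mean treatment count per window.
#' Significant windows closer than `mergeGapWindows + 1` windows apart are
#' merged.
#'
#' @param windows a [RegionCountSet-class] of fixed-width tiling windows.
#' @param treatment,input column name or index of the treatment and input
#'   samples.
#' @param pThreshold per-window significance threshold (default 1e-5).
#' @param mergeGapWindows merge significant windows separated by at most this
#'   many non-significant windows (default 1).
#' @return GRanges of merged peak intervals (possibly empty), sorted.
#' @export
callPeaks <- function(windows, treatment, input, pThreshold = 1e-5,
                      mergeGapWindows = 1L) {
  stopifnot(is(windows, "RegionCountSet"))
  cnt <- assay(windows, "counts")
  if (is.character(treatment)) treatment <- match(treatment, colnames(cnt))
  if (is.character(input)) input <- match(input, colnames(cnt))
  lib <- librarySizes(windows)
  if (lib[treatment] <= 0 || lib[input] <= 0)
    stop("zero-depth library")
  w <- width(rowRanges(windows))
  if (length(unique(w)) != 1L)
    stop("callPeaks expects fixed-width windows")
  trt <- cnt[, treatment]
  depthRatio <- lib[treatment] / lib[input]
  background <- mean(trt)
  lambda <- pmax(cnt[, input] * depthRatio, background) + 0.5
  p <- ppois(trt - 1, lambda, lower.tail = FALSE)
  sig <- p < pThreshold
  if (!any(sig)) return(GRanges())
  gr <- rowRanges(windows)[sig]
  GenomicRanges::sort(reduce(gr, min.gapwidth = mergeGapWindows * w[1] + 1L,
                             ignore.strand = TRUE))
}

#' Consensus regions across per-sample peak sets
#'
#' Union of all peak intervals — a region is retained when a peak is present
#' in at least one sample — with overlapping or book-ended intervals merged.
#'
#' @param peakSets list of GRanges (one per sample; some may be empty).
#' @return sorted GRanges of merged consensus regions.
#' @export
consensusRegions <- function(peakSets) {
  if (length(peakSets) == 0L) stop("need >= 1 peak set")
  all <- do.call(c, lapply(peakSets, function(g) {
    GenomicRanges::strand(g) <- "*"
    g
  }))
  GenomicRanges::sort(reduce(all, ignore.strand = TRUE))
}

#' Sum window counts into region counts
#'
#' Aggregates a windowed [RegionCountSet-class] over a set of (consensus)
#' regions by summing the counts of all windows overlapping each region.
#'
#' @param windows a windowed [RegionCountSet-class].
#' @param regions GRanges of target regions.
#' @return a [RegionCountSet-class] over `regions` with the same samples;
#'   library sizes carried over from `windows`.
#' @export
countRegions <- function(windows, regions) {
  stopifnot(is(windows, "RegionCountSet"))
  hits <- findOverlaps(regions, rowRanges(windows), ignore.strand = TRUE)
  cnt <- assay(windows, "counts")
  agg <- matrix(0, nrow = length(regions), ncol = ncol(cnt),
                dimnames = list(NULL, colnames(cnt)))
  if (length(hits)) {
    f <- factor(queryHits(hits), levels = seq_along(regions))
    agg <- apply(cnt[subjectHits(hits), , drop = FALSE], 2, function(col)
      as.numeric(tapply(col, f, sum, default = 0)))
    if (length(regions) == 1L) agg <- matrix(agg, nrow = 1L,
                                             dimnames = list(NULL, colnames(cnt)))
  }
  regionCountSet(agg, regions, condition = sampleCondition(windows),
                 replicate = colData(windows)$replicate,
                 libSize = librarySizes(windows))
}

#' Differential methylation test on region counts
#'
#' Library-size-normalized negative-binomial exact test (the machinery of
#' [nbExactTest()]) per region, comparing a knockout condition against the
#' parental condition. Direction is `gain` when the normalized KO mean
#' exceeds the parental mean.
#'
#' @param counts a [RegionCountSet-class] over consensus regions.
#' @param koCondition,parentalCondition condition labels present in
#'   `sampleCondition(counts)`.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param dispersion passed to [nbExactTest()].
#' @return GRanges of the regions with metadata columns `log2Fc`, `p.value`,
#'   `direction`, `significant`.
#' @export
testDifferentialMethylation <- function(counts, koCondition = "KO1",
                                        parentalCondition = "parental",
                                        alpha = 0.05, dispersion = "auto") {
  stopifnot(is(counts, "RegionCountSet"))
  cond <- sampleCondition(counts)
  ko <- which(cond == koCondition)
  par <- which(cond == parentalCondition)
  if (length(ko) == 0L) stop("condition not found: ", koCondition)
  if (length(par) == 0L) stop("condition not found: ", parentalCondition)
  if (length(ko) < 2L || length(par) < 2L)
    warning("fewer than 2 replicates in a condition; ",
            "dispersion cannot be estimated reliably")
  cnt <- assay(counts, "counts")
  ## library-size normalization (capture depth, not composition, dominates
  ## region counts)
  lib <- librarySizes(counts)[c(ko, par)]
  sf <- lib / exp(mean(log(lib)))
  res <- nbExactTest(cnt[, c(ko, par), drop = FALSE],
                     group1 = seq_along(ko),
                     group2 = seq_along(par) + length(ko),
                     dispersion = dispersion, sizeFactors = sf)
  gr <- rowRanges(counts)
  mcols(gr)$log2Fc <- res$log2Fc
  mcols(gr)$p.value <- res$p.value
  mcols(gr)$direction <- ifelse(res$foldChange > 1, "gain",
                                ifelse(res$foldChange < 1, "loss", "none"))
  mcols(gr)$significant <- res$p.value < alpha & mcols(gr)$direction != "none"
  gr
}

#' Tally DMRs by direction and genomic feature
#'
#' @param dmrs GRanges of DMRs carrying `direction` and `featureClass`
#'   columns (see [testDifferentialMethylation()] and [classifyRegion()]);
#'   pass only significant records to mirror reported DMR counts.
#' @return data.frame with rows `gain`/`loss` and columns `promoter`,
#'   `gene_body`, `intergenic`, `overall`.
#' @export
tallyDmrs <- function(dmrs) {
  feats <- c("promoter", "gene_body", "intergenic")
  out <- matrix(0L, nrow = 2, ncol = 4,
                dimnames = list(c("gain", "loss"), c(feats, "overall")))
  if (length(dmrs)) {
    dir <- mcols(dmrs)$direction
    fc <- mcols(dmrs)$featureClass
    for (d in c("gain", "loss")) {
      tb <- table(factor(fc[dir == d], levels = feats))
      out[d, feats] <- as.integer(tb)
      out[d, "overall"] <- sum(tb)
    }
  }
  as.data.frame(out)
}
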