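#' @importFrom GenomicRanges findOverlaps distanceToNearest reduce sort
#'   GRanges seqnames start end strand promoters resize
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols DataFrame
NULL

## Coordinates are BED-style 0-based half-open at the interface; GRanges
## (1-based closed) internally. These two helpers are the only place the
## conversion happens.

#' Convert BED-style 0-based half-open coordinates to GRanges
#'
#' @param chrom,start,end vectors of chromosome, 0-based start, half-open end.
#' @param ... further metadata columns passed to [GenomicRanges::GRanges].
#' @param strand strand characters (`"+"`, `"-"`, `"*"`).
#' @return A `GRanges`.
#' @export
bedToGRanges <- function(chrom, start, end, strand = "*", ...) {
  if (any(end <= start)) stop("interval end must exceed start")
  if (any(start < 0)) stop("negative start coordinate")
  GRanges(chrom, IRanges(start + 1L, end), strand = strand, ...)
}

#' Convert GRanges to BED-style 0-based half-open coordinates
#'
#' @param gr a `GRanges`.
#' @return data.frame with `chrom`, `start` (0-based), `end` (half-open).
#' @export
grangesToBed <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

#' Build a gene model GRanges
#'
#' @param geneId gene identifiers.
#' @param chrom chromosome names.
#' @param start,end gene span in 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return GRanges with `geneId` and a `tss` metadata column (0-based TSS:
#'   span start on `+`, span end - 1 on `-`).
#' @export
geneModel <- function(geneId, chrom, start, end, strand) {
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  gr <- bedToGRanges(chrom, start, end, strand = strand, geneId = geneId)
  mcols(gr)$tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                          start, end - 1L)
  gr
}

#' Strand-aware promoter window around the TSS
#'
#' The promoter is defined as -1500 bp to +500 bp around the transcription
#' start site, in the direction of transcription, clipped at coordinate 0.
#' In 0-based half-open terms a plus-strand gene with TSS t gets
#' `[t - upstream, t + downstream)`; a minus-strand gene gets
#' `[t - downstream, t + upstream)`.
#'
#' @param genes gene model GRanges from [geneModel()].
#' @param upstream,downstream window extents in bp (defaults 1500 / 500).
#' @return GRanges of promoter windows, same order and `geneId` as `genes`.
#' @export
promoterOf <- function(genes, upstream = 1500L, downstream = 500L) {
  tss <- mcols(genes)$tss
  plus <- as.character(strand(genes)) == "+"
  s0 <- ifelse(plus, tss - upstream, tss - downstream)
  e0 <- ifelse(plus, tss + downstream, tss + upstream)
  s0 <- pmax(s0, 0L)
  out <- GRanges(seqnames(genes), IRanges(s0 + 1L, e0),
                 strand = strand(genes))
  mcols(out)$geneId <- mcols(genes)$geneId
  out
}

#' Classify regions against a gene model
#'
#' Assigns each region a genomic feature class with precedence
#' promoter > gene body > intergenic, and a gene: the overlapped gene
#' (nearest TSS on ties), or for intergenic regions the nearest TSS within
#' `maxDistance`, else none.
#'
#' @param regions GRanges of regions (e.g. DMRs).
#' @param genes gene model GRanges from [geneModel()].
#' @param upstream,downstream promoter window, passed to [promoterOf()].
#' @param maxDistance assignment cap for intergenic regions (bp).
#' @return the input `regions` with `featureClass` and `geneId` metadata
#'   columns added (`geneId` is `NA` when unassigned).
#' @export
classifyRegion <- function(regions, genes, upstream = 1500L,
                           downstream = 500L, maxDistance = 1e5) {
  if (length(genes) == 0L) stop("empty gene table")
  prom <- promoterOf(genes, upstream, downstream)
  n <- length(regions)
  cls <- rep("intergenic", n)
  gid <- rep(NA_character_, n)
  tss <- mcols(genes)$tss

  ## among overlapping genes, break ties by nearest TSS, then gene id;
  ## q holds region indices (global), s gene indices
  assignNearestTss <- function(q, s) {
    mid <- (start(regions)[q] + end(regions)[q]) / 2
    d <- abs(mid - (tss[s] + 1L))
    ord <- order(q, d, mcols(genes)$geneId[s])
    q <- q[ord]; s <- s[ord]
    keep <- !duplicated(q)
    list(region = q[keep], gene = s[keep])
  }

  ph <- findOverlaps(regions, prom, ignore.strand = TRUE)
  if (length(ph)) {
    a <- assignNearestTss(queryHits(ph), subjectHits(ph))
    cls[a$region] <- "promoter"
    gid[a$region] <- mcols(genes)$geneId[a$gene]
  }
  todo <- cls == "intergenic"
  bh <- findOverlaps(regions[todo], genes, ignore.strand = TRUE)
  if (length(bh)) {
    idx <- which(todo)
    a <- assignNearestTss(idx[queryHits(bh)], subjectHits(bh))
    cls[a$region] <- "gene_body"
    gid[a$region] <- mcols(genes)$geneId[a$gene]
  }
  todo <- cls == "intergenic"
  if (any(todo)) {
    tssGr <- GRanges(seqnames(genes), IRanges(tss + 1L, width = 1L))
    nh <- distanceToNearest(regions[todo], tssGr, ignore.strand = TRUE)
    ok <- mcols(nh)$distance <= maxDistance
    idx <- which(todo)[queryHits(nh)[ok]]
    gid[idx] <- mcols(genes)$geneId[subjectHits(nh)[ok]]
  }
  mcols(regions)$featureClass <- cls
  mcols(regions)$geneId <- gid
  regions
}

#' Build a probe manifest GRanges
#'
#' @param probeId probe identifiers.
#' @param chrom chromosome names.
#' @param pos 0-based single-CpG coordinates.
#' @param ... further metadata columns.
#' @return GRanges of width-1 probe positions with a `probeId` column.
#' @export
probeManifest <- function(probeId, chrom, pos, ...) {
  if (any(pos < 0)) stop("probe position must be >= 0")
  GRanges(chrom, IRanges(pos + 1L, width = 1L), probeId = probeId, ...)
}

#' Map methylation-array probes to regions by proximity
#'
#' A probe is assigned to a region when it lies inside it (gap 0) or within
#' `window` bp of its nearest edge (inclusive: a probe exactly `window` bp
#' away is assigned). The gap is the number of bases strictly between the
#' probe and the region.
#'
#' @param probes probe GRanges from [probeManifest()].
#' @param regions GRanges of regions (e.g. KO gain-DMRs).
#' @param window maximum gap in bp (default 500).
#' @return DataFrame with `probeId`, `regionIndex`, `gap` — one row per
#'   assigned probe (nearest region wins).
#' @export
mapProbesToRegions <- function(probes, regions, window = 500L) {
  if (length(probes) == 0L || length(regions) == 0L)
    return(DataFrame(probeId = character(), regionIndex = integer(),
                     gap = integer()))
  nh <- distanceToNearest(probes, regions, ignore.strand = TRUE)
  keep <- mcols(nh)$distance <= window
  DataFrame(probeId = mcols(probes)$probeId[queryHits(nh)[keep]],
            regionIndex = subjectHits(nh)[keep],
            gap = as.integer(mcols(nh)$distance[keep]))
}

#' Percent of conserved CpG sites
#'
#' Small arithmetic helper used when summarising cross-species conservation
#' of differentially methylated CpGs (e.g. 5 of 7 conserved sites = 71.4%).
#'
#' @param nConserved number of conserved sites.
#' @param nTotal total sites examined.
#' @param digits decimal places to round to (default 1).
#' @return percentage, rounded.
#' @export
percentConserved <- function(nConserved, nTotal, digits = 1) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nConserved < 0 || nConserved > nTotal)
    stop("nConserved must be in [0, nTotal]")
  round(100 * nConserved / nTotal, digits)
}
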