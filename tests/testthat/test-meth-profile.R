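makeWindows <- function(counts, width = 200L, chrom = "chr1",
                        condition = colnames(counts)) {
  n <- nrow(counts)
  starts <- (seq_len(n) - 1L) * width
  regionCountSet(counts, bedToGRanges(rep(chrom, n), starts, starts + width),
                 condition = condition)
}

test_that("per-window Poisson tail matches direct summation", {
  # treatment 20 where scaled input expectation is 5 => lambda 5.5
  # (background windows kept below 5 so the global rate does not override)
  trt <- c(rep(4L, 200), 20L)
  inp <- rep(5L, 201)
  counts <- cbind(trt = trt, input = inp)
  rcs <- makeWindows(counts, condition = c("parental", "input"))
  # force equal depths so the scaled expectation is the raw input count
  SummarizedExperiment::colData(rcs)$libSize <- c(1000, 1000)
  pOracle <- sum(dpois(20:10000, 5.5))
  expect_lt(pOracle, 1e-5)  # the example window is significant at 1e-5
  peaks <- callPeaks(rcs, "trt", "input", pThreshold = pOracle * 1.0001)
  expect_equal(length(peaks), 1L)
  expect_equal(grangesToBed(peaks)$start, 200 * 200)
  # just below the oracle p the same window is no longer called
  expect_equal(length(callPeaks(rcs, "trt", "input",
                                pThreshold = pOracle * 0.9999)), 0L)
})

test_that("treatment identical to scaled input yields no peaks", {
  counts <- cbind(trt = rep(7L, 100), input = rep(7L, 100))
  rcs <- makeWindows(counts, condition = c("parental", "input"))
  expect_equal(length(callPeaks(rcs, "trt", "input")), 0L)
  expect_error(callPeaks(makeWindows(cbind(a = 0L, b = 0L),
                                     condition = c("parental", "input")),
                         "a", "b"), "zero-depth")
})

test_that("significant windows merge across one non-significant gap", {
  trt <- rep(3L, 60); trt[c(20, 22)] <- 60L     # windows 20 and 22
  inp <- rep(3L, 60)
  counts <- cbind(trt = trt, input = inp)
  rcs <- makeWindows(counts, condition = c("parental", "input"))
  SummarizedExperiment::colData(rcs)$libSize <- c(1000, 1000)
  merged <- callPeaks(rcs, "trt", "input", mergeGapWindows = 1L)
  expect_equal(length(merged), 1L)
  expect_equal(grangesToBed(merged)$start, 19 * 200)
  expect_equal(grangesToBed(merged)$end, 22 * 200)
  unmerged <- callPeaks(rcs, "trt", "input", mergeGapWindows = 0L)
  expect_equal(length(unmerged), 2L)
  # peak output never overlaps itself and is sorted
  expect_true(all(diff(grangesToBed(merged)$start) > 0))
})

test_that("consensus regions are the union-merge across peak sets", {
  a <- bedToGRanges("chr1", 0, 100)
  b <- bedToGRanges("chr1", 50, 150)
  cons <- consensusRegions(list(a, b))
  expect_equal(grangesToBed(cons), data.frame(chrom = "chr1", start = 0,
                                              end = 150))
  # one empty set: the non-empty set survives ("at least one sample")
  cons2 <- consensusRegions(list(GRanges(), a))
  expect_equal(grangesToBed(cons2)$start, 0)
  # disjoint sets concatenate, sorted
  c2 <- bedToGRanges("chr1", c(500, 200), c(600, 300))
  cons3 <- consensusRegions(list(a, c2))
  expect_equal(grangesToBed(cons3)$start, c(0, 200, 500))
})

test_that("differential methylation has symmetric directions and null p", {
  set.seed(14)
  counts <- matrix(rpois(200, 50), 50)
  colnames(counts) <- c(paste0("KO1_", 1:2), paste0("parental_", 1:2))
  rcs <- makeWindows(counts, condition = rep(c("KO1", "parental"), each = 2))
  d1 <- testDifferentialMethylation(rcs, "KO1", "parental")
  d2 <- testDifferentialMethylation(rcs, "parental", "KO1")
  swap <- mcols(d1)$direction != "none"
  expect_true(all(mcols(d1)$direction[swap] !=
                  mcols(d2)$direction[swap]))
  expect_equal(mcols(d1)$p.value, mcols(d2)$p.value, tolerance = 1e-9)
  expect_error(testDifferentialMethylation(rcs, "KO9", "parental"),
               "KO9")
})

test_that("planted promoter gains are called with high power", {
  hits <- 0; total <- 0
  for (s in 1:6) {
    cfg <- simulationConfig(seed = 400 + s, nGenes = 60L,
                            nPlantedDrivers = 6L)
    ko <- simulateKoExperiment(cfg)
    cond <- sampleCondition(ko$methWindows)
    peaks <- lapply(which(cond != "input"), function(j)
      callPeaks(ko$methWindows, j, which(cond == "input")[1]))
    cons <- consensusRegions(peaks)
    rc <- countRegions(ko$methWindows, cons)
    dmr <- testDifferentialMethylation(rc, "KO1", "parental")
    dmr <- classifyRegion(dmr, ko$genes)
    called <- unique(mcols(dmr)$geneId[
      mcols(dmr)$significant & mcols(dmr)$direction == "gain" &
      mcols(dmr)$featureClass == "promoter"])
    hits <- hits + sum(driverGenes(ko$truth) %in% called)
    total <- total + length(driverGenes(ko$truth))
  }
  expect_gte(hits / total, 0.95)
})

test_that("DMR tallies partition and add up", {
  dmr <- bedToGRanges(rep("chr1", 6), (0:5) * 1000, (0:5) * 1000 + 100)
  mcols(dmr)$direction <- c("gain", "gain", "gain", "gain", "loss", "gain")
  mcols(dmr)$featureClass <- c("promoter", "promoter", "promoter",
                               "gene_body", "gene_body", "intergenic")
  tl <- tallyDmrs(dmr)
  expect_equal(tl["gain", "promoter"], 3L)
  expect_equal(tl["gain", "gene_body"], 1L)
  expect_equal(tl["gain", "overall"], 5L)
  expect_equal(tl["loss", "overall"], 1L)
  expect_equal(sum(tl[, "overall"]), length(dmr))
  empty <- tallyDmrs(GRanges())
  expect_true(all(empty == 0))
})

test_that("null differential-methylation p-values are uniform", {
  # counts at consensus-region scale (~150/sample), where the conditional
  # exact test's support is dense enough for uniformity
  withr::with_seed(31, {
    counts <- cbind(matrix(rcounts(2000, 150, 0.01), 1000),
                    matrix(rcounts(2000, 150, 0.01), 1000))
  })
  colnames(counts) <- c("KO1_1", "KO1_2", "parental_1", "parental_2")
  rcs <- makeWindows(counts, condition = c("KO1", "KO1", "parental",
                                           "parental"))
  d <- testDifferentialMethylation(rcs, "KO1", "parental")
  ks <- suppressWarnings(ks.test(mcols(d)$p.value, "punif"))
  expect_gt(ks$p.value, 0.01)
})
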