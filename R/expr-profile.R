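#' @importFrom stats dnbinom dbinom median var
NULL

#' Filter to expressed genes
#'
#' Keeps genes whose counts-per-million reach `minCpm` in at least
#' `minSamples` samples (both thresholds inclusive).
#'
#' @param counts gene x sample matrix of non-negative integer counts.
#' @param minCpm minimum counts-per-million (default 1).
#' @param minSamples minimum number of samples meeting `minCpm` (default 2).
#' @return character vector of retained gene ids (rownames), or row indices
#'   when `counts` has no rownames.
#' @export
filterExpressed <- function(counts, minCpm = 1, minSamples = 2) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  cpm <- t(t(counts) / lib) * 1e6
  keep <- rowSums(cpm >= minCpm) >= minSamples
  if (!is.null(rownames(counts))) rownames(counts)[keep] else which(keep)
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors computed as the median across genes of the ratio
#' of each count to the gene's geometric mean, using only genes with all
#' counts positive. Falls back to library-size ratios when no gene qualifies.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    lg <- log(counts[pos, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- apply(exp(lg - geo), 2, median)
  } else {
    lib <- colSums(counts)
    sf <- lib / exp(mean(log(lib)))
  }
  sf / exp(mean(log(sf)))
}

## Conditional two-sided exact NB test on group totals.
## s1 ~ NB(mu = n1*mu0, size = n1/phi), s2 ~ NB(mu = n2*mu0, size = n2/phi);
## conditioning on s1 + s2 = t, the two-sided p sums all splits whose
## conditional probability does not exceed that of the observed split.
## phi = 0 degenerates to Binomial(t, n1/(n1+n2)).
nbConditionalP <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  s <- 0:t
  if (phi <= 0) {
    lp <- dbinom(s, t, n1 / (n1 + n2), log = TRUE)
  } else {
    mu0 <- t / (n1 + n2)
    lp <- dnbinom(s, size = n1 / phi, mu = n1 * mu0, log = TRUE) +
      dnbinom(t - s, size = n2 / phi, mu = n2 * mu0, log = TRUE)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  pObs <- lp[s1 + 1]
  min(1, sum(exp(lp[lp <= pObs + 1e-12])))
}

#' Two-group negative-binomial exact test on counts
#'
#' The differential test used for both expression and region methylation
#' counts: median-of-ratios size-factor normalization, a common
#' method-of-moments dispersion (floored at 0), and a conditional exact test
#' on the group sums of the normalized (equalized) pseudo-counts. Two-sided
#' p-values sum the conditional probabilities not exceeding that of the
#' observed split, capped at 1. In the dispersion-0 limit the test is the
#' exact conditional binomial test.
#'
#' @param counts gene (or region) x sample non-negative integer matrix.
#' @param group1,group2 column indices or names for the two conditions
#'   (group1 is the numerator of the fold change, e.g. KO).
#' @param dispersion `"auto"` (method of moments) or a fixed value >= 0.
#' @param sizeFactors optional per-sample size factors for all columns of
#'   `counts`; computed by [sizeFactorsMedianRatio()] when `NULL`.
#' @return data.frame with `geneId`, `foldChange` (group1/group2 on the
#'   normalized scale; 1 with `allZero = TRUE` for all-zero rows), `log2Fc`,
#'   `p.value`, `allZero`; the dispersion used is attached as attribute
#'   `dispersion`.
#' @export
nbExactTest <- function(counts, group1, group2, dispersion = "auto",
                        sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (is.character(group1)) group1 <- match(group1, colnames(counts))
  if (is.character(group2)) group2 <- match(group2, colnames(counts))
  if (length(group1) < 1L || length(group2) < 1L || anyNA(c(group1, group2)))
    stop("each condition needs >= 1 sample present in the count matrix")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(counts)
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  norm <- t(t(counts) / sizeFactors)
  n1 <- length(group1); n2 <- length(group2)
  if (identical(dispersion, "auto")) {
    z <- norm[, c(group1, group2), drop = FALSE]
    g <- rep(1:2, c(n1, n2))
    m <- rowMeans(z)
    ## pooled within-condition variance so planted differences do not
    ## inflate the dispersion estimate
    vw <- rep(0, nrow(z))
    for (gi in 1:2) {
      zi <- z[, g == gi, drop = FALSE]
      if (ncol(zi) >= 2)
        vw <- vw + apply(zi, 1, var) * (ncol(zi) - 1)
    }
    dfW <- max(1, (n1 - 1) + (n2 - 1))
    vw <- vw / dfW
    ok <- m > 0
    ## weighted moment estimator, floored after pooling so that sampling
    ## noise at n = 2 does not bias the estimate upward
    phi <- if ((n1 > 1 || n2 > 1) && any(ok))
      max(0, sum(vw[ok] - m[ok]) / sum(m[ok]^2)) else 0
  } else {
    phi <- as.numeric(dispersion)
    if (phi < 0) stop("dispersion must be >= 0")
  }
  s1 <- round(rowSums(norm[, group1, drop = FALSE]))
  s2 <- round(rowSums(norm[, group2, drop = FALSE]))
  m1 <- rowMeans(norm[, group1, drop = FALSE])
  m2 <- rowMeans(norm[, group2, drop = FALSE])
  allZero <- (s1 + s2) == 0
  fc <- ifelse(allZero, 1, m1 / m2)
  p <- vapply(seq_along(s1), function(i)
    nbConditionalP(s1[i], s2[i], n1, n2, phi), numeric(1))
  out <- data.frame(
    geneId = rownames(counts) %||% as.character(seq_along(s1)),
    foldChange = fc, log2Fc = log2(fc), p.value = p,
    allZero = allZero, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  out
}

#' Classify differential-expression results
#'
#' Deterministic thresholding into `down`, `up` and `ns`. The default scheme
#' is the 1.5-fold rule (down when FC < 1/1.5, up when FC > 1.5, both with
#' p < alpha); the candidate cascade instead uses the one-sided scheme
#' FC < 0.75 for its down-call, available via `downFc = 0.75, upFc = Inf`.
#'
#' @param results data.frame from [nbExactTest()].
#' @param alpha significance level (default 0.05).
#' @param downFc upper fold-change bound for a down call (default 1/1.5).
#' @param upFc lower fold-change bound for an up call (default 1.5).
#' @return `results` with a `status` factor column added.
#' @export
classifyDe <- function(results, alpha = 0.05, downFc = 1 / 1.5, upFc = 1.5) {
  status <- rep("ns", nrow(results))
  sig <- results$p.value < alpha
  status[sig & results$foldChange < downFc] <- "down"
  status[sig & results$foldChange > upFc] <- "up"
  results$status <- factor(status, levels = c("down", "ns", "up"))
  results
}
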