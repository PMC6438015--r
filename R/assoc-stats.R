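#' @importFrom stats wilcox.test kruskal.test pnorm pchisq p.adjust
NULL

## Rank-based statistics used throughout the cascade. Exact modes are only
## engaged at enumeration scale (combined n <= 12, no ties); the cohort-sized
## comparisons always take the tie- and continuity-corrected normal
## approximation, as the original analyses did.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. With `mode = "auto"` the exact null distribution
#' is used when the combined sample size is at most 12 and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction. `U` is reported for `x` (number of (x, y) pairs with x > y,
#' ties counted 1/2).
#'
#' @param x,y numeric vectors, each non-empty.
#' @param mode `"auto"`, `"exact"` or `"approximate"`. `"exact"` with ties
#'   present is an error.
#' @return list with `U`, `p.value`, `method`.
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
    auto = (length(x) + length(y)) <= 12L && !ties,
    exact = if (ties)
      stop("exact mode is undefined with ties; use mode = 'approximate'")
      else TRUE,
    approximate = FALSE)
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p.value = unname(ht$p.value),
       method = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom. When every value is identical the statistic is defined as 0 with
#' p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @return list with `H`, `p.value`, `df`.
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  vals <- unlist(groups, use.names = FALSE)
  if (length(vals) < 3L) stop("need total n >= 3")
  if (length(unique(vals)) == 1L)
    return(list(H = 0, p.value = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- kruskal.test(vals, g)
  list(H = unname(ht$statistic), p.value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Dunn post-hoc test after Kruskal-Wallis
#'
#' Pairwise mean-rank comparisons on the joint ranking, with the usual tie
#' correction:
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' Two-sided normal p-values, Bonferroni-adjusted across the pairs
#' (capped at 1).
#'
#' @param groups named list of numeric vectors; all sizes >= 1.
#' @param adjust only `"bonferroni"` is supported (the method the pipeline
#'   uses throughout).
#' @return data.frame with `group1`, `group2`, `z`, `p.raw`, `p.adjusted`.
#' @export
dunnPosthoc <- function(groups, adjust = "bonferroni") {
  adjust <- match.arg(adjust, "bonferroni")
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  vals <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(vals)
  N <- length(vals)
  tieTab <- table(vals)
  tieTerm <- sum(tieTab^3 - tieTab) / (12 * (N - 1))
  varCore <- N * (N + 1) / 12 - tieTerm
  meanRank <- tapply(r, g, mean)[names(groups)]
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(varCore * (1 / n[i1] + 1 / n[i2]))
    z[j] <- if (se > 0) (meanRank[i1] - meanRank[i2]) / se else 0
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = z, p.raw = p,
             p.adjusted = pmin(1, p * ncol(pairs)),
             stringsAsFactors = FALSE)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences with continuity
#' correction in the normal approximation. Zero differences are dropped and
#' counted; the exact null distribution is used when the effective number of
#' pairs is at most 12 and the absolute differences are untied.
#'
#' @param x,y equal-length paired vectors (e.g. tumor and matched normal).
#' @param continuity apply the continuity correction in the approximate mode.
#' @return list with `W`, `p.value`, `nEffective`, `nZeroDropped`, `method`.
#' @export
wilcoxonSignedRankPaired <- function(x, y, continuity = TRUE) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  nz <- d != 0
  nZero <- sum(!nz)
  d <- d[nz]
  if (length(d) == 0L)
    stop("all paired differences are zero; the signed-rank test is undefined")
  exact <- length(d) <= 12L && anyDuplicated(abs(d)) == 0L
  ht <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = continuity))
  list(W = unname(ht$statistic), p.value = unname(ht$p.value),
       nEffective = length(d), nZeroDropped = nZero,
       method = if (exact) "exact" else "normal approximation")
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param mTests number of tests in the family (>= 1).
#' @return per-test threshold `alpha / mTests`.
#' @examples
#' bonferroniThreshold(0.05, 4192)  # 1.193e-05
#' @export
bonferroniThreshold <- function(alpha = 0.05, mTests) {
  if (mTests < 1) stop("mTests must be >= 1")
  alpha / mTests
}

#' Map a Gleason primary + secondary pattern to a grade group label
#'
#' Two schemes are used in the pipeline: the expression scheme collapses
#' Gleason 7 (`GS6`, `GS7`, `GS8+`) while the methylation scheme separates
#' 3+4 (`GS7a`) from 4+3 (`GS7b`) and admits a `normal` label for benign
#' samples.
#'
#' @param primary,secondary Gleason pattern components, each in 3..5 (or `NA`
#'   with `tissue = "normal"` under the `meth` scheme).
#' @param scheme `"expr"` (GS6/GS7/GS8+) or `"meth"`
#'   (GS6/GS7a/GS7b/GS8+/normal).
#' @param tissue `"tumor"` or `"normal"`; normals are only representable in
#'   the `meth` scheme.
#' @return group label string.
#' @export
gleasonGroup <- function(primary, secondary, scheme = c("expr", "meth"),
                         tissue = "tumor") {
  scheme <- match.arg(scheme)
  if (tissue == "normal") {
    if (scheme != "meth") stop("normals only belong to the 'meth' scheme")
    return("normal")
  }
  if (!(primary %in% 3:5 && secondary %in% 3:5))
    stop("invalid Gleason pattern: ", primary, "+", secondary)
  total <- primary + secondary
  if (total >= 8) return("GS8+")
  if (total == 6) return("GS6")
  ## total == 7
  if (scheme == "expr") return("GS7")
  if (primary == 3) "GS7a" else "GS7b"
}

#' Batch clinicopathological association runner
#'
#' For each marker (a row of `values`: gene expression or probe beta across
#' cohort samples) this runs the comparisons of the clinical association
#' tables: matched tumor vs normal and all tumors vs normal (Mann-Whitney),
#' recurrence, binary stage group (Mann-Whitney), Gleason overall
#' (Kruskal-Wallis) and Bonferroni-adjusted Dunn contrasts between Gleason
#' groups. Dunn contrasts are reported as `NA` when the Kruskal-Wallis test
#' is not significant at `alpha`, mirroring the convention of reporting the
#' post hoc only under a significant omnibus.
#'
#' @param values marker x sample matrix; columns named by sample id.
#' @param cohort a [CohortData-class] providing the clinical table.
#' @param scheme Gleason scheme for grouping, see [gleasonGroup()].
#' @param alpha omnibus significance gate for the Dunn contrasts.
#' @return data.frame, one row per marker, one column per comparison.
#' @export
associationTable <- function(values, cohort, scheme = c("expr", "meth"),
                             alpha = 0.05) {
  scheme <- match.arg(scheme)
  cl <- as.data.frame(cohortClinical(cohort))
  values <- as.matrix(values)
  tum <- cl[cl$tissue == "tumor", , drop = FALSE]
  nor <- cl[cl$tissue == "normal", , drop = FALSE]
  matchedT <- tum$sampleId[!is.na(tum$matchedPairId)]
  matchedN <- nor$sampleId[match(tum$matchedPairId[!is.na(tum$matchedPairId)],
                                 nor$matchedPairId)]
  gg <- vapply(seq_len(nrow(tum)), function(i)
    gleasonGroup(tum$gleasonPrimary[i], tum$gleasonSecondary[i],
                 scheme = scheme), character(1))
  if (scheme == "meth")
    gg <- c(gg, rep("normal", nrow(nor)))
  ggSamples <- if (scheme == "meth") c(tum$sampleId, nor$sampleId) else
    tum$sampleId

  oneMarker <- function(v) {
    pick <- function(ids) v[match(ids, colnames(values))]
    res <- list()
    res$p.matched <- if (length(matchedT) >= 1)
      mannWhitneyU(pick(matchedT), pick(matchedN))$p.value else NA_real_
    res$p.allTumors <- mannWhitneyU(pick(tum$sampleId),
                                    pick(nor$sampleId))$p.value
    rec <- tum$recurrence
    res$p.recurrence <- if (all(c("yes", "no") %in% rec))
      mannWhitneyU(pick(tum$sampleId[rec == "yes"]),
                   pick(tum$sampleId[rec == "no"]))$p.value else NA_real_
    st <- tum$stageGroup
    res$p.stage <- if (length(unique(stats::na.omit(st))) == 2) {
      lv <- sort(unique(stats::na.omit(st)))
      mannWhitneyU(pick(tum$sampleId[!is.na(st) & st == lv[1]]),
                   pick(tum$sampleId[!is.na(st) & st == lv[2]]))$p.value
    } else NA_real_
    grp <- split(pick(ggSamples), gg)
    grp <- grp[lengths(grp) > 0]
    if (length(grp) >= 2) {
      kw <- kruskalWallis(grp)
      res$p.gleasonKW <- kw$p.value
      dn <- dunnPosthoc(grp)
      for (j in seq_len(nrow(dn))) {
        nm <- paste0("p.dunn.", dn$group1[j], ".vs.", dn$group2[j])
        res[[nm]] <- if (kw$p.value < alpha) dn$p.adjusted[j] else NA_real_
      }
    } else {
      res$p.gleasonKW <- NA_real_
    }
    res
  }

  rows <- lapply(seq_len(nrow(values)), function(i) oneMarker(values[i, ]))
  cols <- unique(unlist(lapply(rows, names)))
  out <- data.frame(marker = rownames(values) %||% as.character(seq_along(rows)),
                    stringsAsFactors = FALSE)
  for (cn in cols)
    out[[cn]] <- vapply(rows, function(r) r[[cn]] %||% NA_real_, numeric(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
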