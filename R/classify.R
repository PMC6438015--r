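#' @importFrom stats glm binomial coef qnorm
NULL

#' ROC AUC with DeLong confidence interval
#'
#' AUC computed by the rank (concordant-pair) formulation with half credit
#' for ties, oriented so that higher scores indicate the positive class.
#' The 95% confidence interval uses the DeLong placement variance, truncated
#' to [0, 1].
#'
#' @param scores numeric marker values.
#' @param labels logical or 0/1 vector; `TRUE`/1 is the positive class
#'   (tumor).
#' @return list with `auc`, `ci95` (length-2), `varAuc`, `n1`, `n0`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]
  n1 <- length(x); n0 <- length(y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ## placements: V10[i] = fraction of negatives below positive i (ties 1/2)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  auc <- mean(v10)
  varAuc <- if (n1 > 1 && n0 > 1)
    stats::var(v10) / n1 + stats::var(v01) / n0 else NA_real_
  half <- if (is.na(varAuc)) NA_real_ else qnorm(0.975) * sqrt(varAuc)
  ci <- c(max(0, auc - half), min(1, auc + half))
  list(auc = auc, ci95 = ci, varAuc = varAuc, n1 = n1, n0 = n0)
}

#' Optimal ROC cutoff maximizing sensitivity + specificity
#'
#' Scans every midpoint between adjacent distinct scores and returns the
#' cutoff maximizing Youden's J = sensitivity + specificity - 1. The marker
#' direction (whether high or low scores indicate the positive class) is
#' auto-detected from the AUC side and reported. Ties on J are broken toward
#' higher specificity, then toward the lower cutoff.
#'
#' @param scores numeric marker values.
#' @param labels logical or 0/1; `TRUE`/1 is the positive class.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `direction`
#'   (`"high"` when scores above the cutoff call the positive class).
#' @export
optimalCutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(scores)) < 2L)
    stop("constant scores: no informative cutoff")
  direction <- if (rocAuc(scores, labels)$auc >= 0.5) "high" else "low"
  s <- sort(unique(scores))
  cuts <- (s[-1] + s[-length(s)]) / 2
  best <- NULL
  for (ct in cuts) {
    pos <- if (direction == "high") scores > ct else scores < ct
    sens <- mean(pos[labels])
    spec <- mean(!pos[!labels])
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && ct < best$cutoff)))) {
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec,
                   j = j)
    }
  }
  list(cutoff = best$cutoff, sensitivity = best$sensitivity,
       specificity = best$specificity, direction = direction)
}

#' Beta to M-value (logistic) transform
#'
#' `M = log2(beta / (1 - beta))` with epsilon clipping to keep the transform
#' finite at the boundaries.
#'
#' @param beta values in [0, 1].
#' @param epsilon clipping bound (default 1e-6).
#' @return M-values; clipped inputs are flagged via the `clipped` attribute.
#' @export
mValue <- function(beta, epsilon = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  attr(m, "clipped") <- which(beta < epsilon | beta > 1 - epsilon)
  m
}

#' Logistic regression with Wald tests and odds ratios
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' the binomial GLM machinery) with per-coefficient Wald p-values, odds
#' ratios and 95% CIs (`exp(coef +/- 1.96 SE)`). Non-convergence and
#' (quasi-)separation are detected and reported in the result rather than
#' silently returned.
#'
#' @param x predictor matrix (no intercept column; one is added).
#' @param y response, logical or 0/1.
#' @param maxIter,tol IRLS iteration controls.
#' @return list with `coef`, `se`, `wald.p`, `oddsRatio`, `orCi95` (matrix),
#'   `converged`, `separation`, `logLik`.
#' @export
logisticFit <- function(x, y, maxIter = 50L, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(as.logical(y))
  if (nrow(x) != length(y)) stop("x and y dimensions disagree")
  if (nrow(x) <= ncol(x) + 1L) stop("need n > number of parameters")
  constCol <- apply(x, 2, function(c) length(unique(c)) == 1L)
  if (any(constCol))
    stop("constant predictor column(s): ",
         paste(colnames(x)[constCol], collapse = ", "))
  fit <- suppressWarnings(
    glm(y ~ x, family = binomial(),
        control = list(maxit = maxIter, epsilon = tol)))
  sm <- summary(fit)
  cf <- coef(sm)
  mu <- fitted(fit)
  separation <- any(mu > 1 - 1e-8 | mu < 1e-8) ||
    any(abs(coef(fit)[-1]) > 15 / max(apply(x, 2, stats::sd)))
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  orCi <- cbind(lo = exp(est - qnorm(0.975) * se),
                hi = exp(est + qnorm(0.975) * se))
  nm <- c("(Intercept)", colnames(x) %||% paste0("x", seq_len(ncol(x))))
  names(est) <- names(se) <- rownames(orCi) <- nm
  list(coef = est, se = se, wald.p = unname(cf[, 4]),
       oddsRatio = exp(est), orCi95 = orCi,
       converged = fit$converged, separation = separation,
       logLik = as.numeric(stats::logLik(fit)))
}

#' Tumor-vs-normal classification suite over a marker panel
#'
#' For each expression marker (gene) and each methylation probe (as
#' M-values), computes ROC AUC with DeLong CI, the optimal cutoff with
#' sensitivity and specificity, and a univariate logistic fit; then one
#' joint multivariate logistic fit across all panel members of each type.
#' Probes with all-missing betas are skipped and logged.
#'
#' @param cohort a [CohortData-class].
#' @param genes character vector of panel gene ids (may be empty).
#' @param probeIds character vector of panel probe ids (may be empty).
#' @return list with data.frames `expression` and `probes` (per-marker rows:
#'   sens, spec, AUC + CI, univariate p/OR/CI, multivariate p/OR/CI),
#'   the multivariate fits, and `skipped` (probe ids with no data).
#' @export
runClassificationSuite <- function(cohort, genes = character(),
                                   probeIds = character()) {
  cl <- as.data.frame(cohortClinical(cohort))
  labels <- cl$tissue == "tumor"
  samples <- cl$sampleId

  buildTable <- function(markerMat) {
    ## markerMat: marker x sample, aligned to `samples`
    keep <- rowSums(is.finite(markerMat)) > 0
    skipped <- rownames(markerMat)[!keep]
    markerMat <- markerMat[keep, , drop = FALSE]
    rows <- lapply(rownames(markerMat), function(mk) {
      v <- markerMat[mk, ]
      ok <- is.finite(v)
      roc <- rocAuc(v[ok], labels[ok])
      if (roc$auc < 0.5) {
        ## report the classifier's AUC: orient the marker so tumors score
        ## high (markers lost in tumors discriminate by low values)
        roc <- rocAuc(-v[ok], labels[ok])
      }
      cut <- optimalCutoff(v[ok], labels[ok])
      uni <- logisticFit(matrix(v[ok], ncol = 1,
                                dimnames = list(NULL, mk)), labels[ok])
      data.frame(marker = mk, auc = roc$auc,
                 aucLo = roc$ci95[1], aucHi = roc$ci95[2],
                 cutoff = cut$cutoff, sensitivity = cut$sensitivity,
                 specificity = cut$specificity,
                 uniP = uni$wald.p[2], uniOr = uni$oddsRatio[2],
                 uniOrLo = uni$orCi95[2, "lo"], uniOrHi = uni$orCi95[2, "hi"],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    multi <- NULL
    if (nrow(markerMat) >= 2) {
      X <- t(markerMat)
      ok <- stats::complete.cases(X) & apply(is.finite(X), 1, all)
      multi <- tryCatch(logisticFit(X[ok, , drop = FALSE], labels[ok]),
                        error = function(e) NULL)
      if (!is.null(multi) && !is.null(tab)) {
        idx <- match(tab$marker, names(multi$coef))
        tab$multiP <- multi$wald.p[idx]
        tab$multiOr <- multi$oddsRatio[idx]
        tab$multiOrLo <- multi$orCi95[idx, "lo"]
        tab$multiOrHi <- multi$orCi95[idx, "hi"]
      }
    }
    list(table = tab, multi = multi, skipped = skipped)
  }

  exprOut <- list(table = NULL, multi = NULL, skipped = character())
  if (length(genes)) {
    em <- cohortExpr(cohort)[intersect(genes, rownames(cohortExpr(cohort))),
                             samples, drop = FALSE]
    exprOut <- buildTable(em)
  }
  probeOut <- list(table = NULL, multi = NULL, skipped = character())
  if (length(probeIds)) {
    pm <- cohortBetas(cohort)
    rownames(pm) <- mcols(cohortProbes(cohort))$probeId
    pm <- pm[intersect(probeIds, rownames(pm)), samples, drop = FALSE]
    mm <- apply(pm, c(1, 2), function(b) if (is.na(b)) NA_real_ else mValue(b))
    probeOut <- buildTable(mm)
  }
  list(expression = exprOut$table, probes = probeOut$table,
       multivariateExpression = exprOut$multi,
       multivariateProbes = probeOut$multi,
       skipped = c(exprOut$skipped, probeOut$skipped))
}
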