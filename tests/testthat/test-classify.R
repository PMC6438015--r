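test_that("AUC matches all-pairs counting and flips with labels", {
  expect_equal(rocAuc(c(3, 2.6, 2, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    scores <- round(rnorm(n), 1)   # rounding induces ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    a <- rocAuc(scores, labels)$auc
    expect_equal(a, pairAuc(scores, labels), tolerance = 1e-12)
    expect_equal(rocAuc(scores, 1 - labels)$auc, 1 - a, tolerance = 1e-12)
  }
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong variance agrees with pROC and with a bootstrap", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- c(rnorm(60, 1), rnorm(60))
  labels <- rep(c(1, 0), each = 60)
  res <- rocAuc(scores, labels)
  ci <- suppressMessages(pROC::ci.auc(labels, scores, method = "delong"))
  expect_equal(res$auc, as.numeric(pROC::auc(labels, scores)),
               tolerance = 1e-10)
  expect_equal(res$ci95[1], ci[1], tolerance = 1e-6)
  expect_equal(res$ci95[2], ci[3], tolerance = 1e-6)

  boot <- replicate(2000, {
    i <- sample(which(labels == 1), replace = TRUE)
    j <- sample(which(labels == 0), replace = TRUE)
    rocAuc(c(scores[i], scores[j]), c(labels[i], labels[j]))$auc
  })
  expect_lt(abs(var(boot) - res$varAuc) / res$varAuc, 0.2)
})

test_that("optimal cutoff maximizes Youden J with documented tie-breaks", {
  res <- optimalCutoff(c(3, 2.6, 2, 0), c(1, 1, 0, 0))
  expect_equal(res$cutoff, 2.3)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$direction, "high")

  # anti-informative marker: direction flips before the search
  res2 <- optimalCutoff(c(0, 1, 2, 3), c(1, 1, 0, 0))
  expect_equal(res2$direction, "low")
  expect_equal(res2$sensitivity, 1)
  expect_equal(res2$specificity, 1)

  # exhaustive check of the maximization on random fixtures
  set.seed(4)
  for (rep in 1:10) {
    scores <- rnorm(30)
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    res <- optimalCutoff(scores, labels)
    s <- sort(unique(scores))
    jAll <- vapply((s[-1] + s[-length(s)]) / 2, function(ct) {
      pos <- if (res$direction == "high") scores > ct else scores < ct
      mean(pos[labels == 1]) + mean(!pos[labels == 0]) - 1
    }, numeric(1))
    expect_equal(res$sensitivity + res$specificity - 1, max(jAll),
                 tolerance = 1e-12)
  }
  expect_error(optimalCutoff(rep(1, 6), c(1, 1, 1, 0, 0, 0)), "constant")
})

test_that("M-value transform is the clipped base-2 logit", {
  expect_equal(mValue(0.5), 0, ignore_attr = TRUE)
  expect_equal(mValue(0.8), 2, ignore_attr = TRUE)
  eps <- 1e-6
  m0 <- mValue(0)
  expect_equal(as.numeric(m0), log2(eps / (1 - eps)))
  expect_equal(attr(m0, "clipped"), 1L)
  expect_error(mValue(1.2), "beta")
})

test_that("logistic fit matches brute-force likelihood maximization", {
  x <- c(-2, -1, 0, 0.5, 1, 2, 3, -1.5)
  y <- c(0, 0, 1, 0, 1, 1, 1, 0)
  fit <- logisticFit(matrix(x, ncol = 1, dimnames = list(NULL, "m")), y)
  nll <- function(b) -sum(y * (b[1] + b[2] * x) -
                          log1p(exp(b[1] + b[2] * x)))
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coef), opt$par, tolerance = 1e-6)
  expect_equal(fit$logLik, -opt$value, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_false(fit$separation)
  # odds-ratio CI brackets the odds ratio
  expect_true(all(fit$orCi95[, "lo"] <= fit$oddsRatio &
                  fit$oddsRatio <= fit$orCi95[, "hi"]))
})

test_that("uncorrelated predictors give matching uni/multivariate fits", {
  # orthogonal balanced design: univariate and joint coefficients agree
  set.seed(6)
  n <- 200
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  eta <- 0.8 * x1 - 0.5 * x2
  y <- rbinom(n, 1, plogis(eta))
  X <- cbind(a = x1, b = x2)
  multi <- logisticFit(X, y)
  uni1 <- logisticFit(X[, "a", drop = FALSE], y)
  uni2 <- logisticFit(X[, "b", drop = FALSE], y)
  expect_equal(unname(multi$coef["a"]), unname(uni1$coef["a"]),
               tolerance = 0.15)
  expect_equal(unname(multi$coef["b"]), unname(uni2$coef["b"]),
               tolerance = 0.15)
})

test_that("perfect separation is flagged, constant columns rejected", {
  x <- matrix(c(1, 2, 3, 10, 11, 12, 13), ncol = 1,
              dimnames = list(NULL, "m"))
  y <- c(0, 0, 0, 1, 1, 1, 1)
  fit <- logisticFit(x, y)
  expect_true(fit$separation)
  expect_error(logisticFit(matrix(1, 10, 1), rep(c(0, 1), 5)), "constant")
})

test_that("the classification suite covers panel genes and probes", {
  cfg <- smallConfig()
  ko <- simulateKoExperiment(cfg)
  cohort <- simulateCohort(cfg, ko$truth, ko$genes)
  dr <- driverGenes(ko$truth)[1:4]
  pr <- mcols(cohortProbes(cohort))
  probeIds <- pr$probeId[pr$geneId %in% dr][1:4]
  suite <- runClassificationSuite(cohort, genes = dr, probeIds = probeIds)
  expect_equal(sort(suite$expression$marker), sort(dr))
  expect_equal(sort(suite$probes$marker), sort(probeIds))
  # planted drivers discriminate in the expected direction
  expect_true(all(suite$expression$auc > 0.5))
  expect_true(all(suite$probes$auc > 0.5))
  expect_true(all(c("multiP", "multiOr") %in% colnames(suite$expression)))
  # empty panel: empty tables
  empty <- runClassificationSuite(cohort)
  expect_null(empty$expression)
  expect_null(empty$probes)
})
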