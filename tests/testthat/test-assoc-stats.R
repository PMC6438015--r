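test_that("exact Mann-Whitney matches exhaustive enumeration", {
  res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p.value, 0.1)

  set.seed(7)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    repeat {
      x <- round(rnorm(n1), 3); y <- round(rnorm(n2), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    res <- mannWhitneyU(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p.value, enumMwuP(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles ties and degenerate inputs per contract", {
  x <- c(1, 1, 2, 3)
  expect_error(mannWhitneyU(x, x, mode = "exact"), "ties")
  expect_gte(mannWhitneyU(x, x)$p.value, 0.99)
  expect_error(mannWhitneyU(numeric(0), 1:3), "empty")
})

test_that("Kruskal-Wallis matches hand evaluation and the two-group identity", {
  # groups [1,2],[3,4],[5,6]: mean ranks 1.5/3.5/5.5
  # H = 12/(6*7) * 2*((1.5-3.5)^2 + 0 + (5.5-3.5)^2) = 32/7
  kw <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 2)

  expect_equal(kruskalWallis(list(c(2, 2), c(2, 2)))$p.value, 1)

  # two groups, no ties: H equals z^2 of the uncorrected normal-approx MWU
  set.seed(9)
  x <- rnorm(8); y <- rnorm(9)
  kw2 <- kruskalWallis(list(x, y))
  n1 <- 8; n2 <- 9
  u <- sum(outer(x, y, ">"))
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(kw2$H, z^2, tolerance = 1e-10)
})

test_that("Dunn post hoc reproduces the rank formula with Bonferroni cap", {
  dn <- dunnPosthoc(list(g1 = c(1, 2), g2 = c(3, 4), g3 = c(5, 6)))
  row <- dn[dn$group1 == "g1" & dn$group2 == "g3", ]
  expect_equal(abs(row$z), 4 / sqrt(3.5), tolerance = 1e-12)
  expect_equal(row$p.raw, 2 * pnorm(-4 / sqrt(3.5)), tolerance = 1e-12)
  expect_equal(row$p.adjusted, 3 * row$p.raw, tolerance = 1e-12)
  expect_true(all(dn$p.adjusted <= 1))

  # identical groups: z = 0, adjusted p capped at 1
  dn0 <- dunnPosthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(dn0$z, 0)
  expect_equal(dn0$p.adjusted, 1)

  # monotone: adjusted p non-decreasing in raw p within the family
  set.seed(3)
  dn2 <- dunnPosthoc(split(rnorm(40), rep(1:4, 10)))
  expect_true(all(diff(dn2$p.adjusted[order(dn2$p.raw)]) >= -1e-12))
})

test_that("paired signed-rank test matches sign-pattern enumeration", {
  res <- wilcoxonSignedRankPaired(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$p.value, 0.25)
  expect_equal(res$method, "exact")

  set.seed(5)
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    repeat {
      d <- round(rnorm(n), 3)
      if (!anyDuplicated(abs(d)) && all(d != 0)) break
    }
    res <- wilcoxonSignedRankPaired(d, rep(0, n))
    expect_equal(res$p.value, enumSignedRankP(d), tolerance = 1e-12)
  }

  # antisymmetric differences
  expect_equal(wilcoxonSignedRankPaired(c(0, 2), c(1, 1))$p.value, 1)
  # zero differences dropped and recorded; all-zero errors
  res <- wilcoxonSignedRankPaired(c(1, 2, 3, 5), c(1, 1, 1, 5))
  expect_equal(res$nEffective, 2)
  expect_equal(res$nZeroDropped, 2)
  expect_error(wilcoxonSignedRankPaired(1:3, 1:3), "zero")
})

test_that("Bonferroni thresholds reproduce the published cutoffs", {
  expect_equal(signif(bonferroniThreshold(0.05, 4192), 4), 1.193e-5)
  expect_equal(signif(bonferroniThreshold(0.05, 118), 5), 4.2373e-4)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_error(bonferroniThreshold(0.05, 0), "mTests")
})

test_that("Gleason grouping distinguishes 3+4 from 4+3 and schemes differ", {
  expect_equal(gleasonGroup(3, 4, "meth"), "GS7a")
  expect_equal(gleasonGroup(4, 3, "meth"), "GS7b")
  expect_equal(gleasonGroup(3, 4, "expr"), "GS7")
  expect_equal(gleasonGroup(3, 3, "expr"), "GS6")
  expect_equal(gleasonGroup(4, 4, "expr"), "GS8+")
  expect_equal(gleasonGroup(4, 5, "meth"), "GS8+")
  expect_equal(gleasonGroup(NA, NA, "meth", tissue = "normal"), "normal")
  expect_error(gleasonGroup(NA, NA, "expr", tissue = "normal"), "meth")
  expect_error(gleasonGroup(2, 3, "expr"), "invalid")
})

test_that("the association runner produces the table-shaped output", {
  cfg <- smallConfig()
  ko <- simulateKoExperiment(cfg)
  cohort <- simulateCohort(cfg, ko$truth, ko$genes)
  dr <- driverGenes(ko$truth)[1:3]
  tab <- associationTable(cohortExpr(cohort)[dr, , drop = FALSE], cohort,
                          scheme = "expr")
  expect_equal(tab$marker, dr)
  expect_true(all(c("p.matched", "p.allTumors", "p.recurrence", "p.stage",
                    "p.gleasonKW") %in% colnames(tab)))
  ps <- unlist(tab[, -1])
  expect_true(all(is.na(ps) | (ps >= 0 & ps <= 1)))
  # planted drivers separate tumors from normals
  expect_true(all(tab$p.allTumors < 0.05))
})
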