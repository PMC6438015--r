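# Shared fixtures, built in code at test time.

smallConfig <- function(seed = 11L, ...) {
  args <- list(seed = seed, nGenes = 120L, nPlantedDrivers = 8L,
               cohortNTumor = 60L, cohortNNormal = 20L)
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

tinyGenes <- function() {
  geneModel(geneId = c("A", "B", "C"),
            chrom = c("chr1", "chr1", "chr2"),
            start = c(10000, 40000, 10000),
            end = c(15000, 45000, 20000),
            strand = c("+", "-", "+"))
}

# exhaustive two-sided Mann-Whitney oracle: all label assignments
enumMwuP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  uFor <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  uObs <- uFor(x, y)
  uAll <- apply(idx, 2, function(i) uFor(vals[i], vals[-i]))
  pLo <- mean(uAll <= uObs); pHi <- mean(uAll >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# exhaustive signed-rank oracle: all sign patterns of the differences
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- signs %*% r
  pLo <- mean(wAll <= wObs); pHi <- mean(wAll >= wObs)
  min(1, 2 * min(pLo, pHi))
}

# all-pairs AUC oracle
pairAuc <- function(scores, labels) {
  x <- scores[as.logical(labels)]; y <- scores[!as.logical(labels)]
  s <- 0
  for (a in x) for (b in y) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x) * length(y))
}

# negative binomial / poisson draw used by null-simulation tests
rcounts <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
}
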