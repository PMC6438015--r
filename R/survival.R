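#' @importFrom survival survfit Surv
#' @importFrom stats pchisq
#' @importFrom withr with_seed
NULL

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times (>= 0).
#' @param event 1 = event (biochemical recurrence), 0 = censored.
#' @return data.frame with `time`, `nRisk`, `nEvent`, `surv` — the stepwise
#'   survival function at the observed event/censoring times (events-first
#'   convention at ties).
#' @export
kmEstimate <- function(time, event) {
  if (length(time) < 1L) stop("need >= 1 record")
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survfit(Surv(time, event) ~ 1)
  data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
             surv = fit$surv)
}

## Fast two-group log-rank statistic, vectorized over distinct event times.
## Standard hypergeometric accounting at ties. Used directly by the cutpoint
## scan (thousands of evaluations); cross-checked against survival::survdiff
## in the test suite.
logrankChi2 <- function(time1, event1, time2, event2) {
  t <- c(time1, time2)
  e <- c(event1, event2)
  g <- rep(1:2, c(length(time1), length(time2)))
  et <- sort(unique(t[e == 1]))
  if (length(et) == 0L) return(c(chi2 = 0, obs1 = 0, exp1 = 0))
  nAtRisk <- outer(et, t, function(a, b) b >= a)      # times x subjects
  n1 <- nAtRisk %*% (g == 1)
  nTot <- rowSums(nAtRisk)
  isEvent <- outer(et, t, `==`) * rep(e, each = length(et))
  d1 <- isEvent %*% (g == 1)
  dTot <- rowSums(isEvent)
  exp1 <- dTot * n1 / nTot
  v <- ifelse(nTot > 1,
              dTot * (n1 / nTot) * (1 - n1 / nTot) *
                (nTot - dTot) / (nTot - 1), 0)
  V <- sum(v)
  O <- sum(d1); E <- sum(exp1)
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  c(chi2 = chi2, obs1 = O, exp1 = E)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic with a 1-df chi-square reference.
#'
#' @param timeA,eventA follow-up and 0/1 event indicator, group A.
#' @param timeB,eventB follow-up and 0/1 event indicator, group B.
#' @return list with `chi2`, `p.value`, `nA`, `nB`.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  if (length(timeA) == 0L || length(timeB) == 0L)
    stop("both groups must be non-empty")
  if (any(c(timeA, timeB) < 0)) stop("negative follow-up time")
  st <- logrankChi2(timeA, eventA, timeB, eventB)
  list(chi2 = unname(st["chi2"]),
       p.value = pchisq(unname(st["chi2"]), df = 1, lower.tail = FALSE),
       nA = length(timeA), nB = length(timeB))
}

#' Log-rank statistic at every admissible marker cutpoint
#'
#' Evaluates the two-group log-rank chi-square at every midpoint between
#' adjacent distinct marker values that leaves at least
#' `minGroupFraction` of the samples on each side.
#'
#' @param time,event,marker aligned vectors.
#' @param minGroupFraction minimum fraction of samples per side (default
#'   0.10).
#' @return data.frame with `cutpoint`, `chi2`, `nBelow`, `nAbove`, sorted by
#'   cutpoint; attribute `best` holds the argmax row (ties -> lower
#'   cutpoint).
#' @export
cutpointScan <- function(time, event, marker, minGroupFraction = 0.10) {
  s <- sort(unique(marker))
  if (length(s) < 2L) stop("no admissible cutpoint: marker is constant")
  cuts <- (s[-1] + s[-length(s)]) / 2
  n <- length(marker)
  minN <- ceiling(minGroupFraction * n)
  rows <- lapply(cuts, function(ct) {
    lo <- marker <= ct
    if (sum(lo) < minN || sum(!lo) < minN) return(NULL)
    st <- logrankChi2(time[lo], event[lo], time[!lo], event[!lo])
    data.frame(cutpoint = ct, chi2 = unname(st["chi2"]),
               nBelow = sum(lo), nAbove = sum(!lo))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no admissible cutpoint under the group-size constraint")
  out <- do.call(rbind, rows)
  best <- out[which.max(out$chi2), ]   # which.max takes the first = lowest
  attr(out, "best") <- best
  out
}

#' Outcome-driven optimal cutpoint with training/validation split
#'
#' X-tile-style cutpoint selection: the cohort is split at random (seeded)
#' into training and validation parts; the log-rank chi-square is evaluated
#' at every admissible data division of the training part; the cutpoint
#' maximizing the training chi-square (ties to the lower cutpoint) is then
#' applied to the validation part, whose log-rank p-value is the honest
#' measure of association. Setting `trainFraction = 1` disables the split
#' and returns the optimized whole-cohort p-value, which is anti-conservative
#' and reported as `naive = TRUE`.
#'
#' @param time,event,marker aligned vectors (>= 20 records, >= 5 events).
#' @param trainFraction fraction of samples in the training part (default
#'   0.5).
#' @param seed integer seed for the split (mandatory when splitting).
#' @param minGroupFraction per-side minimum for the scan (default 0.10).
#' @return list with `cutpoint`, `trainChi2`, `validationChi2`,
#'   `validationP`, `nBelow`, `nAbove` (validation groups), `naive`,
#'   and the training scan table as `scan`.
#' @export
xtileCutpoint <- function(time, event, marker, trainFraction = 0.5, seed,
                          minGroupFraction = 0.10) {
  n <- length(time)
  if (n < 20L) stop("need >= 20 records")
  if (sum(event) < 5L) stop("need >= 5 events")
  if (trainFraction >= 1) {
    scan <- cutpointScan(time, event, marker, minGroupFraction)
    best <- attr(scan, "best")
    lo <- marker <= best$cutpoint
    lt <- logrankTest(time[lo], event[lo], time[!lo], event[!lo])
    return(list(cutpoint = best$cutpoint, trainChi2 = best$chi2,
                validationChi2 = lt$chi2, validationP = lt$p.value,
                nBelow = sum(lo), nAbove = sum(!lo), naive = TRUE,
                scan = scan))
  }
  if (missing(seed)) stop("'seed' is mandatory for the random split")
  idx <- withr::with_seed(seed, sample(n, size = round(trainFraction * n)))
  tr <- logical(n); tr[idx] <- TRUE
  scan <- cutpointScan(time[tr], event[tr], marker[tr], minGroupFraction)
  ## highest training chi-square first (ties -> lower cutpoint); fall back
  ## to the next division when a cutpoint empties a validation group
  ord <- order(-scan$chi2, scan$cutpoint)
  best <- NULL
  for (i in ord) {
    loV <- marker[!tr] <= scan$cutpoint[i]
    if (sum(loV) > 0L && sum(!loV) > 0L) { best <- scan[i, ]; break }
  }
  if (is.null(best))
    stop("every admissible cutpoint empties a validation group")
  loV <- marker[!tr] <= best$cutpoint
  lt <- logrankTest(time[!tr][loV], event[!tr][loV],
                    time[!tr][!loV], event[!tr][!loV])
  list(cutpoint = best$cutpoint, trainChi2 = best$chi2,
       validationChi2 = lt$chi2, validationP = lt$p.value,
       nBelow = sum(loV), nAbove = sum(!loV), naive = FALSE, scan = scan)
}
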