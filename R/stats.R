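#' @include utils.R
NULL

#' Equality-of-variance gate for the two-sample t test
#'
#' Two-sided F test of equal variances computed from summary statistics:
#' \code{F = sd1^2/sd2^2} on \code{(n1-1, n2-1)} degrees of freedom. The
#' verdict is \code{"equal"} iff the test is not rejected at \code{alpha},
#' routing the downstream t test to its pooled or Welch form. Symmetric in
#' the two groups. Two zero SDs are treated as equal (degenerate case).
#'
#' @param sd1,sd2 group standard deviations (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha gate significance level.
#' @return \code{"equal"} or \code{"unequal"}.
#' @examples
#' varianceGate(0.049, 29, 0.108, 30)   # "unequal" (F ~ 4.86)
#' @export
varianceGate <- function(sd1, n1, sd2, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    message("both SDs are zero; variance gate returns 'equal'")
    return("equal")
  }
  if (sd1 == 0 || sd2 == 0) return("unequal")
  F <- sd1^2 / sd2^2
  pf1 <- stats::pf(F, n1 - 1, n2 - 1)
  p <- 2 * min(pf1, 1 - pf1)
  if (p < alpha) "unequal" else "equal"
}

#' Two-sample t test from summary statistics
#'
#' Unpaired two-tailed t test computed from (mean, SD, n) per group.
#' Pooled mode: \code{t = (m1-m2)/(sp sqrt(1/n1+1/n2))} with
#' \code{sp^2 = ((n1-1)s1^2+(n2-1)s2^2)/(n1+n2-2)} and \code{df =
#' n1+n2-2}. Welch mode: \code{t = (m1-m2)/sqrt(s1^2/n1+s2^2/n2)} with
#' Welch-Satterthwaite (fractional, unrounded) degrees of freedom. Mode
#' \code{"auto"} routes through [varianceGate()].
#'
#' @param summary optional one-row data.frame (or list) with
#'   \code{mean1, sd1, n1, mean2, sd2, n2}; alternatively pass the six
#'   values directly.
#' @param mode \code{"auto"}, \code{"pooled"} or \code{"welch"}.
#' @param gateAlpha significance level of the variance gate.
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics (used when
#'   \code{summary} is NULL).
#' @return A list with \code{t}, \code{df}, \code{p} (two-tailed) and
#'   \code{mode} (\code{"pooled"} or \code{"welch"} as applied).
#' @examples
#' ## Villous lactate, normal vs RSA: p ~ 0.087
#' tTestSummary(mean1 = 3.367, sd1 = 1.221, n1 = 30,
#'              mean2 = 2.881, sd2 = 0.921, n2 = 30)
#' @export
tTestSummary <- function(summary = NULL, mode = c("auto", "pooled", "welch"),
                         gateAlpha = 0.05, mean1, sd1, n1, mean2, sd2, n2) {
  mode <- match.arg(mode)
  if (!is.null(summary)) {
    mean1 <- summary$mean1; sd1 <- summary$sd1; n1 <- summary$n1
    mean2 <- summary$mean2; sd2 <- summary$sd2; n2 <- summary$n2
  }
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (mode == "auto")
    mode <- if (varianceGate(sd1, n1, sd2, n2, gateAlpha) == "equal")
      "pooled" else "welch"
  d <- mean1 - mean2
  if (mode == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- if (se == 0) { if (d == 0) 0 else sign(d) * Inf } else d / se
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mode = mode)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with \code{m} input p values
#' sorted ascending, \code{adj(i) = min(1, min over j >= i of p(j) m / j)},
#' returned in input order. Validates the input and delegates the step-up
#' computation to \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvals numeric vector of p values in \code{[0, 1]}.
#' @return Adjusted p values, same length and order; elementwise >= the
#'   raw values and capped at 1.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Percent change relative to a reference group
#'
#' \code{(ref - other)/ref x 100}: positive values mean the other (case)
#' group is lower than the reference.
#'
#' @param refMean reference-group mean (non-zero).
#' @param otherMean comparison-group mean.
#' @return Percent change.
#' @examples
#' percentChange(3.367, 2.881)   # 14.4% lower
#' @export
percentChange <- function(refMean, otherMean) {
  if (any(refMean == 0)) stop("reference mean must be non-zero")
  (refMean - otherMean) / refMean * 100
}

#' Power of the two-sided two-sample t test
#'
#' Power under the noncentral t distribution for the effect
#' \code{(m1-m2)/sd_pooled}, with \code{sd_pooled = sqrt((sd1^2+sd2^2)/2)}
#' and \code{n} per group, computed via \code{stats::power.t.test}.
#'
#' @param mean1,sd1,mean2,sd2 the two group means and SDs.
#' @param nPerGroup samples per group (>= 2).
#' @param alpha two-sided significance level.
#' @return The power, in \code{[0, 1]}; equals \code{alpha} when the means
#'   coincide, and 1 (degenerate) when the pooled SD is zero but the means
#'   differ.
#' @examples
#' ## villous succinate design: power well above the 0.95 threshold
#' powerTwoSample(0.589, 0.121, 0.429, 0.109, nPerGroup = 30)
#' @export
powerTwoSample <- function(mean1, sd1, mean2, sd2, nPerGroup,
                           alpha = 0.05) {
  stopifnot(nPerGroup >= 2)
  sdp <- sqrt((sd1^2 + sd2^2) / 2)
  delta <- abs(mean1 - mean2)
  if (sdp == 0) {
    if (delta == 0) return(alpha)
    message("zero pooled SD with differing means: power = 1 (degenerate)")
    return(1)
  }
  if (delta == 0) return(alpha)
  stats::power.t.test(n = nPerGroup, delta = delta, sd = sdp,
                      sig.level = alpha, type = "two.sample",
                      alternative = "two.sided")$power
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition (between/within sums of squares)
#' via \code{stats::oneway.test} with \code{var.equal = TRUE}.
#'
#' @param groups list of (>= 2) numeric vectors, each with n >= 2.
#' @return A list with \code{F}, \code{dfBetween}, \code{dfWithin} and
#'   \code{p}.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df (2, 6)
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least two numeric vectors")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), dfBetween = unname(fit$parameter[1]),
       dfWithin = unname(fit$parameter[2]), p = unname(fit$p.value))
}

#' Embryo-resorption (fetal loss) rate
#'
#' \code{R/(R + V) x 100} where R is the number of hemorrhagic
#' implantation sites and V the number of viable fetuses.
#'
#' @param R hemorrhagic implantations (>= 0).
#' @param V viable fetuses (>= 0); \code{R + V} must be >= 1.
#' @return Percentage in \code{[0, 100]}.
#' @examples
#' fetalLossRate(3, 7)   # 30
#' @export
fetalLossRate <- function(R, V) {
  if (any(R < 0) || any(V < 0)) stop("counts must be >= 0")
  if (any(R + V < 1)) stop("R + V must be >= 1")
  R / (R + V) * 100
}

## Summarize a concentration table into per-metabolite mean/sd/n.
.summarizeCohort <- function(tab) {
  mets <- .metaboliteCols(tab)
  data.frame(metabolite = mets,
             mean = vapply(mets, function(m) mean(tab[[m]]), numeric(1)),
             sd = vapply(mets, function(m) stats::sd(tab[[m]]), numeric(1)),
             n = nrow(tab), row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group differential metabolite table
#'
#' Runs, per metabolite: the variance gate, the routed pooled/Welch
#' two-tailed t test, percent change relative to group 1, and
#' Benjamini-Hochberg adjustment across exactly the metabolites supplied
#' (\code{m} = number of rows). Accepts either a summary-statistics table
#' (one data.frame with \code{metabolite, mean1, sd1, n1, mean2, sd2, n2},
#' as from [readSummaryTable()]) or two raw concentration tables, which
#' are summarized first.
#'
#' @param x summary data.frame, or the group-1 concentration table.
#' @param y \code{NULL}, or the group-2 concentration table.
#' @param mode t-test routing: \code{"auto"}, \code{"pooled"} or
#'   \code{"welch"}.
#' @param gateAlpha significance level of the variance gate.
#' @return A comparison data.frame (one row per metabolite, input order)
#'   with columns \code{metabolite, mean1, sd1, n1, mean2, sd2, n2,
#'   test_mode, t, df, p, adjusted_p, percent_change}.
#' @examples
#' t1 <- readSummaryTable(system.file("extdata", "table1_villi_rsa.tsv",
#'                                    package = "quantNMR"))
#' cmp <- differentialTable(t1)
#' cmp[cmp$metabolite == "Succinate", c("p", "percent_change")]
#' @export
differentialTable <- function(x, y = NULL, mode = c("auto", "pooled", "welch"),
                              gateAlpha = 0.05) {
  mode <- match.arg(mode)
  if (is.null(y)) {
    need <- c("metabolite", "mean1", "sd1", "n1", "mean2", "sd2", "n2")
    if (!all(need %in% names(x)))
      stop("summary input must have columns: ", paste(need, collapse = ", "))
    summ <- x[, need]
  } else {
    metsA <- .metaboliteCols(x); metsB <- .metaboliteCols(y)
    if (!setequal(metsA, metsB))
      stop("metabolite sets differ between groups: ",
           paste(union(setdiff(metsA, metsB), setdiff(metsB, metsA)),
                 collapse = ", "))
    sA <- .summarizeCohort(x)
    sB <- .summarizeCohort(y)
    sB <- sB[match(sA$metabolite, sB$metabolite), ]
    summ <- data.frame(metabolite = sA$metabolite,
                       mean1 = sA$mean, sd1 = sA$sd, n1 = sA$n,
                       mean2 = sB$mean, sd2 = sB$sd, n2 = sB$n,
                       stringsAsFactors = FALSE)
  }
  res <- lapply(seq_len(nrow(summ)), function(i)
    tTestSummary(summ[i, ], mode = mode, gateAlpha = gateAlpha))
  out <- summ
  out$test_mode <- vapply(res, `[[`, character(1), "mode")
  out$t <- vapply(res, `[[`, numeric(1), "t")
  out$df <- vapply(res, `[[`, numeric(1), "df")
  out$p <- vapply(res, `[[`, numeric(1), "p")
  out$adjusted_p <- bhAdjust(out$p)
  ## a zero reference mean (e.g. a metabolite floored at the noise level)
  ## has no defined percent change
  out$percent_change <- ifelse(out$mean1 == 0, NA_real_,
                               (out$mean1 - out$mean2) / out$mean1 * 100)
  rownames(out) <- NULL
  out
}
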