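# Diagnostic and prognostic evaluation: rank-based ROC/AUC and
# Kaplan-Meier survival with the two-sample log-rank test.

#' ROC curve and AUC by rank statistics
#'
#' AUC is the Mann-Whitney probability that a random case outscores a
#' random control, with ties half-credited; the curve is the empirical
#' (FPR, TPR) staircase over score thresholds, whose trapezoidal area
#' equals the rank AUC.  Higher score is taken as case-like; set
#' `direction = "low"` to invert.
#'
#' @param scores numeric marker values.
#' @param labels parallel labels, `"case"`/`"control"` (or logical with
#'   `TRUE` = case).
#' @param direction `"high"` (default) if cases score high, else `"low"`.
#' @return list with `auc` and `curve` (data.frame fpr, tpr from (0,0) to
#'   (1,1)).
#' @examples
#' rocAuc(c(3, 4, 1, 2), c("case", "case", "control", "control"))$auc
#' @export
rocAuc <- function(scores, labels, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  pos <- labels == "case"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (direction == "low") scores <- -scores
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  list(auc = auc, curve = curve)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame(time, n_risk, n_event, survival) at distinct event
#'   times.
#' @export
kmEstimate <- function(time, event) {
  stopifnot(all(time > 0))
  tj <- sort(unique(time[event == 1]))
  s <- 1
  rows <- lapply(tj, function(t) {
    nRisk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <<- s * (1 - d / nRisk)
    data.frame(time = t, n_risk = nRisk, n_event = d, survival = s)
  })
  if (!length(rows))
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), survival = numeric()))
  do.call(rbind, rows)
}

#' Median-split Kaplan-Meier comparison with the log-rank test
#'
#' Samples are split on the marker: `high` when expression strictly exceeds
#' the split value (the median by default), `low` otherwise — so samples
#' exactly at the median fall in the low group.  The two-sample log-rank
#' statistic accumulates observed minus expected events over pooled
#' distinct event times with the standard hypergeometric variance; the
#' p-value is the chi-square (df = 1) upper tail.
#'
#' @param expression named numeric vector (marker per sample).
#' @param survival data.frame(sample, time, event) covering the same
#'   samples.
#' @param split `"median"` or a numeric cut value.
#' @return list with `groups` (named character), `curves` (list of KM
#'   tables for high/low), `chi2`, `p`, `nHigh`, `nLow`.
#' @export
kmLogrank <- function(expression, survival, split = "median") {
  stopifnot(all(survival$sample %in% names(expression)))
  x <- expression[survival$sample]
  cut <- if (identical(split, "median")) median(x) else as.numeric(split)
  grp <- ifelse(x > cut, "high", "low")
  if (sum(grp == "high") < 2 || sum(grp == "low") < 2)
    stop("degenerate split: fewer than 2 samples in a group")
  time <- survival$time; event <- survival$event
  tj <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tj) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & grp == "high")
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == "high")
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- if (V > 0) pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  list(groups = setNames(grp, survival$sample),
       curves = list(high = kmEstimate(time[grp == "high"],
                                       event[grp == "high"]),
                     low = kmEstimate(time[grp == "low"],
                                      event[grp == "low"])),
       chi2 = chi2, p = p,
       nHigh = sum(grp == "high"), nLow = sum(grp == "low"))
}
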