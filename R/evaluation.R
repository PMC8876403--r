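# ---- ROC / AUC ---------------------------------------------------------------

#' ROC curve and AUC
#'
#' Midrank (Mann-Whitney) AUC: ties count one half, so
#' `auc = U / (n1 * n0)`. ROC points are the step function over the distinct
#' score thresholds, from (0, 0) to (1, 1).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return list with `roc` (data.frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)),
            all(is.finite(scores)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  list(roc = roc, auc = auc)
}

# DeLong structural components (midrank algorithm): V10 over positives,
# V01 over negatives. cov(auc_A, auc_B) = cov10/m + cov01/n.
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  pos_r <- rank(pos, ties.method = "average")
  neg_r <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - pos_r) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - neg_r) / m
  list(auc = sum(all_r[seq_len(m)] - pos_r) / (m * n), v10 = v10, v01 = v01,
       m = m, n = n)
}

#' AUC with a DeLong confidence interval
#'
#' Structural-components variance with a normal-approximation interval,
#' clipped to \[0, 1\]. Perfect separation yields zero variance; the
#' degenerate interval is returned with `degenerate = TRUE`.
#'
#' @param scores,labels as in [roc_auc()] (>= 2 records per class).
#' @param level confidence level (default 0.95).
#' @return list: `auc`, `lo`, `hi`, `se`, `degenerate`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  stopifnot(sum(labels == 1L) >= 2L, sum(labels == 0L) >= 2L)
  cp <- delong_components(scores, labels)
  v <- var(cp$v10) / cp$m + var(cp$v01) / cp$n
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = cp$auc, lo = max(0, cp$auc - z * se),
       hi = min(1, cp$auc + z * se), se = se, degenerate = se == 0)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both models are scored on the same records. Two-sided p from the paired
#' z statistic; antisymmetric in (A, B). With zero paired variance
#' (e.g. A compared with itself) the difference is exactly 0 and p = 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared 0/1 labels.
#' @return list: `auc_a`, `auc_b`, `delta_auc`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must be paired (equal length)")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  delta <- ca$auc - cb$auc
  v <- (var(ca$v10) + var(cb$v10) - 2 * cov(ca$v10, cb$v10)) / ca$m +
       (var(ca$v01) + var(cb$v01) - 2 * cov(ca$v01, cb$v01)) / ca$n
  if (v <= 0) {
    z <- if (abs(delta) < 1e-15) 0 else sign(delta) * Inf
  } else z <- delta / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, delta_auc = delta, z = z,
       p = 2 * pnorm(-abs(z)))
}

# ---- confusion metrics -------------------------------------------------------

#' Build a 2x2 classification table
#' @param calls logical/0-1 predicted positives.
#' @param labels 0/1 outcomes.
#' @return class `drabc_2x2`: counts `tp`, `fp`, `fn`, `tn`.
#' @export
two_by_two <- function(calls, labels) {
  calls <- as.logical(calls); labels <- as.integer(labels)
  structure(c(tp = sum(calls & labels == 1L),
              fp = sum(calls & labels == 0L),
              fn = sum(!calls & labels == 1L),
              tn = sum(!calls & labels == 0L)), class = "drabc_2x2")
}

#' Confusion metrics of a 2x2 table
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, and the Youden
#' index J = sensitivity + specificity - 1.
#'
#' @param tp,fp,fn,tn cell counts, or a `drabc_2x2` as `tp`.
#' @return named list: `sensitivity`, `specificity`, `accuracy`, `youden`
#'   (a metric with an empty denominator is `NA`).
#' @export
confusion_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (inherits(tp, "drabc_2x2")) {
    x <- tp; tp <- x[["tp"]]; fp <- x[["fp"]]; fn <- x[["fn"]]; tn <- x[["tn"]]
  }
  stopifnot(all(c(tp, fp, fn, tn) >= 0), tp + fp + fn + tn > 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / (tp + fp + fn + tn),
       youden = sens + spec - 1)
}

#' Odds ratio with a Woolf confidence interval
#'
#' OR = (a d)/(b c) for the table \[a b; c d\] (exposure x outcome). The
#' log-scale Woolf interval; when any cell is zero the Haldane-Anscombe
#' +0.5 correction is applied to all four cells and flagged.
#'
#' @param a,b,c,d cell counts.
#' @param level confidence level (default 0.95).
#' @return list: `or`, `lo`, `hi`, `corrected`.
#' @export
odds_ratio <- function(a, b, c, d, level = 0.95) {
  stopifnot(all(c(a, b, c, d) >= 0), a + b + c + d > 0)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - level) / 2)
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       corrected = corrected)
}

#' Class-conditional association tests
#'
#' Table-1-style report: for every feature and every carrier group versus
#' non-carriers, counts/proportions over known values and a two-sided p
#' (equal-variance t-test for age; Pearson chi-square, or Fisher's exact
#' test when any expected cell is < 5, for proportions). This is the same
#' computation as [summarize_cohort()].
#'
#' @param cohort labeled `drabc_cohort`.
#' @return a `drabc_summary` (see [summarize_cohort()]).
#' @export
association_tests <- function(cohort) summarize_cohort(cohort)
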