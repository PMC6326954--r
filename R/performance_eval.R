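#' One-sided Mann-Whitney test (positives stochastically greater)
#'
#' `U` counts (positive, negative) score pairs with the positive score
#' higher, plus half a count per tie. The one-sided p-value is exact
#' (Wilcoxon null distribution) when `n1 * n2 <= 400` and there are no
#' ties, and a tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param scores_pos Scores of the positive (relapsed) group.
#' @param scores_neg Scores of the negative group.
#' @return List with `U`, `p`, and `method` ("exact" or "normal").
#' @export
mann_whitney_one_sided <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  stop_if_not(n1 > 0 && n2 > 0, "both groups must be nonempty")
  all_s <- c(scores_pos, scores_neg)
  r <- rank(all_s)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_s)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    p <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)  # P(W >= U), U integer
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      # fully tied: the test is uninformative
      return(list(U = U, p = 0.5, method = "degenerate"))
    }
    z <- (U - mu - 0.5) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(U = U, p = min(max(p, .Machine$double.xmin), 1), method = method)
}

#' ROC AUC by the rank (Mann-Whitney) method
#'
#' `AUC = P(score_pos > score_neg) + P(tie)/2 = U / (n1 * n2)`, with
#' midranks for ties.
#'
#' @param scores Predicted scores.
#' @param labels 0/1 outcomes.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stop_if_not(length(unique(labels)) == 2, "both classes must be present")
  n1 <- sum(labels == 1); n2 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve coordinates
#'
#' @param scores Predicted scores.
#' @param labels 0/1 outcomes.
#' @return `data.frame` with `threshold`, `tpr`, `fpr`, ordered from
#'   permissive to strict.
#' @export
roc_curve <- function(scores, labels) {
  thr <- c(-Inf, sort(unique(scores)))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Bootstrap configuration for AUC confidence intervals
#'
#' @param n_boot Number of resamples (default 2000).
#' @param level Interval coverage (default 0.95).
#' @param stratified Resample within outcome classes (default TRUE, which
#'   also guarantees both classes in every resample).
#' @param seed Integer seed.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_boot = 2000, level = 0.95, stratified = TRUE,
                             seed = 1L) {
  stop_if_not(level > 0 && level < 1, "level must be in (0,1)")
  stop_if_not(n_boot >= 100, "n_boot must be >= 100")
  structure(list(n_boot = as.integer(n_boot), level = level,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' @param scores Predicted scores.
#' @param labels 0/1 outcomes.
#' @param cfg A [bootstrap_config()].
#' @return Numeric `c(low, high)` with the bootstrap AUC draws in the
#'   `boot_aucs` attribute.
#' @export
bootstrap_auc_ci <- function(scores, labels, cfg = bootstrap_config()) {
  stop_if_not(length(unique(labels)) == 2, "both classes must be present")
  pos <- which(labels == 1); neg <- which(labels == 0)
  with_seed(cfg$seed, {
    aucs <- vapply(seq_len(cfg$n_boot), function(b) {
      idx <- if (cfg$stratified) {
        c(sample(pos, length(pos), replace = TRUE),
          sample(neg, length(neg), replace = TRUE))
      } else {
        repeat {
          cand <- sample(seq_along(labels), length(labels), replace = TRUE)
          if (length(unique(labels[cand])) == 2) break
        }
        cand
      }
      roc_auc(scores[idx], labels[idx])
    }, 0)
    ci <- unname(quantile(aucs, c((1 - cfg$level) / 2, 1 - (1 - cfg$level) / 2)))
    attr(ci, "boot_aucs") <- aucs
    ci
  })
}

#' Power of the one-sided AUC test against AUC = 0.5
#'
#' Normal-approximation power using the exact null variance
#' \eqn{(n_1+n_2+1)/(12 n_1 n_2)} and the Hanley-McNeil variance
#' approximation under the alternative.
#'
#' @param auc Alternative-hypothesis AUC.
#' @param n_pos,n_neg Group sizes.
#' @param alpha One-sided significance level (default 0.01).
#' @return Power in \[0, 1\]; for `auc <= 0.5` the (<= alpha) value is
#'   returned with a `note` attribute.
#' @export
auc_power <- function(auc, n_pos, n_neg, alpha = 0.01) {
  stop_if_not(n_pos >= 1 && n_neg >= 1, "group sizes must be >= 1")
  stop_if_not(auc > 0 && auc < 1, "auc must be in (0,1)")
  v0 <- (n_pos + n_neg + 1) / (12 * n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v1 <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
           (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  v1 <- max(v1, .Machine$double.eps)
  pw <- pnorm((auc - 0.5 - qnorm(1 - alpha) * sqrt(v0)) / sqrt(v1))
  if (auc <= 0.5) attr(pw, "note") <- "auc <= 0.5: power does not exceed alpha"
  pw
}

#' Odds ratio of correct prediction along the score axis
#'
#' For each threshold `t`, scores `>= t` are classified as relapse and the
#' odds ratio `(TP*TN)/(FP*FN)` of the resulting 2x2 table is reported,
#' with the Haldane-Anscombe +0.5 correction whenever a cell is empty.
#'
#' @param scores Predicted scores.
#' @param labels 0/1 outcomes.
#' @param thresholds Threshold grid; default = the unique observed score
#'   values.
#' @param default_threshold Operating point whose OR is exposed in the
#'   `or_at_default` attribute (default 0.5).
#' @return `data.frame` with `threshold`, `tp`, `fp`, `fn`, `tn`,
#'   `odds_ratio`, `corrected`.
#' @export
correct_prediction_odds <- function(scores, labels, thresholds = NULL,
                                    default_threshold = 0.5) {
  stop_if_not(length(unique(labels)) == 2, "both classes must be present")
  thresholds <- thresholds %||% sort(unique(scores))
  one <- function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
    corrected <- any(c(tp, fp, fn, tn) == 0)
    h <- if (corrected) 0.5 else 0
    c(tp, fp, fn, tn,
      ((tp + h) * (tn + h)) / ((fp + h) * (fn + h)), corrected)
  }
  res <- t(vapply(thresholds, one, numeric(6)))
  out <- data.frame(threshold = thresholds, tp = res[, 1], fp = res[, 2],
                    fn = res[, 3], tn = res[, 4], odds_ratio = res[, 5],
                    corrected = as.logical(res[, 6]))
  attr(out, "or_at_default") <- one(default_threshold)[5]
  out
}

#' Full performance report for a prediction set
#'
#' Bundles the statistics of a model evaluation: one-sided Mann-Whitney
#' test, AUC with percentile-bootstrap CI, AUC power at the stated alpha,
#' and the odds-ratio-of-correct-prediction curve.
#'
#' @param ps A [prediction_set()] (or anything with `scores` and `labels`).
#' @param boot A [bootstrap_config()].
#' @param power_alpha One-sided alpha for the AUC power (default 0.01).
#' @return An `eval_report` list with `auc`, `auc_ci`, `mw_u`, `mw_p`,
#'   `power`, `or_curve`, `n_pos`, `n_neg`.
#' @export
evaluate_predictions <- function(ps, boot = bootstrap_config(),
                                 power_alpha = 0.01) {
  scores <- ps$scores; labels <- ps$labels
  mw <- mann_whitney_one_sided(scores[labels == 1], scores[labels == 0])
  auc <- roc_auc(scores, labels)
  ci <- bootstrap_auc_ci(scores, labels, boot)
  pw <- if (auc > 0.5 && auc < 1) {
    auc_power(auc, sum(labels == 1), sum(labels == 0), power_alpha)
  } else if (auc <= 0.5) {
    power_alpha
  } else {
    1.0
  }
  structure(list(auc = auc, auc_ci = ci, mw_u = mw$U, mw_p = mw$p,
                 power = as.numeric(pw),
                 or_curve = correct_prediction_odds(scores, labels),
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUC %.3f [%.3f-%.3f], one-sided MW p = %.3g (U = %.1f), power(alpha=0.01) %.3f, n = %d/%d\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$mw_p, x$mw_u, x$power, x$n_pos,
    x$n_neg))
  invisible(x)
}
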