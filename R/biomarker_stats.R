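#' ROC analysis with a less-than-or-equal positivity rule
#'
#' Low diffusivity marks restricted diffusion, so a subject tests positive
#' for transformation when the biomarker is less than or equal to the
#' cutoff. The curve is evaluated at the midpoints between consecutive
#' sorted unique values plus -Inf/+Inf endpoints; the AUC is the trapezoidal
#' integral over (1 - specificity, sensitivity), which equals the
#' Mann-Whitney concordance probability with half credit for ties. The
#' operating cutoff maximises Youden's J = sensitivity + specificity - 1
#' (ties broken toward the smallest cutoff); sensitivity, specificity and
#' the positive predictive value are read off the confusion counts there.
#' The AUC standard error uses the Hanley-McNeil formula.
#'
#' @param values numeric biomarker values (e.g. `ad_min` in 1e-3 mm^2/s).
#' @param labels 0/1 vector, 1 = transformed (the positive class).
#' @param direction positivity direction; only `"le"` (positive if value
#'   <= cutoff) is supported, matching the biomarker's orientation.
#' @param parameter_name label carried into the summary.
#' @return An object of class `roc_summary`: list with `parameter_name`,
#'   `cutoff`, `sensitivity`, `specificity`, `ppv` (percentages), `auc`,
#'   `auc_se`, `confusion` (named TP/FP/TN/FN vector) and `curve` (data
#'   frame of threshold, sensitivity, specificity in percent).
#' @export
roc_analysis <- function(values, labels, direction = "le",
                         parameter_name = deparse(substitute(values))) {
  direction <- match.arg(direction, "le")
  values <- as.numeric(values)
  labels <- as.integer(labels)
  if (length(values) != length(labels))
    stop("values and labels must have the same length")
  if (any(!is.finite(values))) stop("biomarker values must be finite")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present for ROC analysis")
  u <- sort(unique(values))
  thr <- c(-Inf, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2, Inf)
  # positive if value <= threshold: cumulative class counts per unique value
  cnt1 <- unname(vapply(split(labels, match(values, u)), sum, numeric(1)))
  cnt0 <- unname(vapply(split(1L - labels, match(values, u)), sum, numeric(1)))
  tp <- c(0, cumsum(cnt1))
  fp <- c(0, cumsum(cnt0))
  sens <- tp / n1
  spec <- (n0 - fp) / n0
  curve <- data.frame(threshold = thr, sensitivity = 100 * sens,
                      specificity = 100 * spec)
  # trapezoid over the ROC plane; thresholds ascend, so fpr ascends too
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which.max(j)                  # first maximum = smallest cutoff
  cTP <- tp[best]; cFP <- fp[best]
  confusion <- c(TP = cTP, FP = cFP, TN = n0 - cFP, FN = n1 - cTP)
  structure(list(parameter_name = parameter_name,
                 cutoff = thr[best],
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 auc = auc,
                 auc_se = hanley_mcneil_se(auc, n1, n0),
                 ppv = if (cTP + cFP >= 1) ppv_from_confusion(confusion)
                       else NA_real_,
                 confusion = confusion,
                 curve = curve),
            class = "roc_summary")
}

# Hanley & McNeil (1982) standard error of the empirical AUC
hanley_mcneil_se <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(
    "ROC for %s (positive if <= cutoff): cutoff %.3g, sens %.1f%%, spec %.1f%%, AUC %.3f (SE %.3f), PPV %.1f%%\n",
    x$parameter_name, x$cutoff, x$sensitivity, x$specificity, x$auc,
    x$auc_se, x$ppv))
  invisible(x)
}

#' Positive predictive value from confusion counts
#'
#' @param confusion named numeric vector with elements `TP`, `FP` (elements
#'   `TN`, `FN` are allowed and ignored).
#' @return PPV as a percentage, `100 * TP / (TP + FP)`.
#' @export
ppv_from_confusion <- function(confusion) {
  tp <- confusion[["TP"]]; fp <- confusion[["FP"]]
  if (tp + fp < 1) stop("PPV undefined: no test-positive subjects (TP + FP = 0)")
  100 * tp / (tp + fp)
}

#' Weighted Cohen's kappa for two readers
#'
#' Chance-corrected agreement `kappa = 1 - sum(w * o) / sum(w * e)` where
#' `o` is the observed joint rating table (proportions), `e` the expected
#' table from the marginal products, and `w` disagreement weights: linear
#' `|i - j|` or quadratic `(i - j)^2` in category distance. For binary
#' ratings both schemes reduce to unweighted Cohen's kappa. The agreement
#' band uses the reported interpretation scale: 0 < k <= 0.20 slight,
#' 0.20 < k <= 0.40 fair, 0.40 < k <= 0.60 moderate, 0.60 < k <= 0.80 very
#' good, 0.80 < k <= 1 substantial (k <= 0 is labelled "poor").
#'
#' @param ratings_r1,ratings_r2 equal-length categorical vectors (factors,
#'   integers or characters); categories are ordered by their sorted union.
#' @param weighting `"linear"` or `"quadratic"`.
#' @return An object of class `kappa_result`: list with `kappa`,
#'   `weighting`, `band_label` and `contingency` (counts, rater 1 in rows).
#' @export
weighted_kappa <- function(ratings_r1, ratings_r2,
                           weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(ratings_r1) != length(ratings_r2))
    stop("rating vectors must have equal length")
  if (length(ratings_r1) < 2L) stop("need at least 2 rated units")
  lev <- sort(unique(c(as.character(ratings_r1), as.character(ratings_r2))))
  f1 <- factor(as.character(ratings_r1), levels = lev)
  f2 <- factor(as.character(ratings_r2), levels = lev)
  tab <- table(r1 = f1, r2 = f2)
  n <- sum(tab)
  o <- tab / n
  e <- outer(rowSums(o), colSums(o))
  k <- length(lev)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- if (weighting == "linear") d else d^2
  we <- sum(w * e)
  if (we == 0)
    stop("kappa undefined: expected agreement is 1 (degenerate marginals)")
  kap <- 1 - sum(w * o) / we
  structure(list(kappa = kap, weighting = weighting,
                 band_label = kappa_band(kap), contingency = tab),
            class = "kappa_result")
}

#' @param kappa a kappa value in [-1, 1].
#' @rdname weighted_kappa
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.finite(kappa), kappa >= -1, kappa <= 1 + 1e-12)
  if (kappa <= 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "very good"
  else "substantial"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s weights): %.3f (%s agreement)\n",
              x$weighting, x$kappa, x$band_label))
  invisible(x)
}

#' Group comparison of the three minimum-diffusivity biomarkers
#'
#' One-way ANOVA (stable vs transformed) per parameter — for two groups the
#' F statistic equals the square of the pooled-variance t statistic — with
#' Bonferroni correction over the three-parameter family
#' (`p_bonferroni = min(1, 3 p)`), plus group means, standard deviations
#' and t-based 95% confidence intervals in the layout of the study's
#' group-comparison table.
#'
#' @param cohort a cohort data frame (see [simulate_cohort()]).
#' @param parameters biomarker columns to compare.
#' @return A data frame with one row per parameter and group, carrying
#'   `mean`, `sd`, `ci_lo`, `ci_hi`, and per-parameter `f_statistic`,
#'   `p_raw`, `p_bonferroni`.
#' @export
group_compare <- function(cohort,
                          parameters = c("ad_min", "md_min", "rd_min")) {
  stopifnot(all(parameters %in% names(cohort)),
            all(cohort$label %in% c(0L, 1L)))
  g <- factor(cohort$label, levels = c(0L, 1L),
              labels = c("stable", "transformed"))
  if (any(table(g) < 2L)) stop("both groups need at least 2 subjects")
  out <- list()
  for (p in parameters) {
    x <- cohort[[p]]
    if (stats::var(x) == 0) stop("zero variance in ", p, ": F undefined")
    a <- stats::anova(stats::lm(x ~ g))
    f <- a$`F value`[1L]
    praw <- a$`Pr(>F)`[1L]
    rows <- do.call(rbind, lapply(levels(g), function(lv) {
      xi <- x[g == lv]
      half <- stats::qt(0.975, length(xi) - 1L) * stats::sd(xi) / sqrt(length(xi))
      data.frame(parameter = p, group = lv, n = length(xi),
                 mean = mean(xi), sd = stats::sd(xi),
                 ci_lo = mean(xi) - half, ci_hi = mean(xi) + half)
    }))
    rows$f_statistic <- f
    rows$p_raw <- praw
    rows$p_bonferroni <- min(1, length(parameters) * praw)
    out[[p]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Closed-form AUC of the binormal two-group generator
#'
#' For the low-is-positive rule, the AUC of two normal groups is
#' `pnorm((mu_ref - mu_event) / sqrt(sd_ref^2 + sd_event^2))` — the
#' probability that a transformed subject's value falls below a stable
#' subject's. Used as the analytic reference for the cohort generator.
#'
#' @param mean_event,sd_event event-group (transformed) parameters.
#' @param mean_ref,sd_ref reference-group (stable) parameters.
#' @return AUC in [0, 1].
#' @export
binormal_auc <- function(mean_event, sd_event, mean_ref, sd_ref) {
  stats::pnorm((mean_ref - mean_event) / sqrt(sd_ref^2 + sd_event^2))
}
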