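# Four-metric peptide quality scoring, ROC/Youden calibration and the
# High/Medium/Low/Filtered confidence classifier.

#' Published confidence criteria
#'
#' A peptide meets a criterion when: it is observed in `min_replicates` or
#' more replicates; it has `min_overlapping` or more overlapping peptides;
#' its PSSM specificity-determinant p-value is strictly below `pssm_p_max`;
#' its mean normalized count is strictly above `norm_count_min`.
#'
#' @param min_replicates minimum replicate occurrences (2).
#' @param min_overlapping minimum overlapping peptides (1).
#' @param pssm_p_max PSSM p-value bound, strict (1e-4).
#' @param norm_count_min normalized count bound, strict (5e-4).
#' @return a list of class `confidence_criteria`.
#' @export
confidence_criteria <- function(min_replicates = 2L, min_overlapping = 1L,
                                pssm_p_max = 1e-4, norm_count_min = 5e-4) {
  stopifnot(min_replicates > 0, min_overlapping > 0,
            pssm_p_max > 0, norm_count_min > 0)
  structure(list(min_replicates = as.integer(min_replicates),
                 min_overlapping = as.integer(min_overlapping),
                 pssm_p_max = pssm_p_max, norm_count_min = norm_count_min),
            class = "confidence_criteria")
}

#' Compute the four peptide quality metrics
#'
#' Populates, per peptide: replicate occurrences, overlapping-peptide count,
#' PSSM specificity-determinant p-value and mean normalized count.  When no
#' enriched motif (hence no PSSM) is available, `pssm_p` is set to 1 with a
#' warning, so the criterion is unmet for every peptide.
#'
#' @param merged data.frame from [merge_replicates()] (peptide,
#'   n_replicates, mean_norm_count).
#' @param hits mapping table from [map_peptides()].
#' @param pssm optional PSSM from [build_pssm()].
#' @param background_seqs background sequences for [pssm_probability()]
#'   (required when `pssm` is given).
#' @return `merged` with columns n_overlapping and pssm_p added.
#' @export
compute_metrics <- function(merged, hits, pssm = NULL,
                            background_seqs = NULL) {
  merged$n_overlapping <- count_overlaps(merged$peptide, hits)
  if (is.null(pssm)) {
    warning("no PSSM available; pssm_p set to 1 for all peptides")
    merged$pssm_p <- 1
  } else {
    merged$pssm_p <- pssm_probability(merged$peptide, pssm, background_seqs)
  }
  merged
}

#' ROC curve with AUC and Mann-Whitney p-value
#'
#' Standard ROC over all distinct score thresholds (predicted positive when
#' score >= threshold), trapezoid AUC, and a two-sided Mann-Whitney test
#' between the two score samples.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 class labels; both classes must be present.
#' @return list of class `roc_result` with thresholds, tpr, fpr, auc,
#'   mann_whitney_p.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  N <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / N, numeric(1))
  # anchor at (0,0); (1,1) is reached at the lowest threshold
  auc <- sum(diff(c(0, fpr)) * (c(0, tpr)[-1] + c(0, tpr)[-length(tpr) - 1]) / 2)
  mw <- suppressWarnings(wilcox.test(scores[labels], scores[!labels],
                                     alternative = "two.sided"))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 mann_whitney_p = mw$p.value),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f over %d thresholds (MWW p = %.3g)\n",
              x$auc, length(x$thresholds), x$mann_whitney_p))
  invisible(x)
}

#' Youden-optimal threshold of a ROC curve
#'
#' Maximizes J = TPR - FPR; ties are broken toward the higher TPR, then the
#' lower threshold.  A non-positive maximal J is flagged as degenerate.
#'
#' @param roc a `roc_result` from [roc_curve()].
#' @return list with threshold, J, tpr, fpr, degenerate.
#' @export
youden_cutoff <- function(roc) {
  J <- roc$tpr - roc$fpr
  best <- which(J == max(J))
  if (length(best) > 1L) best <- best[roc$tpr[best] == max(roc$tpr[best])]
  if (length(best) > 1L) best <- best[which.min(roc$thresholds[best])]
  list(threshold = roc$thresholds[best], J = J[best], tpr = roc$tpr[best],
       fpr = roc$fpr[best], degenerate = max(J) <= 0)
}

#' Assign High/Medium/Low/Filtered confidence levels
#'
#' Counts how many of the four criteria each peptide meets and maps
#' 4 -> High, 2-3 -> Medium, 1 -> Low, 0 -> Filtered.
#'
#' @param metrics data.frame with n_replicates, n_overlapping, pssm_p,
#'   mean_norm_count.
#' @param criteria a [confidence_criteria()].
#' @return `metrics` with integer `n_criteria_met` and factor `confidence`
#'   (levels High, Medium, Low, Filtered) added.
#' @export
assign_confidence <- function(metrics, criteria = confidence_criteria()) {
  met <- (metrics$n_replicates >= criteria$min_replicates) +
    (metrics$n_overlapping >= criteria$min_overlapping) +
    (metrics$pssm_p < criteria$pssm_p_max) +
    (metrics$mean_norm_count > criteria$norm_count_min)
  lev <- c("Filtered", "Low", "Medium", "Medium", "High")[met + 1L]
  metrics$n_criteria_met <- as.integer(met)
  metrics$confidence <- factor(lev, levels = c("High", "Medium", "Low",
                                               "Filtered"))
  metrics
}

#' Benchmark the four metrics by ROC against a validated set
#'
#' One ROC per metric (replicates, overlaps, -log10 PSSM p, log10 count)
#' against benchmark membership, with Bonferroni correction of the
#' Mann-Whitney p-values by the number of metrics tested.
#'
#' @param metrics data.frame as in [assign_confidence()].
#' @param in_benchmark logical vector: peptide overlaps a validated motif
#'   instance.
#' @return data.frame with metric, auc, p, p_bonferroni (empty with a
#'   warning when the benchmark does not intersect the table).
#' @export
benchmark_metric_auc <- function(metrics, in_benchmark) {
  if (!any(in_benchmark) || all(in_benchmark)) {
    warning("benchmark does not split the table; no ROC possible")
    return(data.frame(metric = character(), auc = numeric(), p = numeric(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE))
  }
  scores <- list(
    n_replicates = metrics$n_replicates,
    n_overlapping = metrics$n_overlapping,
    pssm_p = -log10(metrics$pssm_p),
    mean_norm_count = log10(metrics$mean_norm_count))
  rows <- lapply(names(scores), function(m) {
    r <- roc_curve(scores[[m]], in_benchmark)
    data.frame(metric = m, auc = r$auc, p = r$mann_whitney_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}
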