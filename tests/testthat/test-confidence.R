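# ROC/Youden calibration and the four-criterion confidence classifier.

test_that("ROC handles perfect, degenerate and tied score sets", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1.0)
  tied <- roc_curve(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals brute-force pair counting (ties = 1/2)", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    scores <- sample(1:8, n, replace = TRUE)   # force ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_curve(scores, labels)$auc, auc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(92)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  ours <- roc_curve(scores, labels)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("Youden threshold maximizes J with the stated tie-breaks", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  y <- youden_cutoff(r)
  expect_equal(y$J, 1)
  expect_equal(y$threshold, 0.8)
  expect_false(y$degenerate)
  # anti-informative scores: J stays at 0 and is flagged
  anti <- roc_curve(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_true(youden_cutoff(anti)$degenerate)
  # oracle: exhaustive threshold scan
  set.seed(93)
  scores <- round(rnorm(40), 1)
  labels <- rbinom(40, 1, 0.5)
  if (any(labels == 1) && any(labels == 0)) {
    r2 <- roc_curve(scores, labels)
    y2 <- youden_cutoff(r2)
    jmax <- max(vapply(unique(scores), function(t) {
      mean(scores[labels == 1] >= t) - mean(scores[labels == 0] >= t)
    }, numeric(1)))
    expect_equal(y2$J, jmax, tolerance = 1e-12)
  }
})

test_that("confidence levels follow the published four criteria", {
  m <- data.frame(
    n_replicates = c(3L, 2L, 1L, 1L),
    n_overlapping = c(2L, 0L, 0L, 0L),
    pssm_p = c(1e-5, 1e-5, 0.5, 0.5),
    mean_norm_count = c(1e-3, 1e-5, 1e-3, 1e-5))
  out <- assign_confidence(m)
  expect_equal(as.character(out$confidence),
               c("High", "Medium", "Low", "Filtered"))
  expect_equal(out$n_criteria_met, c(4L, 2L, 1L, 0L))
})

test_that("criteria inequalities are strict exactly where published", {
  m <- data.frame(n_replicates = 2L, n_overlapping = 1L,
                  pssm_p = 1e-4, mean_norm_count = 5e-4)
  out <- assign_confidence(m)
  # >= 2 replicates and >= 1 overlap count; p-value and count bounds are
  # strict, so boundary values do not count
  expect_equal(out$n_criteria_met, 2L)
  m2 <- m
  m2$pssm_p <- 1e-4 - 1e-12
  m2$mean_norm_count <- 5e-4 + 1e-12
  expect_equal(assign_confidence(m2)$n_criteria_met, 4L)
})

test_that("classification is total and monotone in the thresholds", {
  set.seed(94)
  m <- data.frame(
    n_replicates = sample(1:4, 100, replace = TRUE),
    n_overlapping = sample(0:3, 100, replace = TRUE),
    pssm_p = 10^runif(100, -6, 0),
    mean_norm_count = 10^runif(100, -6, -1))
  out <- assign_confidence(m)
  expect_equal(sum(table(out$confidence)), 100L)
  stricter <- confidence_criteria(min_replicates = 3, min_overlapping = 2,
                                  pssm_p_max = 1e-5, norm_count_min = 5e-3)
  out2 <- assign_confidence(m, stricter)
  expect_true(all(out2$n_criteria_met <= out$n_criteria_met))
  rank <- function(x) match(as.character(x), c("Filtered", "Low", "Medium",
                                               "High"))
  expect_true(all(rank(out2$confidence) <= rank(out$confidence)))
})

test_that("Youden re-derivation recovers planted thresholds", {
  # benchmark peptides score above 0.35, the rest below: every threshold in
  # (0.35, 0.45] separates perfectly and the tie-break picks the lowest
  # observed score above the gap
  set.seed(95)
  pos <- runif(50, 0.45, 1)
  neg <- runif(150, 0, 0.35)
  r <- roc_curve(c(pos, neg), c(rep(1, 50), rep(0, 150)))
  y <- youden_cutoff(r)
  expect_equal(y$J, 1)
  expect_equal(y$threshold, min(pos))
})

test_that("metric benchmarking produces one ROC per metric", {
  set.seed(96)
  n <- 60
  bench <- rep(c(TRUE, FALSE), c(20, 40))
  m <- data.frame(
    n_replicates = ifelse(bench, 3L, 1L) + sample(0:1, n, replace = TRUE),
    n_overlapping = ifelse(bench, 2L, 0L) + sample(0:1, n, replace = TRUE),
    pssm_p = ifelse(bench, 1e-5, 1e-2) * 10^runif(n, -1, 1),
    mean_norm_count = ifelse(bench, 1e-3, 1e-5) * 10^runif(n, -0.5, 0.5))
  out <- benchmark_metric_auc(m, bench)
  expect_equal(nrow(out), 4L)
  expect_true(all(out$auc > 0.5))
  expect_equal(out$p_bonferroni, pmin(1, out$p * 4))
  # shuffled labels give chance-level AUC on average
  aucs <- replicate(50, {
    benchmark_metric_auc(m, sample(bench))$auc[1]
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(50) + 0.02)
  expect_warning(benchmark_metric_auc(m, rep(TRUE, n)), "benchmark")
})

test_that("compute_metrics assembles the four metrics from module outputs", {
  merged <- data.frame(peptide = c("AAKL", "KLMN", "QRST"),
                       n_replicates = c(3L, 2L, 1L),
                       mean_norm_count = c(1e-3, 2e-4, 5e-5),
                       stringsAsFactors = FALSE)
  hits <- data.frame(peptide = c("AAKL", "KLMN"), accession = "p1",
                     start = c(1L, 3L), end = c(4L, 6L),
                     stringsAsFactors = FALSE)
  expect_warning(m <- compute_metrics(merged, hits), "no PSSM")
  expect_equal(m$n_overlapping, c(1L, 1L, 0L))
  expect_equal(m$pssm_p, rep(1, 3))
})
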