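# Benchmarking and enrichment statistics.

test_that("recall counts findable instances, precision motif peptides", {
  bench <- data.frame(accession = paste0("p", 1:4),
                      start = 10L, end = 13L, stringsAsFactors = FALSE)
  lib_hits <- data.frame(peptide = paste0("L", 1:3),
                         accession = paste0("p", 1:3),
                         start = 5L, end = 20L,
                         primary_accession = paste0("p", 1:3),
                         stringsAsFactors = FALSE)
  sel_hits <- data.frame(peptide = c("S1", "S2"),
                         accession = c("p1", "p2"),
                         start = c(5L, 30L), end = c(20L, 45L),
                         primary_accession = c("p1", "p2"),
                         stringsAsFactors = FALSE)
  out <- recall_precision(sel_hits, bench, lib_hits)
  # p4 has no covering library peptide: findable = 3 (p1..p3); found = p1
  expect_equal(out$n_findable, 3L)
  expect_equal(out$recall, 1 / 3)
  # S1 overlaps an instance, S2 does not
  expect_equal(out$precision, 0.5)
  expect_error(recall_precision(sel_hits, bench[0, ], lib_hits), "empty")
})

test_that("recall is monotone when confidence levels are unioned", {
  set.seed(101)
  bench <- data.frame(accession = paste0("p", 1:6), start = 20L, end = 25L,
                      stringsAsFactors = FALSE)
  mk <- function(accs) data.frame(
    peptide = paste0("pep_", accs), accession = accs, start = 15L,
    end = 30L, primary_accession = accs, stringsAsFactors = FALSE)
  lib_hits <- mk(paste0("p", 1:6))
  high <- mk(paste0("p", 1:2))
  high_med <- mk(paste0("p", 1:4))
  r1 <- recall_precision(high, bench, lib_hits)$recall
  r2 <- recall_precision(high_med, bench, lib_hits)$recall
  expect_lte(r1, r2)
  expect_true(all(c(r1, r2) >= 0 & c(r1, r2) <= 1))
})

test_that("consensus enrichment is an upper-tail binomial", {
  lib <- c(random_peptides(90), vapply(random_peptides(10), plant_instance,
                                       character(1), consensus = "TGE"))
  none <- consensus_enrichment(random_peptides(5, len = 8), "TGE", lib)
  expect_equal(none$p, 1)  # k = 0
  all10 <- consensus_enrichment(
    vapply(random_peptides(10), plant_instance, character(1),
           consensus = "TGE"), "TGE", lib)
  expect_equal(all10$k, 10L)
  p0 <- all10$p0
  expect_equal(all10$p, pbinom(9, 10, p0, lower.tail = FALSE))
  # enumeration oracle at n <= 12
  set.seed(102)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    k <- sample(0:n, 1)
    pp <- runif(1, 0.05, 0.6)
    expect_equal(pbinom(k - 1, n, pp, lower.tail = FALSE),
                 binom_tail_enum(k, n, pp), tolerance = 1e-12)
  }
  # degenerate: a consensus absent from the library but present in the
  # selection is flagged
  deg <- consensus_enrichment("AAATGEAAA", "TGE", random_peptides(20))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("interactor resampling p-values behave at the extremes", {
  # one peptide per protein: any draw hits exactly |selection| interactors
  pool <- data.frame(peptide = paste0("pep", 1:40),
                     accession = paste0("p", 1:40),
                     stringsAsFactors = FALSE)
  sel <- paste0("pep", 1:8)
  everything <- interactor_enrichment(sel, paste0("p", 1:40), pool,
                                      n_iter = 200, seed = 1)
  expect_equal(everything$p, 1)
  nothing <- interactor_enrichment(sel, character(0), pool,
                                   n_iter = 200, seed = 1)
  expect_equal(nothing$p, 1)
  expect_error(interactor_enrichment(paste0("pep", 1:99), "p1", pool),
               "pool smaller")
})

test_that("planted interactor enrichment is detected", {
  set.seed(103)
  hits <- 0
  for (s in 1:10) {
    pool <- data.frame(peptide = paste0("pep", 1:100),
                       accession = paste0("p", rep(1:50, 2)),
                       stringsAsFactors = FALSE)
    # selection concentrated on interactor proteins
    inter <- paste0("p", 1:5)
    sel <- pool$peptide[pool$accession %in% inter][1:8]
    r <- interactor_enrichment(sel, inter, pool, n_iter = 1000, seed = s)
    if (r$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 10, 0.95)
})

test_that("null resampling p-values are approximately uniform", {
  set.seed(104)
  pool <- data.frame(peptide = paste0("pep", 1:60),
                     accession = paste0("p", rep(1:30, 2)),
                     stringsAsFactors = FALSE)
  inter <- paste0("p", 1:10)
  p <- vapply(1:100, function(s) {
    sel <- sample(pool$peptide, 10)
    interactor_enrichment(sel, inter, pool, n_iter = 300, seed = 100 + s)$p
  }, numeric(1))
  # discrete and conservative, but far from degenerate
  expect_gt(mean(p), 0.3)
  expect_lt(mean(p), 0.75)
  expect_gt(mean(p < 0.25), 0.05)
})

test_that("pairwise selection overlap distinguishes shared from positional", {
  hits <- data.frame(
    peptide = c("AAAA", "BBBB", "CCCC"),
    accession = c("p1", "p1", "p2"),
    start = c(1L, 13L, 1L), end = c(16L, 28L, 16L),
    stringsAsFactors = FALSE)
  same <- pairwise_selection_overlap(c("AAAA"), c("AAAA"), hits)
  expect_equal(same, list(shared = 1, overlapping = 1))
  disjoint <- pairwise_selection_overlap("AAAA", "CCCC", hits)
  expect_equal(disjoint, list(shared = 0, overlapping = 0))
  shifted <- pairwise_selection_overlap("AAAA", "BBBB", hits)
  expect_equal(shifted$shared, 0)
  expect_gt(shifted$overlapping, 0)
  expect_error(pairwise_selection_overlap(character(0), "AAAA", hits),
               "empty")
})

test_that("hypergeometric enrichment matches enumeration and the formulas", {
  set.seed(105)
  for (i in 1:10) {
    N <- sample(10:30, 1)
    n_term <- sample(1:N, 1)
    M <- sample(1:N, 1)
    m <- sample(0:min(n_term, M), 1)
    expect_equal(phyper(m, n_term, N - n_term, M, lower.tail = FALSE),
                 hyper_tail_enum(m, n_term, N, M), tolerance = 1e-12)
  }
  bg <- paste0("p", 1:20)
  ann <- data.frame(term = "T1", accession = paste0("p", 1:10),
                    stringsAsFactors = FALSE)
  out <- go_enrichment(paste0("p", 1:5), ann, bg)
  expect_equal(out$m, 5L)
  expect_equal(out$fold, (5 / 10) / (5 / 20))
  expect_equal(out$p, hyper_tail_enum(5, 10, 20, 5), tolerance = 1e-12)
  # m = 0: zero fold, p near 1
  out0 <- go_enrichment(paste0("p", 11:15),
                        data.frame(term = "T2",
                                   accession = paste0("p", 1:5)), bg)
  expect_equal(out0$fold, 0)
  expect_equal(out0$p, hyper_tail_enum(0, 5, 20, 5), tolerance = 1e-12)
  expect_gt(out0$p, 0.5)
})

test_that("BH adjustment follows the step-up arithmetic", {
  bg <- paste0("p", 1:30)
  ann <- rbind(
    data.frame(term = "T1", accession = paste0("p", 1:10)),
    data.frame(term = "T2", accession = paste0("p", 1:20)),
    data.frame(term = "T3", accession = paste0("p", 11:30)))
  out <- go_enrichment(paste0("p", 1:6), ann, bg)
  expect_equal(out$p_adjust, p.adjust(out$p, "BH")[order(out$p)][
    rank(out$p, ties.method = "first")], tolerance = 1e-12)
  expect_true(all(out$p_adjust >= out$p - 1e-15))
  expect_true(all(out$p_adjust <= 1))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("cluster representatives de-duplicate paralogous counts", {
  bg <- paste0("p", 1:20)
  cm <- c(p2 = "p1")  # p2 collapses onto p1
  ann <- data.frame(term = "T1", accession = c("p1", "p2", "p3"),
                    stringsAsFactors = FALSE)
  out <- go_enrichment(c("p1", "p2"), ann, bg, cluster_map = cm)
  expect_equal(out$m, 1L)   # one representative, not two paralogues
  expect_equal(out$n, 2L)
  expect_equal(out$N, 19L)
})

test_that("interactome enrichment reuses the GO machinery", {
  bg <- paste0("p", 1:20)
  inter <- data.frame(hub = "HUB1", partner = paste0("p", 1:10),
                      stringsAsFactors = FALSE)
  ann <- data.frame(term = "HUB1", accession = paste0("p", 1:10),
                    stringsAsFactors = FALSE)
  a <- interactome_enrichment(paste0("p", 1:5), inter, bg)
  b <- go_enrichment(paste0("p", 1:5), ann, bg)
  expect_equal(a, b)
})

test_that("shared-term probability follows the closed form", {
  expect_equal(shared_term_probability(2, 4), 1 / 6)
  expect_equal(shared_term_probability(4, 4), 1)
  expect_equal(shared_term_probability(0, 10), 0)
  expect_equal(shared_term_probability(1, 10), 0)
  expect_error(shared_term_probability(1, 1), "at least 2")
})

test_that("amino-acid bias flags strong deviations only", {
  f <- setNames(rep(0.05, 20), names(uniform_bg))
  same <- aa_bias(f, f)
  expect_equal(same$log2_ratio, rep(0, 20))
  expect_false(any(same$flagged))
  # double one residue, renormalize the rest
  g <- f
  g["P"] <- 0.10
  g <- g / sum(g)
  out <- aa_bias(g, f)
  expect_equal(out$log2_ratio[out$aa == "P"],
               log2(unname(g["P"]) / 0.05), tolerance = 1e-12)
  expect_equal(out$aa[which.max(abs(out$z))], "P")
  # flag set is invariant to input ordering
  perm <- sample(20)
  out2 <- aa_bias(g[perm], f[perm])
  expect_equal(out2$flagged, out$flagged)
})
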