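# Motif enumeration, consensus matching, PSSMs and logo heights.

test_that("consensus matching follows the pattern grammar", {
  m <- consensus_to_matcher("PPxY")
  expect_equal(m("TPPNYDEA"), cbind(start = 2L, end = 5L))
  m2 <- consensus_to_matcher("[LMP]xLPx[FIL]")
  expect_equal(nrow(m2("PALPAF")), 1L)
  expect_equal(nrow(consensus_to_matcher("TGE")("AAAKLM")), 0L)
  # negation, repetition, anchors
  expect_equal(nrow(consensus_to_matcher("[^P]GG")("AGG")), 1L)
  expect_equal(nrow(consensus_to_matcher("[^P]GG")("PGG")), 0L)
  expect_equal(nrow(consensus_to_matcher("Kx{2}K")("KAAK")), 1L)
  expect_equal(nrow(consensus_to_matcher("^MK")("MKL")), 1L)
  expect_equal(nrow(consensus_to_matcher("^MK")("AMKL")), 0L)
  expect_error(consensus_to_matcher("P[QR"), "parse error")
  expect_error(consensus_to_matcher("P{a}"), "parse error")
  expect_error(consensus_to_matcher("Pq"), "parse error")
})

test_that("the matcher agrees with positionwise matching on random pairs", {
  set.seed(41)
  classes <- c("ST", "KRH", "ILMV", "DE")
  for (i in 1:250) {
    k <- sample(2:4, 1)
    els <- vapply(seq_len(k), function(j) {
      r <- runif(1)
      if (r < 0.4) sample(names(uniform_bg), 1)
      else if (r < 0.7) "x"
      else sample(classes, 1)
    }, character(1))
    cons <- paste(ifelse(nchar(els) > 1, paste0("[", els, "]"), els),
                  collapse = "")
    pep <- random_peptides(1, len = 12)
    found <- nrow(consensus_to_matcher(cons)(pep)) > 0
    # independent positionwise check
    pl <- strsplit(pep, "")[[1]]
    ok <- FALSE
    for (s in seq_len(length(pl) - k + 1)) {
      hit <- all(vapply(seq_len(k), function(j) {
        e <- els[j]
        e == "x" || grepl(pl[s + j - 1], e, fixed = TRUE)
      }, logical(1)))
      if (hit) { ok <- TRUE; break }
    }
    expect_equal(found, ok, info = cons)
  }
})

test_that("binomial tails match enumeration for small n", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(1:12, 1)
    k <- sample(0:n, 1)
    p <- runif(1)
    expect_equal(pbinom(k - 1, n, p, lower.tail = FALSE),
                 binom_tail_enum(k, n, p), tolerance = 1e-12)
  }
})

test_that("PSSM weights follow the pseudocount log-odds formula", {
  pssm <- build_pssm(rep("K", 19), uniform_bg)
  expect_equal(unname(pssm[1, "K"]), log2((19 + 0.05) / (20 * 0.05)),
               tolerance = 1e-12)
  expect_true(all(is.finite(pssm)))          # pseudocount keeps weights finite
  expect_lt(pssm[1, "A"], 0)
  # a column matching the background is near log-odds 0 as alpha -> 0
  aligned <- vapply(names(uniform_bg), function(a) a, character(1))
  p0 <- build_pssm(aligned, uniform_bg, alpha = 1e-9)
  expect_equal(unname(p0[1, ]), rep(0, 20), tolerance = 1e-6)
  expect_error(build_pssm(c("AA", "AAA")), "ragged")
  expect_error(build_pssm("AA"), "at least 2")
})

test_that("the consensus of an alignment achieves the maximal PSSM score", {
  set.seed(61)
  aligned <- random_peptides(20, len = 8)
  pssm <- build_pssm(aligned, uniform_bg)
  consensus <- paste(colnames(pssm)[apply(pssm, 1, which.max)],
                     collapse = "")
  best <- pssm_score(consensus, pssm)
  expect_gte(best, max(pssm_score(aligned, pssm)))
  expect_equal(best, sum(apply(pssm, 1, max)), tolerance = 1e-12)
})

test_that("empirical PSSM p-values use add-one smoothing", {
  aligned <- c("KKKK", "KKKK", "KKKR")
  pssm <- build_pssm(aligned, uniform_bg)
  # background with 999 windows (one 1002-residue sequence), all poor
  bg <- strrep("E", 1002)
  p_top <- pssm_probability("KKKK", pssm, bg)
  expect_equal(p_top, 1 / 1000)
  p_bottom <- pssm_probability("EEEE", pssm, bg)
  expect_equal(p_bottom, 1)
  expect_error(pssm_probability("KKKK", pssm, character(0)), "background")
})

test_that("reversal-invariant PSSM p-values are uniform on null input", {
  set.seed(71)
  # a diverse alignment gives near-distinct weights (few score ties),
  # then symmetrizing makes the matrix invariant under position reversal
  aligned <- random_peptides(60, len = 4)
  pssm <- build_pssm(aligned, uniform_bg)
  pssm[] <- (pssm + pssm[4:1, ]) / 2
  bg <- random_peptides(30, len = 40)
  p <- pssm_probability(random_peptides(300, len = 4), pssm, bg)
  # Kolmogorov distance to uniform (tie-robust; 0.094 is the 1% point
  # for n = 300, plus discreteness slack from the finite null)
  D <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(D, 0.12)
  expect_gt(mean(p), 0.4)
  expect_lt(mean(p), 0.6)
})

test_that("logo heights are minus log10 binomial tails", {
  h <- logo_heights(rep("K", 10), uniform_bg)
  expect_equal(unname(h[1, "K"]), -log10(0.05^10), tolerance = 1e-9)
  expect_equal(unname(h[1, "A"]), 0)   # k = 0 has height 0
  aligned <- random_peptides(15, len = 6)
  hh <- logo_heights(aligned, uniform_bg)
  expect_true(all(hh >= 0))
  # per-position observed counts are conserved
  chs <- do.call(rbind, strsplit(aligned, ""))
  for (pos in 1:6) expect_equal(length(chs[, pos]), 15L)
})

test_that("planted motifs are recovered across seeded simulations", {
  hits <- 0L
  n_seeds <- 50L
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    peps <- random_peptides(40)
    peps[1:20] <- vapply(peps[1:20], plant_instance, character(1),
                         consensus = "PxLP")
    res <- find_enriched_motifs(peps, background_freqs = uniform_bg)
    if (nrow(res) && res$pattern[1] == "PxLP") hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("random peptide sets rarely yield a significant motif", {
  fp <- 0L
  n_seeds <- 100L
  for (seed in seq_len(n_seeds)) {
    set.seed(1000 + seed)
    res <- find_enriched_motifs(random_peptides(20),
                                background_freqs = uniform_bg)
    if (nrow(res)) fp <- fp + 1L
  }
  expect_lte(fp / n_seeds, 0.05)
})

test_that("degenerate and undersized inputs behave as specified", {
  expect_warning(out <- find_enriched_motifs(random_peptides(3)),
                 "fewer than 5")
  expect_equal(nrow(out), 0L)
  # identical sequences collapse to one unique peptide (sibling-inflation
  # guard), so a fully duplicated input cannot be tested for enrichment
  expect_warning(out2 <- find_enriched_motifs(rep("PKLPDEFG", 10)),
                 "fewer than 5")
  expect_equal(nrow(out2), 0L)
  # when every (unique) peptide carries the motif, support reaches n
  set.seed(81)
  peps <- vapply(random_peptides(8), plant_instance, character(1),
                 consensus = "PKLP")
  res <- find_enriched_motifs(peps, background_freqs = uniform_bg)
  expect_gt(nrow(res), 0L)
  expect_equal(res$support[1], 8L)
})
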