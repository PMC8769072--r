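# Search-space definition and library tiling.

test_that("secreted proteins without intracellular keywords are excluded", {
  p <- protein_record("P1", strrep("A", 30), keywords = "Secreted")
  expect_equal(nrow(strip_extracellular(p)), 0L)
  p2 <- protein_record("P2", strrep("A", 30),
                       keywords = c("Secreted", "Cytoplasm"))
  expect_equal(unname(strip_extracellular(p2)[1, ]), c(1L, 30L))
})

test_that("TM and extracellular spans are subtracted from the protein", {
  p <- protein_record("P1", strrep("A", 30), keywords = "Cytoplasm",
                      tm_spans = cbind(11, 20))
  out <- strip_extracellular(p)
  expect_equal(unname(out), cbind(c(1L, 21L), c(10L, 30L)),
               ignore_attr = TRUE)
  expect_error(
    strip_extracellular(
      protein_record("P3", strrep("A", 30), tm_spans = cbind(5, 15),
                     extracellular_spans = cbind(10, 20))),
    "overlapping")
  expect_error(protein_record("P4", "ADKL", tm_spans = cbind(3, 9)),
               "outside")
})

test_that("disorder binarization uses an inclusive 0.4 cutoff", {
  expect_equal(binarize_disorder(c(0.50, 0.39, 0.41)), c(TRUE, FALSE, TRUE))
  expect_equal(binarize_disorder(c(0, 0, 0)), c(FALSE, FALSE, FALSE))
  expect_true(binarize_disorder(0.40))
  expect_error(binarize_disorder(1.2), "0, 1")
})

test_that("structural SA normalizes, clips, handles unresolved and medians", {
  mx <- c(A = 100)
  one <- list(list(abs = c(50, NA), unresolved = c(FALSE, TRUE)))
  expect_equal(sa_from_structures(one, "AA", mx), c(50, 100))
  eq <- list(list(abs = 100, unresolved = FALSE))
  expect_equal(sa_from_structures(eq, "A", mx), 100)
  three <- list(list(abs = 10, unresolved = FALSE),
                list(abs = 40, unresolved = FALSE),
                list(abs = 90, unresolved = FALSE))
  expect_equal(sa_from_structures(three, "A", mx), 40)
  expect_error(sa_from_structures(eq, "C", mx), "missing")
})

test_that("homology SA transfer copies through aligned columns", {
  q <- "MKVLTDAESWQRNPLY"
  tr <- seq(5, 80, by = 5)
  expect_equal(map_homology_sa(q, q, tr), tr)
  # structure covering a suffix only: prefix stays NA
  out <- map_homology_sa(q, substr(q, 5, 16), tr[1:12])
  expect_true(all(is.na(out[1:4])))
  expect_equal(out[5:16], tr[1:12])
  # one substitution: values still transferred at aligned columns
  q2 <- q
  substr(q2, 8, 8) <- "G"
  out2 <- map_homology_sa(q2, q, tr)
  expect_equal(out2[-8], tr[-8])
})

test_that("experimental accessibility overrides predictions", {
  pred <- c(TRUE, TRUE, FALSE)
  exp_ <- c(FALSE, NA, TRUE)
  m <- merge_hierarchy(pred, exp_)
  expect_equal(m$accessible, c(FALSE, TRUE, TRUE))
  expect_equal(m$source, c("structure", "predicted", "structure"))
  none <- merge_hierarchy(pred, c(NA, NA, NA))
  expect_equal(none$accessible, pred)
  expect_error(merge_hierarchy(pred, c(NA, NA)), "length")
})

test_that("smoothing flips short inconsistent runs and is idempotent", {
  expect_equal(smooth_track(c(T, T, F, F, T, T)), rep(TRUE, 6))
  run5 <- c(T, T, rep(F, 5), T)
  expect_equal(smooth_track(run5), run5)
  expect_equal(smooth_track(rep(TRUE, 10)), rep(TRUE, 10))
  set.seed(42)
  for (i in 1:20) {
    x <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    s <- smooth_track(x)
    expect_identical(smooth_track(s), s)
    o <- include_order_islands(s)
    expect_identical(include_order_islands(o), o)
  }
})

test_that("ordered islands under 25 residues become accessible", {
  expect_true(all(include_order_islands(c(TRUE, rep(FALSE, 24), TRUE))))
  at25 <- c(TRUE, rep(FALSE, 25), TRUE)
  expect_equal(include_order_islands(at25), at25)
  terminal <- c(rep(FALSE, 10), rep(TRUE, 20))
  expect_equal(include_order_islands(terminal), terminal)
})

test_that("the 8-of-16 window rule defines the search space", {
  expect_equal(unname(define_search_space(c(rep(TRUE, 8), rep(FALSE, 8)))),
               cbind(1L, 16L), ignore_attr = TRUE)
  expect_equal(nrow(define_search_space(c(rep(TRUE, 7), rep(FALSE, 9)))), 0L)
  expect_equal(unname(define_search_space(rep(TRUE, 40))), cbind(1L, 40L),
               ignore_attr = TRUE)
})

test_that("search space equals the brute-force window scan", {
  cfg <- accessibility_config(min_loop_len = 16L)  # window rule only
  set.seed(7)
  for (i in 1:25) {
    L <- sample(10:100, 1)
    acc <- sample(c(TRUE, FALSE), L, replace = TRUE)
    expect_equal(unname(define_search_space(acc, cfg)),
                 unname(search_space_naive(acc, cfg)))
  }
})

test_that("8-residue loops are retained, 7-residue runs are not", {
  # an 8-residue accessible loop in an ordered context satisfies the
  # window rule for every window containing it
  acc <- c(rep(FALSE, 20), rep(TRUE, 8), rep(FALSE, 20))
  out <- define_search_space(acc)
  expect_equal(nrow(out), 1L)
  expect_true(out[1, 1] <= 21 && out[1, 2] >= 28)
  expect_gte(out[1, 2] - out[1, 1] + 1L, 16L)
  acc7 <- c(rep(FALSE, 20), rep(TRUE, 7), rep(FALSE, 20))
  expect_equal(nrow(define_search_space(acc7)), 0L)
})

test_that("tiling advances by 4 with an end-anchored terminal window", {
  seqs <- paste(rep("ADKLMNPQRSTVWYEHGFIK", 3), collapse = "")
  expect_equal(nrow(tile_region(c(1, 16), seqs)), 1L)
  t28 <- tile_region(c(1, 28), seqs)
  expect_equal(t28$start, c(1L, 5L, 9L, 13L))
  t18 <- tile_region(c(1, 18), seqs)
  expect_equal(t18$start, c(1L, 3L))
  expect_false(any(grepl("C", tile_region(c(1, 20), strrep("CADK", 10))$display_seq)))
})

test_that("tiles cover every region residue, interior residues twice", {
  seqs <- strrep("ADKLMNPQRSTVWYEH", 10)
  set.seed(3)
  for (i in 1:20) {
    s <- sample(1:40, 1)
    e <- s + 15L + sample(0:60, 1)
    tiles <- tile_region(c(s, e), seqs)
    cov <- integer(e - s + 1L)
    for (j in seq_len(nrow(tiles))) {
      idx <- (tiles$start[j]:tiles$end[j]) - s + 1L
      cov[idx] <- cov[idx] + 1L
    }
    expect_true(all(cov >= 1L))
    interior <- seq_len(e - s + 1L)
    interior <- interior[interior > 4 & interior <= (e - s + 1L - 4L)]
    expect_true(all(cov[interior] >= 2L))
  }
})

test_that("sublibrary assignment follows the pool combination rules", {
  nuc <- protein_record("P1", strrep("A", 20), keywords = "Nucleus")
  expect_equal(assign_sublibrary(nuc)$sublibrary, "Nucleus")
  both <- protein_record("P2", strrep("A", 20),
                         keywords = c("Nucleus", "Cytoplasm"))
  expect_equal(assign_sublibrary(both)$sublibrary,
               "Nucleocytoplasmic shuttling")
  none <- protein_record("P3", strrep("A", 20))
  expect_equal(assign_sublibrary(none)$sublibrary, "Other")
  endo <- protein_record("P4", strrep("A", 20), go_terms = "GO:0012505")
  expect_equal(assign_sublibrary(endo)$sublibrary, "Endomembrane System")
})

test_that("design_library is deterministic and collapses duplicates", {
  expect_equal(nrow(design_library(list(), list())), 0L)
  one <- protein_record("P1", "MKNTDAESWQRNPLYG", keywords = "Cytoplasm")
  lib1 <- design_library(list(one), list(P1 = list(disorder = rep(0.8, 16))))
  expect_equal(nrow(lib1), 1L)
  expect_equal(lib1$native_seq, "MKNTDAESWQRNPLYG")
  # two proteins sharing a display sequence collapse with joint provenance
  two <- protein_record("P2", "MKNTDAESWQRNPLYG", keywords = "Cytoplasm")
  lib2 <- design_library(list(one, two),
                         list(P1 = list(disorder = rep(0.8, 16)),
                              P2 = list(disorder = rep(0.8, 16))))
  expect_equal(nrow(lib2), 1L)
  expect_match(lib2$provenance, "P1:1-16;P2:1-16", fixed = TRUE)
  fx <- make_proteome(simulation_config(n_proteins = 10), seed = 5)
  a <- design_library(fx$records, fx$tracks)
  b <- design_library(fx$records, fx$tracks)
  expect_identical(a, b)
})

test_that("lowering the disorder cutoff never shrinks the accessible set", {
  set.seed(9)
  scores <- runif(200)
  lo <- binarize_disorder(scores, accessibility_config(iupred_cutoff = 0.3))
  hi <- binarize_disorder(scores, accessibility_config(iupred_cutoff = 0.5))
  expect_true(all(lo >= hi))
})
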