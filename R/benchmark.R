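# Benchmarking and enrichment statistics: recall/precision against validated
# motif instances, consensus and interactor enrichment, pairwise selection
# overlap, GO/interactome enrichment, shared-term probability, and amino-acid
# composition bias.

#' Recall and precision against a validated motif benchmark
#'
#' Recall is computed over findable instances only: benchmark instances
#' covered by at least one library peptide.  An instance counts as found
#' when at least one selected peptide's mapping overlaps it (after paralogue
#' collapse).  Precision is the fraction of selected peptides that overlap
#' any validated instance.
#'
#' @param selected_hits mapping table of the selected peptides (with
#'   `primary_accession` from [collapse_paralogues()]).
#' @param benchmark data.frame of instances: accession, start, end.
#' @param library_hits mapping table of the full library design (also
#'   collapsed), defining which instances are findable.
#' @param cluster_map named accession -> representative map applied to the
#'   benchmark accessions.
#' @return list with recall, precision, n_findable, n_found.
#' @export
recall_precision <- function(selected_hits, benchmark, library_hits,
                             cluster_map = character()) {
  if (!nrow(benchmark)) stop("empty benchmark")
  bench_acc <- cluster_map[benchmark$accession]
  bench_acc[is.na(bench_acc)] <- benchmark$accession[is.na(bench_acc)]
  overlaps_any <- function(hits, acc, s, e) {
    any(hits$primary_accession == acc & hits$start <= e & hits$end >= s)
  }
  findable <- vapply(seq_len(nrow(benchmark)), function(i)
    overlaps_any(library_hits, bench_acc[i], benchmark$start[i],
                 benchmark$end[i]), logical(1))
  found <- vapply(seq_len(nrow(benchmark)), function(i)
    findable[i] && overlaps_any(selected_hits, bench_acc[i],
                                benchmark$start[i], benchmark$end[i]),
    logical(1))
  peptides <- unique(selected_hits$peptide)
  motif_containing <- vapply(peptides, function(p) {
    h <- selected_hits[selected_hits$peptide == p, , drop = FALSE]
    any(vapply(seq_len(nrow(h)), function(j)
      any(bench_acc == h$primary_accession[j] &
            benchmark$start <= h$end[j] & benchmark$end >= h$start[j]),
      logical(1)))
  }, logical(1))
  list(recall = if (sum(findable)) sum(found) / sum(findable) else NA_real_,
       precision = if (length(peptides)) mean(motif_containing) else NA_real_,
       n_findable = sum(findable), n_found = sum(found))
}

#' Binomial enrichment of a consensus in a selection
#'
#' `P(X >= k | n, p0)` where `k` selected peptides match the consensus out
#' of `n` selected, and `p0` is the fraction of the whole library matching.
#'
#' @param selected character vector of selected peptides.
#' @param consensus consensus string.
#' @param library character vector of all library peptides.
#' @return list with k, n, p0, p (flagged degenerate when p0 = 0 with
#'   k > 0).
#' @export
consensus_enrichment <- function(selected, consensus, library) {
  rx <- attr(consensus_to_matcher(consensus), "regex")
  k <- sum(grepl(rx, selected, perl = TRUE))
  n <- length(selected)
  p0 <- mean(grepl(rx, library, perl = TRUE))
  degenerate <- p0 == 0 && k > 0
  p <- if (degenerate) 0 else pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(k = k, n = n, p0 = p0, p = p, degenerate = degenerate)
}

#' Resampling enrichment of known interactors in a selection
#'
#' Draws `|selection|` peptides from the pooled peptides of all selections
#' `n_iter` times and counts distinct known-interactor proteins hit; the
#' empirical p-value uses add-one smoothing.
#'
#' @param selected character vector of peptides selected for the bait.
#' @param interactors character vector of known interactor accessions.
#' @param pool data.frame of the global peptide pool with columns peptide
#'   and accession (pool must contain the selection).
#' @param n_iter resampling iterations (10000).
#' @param seed integer seed.
#' @return list with observed, p, null_mean.
#' @export
interactor_enrichment <- function(selected, interactors, pool,
                                  n_iter = 10000L, seed = 1L) {
  stopifnot(n_iter >= 1L)
  peps <- unique(pool$peptide)
  if (length(peps) < length(selected)) stop("pool smaller than selection")
  acc_of <- split(pool$accession, pool$peptide)
  hit_count <- function(pepset) {
    length(intersect(unique(unlist(acc_of[pepset], use.names = FALSE)),
                     interactors))
  }
  observed <- hit_count(selected)
  set.seed(seed)
  null <- vapply(seq_len(n_iter), function(i)
    hit_count(sample(peps, length(selected))), numeric(1))
  list(observed = observed,
       p = (sum(null >= observed) + 1) / (n_iter + 1),
       null_mean = mean(null))
}

#' Pairwise overlap between two selections
#'
#' Directional: the shared fraction is `|A intersect B| / |A|`, and the
#' overlapping fraction is the fraction of A's peptides with positional
#' overlap (via protein mapping) to any peptide of B.
#'
#' @param a,b character vectors of selected peptides (non-empty).
#' @param hits mapping table covering both selections.
#' @return list with shared, overlapping (fractions relative to `a`).
#' @export
pairwise_selection_overlap <- function(a, b, hits) {
  if (!length(a) || !length(b)) stop("empty selection")
  a <- unique(a); b <- unique(b)
  shared <- length(intersect(a, b)) / length(a)
  hb <- hits[hits$peptide %in% b, , drop = FALSE]
  overlapping <- mean(vapply(a, function(p) {
    ha <- hits[hits$peptide == p, , drop = FALSE]
    if (!nrow(ha) || !nrow(hb)) return(FALSE)
    any(vapply(seq_len(nrow(ha)), function(i)
      any(hb$accession == ha$accession[i] & hb$start <= ha$end[i] &
            hb$end >= ha$start[i]), logical(1)))
  }, logical(1)))
  list(shared = shared, overlapping = overlapping)
}

#' Hypergeometric GO term enrichment over cluster representatives
#'
#' For each term: `m` peptide-containing proteins with the term, `n`
#' proteome proteins with the term, `M` peptide-containing proteins, `N`
#' proteome size, all counted over cluster representatives.  The p-value is
#' the strict upper tail `P(x > m)`; fold enrichment is `(m/n) / (M/N)`;
#' Benjamini-Hochberg adjustment across terms.
#'
#' @param protein_set character vector of accessions (peptide-containing).
#' @param annotation data.frame with columns term, accession
#'   (ancestor-closed).
#' @param background character vector of proteome accessions.
#' @param cluster_map named accession -> representative map.
#' @param tail `"greater"` for the printed strict tail P(x > m), or
#'   `"geq"` for P(x >= m).
#' @return data.frame with term, m, n, M, N, fold, p, p_adjust.
#' @export
go_enrichment <- function(protein_set, annotation, background,
                          cluster_map = character(), tail = c("greater", "geq")) {
  tail <- match.arg(tail)
  to_rep <- function(acc) {
    r <- cluster_map[acc]
    r[is.na(r)] <- acc[is.na(r)]
    unique(unname(r))
  }
  set_r <- to_rep(protein_set)
  bg_r <- to_rep(background)
  set_r <- intersect(set_r, bg_r)
  M <- length(set_r)
  N <- length(bg_r)
  terms <- unique(annotation$term)
  rows <- lapply(terms, function(tm) {
    with_term <- to_rep(annotation$accession[annotation$term == tm])
    with_term <- intersect(with_term, bg_r)
    n <- length(with_term)
    if (n == 0L) return(NULL)  # term absent from background
    m <- length(intersect(set_r, with_term))
    q <- if (tail == "greater") m else m - 1L
    p <- phyper(q, n, N - n, M, lower.tail = FALSE)
    data.frame(term = tm, m = m, n = n, M = M, N = N,
               fold = if (m == 0L) 0 else (m / n) / (M / N),
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term = character(), m = integer(), n = integer(),
                      M = integer(), N = integer(), fold = numeric(),
                      p = numeric(), p_adjust = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Interactome enrichment
#'
#' Identical machinery to [go_enrichment()], with per-hub interactor sets in
#' place of GO term annotations.
#'
#' @param protein_set character vector of accessions.
#' @param interactions data.frame with columns hub, partner.
#' @param background character vector of proteome accessions.
#' @param cluster_map named accession -> representative map.
#' @return data.frame as from [go_enrichment()] with `term` = hub.
#' @export
interactome_enrichment <- function(protein_set, interactions, background,
                                   cluster_map = character()) {
  ann <- data.frame(term = interactions$hub, accession = interactions$partner,
                    stringsAsFactors = FALSE)
  go_enrichment(protein_set, ann, background, cluster_map)
}

#' Probability that two random proteins share a GO term
#'
#' `p = Ng (Ng - 1) / (N (N - 1))` for a term carried by `Ng` of `N`
#' proteins.
#'
#' @param Ng number of proteins with the term.
#' @param N proteome size (>= 2).
#' @return probability in `[0, 1]`.
#' @export
shared_term_probability <- function(Ng, N) {
  if (N < 2) stop("N must be at least 2")
  stopifnot(Ng >= 0, Ng <= N)
  Ng * (Ng - 1) / (N * (N - 1))
}

#' Amino-acid composition bias of a selection
#'
#' Log2 ratios of the selection's residue frequencies over a background
#' (typically the disordered proteome), and a z-score of each ratio against
#' the mean and standard deviation of the 20 ratios; |z| > 2 is flagged.
#'
#' @param selection_freqs,background_freqs named frequency vectors over the
#'   20 residues, each summing to 1.
#' @return data.frame with aa, selection, background, log2_ratio, z, flagged.
#' @export
aa_bias <- function(selection_freqs, background_freqs) {
  sel <- selection_freqs[AA20]
  bg <- background_freqs[AA20]
  stopifnot(abs(sum(sel) - 1) < 1e-6, abs(sum(bg) - 1) < 1e-6)
  undefined <- bg == 0
  ratio <- ifelse(undefined, NA_real_, log2(sel / bg))
  s <- sd(ratio, na.rm = TRUE)
  z <- if (is.na(s) || s == 0) ifelse(is.na(ratio), NA_real_, 0) else
    (ratio - mean(ratio, na.rm = TRUE)) / s
  data.frame(aa = AA20, selection = unname(sel), background = unname(bg),
             log2_ratio = unname(ratio), z = unname(z),
             flagged = unname(undefined | abs(z) > 2),
             stringsAsFactors = FALSE)
}
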