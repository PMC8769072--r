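# Shared test fixtures and independent oracles.

uniform_bg <- setNames(rep(0.05, 20),
                       strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])

random_peptides <- function(n, len = 16L, freqs = uniform_bg) {
  vapply(seq_len(n), function(i)
    paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
          collapse = ""), character(1))
}

# plant a concrete match of a fixed-width consensus at a random position
plant_instance <- function(peptide, consensus) {
  el <- attr(proppd::consensus_to_matcher(consensus), "elements")
  inst <- paste(vapply(el, function(e) {
    if (e == "x") sample(names(uniform_bg), 1)
    else if (nchar(e) == 1L) e
    else sample(strsplit(e, "")[[1]], 1)
  }, character(1)), collapse = "")
  pos <- sample.int(nchar(peptide) - nchar(inst) + 1L, 1)
  substr(peptide, pos, pos + nchar(inst) - 1L) <- inst
  peptide
}

# independent upper-tail binomial P(X >= k) by direct enumeration
binom_tail_enum <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# independent strict upper-tail hypergeometric P(X > m) by enumeration
hyper_tail_enum <- function(m, n_term, N, M) {
  upper <- min(M, n_term)
  if (m >= upper) return(0)
  sum(vapply((m + 1):upper, function(i)
    choose(n_term, i) * choose(N - n_term, M - i) / choose(N, M),
    numeric(1)))
}

# AUC by brute-force pair counting with ties scored 1/2
auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# naive all-positions peptide scan honoring the peptide-side A<->C wildcard
map_peptides_naive <- function(peptides, proteome) {
  rows <- list()
  for (pep in peptides) {
    pl <- strsplit(pep, "")[[1]]
    for (acc in names(proteome)) {
      sl <- strsplit(proteome[[acc]], "")[[1]]
      for (s in seq_len(max(0L, length(sl) - length(pl) + 1L))) {
        win <- sl[s:(s + length(pl) - 1L)]
        ok <- all(win == pl | (pl == "A" & win == "C"))
        if (ok) rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, accession = acc, start = s,
          end = s + length(pl) - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), accession = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# brute-force search space: mark residues of every qualifying 16-mer window
search_space_naive <- function(accessible, cfg = accessibility_config()) {
  L <- length(accessible)
  mask <- rep(FALSE, L)
  if (L >= cfg$window_len) {
    for (s in seq_len(L - cfg$window_len + 1L)) {
      win <- accessible[s:(s + cfg$window_len - 1L)]
      if (sum(win) >= cfg$window_min_accessible) {
        mask[s:(s + cfg$window_len - 1L)] <- TRUE
      }
    }
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
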