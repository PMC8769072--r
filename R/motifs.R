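# SLiM discovery: bounded enumeration of consensus patterns with binomial
# enrichment significance, PSSM construction, specificity-determinant
# p-values, and binomial logo heights.

#' Motif discovery parameters
#'
#' @param min_ic minimum information content of a returned pattern, summed
#'   over defined positions as log2(20 / class size) (default 1.1).
#' @param equiv_groups physicochemical equivalence groups usable at
#'   ambiguous positions.
#' @param max_wild maximum number of consecutive wildcard positions (5).
#' @param sig_cutoff corrected significance cutoff for returned motifs
#'   (0.001).
#' @param max_defined_positions enumeration bound on defined positions (5).
#' @param min_support_frac minimum fraction of input peptides a pattern must
#'   occur in to be evaluated (floor of 3 peptides).
#' @param extend_p uncorrected-significance gate for growing a pattern by a
#'   further defined position.
#' @param beam maximum number of patterns carried to the next enumeration
#'   depth (most significant first); bounds the search.
#' @return a list of class `motif_params`.
#' @export
motif_params <- function(min_ic = 1.1,
                         equiv_groups = c("AGS", "ILMV", "IVMLFAP",
                                          "IVMLFWHYA", "FYWH", "KRH", "ST",
                                          "STNQ", "DEST"),
                         max_wild = 5L, sig_cutoff = 0.001,
                         max_defined_positions = 5L,
                         min_support_frac = 0.05, extend_p = 0.05,
                         beam = 50L) {
  stopifnot(min_ic > 0, max_wild >= 0, max_defined_positions >= 2, beam >= 1)
  structure(list(min_ic = min_ic, equiv_groups = equiv_groups,
                 max_wild = as.integer(max_wild), sig_cutoff = sig_cutoff,
                 max_defined_positions = as.integer(max_defined_positions),
                 min_support_frac = min_support_frac, extend_p = extend_p,
                 beam = as.integer(beam)),
            class = "motif_params")
}

#' Amino-acid frequencies of a sequence set
#'
#' @param seqs character vector of sequences.
#' @return named numeric vector over the 20 standard residues, summing to 1.
#' @export
aa_frequencies <- function(seqs) {
  ch <- unlist(strsplit(seqs, ""))
  ch <- ch[ch %in% AA20]
  tab <- table(factor(ch, levels = AA20))
  f <- as.numeric(tab) / sum(tab)
  setNames(f, AA20)
}

# A pattern is a list(elements = character vector, each the allowed residues
# of a defined position; gaps = integer wildcard run lengths between
# consecutive defined positions).
pattern_regex <- function(pat) {
  el <- ifelse(nchar(pat$elements) == 1L, pat$elements,
               paste0("[", pat$elements, "]"))
  gaps <- c("", vapply(pat$gaps, function(g)
    if (g == 0L) "" else sprintf(".{%d}", g), character(1)))
  paste0(paste0(gaps, el), collapse = "")
}

pattern_string <- function(pat) {
  el <- ifelse(nchar(pat$elements) == 1L, pat$elements,
               paste0("[", pat$elements, "]"))
  gaps <- c("", vapply(pat$gaps, function(g)
    strrep("x", g), character(1)))
  paste0(paste0(gaps, el), collapse = "")
}

pattern_ic <- function(pat) sum(log2(20 / nchar(pat$elements)))

pattern_span <- function(pat) length(pat$elements) + sum(pat$gaps)

# Probability that a random peptide of length len (residues iid from bg)
# contains the pattern at one or more offsets.
pattern_match_prob <- function(pat, bg, len) {
  p_pos <- prod(vapply(strsplit(pat$elements, ""), function(cls)
    sum(bg[cls]), numeric(1)))
  nwin <- len - pattern_span(pat) + 1L
  if (nwin < 1L) return(0)
  1 - (1 - p_pos)^nwin
}

pattern_support <- function(pat, peptides) {
  sum(grepl(pattern_regex(pat), peptides, perl = TRUE))
}

#' Find enriched motif patterns in a peptide set
#'
#' A bounded re-implementation of SLiMFinder-style motif enumeration:
#' candidate patterns (fixed residues or equivalence-class positions
#' separated by up to `max_wild` wildcards, up to `max_defined_positions`
#' defined positions) occurring in the input are grown greedily; each
#' evaluated pattern's significance is the upper-tail binomial probability
#' of its support given the per-peptide match probability under the
#' background amino-acid frequencies, Bonferroni-corrected by the size of
#' the enumerable pattern space at the pattern's depth (the guided search
#' implicitly selects over that whole space).
#'
#' @param peptides character vector of (unique) peptides; at least 5.
#' @param background_freqs background amino-acid frequencies; defaults to
#'   the input peptides' own frequencies.
#' @param params a [motif_params()].
#' @return data.frame of motifs ranked by corrected significance, with
#'   columns pattern, regex, support, n, ic, p, p_corrected, n_evaluated;
#'   empty (with a warning) for fewer than 5 peptides.
#' @export
find_enriched_motifs <- function(peptides, background_freqs = NULL,
                                 params = motif_params()) {
  empty <- data.frame(pattern = character(), regex = character(),
                      support = integer(), n = integer(), ic = numeric(),
                      p = numeric(), p_corrected = numeric(),
                      n_evaluated = integer(), stringsAsFactors = FALSE)
  peptides <- unique(peptides)
  n <- length(peptides)
  if (n < 5L) {
    warning("fewer than 5 peptides; no motif enrichment attempted")
    return(empty)
  }
  bg <- background_freqs %||% aa_frequencies(peptides)
  bg <- bg[AA20]
  bg <- bg / sum(bg)
  len <- round(mean(nchar(peptides)))
  min_support <- max(3L, ceiling(params$min_support_frac * n))
  vocab <- c(AA20, params$equiv_groups)
  el_rx <- ifelse(nchar(vocab) == 1L, vocab, paste0("[", vocab, "]"))
  el_p <- vapply(strsplit(vocab, ""), function(cls) sum(bg[cls]), numeric(1))
  names(el_rx) <- names(el_p) <- vocab
  keep1 <- vapply(vocab, function(e)
    sum(grepl(el_rx[e], peptides, perl = TRUE)) >= min_support, logical(1))
  viable <- vocab[keep1]
  if (!length(viable)) return(empty)

  # anchored matching: a candidate only matches peptides its parent matched,
  # so support is counted on the parent's match subset
  frontier <- lapply(viable, function(e) {
    idx <- which(grepl(el_rx[e], peptides, perl = TRUE))
    list(elements = e, gaps = integer(0), rx = el_rx[[e]],
         p_pos = el_p[[e]], span = 1L, idx = idx)
  })
  evaluated <- list()
  n_tested <- length(vocab)  # the single-element screens count as tests
  for (k in 2:params$max_defined_positions) {
    nxt <- list()
    for (pat in frontier) {
      sub <- peptides[pat$idx]
      for (g in 0:min(params$max_wild, len - pat$span - 1L)) {
        gap_rx <- if (g == 0L) "" else sprintf(".{%d}", g)
        for (e in viable) {
          n_tested <- n_tested + 1L
          rx <- paste0(pat$rx, gap_rx, el_rx[[e]])
          hit <- grepl(rx, sub, perl = TRUE)
          sup <- sum(hit)
          if (sup < min_support) next
          span <- pat$span + g + 1L
          p_pos <- pat$p_pos * el_p[[e]]
          q <- 1 - (1 - p_pos)^(len - span + 1L)
          p <- pbinom(sup - 1L, n, q, lower.tail = FALSE)
          cand <- list(elements = c(pat$elements, e),
                       gaps = c(pat$gaps, g), rx = rx, p_pos = p_pos,
                       span = span, idx = pat$idx[hit],
                       support = sup, p = p)
          evaluated[[length(evaluated) + 1L]] <- cand
          if (k < params$max_defined_positions && p <= params$extend_p) {
            nxt[[length(nxt) + 1L]] <- cand
          }
        }
      }
    }
    if (length(nxt) > params$beam) {
      ord <- order(vapply(nxt, function(x) x$p, numeric(1)))
      nxt <- nxt[ord[seq_len(params$beam)]]
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  if (!length(evaluated)) return(empty)
  # The guided search implicitly selects from the full enumerable pattern
  # space, so each pattern is Bonferroni-corrected by the number of
  # patterns expressible at its depth: V defined-position choices times
  # G = max_wild + 1 gap choices per additional position.  Correcting only
  # by the candidates actually examined would ignore the selection bias of
  # the support floor and the guided extension.
  V <- length(vocab)
  G <- params$max_wild + 1L
  space_at <- function(k) V * (V * G)^(k - 1)
  out <- data.frame(
    pattern = vapply(evaluated, pattern_string, character(1)),
    regex = vapply(evaluated, function(x) x$rx, character(1)),
    support = vapply(evaluated, function(x) x$support, integer(1)),
    n = n,
    ic = vapply(evaluated, pattern_ic, numeric(1)),
    p = vapply(evaluated, function(x) x$p, numeric(1)),
    stringsAsFactors = FALSE)
  depth <- vapply(evaluated, function(x) length(x$elements), numeric(1))
  out$p_corrected <- pmin(1, out$p * space_at(depth))
  out$n_evaluated <- n_tested
  out <- out[out$ic >= params$min_ic & out$p_corrected <= params$sig_cutoff, ,
             drop = FALSE]
  out <- out[order(out$p_corrected, out$p, -out$ic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compile a consensus pattern into a matcher
#'
#' Grammar: residue literals; `x` or `.` wildcards; bracketed classes with
#' optional leading `^` negation; `{m,n}` repetition of the preceding
#' element; `^` and `$` anchors.
#'
#' @param consensus consensus string, e.g. `"[LMP]xLPx[FIL]"`.
#' @return a function taking a peptide and returning a matrix of match
#'   spans (columns start, end; 0 rows for no match).  The translated
#'   regular expression is in attribute `regex`, the per-position elements
#'   (for fixed-width consensi) in attribute `elements`.
#' @export
consensus_to_matcher <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  i <- 1L
  rx <- character(0)
  elements <- list()
  fixed_width <- TRUE
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "^") {
      if (i != 1L) stop("parse error at position ", i, ": '^' only anchors the start")
      rx <- c(rx, "^")
      i <- i + 1L
    } else if (ch == "$") {
      if (i != length(chars)) stop("parse error at position ", i,
                                   ": '$' only anchors the end")
      rx <- c(rx, "$")
      i <- i + 1L
    } else if (ch %in% c("x", ".")) {
      rx <- c(rx, ".")
      elements[[length(elements) + 1L]] <- "x"
      i <- i + 1L
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("parse error at position ", i, ": unclosed '['")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^\\^?[A-Z]+$", body)) {
        stop("parse error at position ", i, ": bad class [", body, "]")
      }
      rx <- c(rx, paste0("[", body, "]"))
      elements[[length(elements) + 1L]] <- body
      i <- j + 1L
    } else if (ch == "{") {
      j <- which(chars == "}" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("parse error at position ", i, ": unclosed '{'")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]+(,[0-9]+)?$", body) || !length(rx)) {
        stop("parse error at position ", i, ": bad repetition {", body, "}")
      }
      rx[length(rx)] <- paste0(rx[length(rx)], "{", body, "}")
      fixed_width <- fixed_width && !grepl(",", body)
      if (!grepl(",", body)) {
        rep_el <- elements[[length(elements)]]
        times <- as.integer(body)
        elements <- c(elements[-length(elements)],
                      rep(list(rep_el), times))
      }
      i <- j + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      rx <- c(rx, ch)
      elements[[length(elements) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("parse error at position ", i, ": unexpected '", ch, "'")
    }
  }
  regex <- paste(rx, collapse = "")
  width <- if (fixed_width) length(elements) else NA_integer_
  matcher <- function(peptide) {
    if (!is.na(width) && !grepl("^\\^|\\$$", regex)) {
      m <- gregexpr(paste0("(?=", regex, ")"), peptide, perl = TRUE)[[1]]
      if (m[1] == -1L) {
        return(matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("start", "end"))))
      }
      cbind(start = as.integer(m), end = as.integer(m) + width - 1L)
    } else {
      m <- gregexpr(regex, peptide, perl = TRUE)[[1]]
      if (m[1] == -1L) {
        return(matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("start", "end"))))
      }
      cbind(start = as.integer(m),
            end = as.integer(m) + attr(m, "match.length") - 1L)
    }
  }
  attr(matcher, "regex") <- regex
  attr(matcher, "elements") <- if (fixed_width)
    vapply(elements, identity, character(1)) else NULL
  matcher
}

#' Does a peptide match a consensus?
#'
#' @param peptides character vector.
#' @param consensus consensus string (see [consensus_to_matcher()]).
#' @return logical vector.
#' @export
matches_consensus <- function(peptides, consensus) {
  rx <- attr(consensus_to_matcher(consensus), "regex")
  grepl(rx, peptides, perl = TRUE)
}

#' Build a position-specific scoring matrix from aligned peptides
#'
#' Log-odds weights with a background-proportional pseudocount:
#' `weight(pos, aa) = log2((count + alpha * bg_aa) / ((n + alpha) * bg_aa))`.
#'
#' @param aligned character vector of equal-length peptides (>= 2).
#' @param background_freqs background amino-acid frequencies (defaults to
#'   uniform 1/20).
#' @param alpha pseudocount mass (default 1), apportioned by background.
#' @return an L x 20 numeric matrix of class `pssm` with the alignment size
#'   in attribute `n`.
#' @export
build_pssm <- function(aligned, background_freqs = NULL, alpha = 1) {
  if (length(aligned) < 2L) stop("need at least 2 aligned peptides")
  if (length(unique(nchar(aligned))) != 1L) stop("ragged alignment")
  bg <- background_freqs %||% setNames(rep(1 / 20, 20), AA20)
  bg <- bg[AA20] / sum(bg[AA20])
  L <- nchar(aligned[1])
  n <- length(aligned)
  mat <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  chs <- do.call(rbind, strsplit(aligned, ""))
  for (pos in seq_len(L)) {
    counts <- table(factor(chs[, pos], levels = AA20))
    mat[pos, ] <- unname(log2((as.numeric(counts) + alpha * bg) /
                                ((n + alpha) * bg)))
  }
  structure(mat, n = n, background = bg, class = c("pssm", "matrix", "array"))
}

# integer-encode sequences over AA20; non-standard residues -> NA
encode_aa <- function(seqs) {
  lapply(strsplit(seqs, ""), function(ch) match(ch, AA20))
}

#' Score peptides against a PSSM (best-window sum)
#'
#' @param peptides character vector with lengths >= the PSSM width.
#' @param pssm matrix from [build_pssm()].
#' @return numeric best-window scores (non-standard residues score the
#'   position's minimum weight).
#' @export
pssm_score <- function(peptides, pssm) {
  L <- nrow(pssm)
  mins <- apply(pssm, 1L, min)
  enc <- encode_aa(peptides)
  vapply(enc, function(idx) {
    nw <- length(idx) - L + 1L
    if (nw < 1L) return(NA_real_)
    best <- -Inf
    for (s in seq_len(nw)) {
      w <- idx[s:(s + L - 1L)]
      v <- pssm[cbind(seq_len(L), w)]
      v[is.na(w)] <- mins[is.na(w)]
      best <- max(best, sum(v))
    }
    best
  }, numeric(1))
}

# All length-L windows of a set of background sequences, integer-encoded.
background_windows <- function(seqs, L) {
  enc <- encode_aa(seqs)
  wins <- list()
  for (idx in enc) {
    nw <- length(idx) - L + 1L
    if (nw < 1L) next
    m <- matrix(NA_integer_, nrow = nw, ncol = L)
    for (j in seq_len(L)) m[, j] <- idx[j:(j + nw - 1L)]
    wins[[length(wins) + 1L]] <- m
  }
  if (!length(wins)) stop("background contains no window of width ", L)
  do.call(rbind, wins)
}

score_windows <- function(win_mat, pssm) {
  L <- nrow(pssm)
  mins <- apply(pssm, 1L, min)
  sc <- numeric(nrow(win_mat))
  for (j in seq_len(L)) {
    v <- pssm[j, win_mat[, j]]
    v[is.na(win_mat[, j])] <- mins[j]
    sc <- sc + v
  }
  sc
}

#' Empirical PSSM match p-value against a reversed-matrix background
#'
#' The specificity-determinant score of a peptide: its best-window PSSM
#' score is ranked against null scores obtained by scanning background
#' sequences with the position-reversed PSSM, with add-one smoothing
#' `p = (r + 1) / (N + 1)` where `r` is the number of null windows scoring
#' at least as high.
#'
#' @param peptides character vector.
#' @param pssm matrix from [build_pssm()].
#' @param background_seqs character vector of background sequences (e.g.,
#'   the disordered proteome); all their width-L windows form the null.
#' @return numeric p-values in `(0, 1]`, parallel to `peptides`.
#' @export
pssm_probability <- function(peptides, pssm, background_seqs) {
  if (!length(background_seqs)) stop("empty background")
  L <- nrow(pssm)
  rev_pssm <- pssm[L:1, , drop = FALSE]
  wins <- background_windows(background_seqs, L)
  null_scores <- sort(score_windows(wins, rev_pssm))
  N <- length(null_scores)
  obs <- pssm_score(peptides, pssm)
  r <- vapply(obs, function(s) sum(null_scores >= s), numeric(1))
  (r + 1) / (N + 1)
}

#' Binomial logo heights for an alignment
#'
#' Per position and residue, `-log10 P(X >= k)` for
#' `X ~ Binomial(n, p_aa)`, where `k` is the observed residue count, `n`
#' the number of aligned peptides and `p_aa` the residue's background
#' frequency; a residue absent from a column has height 0.
#'
#' @param aligned character vector of equal-length peptides.
#' @param background_freqs background amino-acid frequencies.
#' @param max_height optional clip for rendering (default Inf).
#' @return L x 20 matrix of heights (>= 0).
#' @export
logo_heights <- function(aligned, background_freqs = NULL, max_height = Inf) {
  if (!length(aligned)) stop("empty alignment")
  if (length(unique(nchar(aligned))) != 1L) stop("ragged alignment")
  bg <- background_freqs %||% setNames(rep(1 / 20, 20), AA20)
  bg <- bg[AA20] / sum(bg[AA20])
  L <- nchar(aligned[1])
  n <- length(aligned)
  chs <- do.call(rbind, strsplit(aligned, ""))
  out <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  for (pos in seq_len(L)) {
    k <- as.numeric(table(factor(chs[, pos], levels = AA20)))
    h <- -pbinom(k - 1, n, bg, lower.tail = FALSE, log.p = TRUE) / log(10)
    h[k == 0] <- 0
    out[pos, ] <- unname(pmin(h, max_height))
  }
  out
}
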