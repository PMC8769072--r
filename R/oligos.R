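# Reverse translation of designed peptides into sanitized, adapter-flanked
# coding oligonucleotides, and partitioning into synthesis pools.

#' Load a codon usage table
#'
#' Relative synonymous codon fractions per amino acid; frequencies are
#' renormalized per amino acid on load.  The shipped default is an
#' Escherichia coli K-12 usage table.
#'
#' @param path TSV with columns aa, codon, fraction (default: shipped table).
#' @return named list (by amino acid) of named numeric vectors
#'   (codon -> fraction, summing to 1).
#' @export
load_codon_usage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ecoli_codon_usage.tsv",
                        package = "proppd", mustWork = TRUE)
  }
  tab <- read_tsv_file(path)
  usage <- lapply(split(tab, tab$aa), function(d) {
    v <- setNames(d$fraction / sum(d$fraction), d$codon)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(names(v)), no.init.codon = TRUE))
    if (!all(aa == d$aa[1])) stop("codon table: codon does not encode its amino acid")
    v
  })
  usage
}

#' Oligonucleotide design constraints
#'
#' @param adapter5,adapter3 constant annealing adapters flanking the 48-nt
#'   coding insert.
#' @param forbidden_sites restriction sites that must not occur (SmaI/ApaI
#'   hexamers by default).
#' @param max_selfcomp maximum tolerated contiguous self-complementarity in
#'   nucleotides; reverse-complement matches of length
#'   `max_selfcomp + 1` or more are violations (default 7).
#' @param pool_size synthesis pool size (92918).
#' @param max_redesign_iter resampling attempts before a record is flagged.
#' @return a list of class `oligo_constraints`.
#' @export
oligo_constraints <- function(adapter5 = "CAGCCTCTTCATCTGGC",
                              adapter3 = "GGTGGAGGATCCGGAG",
                              forbidden_sites = c("GGGCCC", "CCCGGG"),
                              max_selfcomp = 7L, pool_size = 92918L,
                              max_redesign_iter = 50L) {
  stopifnot(pool_size > 0, max_selfcomp >= 1)
  structure(list(adapter5 = adapter5, adapter3 = adapter3,
                 forbidden_sites = forbidden_sites,
                 max_selfcomp = as.integer(max_selfcomp),
                 pool_size = as.integer(pool_size),
                 max_redesign_iter = as.integer(max_redesign_iter)),
            class = "oligo_constraints")
}

#' Reverse translate a peptide with codon-usage-weighted sampling
#'
#' Each codon is drawn independently with probability proportional to its
#' relative usage; a fixed seed makes the draw reproducible.
#'
#' @param peptide amino-acid string (standard residues).
#' @param usage codon usage table from [load_codon_usage()].
#' @param seed optional integer seed.
#' @return coding nucleotide string of length `3 * nchar(peptide)`.
#' @export
reverse_translate <- function(peptide, usage = load_codon_usage(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- strsplit(peptide, "")[[1]]
  missing <- setdiff(res, names(usage))
  if (length(missing)) stop("no codons for residue(s): ",
                            paste(missing, collapse = ", "))
  codons <- vapply(res, function(a) {
    u <- usage[[a]]
    if (length(u) == 1L) names(u) else sample(names(u), 1L, prob = u)
  }, character(1))
  paste(codons, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan an oligonucleotide for constraint violations
#'
#' Reports every forbidden-site occurrence, and every self-complementary
#' pair: a substring of length `max_selfcomp + 1` whose reverse complement
#' occurs elsewhere in the same oligo (an identical span, as for a palindrome
#' matching itself in place, is not a violation).  The scan covers the full
#' oligo including adapters, since a junction can create a site.
#'
#' @param oligo full nucleotide string.
#' @param constraints an [oligo_constraints()].
#' @return data.frame of violations with columns type, start, end, detail
#'   (0 rows when compliant).
#' @export
check_constraints <- function(oligo, constraints = oligo_constraints()) {
  out <- list()
  for (site in constraints$forbidden_sites) {
    hits <- gregexpr(site, oligo, fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      out[[length(out) + 1L]] <- data.frame(
        type = "forbidden_site", start = as.integer(hits),
        end = as.integer(hits) + nchar(site) - 1L, detail = site,
        stringsAsFactors = FALSE)
    }
  }
  k <- constraints$max_selfcomp + 1L
  L <- nchar(oligo)
  if (L >= k) {
    starts <- seq_len(L - k + 1L)
    kmers <- substring(oligo, starts, starts + k - 1L)
    uk <- unique(kmers)
    rcs <- setNames(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(uk))), uk)
    rc_of <- rcs[kmers]
    pos_of <- split(starts, kmers)
    for (i in starts) {
      js <- pos_of[[rc_of[i]]]
      js <- js[js != i]
      if (length(js)) {
        out[[length(out) + 1L]] <- data.frame(
          type = "self_complementarity", start = i, end = i + k - 1L,
          detail = sprintf("%s~%d", kmers[i], js[1]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(), start = integer(), end = integer(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Redesign an oligonucleotide until compliant
#'
#' Only codons overlapping a violating span are resampled (minimal
#' perturbation); the peptide translation is invariant.  When
#' `max_redesign_iter` resampling rounds do not produce a compliant oligo
#' the record is returned flagged, never silently dropped.
#'
#' @param insert_nt coding insert (multiple of 3 nt).
#' @param peptide the encoded peptide (translation invariant check).
#' @param usage codon usage table.
#' @param constraints an [oligo_constraints()].
#' @param seed optional integer seed.
#' @return list with `insert_nt`, `full_nt`, `compliant` (logical) and
#'   `iterations`.
#' @export
redesign <- function(insert_nt, peptide, usage = load_codon_usage(),
                     constraints = oligo_constraints(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a5 <- constraints$adapter5
  offset <- nchar(a5)
  ins_len <- nchar(insert_nt)
  full <- paste0(a5, insert_nt, constraints$adapter3)
  iter <- 0L
  repeat {
    viol <- check_constraints(full, constraints)
    if (!nrow(viol)) {
      return(list(insert_nt = insert_nt, full_nt = full,
                  compliant = TRUE, iterations = iter))
    }
    if (iter >= constraints$max_redesign_iter) {
      return(list(insert_nt = insert_nt, full_nt = full,
                  compliant = FALSE, iterations = iter))
    }
    iter <- iter + 1L
    # codons of the insert overlapping any violating span
    bad <- integer(0)
    for (i in seq_len(nrow(viol))) {
      s <- max(viol$start[i] - offset, 1L)
      e <- min(viol$end[i] - offset, ins_len)
      if (e >= 1L && s <= ins_len) {
        bad <- union(bad, ((s - 1L) %/% 3L + 1L):((e - 1L) %/% 3L + 1L))
      }
    }
    if (!length(bad)) {
      # violation lies entirely within the constant adapters; unfixable
      return(list(insert_nt = insert_nt, full_nt = full,
                  compliant = FALSE, iterations = iter))
    }
    codons <- substring(insert_nt, 3L * seq_len(ins_len %/% 3L) - 2L,
                        3L * seq_len(ins_len %/% 3L))
    res <- strsplit(peptide, "")[[1]]
    for (ci in bad) {
      u <- usage[[res[ci]]]
      codons[ci] <- if (length(u) == 1L) names(u) else
        sample(names(u), 1L, prob = u)
    }
    insert_nt <- paste(codons, collapse = "")
    full <- paste0(a5, insert_nt, constraints$adapter3)
  }
}

n_encodings <- function(peptide, usage) {
  prod(vapply(strsplit(peptide, "")[[1]],
              function(a) length(usage[[a]]), numeric(1)))
}

#' Emit k distinct synonymous encodings of one peptide
#'
#' Produces `k` nucleotide-distinct, constraint-compliant coding inserts of
#' the same peptide, as used for terminal peptides and for padding synthesis
#' pools with redundant copies.
#'
#' @param peptide amino-acid string.
#' @param usage codon usage table.
#' @param k number of distinct encodings required.
#' @param constraints an [oligo_constraints()].
#' @param seed optional integer seed.
#' @return data.frame with columns peptide, insert_nt, full_nt, synonym_index,
#'   compliant.
#' @export
emit_synonyms <- function(peptide, usage = load_codon_usage(), k = 2L,
                          constraints = oligo_constraints(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_encodings(peptide, usage) < k) {
    stop("peptide has fewer than ", k, " distinct encodings")
  }
  inserts <- character(0)
  fulls <- character(0)
  ok <- logical(0)
  attempts <- 0L
  max_attempts <- 50L * k
  while (length(inserts) < k && attempts < max_attempts) {
    attempts <- attempts + 1L
    rec <- redesign(reverse_translate(peptide, usage), peptide, usage,
                    constraints)
    if (rec$insert_nt %in% inserts) next
    inserts <- c(inserts, rec$insert_nt)
    fulls <- c(fulls, rec$full_nt)
    ok <- c(ok, rec$compliant)
  }
  if (length(inserts) < k) stop("could not generate ", k,
                                " distinct compliant encodings")
  data.frame(peptide = peptide, insert_nt = inserts, full_nt = fulls,
             synonym_index = seq_along(inserts), compliant = ok,
             stringsAsFactors = FALSE)
}

#' Design oligonucleotides for a peptide library
#'
#' Reverse translates every display peptide, sanitizes the resulting oligos
#' (restriction sites, self-complementarity) and flags records that resist
#' redesign.
#'
#' @param library library table from [design_library()] (needs a
#'   `display_seq` column) or a character vector of peptides.
#' @param usage codon usage table.
#' @param constraints an [oligo_constraints()].
#' @param seed integer seed for the stochastic codon choice.
#' @return data.frame with peptide, insert_nt, full_nt, synonym_index,
#'   compliant.
#' @export
design_oligos <- function(library, usage = load_codon_usage(),
                          constraints = oligo_constraints(), seed = 1L) {
  peptides <- if (is.data.frame(library)) library$display_seq else library
  set.seed(seed)
  recs <- lapply(peptides, function(p) {
    rec <- redesign(reverse_translate(p, usage), p, usage, constraints)
    data.frame(peptide = p, insert_nt = rec$insert_nt, full_nt = rec$full_nt,
               synonym_index = 1L, compliant = rec$compliant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Partition oligos into synthesis pools, padding with synonyms
#'
#' Oligos are split in stable input order into pools of `pool_size`; when
#' padding is possible, the last pool is filled to exactly `pool_size` with
#' redundant peptides encoded by distinct synonymous oligonucleotides.
#'
#' @param oligos data.frame from [design_oligos()].
#' @param constraints an [oligo_constraints()].
#' @param usage codon usage table (for padding synonyms).
#' @param seed integer seed.
#' @return `oligos` with a `pool_id` column, padded rows appended.
#' @export
partition_pools <- function(oligos, constraints = oligo_constraints(),
                            usage = load_codon_usage(), seed = 1L) {
  n <- nrow(oligos)
  if (n == 0L) {
    oligos$pool_id <- integer(0)
    return(oligos)
  }
  set.seed(seed)
  ps <- constraints$pool_size
  deficit <- (ps - n %% ps) %% ps
  pad <- list()
  i <- 1L
  syn_next <- tapply(oligos$synonym_index, oligos$peptide, max)
  max_attempts <- 20L * (n + deficit)
  while (deficit > 0L && i <= max_attempts) {
    pep <- oligos$peptide[(i - 1L) %% n + 1L]
    i <- i + 1L
    rec <- redesign(reverse_translate(pep, usage), pep, usage, constraints)
    existing <- c(oligos$insert_nt[oligos$peptide == pep],
                  vapply(pad, function(x) x$insert_nt, character(1)))
    if (rec$insert_nt %in% existing) next
    syn_next[pep] <- syn_next[pep] + 1L
    pad[[length(pad) + 1L]] <- data.frame(
      peptide = pep, insert_nt = rec$insert_nt, full_nt = rec$full_nt,
      synonym_index = unname(syn_next[pep]), compliant = rec$compliant,
      stringsAsFactors = FALSE)
    deficit <- deficit - 1L
  }
  out <- rbind(oligos, if (length(pad)) do.call(rbind, pad))
  out$pool_id <- (seq_len(nrow(out)) - 1L) %/% ps + 1L
  rownames(out) <- NULL
  out
}
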