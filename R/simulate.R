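# Synthetic fixtures: a proteome with ordered/disordered architecture and
# planted motif instances, plus barcoded selection reads with motif-carrier
# enrichment.  Everything downstream of the generator sees only standard
# inputs (sequences, tracks, tables, FASTQ); truth records are carried
# separately and never feed the pipeline.

# Residue background frequencies: globular-like vs disorder-promoting.
ordered_freqs <- function() {
  f <- c(A = 0.08, C = 0.02, D = 0.05, E = 0.06, F = 0.04, G = 0.07,
         H = 0.02, I = 0.06, K = 0.05, L = 0.10, M = 0.02, N = 0.04,
         P = 0.04, Q = 0.04, R = 0.05, S = 0.06, T = 0.05, V = 0.07,
         W = 0.015, Y = 0.035)
  f / sum(f)
}

disordered_freqs <- function() {
  f <- c(A = 0.08, C = 0.005, D = 0.06, E = 0.09, F = 0.015, G = 0.08,
         H = 0.02, I = 0.025, K = 0.07, L = 0.05, M = 0.015, N = 0.04,
         P = 0.09, Q = 0.06, R = 0.06, S = 0.10, T = 0.06, V = 0.04,
         W = 0.005, Y = 0.015)
  f / sum(f)
}

#' Simulation configuration for a synthetic selection campaign
#'
#' The defaults describe the standard validation scenario: 200 proteins of
#' 200-500 residues with roughly 40 percent disordered sequence, one planted
#' motif (consensus `PxLP`) carried by 10 percent of proteins inside a
#' disordered segment, three replicate selections sequenced on two days at
#' 50,000 reads per sample, a 0.5 percent per-base substitution error rate
#' and a 5 percent admixture of low-quality reads.  The default
#' `enrichment_factor` of 1000 represents the compounded over-representation
#' of binding clones after several rounds of selection, under which
#' non-binding clones are largely washed out of the sequenced pool - the
#' regime a real binding-enriched phage pool is in.
#'
#' @param n_proteins number of proteins.
#' @param length_range protein length range (uniform).
#' @param fraction_disordered probability that a segment is disordered.
#' @param consensus planted motif consensus (fixed-width grammar of
#'   [consensus_to_matcher()]).
#' @param carrier_fraction fraction of proteins carrying one instance.
#' @param enrichment_factor read-weight fold of motif-carrier peptides.
#' @param n_replicates replicate selections.
#' @param n_days sequenced selection days per replicate.
#' @param reads_per_sample reads per (replicate, day) sample.
#' @param error_rate per-base substitution probability.
#' @param low_quality_fraction fraction of reads emitted below the mean
#'   quality threshold.
#' @param abundance_sd log-normal spread of per-replicate phage abundances.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 200L, length_range = c(200L, 500L),
                              fraction_disordered = 0.4, consensus = "PxLP",
                              carrier_fraction = 0.1,
                              enrichment_factor = 1000,
                              n_replicates = 3L, n_days = 2L,
                              reads_per_sample = 50000L, error_rate = 0.005,
                              low_quality_fraction = 0.05,
                              abundance_sd = 1.5) {
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1,
            fraction_disordered >= 0, fraction_disordered <= 1,
            enrichment_factor >= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 fraction_disordered = fraction_disordered,
                 consensus = consensus,
                 carrier_fraction = carrier_fraction,
                 enrichment_factor = enrichment_factor,
                 n_replicates = as.integer(n_replicates),
                 n_days = as.integer(n_days),
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate,
                 low_quality_fraction = low_quality_fraction,
                 abundance_sd = abundance_sd),
            class = "simulation_config")
}

sample_residues <- function(n, freqs) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# concrete instance of a fixed-width consensus
instance_of <- function(consensus, freqs) {
  el <- attr(consensus_to_matcher(consensus), "elements")
  if (is.null(el)) stop("planted consensus must be fixed-width")
  paste(vapply(el, function(e) {
    if (e == "x") sample(names(freqs), 1, prob = freqs)
    else if (nchar(e) == 1L) e
    else sample(strsplit(e, "")[[1]], 1)
  }, character(1)), collapse = "")
}

#' Generate a synthetic proteome fixture
#'
#' Proteins are built from alternating segments whose disorder scores
#' straddle the 0.4 cutoff (disordered segments score 0.45-0.95, ordered
#' 0.02-0.38), with disorder-promoting residue composition inside disordered
#' segments.  One concrete instance of the planted consensus is written into
#' a disordered segment of each carrier protein and recorded in the truth
#' table.  Localization keywords, GO terms, a paralogue cluster map (with a
#' few duplicated-sequence paralogue pairs) and a GO annotation table are
#' generated alongside.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; fixed seeds give byte-identical fixtures.
#' @return list with `records` (list of [protein_record()]), `sequences`
#'   (named character), `tracks` (per-accession disorder tracks),
#'   `annotation` (data.frame), `go` (term/accession data.frame),
#'   `cluster_map` (named character) and `truth` (list with `instances`
#'   data.frame and `carriers`).
#' @export
make_proteome <- function(cfg = simulation_config(), seed = 1L) {
  set.seed(seed)
  of <- ordered_freqs()
  df <- disordered_freqs()
  n <- cfg$n_proteins
  accs <- sprintf("SP%04d", seq_len(n))
  n_carriers <- round(cfg$carrier_fraction * n)
  carriers <- if (n_carriers) sort(sample(n, n_carriers)) else integer(0)
  sequences <- character(n)
  tracks <- vector("list", n)
  inst_rows <- list()
  kw_list <- vector("list", n)
  go_list <- vector("list", n)
  go_vocab <- c("GO:0005634", "GO:0005737", "GO:0012505", "GO:0005576",
                "GO:0008150", "GO:0003674", "GO:0005515", "GO:0016301")
  for (i in seq_len(n)) {
    L <- sample(cfg$length_range[1]:cfg$length_range[2], 1)
    seqs <- character(0)
    scores <- numeric(0)
    dis_flags <- logical(0)
    while (sum(nchar(seqs)) < L) {
      seg_len <- sample(30:80, 1)
      dis <- runif(1) < cfg$fraction_disordered
      seqs <- c(seqs, sample_residues(seg_len, if (dis) df else of))
      scores <- c(scores, if (dis) runif(seg_len, 0.45, 0.95)
                  else runif(seg_len, 0.02, 0.38))
      dis_flags <- c(dis_flags, rep(dis, seg_len))
    }
    s <- paste(seqs, collapse = "")
    s <- substr(s, 1, L)
    scores <- scores[seq_len(L)]
    dis_flags <- dis_flags[seq_len(L)]
    if (i %in% carriers) {
      span <- length(attr(consensus_to_matcher(cfg$consensus), "elements"))
      runs <- mask_to_spans(dis_flags)
      runs <- runs[runs[, 2] - runs[, 1] + 1L >= 16L + span, , drop = FALSE]
      if (nrow(runs)) {
        r <- runs[sample.int(nrow(runs), 1), ]
        cand <- (r[1] + 6L):(r[2] - span - 6L + 1L)
        pos <- cand[sample.int(length(cand), 1)]
        inst <- instance_of(cfg$consensus, df)
        substr(s, pos, pos + span - 1L) <- inst
        inst_rows[[length(inst_rows) + 1L]] <- data.frame(
          accession = accs[i], start = pos, end = pos + span - 1L,
          instance = inst, stringsAsFactors = FALSE)
      }
    }
    sequences[i] <- s
    tracks[[i]] <- list(disorder = scores)
    kw <- sample(c("Cytoplasm", "Nucleus", "Membrane"), 1,
                 prob = c(0.6, 0.3, 0.1))
    if (i %in% carriers) kw <- "Cytoplasm"
    kw_list[[i]] <- kw
    go_list[[i]] <- sample(go_vocab, sample(1:3, 1))
  }
  names(sequences) <- names(tracks) <- accs
  # a few paralogue pairs: duplicate a disordered stretch between neighbours
  cluster_map <- setNames(accs, accs)
  n_para <- max(1L, n %/% 50L)
  para_from <- sample(setdiff(seq_len(n), carriers), n_para)
  for (i in para_from) {
    j <- if (i < n) i + 1L else i - 1L
    cluster_map[accs[j]] <- accs[i]
  }
  annotation <- data.frame(
    accession = accs,
    keywords = vapply(kw_list, paste, character(1), collapse = ";"),
    go_terms = vapply(go_list, paste, character(1), collapse = ";"),
    tm_spans = "", extracellular_spans = "",
    stringsAsFactors = FALSE)
  go <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(term = go_list[[i]], accession = accs[i],
               stringsAsFactors = FALSE)))
  records <- lapply(seq_len(n), function(i)
    protein_record(accs[i], sequences[i], keywords = kw_list[[i]],
                   go_terms = go_list[[i]]))
  truth <- list(
    instances = if (length(inst_rows)) do.call(rbind, inst_rows) else
      data.frame(accession = character(), start = integer(),
                 end = integer(), instance = character(),
                 stringsAsFactors = FALSE),
    carriers = accs[carriers])
  list(records = records, sequences = sequences, tracks = tracks,
       annotation = annotation, go = go, cluster_map = cluster_map,
       truth = truth, cfg = cfg)
}

# deterministic barcode set: base-4 digit blocks, pairwise Hamming >= block
make_barcodes <- function(n, block = 3L) {
  digits <- 2L
  while (4^digits < n) digits <- digits + 1L
  letters4 <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    d <- integer(digits)
    for (k in seq_len(digits)) {
      d[k] <- i %% 4L
      i <- i %/% 4L
    }
    paste(strrep(letters4[d + 1L], block), collapse = "")
  }, character(1))
}

#' Simulate a binding-enriched selection campaign
#'
#' Reads are multinomially sampled from the library's coding oligos with
#' motif-carrier oligos up-weighted by `enrichment_factor` and a log-normal
#' per-replicate abundance spread emulating clonal phage amplification.
#' Substitution errors are applied at the configured per-base rate, and a
#' configured fraction of reads carries sub-threshold quality strings.  Days
#' within a replicate share the replicate's phage pool.
#'
#' @param library design table from [design_library()].
#' @param oligos oligo table from [design_oligos()] for `library` (built on
#'   the fly when NULL).
#' @param cfg a [simulation_config()].
#' @param seed integer seed.
#' @return list with `reads` (list of seq/qual/id vectors), `scheme`
#'   (a [barcode_scheme()]), `sample_key` (data.frame with sample,
#'   barcode5, barcode3, bait, replicate, day), `truth_counts` (per-sample
#'   named true read counts per peptide) and `carrier_peptides`.
#' @export
simulate_selection <- function(library, oligos = NULL,
                               cfg = simulation_config(), seed = 1L) {
  set.seed(seed)
  if (is.null(oligos)) oligos <- design_oligos(library, seed = seed)
  constraints <- oligo_constraints()
  rx <- attr(consensus_to_matcher(cfg$consensus), "regex")
  carrier <- grepl(rx, oligos$peptide, perl = TRUE)
  b5 <- make_barcodes(cfg$n_replicates)
  b3 <- make_barcodes(cfg$n_days)
  names(b5) <- sprintf("R%d", seq_len(cfg$n_replicates))
  names(b3) <- sprintf("D%d", seq_len(cfg$n_days))
  scheme <- barcode_scheme(b5, b3, adapter5 = constraints$adapter5,
                           adapter3 = constraints$adapter3)
  sample_key <- expand.grid(replicate = seq_len(cfg$n_replicates),
                            day = seq_len(cfg$n_days))
  sample_key <- sample_key[order(sample_key$replicate, sample_key$day), ]
  sample_key$sample <- sprintf("rep%d_day%d", sample_key$replicate,
                               sample_key$day)
  sample_key$barcode5 <- names(b5)[sample_key$replicate]
  sample_key$barcode3 <- names(b3)[sample_key$day]
  sample_key$bait <- "BAIT1"
  rownames(sample_key) <- NULL

  n_oligo <- nrow(oligos)
  base_w <- ifelse(carrier, cfg$enrichment_factor, 1)
  seqs <- character(0)
  quals <- character(0)
  ids <- character(0)
  truth_counts <- list()
  read_len <- nchar(b5[1]) + nchar(scheme$adapter5) + 48L +
    nchar(scheme$adapter3) + nchar(b3[1])
  hi_q <- strrep(rawToChar(as.raw(33L + 37L)), read_len)   # Q37
  lo_q <- strrep(rawToChar(as.raw(33L + 12L)), read_len)   # Q12
  for (r in seq_len(cfg$n_replicates)) {
    w <- base_w * exp(rnorm(n_oligo, 0, cfg$abundance_sd))
    for (d in seq_len(cfg$n_days)) {
      nm <- sprintf("rep%d_day%d", r, d)
      pick <- sample.int(n_oligo, cfg$reads_per_sample, replace = TRUE,
                         prob = w)
      tc <- table(oligos$peptide[pick])
      truth_counts[[nm]] <- setNames(as.integer(tc), names(tc))
      reads <- paste0(b5[r], scheme$adapter5, oligos$insert_nt[pick],
                      scheme$adapter3, b3[d])
      # substitution errors
      n_err <- rbinom(length(reads), read_len, cfg$error_rate)
      for (pass in seq_len(max(n_err, 0))) {
        idx <- which(n_err >= pass)
        if (!length(idx)) break
        pos <- sample.int(read_len, length(idx), replace = TRUE)
        cur <- substr(reads[idx], pos, pos)
        ci <- match(cur, c("A", "C", "G", "T"))
        newb <- c("A", "C", "G", "T")[
          ((ci - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L]
        substr(reads[idx], pos, pos) <- newb
      }
      q <- ifelse(runif(length(reads)) < cfg$low_quality_fraction, lo_q, hi_q)
      seqs <- c(seqs, reads)
      quals <- c(quals, q)
      ids <- c(ids, sprintf("%s_read%d", nm, seq_along(reads)))
    }
  }
  list(reads = list(seq = seqs, qual = quals, id = ids), scheme = scheme,
       sample_key = sample_key, truth_counts = truth_counts,
       carrier_peptides = unique(oligos$peptide[carrier]), oligos = oligos)
}

#' Write simulated reads as FASTQ
#'
#' @param reads `reads` element from [simulate_selection()].
#' @param path output FASTQ path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Write a proteome fixture to standard files
#'
#' Emits FASTA, annotation TSV, disorder-track TSV, GO TSV and cluster-map
#' TSV into a directory.
#'
#' @param fixture result of [make_proteome()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_proteome_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(fixture$sequences)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteome.fasta"))
  write_tsv_file(fixture$annotation, file.path(dir, "annotation.tsv"))
  tr <- do.call(rbind, lapply(names(fixture$tracks), function(acc)
    data.frame(accession = acc,
               position = seq_along(fixture$tracks[[acc]]$disorder),
               score = fixture$tracks[[acc]]$disorder, source = "predicted",
               stringsAsFactors = FALSE)))
  write_tsv_file(tr, file.path(dir, "disorder.tsv"))
  write_tsv_file(fixture$go, file.path(dir, "go.tsv"))
  write_tsv_file(data.frame(accession = names(fixture$cluster_map),
                            representative = unname(fixture$cluster_map),
                            stringsAsFactors = FALSE),
                 file.path(dir, "clusters.tsv"))
  invisible(dir)
}
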