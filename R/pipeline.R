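# End-to-end orchestration of a single bait screen: demultiplex, count,
# normalize, merge, map, discover motifs, score, classify.

#' Analyze one ProP-PD screen from reads to confidence levels
#'
#' Runs the full per-bait pipeline: demultiplexing, translation, singleton
#' removal, per-sample normalization, day pooling, replicate merging,
#' proteome mapping with paralogue collapse, motif enrichment on the
#' replicated peptides, PSSM construction from the top motif's aligned
#' matches, specificity-determinant p-values against a reversed-PSSM
#' proteome background, and the four-criterion confidence classification.
#'
#' @param reads FASTQ path or list with `seq`/`qual` vectors.
#' @param scheme a [barcode_scheme()].
#' @param sample_key data.frame with sample, barcode5, barcode3, replicate,
#'   day.
#' @param proteome named character vector of protein sequences.
#' @param cluster_map named accession -> representative map.
#' @param params a [motif_params()].
#' @param criteria a [confidence_criteria()].
#' @param background_seqs sequences for the PSSM null model (defaults to
#'   the proteome).
#' @return list with `table` (per-peptide metrics + confidence), `motifs`,
#'   `pssm`, `hits`, `demux_log`, `qc`, `normalized`, `replicate_tables`.
#' @export
analyze_screen <- function(reads, scheme, sample_key, proteome,
                           cluster_map = character(),
                           params = motif_params(),
                           criteria = confidence_criteria(),
                           background_seqs = NULL) {
  dm <- demultiplex(reads, scheme, sample_key)
  tc <- translate_counts(dm$samples, insert_len = scheme$insert_len)
  counts <- drop_singletons(tc$counts)
  norm <- normalize_counts(counts)
  rep_samples <- split(sample_key$sample, sample_key$replicate)
  rep_tables <- list()
  for (r in names(rep_samples)) {
    present <- intersect(rep_samples[[r]], names(norm))
    if (!length(present)) next
    rep_tables[[r]] <- pool_replicate_days(norm[present])
  }
  if (!length(rep_tables)) stop("no sample yielded any peptide")
  merged <- merge_replicates(rep_tables)
  hits <- collapse_paralogues(map_peptides(merged$peptide, proteome),
                              cluster_map)
  # motif discovery runs on proteome-mapped peptides only: unmappable reads
  # (dominated by recurrent sequencing errors of abundant clones) carry no
  # positional information and would inflate sequence-similarity patterns
  mapped <- unique(hits$peptide)
  replicated <- intersect(merged$peptide[merged$n_replicates >= 2L], mapped)
  motif_input <- if (length(replicated) >= 5L) replicated else
    intersect(merged$peptide, mapped)
  motifs <- find_enriched_motifs(motif_input, params = params)
  pssm <- NULL
  if (nrow(motifs)) {
    matcher_rx <- motifs$regex[1]
    m <- regexpr(matcher_rx, motif_input, perl = TRUE)
    matched <- m != -1L
    aligned <- substring(motif_input[matched], m[matched],
                         m[matched] + attr(m, "match.length")[matched] - 1L)
    aligned <- aligned[nchar(aligned) == max(nchar(aligned))]
    if (length(unique(aligned)) >= 2L || length(aligned) >= 2L) {
      pssm <- build_pssm(aligned, aa_frequencies(motif_input))
    }
  }
  bg <- background_seqs %||% unname(proteome)
  table <- if (is.null(pssm)) {
    compute_metrics(merged, hits)
  } else {
    compute_metrics(merged, hits, pssm, bg)
  }
  table <- assign_confidence(table, criteria)
  list(table = table, motifs = motifs, pssm = pssm, hits = hits,
       demux_log = dm$log, qc = tc$qc, normalized = norm,
       replicate_tables = rep_tables)
}
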