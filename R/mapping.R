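# Peptide-to-proteome mapping, replicate merging, overlap annotation,
# paralogue collapsing and variant/PTM site classification.

#' Map peptides to a proteome with the alanine wildcard rule
#'
#' Reports every exact occurrence of each peptide in the proteome, where an
#' alanine in the peptide may match either alanine or cysteine in the
#' proteome (library cysteines were rewritten to alanine at design time; the
#' wildcard applies peptide-side only).
#'
#' @param peptides character vector of peptide sequences.
#' @param proteome named character vector of protein sequences
#'   (accession -> sequence).
#' @return data.frame with columns peptide, accession, start, end.
#' @export
map_peptides <- function(peptides, proteome) {
  stopifnot(!is.null(names(proteome)))
  # scan one concatenated sequence (separator cannot match any residue),
  # then project global matches back to per-protein coordinates
  lens <- nchar(proteome)
  offsets <- cumsum(c(0L, lens + 1L))[seq_along(proteome)]
  big <- paste(proteome, collapse = "#")
  pats <- gsub("A", "[AC]", peptides, fixed = TRUE)
  rows <- lapply(seq_along(peptides), function(i) {
    pat <- paste0("(?=", pats[i], ")")  # lookahead: overlapping occurrences
    m <- gregexpr(pat, big, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    g <- as.integer(m)
    pi <- findInterval(g, offsets + 1L)
    start <- g - offsets[pi]
    data.frame(peptide = peptides[i], accession = names(proteome)[pi],
               start = start, end = start + nchar(peptides[i]) - 1L,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(peptide = character(), accession = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge per-replicate selections into one peptide table
#'
#' @param replicate_tables list of named numeric vectors, one per replicate
#'   selection: peptide -> per-replicate mean normalized count.
#' @return data.frame with peptide, n_replicates and mean_norm_count (mean
#'   over the replicates containing the peptide).
#' @export
merge_replicates <- function(replicate_tables) {
  stopifnot(length(replicate_tables) >= 1L)
  peps <- unique(unlist(lapply(replicate_tables, names)))
  n_rep <- integer(length(peps))
  total <- numeric(length(peps))
  names(n_rep) <- names(total) <- peps
  for (r in replicate_tables) {
    n_rep[names(r)] <- n_rep[names(r)] + 1L
    total[names(r)] <- total[names(r)] + r
  }
  data.frame(peptide = peps, n_replicates = unname(n_rep),
             mean_norm_count = unname(total / pmax(n_rep, 1L)),
             stringsAsFactors = FALSE)
}

#' Count overlapping peptides via shared protein mappings
#'
#' For each peptide, the number of distinct other peptide sequences (across
#' all replicates of the same bait) whose mapping shares at least one
#' residue of a common protein.  Identical sequences found in several
#' replicates are replication, not overlap.
#'
#' @param peptides character vector of (unique) peptide sequences.
#' @param hits mapping table from [map_peptides()] covering `peptides`.
#' @return integer vector of n_overlapping, parallel to `peptides`.
#' @export
count_overlaps <- function(peptides, hits) {
  sets <- new.env(parent = emptyenv())
  hits <- hits[hits$peptide %in% peptides, , drop = FALSE]
  for (acc in unique(hits$accession)) {
    h <- hits[hits$accession == acc, , drop = FALSE]
    if (nrow(h) < 2L) next
    for (i in seq_len(nrow(h))) {
      j <- h$start <= h$end[i] & h$end >= h$start[i] & h$peptide != h$peptide[i]
      if (!any(j)) next
      p <- h$peptide[i]
      prev <- if (exists(p, envir = sets)) get(p, envir = sets) else character(0)
      assign(p, union(prev, h$peptide[j]), envir = sets)
    }
  }
  vapply(peptides, function(p) {
    if (exists(p, envir = sets)) length(get(p, envir = sets)) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Collapse paralogous hits to a primary accession
#'
#' Hits to several members of one sequence-similarity cluster (UniRef-style)
#' collapse to the cluster representative, so benchmark counting is not
#' inflated by sibling paralogues.  Accessions absent from the map fall back
#' to themselves.
#'
#' @param hits mapping table from [map_peptides()].
#' @param cluster_map named character vector: accession -> representative.
#' @return `hits` with a `primary_accession` column, de-duplicated per
#'   (peptide, primary_accession, start, end).
#' @export
collapse_paralogues <- function(hits, cluster_map = character()) {
  rep_of <- cluster_map[hits$accession]
  rep_of[is.na(rep_of)] <- hits$accession[is.na(rep_of)]
  hits$primary_accession <- unname(rep_of)
  hits[!duplicated(hits[, c("peptide", "primary_accession", "start", "end")]), ,
       drop = FALSE]
}

#' Classify annotated sites against motif key positions
#'
#' Each site annotation (variant or phosphosite) falling inside a mapped
#' peptide is classified as hitting a key specificity-determinant position
#' (a defined position of the consensus match), a flank (within 2 residues
#' of a key position), or outside.
#'
#' @param hit one row of a mapping table (accession, start, end).
#' @param key_positions integer protein coordinates of the defined consensus
#'   positions within the peptide.
#' @param annotations data.frame with accession, position, kind, payload.
#' @param flank flank width around key positions (2).
#' @return `annotations` restricted to the peptide span, with a `class`
#'   column in {key-position, flank, outside}; sites outside the span are
#'   dropped.
#' @export
annotate_motif_sites <- function(hit, key_positions, annotations, flank = 2L) {
  ann <- annotations[annotations$accession == hit$accession &
                       annotations$position >= hit$start &
                       annotations$position <= hit$end, , drop = FALSE]
  if (!nrow(ann)) {
    ann$class <- character(0)
    return(ann)
  }
  dist <- vapply(ann$position, function(p) {
    if (!length(key_positions)) Inf else min(abs(p - key_positions))
  }, numeric(1))
  ann$class <- ifelse(dist == 0, "key-position",
                      ifelse(dist <= flank, "flank", "outside"))
  ann
}
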