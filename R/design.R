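# Search-space definition, 16-mer tiling and sublibrary assignment.

#' Define the retained search-space regions of a protein
#'
#' Retains the union of all 16-mer windows containing at least
#' `window_min_accessible` accessible residues, merged into maximal
#' contiguous regions.  Accessible loops of length `min_loop_len` to
#' `window_len - 1` that escaped the window rule are extended symmetrically
#' into flanking sequence to reach `window_len` when the protein allows it.
#'
#' @param accessible finalized logical accessibility track.
#' @param cfg an [accessibility_config()].
#' @return two-column matrix of retained (start, end) regions, each of
#'   length >= `window_len`.
#' @export
define_search_space <- function(accessible, cfg = accessibility_config()) {
  L <- length(accessible)
  acc <- accessible & !is.na(accessible)
  w <- cfg$window_len
  mask <- rep(FALSE, L)
  if (L >= w) {
    cs <- cumsum(c(0L, as.integer(acc)))
    starts <- seq_len(L - w + 1L)
    keep <- (cs[starts + w] - cs[starts]) >= cfg$window_min_accessible
    # mark covered residues via a difference array
    d <- integer(L + 1L)
    for (s in starts[keep]) {
      d[s] <- d[s] + 1L
      d[s + w] <- d[s + w] - 1L
    }
    mask <- cumsum(d[seq_len(L)]) > 0L
  }
  regions <- mask_to_spans(mask)
  # short disordered loops: pad to window length where possible
  if (L >= w) {
    runs <- mask_to_spans(acc)
    if (nrow(runs)) {
      lens <- runs[, 2] - runs[, 1] + 1L
      for (i in which(lens >= cfg$min_loop_len & lens < w)) {
        covered <- nrow(regions) &&
          any(regions[, 1] <= runs[i, 2] & regions[, 2] >= runs[i, 1])
        if (covered) next
        pad <- w - lens[i]
        s <- runs[i, 1] - pad %/% 2L
        e <- runs[i, 2] + (pad - pad %/% 2L)
        if (s < 1L) { e <- e + (1L - s); s <- 1L }
        if (e > L)  { s <- s - (e - L); e <- L }
        regions <- rbind(regions, c(s, e))
      }
    }
  }
  if (nrow(regions)) merge_spans(regions) else regions
}

#' Tile a region into 16-mer peptides
#'
#' Windows start at the region start and advance by `tiling_step` (4, i.e.,
#' an overlap of 12).  When the last stepped window does not reach the region
#' end, an extra window anchored at the end is emitted so the terminus is
#' covered.  Cysteines are replaced by alanine in the display sequence.
#'
#' @param region (start, end) vector, length >= `window_len`.
#' @param sequence full protein sequence.
#' @param cfg an [accessibility_config()].
#' @return data.frame with start, end, native_seq, display_seq.
#' @export
tile_region <- function(region, sequence, cfg = accessibility_config()) {
  w <- cfg$window_len
  rs <- region[1]; re <- region[2]
  stopifnot(re - rs + 1L >= w)
  last <- re - w + 1L
  starts <- seq.int(rs, last, by = cfg$tiling_step)
  if (starts[length(starts)] != last) starts <- c(starts, last)
  native <- substring(sequence, starts, starts + w - 1L)
  data.frame(start = starts, end = starts + w - 1L,
             native_seq = native,
             display_seq = gsub("C", "A", native, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Keyword/GO rule sets for the five protein pools
#'
#' GO identifiers are compared against the protein's ancestor-closed term
#' set, so descendant terms are matched through the closure.
#'
#' @return named list of pool rules, each with `go` and `keywords`.
#' @export
sublibrary_rules <- function() {
  list(
    Endomembrane = list(
      go = "GO:0012505",  # endomembrane system
      keywords = c("Endoplasmic reticulum membrane", "Endoplasmic reticulum",
                   "Golgi apparatus membrane", "Golgi apparatus",
                   "Golgi cisterna membrane", "Golgi membrane",
                   "ER to Golgi transport vesicle membrane",
                   "Cytoplasmic vesicle membrane", "Cytoplasmic vesicle",
                   "Early endosome membrane", "Early endosome",
                   "Endosome membrane", "Late endosome membrane",
                   "Late endosome", "Recycling endosome membrane")),
    Nuclear = list(
      go = c("GO:0005634", "GO:0005694"),  # nucleus, chromosome
      keywords = c("Nucleus", "Chromosome")),
    Cytoplasmic = list(
      # cytoplasm, mitochondrion, cytoskeleton, cilium, plasma membrane
      go = c("GO:0005737", "GO:0005739", "GO:0005856", "GO:0005929",
             "GO:0005886"),
      keywords = c("Cytoplasm", "Cell membrane", "Membrane")),
    Extracellular = list(
      go = c("GO:0005576", "GO:0044421"),  # extracellular region (+ part)
      keywords = c("extracellular space", "extracellular exosome",
                   "extracellular region", "exocyst",
                   "endoplasmic reticulum lumen",
                   "Endoplasmic reticulum lumen")))
}

#' Assign a protein to its sublibrary
#'
#' Proteins are first assigned to pools (Endomembrane, Nuclear, Cytoplasmic,
#' Extracellular) by keyword/GO rules, then to one of six sublibraries:
#' Nuclear plus Cytoplasmic or Endomembrane gives "Nucleocytoplasmic
#' shuttling"; Nuclear alone "Nucleus"; Endomembrane "Endomembrane System";
#' Cytoplasmic alone "Cytoplasm"; Extracellular requires no other pool and no
#' transmembrane region; unannotated proteins fall into "Other".
#'
#' @param protein a [protein_record()] with ancestor-closed GO terms.
#' @param rules rule sets, see [sublibrary_rules()].
#' @return list with `pools` (character vector) and `sublibrary` (string).
#' @export
assign_sublibrary <- function(protein, rules = sublibrary_rules()) {
  in_pool <- function(rule) {
    any(rule$go %in% protein$go_terms) || any(rule$keywords %in% protein$keywords)
  }
  endo <- in_pool(rules$Endomembrane)
  nuc <- in_pool(rules$Nuclear)
  cyt <- in_pool(rules$Cytoplasmic)
  extra <- !endo && !nuc && !cyt && nrow(protein$tm_spans) == 0L &&
    in_pool(rules$Extracellular)
  pools <- c("Endomembrane", "Nuclear", "Cytoplasmic", "Extracellular")[
    c(endo, nuc, cyt, extra)]
  sublibrary <-
    if (nuc && (cyt || endo)) "Nucleocytoplasmic shuttling"
    else if (nuc) "Nucleus"
    else if (endo) "Endomembrane System"
    else if (cyt) "Cytoplasm"
    else if (extra) "Extracellular"
    else "Other"
  list(pools = pools, sublibrary = sublibrary)
}

# Build the finalized accessibility track for one protein.
# Pass order: binarize -> merge hierarchy -> smooth -> order islands,
# each smoothing pass restricted to chain/topology segments when present;
# hard constraints (nonstandard residues, TM/extracellular removal) are
# applied after smoothing so they can never be smoothed away.
finalize_track <- function(protein, disorder, sa = NULL, sa_source = NULL,
                           cfg = accessibility_config()) {
  L <- nchar(protein$sequence)
  stopifnot(length(disorder) == L)
  predicted <- binarize_disorder(disorder, cfg)
  experimental <- if (is.null(sa)) rep(NA, L) else binarize_sa(sa, cfg)
  merged <- merge_hierarchy(predicted, experimental, sa_source)
  acc <- merged$accessible
  segs <- if (is.null(protein$chain_spans) || nrow(protein$chain_spans) == 0L) {
    matrix(c(1L, L), ncol = 2)
  } else protein$chain_spans
  for (i in seq_len(nrow(segs))) {
    idx <- segs[i, 1]:segs[i, 2]
    acc[idx] <- include_order_islands(smooth_track(acc[idx], cfg), cfg)
  }
  res <- strsplit(protein$sequence, "")[[1]]
  acc[res %in% c("X", "U")] <- FALSE
  intra <- strip_extracellular(protein)
  keep <- rep(FALSE, L)
  if (nrow(intra)) for (i in seq_len(nrow(intra))) keep[intra[i, 1]:intra[i, 2]] <- TRUE
  acc <- acc & keep
  list(accessible = acc, source = merged$source)
}

#' Design a tiled peptide library over a proteome
#'
#' Orchestrates search-space definition and tiling for every protein:
#' disorder binarization, the experimental-over-predicted accessibility
#' hierarchy, smoothing, order-island inclusion, the 8-of-16 window rule,
#' tiling into 16-mers overlapping by 12, Cys-to-Ala display conversion and
#' sublibrary assignment.  Duplicate display sequences are collapsed to one
#' row whose `provenance` column retains every source occurrence.
#'
#' @param proteome list of [protein_record()] objects.
#' @param tracks named list (by accession), each element a list with numeric
#'   `disorder` and optional `sa` / `sa_source` tracks.
#' @param cfg an [accessibility_config()].
#' @return data.frame with columns accession, start, end, native_seq,
#'   display_seq, region_id, sublibrary, provenance.
#' @export
design_library <- function(proteome, tracks, cfg = accessibility_config()) {
  rows <- list()
  for (p in proteome) {
    tr <- tracks[[p$accession]]
    if (is.null(tr)) stop("no track for ", p$accession)
    fin <- finalize_track(p, tr$disorder, tr$sa, tr$sa_source, cfg)
    regions <- define_search_space(fin$accessible, cfg)
    if (!nrow(regions)) next
    sub <- assign_sublibrary(p)$sublibrary
    for (i in seq_len(nrow(regions))) {
      tiles <- tile_region(regions[i, ], p$sequence, cfg)
      tiles <- tiles[!grepl("[XU]", tiles$native_seq), , drop = FALSE]
      if (!nrow(tiles)) next
      tiles$accession <- p$accession
      tiles$region_id <- sprintf("%s_r%d", p$accession, i)
      tiles$sublibrary <- sub
      rows[[length(rows) + 1L]] <- tiles
    }
  }
  if (!length(rows)) {
    return(data.frame(accession = character(), start = integer(),
                      end = integer(), native_seq = character(),
                      display_seq = character(), region_id = character(),
                      sublibrary = character(), provenance = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[, c("accession", "start", "end", "native_seq", "display_seq",
                 "region_id", "sublibrary")]
  prov <- sprintf("%s:%d-%d", tab$accession, tab$start, tab$end)
  by_display <- split(prov, tab$display_seq)
  out <- tab[!duplicated(tab$display_seq), , drop = FALSE]
  out$provenance <- vapply(by_display[out$display_seq], paste, character(1),
                           collapse = ";")
  rownames(out) <- NULL
  out
}
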