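# Accessible (disordered) search-space definition: per-residue accessibility
# tracks from disorder predictions and structural surface accessibility.

#' Construct a protein record
#'
#' A minimal annotated protein: sequence plus the UniProt-style annotation
#' needed for search-space definition (keywords, GO terms with ancestor
#' closure applied upstream, transmembrane/extracellular spans, and optional
#' chain/topology segments that are scored independently).
#'
#' @param accession protein identifier.
#' @param sequence amino-acid string (20 standard residues plus optional X/U).
#' @param keywords character vector of annotation keywords.
#' @param go_terms character vector of GO identifiers (ancestor-closed).
#' @param tm_spans,extracellular_spans,chain_spans two-column matrices of
#'   1-based inclusive (start, end) intervals, or NULL.
#' @return an object of class `protein_record`.
#' @export
#' @examples
#' protein_record("P1", "MKNTDAAPLLSQRSTV", keywords = "Cytoplasm")
protein_record <- function(accession, sequence, keywords = character(),
                           go_terms = character(), tm_spans = NULL,
                           extracellular_spans = NULL, chain_spans = NULL) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYXU]*$", sequence)) {
    stop("sequence contains characters outside the 20 standard residues + X/U")
  }
  len <- nchar(sequence)
  structure(list(
    accession = accession,
    sequence = sequence,
    keywords = as.character(keywords),
    go_terms = as.character(go_terms),
    tm_spans = validate_spans(tm_spans, len, "tm_span"),
    extracellular_spans = validate_spans(extracellular_spans, len,
                                         "extracellular_span"),
    chain_spans = if (is.null(chain_spans)) NULL else
      validate_spans(chain_spans, len, "chain_span")
  ), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$accession, "-", nchar(x$sequence), "aa\n")
  invisible(x)
}

#' Accessibility configuration
#'
#' Thresholds and window parameters controlling the definition of the
#' accessible (disordered) search space and its tiling.
#'
#' @param iupred_cutoff disorder-propensity threshold; residues with score
#'   >= cutoff are accessible (default 0.4).
#' @param sa_cutoff surface-accessibility threshold in percent; residues with
#'   SA >= cutoff are accessible (default 33).
#' @param smoothing_max_run maximum length of an inconsistent run removed by
#'   smoothing (default 4).
#' @param order_island_max ordered runs strictly shorter than this inside a
#'   disordered context are re-marked accessible (default 25, exclusive).
#' @param window_len peptide window length (16).
#' @param window_min_accessible minimum accessible residues per retained
#'   window (8).
#' @param tiling_step tiling step; `window_len - overlap` with overlap 12.
#' @param min_loop_len minimum retained loop length (8).
#' @return a list of class `accessibility_config`.
#' @export
accessibility_config <- function(iupred_cutoff = 0.4, sa_cutoff = 33,
                                 smoothing_max_run = 4L, order_island_max = 25L,
                                 window_len = 16L, window_min_accessible = 8L,
                                 tiling_step = 4L, min_loop_len = 8L) {
  stopifnot(iupred_cutoff >= 0, iupred_cutoff <= 1,
            sa_cutoff >= 0, sa_cutoff <= 100,
            window_min_accessible <= window_len, tiling_step >= 1)
  structure(list(iupred_cutoff = iupred_cutoff, sa_cutoff = sa_cutoff,
                 smoothing_max_run = as.integer(smoothing_max_run),
                 order_island_max = as.integer(order_island_max),
                 window_len = as.integer(window_len),
                 window_min_accessible = as.integer(window_min_accessible),
                 tiling_step = as.integer(tiling_step),
                 min_loop_len = as.integer(min_loop_len)),
            class = "accessibility_config")
}

#' Intracellular intervals of a protein
#'
#' Removes transmembrane spans and the extracellular spans of transmembrane
#' proteins; proteins carrying the keyword "Secreted" without "Cytoplasm" or
#' "Nucleus" are excluded entirely.
#'
#' @param protein a [protein_record()].
#' @return two-column matrix of retained (start, end) intervals (0 rows when
#'   the protein is excluded).
#' @export
strip_extracellular <- function(protein) {
  stopifnot(inherits(protein, "protein_record"))
  kw <- protein$keywords
  if ("Secreted" %in% kw && !any(c("Cytoplasm", "Nucleus") %in% kw)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  removed <- rbind(protein$tm_spans, protein$extracellular_spans)
  if (nrow(removed) > 1L) {
    o <- removed[order(removed[, 1]), , drop = FALSE]
    if (any(o[-1L, 1] <= o[-nrow(o), 2])) {
      stop("overlapping TM/extracellular spans for ", protein$accession)
    }
  }
  subtract_spans(nchar(protein$sequence), removed)
}

#' Binarize a disorder-propensity track
#'
#' A residue is called accessible (disordered) when its score is greater than
#' or equal to the cutoff (boundary values count as accessible).
#'
#' @param scores numeric disorder propensities in `[0, 1]`.
#' @param cfg an [accessibility_config()].
#' @return logical vector, one call per residue.
#' @export
binarize_disorder <- function(scores, cfg = accessibility_config()) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stop("disorder scores must lie in [0, 1]")
  }
  scores >= cfg$iupred_cutoff
}

# Same convention for percent surface accessibility.
#' @rdname binarize_disorder
#' @export
binarize_sa <- function(scores, cfg = accessibility_config()) {
  if (any(scores < 0 | scores > 100, na.rm = TRUE)) {
    stop("SA scores must lie in [0, 100]")
  }
  scores >= cfg$sa_cutoff
}

#' Per-residue surface accessibility from solved structures
#'
#' Absolute accessibilities are normalized by the residue's maximum possible
#' accessibility in a GGXGG peptide context and expressed in percent, clipped
#' to `[0, 100]`.  Residues unresolved in a structure are set to 100 percent.
#' When several structures cover a residue the median percent SA is used.
#'
#' @param structures list of structures; each a list with numeric `abs`
#'   (absolute accessibility, NA where the structure does not cover the
#'   residue) and logical `unresolved` flags, both of protein length.
#' @param sequence protein amino-acid sequence.
#' @param max_access named numeric vector of maximum accessibilities per
#'   residue (defaults to the shipped theoretical GGXGG table).
#' @return numeric percent SA track; NA where no structure covers a residue.
#' @export
sa_from_structures <- function(structures, sequence,
                               max_access = load_max_accessibility()) {
  res <- strsplit(sequence, "")[[1]]
  std <- res %in% AA20
  if (any(std & !(res %in% names(max_access)))) {
    stop("residue missing from the maximum-accessibility table")
  }
  if (any(max_access[names(max_access) %in% AA20] <= 0)) {
    stop("maximum accessibilities must be positive")
  }
  per <- vapply(structures, function(s) {
    sa <- 100 * s$abs / unname(max_access[res])
    sa <- pmin(100, pmax(0, sa))
    sa[which(s$unresolved)] <- 100
    sa
  }, numeric(length(res)))
  per <- matrix(per, nrow = length(res))
  apply(per, 1L, function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
}

#' Transfer a structural SA track onto a query by local alignment
#'
#' Aligns the query protein to the structure's sequence (Smith-Waterman,
#' BLOSUM62) and copies SA values through aligned, non-gap columns.  Query
#' residues outside the alignment stay NA (source "none").  The caller is
#' expected to have screened homology hits by e-value/coverage already.
#'
#' @param query query amino-acid sequence.
#' @param structure_seq structure construct sequence.
#' @param structure_track numeric SA percent track on `structure_seq`.
#' @param params list with `gap_open` and `gap_extend` penalties
#'   (defaults 11 / 1) as used with BLOSUM62.
#' @return numeric SA track on the query (NA outside the alignment).
#' @export
map_homology_sa <- function(query, structure_seq, structure_track,
                            params = homology_params()) {
  stopifnot(nchar(structure_seq) == length(structure_track))
  out <- rep(NA_real_, nchar(query))
  if (!nchar(query) || !nchar(structure_seq)) return(out)
  blosum <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(structure_seq),
    type = "local", substitutionMatrix = blosum,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  if (Biostrings::nchar(Biostrings::alignedPattern(pa)) == 0L) return(out)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- pa@pattern@range@start - 1L
  spos <- pa@subject@range@start - 1L
  for (k in seq_along(p)) {
    if (p[k] != "-") qpos <- qpos + 1L
    if (s[k] != "-") spos <- spos + 1L
    if (p[k] != "-" && s[k] != "-") out[qpos] <- structure_track[spos]
  }
  out
}

#' Homology-mapping screening parameters
#'
#' @param evalue_cutoff BLAST e-value cutoff for accepting a structural
#'   homologue (default 1e-15).
#' @param coverage_cutoff minimum percent of the structure covered (85).
#' @param gap_open,gap_extend alignment gap penalties with BLOSUM62.
#' @return a parameter list.
#' @export
homology_params <- function(evalue_cutoff = 1e-15, coverage_cutoff = 85,
                            gap_open = 11, gap_extend = 1) {
  stopifnot(evalue_cutoff > 0, coverage_cutoff > 0, coverage_cutoff <= 100)
  list(evalue_cutoff = evalue_cutoff, coverage_cutoff = coverage_cutoff,
       gap_open = gap_open, gap_extend = gap_extend)
}

get_blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Merge predicted and experimental accessibility calls
#'
#' Experimental calls (direct structure or homology-mapped, in that order of
#' precedence) are used in place of disorder predictions wherever available.
#'
#' @param predicted logical track from [binarize_disorder()].
#' @param experimental logical track from binarized SA (NA where no
#'   structural information exists).
#' @param source optional character track tagging experimental calls
#'   ("structure" or "homology"); defaults to "structure" where experimental
#'   is non-NA.
#' @return list with `accessible` (logical) and `source` (character in
#'   predicted/structure/homology/none).
#' @export
merge_hierarchy <- function(predicted, experimental, source = NULL) {
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental tracks differ in length")
  }
  has_exp <- !is.na(experimental)
  acc <- ifelse(has_exp, experimental, predicted)
  src <- if (is.null(source)) {
    ifelse(has_exp, "structure", "predicted")
  } else {
    stopifnot(length(source) == length(predicted))
    ifelse(has_exp, source, "predicted")
  }
  src[is.na(acc)] <- "none"
  list(accessible = as.logical(acc), source = src)
}

#' Smooth a binary accessibility track
#'
#' Runs of length <= `smoothing_max_run` whose two flanking runs both carry
#' the opposite category are flipped to that category; the pass is repeated
#' until the track is stable.  Terminal runs (only one flank) are never
#' flipped, and a short run whose flanks disagree is left unchanged.
#'
#' @param accessible logical track.
#' @param cfg an [accessibility_config()].
#' @return smoothed logical track.
#' @export
smooth_track <- function(accessible, cfg = accessibility_config()) {
  x <- accessible
  repeat {
    r <- rle(x)
    n <- length(r$values)
    if (n < 3L) return(x)
    changed <- FALSE
    for (i in 2:(n - 1L)) {
      if (r$lengths[i] <= cfg$smoothing_max_run &&
          r$values[i - 1L] == r$values[i + 1L] &&
          r$values[i] != r$values[i - 1L]) {
        r$values[i] <- r$values[i - 1L]
        changed <- TRUE
        break  # restart from the merged run structure (left-to-right)
      }
    }
    x <- inverse.rle(r)
    if (!changed) return(x)
  }
}

#' Re-mark short ordered islands inside disorder as accessible
#'
#' Any inaccessible run strictly shorter than `order_island_max` residues
#' that is flanked on both sides by accessible runs becomes accessible.
#' Terminal ordered runs are unchanged (no disordered context on both sides).
#'
#' @inheritParams smooth_track
#' @return logical track with order islands included.
#' @export
include_order_islands <- function(accessible, cfg = accessibility_config()) {
  r <- rle(accessible)
  n <- length(r$values)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (!r$values[i] && r$lengths[i] < cfg$order_island_max &&
          r$values[i - 1L] && r$values[i + 1L]) {
        r$values[i] <- TRUE
      }
    }
  }
  inverse.rle(r)
}

#' Load the GGXGG maximum-accessibility table
#'
#' Published theoretical maximum solvent accessibilities of each residue X in
#' a Gly-Gly-X-Gly-Gly peptide, used to express absolute accessibilities in
#' percent.  Override by supplying any named vector to
#' [sa_from_structures()].
#'
#' @param path optional TSV with columns residue, max_access.
#' @return named numeric vector over the 20 standard residues.
#' @export
load_max_accessibility <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "max_accessibility_ggxgg.tsv",
                        package = "proppd", mustWork = TRUE)
  }
  tab <- read_tsv_file(path)
  setNames(as.numeric(tab$max_access), tab$residue)
}
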