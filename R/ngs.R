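# Demultiplexing of dual-barcoded amplicon reads and peptide count tables.

#' Dual-barcode scheme for amplicon reads
#'
#' A read is laid out as `barcode5 + adapter5 + insert + adapter3 + barcode3`
#' with fixed-width barcodes.  Barcodes and adapters are matched allowing at
#' most `max_mismatch` substitutions each; reads compatible with more than
#' one barcode are ambiguous.
#'
#' @param barcodes5,barcodes3 named character vectors of barcode sequences
#'   (all the same width within a set).
#' @param adapter5,adapter3 constant flanking sequences.
#' @param insert_len coding insert width (48 nt).
#' @param max_mismatch maximum substitutions per barcode/adapter (1).
#' @param min_mean_quality minimum mean Phred quality per read (20).
#' @return a list of class `barcode_scheme`.
#' @export
barcode_scheme <- function(barcodes5, barcodes3,
                           adapter5 = "CAGCCTCTTCATCTGGC",
                           adapter3 = "GGTGGAGGATCCGGAG",
                           insert_len = 48L, max_mismatch = 1L,
                           min_mean_quality = 20) {
  stopifnot(!anyDuplicated(barcodes5), !anyDuplicated(barcodes3),
            length(unique(nchar(barcodes5))) == 1L,
            length(unique(nchar(barcodes3))) == 1L,
            max_mismatch >= 0)
  if (is.null(names(barcodes5))) names(barcodes5) <- barcodes5
  if (is.null(names(barcodes3))) names(barcodes3) <- barcodes3
  structure(list(barcodes5 = barcodes5, barcodes3 = barcodes3,
                 adapter5 = adapter5, adapter3 = adapter3,
                 insert_len = as.integer(insert_len),
                 max_mismatch = as.integer(max_mismatch),
                 min_mean_quality = min_mean_quality),
            class = "barcode_scheme")
}

# Hamming distances of equal-width strings to a single target (vectorized
# over the strings; substitutions only, by design of the amplicon layout).
hamming_to <- function(strings, target) {
  w <- nchar(target)
  d <- integer(length(strings))
  for (i in seq_len(w)) {
    d <- d + (substring(strings, i, i) != substring(target, i, i))
  }
  d
}

# Match fixed-position barcode regions against a barcode set.
# Returns the matched barcode name, NA_unassigned, or "*ambiguous*".
match_barcode <- function(regions, barcodes, max_mismatch) {
  dists <- vapply(barcodes, function(b) hamming_to(regions, b),
                  integer(length(regions)))
  dists <- matrix(dists, nrow = length(regions))
  within <- dists <= max_mismatch
  nhit <- rowSums(within)
  hit <- max.col(-dists, ties.method = "first")
  out <- ifelse(nhit == 1L, names(barcodes)[hit], NA_character_)
  out[nhit > 1L] <- "*ambiguous*"
  out
}

#' Demultiplex dual-barcoded FASTQ reads
#'
#' Drops reads with mean Phred quality below the scheme's threshold, matches
#' both barcodes and both adapters with at most one substitution each,
#' excludes reads compatible with more than one barcode as ambiguous, and
#' trims survivors to the coding insert.
#'
#' @param fastq path to a FASTQ file (Phred+33), or a list with elements
#'   `seq` and `qual` (equal-length character vectors).
#' @param scheme a [barcode_scheme()].
#' @param sample_key data.frame with columns sample, barcode5, barcode3
#'   (barcode names), uniquely keyed by the barcode pair.
#' @return list with `samples` (named list of insert sequences per sample)
#'   and `log` (data.frame with total, low_quality, unassigned, ambiguous,
#'   assigned counts; categories partition the input).
#' @export
demultiplex <- function(fastq, scheme, sample_key) {
  if (is.character(fastq)) {
    reads <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                          with.qualities = TRUE)
    seqs <- as.character(reads)
    quals <- as.character(S4Vectors::mcols(reads)$qualities)
  } else {
    seqs <- fastq$seq
    quals <- fastq$qual
  }
  key <- paste(sample_key$barcode5, sample_key$barcode3, sep = "|")
  if (anyDuplicated(key)) stop("sample_key barcode pairs are not unique")
  n <- length(seqs)
  b5w <- nchar(scheme$barcodes5[1])
  b3w <- nchar(scheme$barcodes3[1])
  a5w <- nchar(scheme$adapter5)
  a3w <- nchar(scheme$adapter3)
  exp_len <- b5w + a5w + scheme$insert_len + a3w + b3w

  mean_q <- if (n) {
    vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
           USE.NAMES = FALSE)
  } else numeric(0)
  lowq <- mean_q < scheme$min_mean_quality
  ok_len <- nchar(seqs) == exp_len & !lowq

  status <- rep("unassigned", n)
  status[lowq] <- "low_quality"
  sample_of <- rep(NA_character_, n)

  idx <- which(ok_len)
  if (length(idx)) {
    s <- seqs[idx]
    b5 <- match_barcode(substring(s, 1L, b5w), scheme$barcodes5,
                        scheme$max_mismatch)
    b3 <- match_barcode(substring(s, exp_len - b3w + 1L, exp_len),
                        scheme$barcodes3, scheme$max_mismatch)
    a5_ok <- hamming_to(substring(s, b5w + 1L, b5w + a5w),
                        scheme$adapter5) <= scheme$max_mismatch
    a3_ok <- hamming_to(substring(s, b5w + a5w + scheme$insert_len + 1L,
                                  exp_len - b3w), scheme$adapter3) <=
      scheme$max_mismatch
    amb <- (b5 %in% "*ambiguous*") | (b3 %in% "*ambiguous*")
    status[idx[amb]] <- "ambiguous"
    good <- !amb & !is.na(b5) & !is.na(b3) & a5_ok & a3_ok
    pair <- paste(b5, b3, sep = "|")
    samp <- sample_key$sample[match(pair, key)]
    good <- good & !is.na(samp)
    status[idx[good]] <- "assigned"
    sample_of[idx[good]] <- samp[good]
  }
  inserts <- substring(seqs, b5w + a5w + 1L, b5w + a5w + scheme$insert_len)
  samples <- split(inserts[status == "assigned"],
                   sample_of[status == "assigned"])
  samples <- samples[intersect(sample_key$sample, names(samples))]
  log <- data.frame(total = n,
                    low_quality = sum(status == "low_quality"),
                    unassigned = sum(status == "unassigned"),
                    ambiguous = sum(status == "ambiguous"),
                    assigned = sum(status == "assigned"))
  list(samples = samples, status = status, sample_of = sample_of, log = log)
}

#' Translate per-sample inserts into peptide count tables
#'
#' Each unique trimmed insert is translated in frame 0; inserts of the wrong
#' length or containing an internal stop codon are tallied separately as
#' non-conforming (they feed the library QC statistics, not the peptide
#' tables).  Synonymous inserts of one peptide pool their counts.
#'
#' @param samples named list of insert sequence vectors (one per sample).
#' @param insert_len expected coding length (48 nt).
#' @return list with `counts` (named list of peptide -> integer count) and
#'   `qc` (per-sample data.frame: total, correct_length, coding,
#'   nonconforming).
#' @export
translate_counts <- function(samples, insert_len = 48L) {
  counts <- list()
  qc <- list()
  for (nm in names(samples)) {
    ins <- samples[[nm]]
    tab <- table(ins)
    uniq <- names(tab)
    good_len <- nchar(uniq) == insert_len & !grepl("[^ACGT]", uniq)
    pep <- rep(NA_character_, length(uniq))
    if (any(good_len)) {
      pep[good_len] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(uniq[good_len]), no.init.codon = TRUE))
    }
    coding <- good_len & !grepl("*", pep, fixed = TRUE)
    cnt <- as.integer(tab)
    pooled <- tapply(cnt[coding], pep[coding], sum)
    counts[[nm]] <- setNames(as.integer(pooled), names(pooled))
    qc[[nm]] <- data.frame(
      sample = nm, total = sum(cnt),
      correct_length = sum(cnt[good_len]),
      coding = sum(cnt[coding]),
      nonconforming = sum(cnt[!coding]),
      stringsAsFactors = FALSE)
  }
  list(counts = counts, qc = do.call(rbind, c(qc, list(make.row.names = FALSE))))
}

#' Discard peptides observed only once
#'
#' @param counts named integer vector (peptide -> count) or a list of them.
#' @return same shape with count-1 entries removed.
#' @export
drop_singletons <- function(counts) {
  if (is.list(counts)) return(lapply(counts, drop_singletons))
  counts[counts >= 2L]
}

#' Normalize peptide counts to per-sample fractions
#'
#' Divides each peptide's count by the sample total so that counts sum to 1
#' per sample, making screens and sequencing batches comparable.
#'
#' @param counts named integer vector (peptide -> count) or a list of them.
#' @return named numeric vector(s) summing to 1 per sample (empty samples
#'   yield an empty vector).
#' @export
normalize_counts <- function(counts) {
  if (is.list(counts)) return(lapply(counts, normalize_counts))
  if (!length(counts) || sum(counts) == 0) return(setNames(numeric(0), NULL))
  counts / sum(counts)
}

#' Pool selection days into per-replicate mean normalized counts
#'
#' The mean over all sequenced days of a replicate; a peptide absent on a
#' sequenced day contributes 0 to its mean.
#'
#' @param day_tables list of normalized count vectors, one per sequenced day
#'   of a single replicate.
#' @return named numeric vector: peptide -> mean normalized count.
#' @export
pool_replicate_days <- function(day_tables) {
  stopifnot(length(day_tables) >= 1L)
  peps <- unique(unlist(lapply(day_tables, names)))
  if (!length(peps)) return(setNames(numeric(0), NULL))
  acc <- setNames(numeric(length(peps)), peps)
  for (d in day_tables) acc[names(d)] <- acc[names(d)] + d
  acc / length(day_tables)
}
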