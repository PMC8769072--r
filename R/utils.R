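# Shared internal helpers: interval arithmetic, validation, TSV I/O.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a list of 1-based inclusive spans against a sequence length
#'
#' Spans must lie within `[1, len]` and be pairwise non-overlapping.
#'
#' @param spans matrix/data.frame with columns start, end, or NULL/empty.
#' @param len sequence length.
#' @param what label used in error messages.
#' @return a two-column integer matrix (possibly 0-row), sorted by start.
#' @keywords internal
validate_spans <- function(spans, len, what = "span") {
  if (is.null(spans) || length(spans) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  m <- as.matrix(spans)[, 1:2, drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  if (any(m[, 1] < 1L) || any(m[, 2] > len) || any(m[, 1] > m[, 2])) {
    stop(what, " outside [1, ", len, "] or start > end", call. = FALSE)
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1] <= m[-nrow(m), 2])) {
    stop("overlapping ", what, "s", call. = FALSE)
  }
  m
}

# Subtract a set of spans from [1, len]; returns remaining intervals.
subtract_spans <- function(len, spans) {
  keep <- rep(TRUE, len)
  if (nrow(spans)) {
    for (i in seq_len(nrow(spans))) keep[spans[i, 1]:spans[i, 2]] <- FALSE
  }
  mask_to_spans(keep)
}

# Convert a logical mask to a two-column matrix of TRUE runs (1-based inclusive).
mask_to_spans <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  cbind(start = starts[i], end = ends[i])
}

# Merge overlapping/adjacent spans into maximal intervals.
merge_spans <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2] + 1L) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

read_tsv_file <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parse "start-end;start-end" span notation used in annotation tables.
parse_span_field <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
  colnames(m) <- c("start", "end")
  m
}

format_span_field <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return("")
  paste(paste(m[, 1], m[, 2], sep = "-"), collapse = ";")
}
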