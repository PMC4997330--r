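# Reading DHS peak calls from BED.

#' Read DHS peaks from a BED3+ file
#'
#' Coordinates are BED-native (0-based half-open). Midpoints are
#' `floor((start + end) / 2)`. Records are validated individually so format
#' errors carry the offending line number. Lines starting with `#`,
#' `track` or `browser` are skipped.
#'
#' @param path Path to a BED file with at least 3 columns.
#' @return Data frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `score` (NA when absent) and `midpoint`, sorted by `(chrom, start)`.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path))
    stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  if (!length(lineno)) {
    warning("no peak records in ", path)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_id = character(),
                      score = numeric(), midpoint = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[lineno], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("invalid BED record at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 fields", call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("invalid BED record at line ", lineno[bad[1L]],
         ": start/end not integers with start < end", call. = FALSE)
  peak_id <- vapply(seq_along(fields), function(k) {
    if (nf[k] >= 4L) fields[[k]][4L] else sprintf("peak%05d", k)
  }, "")
  score <- vapply(seq_along(fields), function(k) {
    if (nf[k] >= 5L) suppressWarnings(as.numeric(fields[[k]][5L]))
    else NA_real_
  }, 0)
  peaks <- data.frame(chrom = chrom, start = start, end = end,
                      peak_id = peak_id, score = score,
                      midpoint = (start + end) %/% 2L,
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Merge peaks separated by at most a given gap
#'
#' With `merge_gap = 0` merging is disabled (the default behaviour of the
#' classifier); with `merge_gap > 0`, peaks on the same chromosome whose
#' gap (`start` of the next minus `end` of the previous) is `<= merge_gap`
#' are unioned, and midpoints recomputed.
#'
#' @param peaks Peak data frame from [read_bed_peaks()].
#' @param merge_gap Maximum gap in bp; 0 disables merging.
#' @return Peak data frame.
#' @export
merge_close_peaks <- function(peaks, merge_gap = 0) {
  if (merge_gap <= 0 || nrow(peaks) < 2L) return(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  new_run <- c(TRUE, peaks$chrom[-1L] != peaks$chrom[-nrow(peaks)] |
                 peaks$start[-1L] - cummax_by_chrom(peaks) > merge_gap)
  grp <- cumsum(new_run)
  s <- tapply(peaks$start, grp, min)
  e <- tapply(peaks$end, grp, max)
  id <- tapply(peaks$peak_id, grp, function(x) paste(x, collapse = ","))
  chrom <- tapply(peaks$chrom, grp, `[[`, 1L)
  out <- data.frame(chrom = as.character(chrom), start = as.integer(s),
                    end = as.integer(e), peak_id = as.character(id),
                    score = NA_real_,
                    midpoint = (as.integer(s) + as.integer(e)) %/% 2L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Running max of peak ends, lagged by one, used for gap computation.
cummax_by_chrom <- function(peaks) {
  out <- numeric(nrow(peaks) - 1L)
  for (chr in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chr)
    if (length(idx) > 1L)
      out[idx[-length(idx)]] <- cummax(peaks$end[idx])[-length(idx)]
  }
  out
}
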