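# Reading gene models from GFF3.
#
# Internal coordinates are 0-based half-open throughout the package; GFF3 is
# 1-based inclusive, so `start` is shifted down by one on read.

#' Read gene models from a GFF3 file
#'
#' Keeps records of one feature type (default `"gene"`), converts
#' coordinates to the package's 0-based half-open convention, drops
#' strandless records with a warning, and returns the models sorted by
#' `(chrom, start)` as required by [find_bidirectional_pairs()].
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type (column 3) to keep.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"` or `"-"`), sorted by
#'   `(chrom, start, end)`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path))
    stop("GFF3 file not found: ", path, call. = FALSE)

  # readGFF reports file-level failures only; pre-scan so a malformed
  # record is reported with its line number.
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf < 8L]
    if (length(bad))
      stop("malformed GFF3 record at line ", bad[1L],
           ": expected at least 8 tab-separated fields", call. = FALSE)
  }

  gff <- rtracklayer::readGFF(path, columns = c("seqid", "start", "end",
                                                "strand", "type"),
                              tags = c("ID", "Name"))
  gff <- gff[as.character(gff$type) == feature_type, , drop = FALSE]
  if (nrow(gff) == 0L)
    stop("no genes: no records of type '", feature_type, "' in ", path,
         call. = FALSE)

  strand <- as.character(gff$strand)
  keep <- strand %in% c("+", "-")
  if (any(!keep))
    warning(sum(!keep), " record(s) without a +/- strand dropped")
  gff <- gff[keep, , drop = FALSE]
  if (nrow(gff) == 0L)
    stop("no genes: all '", feature_type, "' records lacked a strand",
         call. = FALSE)

  id <- as.character(gff$ID)
  if (anyNA(id)) {
    nm <- as.character(gff$Name)
    id[is.na(id)] <- nm[is.na(id)]
    id[is.na(id)] <- sprintf("%s:%d-%d", as.character(gff$seqid)[is.na(id)],
                             gff$start[is.na(id)], gff$end[is.na(id)])
  }

  genes <- data.frame(gene_id = id,
                      chrom   = as.character(gff$seqid),
                      start   = as.integer(gff$start) - 1L,
                      end     = as.integer(gff$end),
                      strand  = strand[keep],
                      stringsAsFactors = FALSE)
  if (any(genes$start >= genes$end))
    stop("invalid gene interval (start >= end) for ",
         genes$gene_id[genes$start >= genes$end][1L], call. = FALSE)
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Transcription start site of gene models
#'
#' The first transcribed base, 0-based: `start` on the plus strand,
#' `end - 1` on the minus strand.
#'
#' @param genes Data frame of gene models as returned by [read_gff3()].
#' @return Integer vector of TSS positions, one per gene.
#' @export
tss <- function(genes) {
  stopifnot(all(c("start", "end", "strand") %in% names(genes)))
  as.integer(ifelse(genes$strand == "+", genes$start, genes$end - 1L))
}
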