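# Identification of bidirectional gene pairs and their promoters (BDPs).

#' Size class of a bidirectional promoter
#'
#' BDP intervals are classed by intergenic length into I (0, 250],
#' II (250, 500] and III (500, 1000] bp. Upper-inclusive bins so that
#' 250 and 500 each fall in exactly one class. Lengths outside (0, 1000]
#' yield `NA`.
#'
#' @param length Integer vector of BDP lengths in bp.
#' @return Character vector of `"I"`, `"II"`, `"III"` or `NA`.
#' @export
bdp_size_class <- function(length) {
  as.character(cut(length, breaks = c(0, 250, 500, 1000),
                   labels = c("I", "II", "III"), right = TRUE))
}

#' Find divergent (head-to-head) gene pairs and their BDPs
#'
#' A pair is emitted when two genes are adjacent in `(chrom, start)` order
#' on the same chromosome, the left gene is on the minus strand and the
#' right gene on the plus strand, the TSS-to-TSS distance lies in
#' `(0, max_distance]`, the gene bodies do not overlap, and no third gene
#' body intrudes into the intergenic interval. The intergenic interval
#' between the two TSSs is the bidirectional promoter (BDP); its length is
#' classed by [bdp_size_class()].
#'
#' @param genes Gene models sorted by `(chrom, start)`, see [read_gff3()].
#' @param max_distance Maximum TSS-to-TSS distance in bp.
#' @return Data frame with one row per pair: `pair_id`, `chrom`,
#'   `left_gene`, `right_gene`, `left_start`, `left_end`, `right_start`,
#'   `right_end`, `bdp_start`, `bdp_end` (0-based half-open), `bdp_length`
#'   and `size_class`.
#' @export
find_bidirectional_pairs <- function(genes, max_distance = 1000) {
  stopifnot(max_distance > 0)
  n <- nrow(genes)
  o <- order(genes$chrom, genes$start, genes$end)
  if (!identical(o, seq_len(n)))
    stop("genes must be sorted by (chrom, start); sort first, e.g. with ",
         "genes[order(genes$chrom, genes$start, genes$end), ]", call. = FALSE)
  if (n < 2L) return(empty_pairs())

  i <- seq_len(n - 1L)
  same_chrom <- genes$chrom[i] == genes$chrom[i + 1L]
  divergent <- genes$strand[i] == "-" & genes$strand[i + 1L] == "+"

  t <- tss(genes)
  bdp_start <- t[i]         # minus-strand left gene: TSS = end - 1
  bdp_end <- t[i + 1L]      # plus-strand right gene: TSS = start
  len <- bdp_end - bdp_start
  no_overlap <- genes$end[i] <= genes$start[i + 1L]

  # Running max of gene ends upstream of each gene, per chromosome: a third
  # gene body reaching past the left gene's end would intrude into the BDP.
  prev_max_end <- rep(-Inf, n)
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    if (length(idx) > 1L)
      prev_max_end[idx[-1L]] <- cummax(as.numeric(genes$end[idx]))[-length(idx)]
  }
  clean <- prev_max_end[i] <= genes$end[i]

  keep <- which(same_chrom & divergent & no_overlap & clean &
                  len > 0L & len <= max_distance)
  if (!length(keep)) return(empty_pairs())

  pairs <- data.frame(
    pair_id     = sprintf("BDP%05d", seq_along(keep)),
    chrom       = genes$chrom[keep],
    left_gene   = genes$gene_id[keep],
    right_gene  = genes$gene_id[keep + 1L],
    left_start  = genes$start[keep],
    left_end    = genes$end[keep],
    right_start = genes$start[keep + 1L],
    right_end   = genes$end[keep + 1L],
    bdp_start   = bdp_start[keep],
    bdp_end     = bdp_end[keep],
    bdp_length  = len[keep],
    size_class  = bdp_size_class(len[keep]),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  pairs
}

empty_pairs <- function() {
  data.frame(pair_id = character(), chrom = character(),
             left_gene = character(), right_gene = character(),
             left_start = integer(), left_end = integer(),
             right_start = integer(), right_end = integer(),
             bdp_start = integer(), bdp_end = integer(),
             bdp_length = integer(), size_class = character(),
             stringsAsFactors = FALSE)
}

#' Write / read the pairs table (1-based inclusive TSV)
#'
#' The on-disk table uses 1-based inclusive coordinates (browser
#' convention); [read_pairs_tsv()] converts back to the internal 0-based
#' half-open representation.
#'
#' @param pairs Pairs data frame from [find_bidirectional_pairs()].
#' @param path Output path.
#' @param comments Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path, comments = NULL) {
  out <- pairs
  out$bdp_start <- out$bdp_start + 1L
  out$left_start <- out$left_start + 1L
  out$right_start <- out$right_start + 1L
  write_tsv(out, path, comments = comments)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  pairs <- read_tsv(path)
  pairs$bdp_start <- as.integer(pairs$bdp_start) - 1L
  pairs$left_start <- as.integer(pairs$left_start) - 1L
  pairs$right_start <- as.integer(pairs$right_start) - 1L
  pairs
}

#' Write BDP intervals as BED6
#'
#' @param pairs Pairs data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_bed <- function(pairs, path) {
  bed <- data.frame(pairs$chrom, pairs$bdp_start, pairs$bdp_end,
                    pairs$pair_id, pairs$bdp_length, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
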