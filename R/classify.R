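# Positional classification of DHS peaks within bidirectional promoters.
#
# Each BDP falls into one of four categories: "one_mid" (a single peak near
# the middle of the BDP), "one_amesial" (a single off-centre peak), "bi"
# (two or more peaks) and "none". The middle/off-centre boundary is not a
# universal constant; it is controlled by `mid_fraction` in
# `classifier_config()` (a single peak is "mid" when its midpoint lies
# within the central 2*mid_fraction of the BDP).

DHS_CATEGORIES <- c("one_mid", "one_amesial", "bi", "none")

#' Classifier configuration
#'
#' @param mid_fraction A single peak whose midpoint is within
#'   `mid_fraction * bdp_length` of the BDP centre is "one_mid"; must lie
#'   strictly in (0, 0.5). Default 0.25 (the central half of the BDP).
#' @param merge_gap Peaks assigned to the same BDP whose gap is
#'   `<= merge_gap` bp are merged before classification; 0 disables.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(mid_fraction = 0.25, merge_gap = 0) {
  if (!is.numeric(mid_fraction) || length(mid_fraction) != 1L ||
      mid_fraction <= 0 || mid_fraction >= 0.5)
    stop("mid_fraction must be a single number strictly between 0 and 0.5",
         call. = FALSE)
  if (merge_gap < 0) stop("merge_gap must be >= 0", call. = FALSE)
  structure(list(mid_fraction = mid_fraction, merge_gap = merge_gap),
            class = "classifier_config")
}

#' Peaks assigned to one BDP
#'
#' A peak belongs to a BDP when its midpoint lies in
#' `[bdp_start, bdp_end)`; peaks straddling a boundary are not clipped.
#'
#' @param pair One-row pairs data frame.
#' @param peaks Peak data frame from [read_bed_peaks()].
#' @param cfg A [classifier_config()].
#' @return The assigned peaks, sorted by midpoint (merged when
#'   `cfg$merge_gap > 0`).
#' @export
assign_peaks_to_bdp <- function(pair, peaks, cfg = classifier_config()) {
  stopifnot(nrow(pair) == 1L)
  hit <- peaks$chrom == pair$chrom &
    peaks$midpoint >= pair$bdp_start & peaks$midpoint < pair$bdp_end
  assigned <- peaks[hit, , drop = FALSE]
  assigned <- assigned[order(assigned$midpoint), , drop = FALSE]
  if (cfg$merge_gap > 0) assigned <- merge_close_peaks(assigned, cfg$merge_gap)
  rownames(assigned) <- NULL
  assigned
}

#' Four-way DHS category of a BDP
#'
#' @param pair One-row pairs data frame.
#' @param assigned Peaks assigned by [assign_peaks_to_bdp()].
#' @param cfg A [classifier_config()].
#' @return One of `"one_mid"`, `"one_amesial"`, `"bi"`, `"none"`.
#' @export
classify_dhs_category <- function(pair, assigned, cfg = classifier_config()) {
  n <- nrow(assigned)
  if (n == 0L) return("none")
  if (n >= 2L) return("bi")
  centre <- (pair$bdp_start + pair$bdp_end) / 2
  offset <- abs(assigned$midpoint - centre)
  if (offset <= cfg$mid_fraction * pair$bdp_length) "one_mid" else "one_amesial"
}

#' Distance from a peak midpoint to a gene's TSS
#'
#' @param peak One-row peak data frame.
#' @param gene One-row gene-model data frame.
#' @return Non-negative integer distance in bp.
#' @export
dhs_tss_distance <- function(peak, gene) {
  if (peak$chrom != gene$chrom)
    stop("peak and gene are on different chromosomes (", peak$chrom,
         " vs ", gene$chrom, ")", call. = FALSE)
  abs(as.integer(peak$midpoint) - tss(gene))
}

#' Proximal/distal split of a single-peak BDP
#'
#' For a BDP holding exactly one peak, labels the gene whose TSS is closer
#' to the peak midpoint as proximal. An exact tie is broken toward the
#' left gene (deterministic).
#'
#' @param pair One-row pairs data frame.
#' @param assigned Peaks assigned to this BDP; must be exactly one.
#' @return List with `proximal`, `distal` (gene ids), `dist_proximal`,
#'   `dist_distal` (bp).
#' @export
proximal_distal_split <- function(pair, assigned) {
  if (nrow(assigned) != 1L)
    stop("proximal/distal split requires exactly one assigned peak ",
         "(category one_mid or one_amesial); got ", nrow(assigned),
         call. = FALSE)
  d_left <- assigned$midpoint - pair$bdp_start    # left TSS = bdp_start
  d_right <- pair$bdp_end - assigned$midpoint     # right TSS = bdp_end
  if (d_left <= d_right)
    list(proximal = pair$left_gene, distal = pair$right_gene,
         dist_proximal = as.integer(d_left), dist_distal = as.integer(d_right))
  else
    list(proximal = pair$right_gene, distal = pair$left_gene,
         dist_proximal = as.integer(d_right), dist_distal = as.integer(d_left))
}

#' Classify every BDP in a pairs table
#'
#' Driver over [assign_peaks_to_bdp()] and [classify_dhs_category()]. For
#' single-peak BDPs the per-gene peak-to-TSS distances and the
#' proximal/distal labels are recorded.
#'
#' @param pairs Pairs data frame from [find_bidirectional_pairs()].
#' @param peaks Peak data frame from [read_bed_peaks()].
#' @param cfg A [classifier_config()].
#' @return `pairs` with added columns `category`, `n_peaks`, `peak_ids`,
#'   `dist_left`, `dist_right`, `proximal_gene`, `distal_gene`.
#' @export
classify_pairs <- function(pairs, peaks, cfg = classifier_config()) {
  n <- nrow(pairs)
  category <- character(n); n_peaks <- integer(n); peak_ids <- character(n)
  dist_left <- rep(NA_integer_, n); dist_right <- rep(NA_integer_, n)
  proximal <- rep(NA_character_, n); distal <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    pair <- pairs[k, , drop = FALSE]
    assigned <- assign_peaks_to_bdp(pair, peaks, cfg)
    category[k] <- classify_dhs_category(pair, assigned, cfg)
    n_peaks[k] <- nrow(assigned)
    peak_ids[k] <- paste(assigned$peak_id, collapse = ",")
    if (nrow(assigned) == 1L) {
      dist_left[k] <- assigned$midpoint - pair$bdp_start
      dist_right[k] <- pair$bdp_end - assigned$midpoint
      sp <- proximal_distal_split(pair, assigned)
      proximal[k] <- sp$proximal
      distal[k] <- sp$distal
    }
  }
  out <- pairs
  out$category <- factor(category, levels = DHS_CATEGORIES)
  out$n_peaks <- n_peaks
  out$peak_ids <- peak_ids
  out$dist_left <- dist_left
  out$dist_right <- dist_right
  out$proximal_gene <- proximal
  out$distal_gene <- distal
  out
}

#' Group genes by the distance of their single upstream DHS to the TSS
#'
#' Strand-aware: only peaks whose midpoint lies strictly upstream of the
#' TSS within `max_distance` bp qualify. Genes with zero or two or more
#' qualifying peaks are excluded and counted in the `"excluded"` attribute.
#' Bins are `(0, bin_width], (bin_width, 2*bin_width], ...`.
#'
#' @param genes Gene models (typically unidirectional genes).
#' @param peaks Peak data frame.
#' @param bin_width Bin width in bp; must divide `max_distance`.
#' @param max_distance Maximum upstream distance in bp.
#' @return Data frame `gene_id`, `peak_id`, `distance`, `bin`, with
#'   attribute `excluded = c(none = ..., multiple = ...)`.
#' @export
bin_genes_by_dhs_distance <- function(genes, peaks, bin_width = 100,
                                      max_distance = 1000) {
  if (max_distance %% bin_width != 0)
    stop("bin_width (", bin_width, ") must divide max_distance (",
         max_distance, ")", call. = FALSE)
  t <- tss(genes)
  rows <- vector("list", nrow(genes))
  n_none <- 0L; n_multi <- 0L
  for (k in seq_len(nrow(genes))) {
    on_chr <- peaks$chrom == genes$chrom[k]
    d <- if (genes$strand[k] == "+") t[k] - peaks$midpoint
         else peaks$midpoint - t[k]
    hit <- which(on_chr & d > 0 & d <= max_distance)
    if (length(hit) == 0L) { n_none <- n_none + 1L; next }
    if (length(hit) > 1L) { n_multi <- n_multi + 1L; next }
    rows[[k]] <- data.frame(gene_id = genes$gene_id[k],
                            peak_id = peaks$peak_id[hit],
                            distance = as.integer(d[hit]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), peak_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  out$bin <- as.character(cut(out$distance,
                              breaks = seq(0, max_distance, by = bin_width),
                              right = TRUE))
  rownames(out) <- NULL
  attr(out, "excluded") <- c(none = n_none, multiple = n_multi)
  out
}

#' Category counts and percentages per size class
#'
#' `category_summary()` tabulates a classified pairs table;
#' `category_percentages()` is the arithmetic core taking raw counts
#' (a matrix with one row per size class and one column per category),
#' useful for checking printed contingency tables. Percentages are
#' `100 * count / row total` rounded to 2 decimals.
#'
#' @param classified Output of [classify_pairs()].
#' @return Long data frame `size_class`, `category`, `n`, `percent`,
#'   `class_total`.
#' @export
category_summary <- function(classified) {
  stopifnot("category" %in% names(classified))
  sc <- factor(classified$size_class, levels = c("I", "II", "III"))
  tab <- table(size_class = sc,
               category = factor(classified$category,
                                 levels = DHS_CATEGORIES))
  category_percentages(unclass(tab))
}

#' @rdname category_summary
#' @param counts Numeric matrix of counts, rows = size classes, columns =
#'   categories (any labels).
#' @export
category_percentages <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts))
  if (is.null(colnames(counts))) colnames(counts) <- DHS_CATEGORIES[seq_len(ncol(counts))]
  totals <- rowSums(counts)
  pct <- 100 * counts / ifelse(totals == 0, NA, totals)
  out <- data.frame(
    size_class = rep(rownames(counts), each = ncol(counts)),
    category = rep(colnames(counts), times = nrow(counts)),
    n = as.vector(t(counts)),
    percent = round(as.vector(t(pct)), 2),
    class_total = rep(totals, each = ncol(counts)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
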