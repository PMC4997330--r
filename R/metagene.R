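# Windowed, normalized occupancy profiles (MNase-seq / ChIP-seq style)
# around BDPs and TSSs.
#
# Reads (or fragments) are represented by their midpoints. Densities are
# reads per bp per million mapped reads: count / (window_width *
# total_mapped / 1e6). Windows are half-open and tile a region left to
# right without overlap.

#' Load fragment midpoints
#'
#' Accepts a fragment BED (3+ columns; midpoint = `floor((start+end)/2)`)
#' or a two-column TSV of precomputed midpoints with header
#' `chrom`, `pos`. Single-end data must be midpoint-shifted by the caller
#' before loading.
#'
#' @param path Input path.
#' @param total_mapped Library size (all mapped reads); defaults to the
#'   record count, with a message.
#' @param format `"auto"`, `"bed"` or `"midpoints"`.
#' @return Object of class `fragment_midpoints`: list with `mids` (named
#'   list of sorted integer vectors per chromosome) and `total_mapped`.
#' @export
load_fragments <- function(path, total_mapped = NULL,
                           format = c("auto", "bed", "midpoints")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first)) {
    warning("empty fragment file: ", path)
    return(structure(list(mids = list(), total_mapped = total_mapped %||% 0L),
                     class = "fragment_midpoints"))
  }
  if (format == "auto") {
    f1 <- strsplit(first, "[ \t]+")[[1L]]
    format <- if (length(f1) >= 2L && identical(tolower(f1[1:2]), c("chrom", "pos")))
      "midpoints" else "bed"
  }
  if (format == "bed") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            select = 1:3, col.names = c("chrom", "start", "end"),
                            colClasses = list(character = 1),
                            showProgress = FALSE)
    if (!is.numeric(dt$start) || !is.numeric(dt$end))
      stop("malformed fragment BED: non-numeric coordinates in ", path,
           call. = FALSE)
    bad <- which(is.na(dt$start) | is.na(dt$end) | dt$start >= dt$end)
    if (length(bad))
      stop("malformed fragment record at line ", bad[1L], " of ", path,
           call. = FALSE)
    chrom <- dt$chrom
    mid <- (as.integer(dt$start) + as.integer(dt$end)) %/% 2L
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
                            showProgress = FALSE)
    if (!all(c("chrom", "pos") %in% names(dt)))
      stop("midpoint TSV must have columns 'chrom' and 'pos'", call. = FALSE)
    bad <- which(is.na(dt$pos))
    if (length(bad))
      stop("malformed midpoint record at line ", bad[1L] + 1L, " of ", path,
           call. = FALSE)
    chrom <- as.character(dt$chrom)
    mid <- as.integer(dt$pos)
  }
  mids <- lapply(split(mid, chrom), sort)
  if (is.null(total_mapped)) {
    total_mapped <- length(mid)
    message("total_mapped not supplied; using record count (", total_mapped, ")")
  }
  if (total_mapped < length(mid))
    stop("total_mapped (", total_mapped, ") smaller than the number of ",
         "stored midpoints (", length(mid), ")", call. = FALSE)
  structure(list(mids = mids, total_mapped = as.numeric(total_mapped)),
            class = "fragment_midpoints")
}

#' Windowed normalized density over a region
#'
#' Tiles `[start, end)` left to right in half-open windows of `window` bp
#' (a shorter final window is used when the region length is not a
#' multiple, and densities stay per-bp correct). Each value is
#' `count / (width * total_mapped / 1e6)`.
#'
#' @param frags A `fragment_midpoints` object.
#' @param chrom Chromosome name.
#' @param start,end Region, 0-based half-open.
#' @param window Window width in bp.
#' @return Numeric density vector with attributes `counts`, `widths`,
#'   `chrom`, `start`, `end`.
#' @export
windowed_density <- function(frags, chrom, start, end, window = 50) {
  stopifnot(inherits(frags, "fragment_midpoints"))
  if (frags$total_mapped <= 0)
    stop("total_mapped must be > 0 for normalization", call. = FALSE)
  if (end <= start) stop("end must exceed start", call. = FALSE)
  len <- end - start
  n_full <- len %/% window
  rem <- len %% window
  widths <- c(rep(window, n_full), if (rem > 0) rem)
  breaks <- start + cumsum(c(0, widths))
  v <- frags$mids[[chrom]]
  counts <- if (is.null(v) || length(v) == 0L) integer(length(widths)) else
    diff(findInterval(breaks - 0.5, v))
  dens <- counts / (widths * frags$total_mapped / 1e6)
  structure(dens, counts = as.integer(counts), widths = widths,
            chrom = chrom, start = start, end = end)
}

#' Expression-oriented occupancy profile of one BDP pair
#'
#' The profiled region is: 1 kb downstream of the left gene's TSS (the
#' left flank), the BDP interval between the TSSs, and 1 kb downstream of
#' the right gene's TSS (the right flank), tiled in `window`-bp windows.
#' When the left gene has the higher mean FPKM, the whole vector is
#' reversed so the higher-expressed gene always reads rightward; an exact
#' FPKM tie keeps the original orientation.
#'
#' @param pair One-row pairs data frame.
#' @param frags A `fragment_midpoints` object.
#' @param fpkm Named numeric vector of per-gene mean FPKM.
#' @param flank Flank length in bp (downstream of each TSS).
#' @param window Window width in bp.
#' @return List of class `pair_profile` with `flank_left`, `bdp`,
#'   `flank_right` (densities), `bdp_widths`, `flipped`, `pair_id`;
#'   or `NULL` (with a warning) when an FPKM value is missing or the
#'   region runs off the chromosome start.
#' @export
oriented_pair_profile <- function(pair, frags, fpkm, flank = 1000,
                                  window = 50) {
  stopifnot(nrow(pair) == 1L)
  fL <- fpkm[pair$left_gene]; fR <- fpkm[pair$right_gene]
  if (is.na(fL) || is.na(fR) ||
      !all(c(pair$left_gene, pair$right_gene) %in% names(fpkm))) {
    warning("pair ", pair$pair_id, " skipped: missing FPKM")
    return(NULL)
  }
  if (pair$bdp_start - flank < 0) {
    warning("pair ", pair$pair_id, " skipped: flank runs off chromosome start")
    return(NULL)
  }
  left <- windowed_density(frags, pair$chrom, pair$bdp_start - flank,
                           pair$bdp_start, window)
  bdp <- windowed_density(frags, pair$chrom, pair$bdp_start, pair$bdp_end,
                          window)
  right <- windowed_density(frags, pair$chrom, pair$bdp_end,
                            pair$bdp_end + flank, window)
  flipped <- unname(fL > fR)
  prof <- list(flank_left = as.numeric(left), bdp = as.numeric(bdp),
               flank_right = as.numeric(right),
               bdp_widths = attr(bdp, "widths"),
               counts = c(attr(left, "counts"), attr(bdp, "counts"),
                          attr(right, "counts")),
               flipped = flipped, pair_id = pair$pair_id)
  if (flipped) {
    prof <- list(flank_left = rev(prof$flank_right), bdp = rev(prof$bdp),
                 flank_right = rev(prof$flank_left),
                 bdp_widths = rev(prof$bdp_widths),
                 counts = rev(prof$counts),
                 flipped = TRUE, pair_id = prof$pair_id)
  }
  structure(prof, class = "pair_profile")
}

#' TSS-centred oriented occupancy profile (UDP control)
#'
#' Upstream and downstream `flank`-bp of the TSS, in transcription
#' orientation (upstream to the left).
#'
#' @inheritParams oriented_pair_profile
#' @param gene One-row gene-model data frame.
#' @return A `pair_profile` with an empty `bdp` segment, or `NULL` when the
#'   region runs off the chromosome start.
#' @export
oriented_tss_profile <- function(gene, frags, flank = 1000, window = 50) {
  stopifnot(nrow(gene) == 1L)
  t <- tss(gene)
  if (gene$strand == "+") {
    if (t - flank < 0) {
      warning("gene ", gene$gene_id, " skipped: flank off chromosome start")
      return(NULL)
    }
    up <- windowed_density(frags, gene$chrom, t - flank, t, window)
    down <- windowed_density(frags, gene$chrom, t, t + flank, window)
    fl <- as.numeric(up); fr <- as.numeric(down)
    cnt <- c(attr(up, "counts"), attr(down, "counts"))
  } else {
    if (t + 1 - flank < 0) {
      warning("gene ", gene$gene_id, " skipped: flank off chromosome start")
      return(NULL)
    }
    up <- windowed_density(frags, gene$chrom, t + 1, t + 1 + flank, window)
    down <- windowed_density(frags, gene$chrom, t + 1 - flank, t + 1, window)
    fl <- rev(as.numeric(up)); fr <- rev(as.numeric(down))
    cnt <- c(rev(attr(up, "counts")), rev(attr(down, "counts")))
  }
  structure(list(flank_left = fl, bdp = numeric(0), flank_right = fr,
                 bdp_widths = numeric(0), counts = cnt, flipped = FALSE,
                 pair_id = gene$gene_id),
            class = "pair_profile")
}

# Linear rescale of a windowed vector (possibly unequal widths) onto a
# fixed number of equal windows, interpolating between width-weighted
# window centres.
rescale_windows <- function(v, widths, n_out) {
  n <- length(v)
  if (n_out == 0L || n == 0L) return(numeric(0))
  if (n == 1L) return(rep(v, n_out))
  centres <- (cumsum(widths) - widths / 2) / sum(widths)
  xout <- (seq_len(n_out) - 0.5) / n_out
  stats::approx(centres, v, xout = xout, rule = 2)$y
}

#' Average per-pair profiles into a metagene profile
#'
#' Flanks are fixed-length and averaged window-by-window; BDP segments of
#' different lengths are linearly rescaled onto a fixed `bdp_windows`-window
#' frame before averaging.
#'
#' @param profiles List of `pair_profile` objects (NULL entries dropped).
#' @param bdp_windows Number of windows the BDP interval is rescaled to.
#' @return Object of class `metagene_profile`: list with `values`,
#'   `n_regions`, `n_flank_windows`, `bdp_windows`, `segments`.
#' @export
aggregate_profiles <- function(profiles, bdp_windows = 20) {
  profiles <- Filter(Negate(is.null), profiles)
  if (!length(profiles)) stop("no profiles to aggregate", call. = FALSE)
  n_flank <- length(profiles[[1L]]$flank_left)
  has_bdp <- any(vapply(profiles, function(p) length(p$bdp) > 0L, TRUE))
  nb <- if (has_bdp) bdp_windows else 0L
  mat <- t(vapply(profiles, function(p) {
    if (length(p$flank_left) != n_flank)
      stop("inconsistent flank lengths across profiles", call. = FALSE)
    c(p$flank_left, rescale_windows(p$bdp, p$bdp_widths, nb), p$flank_right)
  }, numeric(2L * n_flank + nb)))
  structure(list(values = colMeans(mat),
                 n_regions = length(profiles),
                 n_flank_windows = n_flank,
                 bdp_windows = nb,
                 segments = c(rep("flank_left", n_flank),
                              rep("bdp", nb),
                              rep("flank_right", n_flank))),
            class = "metagene_profile")
}

#' @export
#' @method as.data.frame metagene_profile
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(window = seq_along(x$values), segment = x$segments,
             mean_density = x$values, n_regions = x$n_regions,
             stringsAsFactors = FALSE)
}

#' Normalized density in the +1 nucleosome window downstream of a TSS
#'
#' Density (per bp per million) in the strand-aware window
#' `[TSS + offsets[1], TSS + offsets[2])` (mirrored to
#' `[TSS - offsets[2], TSS - offsets[1])` on the minus strand), the window
#' where the highest downstream occupancy peak is expected.
#'
#' @param gene One-row gene-model data frame.
#' @param frags A `fragment_midpoints` object.
#' @param offsets Two offsets in bp downstream of the TSS.
#' @return A single density, or `NA` (with a warning) when the window runs
#'   off the chromosome start.
#' @export
tss_peak_summary <- function(gene, frags, offsets = c(100, 150)) {
  stopifnot(nrow(gene) == 1L, length(offsets) == 2L, offsets[1] < offsets[2])
  t <- tss(gene)
  if (gene$strand == "+") {
    s <- t + offsets[1]; e <- t + offsets[2]
  } else {
    s <- t - offsets[2]; e <- t - offsets[1]
  }
  if (s < 0) {
    warning("gene ", gene$gene_id, ": peak window off chromosome start")
    return(NA_real_)
  }
  as.numeric(windowed_density(frags, gene$chrom, s, e, window = e - s))
}

#' Estimate the phasing period of an occupancy profile
#'
#' First maximum of the profile autocorrelation at nonzero lag, in bp.
#'
#' @param values Numeric profile (equal window widths).
#' @param window Window width in bp.
#' @param min_lag Smallest lag (in windows) considered.
#' @return Estimated period in bp.
#' @export
estimate_phasing_period <- function(values, window = 50, min_lag = 2) {
  n <- length(values)
  max_lag <- max(min_lag, n %/% 2L)
  ac <- stats::acf(values, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf
  lags <- seq.int(min_lag, max_lag)
  best <- lags[which.max(ac[lags + 1L])]
  best * window
}
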