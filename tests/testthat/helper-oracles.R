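# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive re-implementations used only to check the package's
# optimised code paths.

# Naive double loop over adjacent gene duos applying the pairing predicate.
brute_force_pairs <- function(genes, max_distance = 1000) {
  t <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  hits <- list()
  for (i in seq_len(nrow(genes) - 1L)) {
    j <- i + 1L
    if (genes$chrom[i] != genes$chrom[j]) next
    if (!(genes$strand[i] == "-" && genes$strand[j] == "+")) next
    len <- t[j] - t[i]
    if (len <= 0 || len > max_distance) next
    if (genes$end[i] > genes$start[j]) next
    third <- FALSE
    for (k in seq_len(nrow(genes))) {
      if (k == i || k == j || genes$chrom[k] != genes$chrom[i]) next
      if (genes$end[k] > genes$end[i] && genes$start[k] < genes$start[j]) {
        third <- TRUE; break
      }
    }
    if (third) next
    hits[[length(hits) + 1L]] <- c(genes$gene_id[i], genes$gene_id[j], len)
  }
  hits
}

# Random gene layout (may contain overlaps and nested genes), sorted.
random_genome <- function(n_genes, seed) {
  set.seed(seed)
  g <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(c("c1", "c2"), n_genes, replace = TRUE),
    start = sample.int(30000L, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  g$end <- g$start + sample(200:2500, n_genes, replace = TRUE)
  g <- g[order(g$chrom, g$start, g$end), ]
  rownames(g) <- NULL
  g
}

# Sup-distance between ECDFs evaluated at every pooled sample point.
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# Gene-model and pairs-row constructors for hand-built cases.
make_genes <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = r[[2]], start = as.integer(r[[3]]),
               end = as.integer(r[[4]]), strand = r[[5]],
               stringsAsFactors = FALSE)))
  df[order(df$chrom, df$start, df$end), ]
}

make_pair <- function(bdp_start, bdp_end, chrom = "c1",
                      left_gene = "gL", right_gene = "gR") {
  data.frame(pair_id = "P1", chrom = chrom, left_gene = left_gene,
             right_gene = right_gene,
             left_start = bdp_start - 1000L, left_end = bdp_start + 1L,
             right_start = bdp_end, right_end = bdp_end + 1000L,
             bdp_start = as.integer(bdp_start), bdp_end = as.integer(bdp_end),
             bdp_length = as.integer(bdp_end - bdp_start),
             size_class = bdp_size_class(bdp_end - bdp_start),
             stringsAsFactors = FALSE)
}

make_peaks <- function(starts, ends, chrom = "c1") {
  n <- length(starts)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(starts),
             end = as.integer(ends),
             peak_id = sprintf("pk%02d", seq_len(n)),
             score = rep(NA_real_, n),
             midpoint = (as.integer(starts) + as.integer(ends)) %/% 2L,
             stringsAsFactors = FALSE)
}

write_toy_gff3 <- function(genes, path) {
  write_gff3(genes, path)
  path
}

# Small, fast simulation settings for tests; study-scale parameters are the
# package defaults.
small_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_pairs = c(I = 10, II = 10, III = 10),
               n_filler = 40, library_size = 1e5)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# Match classifier output to planted truth by BDP start coordinate.
match_planted <- function(classified, truth_pairs) {
  merge(classified, truth_pairs[, c("bdp_start", "category")],
        by = "bdp_start", suffixes = c("", ".planted"))
}

# In-memory fragment_midpoints construction for hand-built occupancy cases.
frags_from_mids <- function(mids, chrom = "c1", total_mapped = NULL) {
  structure(list(mids = stats::setNames(list(sort(as.integer(mids))), chrom),
                 total_mapped = total_mapped %||% length(mids)),
            class = "fragment_midpoints")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
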