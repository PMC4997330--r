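# Expression-level statistics: K-S comparisons between gene groups,
# pair coexpression (Pearson over libraries) and its controls.

#' Load a gene x library FPKM matrix from TSV
#'
#' First column holds gene ids, header row holds library ids. Values must
#' be non-negative numbers; a non-numeric or missing cell is an error
#' naming the gene and library (set `na_as_zero = TRUE` to convert missing
#' cells to 0 with a warning).
#'
#' @param path Path to the TSV.
#' @param na_as_zero Replace missing cells by 0 instead of failing.
#' @return Numeric matrix with gene ids as rownames, library ids as
#'   colnames.
#' @export
load_expression <- function(path, na_as_zero = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L)
    stop("expression table needs a gene-id column plus >= 1 library",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated gene id in ", path, ": ", dup[1L], call. = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    suppress <- suppressWarnings(apply(df[, -1L, drop = FALSE], 2,
                                       function(x) as.numeric(as.character(x))))
    bad <- which(is.na(suppress) & !is.na(as.matrix(df[, -1L, drop = FALSE])),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric expression value at gene ", ids[bad[1L, 1L]],
           ", library ", colnames(df)[-1L][bad[1L, 2L]], call. = FALSE)
    mat <- suppress
  }
  if (anyNA(mat)) {
    if (!na_as_zero) {
      bad <- which(is.na(mat), arr.ind = TRUE)
      stop("missing expression value at gene ", ids[bad[1L, 1L]],
           ", library ", colnames(mat)[bad[1L, 2L]],
           " (use na_as_zero = TRUE to zero-fill)", call. = FALSE)
    }
    warning(sum(is.na(mat)), " missing cells set to 0")
    mat[is.na(mat)] <- 0
  }
  if (any(mat < 0))
    stop("negative FPKM values are not allowed", call. = FALSE)
  rownames(mat) <- ids
  mat
}

#' Write an FPKM matrix as TSV
#'
#' @param mat Numeric matrix, genes in rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided, asymptotic p-value (Kolmogorov distribution with effective
#' sample size n1*n2/(n1+n2)); D is the supremum of the absolute ECDF
#' difference over the pooled sample points.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return List of class `ks_result` with `statistic` (D), `p_value`,
#'   `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("empty sample in ks_two_sample()", call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided",
                                        exact = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 n1 = length(x), n2 = length(y)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample K-S: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Returns `NA` (an "undefined" flag, excluded from downstream
#' distributions) when either vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Library columns whose values are all in {0, 1}: presence/absence (DGE)
# libraries, excluded from Pearson coexpression by default because mixing
# binary and continuous scales distorts the correlation.
binary_libraries <- function(mat) {
  which(apply(mat, 2, function(v) all(v %in% c(0, 1))))
}

#' Pair coexpression across expression libraries
#'
#' One Pearson correlation per gene pair over the (continuous) libraries.
#' Pairs where either gene has FPKM = 0 across all libraries are excluded
#' (and counted), as are pairs with a zero-variance gene or a gene missing
#' from the matrix.
#'
#' @param mat FPKM matrix from [load_expression()].
#' @param pairs Data frame with columns `pair_id`, `left_gene`,
#'   `right_gene` (BDP pairs or control duos).
#' @param exclude_binary Drop libraries whose values are all 0/1.
#' @return Data frame `pair_id`, `left_gene`, `right_gene`, `pcc`,
#'   `n_libraries_used`, `excluded`, `reason`.
#' @export
pair_coexpression <- function(mat, pairs, exclude_binary = TRUE) {
  use <- seq_len(ncol(mat))
  if (exclude_binary) {
    bin <- binary_libraries(mat)
    if (length(bin) && length(bin) < ncol(mat)) {
      message(length(bin), " presence/absence (binary) libraries excluded ",
              "from coexpression: ", paste(colnames(mat)[bin], collapse = ", "))
      use <- setdiff(use, bin)
    }
  }
  m <- mat[, use, drop = FALSE]
  n <- nrow(pairs)
  pcc <- rep(NA_real_, n); nl <- rep(length(use), n)
  excluded <- logical(n); reason <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    g1 <- pairs$left_gene[k]; g2 <- pairs$right_gene[k]
    if (!(g1 %in% rownames(m)) || !(g2 %in% rownames(m))) {
      warning("pair ", pairs$pair_id[k], " skipped: gene missing from matrix")
      excluded[k] <- TRUE; reason[k] <- "missing_gene"; next
    }
    x <- m[g1, ]; y <- m[g2, ]
    if (all(mat[g1, ] == 0) || all(mat[g2, ] == 0)) {
      excluded[k] <- TRUE; reason[k] <- "all_zero"; next
    }
    r <- pearson_correlation(x, y)
    if (is.na(r)) { excluded[k] <- TRUE; reason[k] <- "zero_variance"; next }
    pcc[k] <- r
  }
  data.frame(pair_id = pairs$pair_id, left_gene = pairs$left_gene,
             right_gene = pairs$right_gene, pcc = pcc,
             n_libraries_used = nl, excluded = excluded, reason = reason,
             stringsAsFactors = FALSE)
}

#' Random non-adjacent control gene duos
#'
#' Samples `n` gene duos from genes not participating in any BDP pair,
#' rejecting duos that are adjacent in annotation order on the same
#' chromosome. Sampling is without replacement of duos and reproducible
#' given `seed`.
#'
#' @param genes Gene models sorted by annotation order (see [read_gff3()]).
#' @param pairs BDP pairs data frame; its genes are removed from the pool.
#' @param n Number of duos.
#' @param seed Integer seed.
#' @return Data frame `pair_id`, `left_gene`, `right_gene` (usable with
#'   [pair_coexpression()]).
#' @export
random_control_pairs <- function(genes, pairs, n = 1000, seed = 1) {
  in_pair <- genes$gene_id %in% c(pairs$left_gene, pairs$right_gene)
  pool <- which(!in_pair)
  m <- length(pool)
  # adjacent-in-annotation duos within the pool
  adj <- sum(diff(pool) == 1L &
               genes$chrom[pool[-length(pool)]] == genes$chrom[pool[-1L]])
  max_duos <- choose(m, 2) - adj
  if (m < 2L || n > max_duos)
    stop("control pool supports at most ", max(0, max_duos),
         " non-adjacent duos; ", n, " requested", call. = FALSE)
  local_seed(seed, {
    seen <- character(0)
    out_i <- integer(0); out_j <- integer(0)
    while (length(out_i) < n) {
      need <- n - length(out_i)
      a <- sample(pool, 2L * need + 10L, replace = TRUE)
      b <- sample(pool, 2L * need + 10L, replace = TRUE)
      i <- pmin(a, b); j <- pmax(a, b)
      ok <- i != j & !(j - i == 1L & genes$chrom[i] == genes$chrom[j])
      key <- paste(i, j)
      ok <- ok & !(key %in% seen) & !duplicated(key)
      if (any(ok)) {
        take <- which(ok)[seq_len(min(need, sum(ok)))]
        out_i <- c(out_i, i[take]); out_j <- c(out_j, j[take])
        seen <- c(seen, key[take])
      }
    }
    data.frame(pair_id = sprintf("CTRL%05d", seq_len(n)),
               left_gene = genes$gene_id[out_i],
               right_gene = genes$gene_id[out_j],
               stringsAsFactors = FALSE)
  })
}

#' Fraction of coexpressed pairs per intergenic-distance bin
#'
#' @param pairs BDP pairs data frame (needs `pair_id`, `bdp_length`).
#' @param results Output of [pair_coexpression()].
#' @param pcc_threshold Pairs with `pcc >= pcc_threshold` count as
#'   coexpressed. The threshold is a reporting choice, not a biological
#'   constant; always report it with results.
#' @param bin_width Bin width in bp.
#' @param max_distance Largest intergenic distance considered.
#' @return Data frame `bin`, `n_pairs`, `n_coexpressed`, `fraction`,
#'   `percent`.
#' @export
coexpressed_fraction_by_interval <- function(pairs, results,
                                             pcc_threshold = 0.5,
                                             bin_width = 100,
                                             max_distance = 1000) {
  merged <- merge(pairs[, c("pair_id", "bdp_length")],
                  results[, c("pair_id", "pcc", "excluded")], by = "pair_id")
  merged <- merged[!merged$excluded, , drop = FALSE]
  breaks <- seq(0, max_distance, by = bin_width)
  merged$bin <- cut(merged$bdp_length, breaks = breaks, right = TRUE)
  n_pairs <- tapply(merged$pcc, merged$bin, length)
  n_co <- tapply(merged$pcc >= pcc_threshold, merged$bin, sum)
  n_pairs[is.na(n_pairs)] <- 0L
  frac <- ifelse(n_pairs > 0, n_co / n_pairs, NA_real_)
  data.frame(bin = levels(merged$bin),
             n_pairs = as.integer(n_pairs),
             n_coexpressed = ifelse(is.na(n_co), 0L, as.integer(n_co)),
             fraction = as.numeric(frac),
             percent = round(100 * as.numeric(frac), 2),
             stringsAsFactors = FALSE)
}

# Per-gene expression summary used for group comparisons: mean FPKM across
# libraries (or one named library), then log(x + 1).
gene_expression_values <- function(mat, library = NULL, transform = log1p) {
  v <- if (is.null(library)) rowMeans(mat) else {
    if (!library %in% colnames(mat))
      stop("library '", library, "' not in expression matrix", call. = FALSE)
    mat[, library]
  }
  transform(v)
}

#' Pairwise K-S comparisons between gene groups
#'
#' Each gene is summarised by its mean FPKM across libraries (or a single
#' named library) transformed by `log(FPKM + 1)`, and every pair of groups
#' is compared with a two-sided two-sample K-S test.
#'
#' @param mat FPKM matrix.
#' @param groups Named list of gene-id vectors; all groups non-empty.
#' @param alpha Significance threshold for the `significant` flag.
#' @param library Optional single library name instead of the mean.
#' @param transform Transform applied to the per-gene summary.
#' @return Data frame `group1`, `group2`, `n1`, `n2`, `D`, `p_value`,
#'   `significant` (groups of size < 2 yield an NA row, flagged).
#' @export
compare_groups <- function(mat, groups, alpha = 0.05, library = NULL,
                           transform = log1p) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("empty group: ", names(groups)[lengths(groups) == 0L][1L],
         call. = FALSE)
  v <- gene_expression_values(mat, library = library, transform = transform)
  vals <- lapply(groups, function(g) {
    miss <- setdiff(g, rownames(mat))
    if (length(miss))
      warning(length(miss), " group gene(s) missing from matrix dropped")
    v[intersect(g, rownames(mat))]
  })
  cmb <- utils::combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1L, k]; b <- cmb[2L, k]
    x <- vals[[a]]; y <- vals[[b]]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(group1 = a, group2 = b, n1 = length(x),
                        n2 = length(y), D = NA_real_, p_value = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    ks <- ks_two_sample(x, y)
    data.frame(group1 = a, group2 = b, n1 = ks$n1, n2 = ks$n2,
               D = ks$statistic, p_value = ks$p_value,
               significant = ks$p_value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression-matched sample of unidirectional control genes
#'
#' For each BDP gene, draws (without replacement) one gene from the
#' unidirectional pool falling in the same decile of mean `log(FPKM + 1)`;
#' an exhausted decile falls back to the nearest non-empty one (counted in
#' a message). Reproducible given `seed`.
#'
#' @param mat FPKM matrix covering both gene sets.
#' @param bdp_genes Character vector of BDP gene ids.
#' @param udp_pool Character vector of candidate unidirectional gene ids
#'   (disjoint from `bdp_genes`).
#' @param seed Integer seed.
#' @param n_bins Number of quantile bins (default deciles).
#' @return Character vector of matched control gene ids, same length as
#'   `bdp_genes`.
#' @export
expression_matched_udp_sample <- function(mat, bdp_genes, udp_pool, seed = 1,
                                          n_bins = 10) {
  if (!length(udp_pool)) stop("empty UDP pool", call. = FALSE)
  if (length(udp_pool) < length(bdp_genes))
    stop("UDP pool (", length(udp_pool), ") smaller than the BDP gene set (",
         length(bdp_genes), ")", call. = FALSE)
  if (length(intersect(bdp_genes, udp_pool)))
    stop("UDP pool must be disjoint from BDP genes", call. = FALSE)
  v <- gene_expression_values(mat)
  if (anyNA(v[bdp_genes]) || anyNA(v[udp_pool]))
    stop("genes missing from expression matrix", call. = FALSE)
  breaks <- stats::quantile(v[udp_pool], probs = seq(0, 1, length.out = n_bins + 1))
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L), n_bins)
  pool_bin <- bin_of(v[udp_pool])
  target_bin <- bin_of(v[bdp_genes])
  local_seed(seed, {
    available <- split(seq_along(udp_pool), factor(pool_bin, levels = seq_len(n_bins)))
    n_fallback <- 0L
    out <- character(length(bdp_genes))
    for (k in seq_along(bdp_genes)) {
      b <- target_bin[k]
      if (!length(available[[b]])) {
        n_fallback <- n_fallback + 1L
        dists <- abs(seq_len(n_bins) - b)
        dists[lengths(available) == 0L] <- NA
        b <- which.min(dists)
      }
      pick <- if (length(available[[b]]) == 1L) available[[b]]
              else sample(available[[b]], 1L)
      out[k] <- udp_pool[pick]
      available[[b]] <- setdiff(available[[b]], pick)
    }
    if (n_fallback)
      message(n_fallback, " BDP gene(s) matched from a neighbouring decile")
    out
  })
}
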