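# Expression matrix I/O, K-S wrapper, Pearson coexpression and controls.

test_that("expression matrices round-trip and reject bad input", {
  mat <- matrix(c(0, 1.5, 2.25, 10, 0.125, 3), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), c("libA", "libB")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(mat, path)
  back <- load_expression(path)
  expect_identical(back, mat)   # bit-exact round trip

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tl1", "g1\t1", "g1\t2"), dup)
  expect_error(load_expression(dup), "duplicated gene id")

  chr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tl1\tl2", "g1\t1\toops"), chr)
  expect_error(load_expression(chr), "g1.*l2")
})

test_that("K-S statistic equals the pooled-ECDF sup distance", {
  x <- c(1, 2, 3, 4); y <- c(1.5, 2.5)
  ks <- ks_two_sample(x, y)
  expect_equal(ks$statistic, brute_ks_D(x, y))
  expect_equal(ks$n1, 4L)

  expect_equal(ks_two_sample(c(1, 2, 2, 3), c(1, 2, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(5, 6, 7))$statistic, 1)
  expect_error(ks_two_sample(numeric(0), 1), "empty")

  set.seed(8)
  for (k in 1:200) {
    x <- runif(sample(3:40, 1)); y <- runif(sample(3:40, 1))
    expect_equal(ks_two_sample(x, y)$statistic, brute_ks_D(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches the product-moment formula", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  y <- c(2, 1, 4, 3, 9)
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), want)
  expect_equal(pearson_correlation(x, y), pearson_correlation(y, x))
  expect_equal(pearson_correlation(3 * x + 2, y), pearson_correlation(x, y))
  expect_true(is.na(pearson_correlation(x, rep(1, 5))))
  expect_error(pearson_correlation(1:4, 1:3), "equal length")
})

test_that("pair coexpression applies the all-zero filter and binary exclusion", {
  mat <- rbind(gA = c(1, 2, 3, 4, 5),
               gB = c(2, 4, 6, 8, 10),
               gC = c(0, 0, 0, 0, 0),
               gD = c(5, 4, 3, 2, 1))
  colnames(mat) <- paste0("l", 1:5)
  pairs <- data.frame(pair_id = c("p1", "p2", "p3"),
                      left_gene = c("gA", "gC", "gA"),
                      right_gene = c("gB", "gD", "gZ"),
                      stringsAsFactors = FALSE)
  expect_warning(res <- pair_coexpression(mat, pairs), "missing")
  expect_equal(res$pcc[1], 1)
  expect_true(res$excluded[2]); expect_equal(res$reason[2], "all_zero")
  expect_true(res$excluded[3]); expect_equal(res$reason[3], "missing_gene")

  # a presence/absence library must not sway the correlation
  mat2 <- cbind(mat, dge = c(1, 0, 0, 1))
  expect_message(res2 <- pair_coexpression(mat2, pairs[1, ]), "binary")
  expect_equal(res2$pcc, 1)
  expect_equal(res2$n_libraries_used, 5L)
})

test_that("random control duos are seeded, non-adjacent and outside BDPs", {
  g <- random_genome(120, 31)
  p <- find_bidirectional_pairs(g)
  d1 <- random_control_pairs(g, p, n = 200, seed = 5)
  d2 <- random_control_pairs(g, p, n = 200, seed = 5)
  expect_identical(d1, d2)
  d3 <- random_control_pairs(g, p, n = 200, seed = 6)
  expect_false(identical(d1, d3))

  idx <- match(d1$left_gene, g$gene_id)
  jdx <- match(d1$right_gene, g$gene_id)
  expect_true(all(idx != jdx))
  adjacent <- abs(idx - jdx) == 1L & g$chrom[idx] == g$chrom[jdx]
  expect_false(any(adjacent))
  expect_false(any(c(d1$left_gene, d1$right_gene) %in%
                     c(p$left_gene, p$right_gene)))
  expect_equal(anyDuplicated(paste(pmin(idx, jdx), pmax(idx, jdx))), 0L)

  expect_error(random_control_pairs(g[1:4, ], p, n = 1000), "at most")
})

test_that("coexpressed fraction per bin follows the threshold", {
  pairs <- rbind(make_pair(1000, 1150), make_pair(5000, 5450))
  pairs$pair_id <- c("p1", "p2")
  res <- data.frame(pair_id = c("p1", "p2"), pcc = c(1, 1),
                    excluded = c(FALSE, FALSE))
  out <- coexpressed_fraction_by_interval(pairs, res)
  expect_equal(out$percent[out$n_pairs > 0], c(100, 100))
  res$pcc <- c(0, 0)
  out <- coexpressed_fraction_by_interval(pairs, res)
  expect_equal(out$percent[out$n_pairs > 0], c(0, 0))
  expect_true(all(is.na(out$fraction[out$n_pairs == 0])))
})

test_that("group comparisons report D, p and significance tidily", {
  set.seed(13)
  mat <- matrix(rexp(600), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), paste0("l", 1:6)))
  same <- list(a = rownames(mat)[1:50], b = rownames(mat)[1:50])
  res <- compare_groups(mat, same)
  expect_equal(res$D, 0)
  expect_false(res$significant)

  tiny <- list(a = rownames(mat)[1:40], b = rownames(mat)[41])
  res <- compare_groups(mat, tiny)
  expect_true(is.na(res$D))

  shifted <- list(lo = rownames(mat)[1:50], hi = rownames(mat)[51:100])
  mat2 <- mat; mat2[51:100, ] <- mat2[51:100, ] * 50
  res <- compare_groups(mat2, shifted)
  expect_true(res$significant)
})

test_that("expression-matched UDP sampling is seeded and matches deciles", {
  set.seed(77)
  n_pool <- 2000; n_bdp <- 200
  vals <- rexp(n_pool + n_bdp, rate = 0.2)
  mat <- matrix(rep(vals, 3), ncol = 3,
                dimnames = list(sprintf("g%04d", seq_along(vals)), paste0("l", 1:3)))
  bdp <- rownames(mat)[1:n_bdp]
  pool <- rownames(mat)[(n_bdp + 1):(n_bdp + n_pool)]
  s1 <- expression_matched_udp_sample(mat, bdp, pool, seed = 2)
  s2 <- expression_matched_udp_sample(mat, bdp, pool, seed = 2)
  expect_identical(s1, s2)
  expect_equal(length(s1), n_bdp)
  expect_equal(anyDuplicated(s1), 0L)
  expect_error(expression_matched_udp_sample(mat, bdp, character(0)), "empty")

  # matching quality: when the pool shares the BDP genes' distribution the
  # matched sample should rarely differ significantly
  ok <- vapply(1:100, function(seed) {
    s <- expression_matched_udp_sample(mat, bdp, pool, seed = seed)
    ks_two_sample(log1p(rowMeans(mat)[bdp]),
                  log1p(rowMeans(mat)[s]))$p_value > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
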