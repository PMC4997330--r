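# DHS peak reading, BDP assignment, four-way classification and
# distance binning.

test_that("BED peaks are read with midpoints and validated per line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t300", "c1\t50\t70\tmyPeak\t7.5"), path)
  peaks <- read_bed_peaks(path)
  expect_equal(peaks$midpoint, c(60L, 200L))   # sorted by start
  expect_equal(peaks$peak_id[1], "myPeak")
  expect_equal(peaks$score[1], 7.5)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_warning(p0 <- read_bed_peaks(empty), "no peak records")
  expect_equal(nrow(p0), 0L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t300", "c1\t500\t500"), bad)
  expect_error(read_bed_peaks(bad), "line 2")
})

test_that("random peaks keep sorted order and naive midpoints", {
  set.seed(42)
  n <- 1000
  start <- sample.int(1e6L, n)
  end <- start + sample(50:500, n, replace = TRUE)
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d", chrom, start, end), path)
  peaks <- read_bed_peaks(path)
  o <- order(chrom, start, end)
  expect_equal(peaks$start, start[o])
  expect_equal(peaks$midpoint, ((start + end) %/% 2L)[o])
})

test_that("peak-to-BDP assignment uses the half-open midpoint rule", {
  pair <- make_pair(1000, 1500)
  # midpoint exactly at bdp_end: outside the half-open interval
  expect_equal(nrow(assign_peaks_to_bdp(pair, make_peaks(1400, 1600))), 0L)
  # midpoint 1025 inside
  expect_equal(nrow(assign_peaks_to_bdp(pair, make_peaks(900, 1150))), 1L)

  # brute-force membership on random peaks
  set.seed(7)
  for (rep in 1:20) {
    s <- sample(0:2500, 30)
    pk <- make_peaks(s, s + sample(50:400, 30, replace = TRUE),
                     chrom = sample(c("c1", "c2"), 30, replace = TRUE))
    got <- assign_peaks_to_bdp(pair, pk)$peak_id
    want <- pk$peak_id[pk$chrom == "c1" & pk$midpoint >= 1000 & pk$midpoint < 1500]
    expect_setequal(got, want)
    expect_false(is.unsorted(assign_peaks_to_bdp(pair, pk)$midpoint))
  }
})

test_that("four-way classification follows the centred-fraction rule", {
  pair <- make_pair(1000, 1500)
  cfg <- classifier_config(mid_fraction = 0.25)
  expect_equal(classify_dhs_category(pair, make_peaks(integer(0), integer(0)), cfg),
               "none")
  expect_equal(classify_dhs_category(pair, make_peaks(c(1000, 1300), c(1100, 1400)), cfg),
               "bi")
  expect_equal(classify_dhs_category(pair, make_peaks(1200, 1300), cfg),
               "one_mid")      # midpoint 1250, offset 0 <= 125
  expect_equal(classify_dhs_category(pair, make_peaks(960, 1060), cfg),
               "one_amesial")  # midpoint 1010, offset 240 > 125
})

test_that("mid_fraction is monotone and classification is translation-invariant", {
  pair <- make_pair(1000, 1500)
  fracs <- c(0.45, 0.35, 0.25, 0.15, 0.05)
  for (mid in seq(1001, 1499, by = 14)) {
    pk <- make_peaks(mid - 10, mid + 10)
    cats <- vapply(fracs, function(f)
      classify_dhs_category(pair, pk, classifier_config(mid_fraction = f)), "")
    # once a shrinking central zone calls amesial, it never flips back to mid
    amesial <- cats == "one_amesial"
    expect_true(all(diff(amesial) >= 0), info = paste("midpoint", mid))
  }

  shift <- 12345L
  pair2 <- make_pair(1000 + shift, 1500 + shift)
  for (mid in c(1010, 1250, 1490)) {
    pk1 <- make_peaks(mid - 20, mid + 20)
    pk2 <- make_peaks(mid - 20 + shift, mid + 20 + shift)
    expect_equal(classify_dhs_category(pair, pk1, classifier_config()),
                 classify_dhs_category(pair2, pk2, classifier_config()))
  }
})

test_that("merge_gap unions nearby assigned peaks; default leaves them alone", {
  pair <- make_pair(1000, 2000)
  pk <- make_peaks(c(1100, 1260), c(1250, 1400))
  expect_equal(classify_dhs_category(pair, assign_peaks_to_bdp(pair, pk)), "bi")
  cfg <- classifier_config(merge_gap = 20)
  merged <- assign_peaks_to_bdp(pair, pk, cfg)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 1100L)
  expect_equal(merged$end, 1400L)
})

test_that("peak-to-TSS distance is the absolute midpoint difference", {
  gene <- make_genes(list("g", "c1", 150, 900, "+"))
  expect_equal(dhs_tss_distance(make_peaks(150, 250), gene), 50L)
  expect_equal(dhs_tss_distance(make_peaks(100, 200), gene), 0L)
  expect_error(dhs_tss_distance(make_peaks(100, 200, chrom = "c2"), gene),
               "chromosome")
  set.seed(3)
  for (k in 1:100) {
    s <- sample.int(5000L, 1); w <- sample(50:300, 1)
    strand <- sample(c("+", "-"), 1)
    gs <- sample.int(5000L, 1)
    g <- make_genes(list("g", "c1", gs, gs + 1000L, strand))
    pk <- make_peaks(s, s + w)
    t0 <- if (strand == "+") gs else gs + 999L
    expect_equal(dhs_tss_distance(pk, g), abs(pk$midpoint - t0))
  }
})

test_that("proximal/distal split picks the nearer TSS, ties to the left", {
  pair <- make_pair(1000, 1500)
  sp <- proximal_distal_split(pair, make_peaks(1050, 1150))  # midpoint 1100
  expect_equal(sp$proximal, "gL")
  expect_equal(sp$dist_proximal, 100L)
  # exact centre of a 500-bp BDP
  sp <- proximal_distal_split(pair, make_peaks(1200, 1300))
  expect_equal(sp$proximal, "gL")
  expect_error(proximal_distal_split(pair, make_peaks(integer(0), integer(0))),
               "exactly one")
  set.seed(9)
  for (k in 1:50) {
    m <- sample(1001:1499, 1)
    sp <- proximal_distal_split(pair, make_peaks(m - 10, m + 10))
    want <- if ((m - 1000) <= (1500 - m)) "gL" else "gR"
    expect_equal(sp$proximal, want)
  }
})

test_that("distance binning keeps only single-upstream-peak genes", {
  genes <- make_genes(list("a", "c1", 5000, 7000, "+"),
                      list("b", "c1", 10000, 12000, "+"),
                      list("c", "c1", 20000, 22000, "-"))
  peaks <- make_peaks(c(4943, 9000, 9500, 22058),
                      c(4983, 9100, 9600, 22098))
  res <- bin_genes_by_dhs_distance(genes, peaks)
  # gene a: one peak at distance 37 -> bin (0,100]
  expect_equal(res$distance[res$gene_id == "a"], 37L)
  expect_equal(res$bin[res$gene_id == "a"], "(0,100]")
  # gene b has two upstream peaks: excluded
  expect_false("b" %in% res$gene_id)
  # minus-strand gene c: peak downstream in genome coordinates, distance 79
  expect_equal(res$distance[res$gene_id == "c"], 79L)
  expect_equal(attr(res, "excluded"), c(none = 0L, multiple = 1L))
  expect_error(bin_genes_by_dhs_distance(genes, peaks, bin_width = 300),
               "divide")
})

test_that("distance binning matches a naive all-pairs scan", {
  set.seed(21)
  g <- random_genome(40, 99)
  s <- sample.int(32000L, 60)
  pk <- make_peaks(s, s + 100L, chrom = sample(c("c1", "c2"), 60, replace = TRUE))
  res <- bin_genes_by_dhs_distance(g, pk)
  t <- tss(g)
  for (i in seq_len(nrow(g))) {
    d <- if (g$strand[i] == "+") t[i] - pk$midpoint else pk$midpoint - t[i]
    qual <- which(pk$chrom == g$chrom[i] & d > 0 & d <= 1000)
    in_res <- g$gene_id[i] %in% res$gene_id
    expect_equal(in_res, length(qual) == 1L, info = g$gene_id[i])
    if (in_res)
      expect_equal(res$distance[res$gene_id == g$gene_id[i]],
                   as.integer(d[qual]))
  }
})

test_that("category summary percentages are per-row and sum to 100", {
  out <- category_percentages(rbind(x = c(0, 0, 0, 5)))
  expect_equal(out$percent, c(0, 0, 0, 100))
  set.seed(5)
  counts <- matrix(rpois(12, 40), nrow = 3)
  out <- category_percentages(counts)
  sums <- tapply(out$percent, out$size_class, sum)
  expect_true(all(abs(sums - 100) <= 0.02))
  expect_equal(tapply(out$n, out$size_class, sum)[as.character(1:3)],
               tapply(out$class_total, out$size_class, `[`, 1)[as.character(1:3)])
})

test_that("every classified pair lands in exactly one category", {
  sim <- generate_peaks(generate_annotation(small_sim_config(seed = 4)))
  genes <- sim$genes
  pairs <- find_bidirectional_pairs(genes)
  cl <- classify_pairs(pairs, sim$peaks)
  expect_false(anyNA(cl$category))
  summ <- category_summary(cl)
  totals <- tapply(summ$n, summ$size_class, sum)
  expect_equal(sum(totals), nrow(cl))
  for (sc in c("I", "II", "III"))
    expect_equal(unname(totals[sc]), sum(cl$size_class == sc))
})
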