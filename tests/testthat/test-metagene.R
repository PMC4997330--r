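# Fragment loading, windowed densities, oriented profiles and aggregation.

test_that("fragment midpoints are derived, sorted and tallied per chromosome", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t246", "c2\t10\t160", "c1\t50\t196"), path)
  expect_message(fr <- load_fragments(path), "record count")
  expect_equal(fr$mids$c1, c(123L, 173L))   # [100,246) -> 173
  expect_equal(fr$mids$c2, 85L)
  expect_equal(fr$total_mapped, 3)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_warning(f0 <- load_fragments(empty), "empty")
  expect_equal(f0$total_mapped, 0L)

  set.seed(4)
  n <- 500
  chrom <- sample(c("c1", "c2", "c3"), n, replace = TRUE)
  start <- sample.int(1e5L, n)
  p2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d", chrom, start, start + 146L), p2)
  fr <- load_fragments(p2, total_mapped = n)
  expect_equal(lengths(fr$mids)[sort(unique(chrom))],
               table(chrom)[sort(unique(chrom))],
               ignore_attr = TRUE)
})

test_that("windowed density applies the per-bp per-million formula", {
  fr <- frags_from_mids(125, total_mapped = 1e6)
  d <- windowed_density(fr, "c1", 0, 200, window = 50)
  expect_equal(as.numeric(d), c(0, 0, 1 / 50, 0))   # 1/(50 * 1) = 0.02
  expect_equal(as.numeric(windowed_density(frags_from_mids(integer(0), total_mapped = 10),
                                           "c1", 0, 200)), rep(0, 4))
  expect_error(windowed_density(frags_from_mids(1, total_mapped = 0), "c1", 0, 100),
               "total_mapped")

  set.seed(15)
  mids <- sample.int(2000L, 300, replace = TRUE)
  fr <- frags_from_mids(mids, total_mapped = 5e5)
  d <- windowed_density(fr, "c1", 100, 1100, window = 50)
  naive <- vapply(seq(100, 1050, by = 50), function(s)
    sum(mids >= s & mids < s + 50) / (50 * 5e5 / 1e6), 0)
  expect_equal(as.numeric(d), naive)
})

test_that("window counts reconstruct the raw in-region midpoint count", {
  set.seed(16)
  mids <- sample.int(3000L, 500, replace = TRUE)
  fr <- frags_from_mids(mids, total_mapped = 1e5)
  for (region in list(c(0, 1000), c(37, 1037), c(100, 433))) {
    d <- windowed_density(fr, "c1", region[1], region[2], window = 50)
    raw <- sum(mids >= region[1] & mids < region[2])
    expect_equal(sum(attr(d, "counts")), raw)
    # density * width * (total/1e6) recovers the counts
    expect_equal(as.numeric(d) * attr(d, "widths") * 1e5 / 1e6,
                 as.numeric(attr(d, "counts")))
  }
})

test_that("pair profiles orient the higher-FPKM gene rightward", {
  set.seed(17)
  pair <- make_pair(3000, 3470)
  mids <- sample(2000:4470, 600, replace = TRUE)
  fr <- frags_from_mids(mids, total_mapped = 1e5)
  fpkm_hi_right <- c(gL = 1, gR = 5)
  fpkm_hi_left <- c(gL = 5, gR = 1)
  a <- oriented_pair_profile(pair, fr, fpkm_hi_right)
  b <- oriented_pair_profile(pair, fr, fpkm_hi_left)
  expect_false(a$flipped); expect_true(b$flipped)
  expect_equal(c(b$flank_left, b$bdp, b$flank_right),
               rev(c(a$flank_left, a$bdp, a$flank_right)))
  # involution: flipping the labels twice restores the original
  expect_equal(c(a$flank_left, a$bdp, a$flank_right),
               rev(c(b$flank_left, b$bdp, b$flank_right)))
  # exact tie keeps orientation
  expect_false(oriented_pair_profile(pair, fr, c(gL = 2, gR = 2))$flipped)
  expect_warning(p <- oriented_pair_profile(pair, fr, c(gL = 1)), "FPKM")
  expect_null(p)
})

test_that("aggregation averages profiles on a common 20-window BDP frame", {
  set.seed(18)
  pair <- make_pair(3000, 4000)  # 1000-bp BDP: no rescaling distortion
  fr <- frags_from_mids(sample(2000:5000, 400, replace = TRUE),
                        total_mapped = 1e5)
  prof <- oriented_pair_profile(pair, fr, c(gL = 1, gR = 2))
  agg1 <- aggregate_profiles(list(prof))
  expect_equal(agg1$values, c(prof$flank_left, prof$bdp, prof$flank_right))
  expect_equal(agg1$n_regions, 1L)
  agg2 <- aggregate_profiles(list(prof, prof))
  expect_equal(agg2$values, agg1$values)

  # random same-length vectors: aggregate equals the naive mean
  mk <- function() structure(list(flank_left = runif(20), bdp = runif(20),
                                  bdp_widths = rep(50, 20),
                                  flank_right = runif(20), flipped = FALSE,
                                  pair_id = "x"), class = "pair_profile")
  ps <- replicate(7, mk(), simplify = FALSE)
  agg <- aggregate_profiles(ps)
  naive <- colMeans(do.call(rbind, lapply(ps, function(p)
    c(p$flank_left, p$bdp, p$flank_right))))
  expect_equal(agg$values, naive)
  expect_error(aggregate_profiles(list()), "no profiles")
})

test_that("TSS peak window is strand-mirrored and matches windowed_density", {
  fr <- frags_from_mids(c(1120, 1130, 1890, 2000), total_mapped = 1e6)
  gplus <- make_genes(list("gp", "c1", 1000, 3000, "+"))    # TSS 1000
  gminus <- make_genes(list("gm", "c1", 0, 2001, "-"))      # TSS 2000
  dp <- tss_peak_summary(gplus, fr)    # window [1100, 1150): 2 mids
  expect_equal(dp, 2 / 50)
  dm <- tss_peak_summary(gminus, fr)   # window [1850, 1900): 1 mid
  expect_equal(dm, 1 / 50)
  expect_equal(dp, as.numeric(windowed_density(fr, "c1", 1100, 1150, 50)))
  expect_equal(tss_peak_summary(make_genes(list("g0", "c2", 5000, 9000, "+")), fr), 0)
  expect_warning(na <- tss_peak_summary(make_genes(list("ge", "c1", 0, 120, "-")), fr),
                 "off chromosome")
  expect_true(is.na(na))
})

test_that("autocorrelation recovers the period of a damped cosine profile", {
  x <- seq(0, 1950, by = 50)
  v <- exp(-x / 1500) * cos(2 * pi * x / 165)
  expect_lte(abs(estimate_phasing_period(v, window = 50) - 165), 50)
  v2 <- cos(2 * pi * x / 330)
  expect_lte(abs(estimate_phasing_period(v2, window = 50) - 330), 50)
})
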