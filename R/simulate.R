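# Synthetic data generator with known ground truth.
#
# Emulates the statistical structure the pipeline assumes: divergent gene
# pairs at controlled intergenic distances, DHS peaks planted per category,
# FPKM expression with controlled within-pair correlation and a
# distance-dependent mean, and fragment midpoints forming a
# nucleosome-depleted region (NDR) over each planted DHS flanked by damped
# phased nucleosome arrays.
#
# All generators are pure functions of (config, seed): each stage uses its
# own seed derived from the master seed, so regenerating any stage is
# byte-reproducible.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 290/294/627 pairs in size
#' classes I/II/III, the observed four-category mix per class, 11
#' expression libraries, a 165-bp nucleosome repeat and 1-kb flanks.
#'
#' @param seed Master integer seed.
#' @param n_pairs Named integer vector `c(I=, II=, III=)` of pairs per size
#'   class.
#' @param category_mix 3x4 matrix of category probabilities (rows I/II/III,
#'   columns one_mid/one_amesial/bi/none); rows must sum to 1.
#' @param n_filler Number of unidirectional filler genes.
#' @param filler_peak_prob Probability a filler gene gets one upstream DHS.
#' @param n_libraries Number of expression libraries.
#' @param rho_by_category Target FPKM-scale Pearson correlation per planted
#'   category.
#' @param fpkm_meanlog_intercept,fpkm_meanlog_slope Mean log-FPKM of a gene
#'   as a linear function of its planted DHS-to-TSS distance (bp).
#' @param fpkm_sdlog Log-scale spread of FPKM across libraries.
#' @param zero_rate Fraction of genes planted with FPKM = 0 in all
#'   libraries (exercises the all-zero filter).
#' @param gene_length Gene body length (bp); must leave room for 1-kb
#'   flanks.
#' @param intergene_gap Gap between successive gene units (bp).
#' @param mid_jitter_frac Max offset of a planted mid-DHS from the BDP
#'   centre, as a fraction of BDP length. Together with
#'   `amesial_tss_frac`, keeps planted categories unambiguous for any
#'   classifier `mid_fraction` in (0.1, 0.4).
#' @param amesial_tss_frac Max distance of a planted amesial DHS from its
#'   nearest TSS, as a fraction of BDP length.
#' @param peak_width Range of planted peak widths (bp); even widths are
#'   drawn so the BED midpoint equals the planted midpoint exactly.
#' @param nucleosome_period Nucleosome repeat length (bp).
#' @param nucleosome_sd Spread of fragment midpoints around each
#'   nucleosome dyad (bp).
#' @param n_nucleosomes Nucleosomes per phased array downstream of a TSS.
#' @param occupancy_damping Amplitude decay per successive nucleosome.
#' @param background_rate Background intensity relative to the first
#'   nucleosome's peak amplitude.
#' @param amesial_asymmetry Array-amplitude ratio, DHS-proximal over
#'   DHS-distal gene, for amesial pairs.
#' @param library_size Expected total mapped fragments.
#' @param chrom Chromosome name.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_pairs = c(I = 290, II = 294, III = 627),
                              category_mix = default_category_mix(),
                              n_filler = 1000,
                              filler_peak_prob = 0.7,
                              n_libraries = 11,
                              rho_by_category = c(one_mid = 0.6, one_amesial = 0.25,
                                                  bi = 0.5, none = 0.1),
                              fpkm_meanlog_intercept = 2.2,
                              fpkm_meanlog_slope = -0.002,
                              fpkm_sdlog = 0.8,
                              zero_rate = 0.03,
                              gene_length = 2000,
                              intergene_gap = 2000,
                              mid_jitter_frac = 0.08,
                              amesial_tss_frac = 0.08,
                              peak_width = c(150, 400),
                              nucleosome_period = 165,
                              nucleosome_sd = 20,
                              n_nucleosomes = 6,
                              occupancy_damping = 0.8,
                              background_rate = 0.1,
                              amesial_asymmetry = 2,
                              library_size = 1e6,
                              chrom = "Chr1") {
  category_mix <- as.matrix(category_mix)
  stopifnot(length(n_pairs) == 3L, all(n_pairs > 0),
            nrow(category_mix) == 3L, ncol(category_mix) == 4L,
            all(abs(rowSums(category_mix) - 1) < 1e-8),
            all(category_mix >= 0),
            n_libraries >= 3L,
            all(rho_by_category >= -1 & rho_by_category <= 1),
            all(DHS_CATEGORIES %in% names(rho_by_category)),
            fpkm_sdlog > 0, zero_rate >= 0, zero_rate < 1,
            gene_length >= 1500,   # 1-kb flanks must fit in the gene body
            mid_jitter_frac > 0, mid_jitter_frac <= 0.08,
            amesial_tss_frac > 0, amesial_tss_frac <= 0.08,
            nucleosome_period > 0, occupancy_damping > 0,
            occupancy_damping <= 1, amesial_asymmetry >= 1,
            library_size > 0)
  names(n_pairs) <- c("I", "II", "III")
  rownames(category_mix) <- c("I", "II", "III")
  colnames(category_mix) <- DHS_CATEGORIES
  structure(list(seed = as.integer(seed), n_pairs = n_pairs,
                 category_mix = category_mix, n_filler = n_filler,
                 filler_peak_prob = filler_peak_prob,
                 n_libraries = n_libraries,
                 rho_by_category = rho_by_category,
                 fpkm_meanlog_intercept = fpkm_meanlog_intercept,
                 fpkm_meanlog_slope = fpkm_meanlog_slope,
                 fpkm_sdlog = fpkm_sdlog, zero_rate = zero_rate,
                 gene_length = as.integer(gene_length),
                 intergene_gap = as.integer(intergene_gap),
                 mid_jitter_frac = mid_jitter_frac,
                 amesial_tss_frac = amesial_tss_frac,
                 peak_width = as.integer(peak_width),
                 nucleosome_period = nucleosome_period,
                 nucleosome_sd = nucleosome_sd,
                 n_nucleosomes = as.integer(n_nucleosomes),
                 occupancy_damping = occupancy_damping,
                 background_rate = background_rate,
                 amesial_asymmetry = amesial_asymmetry,
                 library_size = library_size, chrom = chrom),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_category_mix <- function() {
  m <- rbind(I   = c(227, 22, 10, 31) / 290,
             II  = c(74, 92, 36, 92) / 294,
             III = c(27, 237, 158, 205) / 627)
  colnames(m) <- DHS_CATEGORIES
  m
}

# Class-specific intergenic length ranges. Class I starts at 20 bp: below
# that no planted category can be made unambiguous for every classifier
# mid_fraction in (0.1, 0.4) once positions are rounded to integers.
bdp_length_range <- function(size_class) {
  switch(size_class,
         I = c(20L, 250L), II = c(251L, 500L), III = c(501L, 1000L))
}

#' Generate a synthetic genome annotation with planted BDP pairs
#'
#' Lays out divergent gene pairs (intergenic lengths uniform within each
#' size class) and unidirectional filler genes along one chromosome, with
#' gaps large enough that no unplanned divergent pair arises and every
#' 1-kb flank fits. Each pair is assigned a ground-truth DHS category drawn
#' from `cfg$category_mix`.
#'
#' @param cfg A [simulation_config()].
#' @return Object of class `bdp_simulation`: list with `cfg`, `genes`
#'   (gene models as in [read_gff3()]), `truth_pairs`, `truth_genes`
#'   (filler-gene truth) and `chrom_len`.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  local_seed(stage_seed(cfg$seed, 0L), {
    n_pairs_total <- sum(cfg$n_pairs)
    unit_class <- c(rep(names(cfg$n_pairs), cfg$n_pairs),
                    rep("filler", cfg$n_filler))
    unit_class <- sample(unit_class)

    glen <- cfg$gene_length; gap <- cfg$intergene_gap
    pos <- 3000L  # left margin so the first 1-kb flank fits
    gene_rows <- vector("list", length(unit_class) * 2L)
    pair_rows <- vector("list", n_pairs_total)
    filler_rows <- vector("list", cfg$n_filler)
    gi <- 0L; pi <- 0L; fi <- 0L

    for (u in unit_class) {
      if (u == "filler") {
        fi <- fi + 1L
        id <- sprintf("udp%04d", fi)
        strand <- sample(c("+", "-"), 1L)
        gi <- gi + 1L
        gene_rows[[gi]] <- data.frame(gene_id = id, chrom = cfg$chrom,
                                      start = pos, end = pos + glen,
                                      strand = strand,
                                      stringsAsFactors = FALSE)
        t <- if (strand == "+") pos else pos + glen - 1L
        has_peak <- stats::runif(1) < cfg$filler_peak_prob
        filler_rows[[fi]] <- data.frame(
          gene_id = id, strand = strand, tss = t,
          peak_distance = if (has_peak) sample.int(1000L, 1L) else NA_integer_,
          stringsAsFactors = FALSE)
        pos <- pos + glen + gap
      } else {
        pi <- pi + 1L
        pid <- sprintf("bdp%04d", pi)
        rng <- bdp_length_range(u)
        L <- sample(seq.int(rng[1L], rng[2L]), 1L)
        left_start <- pos
        left_end <- pos + glen          # minus-strand gene; TSS = end - 1
        bdp_start <- left_end - 1L
        bdp_end <- bdp_start + L        # plus-strand gene; TSS = start
        right_start <- bdp_end
        right_end <- right_start + glen
        gi <- gi + 1L
        gene_rows[[gi]] <- data.frame(gene_id = paste0(pid, "L"),
                                      chrom = cfg$chrom, start = left_start,
                                      end = left_end, strand = "-",
                                      stringsAsFactors = FALSE)
        gi <- gi + 1L
        gene_rows[[gi]] <- data.frame(gene_id = paste0(pid, "R"),
                                      chrom = cfg$chrom, start = right_start,
                                      end = right_end, strand = "+",
                                      stringsAsFactors = FALSE)
        category <- sample(DHS_CATEGORIES, 1L, prob = cfg$category_mix[u, ])
        pair_rows[[pi]] <- data.frame(
          pair_id = pid, size_class = u,
          left_gene = paste0(pid, "L"), right_gene = paste0(pid, "R"),
          bdp_start = bdp_start, bdp_end = bdp_end, bdp_length = L,
          category = category, stringsAsFactors = FALSE)
        pos <- right_end + gap
      }
    }
    genes <- do.call(rbind, gene_rows[seq_len(gi)])
    genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
    structure(list(cfg = cfg, genes = genes,
                   truth_pairs = do.call(rbind, pair_rows),
                   truth_genes = if (fi > 0L) do.call(rbind, filler_rows)
                                 else NULL,
                   chrom_len = pos + 3000L),
              class = "bdp_simulation")
  })
}

# Even peak width so the BED midpoint floor((start+end)/2) equals the
# planted midpoint exactly.
draw_peak_width <- function(cfg) {
  w <- sample(seq.int(cfg$peak_width[1L], cfg$peak_width[2L]), 1L)
  if (w %% 2L == 1L) w + 1L else w
}

#' Plant DHS peaks according to the ground-truth categories
#'
#' one_mid: one peak jittered within `mid_jitter_frac` of the BDP centre;
#' one_amesial: one peak within `amesial_tss_frac` of one TSS (side drawn
#' at random); bi: two peaks near the BDP quarter points; none: no peak.
#' Filler genes with a planted upstream DHS get one peak at their drawn
#' distance.
#'
#' @param sim A `bdp_simulation` from [generate_annotation()].
#' @return `sim` with `$peaks` added and planted peak midpoints/distances
#'   recorded in `$truth_pairs` (`peak_mid1`, `peak_mid2`, `dist_left`,
#'   `dist_right`, `proximal_gene`).
#' @export
generate_peaks <- function(sim) {
  cfg <- sim$cfg
  local_seed(stage_seed(cfg$seed, 1L), {
    tp <- sim$truth_pairs
    n <- nrow(tp)
    mid1 <- rep(NA_integer_, n); mid2 <- rep(NA_integer_, n)
    dl <- rep(NA_integer_, n); dr <- rep(NA_integer_, n)
    prox <- rep(NA_character_, n)
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      L <- tp$bdp_length[k]
      s <- tp$bdp_start[k]; e <- tp$bdp_end[k]
      centre <- (s + e) / 2
      cat_k <- tp$category[k]
      if (cat_k == "none") next
      if (cat_k == "one_mid") {
        off_max <- floor(cfg$mid_jitter_frac * L)
        m <- as.integer(floor(centre)) + sample(seq.int(-off_max, off_max), 1L)
        mid1[k] <- m
        dl[k] <- m - s; dr[k] <- e - m
        prox[k] <- if (dl[k] <= dr[k]) tp$left_gene[k] else tp$right_gene[k]
      } else if (cat_k == "one_amesial") {
        d <- max(1L, sample.int(max(1L, floor(cfg$amesial_tss_frac * L)), 1L))
        side <- sample(c("L", "R"), 1L)
        m <- if (side == "L") s + d else e - d
        mid1[k] <- m
        dl[k] <- m - s; dr[k] <- e - m
        prox[k] <- if (side == "L") tp$left_gene[k] else tp$right_gene[k]
      } else { # bi
        jit <- max(0L, floor(0.05 * L))
        m1 <- s + as.integer(round(0.25 * L)) +
          if (jit > 0) sample(seq.int(-jit, jit), 1L) else 0L
        m2 <- e - as.integer(round(0.25 * L)) -
          if (jit > 0) sample(seq.int(-jit, jit), 1L) else 0L
        m1 <- min(max(m1, s), e - 1L); m2 <- min(max(m2, s), e - 1L)
        if (m2 <= m1) m2 <- m1 + 1L
        mid1[k] <- m1; mid2[k] <- m2
        dl[k] <- m1 - s; dr[k] <- e - m2   # each gene's nearest peak
      }
      mk <- function(m, tag) {
        w <- draw_peak_width(cfg)
        data.frame(chrom = cfg$chrom, start = m - w %/% 2L,
                   end = m - w %/% 2L + w,
                   peak_id = paste0(tp$pair_id[k], tag),
                   stringsAsFactors = FALSE)
      }
      rows[[k]] <- if (cat_k == "bi")
        rbind(mk(mid1[k], "_a"), mk(mid2[k], "_b")) else mk(mid1[k], "_a")
    }
    frows <- NULL
    if (!is.null(sim$truth_genes)) {
      tg <- sim$truth_genes
      with_peak <- which(!is.na(tg$peak_distance))
      frows <- lapply(with_peak, function(k) {
        m <- if (tg$strand[k] == "+") tg$tss[k] - tg$peak_distance[k]
             else tg$tss[k] + tg$peak_distance[k]
        w <- draw_peak_width(cfg)
        data.frame(chrom = cfg$chrom, start = m - w %/% 2L,
                   end = m - w %/% 2L + w,
                   peak_id = paste0(tg$gene_id[k], "_p"),
                   stringsAsFactors = FALSE)
      })
    }
    peaks <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)], frows))
    peaks$score <- NA_real_
    peaks$midpoint <- (peaks$start + peaks$end) %/% 2L
    peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
    rownames(peaks) <- NULL
    tp$peak_mid1 <- mid1; tp$peak_mid2 <- mid2
    tp$dist_left <- dl; tp$dist_right <- dr
    tp$proximal_gene <- prox
    sim$truth_pairs <- tp
    sim$peaks <- peaks
    sim
  })
}

# Latent Gaussian correlation that yields a target Pearson correlation on
# the lognormal (FPKM) scale: exact inversion of
# cor(exp(X), exp(Y)) = (exp(rho * s^2) - 1) / (exp(s^2) - 1).
latent_rho <- function(rho, sdlog) {
  ifelse(rho == 0, 0, log(1 + rho * (exp(sdlog^2) - 1)) / sdlog^2)
}

#' Generate the expression matrix from the planted ground truth
#'
#' Per pair, FPKM values across libraries are bivariate lognormal with the
#' latent correlation chosen so the population FPKM-scale Pearson
#' correlation equals `rho_by_category[category]`; per-gene mean log-FPKM
#' decreases linearly with the planted DHS-to-TSS distance (no-DHS pairs
#' use the maximum distance of 1000 bp). A `zero_rate` fraction of genes is
#' planted all-zero.
#'
#' @param sim A `bdp_simulation` after [generate_peaks()].
#' @return `sim` with `$expression` (matrix) added, planted per-gene
#'   `meanlog` and `all_zero` flags recorded in the truth tables.
#' @export
generate_expression <- function(sim) {
  cfg <- sim$cfg
  stopifnot(!is.null(sim$truth_pairs$dist_left) || all(sim$truth_pairs$category == "none"))
  local_seed(stage_seed(cfg$seed, 2L), {
    nl <- cfg$n_libraries
    s <- cfg$fpkm_sdlog
    mu_at <- function(d) cfg$fpkm_meanlog_intercept + cfg$fpkm_meanlog_slope * d

    tp <- sim$truth_pairs
    dL <- ifelse(is.na(tp$dist_left), 1000, tp$dist_left)
    dR <- ifelse(is.na(tp$dist_right), 1000, tp$dist_right)
    rho <- unname(cfg$rho_by_category[tp$category])
    rl <- latent_rho(rho, s)

    rows <- vector("list", 2L * nrow(tp) +
                     if (is.null(sim$truth_genes)) 0L else nrow(sim$truth_genes))
    ids <- character(length(rows))
    ri <- 0L
    for (k in seq_len(nrow(tp))) {
      z1 <- stats::rnorm(nl)
      z2 <- rl[k] * z1 + sqrt(1 - rl[k]^2) * stats::rnorm(nl)
      ri <- ri + 1L; ids[ri] <- tp$left_gene[k]
      rows[[ri]] <- exp(mu_at(dL[k]) + s * z1)
      ri <- ri + 1L; ids[ri] <- tp$right_gene[k]
      rows[[ri]] <- exp(mu_at(dR[k]) + s * z2)
    }
    tp$meanlog_left <- mu_at(dL); tp$meanlog_right <- mu_at(dR)
    tp$rho <- rho

    if (!is.null(sim$truth_genes)) {
      tg <- sim$truth_genes
      d <- ifelse(is.na(tg$peak_distance), 500, tg$peak_distance)
      tg$meanlog <- mu_at(d)
      for (k in seq_len(nrow(tg))) {
        ri <- ri + 1L; ids[ri] <- tg$gene_id[k]
        rows[[ri]] <- exp(tg$meanlog[k] + s * stats::rnorm(nl))
      }
      sim$truth_genes <- tg
    }

    mat <- do.call(rbind, rows)
    rownames(mat) <- ids
    colnames(mat) <- sprintf("lib%02d", seq_len(nl))
    zero <- stats::runif(nrow(mat)) < cfg$zero_rate
    mat[zero, ] <- 0
    mat <- round(mat, 4)

    all_zero_ids <- rownames(mat)[zero]
    tp$left_all_zero <- tp$left_gene %in% all_zero_ids
    tp$right_all_zero <- tp$right_gene %in% all_zero_ids
    sim$truth_pairs <- tp
    if (!is.null(sim$truth_genes))
      sim$truth_genes$all_zero <- sim$truth_genes$gene_id %in% all_zero_ids
    sim$expression <- mat
    sim
  })
}

#' Generate fragment midpoints from a phased-nucleosome intensity
#'
#' The per-bp intensity is a uniform background plus, for every gene, a
#' damped train of Gaussian nucleosome bumps starting half a period
#' downstream of its TSS (dyads at `TSS + (k - 1/2) * period` in the
#' direction of transcription). Intensity across each planted DHS interval
#' is suppressed to near zero (the NDR). For amesial pairs the
#' DHS-proximal gene's array is scaled up and the distal gene's down by
#' `sqrt(amesial_asymmetry)` each. The intensity is normalized to integrate
#' to `library_size` and midpoints are Poisson-sampled from it.
#'
#' @param sim A `bdp_simulation` after [generate_peaks()].
#' @return `sim` with `$fragments` (data frame `chrom`, `start`, `end` of
#'   146-bp fragments) and `$total_mapped` added.
#' @export
generate_fragments <- function(sim) {
  cfg <- sim$cfg
  stopifnot(!is.null(sim$peaks))
  local_seed(stage_seed(cfg$seed, 3L), {
    len <- sim$chrom_len
    intensity <- rep(cfg$background_rate, len)
    sd <- cfg$nucleosome_sd
    half_span <- ceiling(3 * sd)
    kern_off <- seq.int(-half_span, half_span)
    kern <- exp(-kern_off^2 / (2 * sd^2))

    amp <- stats::setNames(rep(1, nrow(sim$genes)), sim$genes$gene_id)
    am <- sim$truth_pairs[sim$truth_pairs$category == "one_amesial", ,
                          drop = FALSE]
    if (nrow(am)) {
      a <- sqrt(cfg$amesial_asymmetry)
      for (k in seq_len(nrow(am))) {
        pg <- am$proximal_gene[k]
        dg <- setdiff(c(am$left_gene[k], am$right_gene[k]), pg)
        amp[pg] <- a; amp[dg] <- 1 / a
      }
    }

    t_all <- tss(sim$genes)
    dir_all <- ifelse(sim$genes$strand == "+", 1, -1)
    for (g in seq_len(nrow(sim$genes))) {
      for (k in seq_len(cfg$n_nucleosomes)) {
        dyad <- round(t_all[g] + dir_all[g] * (k - 0.5) * cfg$nucleosome_period)
        idx <- dyad + kern_off + 1L   # genomic pos -> vector index
        ok <- idx >= 1L & idx <= len
        intensity[idx[ok]] <- intensity[idx[ok]] +
          amp[g] * cfg$occupancy_damping^(k - 1) * kern[ok]
      }
    }
    # NDR over every planted DHS
    for (k in seq_len(nrow(sim$peaks))) {
      s <- max(0L, sim$peaks$start[k]); e <- min(len, sim$peaks$end[k])
      if (e > s) intensity[(s + 1L):e] <- intensity[(s + 1L):e] * 0.02
    }

    intensity <- intensity * (cfg$library_size / sum(intensity))
    n_frag <- stats::rpois(1L, cfg$library_size)
    cdf <- cumsum(intensity / sum(intensity))
    mids <- findInterval(stats::runif(n_frag), cdf) # 0-based positions
    mids <- sort(mids[mids >= 73L & mids <= len - 74L])
    n_frag <- length(mids)  # fragments must fit on the chromosome
    sim$fragments <- data.frame(chrom = cfg$chrom, start = mids - 73L,
                                end = mids + 73L, stringsAsFactors = FALSE)
    sim$total_mapped <- n_frag
    sim
  })
}

#' Write a gene-model table as GFF3
#'
#' @param genes Gene models (0-based half-open).
#' @param path Output path.
#' @param source Source field (column 2).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "bdpc") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genes$chrom, source, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Run all generator stages and write a complete synthetic dataset
#'
#' Writes `annotation.gff3`, `dhs_peaks.bed`, `expression.tsv`,
#' `fragments.bed`, `truth_pairs.tsv`, `truth_genes.tsv` and
#' `sim_manifest.json` (configuration echo plus `total_mapped`) into
#' `out_dir`.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param fragments Also generate fragment midpoints (the slowest stage).
#' @return The completed `bdp_simulation`, invisibly.
#' @export
simulate_dataset <- function(cfg, out_dir, fragments = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_expression(generate_peaks(generate_annotation(cfg)))
  if (fragments) sim <- generate_fragments(sim)

  write_gff3(sim$genes, file.path(out_dir, "annotation.gff3"))
  bed <- sim$peaks[, c("chrom", "start", "end", "peak_id")]
  utils::write.table(bed, file.path(out_dir, "dhs_peaks.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_expression(sim$expression, file.path(out_dir, "expression.tsv"))
  if (fragments)
    data.table::fwrite(sim$fragments, file.path(out_dir, "fragments.bed"),
                       sep = "\t", col.names = FALSE)
  write_tsv(sim$truth_pairs, file.path(out_dir, "truth_pairs.tsv"),
            comments = "synthetic ground truth: planted BDP pairs")
  if (!is.null(sim$truth_genes))
    write_tsv(sim$truth_genes, file.path(out_dir, "truth_genes.tsv"),
              comments = "synthetic ground truth: filler (UDP) genes")
  manifest <- list(config = unclass(cfg),
                   total_mapped = if (fragments) sim$total_mapped else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "sim_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}
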