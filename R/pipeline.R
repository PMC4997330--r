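# Pipeline orchestration: each run_*() step consumes raw inputs and the
# files earlier steps emitted, writes tidy TSVs with provenance header
# comments plus a machine-readable manifest, and never mutates its inputs.

PIPELINE_DEFAULTS <- list(
  feature_type = "gene",
  max_distance = 1000,    # TSS-to-TSS limit for pair finding (bp)
  mid_fraction = 0.25,    # central fraction for the one_mid call
  merge_gap = 0,
  pcc_threshold = 0.5,
  bin_width = 100,        # distance-bin width (bp)
  window = 50,            # metagene window (bp)
  flank = 1000,           # flank downstream of each TSS (bp)
  bdp_windows = 20,       # common frame for BDP-interval averaging
  alpha = 0.05,           # K-S significance threshold
  n_control_pairs = 1000, # random non-adjacent control duos
  seed = 1
)

#' Read a flat key=value run configuration
#'
#' Lines are `key = value`; `#` starts a comment. Values that parse as
#' numbers become numeric. Parameters not set fall back to the documented
#' defaults (which equal the study's stated values where it states them).
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return Named list of parameters and paths.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- PIPELINE_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      val <- trimws(paste(kv[-1L], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$mid_fraction <= 0 || cfg$mid_fraction >= 0.5)
    stop("invalid parameter mid_fraction = ", cfg$mid_fraction,
         ": must be in (0, 0.5)", call. = FALSE)
  if (cfg$max_distance <= 0)
    stop("invalid parameter max_distance: must be > 0", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("invalid parameter alpha: must be in (0, 1)", call. = FALSE)
  if (cfg$max_distance %% cfg$bin_width != 0)
    stop("invalid parameter bin_width: must divide max_distance",
         call. = FALSE)
  invisible(cfg)
}

require_input <- function(cfg, key, step) {
  if (is.null(cfg[[key]]) || !file.exists(as.character(cfg[[key]])))
    stop("usage: step '", step, "' requires input '", key,
         "' (missing or not a file)", call. = FALSE)
  as.character(cfg[[key]])
}

# Manifest with parameters, input checksums and package version; no
# timestamps, so reruns are byte-identical.
write_manifest <- function(out_dir, step, cfg, inputs) {
  files <- unlist(inputs)
  checksums <- if (length(files))
    as.list(stats::setNames(unname(tools::md5sum(files)), names(files)))
  else list()
  jsonlite::write_json(
    list(step = step,
         package = "bdpc",
         version = as.character(utils::packageVersion("bdpc")),
         parameters = cfg[setdiff(names(cfg), c("out_dir"))],
         input_md5 = checksums),
    file.path(out_dir, paste0("manifest_", step, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

prov <- function(cfg, keys) {
  sprintf("%s=%s", keys, vapply(cfg[keys], function(x) paste(x, collapse = ","), ""))
}

#' Pipeline steps
#'
#' Each step reads its inputs from the paths in `config`, writes its result
#' TSVs and a JSON manifest into `config$out_dir`, and returns the main
#' result invisibly. Steps are composable: `run_classify()` consumes the
#' pairs table `run_pairs()` wrote, and so on.
#'
#' * `run_pairs`: `gff3` -> `pairs.tsv`, `bdp_intervals.bed`
#' * `run_classify`: `gff3`, `peaks`, pairs -> `classified_pairs.tsv`,
#'   `category_summary.tsv`, `distance_bins.tsv`
#' * `run_expression`: `expression`, classified pairs -> `ks_tests.tsv`
#' * `run_coexpress`: `expression`, `gff3`, classified pairs ->
#'   `coexpression.tsv`, `control_coexpression.tsv`,
#'   `coexpressed_fraction.tsv`, `coexpression_ks.tsv`
#' * `run_metagene`: `fragments`, `expression`, classified pairs ->
#'   `metagene_profiles.tsv`
#' * `run_simulate`: writes a full synthetic dataset
#'
#' @param config Named list from [read_run_config()]; path entries:
#'   `gff3`, `peaks`, `expression`, `fragments`, `out_dir`, and for
#'   `run_metagene` optionally `total_mapped`.
#' @return The step's main data frame, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_pairs <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gff <- require_input(config, "gff3", "pairs")
  genes <- read_gff3(gff, feature_type = config$feature_type)
  pairs <- find_bidirectional_pairs(genes, max_distance = config$max_distance)
  write_pairs_tsv(pairs, file.path(out_dir, "pairs.tsv"),
                  comments = c("bidirectional gene pairs (1-based inclusive)",
                               prov(config, c("max_distance", "feature_type"))))
  write_pairs_bed(pairs, file.path(out_dir, "bdp_intervals.bed"))
  write_manifest(out_dir, "pairs", config, list(gff3 = gff))
  invisible(pairs)
}

#' @rdname pipeline
#' @export
run_classify <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  peaks_path <- require_input(config, "peaks", "classify")
  gff <- require_input(config, "gff3", "classify")
  pairs_path <- config$pairs %||% file.path(out_dir, "pairs.tsv")
  if (!file.exists(pairs_path))
    stop("usage: step 'classify' requires the pairs table (run_pairs first)",
         call. = FALSE)
  pairs <- read_pairs_tsv(pairs_path)
  peaks <- read_bed_peaks(peaks_path)
  cfg <- classifier_config(mid_fraction = config$mid_fraction,
                           merge_gap = config$merge_gap)
  classified <- classify_pairs(pairs, peaks, cfg)
  write_tsv(classified, file.path(out_dir, "classified_pairs.tsv"),
            comments = c("BDPs with DHS positional categories",
                         prov(config, c("mid_fraction", "merge_gap"))))
  write_tsv(category_summary(classified),
            file.path(out_dir, "category_summary.tsv"),
            comments = "category counts and percentages per size class")

  genes <- read_gff3(gff, feature_type = config$feature_type)
  unidir <- genes[!(genes$gene_id %in% c(pairs$left_gene, pairs$right_gene)), ,
                  drop = FALSE]
  bins <- bin_genes_by_dhs_distance(unidir, peaks,
                                    bin_width = config$bin_width,
                                    max_distance = config$max_distance)
  excl <- attr(bins, "excluded")
  write_tsv(bins, file.path(out_dir, "distance_bins.tsv"),
            comments = c("unidirectional genes binned by upstream DHS distance",
                         sprintf("excluded: no_peak=%d multiple_peaks=%d",
                                 excl["none"], excl["multiple"]),
                         prov(config, c("bin_width", "max_distance"))))
  write_manifest(out_dir, "classify", config,
                 list(gff3 = gff, peaks = peaks_path, pairs = pairs_path))
  invisible(classified)
}

#' @rdname pipeline
#' @export
run_expression <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- require_input(config, "expression", "expression")
  cls_path <- config$classified %||% file.path(out_dir, "classified_pairs.tsv")
  if (!file.exists(cls_path))
    stop("usage: step 'expression' requires classified pairs (run_classify first)",
         call. = FALSE)
  mat <- load_expression(expr_path)
  classified <- read_tsv(cls_path)

  pair_genes <- function(sub) c(sub$left_gene, sub$right_gene)
  groups <- list()
  for (sc in c("I", "II", "III")) {
    sub <- classified[classified$size_class == sc, , drop = FALSE]
    if (nrow(sub)) groups[[paste0("BDP_", sc)]] <- pair_genes(sub)
  }
  for (ct in DHS_CATEGORIES) {
    sub <- classified[classified$category == ct, , drop = FALSE]
    if (nrow(sub)) groups[[ct]] <- pair_genes(sub)
  }
  single <- classified[classified$n_peaks == 1, , drop = FALSE]
  if (nrow(single)) {
    groups$proximal <- single$proximal_gene
    groups$distal <- single$distal_gene
  }
  # expression-matched unidirectional control
  bdp_genes <- intersect(pair_genes(classified), rownames(mat))
  pool <- setdiff(rownames(mat), pair_genes(classified))
  if (length(pool) >= length(bdp_genes))
    groups$UDP_matched <- expression_matched_udp_sample(
      mat, bdp_genes, pool, seed = config$seed)

  res <- compare_groups(mat, groups, alpha = config$alpha)
  write_tsv(res, file.path(out_dir, "ks_tests.tsv"),
            comments = c("pairwise two-sided K-S tests on log(mean FPKM + 1)",
                         prov(config, c("alpha", "seed"))))
  write_manifest(out_dir, "expression", config,
                 list(expression = expr_path, classified = cls_path))
  invisible(res)
}

#' @rdname pipeline
#' @export
run_coexpress <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- require_input(config, "expression", "coexpress")
  gff <- require_input(config, "gff3", "coexpress")
  cls_path <- config$classified %||% file.path(out_dir, "classified_pairs.tsv")
  if (!file.exists(cls_path))
    stop("usage: step 'coexpress' requires classified pairs (run_classify first)",
         call. = FALSE)
  mat <- load_expression(expr_path)
  classified <- read_tsv(cls_path)
  genes <- read_gff3(gff, feature_type = config$feature_type)

  coex <- pair_coexpression(mat, classified)
  write_tsv(coex, file.path(out_dir, "coexpression.tsv"),
            comments = "Pearson coexpression per BDP pair (FPKM across libraries)")

  ctrl <- random_control_pairs(genes, classified,
                               n = config$n_control_pairs, seed = config$seed)
  ctrl_coex <- pair_coexpression(mat, ctrl)
  write_tsv(ctrl_coex, file.path(out_dir, "control_coexpression.tsv"),
            comments = c("random non-adjacent control duos",
                         prov(config, c("n_control_pairs", "seed"))))

  frac <- coexpressed_fraction_by_interval(classified, coex,
                                           pcc_threshold = config$pcc_threshold,
                                           bin_width = config$bin_width,
                                           max_distance = config$max_distance)
  write_tsv(frac, file.path(out_dir, "coexpressed_fraction.tsv"),
            comments = c("fraction of coexpressed pairs per intergenic bin",
                         prov(config, c("pcc_threshold", "bin_width"))))

  # K-S comparisons of PCC distributions: each category vs the random control
  merged <- merge(classified[, c("pair_id", "category")], coex, by = "pair_id")
  ks_rows <- list()
  ctrl_pcc <- ctrl_coex$pcc[!ctrl_coex$excluded]
  cats <- c(as.list(split(merged$pcc[!merged$excluded],
                          merged$category[!merged$excluded])),
            list(control = ctrl_pcc))
  nm <- names(cats)
  cmb <- utils::combn(nm, 2L)
  for (k in seq_len(ncol(cmb))) {
    x <- cats[[cmb[1L, k]]]; y <- cats[[cmb[2L, k]]]
    if (length(x) < 2L || length(y) < 2L) next
    ks <- ks_two_sample(x, y)
    ks_rows[[length(ks_rows) + 1L]] <-
      data.frame(group1 = cmb[1L, k], group2 = cmb[2L, k], n1 = ks$n1,
                 n2 = ks$n2, D = ks$statistic, p_value = ks$p_value,
                 significant = ks$p_value < config$alpha,
                 stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, ks_rows), file.path(out_dir, "coexpression_ks.tsv"),
            comments = "K-S tests between PCC distributions (categories and control)")
  write_manifest(out_dir, "coexpress", config,
                 list(expression = expr_path, gff3 = gff, classified = cls_path))
  invisible(coex)
}

#' @rdname pipeline
#' @export
run_metagene <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  frag_path <- require_input(config, "fragments", "metagene")
  expr_path <- require_input(config, "expression", "metagene")
  cls_path <- config$classified %||% file.path(out_dir, "classified_pairs.tsv")
  if (!file.exists(cls_path))
    stop("usage: step 'metagene' requires classified pairs (run_classify first)",
         call. = FALSE)
  frags <- load_fragments(frag_path, total_mapped = config$total_mapped)
  mat <- load_expression(expr_path)
  classified <- read_tsv(cls_path)
  fpkm <- rowMeans(mat)

  rows <- list()
  for (ct in DHS_CATEGORIES) {
    sub <- classified[classified$category == ct, , drop = FALSE]
    if (!nrow(sub)) next
    profs <- lapply(seq_len(nrow(sub)), function(k)
      oriented_pair_profile(sub[k, , drop = FALSE], frags, fpkm,
                            flank = config$flank, window = config$window))
    profs <- Filter(Negate(is.null), profs)
    if (!length(profs)) next
    agg <- aggregate_profiles(profs, bdp_windows = config$bdp_windows)
    df <- as.data.frame(agg)
    df <- data.frame(category = ct, df, stringsAsFactors = FALSE)
    rows[[ct]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_tsv(out, file.path(out_dir, "metagene_profiles.tsv"),
            comments = c("mean occupancy (reads/bp/million) per category",
                         prov(config, c("window", "flank", "bdp_windows"))))
  write_manifest(out_dir, "metagene", config,
                 list(fragments = frag_path, expression = expr_path,
                      classified = cls_path))
  invisible(out)
}

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  out_dir <- config$out_dir %||% "."
  keys <- setdiff(names(formals(simulation_config)), "category_mix")
  args <- config[intersect(names(config), keys)]
  if (!is.null(args$n_pairs) && length(args$n_pairs) == 1L)
    args$n_pairs <- rep(args$n_pairs, 3L)
  cfg <- do.call(simulation_config, args)
  sim <- simulate_dataset(cfg, out_dir, fragments = isTRUE(config$fragments %||% TRUE))
  write_manifest(out_dir, "simulate", config, list())
  invisible(sim)
}
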