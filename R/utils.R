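# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state on
#' exit, so seeded operations never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derived from a master seed; kept < 2^31.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stage * 1000003) %% .Machine$integer.max)
}

# Number of sorted integer positions p with s <= p < e.
count_in_interval <- function(sorted_pos, s, e) {
  if (length(sorted_pos) == 0L) return(0L)
  findInterval(e - 0.5, sorted_pos) - findInterval(s - 0.5, sorted_pos)
}

#' Write a TSV with optional provenance header comments
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()], skipping `#` comment lines
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) <= 1L && all(!nzchar(lines)))
    stop("no data rows in ", path, call. = FALSE)
  as.data.frame(data.table::fread(text = paste(lines, collapse = "\n"),
                                  sep = "\t", header = TRUE))
}
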