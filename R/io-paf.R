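#' Read long-read fragment alignments from PAF
#'
#' Parses the 12 mandatory PAF columns and returns one row per alignment
#' fragment, grouped by query (read) name and sorted by query start within
#' each read. Lines with `query_end <= query_start` are skipped with a
#' warning reporting how many were dropped; lines with fewer than 12
#' columns are an error naming the line.
#'
#' @param path PAF file path.
#' @return tibble with columns `read_id`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `chrom`, `target_len`, `start`, `end`,
#'   `matches`, `block_len`, `mapq` (coordinates 0-based half-open, as PAF).
#' @export
read_paf_fragments <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), query_len = integer(),
                  query_start = integer(), query_end = integer(),
                  strand = character(), chrom = character(),
                  target_len = integer(), start = integer(), end = integer(),
                  matches = integer(), block_len = integer(), mapq = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12)
  if (length(short) > 0) {
    abort(paste0("line ", short[1], ": PAF requires >= 12 columns, found ",
                 lengths(fields)[short[1]]))
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- tibble(
    read_id = mat[, 1],
    query_len = as.integer(mat[, 2]),
    query_start = as.integer(mat[, 3]),
    query_end = as.integer(mat[, 4]),
    strand = mat[, 5],
    chrom = mat[, 6],
    target_len = as.integer(mat[, 7]),
    start = as.integer(mat[, 8]),
    end = as.integer(mat[, 9]),
    matches = as.integer(mat[, 10]),
    block_len = as.integer(mat[, 11]),
    mapq = as.integer(mat[, 12])
  )
  bad <- out$query_end <= out$query_start
  if (any(bad)) {
    warn(paste0("skipped ", sum(bad), " PAF line(s) with query_end <= query_start"))
    out <- out[!bad, ]
  }
  out %>% arrange(match(.data$read_id, unique(.data$read_id)), .data$query_start)
}

#' @rdname read_paf_fragments
#' @param fragments tibble in the layout returned by [read_paf_fragments()].
#' @export
write_paf <- function(fragments, path) {
  lines <- with(fragments, paste(read_id, query_len, query_start, query_end,
                                 strand, chrom, target_len, start, end,
                                 matches, block_len, mapq, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
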