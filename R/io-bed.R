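#' Read and write circle calls in the BED6+ dialect
#'
#' Circle calls travel as BED with six mandatory columns (`chrom`, `start`,
#' `end`, `name`, `score`, `strand`; `score` is the rounded circle score)
#' and, when present, five extra columns `n_split`, `n_discordant`,
#' `cov_inc_start`, `cov_inc_end`, `continuity`. Further columns are
#' preserved opaquely and written back unchanged, so
#' `write_circles_bed(read_circles_bed(f))` round-trips files in the
#' canonical dialect byte-for-byte.
#'
#' @param path file path.
#' @return tibble of circle calls (0-based half-open coordinates).
#' @export
read_circles_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 6)) {
    abort(paste0("line ", which(ncols < 6)[1], ": fewer than 6 BED columns"))
  }
  nmax <- max(ncols)
  mat <- t(vapply(fields, function(f) c(f, rep(NA_character_, nmax - length(f))),
                  character(nmax)))
  std <- c("chrom", "start", "end", "name", "score", "strand",
           "n_split", "n_discordant", "cov_inc_start", "cov_inc_end", "continuity")
  cn <- c(std[seq_len(min(nmax, length(std)))],
          if (nmax > length(std)) paste0("extra", seq_len(nmax - length(std))))
  out <- as_tibble(mat, .name_repair = "minimal")
  names(out) <- cn
  suppressWarnings({
    start <- as.integer(out$start); end <- as.integer(out$end)
  })
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(paste0("line ", bad[1], ": malformed coordinates (need 0 <= start < end)"))
  }
  out$start <- start
  out$end <- end
  out$score <- suppressWarnings(as.integer(out$score))
  for (col in intersect(c("n_split", "n_discordant"), names(out))) {
    out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }
  for (col in intersect(c("cov_inc_start", "cov_inc_end", "continuity"), names(out))) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  out
}

#' @rdname read_circles_bed
#' @param circles circle-call tibble; `circle_score` (if present) is rounded
#'   into the BED `score` column.
#' @export
write_circles_bed <- function(circles, path) {
  validate_intervals(circles, "circles")
  x <- as_tibble(circles)
  if (!"name" %in% names(x)) x$name <- paste0("circle_", seq_len(nrow(x)))
  if (!"score" %in% names(x)) {
    x$score <- if ("circle_score" %in% names(x)) as.integer(round(x$circle_score)) else 0L
  }
  if (!"strand" %in% names(x)) x$strand <- "."
  std <- c("chrom", "start", "end", "name", "score", "strand",
           "n_split", "n_discordant", "cov_inc_start", "cov_inc_end", "continuity")
  cols <- c(intersect(std, names(x)), grep("^extra", names(x), value = TRUE))
  # drop trailing optional columns only if absent; keep dialect order
  fmt <- vapply(cols, function(cl) {
    v <- x[[cl]]
    if (is.numeric(v)) {
      vapply(v, function(z) {
        if (is.na(z)) "." else format(z, trim = TRUE, scientific = FALSE, digits = 15)
      }, character(1))
    } else as.character(v)
  }, character(nrow(x)))
  if (nrow(x) == 1) fmt <- matrix(fmt, nrow = 1)
  writeLines(apply(fmt, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a plain BED file (3-6 columns)
#'
#' Used for repeat annotations and ecDNA amplicon intervals. Coordinates are
#' kept 0-based half-open.
#'
#' @param path file path.
#' @return interval tibble with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_tbl0(gr)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(md)) out$name <- md$name
  if ("score" %in% names(md)) out$score <- md$score
  validate_intervals(out, path)
  out
}

#' @rdname read_bed
#' @param intervals interval tibble.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals, "intervals")
  x <- as_tibble(intervals)
  cols <- list(x$chrom, x$start, x$end)
  if ("name" %in% names(x)) {
    cols <- c(cols, list(x$name,
                         if ("score" %in% names(x)) x$score else 0L,
                         if ("strand" %in% names(x)) x$strand else "."))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read gene models from BED12 or GTF
#'
#' Accepts a BED12 file (one row per gene; blocks are exons, the thick range
#' is the CDS) or a minimal GTF with `gene`/`exon` (and optionally `CDS`)
#' features carrying a `gene_id` attribute. Exons must be sorted,
#' non-overlapping and contained in the gene span.
#'
#' @param path file path ending in `.bed`/`.bed12` or `.gtf`.
#' @return tibble with one row per gene: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `thick_start`, `thick_end` (CDS span; equal to `start` when
#'   absent) and an `exons` list-column of tibbles (`start`, `end`, genome
#'   coordinates, 0-based half-open).
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    genes <- read_gene_models_gtf(path)
  } else {
    genes <- read_gene_models_bed12(path)
  }
  validate_gene_models(genes)
  genes
}

read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  md <- S4Vectors::mcols(gr)
  if (!"blocks" %in% names(md)) {
    abort("BED gene models must be BED12 (12 columns with block definitions)")
  }
  base <- granges_to_tbl0(gr)
  thick <- md$thick
  exons <- purrr::map(seq_along(gr), function(i) {
    bl <- md$blocks[[i]]
    tibble(start = base$start[i] + IRanges::start(bl) - 1L,
           end = base$start[i] + IRanges::end(bl))
  })
  tibble(
    gene_id = as.character(md$name),
    chrom = base$chrom,
    start = base$start,
    end = base$end,
    strand = base$strand,
    thick_start = IRanges::start(thick) - 1L,
    thick_end = IRanges::end(thick),
    exons = exons
  )
}

read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  tb <- granges_to_tbl0(gr)
  tb$type <- as.character(gr$type)
  tb$gene_id <- as.character(gr$gene_id)
  ex <- tb %>% filter(.data$type == "exon")
  cds <- tb %>% filter(.data$type == "CDS")
  span <- tb %>% filter(.data$type == "gene")
  if (nrow(span) == 0) {
    span <- ex %>%
      group_by(.data$gene_id) %>%
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), strand = first(.data$strand),
                .groups = "drop")
  } else {
    span <- span %>% select("gene_id", "chrom", "start", "end", "strand")
  }
  exons <- purrr::map(span$gene_id, function(g) {
    ex %>% filter(.data$gene_id == g) %>% arrange(.data$start) %>%
      select("start", "end")
  })
  thick <- purrr::map(span$gene_id, function(g) {
    cc <- cds %>% filter(.data$gene_id == g)
    if (nrow(cc) == 0) NULL else c(min(cc$start), max(cc$end))
  })
  span %>%
    mutate(
      thick_start = purrr::map2_int(thick, .data$start,
                                    ~ if (is.null(.x)) .y else as.integer(.x[1])),
      thick_end = purrr::map2_int(thick, .data$start,
                                  ~ if (is.null(.x)) .y else as.integer(.x[2])),
      exons = exons
    )
}

validate_gene_models <- function(genes) {
  validate_intervals(genes, "gene models")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0) abort(paste0("gene ", genes$gene_id[i], ": no exons"))
    if (any(ex$start < genes$start[i]) || any(ex$end > genes$end[i])) {
      abort(paste0("gene ", genes$gene_id[i], ": exon outside gene span"))
    }
    if (is.unsorted(ex$start)) {
      abort(paste0("gene ", genes$gene_id[i], ": exons not sorted"))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(paste0("gene ", genes$gene_id[i], ": overlapping exons"))
    }
  }
  invisible(genes)
}

#' Write gene models as BED12
#'
#' @param genes gene-model tibble as returned by [read_gene_models()].
#' @param path output path.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i], 0,
          genes$strand[i], genes$thick_start[i], genes$thick_end[i], "0,0,0",
          nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - genes$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
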