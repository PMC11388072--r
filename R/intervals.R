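#' Genomic interval tibbles
#'
#' All interval-valued tables in circlekit share one convention: `chrom`
#' (character), `start` (0-based, inclusive), `end` (exclusive), and an
#' optional `strand` in `+`, `-`, `.`. BED files are native to this
#' convention; VCF and GTF positions are converted at the I/O boundary.
#' Chromosome names are matched by exact string comparison — no "chr"
#' aliasing is ever applied silently.
#'
#' @param x a data frame with at least `chrom`, `start`, `end` columns.
#' @param what label used in error messages.
#' @return `validate_intervals()` returns `x` invisibly after checking the
#'   invariants (`start < end`, `start >= 0`, non-empty `chrom`).
#' @examples
#' validate_intervals(tibble::tibble(chrom = "chr1", start = 0, end = 100))
#' @export
validate_intervals <- function(x, what = "interval table") {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(is.na(x$chrom) | x$chrom == "" |
                 is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(paste0(what, ": invalid interval at row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 " (need chrom non-empty, 0 <= start < end)"))
  }
  invisible(x)
}

#' Convert an interval tibble to GRanges (and back)
#'
#' Internal coordinates are 0-based half-open; `GRanges` is 1-based closed,
#' so `start` is shifted by +1 on the way in and -1 on the way out. Strand
#' is propagated when present but circle overlap arithmetic ignores it
#' (Circle-Seq junctions are unstranded).
#'
#' @param x interval tibble.
#' @param keep extra columns to carry as metadata columns.
#' @return a [GenomicRanges::GRanges] object.
#' @keywords internal
as_granges0 <- function(x, keep = character()) {
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  for (k in intersect(keep, names(x))) {
    S4Vectors::mcols(gr)[[k]] <- x[[k]]
  }
  gr
}

#' @rdname as_granges0
#' @param gr a GRanges object.
#' @keywords internal
granges_to_tbl0 <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>%
    mutate(strand = if_else(.data$strand == "*", ".", .data$strand))
}

#' Chromosome sizes of a genome
#'
#' @param genome a named [Biostrings::DNAStringSet] (or a path to a FASTA
#'   file, which is read with [Biostrings::readDNAStringSet()]).
#' @return tibble with `chrom` and `size` columns.
#' @export
chrom_sizes <- function(genome) {
  genome <- as_genome(genome)
  tibble(chrom = names(genome), size = Biostrings::width(genome))
}

# Accept a DNAStringSet or a FASTA path.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    names(gs) <- sub("\\s.*$", "", names(gs))
    return(gs)
  }
  abort("`genome` must be a DNAStringSet or a path to a FASTA file")
}

#' Uniformly re-place intervals across a genome (in-silico circles)
#'
#' Produces a randomized interval set with exactly the same length multiset
#' as the input, placed uniformly at random among all valid start positions
#' of the genome (a chromosome is chosen with probability proportional to
#' the number of start positions that can hold the interval). This is the
#' native equivalent of shuffling circle coordinates to build an in-silico
#' baseline for GC, element and repeat profiles.
#'
#' @param circles interval tibble (only lengths are used, order preserved).
#' @param sizes chromosome sizes as returned by [chrom_sizes()], or a
#'   genome (DNAStringSet / FASTA path).
#' @param seed integer seed; the operation is deterministic given the seed.
#' @return tibble with `chrom`, `start`, `end`, `name`, `strand`.
#' @examples
#' sizes <- tibble::tibble(chrom = c("c1", "c2"), size = c(10000, 5000))
#' circ <- tibble::tibble(chrom = "c1", start = 0, end = 1000)
#' shuffle_intervals(circ, sizes, seed = 1)
#' @export
shuffle_intervals <- function(circles, sizes, seed = 1L) {
  validate_intervals(circles, "circles")
  if (!is.data.frame(sizes)) sizes <- chrom_sizes(sizes)
  lens <- circles$end - circles$start
  if (length(lens) > 0 && max(lens) > max(sizes$size)) {
    abort("a circle is longer than the longest chromosome; cannot shuffle")
  }
  with_seed0(seed, {
    n <- length(lens)
    out_chrom <- character(n)
    out_start <- integer(n)
    # vectorized over unique lengths: valid positions per chromosome
    for (L in unique(lens)) {
      idx <- which(lens == L)
      avail <- pmax(0, sizes$size - L + 1)
      if (sum(avail) == 0) abort(paste0("length ", L, " fits on no chromosome"))
      ci <- sample.int(nrow(sizes), length(idx), replace = TRUE, prob = avail)
      out_chrom[idx] <- sizes$chrom[ci]
      out_start[idx] <- floor(runif(length(idx)) * avail[ci])
    }
    tibble(
      chrom = out_chrom,
      start = as.integer(out_start),
      end = as.integer(out_start + lens),
      name = paste0("insilico_", seq_len(n)),
      strand = "."
    )
  })
}

# Deterministic local RNG scope: saves and restores .Random.seed.
with_seed0 <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}
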