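#' eccDNA count per million mapped reads (EPM)
#'
#' Depth-normalized eccDNA load: `EPM = n_circles / (mapped_reads / 1e6)`.
#'
#' @param n_circles detected circle count.
#' @param mapped_reads total mapped reads (> 0).
#' @return EPM (double).
#' @examples
#' compute_epm(540972, 100e6)
#' @export
compute_epm <- function(n_circles, mapped_reads) {
  if (any(mapped_reads <= 0)) abort("mapped_reads must be positive")
  n_circles / (mapped_reads / 1e6)
}

#' Per-gene eccDNA abundance
#'
#' `J_g` is the number of distinct circle start coordinates falling within
#' the gene span (two circles sharing a start site count once — unique
#' junction counting, with the start site standing in for the junction).
#' The normalized abundance is the length- and total-normalized closed
#' form `A_g = (J_g / L_g) / sum_i (J_i / L_i) * 1e6`, so abundances sum
#' to one million whenever any gene is hit.
#'
#' @param circles circle interval tibble.
#' @param genes gene models ([read_gene_models()]).
#' @return tibble with `gene_id`, `J` (unique start-site count), `L` (gene
#'   length, bp), `A` (normalized abundance).
#' @examples
#' genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "c1",
#'                         start = c(0L, 5000L), end = c(4000L, 9000L),
#'                         strand = "+")
#' circ <- tibble::tibble(chrom = "c1", start = c(10L, 10L, 5100L),
#'                        end = c(600L, 800L, 5600L))
#' gene_abundance(circ, genes)
#' @export
gene_abundance <- function(circles, genes) {
  validate_intervals(circles, "circles")
  starts <- circles %>% distinct(.data$chrom, .data$start)
  J <- vapply(seq_len(nrow(genes)), function(i) {
    sum(starts$chrom == genes$chrom[i] &
          starts$start >= genes$start[i] & starts$start < genes$end[i])
  }, numeric(1))
  gene_abundance_from_counts(tibble(gene_id = genes$gene_id,
                                    J = as.integer(J),
                                    L = genes$end - genes$start))
}

#' @rdname gene_abundance
#' @param counts tibble with `gene_id`, `J`, `L`; returns it with `A` added.
#' @export
gene_abundance_from_counts <- function(counts) {
  stopifnot(all(c("gene_id", "J", "L") %in% names(counts)), all(counts$L > 0))
  dens <- counts$J / counts$L
  tot <- sum(dens)
  counts$A <- if (tot > 0) dens / tot * 1e6 else rep(0, nrow(counts))
  as_tibble(counts)
}

#' Genomic-element profile of a circle set
#'
#' Partitions the genome into seven element classes (priority for the
#' per-base partition: CDS > 5'UTR > 3'UTR > intron > upstream 2 kb >
#' downstream 2 kb > intergenic) and reports, per class, the fraction of
#' circles overlapping it by at least 1 bp (a circle spanning exon and
#' intron counts in both classes), the class length, and two enrichment
#' measures: `relative_enrichment` divides the circle fraction by the
#' class's share of the genome, while `enrichment` divides it by the exact
#' probability that a uniformly placed circle of the observed lengths
#' would overlap the class — the calibrated measure that equals 1 in
#' expectation for randomly shuffled circles of any length.
#'
#' @param circles circle interval tibble.
#' @param genes gene models.
#' @param sizes chromosome sizes ([chrom_sizes()]).
#' @return tibble: `class`, `n_hits`, `fraction_of_circles`,
#'   `class_length`, `relative_enrichment`, `expected_fraction`,
#'   `enrichment`. With an empty circle set fractions are 0 and
#'   enrichments `NA`.
#' @export
element_profile <- function(circles, genes, sizes) {
  parts <- element_partition(genes, sizes)
  genome_len <- sum(sizes$size)
  n <- nrow(circles)
  gr_c <- if (n > 0) as_granges0(circles) else NULL
  lens <- if (n > 0) circles$end - circles$start else integer(0)
  purrr::map_dfr(names(parts), function(cl) {
    seg <- parts[[cl]]
    class_len <- sum(IRanges::width(seg))
    hits <- if (n > 0 && length(seg) > 0) {
      sum(IRanges::overlapsAny(gr_c, seg, ignore.strand = TRUE))
    } else 0L
    frac <- if (n > 0) hits / n else 0
    expected <- if (n > 0 && length(seg) > 0) {
      expected_overlap_fraction(seg, sizes, lens)
    } else NA_real_
    tibble(class = cl, n_hits = as.integer(hits), fraction_of_circles = frac,
           class_length = class_len,
           relative_enrichment = if (n > 0 && class_len > 0) {
             frac / (class_len / genome_len)
           } else NA_real_,
           expected_fraction = expected,
           enrichment = if (n > 0 && !is.na(expected) && expected > 0) {
             frac / expected
           } else NA_real_)
  })
}

# Exclusive per-base element partition as a named list of GRanges.
element_partition <- function(genes, sizes) {
  si <- setNames(sizes$size, sizes$chrom)
  mk <- function(tb) {
    if (nrow(tb) == 0) return(GenomicRanges::GRanges(seqinfo = NULL))
    GenomicRanges::reduce(as_granges0(tb), ignore.strand = TRUE)
  }
  ex_rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    genes$exons[[i]] %>% mutate(chrom = genes$chrom[i],
                                strand = genes$strand[i],
                                thick_start = genes$thick_start[i],
                                thick_end = genes$thick_end[i])
  })
  has_thick <- all(c("thick_start", "thick_end") %in% names(genes))
  if (!has_thick) {
    ex_rows$thick_start <- ex_rows$start
    ex_rows$thick_end <- ex_rows$end
  }
  cds <- ex_rows %>%
    mutate(start = pmax(.data$start, .data$thick_start),
           end = pmin(.data$end, .data$thick_end)) %>%
    filter(.data$start < .data$end)
  pre <- ex_rows %>%   # exon bases left of the CDS span
    mutate(end = pmin(.data$end, .data$thick_start)) %>%
    filter(.data$start < .data$end)
  post <- ex_rows %>%  # exon bases right of the CDS span
    mutate(start = pmax(.data$start, .data$thick_end)) %>%
    filter(.data$start < .data$end)
  utr5 <- bind_rows(pre %>% filter(.data$strand == "+"),
                    post %>% filter(.data$strand == "-"))
  utr3 <- bind_rows(post %>% filter(.data$strand == "+"),
                    pre %>% filter(.data$strand == "-"))
  gene_spans <- genes %>% select("chrom", "start", "end")
  up <- genes %>%
    mutate(s = if_else(.data$strand == "+", .data$start - 2000L, .data$end),
           e = if_else(.data$strand == "+", .data$start, .data$end + 2000L)) %>%
    mutate(start = pmax(0L, .data$s),
           end = pmin(si[.data$chrom], .data$e)) %>%
    filter(.data$start < .data$end) %>% select("chrom", "start", "end")
  down <- genes %>%
    mutate(s = if_else(.data$strand == "+", .data$end, .data$start - 2000L),
           e = if_else(.data$strand == "+", .data$end + 2000L, .data$start)) %>%
    mutate(start = pmax(0L, .data$s),
           end = pmin(si[.data$chrom], .data$e)) %>%
    filter(.data$start < .data$end) %>% select("chrom", "start", "end")
  whole <- GenomicRanges::GRanges(sizes$chrom, IRanges::IRanges(1, sizes$size))
  raw <- list(CDS = mk(cds), utr5 = mk(utr5), utr3 = mk(utr3),
              intron = GenomicRanges::setdiff(mk(gene_spans),
                                              mk(bind_rows(cds, pre, post)),
                                              ignore.strand = TRUE),
              upstream2kb = mk(up), downstream2kb = mk(down))
  out <- list()
  taken <- GenomicRanges::GRanges()
  for (cl in names(raw)) {
    seg <- GenomicRanges::setdiff(raw[[cl]], taken, ignore.strand = TRUE)
    out[[cl]] <- seg
    taken <- GenomicRanges::reduce(c(taken, seg), ignore.strand = TRUE)
  }
  out$intergenic <- GenomicRanges::setdiff(whole, taken, ignore.strand = TRUE)
  out[c("utr5", "CDS", "intron", "utr3", "upstream2kb", "downstream2kb",
        "intergenic")]
}

# Exact probability that a uniformly placed circle of each observed length
# overlaps the class by >= 1 bp, averaged over the circle set. A circle of
# length L starting at 1-based position x on a chromosome of size S
# (x in 1..S-L+1) overlaps a segment [s, e] iff x in [s-L+1, e].
expected_overlap_fraction <- function(seg, sizes, lens) {
  seg_by <- split(IRanges::ranges(seg), as.character(GenomicRanges::seqnames(seg)))
  si <- setNames(sizes$size, sizes$chrom)
  ulen <- sort(unique(lens))
  p <- vapply(ulen, function(L) {
    total <- sum(pmax(0, sizes$size - L + 1))
    if (total == 0) return(NA_real_)
    fav <- 0
    for (ch in names(seg_by)) {
      r <- seg_by[[ch]]
      lim <- si[[ch]] - L + 1
      if (lim < 1) next
      s <- pmax(1, IRanges::start(r) - L + 1)
      e <- pmin(IRanges::end(r), lim)
      keep <- s <= e
      if (!any(keep)) next
      fav <- fav + sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(s[keep], e[keep]))))
    }
    fav / total
  }, numeric(1))
  mean(p[match(lens, ulen)])
}

#' Fraction of reads aligned to repeat regions
#'
#' @param reads interval tibble of read alignments (`chrom`, `start`,
#'   `end`), e.g. the `aln` tibble from [read_alignments()].
#' @param repeats repeat interval tibble.
#' @return fraction of reads overlapping any repeat by >= 1 bp.
#' @export
repeat_fraction <- function(reads, repeats) {
  if (nrow(reads) == 0) return(0)
  if (nrow(repeats) == 0) return(0)
  mean(IRanges::overlapsAny(as_granges0(reads), as_granges0(repeats),
                            ignore.strand = TRUE))
}

#' GC content and size-class profile of circles
#'
#' GC is `(G + C) / (A + C + G + T)` of the reference sequence of each
#' circularized region (ambiguous bases excluded from the denominator).
#' Size classes follow the `< 2 kb`, `2-10 kb` (boundaries inclusive) and
#' `> 10 kb` convention.
#'
#' @param circles circle interval tibble.
#' @param genome DNAStringSet or FASTA path.
#' @return list with `per_circle` (adds `gc`, `length`, `size_class`) and
#'   `size_fractions` (per-class fractions; all three classes reported).
#' @export
gc_and_size_profile <- function(circles, genome) {
  genome <- as_genome(genome)
  validate_intervals(circles, "circles")
  si <- setNames(Biostrings::width(genome), names(genome))
  if (any(circles$end > si[circles$chrom])) {
    abort("circle extends beyond its chromosome end")
  }
  gc <- vapply(seq_len(nrow(circles)), function(i) {
    s <- Biostrings::subseq(genome[[circles$chrom[i]]],
                            circles$start[i] + 1L, circles$end[i])
    fr <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
    sum(fr[c("C", "G")]) / sum(fr)
  }, numeric(1))
  len <- circles$end - circles$start
  cls <- ifelse(len < 2000, "lt_2kb", ifelse(len <= 10000, "2_10kb", "gt_10kb"))
  per <- circles %>% mutate(gc = gc, length = len,
                            size_class = factor(cls, c("lt_2kb", "2_10kb",
                                                       "gt_10kb")))
  fr <- as.data.frame(table(per$size_class) / max(1, nrow(per)))
  names(fr) <- c("size_class", "fraction")
  list(per_circle = per, size_fractions = as_tibble(fr))
}
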