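#' Simulate Circle-Seq paired-end reads from planted circles
#'
#' Read pairs are drawn uniformly from each circle's circularized
#' coordinate system, so fragments that span the wrap-around junction
#' produce (a) reads whose alignment acquires a soft-clip at the junction
#' (encoded as a single clipped primary alignment anchored on the longer
#' segment — no supplementary alignments) and (b) outward-facing
#' discordant pairs when the junction falls in the inner gap of the
#' insert. The number of pairs per circle is
#' `depth * copy_count * length / (2 * read_length)`, substitution errors
#' are applied at `error_rate` with matching constant base qualities, and
#' the emitted SAM is coordinate-sorted with every read at its true
#' position and true CIGAR.
#'
#' @param truth circle tibble from [plant_circles()].
#' @param ref output of [build_synthetic_genome()].
#' @param config a [sim_config()].
#' @param dir output directory; receives `reads_1.fastq`, `reads_2.fastq`,
#'   `reads.sam` and `truth.bed` (truth intervals of the single-fragment
#'   circles; chimeric circles have no single-interval truth).
#' @return list with `sam`, `fastq`, `truth_bed` paths, the `truth`
#'   interval tibble, and `n_reads`.
#' @export
simulate_short_reads <- function(truth, ref, config, dir = tempfile("ckshort")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- ref$genome
  rl <- config$read_length
  if (config$insert_mean >= min(truth$total_length)) {
    warn("insert_mean >= smallest circle; inserts are truncated by wrap-around")
  }
  qchar <- if (config$error_rate > 0) {
    intToUtf8(33L + min(41L, as.integer(round(-10 * log10(config$error_rate)))))
  } else "I"

  with_seed0(seed_for(config, "short"), {
    recs <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      fr <- truth$fragments[[i]]
      circ <- circle_sequence(fr, genome)
      clen <- nchar(circ)
      npair <- as.integer(ceiling(config$depth * truth$copy_count[i] * clen /
                                    (2 * rl)))
      a1 <- as.integer(floor(runif(npair) * clen))
      ins <- as.integer(round(rnorm(npair, config$insert_mean, config$insert_sd)))
      ins <- pmin(pmax(ins, rl), clen)
      a2 <- (a1 + ins - rl) %% clen
      circ2 <- strrep(circ, 2)
      s1 <- add_subs(substring(circ2, a1 + 1, a1 + rl), config$error_rate)
      s2 <- add_subs(substring(circ2, a2 + 1, a2 + rl), config$error_rate)
      p1 <- place_reads(fr, clen, a1, rl, s1)
      p2 <- place_reads(fr, clen, a2, rl, s2)
      rev1 <- p1$anchor_strand == "-"
      rev2 <- p2$anchor_strand == "+"
      ids <- sprintf("%s_p%05d", truth$circle_id[i], seq_len(npair))
      qual <- strrep(qchar, rl)
      recs[[i]] <- tibble(
        read_id = rep(ids, 2),
        flag = c(1L + 64L + 16L * rev1 + 32L * rev2,
                 1L + 128L + 16L * rev2 + 32L * rev1),
        chrom = c(p1$chrom, p2$chrom),
        pos = c(p1$pos, p2$pos),
        mapq = 60L,
        cigar = c(p1$cigar, p2$cigar),
        seq = c(p1$stored_seq, p2$stored_seq),
        qual = qual,
        mate_chrom = c(p2$chrom, p1$chrom),
        mate_pos = c(p2$pos, p1$pos),
        fastq1 = rep(s1, 2),
        fastq2 = rep(revcomp_chr(s2), 2),
        is_read1 = rep(c(TRUE, FALSE), each = npair)
      )
    }
    aln <- bind_rows(recs)
    paths <- list(sam = file.path(dir, "reads.sam"),
                  fastq = c(file.path(dir, "reads_1.fastq"),
                            file.path(dir, "reads_2.fastq")),
                  truth_bed = file.path(dir, "truth.bed"))
    write_sam(aln, ref$sizes, paths$sam)
    fq <- aln %>% filter(.data$is_read1)
    write_fastq_pair(tibble(read_id = fq$read_id, seq1 = fq$fastq1,
                            qual1 = fq$qual, seq2 = fq$fastq2, qual2 = fq$qual),
                     paths$fastq[1], paths$fastq[2])
    tb <- truth %>% filter(!.data$is_chimeric)
    truth_tbl <- tibble(
      chrom = vapply(tb$fragments, function(f) f$chrom[1], character(1)),
      start = vapply(tb$fragments, function(f) f$start[1], integer(1)),
      end = vapply(tb$fragments, function(f) f$end[1], integer(1)),
      name = tb$circle_id, score = 0L, strand = "."
    ) %>% arrange(.data$chrom, .data$start)
    write_bed(truth_tbl, paths$truth_bed)
    c(paths, list(truth = truth_tbl, n_reads = nrow(aln)))
  })
}

# Reference placement (pos, CIGAR, stored sequence, anchor strand) for reads
# drawn from the circularized coordinate system. `a` are 0-based circle
# offsets; `seq_cs` the circle-sense read sequences. Vectorized fast path for
# single forward-strand fragments; general piecewise walk otherwise.
place_reads <- function(fr, clen, a, L, seq_cs) {
  n <- length(a)
  if (nrow(fr) == 1 && fr$strand[1] == "+") {
    lenA <- pmin(L, clen - a)
    lenB <- L - lenA
    anchorA <- lenA >= lenB
    pos <- ifelse(anchorA, fr$start[1] + a, fr$start[1])
    cigar <- ifelse(lenB == 0L, paste0(L, "M"),
                    ifelse(anchorA, paste0(lenA, "M", lenB, "S"),
                           paste0(lenA, "S", lenB, "M")))
    return(tibble(chrom = fr$chrom[1], pos = as.integer(pos), cigar = cigar,
                  stored_seq = seq_cs, anchor_strand = "+"))
  }
  out <- vector("list", n)
  for (r in seq_len(n)) {
    pieces <- walk_circle(fr, clen, a[r], L)
    j <- which.max(pieces$len)
    astr <- pieces$strand[j]
    left_cs <- pieces$qstart[j]
    right_cs <- L - (pieces$qstart[j] + pieces$len[j])
    if (astr == "+") {
      lc <- left_cs; rc <- right_cs; stored <- seq_cs[r]
    } else {
      lc <- right_cs; rc <- left_cs; stored <- revcomp_chr(seq_cs[r])
    }
    cigar <- paste0(if (lc > 0) paste0(lc, "S"), pieces$len[j], "M",
                    if (rc > 0) paste0(rc, "S"))
    out[[r]] <- tibble(chrom = pieces$chrom[j], pos = pieces$ref_start[j],
                       cigar = cigar, stored_seq = stored, anchor_strand = astr)
  }
  bind_rows(out)
}

# Decompose circle-coordinate interval [a, a+L) into reference pieces.
walk_circle <- function(fr, clen, a, L) {
  flen <- fr$end - fr$start
  cum <- c(0L, cumsum(flen))
  p <- a %% clen
  remaining <- L
  q <- 0L
  rows <- list()
  while (remaining > 0) {
    j <- findInterval(p, cum, rightmost.closed = FALSE)
    off <- p - cum[j]
    take <- min(remaining, flen[j] - off)
    if (fr$strand[j] == "+") {
      rs <- fr$start[j] + off
    } else {
      rs <- fr$end[j] - off - take
    }
    rows[[length(rows) + 1]] <- tibble(
      chrom = fr$chrom[j], ref_start = as.integer(rs),
      ref_end = as.integer(rs + take), strand = fr$strand[j],
      qstart = q, len = as.integer(take))
    p <- (p + take) %% clen
    q <- q + take
    remaining <- remaining - take
  }
  bind_rows(rows)
}

# Random substitutions at `rate` per base.
add_subs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  L <- nchar(seqs)
  nerr <- rbinom(length(seqs), L, rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    at <- sample.int(L[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(bases, b), 1), character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate multi-pass rolling-circle-amplified long reads
#'
#' Each read is `k` concatenated copies of its circle's sequence (with `k`
#' drawn uniformly from `passes_range`), starting at a uniform random
#' rotation, with substitution errors at `config$error_rate`. The matching
#' perfect PAF lists every fragment traversal in query order (partial
#' fragments at the read ends included), so downstream reconstruction can
#' be tested without running an aligner.
#'
#' @param truth circle tibble from [plant_circles()].
#' @param ref output of [build_synthetic_genome()].
#' @param config a [sim_config()].
#' @param passes_range integer range `c(lo, hi)` of pass counts, within 1-20.
#' @param reads_per_circle long reads simulated per circle.
#' @param dir output directory; receives `rca_reads.fasta`, `rca.paf` and
#'   `rca_truth.tsv`.
#' @return list with `fasta`, `paf`, `truth_tsv` paths and the `truth`
#'   tibble (`read_id`, `circle_id`, `n_passes`, `rotation`).
#' @export
simulate_rca_reads <- function(truth, ref, config, passes_range = c(2, 10),
                               reads_per_circle = 1, dir = tempfile("ckrca")) {
  stopifnot(inherits(config, "sim_config"),
            passes_range[1] >= 1, passes_range[2] <= 20)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- ref$genome
  with_seed0(seed_for(config, "rca"), {
    fa <- character(0)
    paf <- list()
    tr <- list()
    for (i in seq_len(nrow(truth))) {
      fr <- truth$fragments[[i]]
      circ <- circle_sequence(fr, genome)
      clen <- nchar(circ)
      for (r in seq_len(reads_per_circle)) {
        k <- sample(seq(passes_range[1], passes_range[2]), 1)
        rot <- as.integer(floor(runif(1) * clen))
        rid <- sprintf("%s_r%02d", truth$circle_id[i], r)
        seq <- substring(strrep(circ, k + 1), rot + 1, rot + k * clen)
        seq <- add_subs(seq, config$error_rate)
        fa <- c(fa, paste0(">", rid), seq)
        pieces <- walk_circle(fr, clen, rot, k * clen)
        paf[[length(paf) + 1]] <- tibble(
          read_id = rid, query_len = k * clen,
          query_start = pieces$qstart,
          query_end = pieces$qstart + pieces$len,
          strand = pieces$strand, chrom = pieces$chrom,
          target_len = ref$sizes$size[match(pieces$chrom, ref$sizes$chrom)],
          start = pieces$ref_start, end = pieces$ref_end,
          matches = pieces$len, block_len = pieces$len, mapq = 60L)
        tr[[length(tr) + 1]] <- tibble(read_id = rid,
                                       circle_id = truth$circle_id[i],
                                       n_passes = k, rotation = rot)
      }
    }
    paths <- list(fasta = file.path(dir, "rca_reads.fasta"),
                  paf = file.path(dir, "rca.paf"),
                  truth_tsv = file.path(dir, "rca_truth.tsv"))
    writeLines(fa, paths$fasta)
    write_paf(bind_rows(paf), paths$paf)
    truth_tbl <- bind_rows(tr)
    readr::write_tsv(truth_tbl, paths$truth_tsv)
    c(paths, list(truth = truth_tbl))
  })
}
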