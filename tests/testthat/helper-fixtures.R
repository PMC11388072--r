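# Shared fixtures, built once per run and cached.
.ck_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ck_cache)) {
    assign(key, force(expr), envir = .ck_cache)
  }
  get(key, envir = .ck_cache)
}

# small scene used by several unit tests (fast to build)
tiny_cfg <- function() sim_config(genome_length = 2e5, n_circles = 12,
                                  repeat_fraction = 0.1, seed = 42)

tiny_ref <- function() cached("tiny_ref", build_synthetic_genome(tiny_cfg()))

tiny_truth <- function() cached("tiny_truth", plant_circles(tiny_ref(), tiny_cfg()))

tiny_sim <- function() cached("tiny_sim", suppressWarnings(
  simulate_short_reads(tiny_truth(), tiny_ref(), tiny_cfg(),
                       dir = tempfile("tinysim"))))

# error-free variant of the same scene (perfect reads)
tiny_cfg0 <- function() sim_config(genome_length = 2e5, n_circles = 12,
                                   repeat_fraction = 0.1, error_rate = 0,
                                   seed = 42)

tiny_sim0 <- function() cached("tiny_sim0", suppressWarnings(
  simulate_short_reads(plant_circles(tiny_ref(), tiny_cfg0()), tiny_ref(),
                       tiny_cfg0(), dir = tempfile("tinysim0"))))

# one-chromosome toy genome with a known sequence
toy_genome <- function(seq = NULL, name = "c1") {
  if (is.null(seq)) {
    set.seed(99)
    seq <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  }
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# independent brute-force kataegis oracle: enumerate qualifying 6-SNV
# windows and merge those sharing an SNV via interval reduction
kataegis_oracle <- function(snvs, min_snvs = 6L, max_imd = 1000) {
  out <- list()
  for (ch in unique(snvs$chrom)) {
    pos <- sort(unique(snvs$pos[snvs$chrom == ch]))
    n <- length(pos)
    if (n < min_snvs) next
    qual <- list()
    for (i in seq_len(n - min_snvs + 1)) {
      j <- i + min_snvs - 1L
      if ((pos[j] - pos[i]) / (min_snvs - 1) <= max_imd) {
        qual[[length(qual) + 1]] <- c(i, j)
      }
    }
    if (length(qual) == 0) next
    # min.gapwidth = 0: merge only windows sharing at least one SNV
    ir <- IRanges::reduce(IRanges::IRanges(
      start = vapply(qual, `[`, numeric(1), 1),
      end = vapply(qual, `[`, numeric(1), 2)), min.gapwidth = 0L)
    for (k in seq_along(ir)) {
      a <- IRanges::start(ir)[k]; b <- IRanges::end(ir)[k]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, first_pos = pos[a] + 1L, last_pos = pos[b] + 1L,
        n_snvs = b - a + 1L)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), first_pos = integer(),
                          last_pos = integer(), n_snvs = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, first_pos)
}

# full-scale default scene shared by the acceptance checks
default_ref <- function() cached("default_ref",
                                 build_synthetic_genome(sim_config()))

default_truth <- function() cached("default_truth",
                                   plant_circles(default_ref(), sim_config()))

revcomp_test <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# construct a PAF tibble for a read that traverses `frags` (with lengths
# implied by start/end) k times starting at rotation `rot`
make_rca_paf <- function(frags, k, rot, read_id = "r1", target_len = 1e6L) {
  clen <- sum(frags$end - frags$start)
  pieces <- circlekit:::walk_circle(frags, clen, rot, k * clen)
  tibble::tibble(read_id = read_id, query_len = k * clen,
                 query_start = pieces$qstart,
                 query_end = pieces$qstart + pieces$len,
                 strand = pieces$strand, chrom = pieces$chrom,
                 target_len = target_len, start = pieces$ref_start,
                 end = pieces$ref_end, matches = pieces$len,
                 block_len = pieces$len, mapq = 60L)
}
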