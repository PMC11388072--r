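#' Simulation configuration
#'
#' Bundles every tunable of the benchmark simulator. The defaults define
#' the package's standard desk-scale Circle-Seq scene: a 2 Mb genome on
#' two chromosomes, 200 planted circles with log-normal sizes
#' (meanlog 6.7, sdlog 0.6 in log-bp, i.e. a median around 800 bp), 10%
#' chimeric circles of 2-9 fragments, 150 bp paired reads with a 450 bp
#' insert, 0.5% substitution errors and a junction-coverage target of 30x.
#'
#' @param genome_length total genome size in bp (>= 100 kb).
#' @param n_chroms number of chromosomes (equal sizes).
#' @param gc_target genome GC fraction, must lie in (0.2, 0.8).
#' @param repeat_fraction fraction of the genome covered by interspersed
#'   repeat copies (each copy 2% diverged from its unit).
#' @param n_circles number of planted circles.
#' @param size_meanlog,size_sdlog log-normal circle-size parameters (log-bp).
#' @param min_circle_length smallest planted circle (bp); must exceed
#'   `read_length`.
#' @param chimera_prob probability that a circle is chimeric (2-9 fragments).
#' @param read_length,insert_mean,insert_sd short-read geometry (bp).
#' @param error_rate per-base substitution error rate.
#' @param depth junction coverage target (x) per circle copy.
#' @param seed master RNG seed; each simulator operation derives its own
#'   stream from it by a fixed offset, so outputs are reproducible
#'   per-operation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 2e6, n_chroms = 2, gc_target = 0.45,
                       repeat_fraction = 0.15, n_circles = 200,
                       size_meanlog = 6.7, size_sdlog = 0.6,
                       min_circle_length = 200, chimera_prob = 0.1,
                       read_length = 150, insert_mean = 450, insert_sd = 50,
                       error_rate = 0.005, depth = 30, seed = 1L) {
  cfg <- list(genome_length = genome_length, n_chroms = n_chroms,
              gc_target = gc_target, repeat_fraction = repeat_fraction,
              n_circles = n_circles, size_meanlog = size_meanlog,
              size_sdlog = size_sdlog, min_circle_length = min_circle_length,
              chimera_prob = chimera_prob, read_length = read_length,
              insert_mean = insert_mean, insert_sd = insert_sd,
              error_rate = error_rate, depth = depth, seed = as.integer(seed))
  stopifnot(genome_length >= 1e5, n_chroms >= 1,
            repeat_fraction >= 0, repeat_fraction <= 1,
            chimera_prob >= 0, chimera_prob <= 1,
            error_rate >= 0, error_rate < 1,
            min_circle_length > read_length,
            depth > 0, n_circles >= 0)
  if (gc_target <= 0.2 || gc_target >= 0.8) {
    abort("gc_target must lie strictly between 0.2 and 0.8")
  }
  structure(cfg, class = "sim_config")
}

# fixed per-operation seed offsets (documented in sim_config)
seed_for <- function(config, op) {
  off <- c(genome = 101L, circles = 202L, short = 303L, rca = 404L,
           snvs = 505L, tables = 606L)[[op]]
  (config$seed + off) %% .Machine$integer.max
}

#' Build a synthetic genome with gene and repeat annotation
#'
#' Generates `n_chroms` random sequences at the target GC, overlays
#' interspersed repeat copies (a handful of seeded units, each planted copy
#' 2% diverged) until `repeat_fraction` of the genome is covered, and tiles
#' roughly 40% of each chromosome with multi-exon gene models (2-8 exons,
#' a CDS span flanked by UTR stubs, random strand). Everything is
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `genes.bed12` and `repeats.bed` there.
#' @return list with `genome` (DNAStringSet), `genes` (gene-model tibble as
#'   from [read_gene_models()]), `repeats` (interval tibble), `sizes`
#'   (chromosome sizes) and, when `dir` is given, the file `paths`.
#' @export
build_synthetic_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed0(seed_for(config, "genome"), {
    gc <- config$gc_target
    chrom_len <- as.integer(round(config$genome_length / config$n_chroms))
    chroms <- paste0("chr", seq_len(config$n_chroms))
    base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vector("list", config$n_chroms)
    names(seqs) <- chroms
    for (i in seq_along(chroms)) {
      seqs[[i]] <- sample(names(base_prob), chrom_len, replace = TRUE,
                          prob = base_prob)
    }

    # interspersed repeats: 5 seeded units, copies 2% diverged
    repeats <- tibble(chrom = character(), start = integer(), end = integer())
    if (config$repeat_fraction > 0) {
      units <- lapply(sample(300:800, 5, replace = TRUE), function(L) {
        sample(names(base_prob), L, replace = TRUE, prob = base_prob)
      })
      target <- config$repeat_fraction * config$genome_length
      covered <- 0
      occ <- lapply(chroms, function(.) IRanges::IRanges())
      names(occ) <- chroms
      rows <- list()
      tries <- 0
      while (covered < target && tries < 1e5) {
        tries <- tries + 1
        u <- units[[sample.int(length(units), 1)]]
        L <- length(u)
        ci <- sample.int(length(chroms), 1)
        s <- sample.int(chrom_len - L, 1)  # 1-based start
        cand <- IRanges::IRanges(s, s + L - 1)
        if (length(IRanges::findOverlaps(cand, occ[[ci]])) > 0) next
        occ[[ci]] <- c(occ[[ci]], cand)
        copy <- u
        nmut <- rbinom(1, L, 0.02)
        if (nmut > 0) {
          at <- sample.int(L, nmut)
          copy[at] <- vapply(copy[at], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        seqs[[ci]][s:(s + L - 1)] <- copy
        rows[[length(rows) + 1]] <- tibble(chrom = chroms[ci],
                                           start = s - 1L,
                                           end = s - 1L + L)
        covered <- covered + L
      }
      repeats <- bind_rows(rows) %>% arrange(.data$chrom, .data$start)
    }

    genes <- build_gene_models(chroms, chrom_len)

    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                              collapse = ""))
    names(genome) <- chroms
    out <- list(genome = genome, genes = genes, repeats = repeats,
                sizes = tibble(chrom = chroms, size = chrom_len))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(fasta = file.path(dir, "genome.fa"),
                    genes = file.path(dir, "genes.bed12"),
                    repeats = file.path(dir, "repeats.bed"))
      Biostrings::writeXStringSet(genome, paths$fasta)
      write_gene_models_bed12(genes, paths$genes)
      write_bed(out$repeats, paths$repeats)
      out$paths <- paths
    }
    out
  })
}

# Tile ~40% of each chromosome with multi-exon genes.
build_gene_models <- function(chroms, chrom_len) {
  rows <- list()
  gid <- 0
  for (ch in chroms) {
    pos <- 1000L
    while (TRUE) {
      gap <- as.integer(round(rexp(1, 1 / 9000))) + 500L
      glen <- as.integer(round(rlnorm(1, log(6000), 0.5)))
      glen <- max(1500L, min(30000L, glen))
      start <- pos + gap
      end <- start + glen
      if (end > chrom_len - 1000L) break
      k <- sample(2:8, 1)
      w <- sample(100:400, k, replace = TRUE)
      while (sum(w) + (k - 1) * 50 > glen) {
        k <- k - 1
        w <- w[seq_len(k)]
      }
      intron_total <- glen - sum(w)
      if (k > 1) {
        cuts <- sort(runif(k - 1))
        iw <- as.integer(round(diff(c(0, cuts, 1)) * (intron_total - (k - 1) * 50))) + 50L
        iw <- iw[seq_len(k - 1)]
      } else iw <- integer(0)
      ex_start <- integer(k); ex_end <- integer(k)
      p <- start
      for (j in seq_len(k)) {
        ex_start[j] <- p
        ex_end[j] <- p + w[j]
        p <- ex_end[j] + if (j < k) iw[j] else 0L
      }
      ex_end[k] <- end  # last exon absorbs rounding drift
      gid <- gid + 1
      rows[[gid]] <- tibble(
        gene_id = sprintf("gene_%04d", gid),
        chrom = ch, start = start, end = end,
        strand = sample(c("+", "-"), 1),
        thick_start = ex_start[1] + w[1] %/% 2L,
        thick_end = ex_end[k] - min(100L, (ex_end[k] - ex_start[k]) %/% 2L),
        exons = list(tibble(start = ex_start, end = ex_end))
      )
      pos <- end
    }
  }
  bind_rows(rows)
}

#' Plant circles on a synthetic genome
#'
#' Draws circle sizes from the configured log-normal, makes a
#' `chimera_prob` fraction chimeric (2-9 fragments, uniform, possibly
#' spanning chromosomes, every fragment >= 50 bp), and places fragments
#' uniformly on the genome without overlap (200 bp margin between planted
#' fragments; a placement is resampled up to 100 times before erroring).
#' Single-fragment circles are on the forward strand; chimeric fragments
#' may be inverted.
#'
#' @param ref output of [build_synthetic_genome()] (or a list with `sizes`).
#' @param config a [sim_config()].
#' @return tibble of truth circles: `circle_id`, `n_fragments`,
#'   `is_chimeric`, `total_length`, `copy_count` and a `fragments`
#'   list-column of interval tibbles (`chrom`, `start`, `end`, `strand`).
#' @export
plant_circles <- function(ref, config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- ref$sizes
  with_seed0(seed_for(config, "circles"), {
    n <- config$n_circles
    lens <- as.integer(round(rlnorm(n, config$size_meanlog, config$size_sdlog)))
    while (any(lens < config$min_circle_length)) {
      i <- lens < config$min_circle_length
      lens[i] <- as.integer(round(rlnorm(sum(i), config$size_meanlog,
                                         config$size_sdlog)))
    }
    if (any(lens > max(sizes$size))) {
      lens[lens > max(sizes$size)] <- as.integer(max(sizes$size) / 2)
    }
    is_chim <- runif(n) < config$chimera_prob
    occ <- lapply(sizes$chrom, function(.) IRanges::IRanges())
    names(occ) <- sizes$chrom
    margin <- 200L

    place_fragment <- function(flen) {
      for (try in 1:100) {
        avail <- pmax(0, sizes$size - flen + 1)
        ci <- sample.int(nrow(sizes), 1, prob = avail)
        s <- sample.int(avail[ci], 1) - 1L  # 0-based
        cand <- IRanges::IRanges(s + 1 - margin, s + flen + margin)
        if (length(IRanges::findOverlaps(cand, occ[[ci]])) == 0) {
          occ[[sizes$chrom[ci]]] <<- c(occ[[sizes$chrom[ci]]],
                                       IRanges::IRanges(s + 1, s + flen))
          return(tibble(chrom = sizes$chrom[ci], start = s, end = s + flen))
        }
      }
      abort("failed to place a circle fragment after 100 attempts")
    }

    frag_list <- vector("list", n)
    for (i in seq_len(n)) {
      if (!is_chim[i]) {
        fr <- place_fragment(lens[i])
        fr$strand <- "+"
      } else {
        kmax <- max(2L, min(9L, lens[i] %/% 50L))
        k <- sample(seq(2L, kmax), 1)
        w <- stick_break(lens[i], k, min_part = 50L)
        fr <- bind_rows(lapply(w, place_fragment))
        fr$strand <- sample(c("+", "-"), k, replace = TRUE, prob = c(0.75, 0.25))
      }
      frag_list[[i]] <- fr
    }
    tibble(
      circle_id = sprintf("circle_%04d", seq_len(n)),
      n_fragments = vapply(frag_list, nrow, integer(1)),
      is_chimeric = is_chim,
      total_length = lens,
      copy_count = 1L,
      fragments = frag_list
    )
  })
}

# Partition `total` into k integer parts each >= min_part.
stick_break <- function(total, k, min_part = 50L) {
  free <- total - k * min_part
  if (free < 0) abort("circle too small for its fragment count")
  cuts <- sort(runif(k - 1))
  w <- as.integer(round(diff(c(0, cuts, 1)) * free)) + min_part
  w[k] <- total - sum(w[-k])
  if (w[k] < min_part) {  # rebalance rounding drift
    need <- min_part - w[k]
    j <- which.max(w[-k])
    w[j] <- w[j] - need
    w[k] <- min_part
  }
  w
}

#' Sequence of a (possibly chimeric) circle
#'
#' Concatenates the fragment sequences in order, reverse-complementing
#' `-` fragments, giving the circle's forward traversal starting at
#' fragment 1.
#'
#' @param fragments fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @param genome DNAStringSet.
#' @return a single character string.
#' @export
circle_sequence <- function(fragments, genome) {
  pieces <- vapply(seq_len(nrow(fragments)), function(i) {
    s <- Biostrings::subseq(genome[[fragments$chrom[i]]],
                            start = fragments$start[i] + 1L,
                            end = fragments$end[i])
    if (fragments$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  paste(pieces, collapse = "")
}
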