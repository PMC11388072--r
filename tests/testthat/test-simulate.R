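test_that("synthetic genome is deterministic and hits its GC and repeat targets", {
  cfg <- sim_config(genome_length = 3e5, gc_target = 0.45,
                    repeat_fraction = 0.3, seed = 7)
  a <- build_synthetic_genome(cfg)
  b <- build_synthetic_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$repeats, b$repeats)

  rep_cov <- sum(a$repeats$end - a$repeats$start) / cfg$genome_length
  expect_gt(rep_cov, 0.25)
  expect_lt(rep_cov, 0.35)

  gc <- sum(Biostrings::letterFrequency(a$genome, c("G", "C"))) /
    sum(Biostrings::width(a$genome))
  expect_gt(gc, 0.43)
  expect_lt(gc, 0.47)

  expect_error(sim_config(gc_target = 0.85), "gc_target")
})

test_that("planted circle mix follows the chimera probability and size law", {
  ref <- tiny_ref()
  c0 <- plant_circles(ref, sim_config(genome_length = 2e5, n_circles = 30,
                                      chimera_prob = 0, seed = 1))
  expect_true(all(c0$n_fragments == 1))

  c1 <- plant_circles(ref, sim_config(genome_length = 2e5, n_circles = 30,
                                      chimera_prob = 1, seed = 1))
  expect_true(all(c1$n_fragments >= 2))
  expect_true(all(c1$n_fragments <= 9))
  expect_true(all(unlist(lapply(c1$fragments, function(f) f$end - f$start)) >= 50))
  # fragment lengths always sum to the circle length
  expect_equal(vapply(c1$fragments, function(f) sum(f$end - f$start), numeric(1)),
               as.numeric(c1$total_length))

  big_cfg <- sim_config(genome_length = 1e7, n_circles = 1000,
                        chimera_prob = 0, seed = 3)
  big_ref <- list(sizes = tibble::tibble(chrom = c("chr1", "chr2"),
                                         size = 5e6L))
  cc <- plant_circles(big_ref, big_cfg)
  expect_lt(abs(median(cc$total_length) - exp(6.7)) / exp(6.7), 0.15)
})

test_that("error-free simulated reads match the reference at aligned bases", {
  sim <- tiny_sim0()
  ref <- tiny_ref()
  ra <- read_alignments(sim$sam)
  aln <- ra$aln
  set.seed(1)
  idx <- sample(nrow(aln), 300)
  chrom_str <- lapply(seq_along(ref$genome),
                      function(i) as.character(ref$genome[[i]]))
  names(chrom_str) <- names(ref$genome)
  for (i in idx) {
    m <- stringr::str_match(aln$cigar[i], "^(?:([0-9]+)S)?([0-9]+)M(?:([0-9]+)S)?$")
    expect_false(is.na(m[1, 1]))
    lc <- ifelse(is.na(m[1, 2]), 0L, as.integer(m[1, 2]))
    ml <- as.integer(m[1, 3])
    refseq <- substring(chrom_str[[aln$chrom[i]]], aln$pos[i] + 1,
                        aln$pos[i] + ml)
    expect_identical(substr(aln$seq[i], lc + 1, lc + ml), refseq)
  }
})

test_that("junction reads reconstruct a contiguous rotated circle substring", {
  # with zero errors, rejoining the clipped and anchored parts of a
  # junction-spanning read must equal a substring of the doubled circle
  sim <- tiny_sim0()
  ref <- tiny_ref()
  truth <- plant_circles(tiny_ref(), tiny_cfg0())
  single <- truth[!truth$is_chimeric, ]
  circseq <- setNames(
    lapply(single$fragments, circle_sequence, genome = ref$genome),
    single$circle_id)
  aln <- read_alignments(sim$sam)$aln
  clipped <- aln[grepl("S", aln$cigar) & !grepl("I|D", aln$cigar), ]
  clipped$circle <- sub("_p[0-9]+$", "", clipped$read_id)
  clipped <- clipped[clipped$circle %in% single$circle_id, ]
  expect_gt(nrow(clipped), 10)
  set.seed(2)
  for (i in sample(nrow(clipped), min(50, nrow(clipped)))) {
    doubled <- strrep(circseq[[clipped$circle[i]]], 2)
    expect_true(grepl(clipped$seq[i], doubled, fixed = TRUE) ||
                  grepl(revcomp_test(clipped$seq[i]), doubled, fixed = TRUE))
  }
})

test_that("single-circle coverage is enriched inside the planted interval", {
  cfg <- sim_config(genome_length = 1e5, n_chroms = 1, n_circles = 1,
                    chimera_prob = 0, error_rate = 0, seed = 21)
  ref <- build_synthetic_genome(cfg)
  truth <- plant_circles(ref, cfg)
  sim <- suppressWarnings(simulate_short_reads(truth, ref, cfg,
                                               dir = tempfile()))
  ra <- read_alignments(sim$sam)
  cov <- circlekit:::bam_coverage(ra$bam)[[1]]
  iv <- sim$truth
  inside <- mean(as.numeric(cov[(iv$start + 1):iv$end]))
  outside <- mean(as.numeric(cov[-((iv$start + 1):iv$end)]))
  expect_gt(inside, 10 * max(outside, 1e-9))
})

test_that("a constructed junction read carries the documented soft clip", {
  # read starting 50 bp before the wrap junction with 150 bp reads:
  # 50 M on the circle end, ~100 S realigning to the circle start
  ref <- tiny_ref()
  truth <- plant_circles(tiny_ref(), tiny_cfg0())
  single <- truth[!truth$is_chimeric, ][1, ]
  fr <- single$fragments[[1]]
  clen <- fr$end - fr$start
  circ <- circle_sequence(fr, ref$genome)
  a <- clen - 50L
  read <- substring(strrep(circ, 2), a + 1, a + 150)
  # anchored part is the 100 bp clipped continuation at the circle start
  expect_identical(substr(read, 51, 150), substr(circ, 1, 100))
  # and the simulator encodes exactly this geometry
  p <- circlekit:::place_reads(fr, clen, a, 150L, read)
  expect_equal(p$cigar, "50S100M")
  expect_equal(p$pos, fr$start)
})

test_that("planted SNV clusters satisfy the kataegis definition by construction", {
  ref <- tiny_ref()
  ecdna <- tibble::tibble(chrom = "chr1", start = 10000L, end = 40000L)
  cfg <- tiny_cfg()
  pk <- plant_kataegis_snvs(ref, ecdna, cfg, n_clusters = 4,
                            background_imd = 5e4, frac_on_ecdna = 1)
  expect_equal(nrow(pk$truth), 4)
  expect_true(all(pk$truth$n_snvs >= 6))
  expect_true(all(pk$truth$mean_imd <= 1000))
  expect_true(all(pk$truth$label == "on_ecdna"))

  # no planted clusters on a sparse background -> empty truth
  pk0 <- plant_kataegis_snvs(ref, ecdna, cfg, n_clusters = 0,
                             background_imd = 1e5)
  expect_equal(nrow(pk0$truth), 0)

  expect_warning(plant_kataegis_snvs(ref, ecdna, cfg, n_clusters = 0,
                                     background_imd = 2000), "background")
})

test_that("simulator outputs are reproducible for a fixed configuration", {
  cfg <- sim_config(genome_length = 1.5e5, n_circles = 5, seed = 77)
  ref <- build_synthetic_genome(cfg)
  truth <- plant_circles(ref, cfg)
  s1 <- suppressWarnings(simulate_short_reads(truth, ref, cfg, dir = tempfile()))
  s2 <- suppressWarnings(simulate_short_reads(truth, ref, cfg, dir = tempfile()))
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  r1 <- simulate_rca_reads(truth, ref, cfg, dir = tempfile())
  r2 <- simulate_rca_reads(truth, ref, cfg, dir = tempfile())
  expect_identical(readLines(r1$paf), readLines(r2$paf))
  expect_identical(readLines(r1$fasta), readLines(r2$fasta))
})
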