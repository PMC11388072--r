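test_that("kataegis windows qualify by mean gap with an inclusive boundary", {
  # six SNVs at 200 bp gaps -> one event with mean IMD 200
  s1 <- tibble::tibble(chrom = "chr1", pos = cumsum(c(1000L, rep(200L, 5))))
  ev <- detect_kataegis(s1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_snvs, 6L)
  expect_equal(ev$mean_imd, 200)
  expect_equal(ev$first_pos, s1$pos[1] + 1L)

  # mean gap 1000 exactly still qualifies ...
  s2 <- tibble::tibble(chrom = "chr1", pos = cumsum(c(0L, rep(1000L, 5))))
  expect_equal(nrow(detect_kataegis(s2)), 1)

  # ... but gaps (999 x4, 1005) average 1000.2 and do not
  s3 <- tibble::tibble(chrom = "chr1",
                       pos = cumsum(c(0L, rep(999L, 4), 1005L)))
  expect_equal(nrow(detect_kataegis(s3)), 0)

  expect_error(detect_kataegis(tibble::tibble(chrom = "chr1",
                                              pos = c(10L, 5L))), "sorted")
})

test_that("overlapping qualifying windows merge into one maximal event", {
  # twelve SNVs built so windows 1-6 and 5-10 qualify but no later ones
  gaps <- c(200L, 200L, 200L, 200L, 200L, 900L, 900L, 900L, 900L, 5000L, 5000L)
  s <- tibble::tibble(chrom = "chr1", pos = cumsum(c(0L, gaps)))
  ev <- detect_kataegis(s)
  oracle <- kataegis_oracle(s)
  expect_equal(nrow(ev), nrow(oracle))
  expect_equal(ev$first_pos, oracle$first_pos)
  expect_equal(ev$last_pos, oracle$last_pos)
  expect_gte(ev$n_snvs[1], 10L)
})

test_that("detector matches the brute-force oracle on random SNV sets", {
  set.seed(17)
  for (rep in 1:300) {
    n <- sample(6:200, 1)
    # mixed clustered / dispersed spacing to exercise the boundary
    gaps <- sample(c(50:1500, seq(2000, 50000, by = 500)), n - 1,
                   replace = TRUE)
    s <- tibble::tibble(chrom = sample(c("c1", "c2"), 1),
                        pos = cumsum(c(sample(1000L, 1), gaps)))
    ev <- detect_kataegis(s)
    oracle <- kataegis_oracle(s)
    expect_identical(nrow(ev), nrow(oracle))
    if (nrow(ev) > 0) {
      expect_identical(ev$first_pos, oracle$first_pos)
      expect_identical(ev$last_pos, oracle$last_pos)
      expect_identical(ev$n_snvs, oracle$n_snvs)
    }
  }
})

test_that("planted clusters are recovered and sparse backgrounds stay clean", {
  ref <- tiny_ref()
  ecdna <- tibble::tibble(chrom = "chr2", start = 20000L, end = 60000L)
  pk <- plant_kataegis_snvs(ref, ecdna, tiny_cfg(), n_clusters = 6,
                            background_imd = 5e4)
  ev <- detect_kataegis(pk$snvs)
  recovered <- vapply(seq_len(nrow(pk$truth)), function(i) {
    any(ev$chrom == pk$truth$chrom[i] &
          ev$first_pos - 1 <= pk$truth$first_pos[i] &
          ev$last_pos - 1 >= pk$truth$last_pos[i])
  }, logical(1))
  expect_true(all(recovered))
})

test_that("96-context classification complements purine references", {
  # G>T at 0-based position 1 of "AGC": complement -> C>A in G[C>A]T
  g <- toy_genome("AAGCA")
  snv <- tibble::tibble(chrom = "c1", pos = 2L, ref = "G", alt = "T")
  sp <- classify_96(snv, g)
  expect_equal(sum(sp$count), 1)
  expect_equal(sp$context[sp$count == 1], "G[C>A]T")

  # pyrimidine reference is used as-is
  snv2 <- tibble::tibble(chrom = "c1", pos = 3L, ref = "C", alt = "T")
  sp2 <- classify_96(snv2, g)
  expect_equal(sp2$context[sp2$count == 1], "G[C>T]A")

  # reference mismatch is an error naming the site
  expect_error(classify_96(tibble::tibble(chrom = "c1", pos = 2L, ref = "T",
                                          alt = "A"), g), "mismatch")
})

test_that("spectrum counts are conserved and strand-invariant", {
  ref <- tiny_ref()
  set.seed(23)
  n <- 2000
  sizes <- ref$sizes
  ci <- sample(nrow(sizes), n, replace = TRUE, prob = sizes$size)
  pos <- as.integer(floor(runif(n) * (sizes$size[ci] - 4)) + 2)
  snvs <- tibble::tibble(chrom = sizes$chrom[ci], pos = pos) |>
    dplyr::distinct(chrom, pos) |> dplyr::arrange(chrom, pos)
  refb <- vapply(seq_len(nrow(snvs)), function(i) {
    as.character(Biostrings::subseq(ref$genome[[snvs$chrom[i]]],
                                    snvs$pos[i] + 1L, snvs$pos[i] + 1L))
  }, character(1))
  set.seed(24)
  snvs$ref <- refb
  snvs$alt <- vapply(refb, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  sp <- classify_96(snvs, ref$genome)
  expect_equal(sum(sp$count), nrow(snvs))

  # reverse-complement representation: flip the genome and the SNVs
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_genome <- Biostrings::reverseComplement(ref$genome)
  names(rc_genome) <- names(ref$genome)
  lim <- setNames(sizes$size, sizes$chrom)
  rc_snvs <- snvs |>
    dplyr::mutate(pos = lim[chrom] - 1L - pos,
                  ref = unname(comp[ref]), alt = unname(comp[alt])) |>
    dplyr::arrange(chrom, pos)
  sp_rc <- classify_96(rc_snvs, rc_genome)
  expect_equal(sp_rc$count, sp$count)
})

test_that("kyklonas status follows the on/near/none rule with a 10 kb boundary", {
  ecdna <- tibble::tibble(chrom = "c1", start = 50000L, end = 80000L)
  mk_event <- function(pos) {
    detect_kataegis(tibble::tibble(chrom = "c1",
                                   pos = pos + cumsum(c(0L, rep(100L, 5)))))
  }
  on <- classify_kyklonas(mk_event(60000L), ecdna)
  expect_equal(on$kyklonas_status, "on_ecdna")

  near <- classify_kyklonas(mk_event(80001L + 9499L), ecdna)  # 9999 bp away
  expect_equal(near$kyklonas_status, "near_ecdna_10kb")
  expect_equal(near$min_breakpoint_distance, 9500)

  none <- classify_kyklonas(mk_event(95000L), ecdna)
  expect_equal(none$kyklonas_status, "none")

  all_none <- classify_kyklonas(mk_event(60000L), ecdna[0, ])
  expect_equal(all_none$kyklonas_status, "none")
})

test_that("breakpoint distances are exact and missing off-chromosome", {
  iv <- tibble::tibble(chrom = "c1", start = 1000L, end = 5000L)
  mu <- tibble::tibble(chrom = c("c1", "c1", "c2"),
                       pos = c(1000L, 2600L, 100L))
  d <- distance_to_breakpoints(mu, iv)
  expect_equal(d$distance, c(0, 1600, NA))
})

test_that("cluster members sit closer to breakpoints than background SNVs", {
  ref <- tiny_ref()
  ecdna <- tibble::tibble(chrom = "chr1", start = 30000L, end = 70000L)
  pk <- plant_kataegis_snvs(ref, ecdna, tiny_cfg(), n_clusters = 5,
                            background_imd = 2e4, frac_on_ecdna = 1)
  d <- distance_to_breakpoints(pk$snvs, ecdna)
  d1 <- d[d$chrom == "chr1" & !is.na(d$distance), ]
  expect_lt(median(d1$distance[d1$is_clustered]),
            median(d1$distance[!d1$is_clustered]))
})
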