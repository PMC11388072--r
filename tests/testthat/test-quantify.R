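test_that("EPM is the per-million ratio and is linear in circle count", {
  expect_equal(compute_epm(540972, 100e6), 5409.72)
  expect_equal(compute_epm(0, 1e6), 0)
  expect_equal(compute_epm(5, 1e6), 5)
  expect_equal(compute_epm(10, 2e6), 2 * compute_epm(5, 2e6))
  expect_error(compute_epm(5, 0), "positive")
})

test_that("gene abundance counts unique start sites and normalizes to 1e6", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "c1",
                          start = c(0L, 5000L), end = c(4000L, 9000L),
                          strand = "+")
  # single gene hit -> all abundance on it
  one <- gene_abundance(tibble::tibble(chrom = "c1", start = 10L, end = 800L),
                        genes)
  expect_equal(one$A, c(1e6, 0))

  # equal-length genes with equal counts split evenly
  circ <- tibble::tibble(chrom = "c1", start = c(10L, 100L, 5010L, 5100L),
                         end = c(700L, 800L, 5700L, 5800L))
  eq <- gene_abundance(circ, genes)
  expect_equal(eq$A, c(5e5, 5e5))
  expect_equal(sum(eq$A), 1e6)

  # duplicated start coordinates collapse to one junction
  dup <- gene_abundance(tibble::tibble(chrom = "c1", start = c(10L, 10L),
                                       end = c(600L, 900L)), genes)
  expect_equal(dup$J, c(1L, 0L))

  # empty table normalizes to zero, not NaN
  none <- gene_abundance(tibble::tibble(chrom = "c1", start = 4500L,
                                        end = 4600L), genes)
  expect_equal(sum(none$A), 0)
})

test_that("abundance normalization sums to 1e6 on simulated tables", {
  d <- simulate_abundance_tables(sim_config(seed = 8), n_genes = 500,
                                 n_tumor = 3, n_at = 3, n_diff = 10)
  for (tb in c(d$tumor, d$at)) {
    expect_equal(sum(tb$A), 1e6, tolerance = 1e-6)
  }
})

test_that("element profile assigns circles to all overlapped classes", {
  sizes <- tibble::tibble(chrom = "c1", size = 100000L)
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "c1", start = 10000L, end = 20000L, strand = "+",
    thick_start = 11000L, thick_end = 19000L,
    exons = list(tibble::tibble(start = c(10000L, 15000L),
                                end = c(12000L, 20000L))))
  # one circle spanning exon + intron, one fully intergenic
  circ <- tibble::tibble(chrom = "c1", start = c(11500L, 50000L),
                         end = c(14000L, 51000L))
  ep <- element_profile(circ, genes, sizes)
  frac <- setNames(ep$fraction_of_circles, ep$class)
  expect_equal(frac[["CDS"]], 0.5)       # circle 1 overlaps CDS
  expect_equal(frac[["intron"]], 0.5)    # ... and intron (multi-hit)
  expect_equal(frac[["intergenic"]], 0.5)
  expect_equal(frac[["downstream2kb"]], 0)
  # per-base partition is exclusive and covers the genome
  parts <- circlekit:::element_partition(genes, sizes)
  expect_equal(sum(vapply(parts, function(g) sum(IRanges::width(g)),
                          numeric(1))), 100000)
  # empty circle set: zero fractions, missing enrichment
  ep0 <- element_profile(circ[0, ], genes, sizes)
  expect_true(all(ep0$fraction_of_circles == 0))
  expect_true(all(is.na(ep0$enrichment)))
})

test_that("repeat fraction counts reads overlapping repeats by >= 1 bp", {
  reads <- tibble::tibble(chrom = "c1", start = c(0L, 100L, 200L),
                          end = c(50L, 150L, 250L))
  expect_equal(repeat_fraction(reads, reads[0, ]), 0)
  expect_equal(repeat_fraction(reads, tibble::tibble(chrom = "c1", start = 0L,
                                                     end = 300L)), 1)
  expect_equal(repeat_fraction(reads, tibble::tibble(chrom = "c1", start = 149L,
                                                     end = 160L)), 1 / 3)
})

test_that("repeat fraction of uniform reads matches the planted repeat density", {
  ref <- tiny_ref()
  set.seed(3)
  n <- 4000
  sizes <- ref$sizes
  ci <- sample(nrow(sizes), n, replace = TRUE, prob = sizes$size)
  st <- floor(runif(n) * (sizes$size[ci] - 100))
  reads <- tibble::tibble(chrom = sizes$chrom[ci], start = as.integer(st),
                          end = as.integer(st + 100))
  planted <- sum(ref$repeats$end - ref$repeats$start) / sum(sizes$size)
  expect_lt(abs(repeat_fraction(reads, ref$repeats) - planted), 0.03)
})

test_that("GC and size classes follow the stated conventions", {
  g <- toy_genome(paste0(strrep("GC", 1500), strrep("AT", 5000)))
  all_gc <- tibble::tibble(chrom = "c1", start = 0L, end = 3000L)
  prof <- gc_and_size_profile(all_gc, g)
  expect_equal(prof$per_circle$gc, 1)

  circ <- tibble::tibble(chrom = "c1",
                         start = c(0L, 0L, 0L, 0L),
                         end = c(1999L, 2000L, 10000L, 10001L))
  cls <- gc_and_size_profile(circ, g)$per_circle$size_class
  expect_equal(as.character(cls), c("lt_2kb", "2_10kb", "2_10kb", "gt_10kb"))

  # all circles small -> fractions (1, 0, 0)
  small <- gc_and_size_profile(circ[1, ], g)$size_fractions
  expect_equal(small$fraction, c(1, 0, 0))

  expect_error(gc_and_size_profile(
    tibble::tibble(chrom = "c1", start = 0L, end = 99999L), g), "beyond")
})

test_that("interval shuffling preserves lengths, stays in bounds, is seeded", {
  sizes <- tibble::tibble(chrom = c("c1", "c2"), size = c(50000L, 20000L))
  circ <- tibble::tibble(chrom = "c1",
                         start = as.integer(seq(0, 40000, length.out = 50)),
                         end = as.integer(seq(0, 40000, length.out = 50) +
                                            rep(c(500, 1200), 25)))
  sh1 <- shuffle_intervals(circ, sizes, seed = 5)
  sh2 <- shuffle_intervals(circ, sizes, seed = 5)
  expect_identical(sh1, sh2)
  expect_equal(sort(sh1$end - sh1$start), sort(circ$end - circ$start))
  lim <- setNames(sizes$size, sizes$chrom)
  expect_true(all(sh1$start >= 0 & sh1$end <= lim[sh1$chrom]))
  expect_error(shuffle_intervals(
    tibble::tibble(chrom = "c1", start = 0L, end = 60000L), sizes, 1),
    "longer")
})

test_that("shuffled start positions are uniform over valid placements", {
  sizes <- tibble::tibble(chrom = "c1", size = 1000000L)
  circ <- tibble::tibble(chrom = "c1", start = 0L, end = 1000L)[rep(1, 2000), ]
  pvals <- vapply(1:20, function(s) {
    sh <- shuffle_intervals(circ, sizes, seed = s)
    suppressWarnings(ks.test(sh$start, "punif", 0, 999001)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})
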