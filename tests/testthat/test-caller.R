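test_that("soft-clip realignment posterior behaves as a likelihood ratio", {
  set.seed(4)
  win <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  clip <- substr(win, 501, 520)           # unique 20-mer
  hit <- realign_softclip(clip, strrep("?", 20), win)  # '?' = Q30
  expect_equal(hit$offset, 500L)
  expect_gt(hit$posterior, 0.99)

  # two identical copies -> posterior splits to <= 0.5 (+ float slack)
  win2 <- paste0(win, substr(win, 401, 700))  # duplicate a 300 bp block
  hit2 <- realign_softclip(clip, strrep("?", 20), win2)
  expect_lte(hit2$posterior, 0.5 + 1e-6)

  # empty / too-small region contributes nothing
  expect_equal(realign_softclip(clip, strrep("?", 20), "")$offset, -1L)
  expect_error(realign_softclip("ACGTA", strrep("?", 5), win), "min_softclip")
})

test_that("candidate extraction applies the orientation and clip-length rules", {
  base <- tibble::tibble(
    read_id = c("p1", "p1", "p2", "p2", "s1", "s2"),
    flag = 0L,
    chrom = "c1",
    pos = c(100L, 400L, 300L, 150L, 500L, 600L),
    mapq = 60L,
    cigar = c("100M", "100M", "100M", "100M", "5S95M", "80M20S"),
    seq = strrep("A", 100), qual = strrep("I", 100),
    is_paired = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    is_read1 = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    is_reverse = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    mate_is_reverse = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    mate_unmapped = FALSE,
    mate_chrom = "c1",
    mate_pos = c(400L, 100L, 150L, 300L, NA, NA),
    end = c(200L, 500L, 400L, 250L, 595L, 680L)
  ) |> dplyr::arrange(pos)
  cand <- extract_candidates(base, caller_config())
  # p1 is concordant FR (forward leftmost): not discordant
  # p2 is outward-facing (reverse leftmost at 150, forward mate): discordant
  expect_equal(nrow(cand$discordant), 1)
  expect_equal(cand$discordant$span_start, 150L)
  # 5 bp clip ignored under min_softclip_len = 10; the 20 bp clip kept
  expect_equal(nrow(cand$split), 1)
  expect_equal(cand$split$side, "right")

  unsorted <- base[c(3, 1, 2, 4, 5, 6), ]
  expect_error(extract_candidates(unsorted, caller_config()), "sorted")
})

test_that("junction clustering merges within tolerance and scores by posterior", {
  j <- tibble::tibble(chrom = "c1",
                      start = c(1000L, 1004L, 1002L),
                      end = c(2000L, 2000L, 1998L),
                      posterior = c(1, 1, 0.9),
                      read_id = c("a", "b", "c"))
  calls <- score_and_merge(j, NULL, caller_config())
  expect_equal(nrow(calls), 1)           # 4 bp apart with tolerance 10
  expect_equal(calls$n_split, 3L)
  expect_equal(calls$circle_score, 290)  # 100 * (1 + 1 + 0.9)

  # two confident reads sit exactly at the score threshold
  j2 <- j[1:2, ] |> dplyr::mutate(posterior = 1)
  c2 <- score_and_merge(j2, NULL, caller_config())
  expect_equal(c2$circle_score, 200)

  # far-apart junctions stay separate
  j3 <- dplyr::bind_rows(j, dplyr::mutate(j, start = start + 5000L,
                                          end = end + 5000L))
  expect_equal(nrow(score_and_merge(j3, NULL, caller_config())), 2)
})

test_that("filter suite enforces each printed threshold exactly", {
  cfg <- caller_config()
  base <- tibble::tibble(chrom = "c1", start = 0L, end = 1000L,
                         n_split = 2L, circle_score = 200,
                         cov_inc_start = 0.33, cov_inc_end = 0.33,
                         continuity = 0.1, cov_mean = 10, cov_sd = 5,
                         n_discordant = 1L)
  expect_true(apply_circle_filters(base, cfg)$passed)

  at_threshold <- list(
    split_reads = function(x) dplyr::mutate(x, n_split = 1L),
    circle_score = function(x) dplyr::mutate(x, circle_score = 199.99),
    cov_increase_start = function(x) dplyr::mutate(x, cov_inc_start = 0.3299),
    cov_increase_end = function(x) dplyr::mutate(x, cov_inc_end = 0.3299),
    continuity = function(x) dplyr::mutate(x, continuity = 0.1001),
    sd_lt_mean = function(x) dplyr::mutate(x, cov_sd = 10, cov_mean = 10),
    long_no_discordant = function(x) dplyr::mutate(x, end = 2500L,
                                                   n_discordant = 0L)
  )
  for (nm in names(at_threshold)) {
    out <- apply_circle_filters(at_threshold[[nm]](base), cfg)
    expect_false(out$passed, info = nm)
    expect_match(out$fail_reasons, nm, fixed = TRUE)
  }

  # boundary inclusivity: exactly 2 kb triggers the discordant rule,
  # 1999 bp does not
  expect_false(apply_circle_filters(
    dplyr::mutate(base, end = 2000L, n_discordant = 0L), cfg)$passed)
  expect_true(apply_circle_filters(
    dplyr::mutate(base, end = 1999L, n_discordant = 0L), cfg)$passed)
})

test_that("filtering is monotone in every threshold", {
  sim <- tiny_sim()
  ref <- tiny_ref()
  res <- call_circles(sim$sam, ref$genome, caller_config(), keep_all = TRUE)
  raw <- res$calls
  n_passed <- function(cfg) sum(apply_circle_filters(raw, cfg)$passed)
  base <- n_passed(caller_config())
  sweeps <- list(
    lapply(c(2, 3, 5, 8, 12), function(v) caller_config(min_split = v)),
    lapply(c(200, 400, 800, 1500, 3000), function(v) caller_config(min_score = v)),
    lapply(c(0.33, 0.5, 0.7, 0.9, 0.99), function(v) caller_config(min_cov_increase = v)),
    lapply(c(0.1, 0.05, 0.02, 0.01, 0), function(v) caller_config(max_continuity = v))
  )
  for (sweep in sweeps) {
    counts <- vapply(sweep, n_passed, numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[1], base)
  }
})

test_that("perfect-alignment scene is called with exact breakpoints", {
  sim <- tiny_sim0()
  ref <- tiny_ref()
  res <- call_circles(sim$sam, ref$genome)
  ev <- evaluate_calls(res, sim$truth)
  expect_equal(ev$summary$capture_rate, 1)
  expect_equal(ev$summary$max_bp_error, 0)
  # determinism: identical input, identical output
  res2 <- call_circles(sim$sam, ref$genome)
  expect_identical(res$calls, res2$calls)
  # score bound: circle_score <= 100 * n_split
  expect_true(all(res$calls$circle_score <= 100 * res$calls$n_split + 1e-9))
})

test_that("call evaluation implements the matching policy", {
  truth <- tibble::tibble(chrom = "c1",
                          start = seq(0L, 90000L, by = 10000L),
                          end = seq(1000L, 91000L, by = 10000L))
  # identity
  ev <- evaluate_calls(truth, truth)
  expect_equal(ev$summary$capture_rate, 1)
  expect_equal(ev$summary$precision, 1)

  # 5 exact + 5 non-overlapping decoys -> capture 0.5, precision 0.5
  calls <- dplyr::bind_rows(truth[1:5, ],
                            dplyr::mutate(truth[6:10, ],
                                          start = start + 5000L,
                                          end = end + 5000L))
  ev2 <- evaluate_calls(calls, truth)
  expect_equal(ev2$summary$capture_rate, 0.5)
  expect_equal(ev2$summary$precision, 0.5)

  # 8 bp breakpoint shift still matches under the +-10 bp policy
  shifted <- dplyr::mutate(truth, start = start + 8L, end = end + 8L)
  expect_equal(evaluate_calls(shifted, truth)$summary$capture_rate, 1)
  # 12 bp shift fails both the breakpoint and reciprocal-overlap rules
  # for these 1 kb circles
  far <- dplyr::mutate(truth, start = start + 60L, end = end + 60L)
  expect_equal(evaluate_calls(far, truth)$summary$capture_rate, 0)

  # empty calls
  ev0 <- evaluate_calls(truth[0, ], truth)
  expect_equal(ev0$summary$capture_rate, 0)
})

test_that("an empty alignment file yields zero candidates and calls", {
  sizes <- tibble::tibble(chrom = "c1", size = 10000L)
  f <- tempfile(fileext = ".sam")
  write_sam(tibble::tibble(read_id = character(), flag = integer(),
                           chrom = character(), pos = integer(),
                           mapq = integer(), cigar = character(),
                           seq = character(), qual = character(),
                           mate_chrom = character(), mate_pos = integer()),
            sizes, f)
  g <- toy_genome(paste(rep("ACGT", 2500), collapse = ""))
  names(g) <- "c1"
  res <- call_circles(f, g)
  expect_equal(nrow(res$calls), 0)
  expect_equal(res$qc$n_split_candidates, 0)
})
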