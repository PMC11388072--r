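#' Circle caller configuration
#'
#' Thresholds of the eccDNA junction caller and its filter suite. The
#' filter defaults are the published cutoffs: at least 2 supporting split
#' reads, circle score at least 200, coverage increase at both boundaries
#' at least 0.33, coverage continuity (zero-coverage fraction inside the
#' circle) at most 0.1, coverage SD smaller than the mean over the circle,
#' and — to remove spuriously long circles whose split and discordant
#' evidence comes from the same reads — calls of at least `long_circle_bp`
#' (2 kb) additionally require a supporting discordant pair.
#'
#' @param min_split minimum supporting split reads (filter 1).
#' @param min_score minimum circle score (filter 2); the score is the sum
#'   over supporting split reads of 100 x their realignment posterior, so
#'   200 is roughly "two confident reads".
#' @param min_cov_increase minimum relative coverage increase at each
#'   boundary (filters 3-4); the denominator is the inside mean, negative
#'   values are clipped to 0.
#' @param max_continuity maximum zero-coverage fraction inside (filter 5).
#' @param require_sd_lt_mean enforce SD(coverage) < mean(coverage) (filter 6).
#' @param long_circle_bp length from which a discordant pair is required.
#' @param boundary_window window (bp) for the boundary coverage means.
#' @param realign_search_window how far (bp) beyond the anchored breakpoint
#'   the soft-clip realignment scans.
#' @param min_softclip_len soft clips shorter than this are ignored.
#' @param junction_merge_tolerance breakpoint clustering tolerance (bp).
#' @param mapq_min minimum mapping quality of used alignments.
#' @param max_circle_span maximum span (bp) considered for a discordant pair.
#' @return a `caller_config` list.
#' @export
caller_config <- function(min_split = 2L, min_score = 200, min_cov_increase = 0.33,
                          max_continuity = 0.1, require_sd_lt_mean = TRUE,
                          long_circle_bp = 2000L, boundary_window = 100L,
                          realign_search_window = 10000L, min_softclip_len = 10L,
                          junction_merge_tolerance = 10L, mapq_min = 20L,
                          max_circle_span = 200000L) {
  structure(list(min_split = min_split, min_score = min_score,
                 min_cov_increase = min_cov_increase,
                 max_continuity = max_continuity,
                 require_sd_lt_mean = require_sd_lt_mean,
                 long_circle_bp = long_circle_bp,
                 boundary_window = boundary_window,
                 realign_search_window = realign_search_window,
                 min_softclip_len = min_softclip_len,
                 junction_merge_tolerance = junction_merge_tolerance,
                 mapq_min = mapq_min, max_circle_span = max_circle_span),
            class = "caller_config")
}

#' Extract split-read and discordant-pair candidates
#'
#' Scans primary alignments for (a) reads carrying a terminal soft clip of
#' at least `min_softclip_len` bases — the clip is the putative
#' junction-crossing part — and (b) same-chromosome read pairs in
#' outward-facing orientation (leftmost read on the reverse strand, its
#' mate downstream on the forward strand), the geometry a read pair takes
#' when its insert wraps across a circular junction. Duplicates,
#' secondary/supplementary records and low-MAPQ reads are excluded;
#' records without mate information are skipped and counted.
#'
#' @param aln alignment tibble from [read_alignments()].
#' @param config a [caller_config()].
#' @return list with `split` (read_id, chrom, side, anchor_start,
#'   anchor_end, clip_seq, clip_qual), `discordant` (chrom, span_start,
#'   span_end) and `n_no_mate`.
#' @export
extract_candidates <- function(aln, config = caller_config()) {
  stopifnot(inherits(config, "caller_config"))
  if (nrow(aln) > 0) {
    shifted <- unlist(tapply(aln$pos, aln$chrom, function(p) c(FALSE, diff(p) < 0)))
    if (any(shifted)) abort("alignments are not coordinate-sorted")
  }
  ok <- aln %>% filter(.data$mapq >= config$mapq_min)

  lead_m <- stringr::str_match(ok$cigar, "^([0-9]+)S")[, 2]
  trail_m <- stringr::str_match(ok$cigar, "([0-9]+)S$")[, 2]
  lead_s <- if_else(is.na(lead_m), 0L, suppressWarnings(as.integer(lead_m)))
  trail_s <- if_else(is.na(trail_m), 0L, suppressWarnings(as.integer(trail_m)))
  rl <- nchar(ok$seq)

  left <- which(lead_s >= config$min_softclip_len)
  right <- which(trail_s >= config$min_softclip_len)
  split <- bind_rows(
    tibble(read_id = ok$read_id[left], chrom = ok$chrom[left], side = "left",
           anchor_start = ok$pos[left], anchor_end = ok$end[left],
           clip_seq = substr(ok$seq[left], 1L, lead_s[left]),
           clip_qual = substr(ok$qual[left], 1L, lead_s[left])),
    tibble(read_id = ok$read_id[right], chrom = ok$chrom[right], side = "right",
           anchor_start = ok$pos[right], anchor_end = ok$end[right],
           clip_seq = substr(ok$seq[right], rl[right] - trail_s[right] + 1L,
                             rl[right]),
           clip_qual = substr(ok$qual[right], rl[right] - trail_s[right] + 1L,
                              rl[right]))
  )

  n_no_mate <- sum(ok$is_paired & (ok$mate_unmapped | is.na(ok$mate_chrom)))
  pair <- ok %>%
    filter(.data$is_paired, !.data$mate_unmapped, !is.na(.data$mate_chrom),
           .data$chrom == .data$mate_chrom,
           .data$pos < .data$mate_pos |
             (.data$pos == .data$mate_pos & .data$is_read1),
           .data$is_reverse, !.data$mate_is_reverse)
  disc <- tibble(chrom = pair$chrom, span_start = pair$pos,
                 span_end = pair$mate_pos + nchar(pair$seq)) %>%
    filter(.data$span_end > .data$span_start,
           .data$span_end - .data$span_start <= config$max_circle_span)

  list(split = split, discordant = disc, n_no_mate = n_no_mate)
}

#' Realign a soft-clipped sequence within a search window
#'
#' Gapless, quality-aware scan of every start offset on the
#' junction-consistent strand of the search region: per base the
#' likelihood is `1 - eps` for a match and `eps / 3` for a mismatch, with
#' `eps` decoded from the base quality. The returned posterior is the best
#' offset's likelihood over the sum across all scanned offsets, so a clip
#' matching two identical repeat copies gets posterior about 0.5 and a
#' unique high-quality match gets posterior near 1.
#'
#' @param clip_seq clipped sequence (character scalar).
#' @param clip_qual phred qualities: an ASCII-33 string or integer vector.
#' @param region_seq search window sequence (character scalar).
#' @param config a [caller_config()] (`min_softclip_len` is enforced).
#' @return list with `offset` (0-based in the region, -1 when nothing was
#'   scanned), `posterior` and `n_positions`.
#' @export
realign_softclip <- function(clip_seq, clip_qual, region_seq,
                             config = caller_config()) {
  if (nchar(clip_seq) < config$min_softclip_len) {
    abort("clip shorter than min_softclip_len")
  }
  q <- if (is.character(clip_qual)) utf8ToInt(clip_qual) - 33L else as.integer(clip_qual)
  eps <- 10^(-q / 10)
  if (is.null(region_seq) || is.na(region_seq) || nchar(region_seq) == 0) {
    return(list(offset = -1L, posterior = 0, n_positions = 0L))
  }
  realign_scan_cpp(clip_seq, eps, region_seq)
}

# Realign all split candidates; returns junction tibble
# (chrom, start, end, posterior, read_id).
realign_candidates <- function(split, chrom_str, sizes, config) {
  if (nrow(split) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  posterior = numeric(), read_id = character()))
  }
  W <- config$realign_search_window
  size_of <- setNames(sizes$size, sizes$chrom)
  out <- vector("list", nrow(split))
  for (i in seq_len(nrow(split))) {
    ch <- split$chrom[i]
    L <- size_of[[ch]]
    if (split$side[i] == "right") {
      e <- split$anchor_end[i]
      r0 <- max(0L, e - W)
      if (e - r0 < nchar(split$clip_seq[i])) next
      region <- substring(chrom_str[[ch]], r0 + 1L, e)
      hit <- realign_softclip(split$clip_seq[i], split$clip_qual[i], region, config)
      if (hit$offset < 0) next
      s <- r0 + hit$offset
      if (s >= e) next
      out[[i]] <- tibble(chrom = ch, start = as.integer(s), end = as.integer(e),
                         posterior = hit$posterior, read_id = split$read_id[i])
    } else {
      s0 <- split$anchor_start[i]
      r1 <- min(L, s0 + W)
      if (r1 - s0 < nchar(split$clip_seq[i])) next
      region <- substring(chrom_str[[ch]], s0 + 1L, r1)
      hit <- realign_softclip(split$clip_seq[i], split$clip_qual[i], region, config)
      if (hit$offset < 0) next
      e <- s0 + hit$offset + nchar(split$clip_seq[i])
      if (e <= s0) next
      out[[i]] <- tibble(chrom = ch, start = as.integer(s0), end = as.integer(e),
                         posterior = hit$posterior, read_id = split$read_id[i])
    }
  }
  bind_rows(out)
}

# value with the largest total weight (ties: smallest value)
modal_weighted <- function(values, weights) {
  agg <- tapply(weights, values, sum)
  as.integer(names(agg)[order(-agg, as.numeric(names(agg)))][1])
}

#' Cluster realigned junctions into raw circle calls
#'
#' Junction pairs are clustered when both breakpoints agree within
#' `junction_merge_tolerance`; the cluster representative is the
#' posterior-weighted modal breakpoint. Per call, `n_split` is the number
#' of supporting realigned reads, `circle_score` the sum of 100 x their
#' posteriors, and `n_discordant` the number of outward-facing pairs whose
#' span lies within the interval (plus tolerance).
#'
#' @param junctions tibble from the realignment stage (`chrom`, `start`,
#'   `end`, `posterior`, `read_id`).
#' @param discordant discordant-span tibble from [extract_candidates()].
#' @param config a [caller_config()].
#' @return raw call tibble.
#' @export
score_and_merge <- function(junctions, discordant, config = caller_config()) {
  if (nrow(junctions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_split = integer(), circle_score = numeric(),
                  n_discordant = integer()))
  }
  tol <- config$junction_merge_tolerance
  j <- junctions %>% arrange(.data$chrom, .data$start, .data$end)
  grp_s <- cumsum(c(TRUE, j$chrom[-1] != j$chrom[-nrow(j)] |
                      diff(j$start) > tol))
  j$g1 <- grp_s
  j <- j %>% arrange(.data$g1, .data$end)
  grp_e <- cumsum(c(TRUE, j$g1[-1] != j$g1[-nrow(j)] | diff(j$end) > tol))
  j$cluster <- grp_e
  calls <- j %>%
    group_by(.data$cluster) %>%
    summarise(chrom = first(.data$chrom),
              start = modal_weighted(.data$start, .data$posterior),
              end = modal_weighted(.data$end, .data$posterior),
              n_split = n(),
              circle_score = sum(100 * .data$posterior),
              .groups = "drop") %>%
    select(-"cluster") %>%
    filter(.data$start < .data$end) %>%
    arrange(.data$chrom, .data$start)
  calls$n_discordant <- count_contained_spans(calls, discordant, tol)
  calls
}

count_contained_spans <- function(calls, discordant, tol) {
  if (nrow(calls) == 0) return(integer(0))
  if (is.null(discordant) || nrow(discordant) == 0) return(rep(0L, nrow(calls)))
  vapply(seq_len(nrow(calls)), function(i) {
    sum(discordant$chrom == calls$chrom[i] &
          discordant$span_start >= calls$start[i] - tol &
          discordant$span_end <= calls$end[i] + tol)
  }, integer(1))
}

#' Annotate calls with coverage statistics and apply the filter suite
#'
#' Computes, per call, the boundary coverage increases
#' `max(0, (m_in - m_out) / m_in)` over `boundary_window` bp inside vs
#' immediately outside each breakpoint (windows shrink for short calls;
#' a zero inside mean fails the boundary filters by definition), the
#' coverage continuity (zero-coverage fraction inside), and the mean/SD of
#' coverage over the interval, then applies the six filters plus the
#' long-circle discordant requirement via [apply_circle_filters()].
#'
#' @param calls raw call tibble from [score_and_merge()].
#' @param cov per-chromosome coverage (RleList from a BAM, see
#'   [bam_coverage()]).
#' @param config a [caller_config()].
#' @return annotated call tibble with `passed` and `fail_reasons`.
#' @export
coverage_filters <- function(calls, cov, config = caller_config()) {
  n <- nrow(calls)
  cov_inc_start <- cov_inc_end <- continuity <- cov_mean <- cov_sd <- numeric(n)
  for (i in seq_len(n)) {
    v <- cov[[calls$chrom[i]]]
    s <- calls$start[i]; e <- calls$end[i]
    len <- e - s
    w <- min(config$boundary_window, len)
    inside <- as.numeric(v[(s + 1):e])
    out_l <- if (s > 0) as.numeric(v[max(1, s - w + 1):s]) else numeric(0)
    out_r <- if (e < length(v)) as.numeric(v[(e + 1):min(length(v), e + w)]) else numeric(0)
    m_in_s <- mean(inside[1:w])
    m_in_e <- mean(inside[(len - w + 1):len])
    m_out_s <- if (length(out_l)) mean(out_l) else 0
    m_out_e <- if (length(out_r)) mean(out_r) else 0
    cov_inc_start[i] <- if (m_in_s > 0) max(0, (m_in_s - m_out_s) / m_in_s) else 0
    cov_inc_end[i] <- if (m_in_e > 0) max(0, (m_in_e - m_out_e) / m_in_e) else 0
    continuity[i] <- mean(inside == 0)
    cov_mean[i] <- mean(inside)
    cov_sd[i] <- sd(inside)
  }
  calls %>%
    mutate(cov_inc_start = cov_inc_start, cov_inc_end = cov_inc_end,
           continuity = continuity, cov_mean = cov_mean,
           cov_sd = if_else(is.na(cov_sd), 0, cov_sd)) %>%
    apply_circle_filters(config)
}

#' Apply the six-part filter suite to annotated calls
#'
#' Pure threshold logic over an annotated call tibble (no I/O), so
#' constructed fixtures can exercise each printed cutoff exactly:
#' `split_reads` (n_split at least 2), `circle_score` (at least 200),
#' `cov_increase_start` / `cov_increase_end` (at least 0.33), `continuity`
#' (at most 0.1), `sd_lt_mean` (SD < mean), and `long_no_discordant`
#' (length of 2 kb or more requires n_discordant of at least 1).
#'
#' @param calls tibble with `n_split`, `circle_score`, `cov_inc_start`,
#'   `cov_inc_end`, `continuity`, `cov_mean`, `cov_sd`, `n_discordant`,
#'   `start`, `end`.
#' @param config a [caller_config()].
#' @return `calls` with `passed` (logical) and `fail_reasons` (comma-joined
#'   filter names, empty when passed).
#' @export
apply_circle_filters <- function(calls, config = caller_config()) {
  len <- calls$end - calls$start
  fails <- list(
    split_reads = calls$n_split < config$min_split,
    circle_score = calls$circle_score < config$min_score,
    cov_increase_start = calls$cov_inc_start < config$min_cov_increase,
    cov_increase_end = calls$cov_inc_end < config$min_cov_increase,
    continuity = calls$continuity > config$max_continuity,
    sd_lt_mean = if (config$require_sd_lt_mean) {
      !(calls$cov_sd < calls$cov_mean)
    } else rep(FALSE, nrow(calls)),
    long_no_discordant = len >= config$long_circle_bp & calls$n_discordant < 1
  )
  reasons <- vapply(seq_len(nrow(calls)), function(i) {
    paste(names(fails)[vapply(fails, `[`, logical(1), i)], collapse = ",")
  }, character(1))
  calls %>% mutate(passed = reasons == "", fail_reasons = reasons)
}

#' Call eccDNA from a coordinate-sorted alignment file
#'
#' End-to-end composition: candidate extraction, quality-aware soft-clip
#' realignment, junction clustering and scoring, coverage annotation and
#' the filter suite. Among overlapping passed calls the higher circle
#' score (then the shorter interval) is kept. The result is deterministic
#' for a given input and configuration.
#'
#' @param path coordinate-sorted SAM or BAM.
#' @param genome reference as a DNAStringSet or FASTA path.
#' @param config a [caller_config()].
#' @param keep_all keep filtered calls (with `fail_reasons`) in the result.
#' @return a `circle_calls` object: list with `calls` (tibble), `qc`
#'   (candidate/filter counts) and `config`.
#' @examples
#' \donttest{
#' cfg <- sim_config(genome_length = 2e5, n_circles = 10, seed = 7)
#' ref <- build_synthetic_genome(cfg)
#' truth <- plant_circles(ref, cfg)
#' sim <- simulate_short_reads(truth, ref, cfg)
#' res <- call_circles(sim$sam, ref$genome)
#' evaluate_calls(res$calls[res$calls$passed, ], sim$truth)$summary
#' }
#' @export
call_circles <- function(path, genome, config = caller_config(),
                         keep_all = FALSE) {
  genome <- as_genome(genome)
  sizes <- chrom_sizes(genome)
  ra <- read_alignments(path)
  cands <- extract_candidates(ra$aln, config)
  chrom_str <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(chrom_str) <- names(genome)
  junctions <- realign_candidates(cands$split, chrom_str, sizes, config)
  raw <- score_and_merge(junctions, cands$discordant, config)
  if (nrow(raw) > 0) {
    cov <- bam_coverage(ra$bam)
    ann <- coverage_filters(raw, cov, config)
  } else {
    ann <- raw %>% mutate(cov_inc_start = numeric(0), cov_inc_end = numeric(0),
                          continuity = numeric(0), cov_mean = numeric(0),
                          cov_sd = numeric(0), passed = logical(0),
                          fail_reasons = character(0))
  }
  ann <- dedupe_overlapping(ann)
  calls <- ann %>%
    mutate(name = sprintf("ecc_%05d", row_number()), length = .data$end - .data$start) %>%
    select("chrom", "start", "end", "name", "circle_score", "n_split",
           "n_discordant", "cov_inc_start", "cov_inc_end", "continuity",
           "cov_mean", "cov_sd", "length", "passed", "fail_reasons")
  qc <- list(n_alignments = nrow(ra$aln),
             n_split_candidates = nrow(cands$split),
             n_discordant_candidates = nrow(cands$discordant),
             n_no_mate = cands$n_no_mate,
             n_junction_reads = nrow(junctions),
             n_raw_calls = nrow(raw),
             n_passed = sum(calls$passed),
             fail_counts = fail_reason_counts(calls))
  if (!keep_all) calls <- calls %>% filter(.data$passed)
  structure(list(calls = calls, qc = qc, config = config),
            class = "circle_calls")
}

fail_reason_counts <- function(calls) {
  rs <- unlist(strsplit(calls$fail_reasons[!calls$passed], ","))
  if (length(rs) == 0) return(integer(0))
  table(rs)
}

# overlapping passed calls: keep higher score, then shorter interval
dedupe_overlapping <- function(calls) {
  if (nrow(calls) < 2) return(calls)
  p <- calls %>% filter(.data$passed) %>%
    arrange(dplyr::desc(.data$circle_score), .data$end - .data$start)
  if (nrow(p) < 2) return(calls)
  keep <- rep(TRUE, nrow(p))
  gr <- as_granges0(p)
  for (i in seq_len(nrow(p))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    if (length(prior) == 0) next
    ov <- IRanges::findOverlaps(gr[i], gr[prior])
    if (length(ov) > 0) keep[i] <- FALSE
  }
  drop_keys <- paste(p$chrom, p$start, p$end)[!keep]
  calls %>% filter(!(.data$passed &
                       paste(.data$chrom, .data$start, .data$end) %in% drop_keys))
}

#' @export
print.circle_calls <- function(x, ...) {
  cat("<circle_calls> ", sum(x$calls$passed), " passed / ",
      nrow(x$calls), " reported calls\n", sep = "")
  print(head(x$calls, 10))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname call_circles
#' @param x a `circle_calls` object.
#' @param ... unused.
#' @method glance circle_calls
#' @export
glance.circle_calls <- function(x, ...) {
  tibble(n_alignments = x$qc$n_alignments,
         n_split_candidates = x$qc$n_split_candidates,
         n_discordant_candidates = x$qc$n_discordant_candidates,
         n_raw_calls = x$qc$n_raw_calls,
         n_passed = x$qc$n_passed)
}

#' Compare calls against truth intervals
#'
#' Greedy one-to-one matching by overlap: a call may match a truth circle
#' if both breakpoints agree within `bp_tol` or the reciprocal overlap is
#' at least `min_reciprocal`; candidate pairs are taken in order of
#' decreasing reciprocal overlap. Capture rate is matched truth over all
#' truth; precision is matched calls over all calls.
#'
#' @param calls call tibble (or `circle_calls` object; passed calls used).
#' @param truth truth interval tibble.
#' @param bp_tol per-breakpoint tolerance (bp).
#' @param min_reciprocal reciprocal-overlap alternative criterion.
#' @return list with `summary` (one-row tibble: `capture_rate`,
#'   `precision`, `n_truth`, `n_calls`, `n_matched`, `mean_bp_error`,
#'   `max_bp_error`) and `matches` (per-match breakpoint errors).
#' @export
evaluate_calls <- function(calls, truth, bp_tol = 10, min_reciprocal = 0.95) {
  if (inherits(calls, "circle_calls")) {
    calls <- calls$calls %>% filter(.data$passed)
  }
  empty_summary <- function(nc, nt) {
    tibble(capture_rate = ifelse(nt > 0, 0, NA_real_),
           precision = ifelse(nc > 0, 0, NA_real_),
           n_truth = nt, n_calls = nc, n_matched = 0L,
           mean_bp_error = NA_real_, max_bp_error = NA_real_)
  }
  if (nrow(calls) == 0 || nrow(truth) == 0) {
    return(list(summary = empty_summary(nrow(calls), nrow(truth)),
                matches = tibble()))
  }
  gc_ <- as_granges0(calls)
  gt <- as_granges0(truth)
  ov <- IRanges::findOverlaps(gc_, gt, ignore.strand = TRUE)
  if (length(ov) == 0) {
    return(list(summary = empty_summary(nrow(calls), nrow(truth)),
                matches = tibble()))
  }
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- IRanges::width(IRanges::pintersect(IRanges::ranges(gc_)[qi],
                                              IRanges::ranges(gt)[si]))
  recip <- pmin(inter / (calls$end[qi] - calls$start[qi]),
                inter / (truth$end[si] - truth$start[si]))
  d_start <- abs(calls$start[qi] - truth$start[si])
  d_end <- abs(calls$end[qi] - truth$end[si])
  eligible <- (d_start <= bp_tol & d_end <= bp_tol) | recip >= min_reciprocal
  ord <- order(-recip)
  used_c <- logical(nrow(calls)); used_t <- logical(nrow(truth))
  mrows <- list()
  for (k in ord) {
    if (!eligible[k]) next
    if (used_c[qi[k]] || used_t[si[k]]) next
    used_c[qi[k]] <- TRUE; used_t[si[k]] <- TRUE
    mrows[[length(mrows) + 1]] <- tibble(
      call_idx = qi[k], truth_idx = si[k],
      d_start = d_start[k], d_end = d_end[k], reciprocal = recip[k])
  }
  matches <- bind_rows(mrows)
  nm <- nrow(matches)
  list(summary = tibble(
    capture_rate = nm / nrow(truth),
    precision = nm / nrow(calls),
    n_truth = nrow(truth), n_calls = nrow(calls), n_matched = nm,
    mean_bp_error = if (nm) mean(c(matches$d_start, matches$d_end)) else NA_real_,
    max_bp_error = if (nm) max(c(matches$d_start, matches$d_end)) else NA_real_),
    matches = matches)
}
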