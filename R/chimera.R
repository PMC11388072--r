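#' Collapse PAF fragments of one read into alignment units
#'
#' Consecutive fragments (in query order) that continue each other on the
#' reference — same chromosome and strand, collinear, with both the
#' reference gap and the query gap within `tol` — are merged into one
#' unit, undoing spurious alignment breaks. Units keep query order.
#'
#' @param frags PAF tibble of one read ([read_paf_fragments()] rows).
#' @param tol merge tolerance (bp).
#' @return unit tibble: `chrom`, `start`, `end`, `strand`, `query_start`,
#'   `query_end`.
#' @export
collapse_fragments <- function(frags, tol = 20) {
  frags <- frags %>% arrange(.data$query_start)
  n <- nrow(frags)
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), query_start = integer(),
                  query_end = integer()))
  }
  grp <- 1L
  gid <- integer(n)
  gid[1] <- grp
  for (i in seq_len(n - 1)) {
    a <- frags[i, ]; b <- frags[i + 1, ]
    q_adj <- abs(b$query_start - a$query_end) <= tol
    same <- b$chrom == a$chrom && b$strand == a$strand
    r_adj <- if (!same) FALSE else if (a$strand == "+") {
      abs(b$start - a$end) <= tol
    } else {
      abs(a$start - b$end) <= tol
    }
    if (!(same && q_adj && r_adj)) grp <- grp + 1L
    gid[i + 1] <- grp
  }
  frags %>%
    mutate(.g = gid) %>%
    group_by(.data$.g) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              query_start = min(.data$query_start),
              query_end = max(.data$query_end), .groups = "drop") %>%
    arrange(.data$query_start) %>% select(-".g")
}

# integer locus keys: first matching earlier unit within tolerance
unit_keys <- function(units, tol) {
  n <- nrow(units)
  keys <- integer(n)
  nk <- 0L
  for (i in seq_len(n)) {
    hit <- 0L
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        if (units$chrom[j] == units$chrom[i] &&
            units$strand[j] == units$strand[i] &&
            abs(units$start[j] - units$start[i]) <= tol &&
            abs(units$end[j] - units$end[i]) <= tol) {
          hit <- keys[j]; break
        }
      }
    }
    if (hit == 0L) { nk <- nk + 1L; hit <- nk }
    keys[i] <- hit
  }
  keys
}

#' Detect the tandem period of a unit sequence
#'
#' Finds the smallest period `p` such that the read's locus-key sequence
#' is a tandem repetition of a length-`p` cycle. The first and last unit
#' of a read are usually truncated traversals of a fragment; they are
#' folded onto a matching complete unit by one-sided coordinate matching
#' (the leading unit as a suffix, the trailing unit as a prefix) and
#' excluded from the consensus coordinates. The pass count is the total
#' aligned query length over the period length — the number of times the
#' read covers the entire circularized region — and reads with fewer than
#' 2 passes are rejected. The period is returned in canonical rotation
#' and orientation (the representation whose fragment signature is
#' lexicographically smallest, comparing the forward traversal and its
#' reverse-complement), with consensus fragment coordinates taken as the
#' median over the complete occurrences.
#'
#' @param units unit tibble from [collapse_fragments()].
#' @param tol locus-key tolerance (bp).
#' @return `NULL` (reject), or list with `period` (fragment tibble),
#'   `n_passes` and `circle_length`.
#' @export
detect_period <- function(units, tol = 20) {
  n <- nrow(units)
  if (n < 2) return(NULL)
  keys <- unit_keys(units, tol)
  partial <- rep(FALSE, n)
  # fold a truncated leading unit (suffix of a later complete unit)
  if (sum(keys == keys[1]) == 1) {
    for (j in 2:n) {
      if (units$chrom[j] == units$chrom[1] &&
          units$strand[j] == units$strand[1] &&
          end_matches_suffix(units[1, ], units[j, ], tol)) {
        keys[1] <- keys[j]; partial[1] <- TRUE; break
      }
    }
  }
  # fold a truncated trailing unit (prefix of an earlier complete unit)
  if (sum(keys == keys[n]) == 1) {
    for (j in seq_len(n - 1)) {
      if (units$chrom[j] == units$chrom[n] &&
          units$strand[j] == units$strand[n] &&
          end_matches_prefix(units[n, ], units[j, ], tol)) {
        keys[n] <- keys[j]; partial[n] <- TRUE; break
      }
    }
  }
  p <- smallest_period(keys)
  # a read's terminal units may be mildly truncated (within tolerance of a
  # complete traversal): keep them for periodicity but not for coordinates
  exclude <- partial
  for (i in unique(c(1L, n))) {
    if (sum(keys == keys[i]) > 1) exclude[i] <- TRUE
  }
  period <- purrr::map_dfr(seq_len(p), function(j) {
    kj <- keys[j]
    occ <- units[keys == kj & !exclude, , drop = FALSE]
    if (nrow(occ) == 0) occ <- units[keys == kj & !partial, , drop = FALSE]
    if (nrow(occ) == 0) return(tibble())  # key seen only as partials
    tibble(chrom = occ$chrom[1],
           start = as.integer(round(median(occ$start))),
           end = as.integer(round(median(occ$end))),
           strand = occ$strand[1])
  })
  if (nrow(period) < p) return(NULL)
  circle_length <- sum(period$end - period$start)
  if (circle_length <= 0) return(NULL)
  total <- sum(units$query_end - units$query_start)
  n_passes <- total %/% circle_length
  if (n_passes < 2) return(NULL)
  period <- canonical_period(period)
  list(period = period, n_passes = as.integer(n_passes),
       circle_length = circle_length)
}

# truncation matches: `a` ends where `b` ends but starts inside it (suffix
# for forward strand); the orientation flips the roles for minus strand
end_matches_suffix <- function(a, b, tol) {
  if (a$strand == "+") {
    abs(a$end - b$end) <= tol && a$start >= b$start - tol
  } else {
    abs(a$start - b$start) <= tol && a$end <= b$end + tol
  }
}

end_matches_prefix <- function(a, b, tol) {
  if (a$strand == "+") {
    abs(a$start - b$start) <= tol && a$end <= b$end + tol
  } else {
    abs(a$end - b$end) <= tol && a$start >= b$start - tol
  }
}

# smallest p with s[i] == s[i + p] for all valid i (p = length(s) if none)
smallest_period <- function(s) {
  m <- length(s)
  for (p in seq_len(m - 1)) {
    if (all(s[seq_len(m - p)] == s[seq_len(m - p) + p])) return(p)
  }
  m
}

# canonical rotation/orientation: lexicographically smallest signature among
# all rotations of the forward period and of its reverse-complement
canonical_period <- function(period) {
  p <- nrow(period)
  flip <- function(x) {
    x %>% mutate(strand = if_else(.data$strand == "+", "-", "+")) %>%
      slice(rev(seq_len(p)))
  }
  candidates <- list()
  for (orient in list(period, flip(period))) {
    for (r in seq_len(p)) {
      rot <- orient[c(seq(r, p), if (r > 1) seq(1, r - 1)), ]
      candidates[[length(candidates) + 1]] <- rot
    }
  }
  sigs <- vapply(candidates, period_signature, character(1))
  # radix = bytewise comparison, independent of the session locale
  candidates[[order(sigs, method = "radix")[1]]]
}

period_signature <- function(period) {
  paste(sprintf("%s:%d-%d:%s", period$chrom, period$start, period$end,
                period$strand), collapse = ";")
}

#' Merge per-read compositions into a circle set
#'
#' Compositions identical up to rotation and orientation (all fragments
#' matching within `tol`) are merged: supporting reads accumulate,
#' consensus fragment intervals are the median of the supporting
#' endpoints, and the reported pass count is the maximum over supporting
#' reads. A circle supported by exactly one read is a single-event
#' circle; one whose period holds at least two distinct loci is chimeric.
#'
#' @param comps list of per-read results from [detect_period()] (each with
#'   a `read_id` added).
#' @param tol fragment matching tolerance (bp).
#' @return composition tibble: `circle_id`, `n_fragments`, `fragments`
#'   (list-column), `circle_length`, `n_passes`, `n_reads`,
#'   `supporting_reads`, `is_chimeric`, `is_single_event`.
#' @export
merge_compositions <- function(comps, tol = 20) {
  comps <- purrr::compact(comps)
  if (length(comps) == 0) {
    return(tibble(circle_id = character(), n_fragments = integer(),
                  fragments = list(), circle_length = integer(),
                  n_passes = integer(), n_reads = integer(),
                  supporting_reads = list(), is_chimeric = logical(),
                  is_single_event = logical()))
  }
  groups <- list()  # each: list(periods = list, passes, reads)
  for (cp in comps) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (periods_match(groups[[k]]$rep, cp$period, tol)) {
        groups[[k]]$periods <- c(groups[[k]]$periods, list(cp$period))
        groups[[k]]$passes <- max(groups[[k]]$passes, cp$n_passes)
        groups[[k]]$reads <- c(groups[[k]]$reads, cp$read_id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1]] <- list(rep = cp$period,
                                           periods = list(cp$period),
                                           passes = cp$n_passes,
                                           reads = cp$read_id)
    }
  }
  purrr::map_dfr(seq_along(groups), function(k) {
    g <- groups[[k]]
    cons <- g$rep
    if (length(g$periods) > 1) {
      for (j in seq_len(nrow(cons))) {
        cons$start[j] <- as.integer(round(median(
          vapply(g$periods, function(pp) pp$start[j], numeric(1)))))
        cons$end[j] <- as.integer(round(median(
          vapply(g$periods, function(pp) pp$end[j], numeric(1)))))
      }
    }
    loci <- distinct(cons, .data$chrom, .data$start, .data$end, .data$strand)
    tibble(circle_id = sprintf("rca_circle_%04d", k),
           n_fragments = nrow(cons),
           fragments = list(cons),
           circle_length = sum(cons$end - cons$start),
           n_passes = g$passes,
           n_reads = length(g$reads),
           supporting_reads = list(g$reads),
           is_chimeric = nrow(loci) >= 2,
           is_single_event = length(g$reads) == 1)
  })
}

# identical up to rotation/orientation within tolerance
periods_match <- function(a, b, tol) {
  p <- nrow(a)
  if (nrow(b) != p) return(FALSE)
  flip <- function(x) {
    x %>% mutate(strand = if_else(.data$strand == "+", "-", "+")) %>%
      slice(rev(seq_len(p)))
  }
  for (orient in list(b, flip(b))) {
    for (r in seq_len(p)) {
      rot <- orient[c(seq(r, p), if (r > 1) seq(1, r - 1)), ]
      if (all(rot$chrom == a$chrom) && all(rot$strand == a$strand) &&
          all(abs(rot$start - a$start) <= tol) &&
          all(abs(rot$end - a$end) <= tol)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Reconstruct eccDNA from rolling-circle long-read alignments
#'
#' End-to-end: PAF fragments are grouped per read, collapsed into units,
#' period-checked (reads without at least two complete passes are
#' rejected) and merged into a non-redundant circle set with support
#' counts and chimeric / single-event summary statistics.
#'
#' @param paf PAF path or tibble from [read_paf_fragments()].
#' @param tol locus/fragment tolerance (bp).
#' @return list with `circles` (composition tibble), `summary` (one-row
#'   tibble: read, rejection and circle counts, chimeric and single-event
#'   fractions, mean circle length) and `rejected_reads`.
#' @export
reconstruct_circles <- function(paf, tol = 20) {
  frags <- if (is.character(paf)) read_paf_fragments(paf) else paf
  by_read <- split(frags, factor(frags$read_id, unique(frags$read_id)))
  comps <- list()
  rejected <- character(0)
  for (rid in names(by_read)) {
    units <- collapse_fragments(by_read[[rid]], tol)
    det <- detect_period(units, tol)
    if (is.null(det)) {
      rejected <- c(rejected, rid)
    } else {
      det$read_id <- rid
      comps[[length(comps) + 1]] <- det
    }
  }
  circles <- merge_compositions(comps, tol)
  summary <- tibble(
    n_reads = length(by_read),
    n_rejected = length(rejected),
    n_circles = nrow(circles),
    chimeric_fraction = if (nrow(circles)) mean(circles$is_chimeric) else NA_real_,
    single_event_fraction = if (nrow(circles)) mean(circles$is_single_event) else NA_real_,
    mean_circle_length = if (nrow(circles)) mean(circles$circle_length) else NA_real_)
  list(circles = circles, summary = summary, rejected_reads = rejected)
}

#' Write reconstructed circles as TSV (and optionally BED)
#'
#' @param circles composition tibble from [reconstruct_circles()].
#' @param path output TSV path.
#' @param bed optional BED path (one line per fragment).
#' @export
write_compositions <- function(circles, path, bed = NULL) {
  flat <- circles %>%
    mutate(fragment_list = vapply(.data$fragments, period_signature,
                                  character(1))) %>%
    select("circle_id", "n_fragments", "fragment_list", "circle_length",
           "n_passes", "n_reads", "is_chimeric", "is_single_event")
  readr::write_tsv(flat, path)
  if (!is.null(bed)) {
    frag <- purrr::map_dfr(seq_len(nrow(circles)), function(i) {
      circles$fragments[[i]] %>% mutate(name = circles$circle_id[i], score = 0L)
    }) %>% select("chrom", "start", "end", "name", "score", "strand")
    write_bed(frag, bed)
  }
  invisible(path)
}
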