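#' Detect kataegis (clustered hypermutation) from an SNV list
#'
#' A window of 6 consecutive SNVs on one chromosome qualifies when the
#' mean of its 5 inter-mutation gaps is at most `max_imd` (1000 bp);
#' overlapping qualifying windows are merged into one maximal event.
#' Events report 1-based first/last positions, member count, and the mean
#' inter-mutation distance over the merged span,
#' `(last - first) / (n - 1)`.
#'
#' @param snvs tibble with `chrom` and `pos` (0-based), sorted by
#'   chromosome and position (an error otherwise); duplicated positions
#'   are collapsed.
#' @param min_snvs window size (>= 6 SNVs).
#' @param max_imd inclusive mean inter-mutation distance cutoff (bp).
#' @return tibble of events: `event_id`, `chrom`, `first_pos`, `last_pos`
#'   (1-based), `n_snvs`, `mean_imd`, and a `members` list-column of the
#'   member SNV rows.
#' @examples
#' snv <- tibble::tibble(chrom = "chr1", pos = cumsum(rep(200, 6)))
#' detect_kataegis(snv)
#' @export
detect_kataegis <- function(snvs, min_snvs = 6L, max_imd = 1000) {
  if (nrow(snvs) == 0) return(empty_events())
  ord <- order(snvs$chrom, snvs$pos)
  if (!identical(ord, seq_len(nrow(snvs)))) {
    abort("SNVs must be sorted by (chrom, pos)")
  }
  snvs <- snvs %>% distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  events <- list()
  for (ch in unique(snvs$chrom)) {
    sub <- snvs %>% filter(.data$chrom == ch)
    n <- nrow(sub)
    if (n < min_snvs) next
    gaps <- diff(sub$pos)
    w <- min_snvs - 1L
    # mean gap of each window of w consecutive gaps
    win_mean <- (cumsum(gaps)[w:length(gaps)] -
                   c(0, cumsum(gaps))[1:(length(gaps) - w + 1)]) / w
    qual <- which(win_mean <= max_imd)  # window i covers SNVs i..i+w
    if (length(qual) == 0) next
    # merge windows sharing at least one SNV
    runs <- split(qual, cumsum(c(TRUE, diff(qual) > w)))
    for (r in runs) {
      a <- min(r); b <- max(r) + w
      events[[length(events) + 1]] <- tibble(
        chrom = ch,
        first_pos = sub$pos[a] + 1L,
        last_pos = sub$pos[b] + 1L,
        n_snvs = b - a + 1L,
        mean_imd = (sub$pos[b] - sub$pos[a]) / (b - a),
        members = list(sub[a:b, ]))
    }
  }
  if (length(events) == 0) return(empty_events())
  bind_rows(events) %>%
    arrange(.data$chrom, .data$first_pos) %>%
    mutate(event_id = sprintf("kat_%03d", row_number()), .before = 1)
}

empty_events <- function() {
  tibble(event_id = character(), chrom = character(), first_pos = integer(),
         last_pos = integer(), n_snvs = integer(), mean_imd = numeric(),
         members = list())
}

#' Classify SNVs into the 96 trinucleotide substitution types
#'
#' Pyrimidine-centered convention: when the reference base is A or G, the
#' mutation and its flanking context are complemented, leaving six base
#' substitutions (C>A, C>G, C>T, T>A, T>C, T>G) in 16 contexts each.
#' SNVs at the first or last base of a chromosome (no flanking context)
#' are dropped with a warning.
#'
#' @param snvs tibble with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param genome DNAStringSet or FASTA path; an error lists SNVs whose
#'   `ref` disagrees with the reference sequence.
#' @return tibble of all 96 bins (`context` like `"A[C>T]G"`,
#'   `substitution`, `count`), counts summing to the classified SNV count.
#' @export
classify_96 <- function(snvs, genome) {
  genome <- as_genome(genome)
  si <- setNames(Biostrings::width(genome), names(genome))
  edge <- snvs$pos < 1 | snvs$pos > si[snvs$chrom] - 2
  if (any(edge)) {
    warn(paste0("dropped ", sum(edge), " SNV(s) at chromosome edges"))
    snvs <- snvs[!edge, ]
  }
  ctx <- vapply(seq_len(nrow(snvs)), function(i) {
    as.character(Biostrings::subseq(genome[[snvs$chrom[i]]],
                                    snvs$pos[i], snvs$pos[i] + 2L))
  }, character(1))
  refg <- substr(ctx, 2, 2)
  bad <- refg != snvs$ref
  if (any(bad)) {
    abort(paste0("reference mismatch at ",
                 paste(paste0(snvs$chrom[bad], ":", snvs$pos[bad] + 1)[
                   seq_len(min(5, sum(bad)))], collapse = ", ")))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- snvs$ref %in% c("A", "G")
  rc <- function(s) {
    vapply(strsplit(s, ""), function(ch) {
      paste(rev(unname(comp[ch])), collapse = "")
    }, character(1))
  }
  ctx[flip] <- rc(ctx[flip])
  ref2 <- ifelse(flip, comp[snvs$ref], snvs$ref)
  alt2 <- ifelse(flip, comp[snvs$alt], snvs$alt)
  key <- paste0(substr(ctx, 1, 1), "[", ref2, ">", alt2, "]", substr(ctx, 3, 3))
  bins <- spectrum_bins()
  counts <- table(factor(key, levels = bins$context))
  bins$count <- as.integer(counts)
  bins
}

#' @rdname classify_96
#' @export
spectrum_bins <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(three = bases, sub = subs, five = bases,
                      stringsAsFactors = FALSE)[, 3:1]
  grid <- grid[order(match(grid$sub, subs), grid$five, grid$three), ]
  tibble(context = paste0(grid$five, "[", grid$sub, "]", grid$three),
         substitution = grid$sub)
}

#' Label kataegis events as kyklonas against ecDNA intervals
#'
#' An event is `on_ecdna` when any member SNV lies inside an ecDNA
#' interval; otherwise `near_ecdna_10kb` when the smallest distance from
#' any member SNV to any interval endpoint is at most 10 kb; otherwise
#' `none`. `min_breakpoint_distance` reports that smallest distance
#' (`NA` when no breakpoint shares a chromosome with the event).
#'
#' @param events event tibble from [detect_kataegis()].
#' @param ecdna ecDNA interval tibble (may be empty).
#' @param near_bp inclusive distance cutoff (bp).
#' @return `events` with `kyklonas_status` and `min_breakpoint_distance`.
#' @export
classify_kyklonas <- function(events, ecdna, near_bp = 10000) {
  if (nrow(events) == 0) {
    return(events %>% mutate(kyklonas_status = character(0),
                             min_breakpoint_distance = numeric(0)))
  }
  status <- character(nrow(events))
  mind <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    mem <- events$members[[i]]
    iv <- if (nrow(ecdna)) ecdna[ecdna$chrom == events$chrom[i], , drop = FALSE] else ecdna
    if (nrow(iv) == 0) { status[i] <- "none"; next }
    inside <- any(vapply(mem$pos, function(p) {
      any(p >= iv$start & p < iv$end)
    }, logical(1)))
    bp <- c(iv$start, iv$end)
    mind[i] <- min(vapply(mem$pos, function(p) min(abs(p - bp)), numeric(1)))
    status[i] <- if (inside) "on_ecdna" else if (mind[i] <= near_bp) {
      "near_ecdna_10kb"
    } else "none"
  }
  events %>% mutate(kyklonas_status = status, min_breakpoint_distance = mind)
}

#' Distance from mutations to the nearest interval breakpoint
#'
#' Breakpoints are all interval endpoints; the distance is to the nearest
#' breakpoint on the same chromosome (`NA` when the chromosome has none).
#'
#' @param mutations tibble with `chrom`, `pos` (0-based).
#' @param intervals interval tibble whose endpoints are the breakpoints.
#' @return `mutations` with a `distance` column.
#' @export
distance_to_breakpoints <- function(mutations, intervals) {
  bp_by <- split(c(intervals$start, intervals$end),
                 rep(intervals$chrom, 2))
  mutations$distance <- vapply(seq_len(nrow(mutations)), function(i) {
    bp <- bp_by[[mutations$chrom[i]]]
    if (is.null(bp)) return(NA_real_)
    min(abs(mutations$pos[i] - bp))
  }, numeric(1))
  mutations
}

#' Group kataegis events by member VAF
#'
#' Utility for VAF-stratified views of kyklonas: adds each event's median
#' member VAF and a high/low grouping at `cut`.
#'
#' @param events event tibble (members need a `vaf` column).
#' @param cut VAF threshold.
#' @return `events` with `median_vaf` and `vaf_group`.
#' @export
vaf_stratify <- function(events, cut = 0.25) {
  events %>%
    mutate(median_vaf = vapply(.data$members, function(m) {
      if (!"vaf" %in% names(m)) NA_real_ else median(m$vaf, na.rm = TRUE)
    }, numeric(1)),
    vaf_group = if_else(.data$median_vaf >= cut, "high", "low"))
}
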