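#' Write alignment records as a coordinate-sorted SAM file
#'
#' Emits a minimal, valid SAM (used by the simulator's "perfect SAM"
#' output): `@HD`/`@SQ` header followed by one line per record, sorted by
#' reference and position. Coordinates in the input tibble are 0-based and
#' converted to SAM's 1-based convention on write.
#'
#' @param aln tibble with columns `read_id`, `flag`, `chrom`, `pos`
#'   (0-based), `mapq`, `cigar`, `mate_chrom`, `mate_pos` (0-based), `seq`,
#'   `qual`.
#' @param sizes chromosome sizes tibble ([chrom_sizes()]).
#' @param path output `.sam` path.
#' @export
write_sam <- function(aln, sizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", sizes$chrom, "\tLN:", sizes$size))
  aln <- aln %>% arrange(match(.data$chrom, sizes$chrom), .data$pos)
  rnext <- ifelse(is.na(aln$mate_chrom), "*",
                  ifelse(aln$mate_chrom == aln$chrom, "=", aln$mate_chrom))
  pnext <- ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos + 1L)
  body <- paste(aln$read_id, aln$flag, aln$chrom, aln$pos + 1L, aln$mapq,
                aln$cigar, rnext, pnext, 0L, aln$seq, aln$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Prepare a BAM file from a SAM or BAM path
#'
#' SAM input is converted, coordinate-sorted and indexed via Rsamtools;
#' BAM input is indexed if needed. Returns the BAM path.
#'
#' @param path `.sam` or `.bam` file.
#' @return path to an indexed, coordinate-sorted BAM.
#' @export
prepare_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai"))) Rsamtools::indexBam(bam)
  }
  bam
}

#' Read primary alignments into a tibble
#'
#' Loads primary, mapped, non-duplicate records from a coordinate-sorted
#' BAM (or SAM, converted on the fly) with the fields the circle caller
#' needs. Positions are 0-based on return; `end` is the 0-based-exclusive
#' reference end computed from the CIGAR.
#'
#' @param path SAM/BAM path.
#' @param region optional interval tibble restricting the fetch.
#' @return list with `aln` (tibble) and `bam` (indexed BAM path).
#' @export
read_alignments <- function(path, region = NULL) {
  bam <- prepare_bam(path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "seq", "qual")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(flag = flag, what = what)
  } else {
    Rsamtools::ScanBamParam(flag = flag, what = what,
                            which = as_granges0(region))
  }
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  fl <- res$flag
  aln <- tibble(
    read_id = res$qname,
    flag = fl,
    chrom = as.character(res$rname),
    pos = res$pos - 1L,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    is_paired = bitwAnd(fl, 1L) > 0,
    is_read1 = bitwAnd(fl, 64L) > 0,
    is_reverse = bitwAnd(fl, 16L) > 0,
    mate_is_reverse = bitwAnd(fl, 32L) > 0,
    mate_unmapped = bitwAnd(fl, 8L) > 0,
    mate_chrom = as.character(res$mrnm),
    mate_pos = res$mpos - 1L
  )
  ref_len <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  aln$end <- aln$pos + ref_len
  list(aln = aln, bam = bam)
}

#' Per-base coverage of a BAM file
#'
#' @param bam indexed BAM path.
#' @return an [IRanges::RleList] of per-chromosome coverage.
#' @keywords internal
bam_coverage <- function(bam) {
  ga <- GenomicAlignments::readGAlignments(
    bam,
    param = Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE)))
  GenomicAlignments::coverage(ga)
}

#' Write paired reads as a FASTQ pair
#'
#' @param reads tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (read-as-sequenced orientation).
#' @param path1,path2 output FASTQ paths for mate 1 and mate 2.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  w <- function(id, seq, qual, path) {
    writeLines(as.vector(rbind(paste0("@", id), seq, "+", qual)), path)
  }
  w(reads$read_id, reads$seq1, reads$qual1, path1)
  w(reads$read_id, reads$seq2, reads$qual2, path2)
  invisible(c(path1, path2))
}
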