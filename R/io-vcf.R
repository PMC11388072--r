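#' Read SNVs from a VCF file
#'
#' Only biallelic single-nucleotide records are returned; other records are
#' dropped with a message. Positions are converted from the 1-based VCF
#' convention to the package's 0-based internal convention on read (and
#' back on write). A `VAF=` INFO key, when present, populates `vaf`.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return tibble with `chrom`, `pos` (0-based), `ref`, `alt`, `vaf`.
#' @export
read_snvs <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fx) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), vaf = numeric()))
  }
  out <- tibble(
    chrom = fx$CHROM,
    pos = as.integer(fx$POS) - 1L,
    ref = fx$REF,
    alt = fx$ALT
  )
  out$vaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "VAF")))
  snv <- nchar(out$ref) == 1 & nchar(out$alt) == 1 &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  if (any(!snv)) inform(paste0("dropped ", sum(!snv), " non-SNV record(s)"))
  out[snv, ]
}

#' @rdname read_snvs
#' @param snvs tibble with `chrom`, `pos` (0-based), `ref`, `alt` and
#'   optionally `vaf`.
#' @param sample_id sample name written in the header.
#' @export
write_snv_vcf <- function(snvs, path, sample_id = "sample") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=circlekit"),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  )
  info <- if ("vaf" %in% names(snvs) && any(!is.na(snvs$vaf))) {
    ifelse(is.na(snvs$vaf), ".", paste0("VAF=", format(snvs$vaf, trim = TRUE, digits = 4)))
  } else rep(".", nrow(snvs))
  body <- paste(snvs$chrom, snvs$pos + 1L, ".", snvs$ref, snvs$alt, ".",
                "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
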