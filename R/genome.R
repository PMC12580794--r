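#' Reference chromosome lengths
#'
#' Approximate GRCh38 chromosome lengths in base pairs, used by the synthetic
#' cohort generator to lay out copy-number segments and variant positions.
#' These are layout coordinates only; no sequence is touched.
#'
#' @return Named integer-valued numeric vector, names `chr1`..`chr22`,
#'   `chrX`, `chrY`.
#' @export
chrom_lengths <- function() {
  c(chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
    chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415)
}

#' Normalize chromosome names to the "chr"-prefixed dialect
#'
#' @param chrom Character vector of chromosome names (`"1"`, `"chr1"`, `"X"`, ...).
#' @return Character vector with a `chr` prefix (`"chr1"`, `"chrX"`, ...).
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Germline copy number of a chromosome given sex
#'
#' Autosomes carry two germline copies. In males chrX and chrY carry one each;
#' in females chrX carries two and chrY zero.
#'
#' @param chrom Character vector of chromosome names.
#' @param sex `"male"` or `"female"`.
#' @return Integer vector of germline copy numbers.
#' @export
germline_cn <- function(chrom, sex) {
  sex <- match.arg(sex, c("male", "female"))
  chrom <- normalize_chrom(chrom)
  out <- rep(2L, length(chrom))
  if (sex == "male") {
    out[chrom %in% c("chrX", "chrY")] <- 1L
  } else {
    out[chrom == "chrY"] <- 0L
  }
  out
}

# GRanges from 1-based closed coordinates (the internal convention)
.as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end)
  )
}
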