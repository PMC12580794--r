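#' Length-weighted baseline copy number
#'
#' The absolute baseline copy number of a tumor (or of one chromosome) is the
#' weighted median of its segments' total copy numbers, weighted by segment
#' length, rounded half-up to an integer.
#'
#' @param total_cn Numeric vector of segment total copy numbers.
#' @param length Numeric vector of segment lengths (same order).
#' @return Integer baseline copy number.
#' @export
baseline_cn <- function(total_cn, length) {
  if (length(total_cn) == 0) stop("no segments: baseline CN undefined")
  if (length(total_cn) != length(length)) stop("total_cn and length differ in length")
  o <- order(total_cn)
  cn <- total_cn[o]
  w <- length[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1]
  med <- if (abs(cw[i] - half) < 1e-9 && i < length(cn)) (cn[i] + cn[i + 1]) / 2 else cn[i]
  as.integer(floor(med + 0.5))
}

#' Per-sample genome and chromosome baseline copy numbers
#'
#' @param segments Segment table (any number of samples).
#' @return list with `genome` (named vector, one per sample) and `chrom`
#'   (data.frame `sample_id`, `chrom`, `baseline`).
#' @export
baseline_table <- function(segments) {
  genome <- vapply(split(segments, segments$sample_id),
                   function(s) baseline_cn(s$total_cn, s$length), integer(1))
  by_sc <- split(segments, list(segments$sample_id, segments$chrom), drop = TRUE)
  chrom <- data.frame(
    sample_id = vapply(by_sc, function(s) s$sample_id[1], character(1)),
    chrom = vapply(by_sc, function(s) s$chrom[1], character(1)),
    baseline = vapply(by_sc, function(s) baseline_cn(s$total_cn, s$length),
                      integer(1)),
    stringsAsFactors = FALSE)
  rownames(chrom) <- NULL
  list(genome = genome, chrom = chrom)
}

#' Classify copy-number segments into event states
#'
#' Event definitions, relative to the sample's baseline copy numbers:
#' \itemize{
#'   \item gain: total CN above the genome baseline;
#'   \item amplification: total CN of at least 7 and more than twice the
#'     baseline of the segment's chromosome (reported in place of plain gain);
#'   \item deletion: total CN below the genome baseline;
#'   \item homozygous_deletion: total CN of 0;
#'   \item neutral: total CN equal to the genome baseline.
#' }
#' LOH (minor-allele copy number 0 with total CN >= 1: hemizygous loss,
#' copy-neutral LOH, or multiple copies of one allele) is tracked as a
#' separate boolean since it can co-occur with any of the above states.
#'
#' @param segments Segment table.
#' @return Segment table with added columns `baseline_cn`,
#'   `chrom_baseline_cn`, `event`, `gain`, `loss`, `amplification`, `loh`.
#' @export
classify_segments <- function(segments) {
  bl <- baseline_table(segments)
  segments$baseline_cn <- as.integer(bl$genome[segments$sample_id])
  key <- paste(segments$sample_id, segments$chrom)
  segments$chrom_baseline_cn <-
    bl$chrom$baseline[match(key, paste(bl$chrom$sample_id, bl$chrom$chrom))]
  cn <- segments$total_cn
  segments$gain <- cn > segments$baseline_cn
  segments$loss <- cn < segments$baseline_cn
  segments$amplification <- cn >= 7 & cn > 2 * segments$chrom_baseline_cn
  segments$loh <- segments$minor_cn == 0 & cn >= 1
  segments$event <- ifelse(cn == 0, "homozygous_deletion",
                    ifelse(segments$loss, "deletion",
                    ifelse(segments$amplification, "amplification",
                    ifelse(segments$gain, "gain", "neutral"))))
  segments
}

# merge runs of adjacent segments with identical total CN (used by LST)
.merge_equal_cn <- function(start, end, cn) {
  if (length(cn) == 0) return(data.frame(start = numeric(), end = numeric(),
                                         cn = numeric()))
  brk <- c(TRUE, cn[-1] != cn[-length(cn)])
  grp <- cumsum(brk)
  data.frame(start = tapply(start, grp, min),
             end = tapply(end, grp, max),
             cn = tapply(cn, grp, function(x) x[1]))
}

#' Chromosomal-instability summary per sample
#'
#' \itemize{
#'   \item `wgii`: unweighted mean over chromosomes of the fraction of the
#'     chromosome's covered length whose total CN differs from the sample's
#'     genome baseline;
#'   \item `pct_loh`: fraction of the covered genome with minor-allele CN 0
#'     (total CN >= 1);
#'   \item `lst`: large-scale state transitions -- after discarding segments
#'     shorter than `lst_smooth` and merging equal-CN neighbours, the number
#'     of adjacent copy-number breakpoints whose flanking segments are both at
#'     least `lst_flank` long;
#'   \item `wgd`: whole-genome duplication proxy, genome baseline CN >=
#'     `wgd_min_baseline`.
#' }
#'
#' @param segments Segment table.
#' @param lst_smooth Minimum segment length kept before counting transitions
#'   (default 3 Mb).
#' @param lst_flank Minimum flanking-segment length for a transition to count
#'   (default 10 Mb).
#' @param wgd_min_baseline Genome baseline CN at or above which a sample is
#'   called whole-genome duplicated (default 3).
#' @return data.frame `sample_id`, `baseline_cn`, `wgii`, `pct_loh`, `lst`,
#'   `wgd`.
#' @export
cin_summary <- function(segments, lst_smooth = 3e6, lst_flank = 1e7,
                        wgd_min_baseline = 3) {
  out <- lapply(split(segments, segments$sample_id), function(s) {
    base <- baseline_cn(s$total_cn, s$length)
    by_chr <- split(s, s$chrom)
    altered_frac <- vapply(by_chr, function(cs)
      sum(cs$length[cs$total_cn != base]) / sum(cs$length), numeric(1))
    loh_len <- sum(s$length[s$minor_cn == 0 & s$total_cn >= 1])
    lst <- sum(vapply(by_chr, function(cs) {
      cs <- cs[order(cs$start), ]
      keep <- cs$length >= lst_smooth
      m <- .merge_equal_cn(cs$start[keep], cs$end[keep], cs$total_cn[keep])
      if (nrow(m) < 2) return(0L)
      len <- m$end - m$start + 1
      sum(len[-nrow(m)] >= lst_flank & len[-1] >= lst_flank)
    }, integer(1)))
    data.frame(sample_id = s$sample_id[1], baseline_cn = base,
               wgii = mean(altered_frac),
               pct_loh = loh_len / sum(s$length),
               lst = lst, wgd = base >= wgd_min_baseline,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-patient truncality of copy-number events over regions
#'
#' For each patient and region (gene interval or recurrent locus), a
#' direction (gain or loss) is truncal when every sample of the patient has
#' at least one overlapping segment with that event, and heterogeneous when
#' some but not all do. Samples with no segment covering the region are
#' treated as having no event (and the call is flagged).
#'
#' @param cohort `patient_cohort`.
#' @param regions Gene-interval table (`gene`, `chrom`, `start`, `end`).
#' @return data.frame `patient_id`, `region`, `direction`, `n_samples`,
#'   `n_event`, `status` (`"truncal"`/`"heterogeneous"`), `uncovered`
#'   (number of samples without coverage of the region).
#' @export
classify_cnv_truncality <- function(cohort, regions) {
  seg <- classify_segments(cohort$segments)
  sg <- .as_granges(paste(seg$sample_id, seg$chrom), seg$start, seg$end)
  res <- list()
  for (p in unique(cohort$samples$patient_id)) {
    ids <- cohort$samples$sample_id[cohort$samples$patient_id == p]
    for (r in seq_len(nrow(regions))) {
      rg <- .as_granges(paste(ids, regions$chrom[r]),
                        rep(regions$start[r], length(ids)),
                        rep(regions$end[r], length(ids)))
      hits <- GenomicRanges::findOverlaps(rg, sg)
      cov_sample <- ids[S4Vectors::queryHits(hits)]
      seg_hit <- S4Vectors::subjectHits(hits)
      covered <- unique(cov_sample)
      for (dir in c("gain", "loss")) {
        has <- seg[[dir]][seg_hit]
        samp_event <- unique(cov_sample[has])
        n_event <- length(samp_event)
        if (n_event == 0) next
        status <- if (n_event == length(ids)) "truncal" else "heterogeneous"
        res[[length(res) + 1]] <- data.frame(
          patient_id = p, region = regions$gene[r], direction = dir,
          n_samples = length(ids), n_event = n_event, status = status,
          uncovered = length(ids) - length(covered),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(patient_id = character(), region = character(),
                      direction = character(), n_samples = integer(),
                      n_event = integer(), status = character(),
                      uncovered = integer(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Per-patient truncality of whole-genome duplication
#'
#' @param cin CIN summary table (from [cin_summary()]) with a `patient_id`
#'   column added, or a `patient_cohort` (summaries are computed).
#' @return data.frame `patient_id`, `status` in
#'   `c("none", "truncal", "heterogeneous")`.
#' @export
classify_wgd_truncality <- function(cin) {
  if (inherits(cin, "patient_cohort")) {
    tab <- cin_summary(cin$segments)
    tab$patient_id <- cin$samples$patient_id[match(tab$sample_id,
                                                   cin$samples$sample_id)]
    cin <- tab
  }
  out <- lapply(split(cin, cin$patient_id), function(x) {
    status <- if (!any(x$wgd)) "none" else if (all(x$wgd)) "truncal"
              else "heterogeneous"
    data.frame(patient_id = x$patient_id[1], status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
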