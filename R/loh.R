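#' @title LOH overlap analyses
#' @description Gene-level loss-of-heterozygosity calls, the cross-sample
#'   LOH overlap permutation test, and pairwise LOH overlap fractions.
#'   A segment is in LOH when its minor-allele copy number is 0 and its
#'   total copy number is at least 1 (hemizygous loss, copy-neutral LOH, or
#'   multiple copies of one allele).
#' @name clonemap-loh
NULL

.is_loh <- function(segments) segments$minor_cn == 0 & segments$total_cn >= 1

# overlap widths between gene intervals and one sample's segments
# (genes x segments matrix)
.gene_segment_overlap <- function(genes, seg) {
  gg <- .as_granges(genes$chrom, genes$start, genes$end)
  sg <- .as_granges(seg$chrom, seg$start, seg$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gg, sg))
  m <- matrix(0, nrow(genes), nrow(seg),
              dimnames = list(genes$gene, NULL))
  if (length(hits) > 0) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    w <- pmin(genes$end[q], seg$end[s]) - pmax(genes$start[q], seg$start[s]) + 1
    m[cbind(q, s)] <- w
  }
  m
}

#' Gene-level LOH call matrix
#'
#' A gene has LOH in a sample when at least `frac_threshold` of its span is
#' covered by LOH segments (default 50 percent). Genes on chromosomes with no
#' segment coverage in a sample are FALSE there.
#'
#' @param segments Segment table (one patient, several samples).
#' @param genes Gene-interval table.
#' @param frac_threshold Minimum covered fraction of the gene span
#'   (default 0.5).
#' @return Logical gene-by-sample matrix.
#' @export
gene_loh_matrix <- function(segments, genes, frac_threshold = 0.5) {
  samples <- sort(unique(segments$sample_id))
  out <- matrix(FALSE, nrow(genes), length(samples),
                dimnames = list(genes$gene, samples))
  glen <- genes$end - genes$start + 1
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    ov <- .gene_segment_overlap(genes, seg)
    out[, s] <- as.vector(ov %*% .is_loh(seg)) >= frac_threshold * glen
  }
  out
}

#' Permutation test for cross-sample LOH overlap at gene level
#'
#' Tests whether the number of genes in LOH simultaneously in all of a
#' patient's samples exceeds what random placement of LOH would produce. Per
#' replicate and per sample, LOH labels are shuffled uniformly over that
#' sample's segments after augmenting the label count by `augment` (rounded
#' up), and replicates in which any sample's realized LOH genome fraction
#' falls below that sample's observed fraction are discarded (the augmented
#' null is an upper bound on random LOH overlap). The statistic is the count
#' of genes with LOH in every sample; the empirical p-value uses the add-one
#' estimator `(1 + #draws >= observed) / (1 + retained)`, so it is never 0.
#'
#' @param segments Segment table (one patient, >= 2 samples; every sample
#'   must have at least one LOH and one non-LOH segment).
#' @param genes Gene-interval table.
#' @param reps Number of permutation replicates (default 1e6).
#' @param augment Fractional LOH-label augmentation (default 0.2).
#' @param seed Integer seed.
#' @param frac_threshold Gene-span LOH threshold (see [gene_loh_matrix()]).
#' @param chunk Replicates processed per vectorized block (memory knob).
#' @return Object of class `loh_test`: list with `observed_overlap`,
#'   `null_draws` (integer vector, retained replicates), `p_value`,
#'   `reps_retained`, `reps`.
#' @export
loh_overlap_test <- function(segments, genes, reps = 1e6, augment = 0.2,
                             seed = 1, frac_threshold = 0.5, chunk = 2e4) {
  samples <- sort(unique(segments$sample_id))
  if (length(samples) < 2) stop("need at least 2 samples")
  seg_by <- lapply(samples, function(s)
    segments[segments$sample_id == s, , drop = FALSE])
  names(seg_by) <- samples
  prep <- lapply(seg_by, function(seg) {
    loh <- .is_loh(seg)
    if (!any(loh) || all(loh))
      stop("each sample needs at least one LOH and one non-LOH segment")
    list(seg = seg, loh = loh, len = seg$length,
         frac = sum(seg$length[loh]) / sum(seg$length),
         n_aug = min(ceiling((1 + augment) * sum(loh)), nrow(seg)),
         ov = .gene_segment_overlap(genes, seg))
  })
  glen <- genes$end - genes$start + 1
  thr <- frac_threshold * glen
  obs_mat <- vapply(prep, function(p)
    as.vector(p$ov %*% p$loh) >= thr, logical(nrow(genes)))
  obs_mat <- matrix(obs_mat, nrow(genes))
  observed <- sum(rowSums(obs_mat) == length(samples))
  set.seed(seed)
  null_draws <- integer(0)
  done <- 0
  while (done < reps) {
    b <- min(chunk, reps - done)
    all_loh <- matrix(TRUE, nrow(genes), b)
    keep <- rep(TRUE, b)
    for (p in prep) {
      nseg <- nrow(p$seg)
      lab <- matrix(0L, nseg, b)
      picks <- vapply(seq_len(b), function(i) sample.int(nseg, p$n_aug),
                      integer(p$n_aug))
      lab[cbind(as.vector(picks), rep(seq_len(b), each = p$n_aug))] <- 1L
      frac <- as.vector(crossprod(p$len, lab)) / sum(p$len)
      keep <- keep & (frac >= p$frac - 1e-12)
      all_loh <- all_loh & ((p$ov %*% lab) >= thr)
    }
    null_draws <- c(null_draws, colSums(all_loh[, keep, drop = FALSE]))
    done <- done + b
  }
  retained <- length(null_draws)
  if (retained == 0)
    stop("no permutation replicates retained; increase `augment`")
  p_value <- (1 + sum(null_draws >= observed)) / (1 + retained)
  structure(list(observed_overlap = observed, null_draws = null_draws,
                 p_value = p_value, reps_retained = retained, reps = reps),
            class = "loh_test")
}

#' @export
print.loh_test <- function(x, ...) {
  cat("loh_test: observed overlap =", x$observed_overlap,
      "genes; p =", signif(x$p_value, 3),
      sprintf("(%d of %d replicates retained)\n", x$reps_retained, x$reps))
  invisible(x)
}

#' LOH overlap of one sample against the rest
#'
#' Base-pair definition: the fraction of sample A's LOH genome length that
#' lies inside the intersection of the other samples' LOH regions. When gene
#' intervals are supplied, a gene-level variant is also reported: the
#' fraction of A's LOH genes (per [gene_loh_matrix()]) that are in LOH in
#' every other sample.
#'
#' @param segments Segment table (one patient).
#' @param sample_a Sample id whose LOH footprint forms the denominator.
#' @param genes Optional gene-interval table for the gene-level variant.
#' @param frac_threshold Gene-span LOH threshold.
#' @return list with `bp` and (when `genes` is given) `gene`.
#' @export
pairwise_loh_overlap <- function(segments, sample_a, genes = NULL,
                                 frac_threshold = 0.5) {
  samples <- sort(unique(segments$sample_id))
  if (!sample_a %in% samples) stop("unknown sample: ", sample_a)
  others <- setdiff(samples, sample_a)
  if (length(others) == 0) stop("need at least one other sample")
  loh_gr <- function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    seg <- seg[.is_loh(seg), , drop = FALSE]
    GenomicRanges::reduce(.as_granges(seg$chrom, seg$start, seg$end))
  }
  a <- loh_gr(sample_a)
  if (sum(as.numeric(GenomicRanges::width(a))) == 0)
    stop("sample ", sample_a, " has no LOH; overlap undefined")
  inter <- loh_gr(others[1])
  for (s in others[-1])
    inter <- GenomicRanges::intersect(inter, loh_gr(s))
  shared <- GenomicRanges::intersect(a, inter)
  out <- list(bp = sum(as.numeric(GenomicRanges::width(shared))) /
                sum(as.numeric(GenomicRanges::width(a))))
  if (!is.null(genes)) {
    m <- gene_loh_matrix(segments, genes, frac_threshold)
    a_genes <- m[, sample_a]
    out$gene <- if (!any(a_genes)) NA_real_ else
      mean(apply(m[a_genes, others, drop = FALSE], 1, all))
  }
  out
}
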