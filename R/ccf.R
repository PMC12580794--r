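#' Expected variant allele fraction for a candidate multiplicity
#'
#' For a mutation carried on `multiplicity` of the `total_cn` tumor copies of
#' its locus, in a sample of purity `P`, the expected allele fraction is
#' \deqn{E_f(M) = \frac{P \cdot M}{P \cdot C + (1 - P) \cdot n_C}}
#' where `C` is the tumor total copy number and `n_C` the germline copy
#' number of the locus.
#'
#' @param multiplicity Integer vector, 1..`total_cn`.
#' @param purity Sample purity in (0, 1].
#' @param total_cn Tumor total copy number (>= 1).
#' @param germline_cn Germline copy number (2 autosomes; sex chromosomes per
#'   [germline_cn()]).
#' @return Expected allele fraction in (0, 1].
#' @export
expected_af <- function(multiplicity, purity, total_cn, germline_cn) {
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (any(total_cn < 1)) stop("total_cn must be >= 1")
  if (any(multiplicity < 1 | multiplicity > total_cn))
    stop("multiplicity must lie in 1..total_cn")
  purity * multiplicity / (purity * total_cn + (1 - purity) * germline_cn)
}

#' Maximum-likelihood mutation multiplicity
#'
#' Scans candidate multiplicities `M = 1..C` and returns the one whose
#' expected allele fraction maximizes a Beta likelihood of the observed read
#' counts, `dbeta(Ef(M), alt_depth + 1, ref_depth + 1)` (posterior density
#' under a uniform prior; the +1 keeps the density finite when either depth
#' is zero). `Ef` is clamped to `[eps, 1 - eps]` with
#' `eps = 1/(alt_depth + ref_depth + 2)` before evaluation, so a candidate
#' with `Ef = 1` is never assigned zero density merely because reference
#' reads exist. Ties break toward the smaller multiplicity.
#'
#' @param alt_depth,ref_depth Observed tumor read counts.
#' @param purity Sample purity.
#' @param total_cn Tumor total copy number at the locus (>= 1).
#' @param germline_cn Germline copy number at the locus.
#' @return Integer multiplicity in 1..`total_cn`.
#' @export
estimate_multiplicity <- function(alt_depth, ref_depth, purity, total_cn,
                                  germline_cn) {
  if (alt_depth + ref_depth <= 0) stop("alt_depth + ref_depth must be > 0")
  if (total_cn < 1) stop("total_cn must be >= 1 (homozygous-deleted loci have no multiplicity)")
  total_cn <- as.integer(round(total_cn))
  if (total_cn == 1L) return(1L)
  m <- seq_len(total_cn)
  ef <- expected_af(m, purity, total_cn, germline_cn)
  eps <- 1 / (alt_depth + ref_depth + 2)
  ef <- pmin(pmax(ef, eps), 1 - eps)
  ll <- stats::dbeta(ef, alt_depth + 1, ref_depth + 1, log = TRUE)
  m[which.max(ll)]  # which.max returns the first (smallest M) on ties
}

#' Cancer cell fraction from allele fraction, purity, and copy number
#'
#' \deqn{CCF = \frac{AF_T \cdot (n_C (1 - P) + C P)}{\hat m P}}
#' capped at 1 (read-count noise can push the raw value above 1).
#'
#' @param vaf Observed tumor allele fraction.
#' @param purity Sample purity in (0, 1].
#' @param total_cn Tumor total copy number.
#' @param germline_cn Germline copy number.
#' @param multiplicity Mutation multiplicity (from
#'   [estimate_multiplicity()]).
#' @return CCF in \[0, 1\].
#' @export
compute_ccf <- function(vaf, purity, total_cn, germline_cn, multiplicity) {
  if (any(purity <= 0)) stop("purity must be > 0")
  raw <- vaf * (germline_cn * (1 - purity) + total_cn * purity) /
    (multiplicity * purity)
  pmin(raw, 1)
}

# assign each variant the containing segment (row index into segments);
# NA when uncovered
.variant_segment <- function(variants, segments) {
  if (nrow(segments) == 0 || nrow(variants) == 0)
    return(rep(NA_integer_, nrow(variants)))
  vg <- .as_granges(paste(variants$sample_id, variants$chrom),
                    variants$pos, variants$pos)
  sg <- .as_granges(paste(segments$sample_id, segments$chrom),
                    segments$start, segments$end)
  hits <- GenomicRanges::findOverlaps(vg, sg, select = "first")
  as.integer(hits)
}

#' Per-variant CCF table for a cohort
#'
#' Joins every variant observation to its sample's purity and the containing
#' copy-number segment, estimates multiplicity, and computes CCF and the
#' clonality call (`ccf > clonal_threshold`). Variants not covered by any
#' segment fall back to `C = round(ploidy)` and are flagged
#' `"no_segment"`; variants inside homozygous deletions are flagged
#' `"homdel"` and receive no CCF.
#'
#' @param cohort `patient_cohort`.
#' @param clonal_threshold CCF above which a mutation is called clonal
#'   (default 0.87, a marginally relaxed version of commonly used clonality
#'   cutoffs, capturing the left tail of the CCF ~ 1 mode).
#' @return data.frame with one row per variant observation: identifiers,
#'   depths, `total_cn`, `minor_cn`, `germline_cn`, `multiplicity`,
#'   `expected_af`, `ccf`, `clonal`, `flag`.
#' @export
ccf_table <- function(cohort, clonal_threshold = 0.87) {
  v <- cohort$variants
  s <- cohort$samples
  if (nrow(v) == 0)
    return(data.frame(patient_id = character(), sample_id = character(),
                      key = character(), stringsAsFactors = FALSE))
  si <- match(v$sample_id, s$sample_id)
  purity <- s$purity[si]
  ploidy <- s$ploidy[si]
  sex <- s$sex[si]
  gcn <- vapply(seq_len(nrow(v)),
                function(i) germline_cn(v$chrom[i], sex[i]), integer(1))
  seg_idx <- .variant_segment(v, cohort$segments)
  total_cn <- ifelse(is.na(seg_idx), round(ploidy),
                     cohort$segments$total_cn[seg_idx])
  minor_cn <- ifelse(is.na(seg_idx), NA_real_,
                     cohort$segments$minor_cn[seg_idx])
  flag <- ifelse(is.na(seg_idx), "no_segment", "")
  flag[total_cn == 0] <- "homdel"
  n <- nrow(v)
  mult <- rep(NA_integer_, n)
  eaf <- rep(NA_real_, n)
  ccf <- rep(NA_real_, n)
  ok <- total_cn >= 1
  for (i in which(ok)) {
    mult[i] <- estimate_multiplicity(v$alt_depth[i], v$ref_depth[i],
                                     purity[i], total_cn[i], gcn[i])
    eaf[i] <- expected_af(mult[i], purity[i], total_cn[i], gcn[i])
    ccf[i] <- compute_ccf(v$vaf[i], purity[i], total_cn[i], gcn[i], mult[i])
  }
  data.frame(patient_id = s$patient_id[si], sample_id = v$sample_id,
             key = variant_key(v), chrom = v$chrom, pos = v$pos,
             gene = v$gene, consequence = v$consequence,
             alt_depth = v$alt_depth, ref_depth = v$ref_depth, vaf = v$vaf,
             purity = purity, total_cn = total_cn, minor_cn = minor_cn,
             germline_cn = gcn, multiplicity = mult, expected_af = eaf,
             ccf = ccf, clonal = !is.na(ccf) & ccf > clonal_threshold,
             flag = flag, stringsAsFactors = FALSE)
}

#' Tumor mutational burden
#'
#' Nonsynonymous mutation count (missense, nonsense, frameshift, splice) per
#' megabase of targeted sequence. No VAF threshold is applied.
#'
#' @param variants Variant table for one sample (or any subset).
#' @param target_mb Size of the targeted regions in megabases.
#' @return data.frame `sample_id`, `nonsyn_count`, `target_mb`, `tmb` (one
#'   row per sample present in `variants`; samples with no rows are absent).
#' @export
compute_tmb <- function(variants, target_mb) {
  if (target_mb <= 0) stop("target_mb must be > 0")
  nonsyn <- variants[variants$consequence %in%
                       c("missense", "nonsense", "frameshift", "splice"), ]
  counts <- table(factor(nonsyn$sample_id,
                         levels = sort(unique(variants$sample_id))))
  data.frame(sample_id = names(counts),
             nonsyn_count = as.integer(counts),
             target_mb = target_mb,
             tmb = as.integer(counts) / target_mb,
             stringsAsFactors = FALSE)
}
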