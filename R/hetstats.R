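#' Presence/clonality summary per mutation per patient
#'
#' A mutation is present in a sample when it has an observation with at least
#' `min_alt` supporting reads; it is clonal there when additionally its CCF
#' exceeds the clonal threshold used in [ccf_table()].
#'
#' @param ccf_tab CCF table from [ccf_table()].
#' @param n_samples Named integer vector: number of sequenced samples per
#'   patient (defaults to the samples seen in `ccf_tab`, which undercounts
#'   samples with zero variants -- pass the sample sheet counts when
#'   available).
#' @param min_alt Minimum alt reads for presence (default 2).
#' @return data.frame `patient_id`, `key`, `gene`, `n_samples`, `n_present`,
#'   `n_clonal`.
#' @export
mutation_presence <- function(ccf_tab, n_samples = NULL, min_alt = 2) {
  tab <- ccf_tab[ccf_tab$alt_depth >= min_alt & !is.na(ccf_tab$ccf), ,
                 drop = FALSE]
  if (is.null(n_samples)) {
    ns <- tapply(ccf_tab$sample_id, ccf_tab$patient_id,
                 function(x) length(unique(x)))
    n_samples <- stats::setNames(as.integer(ns), names(ns))
  }
  agg <- stats::aggregate(cbind(n_present = rep(1L, nrow(tab)),
                                n_clonal = as.integer(tab$clonal)),
                          by = list(patient_id = tab$patient_id,
                                    key = tab$key, gene = tab$gene),
                          FUN = sum)
  agg$n_samples <- as.integer(n_samples[agg$patient_id])
  agg[order(agg$patient_id, agg$key),
      c("patient_id", "key", "gene", "n_samples", "n_present", "n_clonal")]
}

#' Five-class mutation taxonomy
#'
#' Classifies each detected mutation of a multi-sample patient:
#' \itemize{
#'   \item truncal: present and clonal in every sample;
#'   \item clonal_shared: present in 2 or more sites, clonal in at least one,
#'     not truncal;
#'   \item subclonal_shared: present in 2 or more sites, clonal in none;
#'   \item clonal_private: present in exactly one site and clonal there;
#'   \item subclonal_private: present in exactly one site, subclonal there.
#' }
#' The classes are mutually exclusive and exhaustive over detected mutations.
#'
#' @param presence data.frame from [mutation_presence()] (patients with at
#'   least 2 samples are classified; single-sample patients are dropped).
#' @return Input with a `class` column appended.
#' @export
classify_mutations <- function(presence) {
  p <- presence[presence$n_samples >= 2, , drop = FALSE]
  cls <- with(p, ifelse(
    n_present == n_samples & n_clonal == n_samples, "truncal",
    ifelse(n_present >= 2 & n_clonal >= 1, "clonal_shared",
    ifelse(n_present >= 2, "subclonal_shared",
    ifelse(n_clonal >= 1, "clonal_private", "subclonal_private")))))
  p$class <- cls
  p
}

#' Proportion of mutations appearing clonal at subset size k
#'
#' For each mutation, over all size-`k` subsets of the patient's samples in
#' which the mutation is present in at least one member, the fraction of
#' subsets where it is present and clonal in all `k` members:
#' \deqn{P_C(k) = \frac{\binom{n_C}{k}}{\binom{n}{k} - \binom{n - n_A}{k}}}
#' with `n_C` the number of samples where it is present and clonal and `n_A`
#' the number where it is present at all (samples lacking the mutation do not
#' create an illusion of clonality and are excluded from the denominator).
#' The patient value is the mean over that patient's mutations. The curve is
#' non-increasing in `k`.
#'
#' @param presence data.frame from [mutation_presence()].
#' @param k Subset size (k = 1 gives the single-biopsy illusion rate).
#' @return data.frame `patient_id`, `k`, `proportion_clonal`.
#' @export
illusion_of_clonality <- function(presence, k) {
  out <- lapply(split(presence, presence$patient_id), function(p) {
    n <- p$n_samples[1]
    if (k > n) stop("k exceeds the sample count of patient ", p$patient_id[1])
    denom <- choose(n, k) - choose(n - p$n_present, k)
    pc <- choose(p$n_clonal, k) / denom
    data.frame(patient_id = p$patient_id[1], k = k,
               proportion_clonal = mean(pc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detection rate of alterations for k-sample panels
#'
#' For an alteration present in `a` of a patient's `n` samples, the fraction
#' of size-`k` sample subsets containing at least one sample with the
#' alteration is `1 - choose(n - a, k)/choose(n, k)`. The per-patient rate is
#' the mean over the patient's alterations.
#'
#' @param presence Logical alteration-by-sample matrix for one patient
#'   (rownames = alteration ids), or a data.frame from
#'   [mutation_presence()] for many patients.
#' @param k Subset size.
#' @return For a matrix: list with `per_alteration` (named vector) and
#'   `patient_rate`. For a presence data.frame: data.frame `patient_id`, `k`,
#'   `detection_rate`.
#' @export
detection_rate <- function(presence, k) {
  if (is.matrix(presence)) {
    n <- ncol(presence)
    if (k > n) stop("k exceeds the number of samples")
    a <- rowSums(presence)
    rate <- 1 - choose(n - a, k) / choose(n, k)
    names(rate) <- rownames(presence)
    return(list(per_alteration = rate, patient_rate = mean(rate)))
  }
  out <- lapply(split(presence, presence$patient_id), function(p) {
    n <- p$n_samples[1]
    if (k > n) return(NULL)
    rate <- 1 - choose(n - p$n_present, k) / choose(n, k)
    data.frame(patient_id = p$patient_id[1], k = k,
               detection_rate = mean(rate), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise mutational concordance between a patient's samples
#'
#' For each pair of samples, the number of shared detected mutations divided
#' by the size of the union of their detected mutations.
#'
#' @param variants Variant table for one patient.
#' @param min_alt Minimum alt reads for presence (default 2).
#' @return Symmetric matrix of fractions (diagonal 1 when a sample has any
#'   mutation).
#' @export
pairwise_concordance <- function(variants, min_alt = 2) {
  v <- variants[variants$alt_depth >= min_alt, , drop = FALSE]
  samples <- sort(unique(variants$sample_id))
  sets <- lapply(samples, function(s) unique(variant_key(v[v$sample_id == s, ])))
  names(sets) <- samples
  m <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (i in seq_along(samples)) for (j in seq_along(samples)) {
    u <- length(union(sets[[i]], sets[[j]]))
    m[i, j] <- if (u == 0) NA_real_ else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  m
}

#' Presence matrix of a patient's mutations
#'
#' @param variants Variant table for one patient.
#' @param min_alt Minimum alt reads for presence (default 2).
#' @param samples Optional character vector of sample ids (columns); defaults
#'   to the samples observed in `variants`.
#' @return Logical mutation-by-sample matrix.
#' @export
presence_matrix <- function(variants, min_alt = 2, samples = NULL) {
  v <- variants[variants$alt_depth >= min_alt, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  keys <- sort(unique(variant_key(v)))
  m <- matrix(FALSE, length(keys), length(samples),
              dimnames = list(keys, samples))
  m[cbind(match(variant_key(v), keys), match(v$sample_id, samples))] <- TRUE
  m
}
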