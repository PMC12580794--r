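#' Simulation configuration for synthetic multisite cohorts
#'
#' Defaults emulate a rapid-autopsy multisite mCRPC cohort: a median of 3
#' metastatic sites per patient (max 6), ~590X sequencing depth, variable
#' purity within patients, clone trees of roughly 7--14 clones rooted in a
#' truncal clone, WGD in about half the patients (truncal in about half of
#' those), and LOH segments over a gene panel.
#'
#' @param n_patients Number of patients (default 4).
#' @param sites_min,sites_max Range of sites per patient; the default draw
#'   over 2..6 has median 3.
#' @param clones_min,clones_max Clone count range (default 7--14).
#' @param mutations_per_clone Poisson mean mutations per clone (default 30).
#' @param depth_mean Mean sequencing depth (default 590).
#' @param depth_dispersion Negative-binomial size parameter (default 8;
#'   larger = tighter around the mean).
#' @param purity_min,purity_max Uniform purity range (default 0.2--0.9);
#'   lung and bone sites are shifted lower.
#' @param seeding_model `"monoclonal"` (one clone seeds every metastasis),
#'   `"monophyletic"` (seeders form an ancestral chain), or `"polyphyletic"`
#'   (seeders on parallel branches).
#' @param wgd_prob Probability a patient carries WGD in >= 1 site
#'   (default 0.5).
#' @param wgd_truncal_prob Probability a WGD patient has it in all sites
#'   (default 0.5).
#' @param loh_fraction Probability a segment is in LOH (default 0.15).
#' @param cnv_fraction Fraction of segments with a gain/loss relative to
#'   baseline (default 0.25).
#' @param clonal_threshold CCF clonality threshold used for ground-truth
#'   labels (default 0.87).
#' @param min_mutations_per_clone Hard floor on mutations per clone
#'   (default 3).
#' @param grow_prob Probability a child clone arises locally in a site where
#'   its parent is present (default 0.5).
#' @param multi_copy_prob Probability a locally clonal mutation sits on two
#'   copies (early mutation duplicated by a later gain; default 0.3).
#' @param seed Mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 4, sites_min = 2, sites_max = 6,
                       clones_min = 7, clones_max = 14,
                       mutations_per_clone = 30, depth_mean = 590,
                       depth_dispersion = 8, purity_min = 0.2,
                       purity_max = 0.9,
                       seeding_model = c("monophyletic", "monoclonal",
                                         "polyphyletic"),
                       wgd_prob = 0.5, wgd_truncal_prob = 0.5,
                       loh_fraction = 0.15, cnv_fraction = 0.25,
                       clonal_threshold = 0.87, min_mutations_per_clone = 3,
                       grow_prob = 0.5, multi_copy_prob = 0.3, seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  seeding_model <- match.arg(seeding_model)
  stopifnot(sites_min >= 1, sites_max >= sites_min,
            clones_min >= 1, clones_max >= clones_min,
            purity_min > 0, purity_max <= 1, purity_max >= purity_min,
            mutations_per_clone > 0, depth_mean > 0)
  structure(as.list(environment()), class = "sim_config")
}

.SITE_VOCAB <- c("liver", "lymph_node", "bone", "lung", "prostate",
                 "soft_tissue")

# site count with median 3 over 2..6 (truncated for narrower configs)
.draw_n_sites <- function(cfg) {
  support <- cfg$sites_min:cfg$sites_max
  if (length(support) == 1) return(support)
  w <- stats::dgeom(support - 2, 0.42) + 0.02
  w[support == 3] <- w[support == 3] * 1.6
  sample(support, 1, prob = w / sum(w))
}

# k Beta(1,2) sticks over the unit interval, in arrival order
.stick_break <- function(k) {
  if (k == 0) return(numeric(0))
  remaining <- 1
  out <- numeric(k)
  for (i in seq_len(k)) {
    out[i] <- remaining * stats::rbeta(1, 1, 2)
    remaining <- remaining - out[i]
  }
  out
}

#' Simulate one multisite patient with known ground truth
#'
#' The generative model draws a clone tree by random branching from a truncal
#' root, then builds sites sequentially. Site 1 is the primary-like lesion,
#' founded by the root; each later site is founded by a seeding clone chosen
#' per the seeding model and already present in an earlier site (the source
#' of its ground-truth seeding edge). Within a site, the founding clone and
#' its ancestors are clonal (cumulative CCF 1) and descendant clones arise
#' locally with probability `grow_prob`, receiving cumulative CCFs by
#' Beta(1,2) stick-breaking of the parent's residual CCF mass -- so the
#' pigeonhole constraint (parent CCF >= sum of children CCFs) holds exactly
#' by construction. Mutations are assigned to clones; expected allele
#' fractions invert the CCF equation
#' (`AF = CCF * m * P / (nC (1-P) + C P)`); depths are negative binomial and
#' alt reads binomial. Copy-number segments (WGD, gains/losses, LOH) are
#' laid over chr1-chr8 and variants take a multiplicity consistent with the
#' local total copy number. A variant record is emitted only when the
#' simulated alt depth reaches 2 (the pipeline's presence rule).
#'
#' @param cfg `sim_config`.
#' @param patient_id Patient label.
#' @param patient_seed Integer seed for this patient.
#' @return list with `cohort` (a `patient_cohort` slice), `genes` (gene
#'   panel), and `truth`: `tree` (parent vector), `clone_ccf`
#'   (clone-by-sample cumulative CCF), `mutation_clone`, `mutation_class`,
#'   `seeding_clones`, `seeding_edges`, `pattern`, `purity`, `true_ccf`
#'   (mutation-by-sample), `wgd_status`.
#' @export
simulate_patient <- function(cfg, patient_id = "P1", patient_seed = 1) {
  set.seed(patient_seed)
  n_sites <- .draw_n_sites(cfg)
  n_clones <- sample(cfg$clones_min:cfg$clones_max, 1)
  site_names <- sample(.SITE_VOCAB, min(n_sites, length(.SITE_VOCAB)))
  if (n_sites > length(.SITE_VOCAB))
    site_names <- c(site_names, sample(.SITE_VOCAB,
                                       n_sites - length(.SITE_VOCAB)))
  sites <- make.unique(paste0(patient_id, "_", site_names), sep = "_")

  # --- clone tree: random branching from the root (clone 1); polyphyletic
  #     seeding needs two incomparable non-root clones, so redraw pure chains
  draw_tree <- function() {
    parent <- rep(NA_integer_, n_clones)
    for (cl in seq_len(n_clones)[-1])
      parent[cl] <- sample(seq_len(cl - 1), 1)
    parent
  }
  parent <- draw_tree()
  ancestors_of <- function(id) {
    out <- integer(0)
    while (!is.na(parent[id])) { id <- parent[id]; out <- c(out, id) }
    out
  }
  comparable <- function(a, b)
    a %in% ancestors_of(b) || b %in% ancestors_of(a) || a == b
  if (cfg$seeding_model == "polyphyletic") {
    tries <- 0
    repeat {
      cand <- utils::combn(2:n_clones, 2)
      ok <- which(!apply(cand, 2, function(p) comparable(p[1], p[2])))
      if (length(ok) > 0 || tries > 50) break
      parent <- draw_tree(); tries <- tries + 1
    }
    if (length(ok) == 0) stop("could not draw a branching tree for polyphyletic seeding")
    pick <- cand[, sample(ok, 1)]
  }
  children_of <- function(id) which(parent == id)
  depth_of <- vapply(seq_len(n_clones), function(i) length(ancestors_of(i)),
                     integer(1))

  # --- seeding clones: site 1 is founded by the root; later sites by the
  #     model's seeders, each planted in an earlier (source) site first
  root_chain <- {
    tip <- which.max(depth_of)
    c(rev(ancestors_of(tip)), tip)
  }
  seeders <- integer(n_sites)
  seeders[1] <- 1L
  if (n_sites > 1) {
    seeders[-1] <- switch(cfg$seeding_model,
      monoclonal = rep(1L, n_sites - 1),
      monophyletic = root_chain[pmin(2:n_sites, length(root_chain))],
      polyphyletic = {
        extra <- if (n_sites > 3)
          sample(pick, n_sites - 3, replace = TRUE) else integer(0)
        c(pick, extra)[seq_len(n_sites - 1)]
      })
  }

  # --- per-site cumulative CCFs
  ccf <- matrix(0, n_clones, n_sites,
                dimnames = list(seq_len(n_clones), sites))
  min_ccf <- 0.05
  plant <- function(ccf_s, target) {
    path <- c(rev(ancestors_of(target)), target)
    for (i in seq_along(path)[-1]) {
      v <- path[i - 1]; ch <- path[i]
      if (ccf_s[ch] > 0) next
      room <- ccf_s[v] - sum(ccf_s[children_of(v)])
      if (room < 2 * min_ccf) {
        sib <- setdiff(children_of(v), which(ccf_s == 1))
        ccf_s[sib] <- ccf_s[sib] * 0.6
        room <- ccf_s[v] - sum(ccf_s[children_of(v)])
      }
      ccf_s[ch] <- max(room, 0) * stats::runif(1, 0.45, 0.8)
    }
    ccf_s
  }
  grow <- function(ccf_s) {
    for (v in order(depth_of)) {
      if (ccf_s[v] <= 0) next
      ch <- children_of(v)
      un <- ch[ccf_s[ch] == 0]
      if (length(un) == 0) next
      present <- un[stats::runif(length(un)) < cfg$grow_prob]
      if (length(present) == 0) next
      room <- ccf_s[v] - sum(ccf_s[ch])
      if (room <= 2 * min_ccf) next
      sticks <- .stick_break(length(present)) * room
      sticks[sticks < min_ccf] <- 0
      ccf_s[present] <- sticks
    }
    ccf_s
  }
  # clones whose CCF vectors differ by < 0.15 in every sample would be merged
  # by the pipeline's 10% rule, i.e. are unidentifiable; redraw such
  # configurations so the emitted ground truth is recoverable in principle
  distinct_ok <- function(m) {
    for (a in seq_len(nrow(m))) {
      if (max(m[a, ]) < 0.08) return(FALSE)
      for (b in seq_len(a - 1))
        if (max(abs(m[a, ] - m[b, ])) < 0.15) return(FALSE)
    }
    TRUE
  }
  seed_edges <- NULL
  for (try in seq_len(40)) {
    ccf[] <- 0
    seed_edges <- NULL
    for (s in seq_len(n_sites)) {
      sd_cl <- seeders[s]
      ccf_s <- ccf[, s]
      ccf_s[c(rev(ancestors_of(sd_cl)), sd_cl)] <- 1
      if (s < n_sites && seeders[s + 1] != sd_cl &&
          cfg$seeding_model == "monophyletic")
        ccf_s <- plant(ccf_s, seeders[s + 1])  # next seeder needs a source here
      if (s == 1 && cfg$seeding_model == "polyphyletic")
        for (b in unique(seeders[-1])) ccf_s <- plant(ccf_s, b)
      ccf[, s] <- grow(ccf_s)
      if (s > 1) {
        src <- which(ccf[sd_cl, seq_len(s - 1)] > 0)
        src <- src[length(src)]   # most recent site carrying the seeder
        seed_edges <- rbind(seed_edges, data.frame(
          source = sites[src], dest = sites[s], clone = sd_cl,
          kind = "seeding", stringsAsFactors = FALSE))
      }
    }
    if (distinct_ok(ccf)) break
  }
  uniq_seeders <- sort(unique(seeders[-1]))
  pattern <- if (n_sites == 1 || length(uniq_seeders) <= 1) "monoclonal"
  else {
    poly <- FALSE
    for (a in uniq_seeders) for (b in uniq_seeders)
      if (a < b && !comparable(a, b)) poly <- TRUE
    if (poly) "polyphyletic_polyclonal" else "monophyletic_polyclonal"
  }

  # --- sample sheet
  purity <- stats::runif(n_sites, cfg$purity_min, cfg$purity_max)
  low <- grepl("lung|bone", sites)
  purity[low] <- pmax(cfg$purity_min, purity[low] * 0.8)
  wgd_patient <- stats::runif(1) < cfg$wgd_prob
  wgd_truncal <- wgd_patient && stats::runif(1) < cfg$wgd_truncal_prob
  wgd_sample <- if (!wgd_patient) rep(FALSE, n_sites)
    else if (wgd_truncal || n_sites == 1) rep(TRUE, n_sites)
    else { x <- stats::runif(n_sites) < 0.5
           x[1] <- TRUE; x[n_sites] <- FALSE; x }
  ploidy <- ifelse(wgd_sample, 4, 2)
  samples <- data.frame(patient_id = patient_id, sample_id = sites,
                        tissue_site = site_names,
                        purity = round(purity, 3), ploidy = ploidy,
                        sex = "male", stringsAsFactors = FALSE)

  # --- copy-number segments over chr1..chr8
  chroms <- paste0("chr", 1:8)
  clen <- chrom_lengths()[chroms]
  seg_list <- list()
  for (s in seq_len(n_sites)) {
    base <- ploidy[s]
    for (ch in chroms) {
      n_seg <- sample(3:6, 1)
      cuts <- sort(sample.int(clen[[ch]] - 1, n_seg - 1))
      st <- c(1, cuts + 1); en <- c(cuts, clen[[ch]])
      cn <- rep(base, n_seg)
      alter <- stats::runif(n_seg) < cfg$cnv_fraction
      cn[alter] <- pmax(0, base + sample(c(-1, 1, 2), sum(alter),
                                         replace = TRUE,
                                         prob = c(0.5, 0.35, 0.15)))
      minor <- floor(cn / 2)
      loh <- stats::runif(n_seg) < cfg$loh_fraction & cn >= 1
      minor[loh | cn == 0] <- 0
      seg_list[[length(seg_list) + 1]] <- data.frame(
        sample_id = sites[s], chrom = ch, start = st, end = en,
        total_cn = cn, minor_cn = minor, stringsAsFactors = FALSE)
    }
  }
  segments <- as_segment_table(do.call(rbind, seg_list))

  # --- gene panel (synthetic symbols plus recurrent mCRPC drivers)
  drivers <- c("TP53", "AR", "PTEN", "RB1", "FOXA1")
  panel_n <- 40
  genes_panel <- data.frame(
    gene = c(drivers, paste0("GENE", seq_len(panel_n - length(drivers)))),
    chrom = sample(chroms, panel_n, replace = TRUE),
    stringsAsFactors = FALSE)
  gstart <- vapply(genes_panel$chrom,
                   function(ch) sample.int(clen[[ch]] - 3e6, 1), numeric(1))
  genes_panel$start <- gstart
  genes_panel$end <- gstart + sample(2e4:2e6, panel_n, replace = TRUE)

  # --- mutations and reads
  n_mut <- pmax(cfg$min_mutations_per_clone,
                stats::rpois(n_clones, cfg$mutations_per_clone))
  mut_clone <- rep(seq_len(n_clones), n_mut)
  N <- length(mut_clone)
  mchrom <- sample(chroms, N, replace = TRUE)
  mpos <- vapply(mchrom, function(ch) sample.int(clen[[ch]], 1), numeric(1))
  bases <- c("A", "C", "G", "T")
  mref <- sample(bases, N, replace = TRUE)
  malt <- vapply(mref, function(b) sample(setdiff(bases, b), 1), character(1))
  key <- paste(mchrom, mpos, mref, malt, sep = ":")
  while (anyDuplicated(key) > 0) {
    d <- which(duplicated(key))
    mpos[d] <- mpos[d] + 1L
    key <- paste(mchrom, mpos, mref, malt, sep = ":")
  }
  mgene <- sample(genes_panel$gene, N, replace = TRUE)
  mcsq <- sample(CONSEQUENCES, N, replace = TRUE,
                 prob = c(0.5, 0.08, 0.08, 0.06, 0.25, 0.03))
  true_ccf <- ccf[mut_clone, , drop = FALSE]
  rownames(true_ccf) <- key
  nC <- germline_cn(mchrom, "male")
  var_rows <- list()
  mult <- matrix(NA_integer_, N, n_sites, dimnames = list(key, sites))
  for (s in seq_len(n_sites)) {
    seg_s <- segments[segments$sample_id == sites[s], , drop = FALSE]
    segidx <- .variant_segment(
      data.frame(sample_id = sites[s], chrom = mchrom, pos = mpos,
                 stringsAsFactors = FALSE), seg_s)
    C <- ifelse(is.na(segidx), ploidy[s], seg_s$total_cn[segidx])
    # multi-copy mutations are early events duplicated by later gains, so
    # multiplicity 2 is drawn only where the mutation is locally clonal
    m_s <- pmin(ifelse(true_ccf[, s] >= 1,
                       sample(1:2, N, replace = TRUE,
                              prob = c(1 - cfg$multi_copy_prob,
                                       cfg$multi_copy_prob)),
                       1L),
                pmax(C, 1))
    mult[, s] <- m_s
    af <- ifelse(C >= 1 & true_ccf[, s] > 0,
                 true_ccf[, s] * m_s * purity[s] /
                   (nC * (1 - purity[s]) + C * purity[s]), 0)
    dep <- stats::rnbinom(N, size = cfg$depth_dispersion,
                          mu = cfg$depth_mean) + 10L
    alt <- stats::rbinom(N, dep, pmin(af, 1))
    emit <- alt >= 2
    if (any(emit))
      var_rows[[length(var_rows) + 1]] <- data.frame(
        sample_id = sites[s], chrom = mchrom[emit], pos = mpos[emit],
        ref = mref[emit], alt = malt[emit], alt_depth = alt[emit],
        ref_depth = dep[emit] - alt[emit], gene = mgene[emit],
        consequence = mcsq[emit], stringsAsFactors = FALSE)
  }
  variants <- as_variant_table(do.call(rbind, var_rows))
  cohort <- patient_cohort(samples, variants, segments)

  # --- ground-truth mutation classes (from noise-free CCFs)
  thr <- cfg$clonal_threshold
  n_present <- rowSums(true_ccf > 0)
  n_clonal <- rowSums(true_ccf > thr)
  true_class <- ifelse(n_present == n_sites & n_clonal == n_sites, "truncal",
                ifelse(n_present >= 2 & n_clonal >= 1, "clonal_shared",
                ifelse(n_present >= 2, "subclonal_shared",
                ifelse(n_clonal >= 1, "clonal_private", "subclonal_private"))))
  list(cohort = cohort, genes = genes_panel,
       truth = list(tree = parent, clone_ccf = ccf,
                    mutation_clone = stats::setNames(mut_clone, key),
                    mutation_class = stats::setNames(true_class, key),
                    seeding_clones = uniq_seeders,
                    seeding_edges = seed_edges, pattern = pattern,
                    purity = purity, true_ccf = true_ccf,
                    multiplicity = mult, wgd_status = wgd_sample))
}

#' Simulate a cohort and write it to disk in the standard formats
#'
#' Patient seeds are derived from the config seed by fixed offsets, so the
#' output is bit-reproducible given the seed.
#'
#' @param cfg `sim_config`.
#' @param dir Output directory (created if needed). `NULL` skips writing.
#' @return list with `cohort` (merged `patient_cohort` with the gene panel in
#'   `$genes`), `genes`, and `truths` (per-patient ground-truth lists).
#'   Files written: `samples.tsv`, `variants.tsv`, `segments.seg`,
#'   `genes.bed`, `truth_mutations.tsv`, `truth_patterns.tsv`.
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  ids <- sprintf("SIM_%02d", seq_len(cfg$n_patients))
  sims <- lapply(seq_len(cfg$n_patients), function(i)
    simulate_patient(cfg, patient_id = ids[i],
                     patient_seed = cfg$seed + 1000L * i))
  names(sims) <- ids
  cohort <- patient_cohort(
    do.call(rbind, lapply(sims, function(x) x$cohort$samples)),
    do.call(rbind, lapply(sims, function(x) x$cohort$variants)),
    do.call(rbind, lapply(sims, function(x) x$cohort$segments)))
  set.seed(cfg$seed)
  genes <- sims[[1]]$genes
  cohort$genes <- genes
  truths <- lapply(sims, `[[`, "truth")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
    write_variants(cohort$variants, file.path(dir, "variants.tsv"))
    write_segments(cohort$segments, file.path(dir, "segments.seg"))
    write_gene_bed(genes, file.path(dir, "genes.bed"))
    tm <- do.call(rbind, lapply(names(truths), function(p)
      data.frame(patient = p, key = names(truths[[p]]$mutation_clone),
                 clone = truths[[p]]$mutation_clone,
                 class = truths[[p]]$mutation_class,
                 stringsAsFactors = FALSE)))
    utils::write.table(tm, file.path(dir, "truth_mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tp <- data.frame(patient = names(truths),
                     pattern = vapply(truths, `[[`, character(1), "pattern"),
                     stringsAsFactors = FALSE)
    utils::write.table(tp, file.path(dir, "truth_patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(cohort = cohort, genes = genes, truths = truths)
}
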