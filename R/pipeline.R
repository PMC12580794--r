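#' Run the full multisite clonality pipeline on a cohort
#'
#' Orchestrates every stage: per-variant CCFs and clonality, TMB, CN event
#' classification and CIN summaries, WGD and CNV truncality, per-patient
#' clone clustering (with pruning/merging and driver rescue), phylogeny
#' reconstruction, seeding/migration inference, the five-class mutation
#' taxonomy, illusion-of-clonality and detection-rate curves, pairwise
#' concordance, species-accumulation extrapolation, and (where feasible) the
#' cross-sample LOH overlap permutation test. A single global seed fans out
#' to per-stage seeds by fixed offsets, so stages are independently
#' reproducible and a rerun with the same seed is byte-identical.
#'
#' @param cohort `patient_cohort` (with an optional `genes` element used for
#'   CNV truncality and the LOH test), or a directory path readable by
#'   [read_cohort()].
#' @param out_dir Output directory for the report bundle (`NULL` = return
#'   only).
#' @param clonal_threshold CCF clonality cutoff (default 0.87).
#' @param tolerance Pigeonhole slack for tree building (default 0.1).
#' @param presence_threshold Clone presence cutoff (default 0.05).
#' @param k_max Maximum clusters tried per patient (default 12).
#' @param t_max,mt Accumulation extrapolation settings (defaults 100 and 20).
#' @param target_mb Targeted megabases for TMB (default 30).
#' @param driver_genes Genes whose removed variants are rescued into the
#'   nearest cluster.
#' @param loh_reps Permutation replicates for the LOH test (default 2e4;
#'   0 skips the stage).
#' @param seed Global seed (default 1).
#' @return list of class `clonemap_report` with elements `ccf`, `tmb`,
#'   `cin`, `wgd_truncality`, `cnv_truncality`, `mutation_classes`,
#'   `class_proportions`, `clonality_curves`, `detection_rates`,
#'   `concordance`, `accumulation`, `validation`, `patients` (per-patient
#'   clusters/phylogeny/migrations/pattern), `clone_class_proportions`,
#'   `loh_tests`, `params`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, clonal_threshold = 0.87,
                         tolerance = 0.1, presence_threshold = 0.05,
                         k_max = 12, t_max = 100, mt = 20, target_mb = 30,
                         driver_genes = c("TP53", "AR", "PTEN", "RB1",
                                          "FOXA1"),
                         loh_reps = 2e4, seed = 1) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  params <- list(clonal_threshold = clonal_threshold, tolerance = tolerance,
                 presence_threshold = presence_threshold, k_max = k_max,
                 t_max = t_max, mt = mt, target_mb = target_mb,
                 driver_genes = driver_genes, loh_reps = loh_reps,
                 seed = seed)
  samples <- cohort$samples
  n_samples <- table(samples$patient_id)
  n_samples <- stats::setNames(as.integer(n_samples), names(n_samples))

  ## stage 1: CCF + TMB ------------------------------------------------
  ccf_tab <- ccf_table(cohort, clonal_threshold)
  tmb <- compute_tmb(cohort$variants, target_mb)

  ## stage 2: CN metrics ------------------------------------------------
  cin <- cin_summary(cohort$segments)
  cin$patient_id <- samples$patient_id[match(cin$sample_id,
                                             samples$sample_id)]
  wgd_trunc <- classify_wgd_truncality(cin)
  cnv_trunc <- if (!is.null(cohort$genes))
    classify_cnv_truncality(cohort, cohort$genes) else NULL

  ## stage 3: heterogeneity statistics ----------------------------------
  presence <- mutation_presence(ccf_tab, n_samples = n_samples)
  classes <- classify_mutations(presence)
  class_prop <- if (nrow(classes) > 0) {
    tab <- prop.table(table(classes$patient_id, classes$class), 1)
    as.data.frame.matrix(tab)
  } else NULL
  multi <- names(n_samples)[n_samples >= 2]
  curves <- do.call(rbind, lapply(1:4, function(k) {
    p <- presence[presence$patient_id %in% multi &
                    presence$n_samples >= k, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    illusion_of_clonality(p, k)
  }))
  rates <- do.call(rbind, lapply(1:4, function(k) {
    p <- presence[presence$n_samples >= k, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    detection_rate(p, k)
  }))
  conc <- lapply(stats::setNames(multi, multi), function(p)
    pairwise_concordance(
      cohort$variants[cohort$variants$sample_id %in%
                        samples$sample_id[samples$patient_id == p], ,
                      drop = FALSE]))
  pres_mats <- lapply(stats::setNames(multi, multi), function(p)
    presence_matrix(
      cohort$variants[cohort$variants$sample_id %in%
                        samples$sample_id[samples$patient_id == p], ,
                      drop = FALSE],
      samples = samples$sample_id[samples$patient_id == p]))
  accum <- lapply(pres_mats, function(m) {
    f <- freq_counts(m)
    if (sum(f) == 0) return(NULL)
    accumulation_extrapolate(f, ncol(m), t_max = t_max, mt = mt)
  })
  validation <- validate_extrapolation(
    pres_mats[vapply(pres_mats, ncol, integer(1)) >= 4], mt = mt)

  ## stage 4: per-patient clonal reconstruction -------------------------
  patients <- list()
  for (i in seq_along(multi)) {
    p <- multi[i]
    ptab <- ccf_tab[ccf_tab$patient_id == p & ccf_tab$alt_depth >= 2, ,
                    drop = FALSE]
    if (length(unique(ptab$key)) < 3) next
    mats <- ccf_matrix(ptab)
    cl <- cluster_ccfs(mats, k_max = k_max, seed = seed + 100L + i)
    cl <- prune_and_merge(cl)
    phy <- tryCatch(
      build_tree(cl, tolerance = tolerance,
                 presence_threshold = presence_threshold,
                 clonal_threshold = clonal_threshold),
      clonemap_no_truncal_cluster = function(e) e)
    if (inherits(phy, "condition")) {
      patients[[p]] <- list(clusters = cl, phylogeny = NULL,
                            migrations = NULL, pattern = "no_tree",
                            error = conditionMessage(phy))
      next
    }
    if (nrow(phy$removed) > 0) {
      # rescue driver variants from clusters dropped during tree building
      drop_keys <- names(cl$assignment)[cl$assignment %in%
                                          phy$removed$cluster_id]
      kept <- !cl$assignment %in% phy$removed$cluster_id
      kept_cl <- .new_clusters(
        .cluster_means(cl$ccf[kept, , drop = FALSE], cl$assignment[kept]),
        cl$assignment[kept], cl$ccf[kept, , drop = FALSE],
        cl$depth[kept, , drop = FALSE], bic = cl$bic)
      resc <- rescue_drivers(kept_cl,
                             cl$ccf[drop_keys, , drop = FALSE],
                             mats$gene[drop_keys], driver_genes)
      phy$n_mutations <- resc$n_mutations[rownames(phy$centers)]
      cl <- resc
    }
    mig <- infer_migrations(phy)
    patients[[p]] <- list(clusters = cl, phylogeny = phy, migrations = mig,
                          pattern = mig$pattern, error = NULL)
  }
  clone_prop <- do.call(rbind, lapply(names(patients), function(p) {
    phy <- patients[[p]]$phylogeny
    if (is.null(phy)) return(NULL)
    tab <- table(factor(phy$clone_class, c("trunk", "branch", "leaf")))
    data.frame(patient_id = p, trunk = tab[["trunk"]],
               branch = tab[["branch"]], leaf = tab[["leaf"]],
               stringsAsFactors = FALSE)
  }))

  ## stage 5: LOH permutation test where feasible ------------------------
  loh_tests <- list()
  if (loh_reps > 0 && !is.null(cohort$genes)) {
    for (j in seq_along(multi)) {
      p <- multi[j]
      seg <- cohort$segments[cohort$segments$sample_id %in%
                               samples$sample_id[samples$patient_id == p], ,
                             drop = FALSE]
      feasible <- all(vapply(split(seg, seg$sample_id), function(x) {
        l <- .is_loh(x); any(l) && !all(l)
      }, logical(1)))
      if (!feasible) next
      loh_tests[[p]] <- loh_overlap_test(seg, cohort$genes, reps = loh_reps,
                                         seed = seed + 200L + j)
    }
  }

  report <- structure(
    list(ccf = ccf_tab, tmb = tmb, cin = cin, wgd_truncality = wgd_trunc,
         cnv_truncality = cnv_trunc, mutation_classes = classes,
         class_proportions = class_prop, clonality_curves = curves,
         detection_rates = rates, concordance = conc,
         accumulation = accum, validation = validation,
         patients = patients, clone_class_proportions = clone_prop,
         loh_tests = loh_tests, params = params),
    class = "clonemap_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.clonemap_report <- function(x, ...) {
  cat("clonemap_report:",
      length(unique(x$ccf$patient_id)), "patient(s);",
      nrow(x$ccf), "CCF record(s);",
      length(x$patients), "patient(s) with clonal reconstruction\n")
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits per-stage TSV tables, per-patient Newick trees and migration edge
#' lists, a JSON summary, and the parameter set (`params.yaml`).
#'
#' @param report `clonemap_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$ccf, "ccf.tsv")
  wt(report$tmb, "tmb.tsv")
  wt(report$cin, "cin.tsv")
  wt(report$wgd_truncality, "wgd_truncality.tsv")
  wt(report$cnv_truncality, "cnv_truncality.tsv")
  wt(report$mutation_classes, "mutation_classes.tsv")
  wt(report$clonality_curves, "clonality_curves.tsv")
  wt(report$detection_rates, "detection_rates.tsv")
  wt(report$validation, "accumulation_validation.tsv")
  wt(report$clone_class_proportions, "clone_class_proportions.tsv")
  accum_tab <- do.call(rbind, lapply(names(report$accumulation), function(p) {
    a <- report$accumulation[[p]]
    if (is.null(a)) return(NULL)
    data.frame(patient_id = p, t = a$t, predicted = a$predicted,
               stringsAsFactors = FALSE)
  }))
  wt(accum_tab, "accumulation_curves.tsv")
  clus_tab <- do.call(rbind, lapply(names(report$patients), function(p) {
    cl <- report$patients[[p]]$clusters
    data.frame(patient_id = p, key = names(cl$assignment),
               cluster = cl$assignment, stringsAsFactors = FALSE)
  }))
  wt(clus_tab, "clusters.tsv")
  mig_tab <- do.call(rbind, lapply(names(report$patients), function(p) {
    m <- report$patients[[p]]$migrations
    if (is.null(m) || nrow(m$edges) == 0) return(NULL)
    cbind(patient_id = p, m$edges)
  }))
  wt(mig_tab, "migrations.tsv")
  pat_tab <- data.frame(
    patient_id = names(report$patients),
    pattern = vapply(report$patients, `[[`, character(1), "pattern"),
    stringsAsFactors = FALSE)
  wt(pat_tab, "seeding_patterns.tsv")
  trees <- vapply(report$patients, function(x)
    if (is.null(x$phylogeny)) "" else phylo_to_newick(x$phylogeny),
    character(1))
  writeLines(paste0(names(trees), "\t", trees),
             file.path(out_dir, "trees.nwk"))
  summary <- list(
    n_patients = length(unique(report$ccf$patient_id)),
    n_ccf_records = nrow(report$ccf),
    patterns = as.list(table(pat_tab$pattern)),
    loh_p_values = lapply(report$loh_tests, `[[`, "p_value"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(report$params, file.path(out_dir, "params.yaml"))
  invisible(out_dir)
}
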