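# Small deterministic fixtures shared across tests.

tiny_variants <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S2", "S3", "S3", "S3", "S1", "S2"),
    chrom = c("chr1", "chr2", "chr3", "chr1", "chr2", "chr1", "chr2", "chr4",
              "chr5", "chr5"),
    pos = c(100L, 200L, 300L, 100L, 200L, 100L, 200L, 400L, 500L, 500L),
    ref = c("A", "C", "G", "A", "C", "A", "C", "T", "G", "G"),
    alt = c("T", "G", "A", "T", "G", "T", "G", "C", "C", "C"),
    alt_depth = c(30L, 50L, 12L, 28L, 45L, 33L, 8L, 60L, 20L, 22L),
    ref_depth = c(70L, 50L, 88L, 72L, 55L, 67L, 92L, 40L, 80L, 78L),
    gene = c("TP53", "AR", "PTEN", "TP53", "AR", "TP53", "AR", "RB1",
             "FOXA1", "FOXA1"),
    consequence = c("missense", "nonsense", "synonymous", "missense",
                    "nonsense", "missense", "nonsense", "frameshift",
                    "splice", "splice"),
    stringsAsFactors = FALSE)
}

tiny_segments <- function() {
  do.call(rbind, lapply(c("S1", "S2", "S3"), function(s)
    data.frame(sample_id = s,
               chrom = rep(c("chr1", "chr2", "chr3", "chr4", "chr5"),
                           each = 2),
               start = rep(c(1, 1001), 5),
               end = rep(c(1000, 2000), 5),
               total_cn = c(2, 2, 3, 2, 2, 2, 1, 2, 2, 2),
               minor_cn = c(1, 0, 1, 1, 1, 1, 0, 1, 1, 0),
               stringsAsFactors = FALSE)))
}

tiny_samples <- function() {
  data.frame(patient_id = "P1", sample_id = c("S1", "S2", "S3"),
             tissue_site = c("liver", "lung", "bone"),
             purity = c(0.6, 0.5, 0.7), ploidy = 2, sex = "male",
             stringsAsFactors = FALSE)
}

tiny_cohort <- function() {
  patient_cohort(tiny_samples(), tiny_variants(), tiny_segments())
}

# build a clone_clusters object directly from a centers matrix, giving each
# cluster `size` member mutations exactly at the center
make_clusters <- function(centers, size = 5, depth = 600) {
  k <- nrow(centers)
  if (is.null(colnames(centers)))
    colnames(centers) <- paste0("s", seq_len(ncol(centers)))
  ccf <- centers[rep(seq_len(k), each = size), , drop = FALSE]
  rownames(ccf) <- sprintf("chrZ:%d:A:T", seq_len(k * size))
  assign <- stats::setNames(rep(seq_len(k), each = size), rownames(ccf))
  dep <- matrix(depth, nrow(ccf), ncol(ccf), dimnames = dimnames(ccf))
  clonemap:::.new_clusters(
    clonemap:::.cluster_means(ccf, assign), assign, ccf, dep)
}

# equal-length-segment dataset drawn from the label-shuffle null (retention
# filter non-binding); used for permutation calibration
null_loh_dataset <- function(seed, nseg = 50, nloh = 17, seg_len = 4e6,
                             samples = c("A", "B")) {
  set.seed(seed)
  segs <- do.call(rbind, lapply(samples, function(s) {
    st <- (0:(nseg - 1)) * seg_len + 1
    minor <- rep(1, nseg)
    minor[sample.int(nseg, nloh)] <- 0
    data.frame(sample_id = s, chrom = "chr1", start = st,
               end = st + seg_len - 1, total_cn = 2, minor_cn = minor,
               stringsAsFactors = FALSE)
  }))
  as_segment_table(segs)
}

null_loh_genes <- function(n_genes = 250, nseg = 50, seg_len = 4e6,
                           seed = 99) {
  set.seed(seed)
  gst <- sort(sample.int(nseg * seg_len - 3e6, n_genes))
  data.frame(gene = paste0("G", seq_len(n_genes)), chrom = "chr1",
             start = gst,
             end = gst + sample(3e5:2.5e6, n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

# simulation settings used by the recovery tests: 3-5 sites, 5-12 clones,
# >= 10 mutations per clone, depth 600, purity >= 0.4
recovery_config <- function(seed, model) {
  sim_config(n_patients = 1, sites_min = 3, sites_max = 5,
             clones_min = 5, clones_max = 12, mutations_per_clone = 20,
             min_mutations_per_clone = 10, depth_mean = 600,
             purity_min = 0.4, purity_max = 0.9,
             seeding_model = model, seed = seed)
}

# majority-vote map from inferred clusters to true clones
cluster_truth_map <- function(clusters, truth_clone) {
  vapply(rownames(clusters$centers), function(k) {
    members <- names(clusters$assignment)[clusters$assignment ==
                                            as.integer(k)]
    tc <- truth_clone[members]
    as.integer(names(sort(table(tc), decreasing = TRUE))[1])
  }, integer(1))
}

# fraction of tree edges whose parent is the nearest represented true
# ancestor of the child's true clone (or a split of the same clone)
parent_accuracy <- function(phy, clusters, truth_clone, truth_tree) {
  mapv <- cluster_truth_map(clusters, truth_clone)
  anc <- function(id) {
    out <- integer(0)
    while (!is.na(truth_tree[id])) { id <- truth_tree[id]; out <- c(out, id) }
    out
  }
  par <- stats::setNames(phy$edges$parent, phy$edges$child)
  ok <- vapply(phy$edges$child, function(ch) {
    tch <- mapv[[as.character(ch)]]
    tpar <- mapv[[as.character(par[[as.character(ch)]])]]
    if (tpar == tch) return(TRUE)
    a <- anc(tch)
    expected <- a[a %in% mapv][1]
    !is.na(expected) && tpar == expected
  }, logical(1))
  mean(ok)
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(as.character(tools::md5sum(files)),
                  sub(paste0("^", dir, "/?"), "", files))
}
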