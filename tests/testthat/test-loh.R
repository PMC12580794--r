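test_that("gene-level LOH calls use the 50 percent span rule", {
  seg <- as_segment_table(data.frame(
    sample_id = "S1", chrom = "chr1",
    start = c(1, 1001), end = c(1000, 2000),
    total_cn = c(2, 2), minor_cn = c(0, 1)))
  genes <- data.frame(gene = c("IN", "OUT", "STRADDLE60", "STRADDLE40"),
                      chrom = "chr1",
                      start = c(100, 1500, 701, 901),
                      end = c(500, 1900, 1200, 1400))
  m <- gene_loh_matrix(seg, genes)
  expect_true(m["IN", "S1"])          # fully inside the LOH segment
  expect_false(m["OUT", "S1"])        # no LOH overlap
  expect_true(m["STRADDLE60", "S1"])  # 60% of span in LOH
  expect_false(m["STRADDLE40", "S1"]) # only 40%
  # gene on an uncovered chromosome is FALSE
  g2 <- data.frame(gene = "G9", chrom = "chr9", start = 1, end = 100)
  expect_false(gene_loh_matrix(seg, g2)["G9", "S1"])
})

test_that("permutation p-value matches exhaustive enumeration on a toy", {
  # 2 samples x 4 segments x 3 genes; unequal lengths exercise the
  # retention filter; n_loh = 1 so n_aug = ceiling(1.2) = 2
  seg <- as_segment_table(data.frame(
    sample_id = rep(c("A", "B"), each = 4), chrom = "chr1",
    start = rep(c(1, 1001, 3001, 6001), 2),
    end = rep(c(1000, 3000, 6000, 10000), 2),
    total_cn = 2,
    minor_cn = c(0, 1, 1, 1,   1, 1, 0, 1)))
  genes <- data.frame(gene = c("G1", "G2", "G3"), chrom = "chr1",
                      start = c(100, 3200, 6500), end = c(800, 5500, 9500))
  # exact null: enumerate all C(4,2)^2 label placements with the filter
  lens <- c(1000, 2000, 3000, 4000)
  obs_frac <- c(A = 1000, B = 3000) / sum(lens)
  gene_seg <- rbind(G1 = c(1, 0, 0, 0), G2 = c(0, 0, 1, 0), G3 = c(0, 0, 0, 1))
  obs_overlap <- 0  # A has LOH on seg1 (G1), B on seg3 (G2): no shared gene
  placements <- utils::combn(4, 2)
  draws <- c(); weights <- c()
  for (i in seq_len(ncol(placements))) for (j in seq_len(ncol(placements))) {
    la <- lb <- rep(0, 4)
    la[placements[, i]] <- 1; lb[placements[, j]] <- 1
    if (sum(lens * la) / sum(lens) < obs_frac[["A"]]) next
    if (sum(lens * lb) / sum(lens) < obs_frac[["B"]]) next
    stat <- sum((gene_seg %*% la > 0) & (gene_seg %*% lb > 0))
    draws <- c(draws, stat); weights <- c(weights, 1)
  }
  p_exact <- sum(draws >= obs_overlap) / length(draws)  # = 1: overlap is 0
  res <- loh_overlap_test(seg, genes, reps = 1e4, seed = 3)
  expect_equal(res$observed_overlap, obs_overlap)
  se <- sqrt(p_exact * (1 - p_exact) / res$reps_retained) + 2e-4
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-6)
})

test_that("nonzero observed overlap is compared against the filtered null", {
  # both samples carry LOH on the long segment 4 covering G3
  seg <- as_segment_table(data.frame(
    sample_id = rep(c("A", "B"), each = 4), chrom = "chr1",
    start = rep(c(1, 1001, 3001, 6001), 2),
    end = rep(c(1000, 3000, 6000, 10000), 2),
    total_cn = 2,
    minor_cn = c(1, 1, 1, 0,   1, 1, 1, 0)))
  genes <- data.frame(gene = c("G1", "G2", "G3"), chrom = "chr1",
                      start = c(100, 3200, 6500), end = c(800, 5500, 9500))
  lens <- c(1000, 2000, 3000, 4000)
  obs_frac <- 4000 / sum(lens)
  gene_seg <- rbind(G1 = c(1, 0, 0, 0), G2 = c(0, 0, 1, 0), G3 = c(0, 0, 0, 1))
  placements <- utils::combn(4, 2)
  draws <- c()
  for (i in seq_len(ncol(placements))) for (j in seq_len(ncol(placements))) {
    la <- lb <- rep(0, 4)
    la[placements[, i]] <- 1; lb[placements[, j]] <- 1
    if (sum(lens * la) / sum(lens) < obs_frac) next
    if (sum(lens * lb) / sum(lens) < obs_frac) next
    draws <- c(draws, sum((gene_seg %*% la > 0) & (gene_seg %*% lb > 0)))
  }
  p_exact <- sum(draws >= 1) / length(draws)
  res <- loh_overlap_test(seg, genes, reps = 2e4, seed = 8)
  expect_equal(res$observed_overlap, 1L)
  se <- sqrt(p_exact * (1 - p_exact) / res$reps_retained)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-3)
})

test_that("permutation runs are seeded and reproducible", {
  seg <- null_loh_dataset(1, nseg = 12, nloh = 4, samples = c("A", "B"))
  genes <- null_loh_genes(n_genes = 20, nseg = 12)
  a <- loh_overlap_test(seg, genes, reps = 2000, seed = 7)
  b <- loh_overlap_test(seg, genes, reps = 2000, seed = 7)
  expect_identical(a$null_draws, b$null_draws)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$p_value,
               (1 + sum(a$null_draws >= a$observed_overlap)) /
                 (1 + a$reps_retained))
})

test_that("degenerate label sets are rejected", {
  seg <- as_segment_table(data.frame(
    sample_id = rep(c("A", "B"), each = 2), chrom = "chr1",
    start = c(1, 1001), end = c(1000, 2000),
    total_cn = 2, minor_cn = 0))  # all LOH
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 100, end = 800)
  expect_error(loh_overlap_test(seg, genes, reps = 10, seed = 1),
               "at least one LOH and one non-LOH")
})

test_that("pairwise LOH overlap fractions follow interval arithmetic", {
  seg <- as_segment_table(data.frame(
    sample_id = rep(c("A", "B", "C"), each = 2), chrom = "chr1",
    start = rep(c(1, 5001), 3), end = rep(c(5000, 10000), 3),
    total_cn = 2,
    minor_cn = c(0, 1,  0, 1,  0, 1)))  # identical LOH footprints
  expect_equal(pairwise_loh_overlap(seg, "A")$bp, 1)
  seg2 <- as_segment_table(data.frame(
    sample_id = rep(c("A", "B"), each = 2), chrom = "chr1",
    start = rep(c(1, 5001), 2), end = rep(c(5000, 10000), 2),
    total_cn = 2, minor_cn = c(0, 1, 1, 0)))  # disjoint
  expect_equal(pairwise_loh_overlap(seg2, "A")$bp, 0)
  # partial overlap: A loses 1-6000, B loses 4001-10000 -> 2000/6000
  seg3 <- as_segment_table(data.frame(
    sample_id = rep(c("A", "B"), each = 2), chrom = "chr1",
    start = c(1, 6001, 1, 4001), end = c(6000, 10000, 4000, 10000),
    total_cn = 2, minor_cn = c(0, 1, 1, 0)))
  expect_equal(pairwise_loh_overlap(seg3, "A")$bp, 2000 / 6000)
  # gene-level variant
  genes <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                      start = c(1, 9000), end = c(1000, 10000))
  ov <- pairwise_loh_overlap(seg3, "A", genes = genes)
  expect_equal(ov$gene, 0)  # A's only LOH gene (G1) not LOH in B
  # no LOH in the query sample is an error
  seg4 <- as_segment_table(data.frame(
    sample_id = c("A", "B"), chrom = "chr1", start = 1, end = 1000,
    total_cn = 2, minor_cn = c(1, 0)))
  expect_error(pairwise_loh_overlap(seg4, "A"), "no LOH")
})

test_that("higher observed overlap with a fixed null lowers the p-value", {
  seg <- null_loh_dataset(2, nseg = 20, nloh = 7, samples = c("A", "B"))
  genes <- null_loh_genes(n_genes = 40, nseg = 20)
  res <- loh_overlap_test(seg, genes, reps = 3000, seed = 11)
  p_at <- vapply(0:5, function(obs)
    (1 + sum(res$null_draws >= obs)) / (1 + res$reps_retained), numeric(1))
  expect_false(is.unsorted(rev(p_at)))
})
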