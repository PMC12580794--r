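test_that("baseline CN is the length-weighted median, rounded half-up", {
  expect_equal(baseline_cn(c(2, 4), c(60e6, 40e6)), 2L)
  expect_equal(baseline_cn(c(4, 4, 4), c(1, 5, 2)), 4L)
  expect_error(baseline_cn(numeric(0), numeric(0)), "no segments")
  # brute-force oracle: expand integer weights and take the sample median
  set.seed(3)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    cn <- sample(0:8, n, replace = TRUE)
    w <- sample(1:20, n, replace = TRUE)
    oracle <- as.integer(floor(stats::median(rep(cn, w)) + 0.5))
    expect_identical(baseline_cn(cn, w), oracle)
  }
})

test_that("segment events follow the gain/amplification/deletion/LOH rules", {
  seg <- as_segment_table(data.frame(
    sample_id = "S1", chrom = "chr1",
    start = c(1, 101, 201, 301, 401),
    end = c(100, 200, 300, 400, 500),
    total_cn = c(2, 8, 2, 0, 1),
    minor_cn = c(1, 1, 0, 0, 0)))
  cls <- classify_segments(seg)
  expect_equal(cls$baseline_cn, rep(2L, 5))
  byc <- stats::setNames(cls$event, cls$start)
  expect_equal(byc[["101"]], "amplification")  # C=8 > 2x baseline, >= 7
  expect_true(cls$gain[cls$start == 101])
  expect_equal(byc[["201"]], "neutral")        # copy-neutral LOH
  expect_true(cls$loh[cls$start == 201])
  expect_equal(byc[["301"]], "homozygous_deletion")
  expect_false(cls$loh[cls$start == 301])      # LOH requires C >= 1
  expect_equal(byc[["401"]], "deletion")
  expect_true(cls$loh[cls$start == 401])       # hemizygous loss
})

test_that("segment classification matches an independent re-evaluation", {
  set.seed(7)
  seg <- data.frame(sample_id = "S1", chrom = rep(paste0("chr", 1:4), each = 5),
                    start = rep(c(1, 101, 201, 301, 401), 4),
                    end = rep(c(100, 200, 300, 400, 500), 4),
                    total_cn = sample(0:9, 20, replace = TRUE))
  seg$minor_cn <- pmin(floor(seg$total_cn / 2),
                       sample(0:2, 20, replace = TRUE))
  cls <- classify_segments(as_segment_table(seg))
  base <- baseline_cn(cls$total_cn, cls$length)
  for (i in seq_len(nrow(cls))) {
    cb <- cls$chrom_baseline_cn[i]
    want <- if (cls$total_cn[i] == 0) "homozygous_deletion"
    else if (cls$total_cn[i] < base) "deletion"
    else if (cls$total_cn[i] >= 7 && cls$total_cn[i] > 2 * cb) "amplification"
    else if (cls$total_cn[i] > base) "gain"
    else "neutral"
    expect_equal(cls$event[i], want)
    expect_equal(cls$loh[i], cls$minor_cn[i] == 0 && cls$total_cn[i] >= 1)
    # exactly one primary state
    expect_equal(sum(cls$total_cn[i] == 0,
                     cls$total_cn[i] < base,
                     cls$total_cn[i] > base,
                     cls$total_cn[i] == base) -
                   (cls$total_cn[i] == 0), 1L)
  }
})

test_that("CIN summary computes wGII, %LOH, LST, and the WGD call", {
  seg <- as_segment_table(data.frame(
    sample_id = "S1",
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1, 50e6 + 1, 1),
    end = c(50e6, 100e6, 100e6),
    total_cn = c(3, 2, 2), minor_cn = c(1, 1, 1)))
  cs <- cin_summary(seg)
  expect_equal(cs$wgii, mean(c(0.5, 0)))       # chr1 half altered, chr2 none
  expect_equal(cs$pct_loh, 0)
  expect_equal(cs$lst, 1L)                     # one 50 Mb | 50 Mb transition
  expect_false(cs$wgd)
  flat <- as_segment_table(data.frame(
    sample_id = "S1", chrom = c("chr1", "chr2"), start = 1, end = 100e6,
    total_cn = 4, minor_cn = 2))
  cs2 <- cin_summary(flat)
  expect_equal(cs2$wgii, 0)
  expect_equal(cs2$lst, 0L)
  expect_true(cs2$wgd)                         # baseline 4 >= 3
})

test_that("wGII and %LOH are invariant to segment subdivision", {
  seg <- as_segment_table(data.frame(
    sample_id = "S1", chrom = rep(c("chr1", "chr2"), each = 2),
    start = c(1, 40e6 + 1, 1, 60e6 + 1),
    end = c(40e6, 90e6, 60e6, 80e6),
    total_cn = c(3, 2, 2, 1), minor_cn = c(1, 0, 1, 0)))
  split_first <- rbind(
    transform(seg[1, ], end = 20e6),
    transform(seg[1, ], start = 20e6 + 1),
    seg[-1, ])
  a <- cin_summary(seg)
  b <- cin_summary(as_segment_table(split_first[names(seg)]))
  expect_equal(a$wgii, b$wgii)
  expect_equal(a$pct_loh, b$pct_loh)
})

test_that("CNV truncality requires the event in every sample", {
  samples <- tiny_samples()
  mk_seg <- function(cns) do.call(rbind, lapply(seq_along(cns), function(i)
    data.frame(sample_id = samples$sample_id[i], chrom = "chr1",
               start = 1, end = 1e6, total_cn = cns[i],
               minor_cn = pmin(1, floor(cns[i] / 2)))))
  region <- data.frame(gene = "G1", chrom = "chr1", start = 100, end = 2000)
  v <- tiny_variants()[0, ]
  # gain in 3/3 (against per-sample baseline 2 segments added on chr2)
  pad <- do.call(rbind, lapply(samples$sample_id, function(s)
    data.frame(sample_id = s, chrom = "chr2", start = 1, end = 50e6,
               total_cn = 2, minor_cn = 1)))
  coh <- function(cns) patient_cohort(samples, v, rbind(mk_seg(cns), pad))
  t3 <- classify_cnv_truncality(coh(c(3, 3, 3)), region)
  expect_equal(t3$status[t3$direction == "gain"], "truncal")
  t2 <- classify_cnv_truncality(coh(c(3, 3, 2)), region)
  expect_equal(t2$status[t2$direction == "gain"], "heterogeneous")
  t0 <- classify_cnv_truncality(coh(c(2, 2, 2)), region)
  expect_false("loss" %in% t0$direction)  # loss in 0/3: no call
  expect_false("gain" %in% t0$direction)
})

test_that("WGD truncality is none / truncal / heterogeneous", {
  mk <- function(w) data.frame(patient_id = "P", sample_id = seq_along(w),
                               wgd = w)
  expect_equal(classify_wgd_truncality(mk(c(TRUE, TRUE, TRUE)))$status,
               "truncal")
  expect_equal(classify_wgd_truncality(mk(c(TRUE, FALSE, TRUE)))$status,
               "heterogeneous")
  expect_equal(classify_wgd_truncality(mk(c(FALSE, FALSE)))$status, "none")
})
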