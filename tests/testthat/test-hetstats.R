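# presence summary for hand-written per-sample (present, clonal) patterns
make_presence <- function(..., n_samples) {
  pats <- list(...)
  do.call(rbind, lapply(seq_along(pats), function(i)
    data.frame(patient_id = "P", key = paste0("m", i), gene = "",
               n_samples = n_samples, n_present = pats[[i]][1],
               n_clonal = pats[[i]][2], stringsAsFactors = FALSE)))
}

test_that("the five mutation classes are assigned per definition", {
  p <- make_presence(
    c(3, 3),  # present + clonal everywhere -> truncal
    c(3, 1),  # shared, clonal somewhere -> clonal_shared
    c(2, 0),  # shared, never clonal -> subclonal_shared
    c(1, 1),  # one site, clonal -> clonal_private
    c(1, 0),  # one site, subclonal -> subclonal_private
    n_samples = 3)
  cls <- classify_mutations(p)
  expect_equal(cls$class,
               c("truncal", "clonal_shared", "subclonal_shared",
                 "clonal_private", "subclonal_private"))
  # exhaustive: every feasible (n_present, n_clonal) combination gets
  # exactly one class
  grid <- expand.grid(n_present = 1:4, n_clonal = 0:4)
  grid <- grid[grid$n_clonal <= grid$n_present, ]
  all_p <- data.frame(patient_id = "P", key = paste0("g", seq_len(nrow(grid))),
                      gene = "", n_samples = 4, n_present = grid$n_present,
                      n_clonal = grid$n_clonal)
  out <- classify_mutations(all_p)
  expect_false(any(is.na(out$class)))
  expect_true(all(out$class %in% c("truncal", "clonal_shared",
                                   "subclonal_shared", "clonal_private",
                                   "subclonal_private")))
})

test_that("illusion of clonality matches the per-mutation formula", {
  # present in 3, clonal in 2, k = 1 -> 2/3
  p <- make_presence(c(3, 2), n_samples = 4)
  expect_equal(illusion_of_clonality(p, 1)$proportion_clonal, 2 / 3)
  # clonal everywhere -> 1 for every k
  q <- make_presence(c(4, 4), n_samples = 4)
  for (k in 1:4)
    expect_equal(illusion_of_clonality(q, k)$proportion_clonal, 1)
  expect_error(illusion_of_clonality(q, 5), "k exceeds")
})

test_that("illusion of clonality equals exhaustive subset enumeration", {
  set.seed(21)
  n <- 4
  pres <- matrix(runif(40) < 0.7, 10, n)
  pres[rowSums(pres) == 0, 1] <- TRUE
  clon <- pres & matrix(runif(40) < 0.5, 10, n)
  ptab <- data.frame(patient_id = "P", key = paste0("m", 1:10), gene = "",
                     n_samples = n, n_present = rowSums(pres),
                     n_clonal = rowSums(clon))
  for (k in 1:n) {
    oracle <- mean(apply(cbind(rowSums(pres), rowSums(clon)), 1, function(x) {
      subs <- utils::combn(n, k)
      # enumerate over abstract sample identities: clonal samples first
      is_clonal <- seq_len(n) <= x[2]
      is_present <- seq_len(n) <= x[1]
      num <- 0; den <- 0
      for (j in seq_len(ncol(subs))) {
        s <- subs[, j]
        if (!any(is_present[s])) next
        den <- den + 1
        if (all(is_clonal[s])) num <- num + 1
      }
      num / den
    }))
    expect_equal(illusion_of_clonality(ptab, k)$proportion_clonal, oracle)
  }
})

test_that("illusion of clonality is non-increasing in k", {
  set.seed(5)
  ptab <- data.frame(patient_id = "P", key = paste0("m", 1:30), gene = "",
                     n_samples = 5,
                     n_present = sample(1:5, 30, replace = TRUE))
  ptab$n_clonal <- vapply(ptab$n_present,
                          function(a) sample(0:a, 1), integer(1))
  vals <- vapply(1:5, function(k)
    illusion_of_clonality(ptab, k)$proportion_clonal, numeric(1))
  expect_false(is.unsorted(rev(vals)))
})

test_that("detection rates follow the subset combinatorics", {
  m <- matrix(c(TRUE, FALSE, FALSE), 1, 3,
              dimnames = list("alt1", c("a", "b", "c")))
  expect_equal(detection_rate(m, 1)$per_alteration[["alt1"]], 1 / 3)
  expect_equal(detection_rate(m, 2)$per_alteration[["alt1"]], 2 / 3)
  expect_equal(detection_rate(m, 3)$per_alteration[["alt1"]], 1)
  # exhaustive check and monotonicity on a random matrix
  set.seed(13)
  pm <- matrix(runif(24) < 0.4, 8, 3)
  pm[rowSums(pm) == 0, 2] <- TRUE
  rates <- vapply(1:3, function(k) {
    r <- detection_rate(pm, k)
    oracle <- mean(apply(pm, 1, function(row) {
      subs <- utils::combn(3, k)
      mean(apply(subs, 2, function(s) any(row[s])))
    }))
    expect_equal(r$patient_rate, oracle)
    r$patient_rate
  }, numeric(1))
  expect_false(is.unsorted(rates))
})

test_that("pairwise concordance is shared over union", {
  v <- tiny_variants()
  m <- pairwise_concordance(v)
  sets <- lapply(c("S1", "S2", "S3"), function(s)
    variant_key(v[v$sample_id == s & v$alt_depth >= 2, ]))
  for (i in 1:3) for (j in 1:3)
    expect_equal(m[i, j], length(intersect(sets[[i]], sets[[j]])) /
                   length(union(sets[[i]], sets[[j]])))
  # identical and disjoint edge cases
  a <- data.frame(sample_id = c("X", "Y"), chrom = "chr1", pos = 5L,
                  ref = "A", alt = "T", alt_depth = 10L, ref_depth = 10L,
                  gene = "", consequence = "other")
  expect_equal(pairwise_concordance(as_variant_table(a))["X", "Y"], 1)
  b <- a; b$pos <- c(5L, 6L)
  expect_equal(pairwise_concordance(as_variant_table(b))["X", "Y"], 0)
})

test_that("mutation presence applies the 2-read rule and sample counts", {
  coh <- tiny_cohort()
  tab <- ccf_table(coh)
  pres <- mutation_presence(tab, n_samples = c(P1 = 3))
  expect_true(all(pres$n_samples == 3))
  # chr5:500:G:C seen in S1 and S2 only
  expect_equal(pres$n_present[pres$key == "chr5:500:G:C"], 2L)
})
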