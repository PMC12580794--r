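# exhaustive oracle over all rooted labeled trees on the clusters: root must
# be clonal everywhere; every edge must satisfy dominance and the pigeonhole
# sum within tolerance; among valid trees, minimal total parent-child gap
oracle_trees <- function(centers, tol = 0.1, clonal = 0.87) {
  ids <- seq_len(nrow(centers))
  clonal_all <- apply(centers > clonal, 1, all)
  parents_of <- function(assign) assign  # assign[i] = parent of node i (0=root)
  valid <- list(); gaps <- numeric(0)
  grid <- expand.grid(rep(list(c(0, ids)), length(ids)))
  for (r in seq_len(nrow(grid))) {
    assign <- as.integer(grid[r, ])
    if (sum(assign == 0) != 1) next
    root <- which(assign == 0)
    if (!clonal_all[root]) next
    if (any(assign == ids)) next  # self-parent
    # acyclicity via repeated root-reachability
    ok <- TRUE
    for (i in ids) {
      seen <- integer(0); cur <- i
      while (assign[cur] != 0) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur); cur <- assign[cur]
      }
      if (!ok) break
    }
    if (!ok) next
    gap <- 0
    for (i in ids) {
      if (assign[i] == 0) next
      p <- centers[assign[i], ]; c <- centers[i, ]
      if (any(p < c - tol)) { ok <- FALSE; break }
      gap <- gap + sum(p - c)
    }
    if (!ok) next
    for (p in ids) {
      ch <- which(assign == p)
      if (length(ch) > 0 &&
          any(colSums(centers[ch, , drop = FALSE]) >
              centers[p, ] + tol)) { ok <- FALSE; break }
    }
    if (!ok) next
    valid[[length(valid) + 1]] <- assign
    gaps <- c(gaps, gap)
  }
  list(trees = valid, gaps = gaps)
}

phy_parent_vec <- function(phy) {
  ids <- as.integer(rownames(phy$centers))
  out <- integer(length(ids))
  par <- stats::setNames(phy$edges$parent, phy$edges$child)
  for (i in seq_along(ids))
    out[i] <- if (ids[i] == phy$root) 0L else par[[as.character(ids[i])]]
  out
}

test_that("a single clonal cluster yields a one-node trunk tree", {
  cl <- make_clusters(matrix(c(1, 1), 1, 2,
                             dimnames = list("1", c("s1", "s2"))))
  phy <- build_tree(cl)
  expect_equal(phy$root, 1L)
  expect_equal(nrow(phy$edges), 0L)
  expect_equal(unname(phy$clone_class), "trunk")
})

test_that("tree choice matches exhaustive enumeration on 3-cluster toys", {
  # chain: A = (1,1), B = (0.6,0), C = (0.3,0)
  centers <- rbind(c(1, 1), c(0.6, 0), c(0.3, 0))
  colnames(centers) <- c("s1", "s2")
  cl <- make_clusters(centers)
  phy <- build_tree(cl)
  expect_equal(phy_parent_vec(phy), c(0L, 1L, 2L))  # A -> B -> C
  orc <- oracle_trees(centers)
  best <- orc$trees[orc$gaps <= min(orc$gaps) + 1e-9]
  expect_true(any(vapply(best, identical, logical(1), phy_parent_vec(phy))))

  # B and C cannot both be children of A (0.6 + 0.6 > 1 + tol): nested chain
  centers2 <- rbind(c(1, 1), c(0.6, 0), c(0.6, 0))
  colnames(centers2) <- c("s1", "s2")
  phy2 <- build_tree(make_clusters(centers2))
  pv <- phy_parent_vec(phy2)
  orc2 <- oracle_trees(centers2)
  expect_true(any(vapply(orc2$trees, identical, logical(1), pv)))
  expect_false(identical(sort(pv), c(0L, 1L, 1L)))  # not both under A
})

test_that("no truncal cluster raises the typed error", {
  centers <- rbind(c(0.9, 0.2), c(0.2, 0.9))
  colnames(centers) <- c("s1", "s2")
  expect_error(build_tree(make_clusters(centers)),
               class = "clonemap_no_truncal_cluster")
})

test_that("clusters violating every feasible parent are removed", {
  # D (placed first, highest mean) blocks B and C under the root by the sum
  # rule, and D itself cannot dominate either of them
  centers <- rbind(c(1, 1), c(0.95, 0.05), c(0.05, 0.95), c(0.6, 0.6))
  colnames(centers) <- c("s1", "s2")
  phy <- build_tree(make_clusters(centers))
  expect_setequal(phy$removed$cluster_id, c(2L, 3L))
  # every emitted edge satisfies the constraints post hoc
  par <- stats::setNames(phy$edges$parent, phy$edges$child)
  for (ch in phy$edges$child) {
    p <- phy$centers[as.character(par[[as.character(ch)]]), ]
    expect_true(all(p >= phy$centers[as.character(ch), ] - 0.1 - 1e-12))
  }
  for (p in unique(phy$edges$parent)) {
    ch <- phy$edges$child[phy$edges$parent == p]
    expect_true(all(colSums(phy$centers[as.character(ch), , drop = FALSE]) <=
                      phy$centers[as.character(p), ] + 0.1 + 1e-12))
  }
})

test_that("clones partition into trunk, branch, and leaf", {
  centers <- rbind(c(1, 1, 1), c(0.95, 0.93, 0.97), c(0.5, 0.4, 0),
                   c(0.3, 0, 0), c(0, 0, 0.6))
  colnames(centers) <- c("liver", "lung", "bone")
  phy <- build_tree(make_clusters(centers))
  cls <- phy$clone_class
  expect_equal(unname(cls[c("1", "2")]), c("trunk", "trunk"))
  expect_equal(unname(cls[["3"]]), "branch")   # present in 2 of 3 sites
  expect_equal(unname(cls[["4"]]), "leaf")     # liver only
  expect_equal(unname(cls[["5"]]), "leaf")     # bone only
  counts <- table(factor(cls, levels = c("trunk", "branch", "leaf")))
  expect_equal(unname(c(counts)), c(2L, 1L, 2L))
  expect_equal(sum(counts), nrow(phy$centers))  # classes partition the nodes
})

test_that("a clone clonal in one site and subclonal in another seeds it", {
  centers <- rbind(c(1, 1), c(0.4, 0.98))
  colnames(centers) <- c("prostate", "liver")
  phy <- build_tree(make_clusters(centers))
  mig <- infer_migrations(phy)
  e <- mig$edges[mig$edges$clone == 2, ]
  expect_equal(e$source, "prostate")
  expect_equal(e$dest, "liver")
  expect_equal(e$kind, "seeding")
})

test_that("single-site clones contribute no migration edges", {
  centers <- rbind(c(1, 1), c(0.5, 0))
  colnames(centers) <- c("s1", "s2")
  mig <- infer_migrations(build_tree(make_clusters(centers)))
  expect_false(2 %in% mig$edges$clone)
})

test_that("seeding patterns classify monoclonal / monophyletic / polyphyletic", {
  # only the root is clonal in > 1 site
  mono <- rbind(c(1, 1, 1), c(0.4, 0, 0), c(0, 0.5, 0))
  colnames(mono) <- paste0("s", 1:3)
  m1 <- infer_migrations(build_tree(make_clusters(mono)))
  expect_equal(m1$pattern, "monoclonal")
  # chain: B clonal in s2+s3, C (child of B) clonal in s3
  chain <- rbind(c(1, 1, 1), c(0.3, 0.95, 0.9), c(0.1, 0.2, 0.88))
  colnames(chain) <- paste0("s", 1:3)
  m2 <- infer_migrations(build_tree(make_clusters(chain)))
  expect_equal(m2$pattern, "monophyletic_polyclonal")
  # siblings: B clonal in s2, C clonal in s3, incomparable
  sib <- rbind(c(1, 1, 1), c(0.3, 0.95, 0), c(0.25, 0, 0.92))
  colnames(sib) <- paste0("s", 1:3)
  m3 <- infer_migrations(build_tree(make_clusters(sib)))
  expect_equal(m3$pattern, "polyphyletic_polyclonal")
})

test_that("emitted trees satisfy the pigeonhole constraint on simulations", {
  for (s in 1:3) {
    sim <- simulate_patient(recovery_config(s, "monophyletic"), "P",
                            patient_seed = 400 + s)
    tab <- ccf_table(sim$cohort)
    cl <- prune_and_merge(cluster_ccfs(ccf_matrix(tab[tab$alt_depth >= 2, ]),
                                       k_max = 15, seed = s))
    phy <- build_tree(cl)
    for (p in unique(phy$edges$parent)) {
      ch <- phy$edges$child[phy$edges$parent == p]
      expect_true(all(colSums(phy$centers[as.character(ch), , drop = FALSE]) <=
                        phy$centers[as.character(p), ] + 0.1 + 1e-9))
    }
    expect_equal(length(phy$clone_class), nrow(phy$centers))
  }
})

test_that("Newick export encodes topology and mutation branch lengths", {
  centers <- rbind(c(1, 1), c(0.6, 0.5), c(0.3, 0.2), c(0.2, 0.4))
  colnames(centers) <- c("s1", "s2")
  phy <- build_tree(make_clusters(centers, size = 4))
  nwk <- phylo_to_newick(phy)
  tree <- ape::read.tree(text = nwk)
  expect_s3_class(tree, "phylo")
  total_nodes <- ape::Ntip(tree) + tree$Nnode
  expect_equal(total_nodes, nrow(phy$centers))
})
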