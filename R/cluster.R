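#' Per-patient CCF and depth matrices
#'
#' Reshapes a CCF table (one row per variant observation) into
#' mutation-by-sample matrices for clustering. A mutation absent from a
#' sample contributes CCF 0 with a pseudo-depth equal to that sample's
#' median sequencing depth (so absence carries likelihood weight
#' proportional to how deeply the sample was sequenced).
#'
#' @param ccf_tab CCF table from [ccf_table()], restricted to one patient.
#' @return list with matrices `ccf` and `depth` (rows = variant keys, columns
#'   = sample ids) and the named character vector `gene` (by variant key).
#' @export
ccf_matrix <- function(ccf_tab) {
  ccf_tab <- ccf_tab[!is.na(ccf_tab$ccf), , drop = FALSE]
  keys <- sort(unique(ccf_tab$key))
  samples <- sort(unique(ccf_tab$sample_id))
  ccf <- matrix(0, length(keys), length(samples),
                dimnames = list(keys, samples))
  depth <- matrix(NA_real_, length(keys), length(samples),
                  dimnames = list(keys, samples))
  idx <- cbind(match(ccf_tab$key, keys), match(ccf_tab$sample_id, samples))
  ccf[idx] <- ccf_tab$ccf
  depth[idx] <- ccf_tab$alt_depth + ccf_tab$ref_depth
  med <- apply(depth, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 100
  for (j in seq_along(samples))
    depth[is.na(depth[, j]), j] <- med[j]
  gene <- ccf_tab$gene[match(keys, ccf_tab$key)]
  names(gene) <- keys
  list(ccf = ccf, depth = round(depth), gene = gene)
}

.binom_loglik <- function(x, n, theta) {
  # rows: mutations, theta: length-S center; returns per-mutation loglik
  th <- pmin(pmax(theta, 1e-4), 1 - 1e-4)
  rowSums(stats::dbinom(x, n, rep(th, each = nrow(x)), log = TRUE))
}

.em_binom_mixture <- function(x, n, k, seed, max_iter = 200, tol = 1e-8) {
  N <- nrow(x); S <- ncol(x)
  ccf0 <- x / n
  set.seed(seed)
  if (k == 1) {
    centers <- matrix(colSums(x) / colSums(n), 1, S)
  } else {
    km <- suppressWarnings(stats::kmeans(ccf0, centers = k, nstart = 10,
                                         iter.max = 50))
    centers <- km$centers
  }
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lw <- vapply(seq_len(k),
                 function(j) log(pi_k[j]) + .binom_loglik(x, n, centers[j, ]),
                 numeric(N))
    lw <- matrix(lw, N, k)
    m <- apply(lw, 1, max)
    r <- exp(lw - m)
    rs <- rowSums(r)
    ll <- sum(m + log(rs))
    r <- r / rs
    pi_k <- colMeans(r)
    for (j in seq_len(k)) {
      w <- r[, j]
      centers[j, ] <- colSums(w * x) / pmax(colSums(w * n), 1e-12)
    }
    if (ll - ll_old < tol * abs(ll_old) + 1e-10 && iter > 3) break
    ll_old <- ll
  }
  assign <- max.col(lw, ties.method = "first")
  list(centers = centers, assignment = assign, loglik = ll,
       n_par = k * S + (k - 1))
}

#' Cluster mutations into clones by multi-sample CCF
#'
#' Fits finite mixtures of per-sample binomial likelihoods (component
#' location = the clone's per-sample CCF vector) for `k = 1..k_max` and
#' selects the model by BIC. Observed read counts are represented on the CCF
#' scale as `round(ccf * depth)` successes out of `depth` trials; absent
#' mutations contribute 0 successes out of the sample's median depth. The fit
#' is deterministic given `seed` and invariant to the input row order
#' (mutations are sorted by key internally).
#'
#' @param mats List from [ccf_matrix()] (or any list with `ccf` and `depth`
#'   matrices).
#' @param k_max Largest number of clusters tried (default 12).
#' @param seed Integer seed.
#' @return An object of class `clone_clusters`: list with `centers`
#'   (cluster-by-sample mean CCF matrix), `assignment` (named integer vector,
#'   variant key to cluster id), `ccf`, `depth`, `bic` (vector over k).
#' @export
cluster_ccfs <- function(mats, k_max = 12, seed = 1) {
  ccf <- mats$ccf
  depth <- mats$depth
  o <- order(rownames(ccf))
  ccf <- ccf[o, , drop = FALSE]
  depth <- depth[o, , drop = FALSE]
  N <- nrow(ccf)
  if (N < 3) {
    warning("fewer than 3 mutations; returning a single cluster")
    centers <- matrix(colMeans(ccf), 1, ncol(ccf),
                      dimnames = list("1", colnames(ccf)))
    assign <- stats::setNames(rep(1L, N), rownames(ccf))
    return(.new_clusters(centers, assign, ccf, depth, bic = NA_real_))
  }
  x <- round(ccf * depth)
  n <- depth
  k_max <- min(k_max, nrow(unique(ccf)), N)
  fits <- vector("list", k_max)
  bic <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    fit <- tryCatch(.em_binom_mixture(x, n, k, seed = seed + k),
                    error = function(e) NULL)
    if (is.null(fit)) next
    fits[[k]] <- fit
    bic[k] <- -2 * fit$loglik + fit$n_par * log(N)
  }
  best <- which.min(bic)
  fit <- fits[[best]]
  assign <- stats::setNames(fit$assignment, rownames(ccf))
  # relabel clusters 1..k in order of decreasing overall mean CCF, drop empty
  used <- sort(unique(assign))
  ord <- used[order(-vapply(used, function(j)
    mean(ccf[assign == j, , drop = FALSE]), numeric(1)))]
  relab <- stats::setNames(seq_along(ord), ord)
  assign <- stats::setNames(as.integer(relab[as.character(assign)]),
                            names(assign))
  centers <- .cluster_means(ccf, assign)
  .new_clusters(centers, assign, ccf, depth, bic = bic)
}

.cluster_means <- function(ccf, assign) {
  ids <- sort(unique(assign))
  centers <- t(vapply(ids, function(j)
    colMeans(ccf[assign == j, , drop = FALSE]), numeric(ncol(ccf))))
  centers <- matrix(centers, length(ids), ncol(ccf),
                    dimnames = list(ids, colnames(ccf)))
  centers
}

.new_clusters <- function(centers, assign, ccf, depth, bic = NA_real_) {
  structure(list(centers = centers, assignment = assign, ccf = ccf,
                 depth = depth, bic = bic,
                 n_mutations = stats::setNames(
                   as.integer(table(assign)[rownames(centers)]),
                   rownames(centers))),
            class = "clone_clusters")
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat("clone_clusters:", nrow(x$centers), "cluster(s) over",
      length(x$assignment), "mutations and", ncol(x$centers), "sample(s)\n")
  tab <- round(x$centers, 3)
  tab <- cbind(tab, n = x$n_mutations)
  print(tab)
  invisible(x)
}

#' Prune small clusters and merge near-identical ones
#'
#' Applies, to a fixed point, the two post-processing rules used after clone
#' clustering: (i) every cluster must be supported by at least
#' `min_mutations` mutations -- smaller clusters are dissolved and their
#' members reassigned to the nearest surviving cluster (Euclidean distance in
#' per-sample CCF space); (ii) any two clusters whose per-sample mean CCFs
#' differ by less than `merge_tol` in every sample are merged, the merged
#' mean recomputed as the mean over all member mutations per sample. When
#' several pairs are eligible the closest pair merges first, which makes the
#' fixed point independent of input order.
#'
#' @param clusters `clone_clusters`.
#' @param min_mutations Minimum cluster size (default 3).
#' @param merge_tol Per-sample mean-CCF difference below which two clusters
#'   merge (default 0.10).
#' @return `clone_clusters` after pruning and merging.
#' @export
prune_and_merge <- function(clusters, min_mutations = 3, merge_tol = 0.10) {
  assign <- clusters$assignment
  ccf <- clusters$ccf
  repeat {
    changed <- FALSE
    centers <- .cluster_means(ccf, assign)
    sizes <- table(assign)[rownames(centers)]
    # dissolve undersized clusters, smallest first
    small <- rownames(centers)[sizes < min_mutations]
    if (length(small) > 0 && nrow(centers) > 1) {
      victim <- small[order(sizes[small])][1]
      surv <- setdiff(rownames(centers), victim)
      members <- names(assign)[assign == as.integer(victim)]
      for (keym in members) {
        d <- vapply(surv, function(j)
          sqrt(sum((ccf[keym, ] - centers[j, ])^2)), numeric(1))
        assign[keym] <- as.integer(surv[which.min(d)])
      }
      changed <- TRUE
    } else {
      # merge the closest eligible pair
      ids <- rownames(centers)
      if (length(ids) > 1) {
        best <- NULL; bestd <- Inf
        for (a in seq_along(ids)) for (b in seq_len(a - 1)) {
          diffs <- abs(centers[a, ] - centers[b, ])
          if (all(diffs < merge_tol)) {
            d <- sqrt(sum(diffs^2))
            if (d < bestd) { bestd <- d; best <- c(ids[a], ids[b]) }
          }
        }
        if (!is.null(best)) {
          keep <- min(as.integer(best)); drop <- max(as.integer(best))
          assign[assign == drop] <- keep
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # compact ids, ordered by decreasing overall mean CCF
  centers <- .cluster_means(ccf, assign)
  ord <- rownames(centers)[order(-rowMeans(centers))]
  relab <- stats::setNames(seq_along(ord), ord)
  assign <- stats::setNames(as.integer(relab[as.character(assign)]),
                            names(assign))
  .new_clusters(.cluster_means(ccf, assign), assign, ccf, clusters$depth,
                bic = clusters$bic)
}

#' Reassign removed driver variants to their nearest cluster
#'
#' Variants dropped during clustering or tree building that hit a driver gene
#' are merged back into the cluster whose per-sample mean CCF is closest
#' (Euclidean distance) to the variant's own CCF vector. Ties break toward
#' the lower cluster id.
#'
#' @param clusters `clone_clusters`.
#' @param removed_ccf Matrix of CCF vectors for removed variants (rows =
#'   variant keys, columns matching `clusters$centers`).
#' @param gene Named character vector mapping removed variant keys to genes.
#' @param driver_genes Character vector of driver gene symbols.
#' @return `clone_clusters` with rescued variants added; non-driver removed
#'   variants are left out.
#' @export
rescue_drivers <- function(clusters, removed_ccf, gene, driver_genes) {
  if (is.null(removed_ccf) || nrow(removed_ccf) == 0) return(clusters)
  keys <- rownames(removed_ccf)[gene[rownames(removed_ccf)] %in% driver_genes]
  if (length(keys) == 0) return(clusters)
  assign <- clusters$assignment
  ccf <- clusters$ccf
  centers <- clusters$centers
  if (!is.null(colnames(centers)) && !is.null(colnames(removed_ccf)))
    removed_ccf <- removed_ccf[, colnames(centers), drop = FALSE]
  for (keym in keys) {
    d <- vapply(rownames(centers), function(j)
      sqrt(sum((removed_ccf[keym, ] - centers[j, ])^2)), numeric(1))
    # ties (within numerical noise) go to the lowest cluster id
    target <- as.integer(rownames(centers)[which(d <= min(d) + 1e-9)[1]])
    assign[keym] <- target
    ccf <- rbind(ccf, removed_ccf[keym, , drop = FALSE])
    rownames(ccf)[nrow(ccf)] <- keym
  }
  depth <- clusters$depth
  extra <- matrix(stats::median(depth), length(keys), ncol(depth),
                  dimnames = list(keys, colnames(depth)))
  .new_clusters(.cluster_means(ccf, assign), assign, ccf,
                rbind(depth, extra), bic = clusters$bic)
}
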