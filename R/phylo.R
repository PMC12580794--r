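#' Reconstruct a clone phylogeny under pigeonhole and infinite-sites rules
#'
#' The root is the cluster with the highest mean CCF among clusters clonal
#' (CCF above `clonal_threshold`) in every sample; without such a truncal
#' cluster no tree exists and a typed error (`clonemap_no_truncal_cluster`)
#' is raised. Remaining clusters are attached in order of decreasing mean
#' CCF. A placed node `p` is a feasible parent for cluster `c` when, in every
#' sample, `p`'s CCF is at least `c`'s CCF minus `tolerance` and the sum of
#' CCFs of `p`'s children including `c` does not exceed `p`'s CCF plus
#' `tolerance` (the pigeonhole constraint). Among feasible parents the one
#' with the smallest summed CCF gap is chosen; ties go to the deeper
#' candidate (favouring chains, i.e. parsimonious mutation accrual).
#' Clusters with no feasible parent are removed and reported.
#'
#' @param clusters `clone_clusters`.
#' @param tolerance CCF slack for the dominance and sum constraints
#'   (default 0.1).
#' @param presence_threshold Mean CCF at or above which a clone counts as
#'   present in a site (default 0.05).
#' @param clonal_threshold CCF above which a clone is clonal in a site
#'   (default 0.87).
#' @return Object of class `patient_phylogeny`: `centers`, `edges`
#'   (data.frame `parent`, `child`), `root`, `removed` (data.frame
#'   `cluster_id`, `reason`), `n_mutations`, `presence` (logical
#'   cluster-by-sample matrix), `params`.
#' @export
build_tree <- function(clusters, tolerance = 0.1, presence_threshold = 0.05,
                       clonal_threshold = 0.87) {
  centers <- clusters$centers
  ids <- as.integer(rownames(centers))
  clonal_all <- apply(centers > clonal_threshold, 1, all)
  if (!any(clonal_all)) {
    cond <- structure(
      class = c("clonemap_no_truncal_cluster", "error", "condition"),
      list(message = paste0("no truncal cluster: no cluster is clonal in ",
                            "all samples; cannot root a phylogeny"),
           call = sys.call(-1), centers = centers))
    stop(cond)
  }
  root <- ids[clonal_all][which.max(rowMeans(centers[clonal_all, , drop = FALSE]))]
  rest <- setdiff(ids[order(-rowMeans(centers))], root)
  parent <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[as.character(root)] <- 0L
  placed <- root
  removed <- data.frame(cluster_id = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  child_sum <- function(p) {
    ch <- as.integer(names(parent))[!is.na(parent) & parent == p]
    if (length(ch) == 0) return(rep(0, ncol(centers)))
    colSums(centers[as.character(ch), , drop = FALSE])
  }
  for (c_id in rest) {
    cvec <- centers[as.character(c_id), ]
    feasible <- integer(0); gaps <- numeric(0); depths <- integer(0)
    for (p in placed) {
      pvec <- centers[as.character(p), ]
      if (any(pvec < cvec - tolerance)) next
      if (any(child_sum(p) + cvec > pvec + tolerance)) next
      feasible <- c(feasible, p)
      gaps <- c(gaps, sum(pvec - cvec))
      depths <- c(depths, depth[as.character(p)])
    }
    if (length(feasible) == 0) {
      removed <- rbind(removed,
                       data.frame(cluster_id = c_id,
                                  reason = "violates pigeonhole for every feasible parent",
                                  stringsAsFactors = FALSE))
      next
    }
    o <- order(gaps, -depths)
    best <- feasible[o[1]]
    parent[as.character(c_id)] <- best
    depth[as.character(c_id)] <- depth[as.character(best)] + 1L
    placed <- c(placed, c_id)
  }
  keep <- as.character(placed)
  edges <- data.frame(parent = as.integer(parent[keep]),
                      child = as.integer(keep),
                      stringsAsFactors = FALSE)
  edges <- edges[!is.na(edges$parent), , drop = FALSE]
  rownames(edges) <- NULL
  centers_kept <- centers[keep, , drop = FALSE]
  phy <- structure(list(
    centers = centers_kept,
    edges = edges,
    root = root,
    removed = removed,
    n_mutations = clusters$n_mutations[keep],
    presence = centers_kept >= presence_threshold,
    params = list(tolerance = tolerance,
                  presence_threshold = presence_threshold,
                  clonal_threshold = clonal_threshold)),
    class = "patient_phylogeny")
  phy$clone_class <- classify_clones(phy)
  phy
}

#' @export
print.patient_phylogeny <- function(x, ...) {
  cat("patient_phylogeny:", nrow(x$centers), "clone(s),",
      ncol(x$centers), "sample(s), root =", x$root, "\n")
  if (nrow(x$removed) > 0)
    cat("removed clusters:", paste(x$removed$cluster_id, collapse = ", "), "\n")
  invisible(x)
}

.phylo_parent <- function(phy) {
  stats::setNames(phy$edges$parent, phy$edges$child)
}

.ancestors <- function(phy, id) {
  par <- .phylo_parent(phy)
  out <- integer(0)
  cur <- id
  while (!is.na(par[as.character(cur)]) &&
         length(par[as.character(cur)]) > 0 &&
         as.character(cur) %in% names(par)) {
    cur <- par[[as.character(cur)]]
    out <- c(out, cur)
  }
  out
}

.node_depth <- function(phy, id) length(.ancestors(phy, id))

#' Classify clones as trunk, branch, or leaf
#'
#' Trunk clones sit on the unbroken root path of clones that are present and
#' clonal in all sites; leaf clones are present in exactly one site; all
#' remaining clones are branch.
#'
#' @param phy `patient_phylogeny`.
#' @return Named character vector (by cluster id) with values `"trunk"`,
#'   `"branch"`, `"leaf"`.
#' @export
classify_clones <- function(phy) {
  centers <- phy$centers
  ids <- as.integer(rownames(centers))
  clonal_all <- apply(centers > phy$params$clonal_threshold, 1, all)
  names(clonal_all) <- rownames(centers)
  n_sites <- rowSums(phy$presence)
  out <- stats::setNames(rep("branch", length(ids)), rownames(centers))
  # trunk: clonal everywhere and all ancestors clonal everywhere
  for (id in ids) {
    anc <- .ancestors(phy, id)
    if (clonal_all[[as.character(id)]] &&
        all(clonal_all[as.character(anc)]))
      out[as.character(id)] <- "trunk"
  }
  out[out != "trunk" & n_sites == 1] <- "leaf"
  out
}

#' Infer seeding and migration edges between sites
#'
#' For each clone present in more than one site, sites where the clone is
#' clonal (CCF above the clonal threshold) are treated as seeding
#' destinations; a destination already explained by a clonal descendant
#' (which carried this clone's mutations with it) is skipped. The source is
#' the presence site with the highest CCF among sites where the clone is
#' subclonal; a clone clonal everywhere takes as origin the site where its
#' parent clone has the highest CCF (the root takes its own highest-CCF
#' site). Clones subclonal everywhere contribute migration edges from their
#' highest-CCF site. Using a single source per clone minimizes the number of
#' migrations.
#'
#' @param phy `patient_phylogeny`.
#' @return Object of class `migration_graph`: list with `edges` (data.frame
#'   `source`, `dest`, `clone`, `kind`), `seeding_clones` (per-site founder
#'   clones), and `pattern`.
#' @export
infer_migrations <- function(phy) {
  centers <- phy$centers
  thr <- phy$params$clonal_threshold
  sites <- colnames(centers)
  ids <- as.integer(rownames(centers))
  par <- .phylo_parent(phy)
  desc <- function(id) {
    out <- integer(0); queue <- id
    while (length(queue) > 0) {
      ch <- phy$edges$child[phy$edges$parent == queue[1]]
      out <- c(out, ch); queue <- c(queue[-1], ch)
    }
    out
  }
  edges <- list()
  for (id in ids) {
    key <- as.character(id)
    pres <- sites[phy$presence[key, ]]
    if (length(pres) < 2) next
    ccf <- centers[key, ]
    clonal_sites <- sites[ccf > thr]
    sub_sites <- setdiff(pres, clonal_sites)
    d <- desc(id)
    explained <- if (length(d) > 0)
      sites[apply(centers[as.character(d), , drop = FALSE] > thr, 2, any)]
    else character(0)
    dests <- setdiff(clonal_sites, explained)
    if (length(clonal_sites) > 0) {
      if (length(sub_sites) > 0) {
        src <- sub_sites[which.max(ccf[sub_sites])]
      } else if (!is.na(par[key] %||% NA)) {
        pvec <- centers[as.character(par[[key]]), pres]
        src <- pres[which.max(pvec)]
      } else {
        src <- pres[which.max(ccf[pres])]
      }
      dests <- setdiff(dests, src)
      for (dst in dests)
        edges[[length(edges) + 1]] <- data.frame(
          source = src, dest = dst, clone = id, kind = "seeding",
          stringsAsFactors = FALSE)
      for (dst in setdiff(sub_sites, src))
        edges[[length(edges) + 1]] <- data.frame(
          source = src, dest = dst, clone = id, kind = "migration",
          stringsAsFactors = FALSE)
    } else {
      src <- pres[which.max(ccf[pres])]
      for (dst in setdiff(pres, src))
        edges[[length(edges) + 1]] <- data.frame(
          source = src, dest = dst, clone = id, kind = "migration",
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(source = character(), dest = character(), clone = integer(),
               kind = character(), stringsAsFactors = FALSE)
  # founder clone per site: deepest clone clonal in the site that is also
  # present in another site (it must have arrived from somewhere)
  seeders <- integer(0)
  for (s in sites) {
    cand <- ids[centers[, s] > thr &
                  rowSums(phy$presence) > 1]
    if (length(cand) == 0) next
    dep <- vapply(cand, function(i) .node_depth(phy, i), integer(1))
    seeders <- c(seeders, cand[dep == max(dep)])
  }
  seeders <- sort(unique(seeders))
  g <- structure(list(edges = edges, seeding_clones = seeders,
                      pattern = NA_character_),
                 class = "migration_graph")
  g$pattern <- classify_seeding_pattern(phy, g)
  g
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Classify the metastatic seeding pattern of a patient
#'
#' Monoclonal: a single clone founded every metastatic site. Monophyletic
#' polyclonal: several founding clones, all on one ancestral root-to-leaf
#' chain. Polyphyletic polyclonal: at least two founding clones on parallel
#' branches (neither ancestral to the other).
#'
#' @param phy `patient_phylogeny`.
#' @param mig `migration_graph` from [infer_migrations()].
#' @return One of `"monoclonal"`, `"monophyletic_polyclonal"`,
#'   `"polyphyletic_polyclonal"`.
#' @export
classify_seeding_pattern <- function(phy, mig) {
  seeders <- mig$seeding_clones
  if (length(seeders) <= 1) return("monoclonal")
  for (a in seeders) for (b in seeders) {
    if (a >= b) next
    if (!(a %in% .ancestors(phy, b)) && !(b %in% .ancestors(phy, a)))
      return("polyphyletic_polyclonal")
  }
  "monophyletic_polyclonal"
}

#' Export a clone tree as a Newick string
#'
#' Branch lengths are the number of mutations assigned to the child clone;
#' node labels are the cluster ids.
#'
#' @param phy `patient_phylogeny`.
#' @return Newick string (terminated with `;`), readable with
#'   [ape::read.tree()].
#' @export
phylo_to_newick <- function(phy) {
  children <- function(id) sort(phy$edges$child[phy$edges$parent == id])
  rec <- function(id) {
    ch <- children(id)
    lab <- paste0("clone", id, ":", phy$n_mutations[[as.character(id)]])
    if (length(ch) == 0) return(lab)
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", lab)
  }
  paste0(rec(phy$root), ";")
}
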