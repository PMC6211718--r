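# Module detection: average-linkage clustering of the TOM dissimilarity and a
# hybrid dynamic tree cut.  The cut walks the dendrogram top-down, splitting a
# branch when its sub-branches look like distinct modules (tight core, clear
# gap below the merge), and finally assigns borderline leaves to the nearest
# module core.  Branch tightness and gaps are measured on merge heights
# normalized to the span between the 5th-percentile height and the maximum.

#' Average-linkage (UPGMA) hierarchical clustering of a dissimilarity matrix
#'
#' @param dissimilarity Square symmetric matrix with zero diagonal (typically
#'   `1 - TOM`).
#' @return An [stats::hclust] object.
#' @export
average_linkage_cluster <- function(dissimilarity) {
  check_square_symmetric(dissimilarity, "dissimilarity")
  if (any(abs(diag(dissimilarity)) > 1e-12)) stop2("dissimilarity diagonal must be zero")
  if (nrow(dissimilarity) < 2L) stop2("need at least 2 genes to cluster")
  stats::hclust(stats::as.dist(dissimilarity), method = "average")
}

# deep_split -> (max_core_scatter, min_gap) mapping of the hybrid procedure
deep_split_params <- function(deep_split) {
  if (!deep_split %in% 0:4) stop2("deep_split must be in 0..4")
  ms <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1L]
  list(max_core_scatter = ms, min_gap = (1 - ms) * 3 / 4)
}

#' Dynamic tree cut of a dendrogram into subnetworks
#'
#' Hybrid-style adaptive cut: merges in the top `1 - cut_height` fraction of
#' the normalized height range are always split; below that, a branch is split
#' when each sub-branch of admissible size has a tight core (core scatter at
#' most `max_core_scatter`) and attaches to its parent with a clear gap (at
#' least `min_gap`); a terminal branch becomes a module when it has at least
#' `min_size` leaves and a tight core.  Leaves left over (outliers, small
#' side-branches) are then assigned to the closest module core when their
#' normalized mean dissimilarity to it is within `max_core_scatter`, and
#' labeled 0 otherwise.  `deep_split` (0..4) tunes `max_core_scatter`
#' in {0.64, 0.73, 0.82, 0.91, 0.95} with `min_gap = (1 -
#' max_core_scatter) * 3/4`; larger values split more aggressively.
#'
#' @param dendrogram [stats::hclust] object from [average_linkage_cluster()].
#' @param dissimilarity The matrix the dendrogram was built from.
#' @param deep_split Split sensitivity, integer 0..4 (default 2).
#' @param min_size Minimum module size (default 10).
#' @param cut_height Normalized static-cut level in (0, 1] (default 0.99).
#' @return Integer vector of module labels (0 = unassigned) named by gene,
#'   labels contiguous from 1 and ordered by decreasing module size.
#' @export
dynamic_tree_cut <- function(dendrogram, dissimilarity, deep_split = 2,
                             min_size = 10, cut_height = 0.99) {
  stopifnot(inherits(dendrogram, "hclust"))
  if (min_size < 2) stop2("min_size must be >= 2")
  n <- length(dendrogram$order)
  if (nrow(dissimilarity) != n)
    stop2("dendrogram and dissimilarity disagree on the number of genes")
  pars <- deep_split_params(deep_split)
  ms <- pars$max_core_scatter
  mg <- pars$min_gap

  h <- dendrogram$height
  merge <- dendrogram$merge
  q05 <- stats::quantile(h, 0.05, names = FALSE)
  span <- max(h) - q05
  norm_h <- if (span > 0) pmax(0, pmin(1, (h - q05) / span)) else rep(0, n - 1L)

  core_size <- as.integer(min(min_size, n))
  # per merge node: leaves, size, and the smallest internal normalized merge
  # heights (enough of them to compute any core scatter)
  leaves <- vector("list", n - 1L)
  low_h <- vector("list", n - 1L)
  node_leaves <- function(x) if (x < 0) -x else leaves[[x]]
  node_lowh <- function(x) if (x < 0) numeric(0) else low_h[[x]]
  for (i in seq_len(n - 1L)) {
    l <- merge[i, 1L]; r <- merge[i, 2L]
    leaves[[i]] <- c(node_leaves(l), node_leaves(r))
    hh <- sort(c(node_lowh(l), node_lowh(r), norm_h[i]))
    low_h[[i]] <- utils::head(hh, core_size - 1L)
  }
  node_size <- function(x) if (x < 0) 1L else length(leaves[[x]])
  # mean height of the earliest merges inside the branch (its "core")
  scatter <- function(x) {
    if (x < 0) return(0)
    k <- min(core_size - 1L, length(low_h[[x]]))
    mean(low_h[[x]][seq_len(k)])
  }
  root_h <- function(x) if (x < 0) 0 else norm_h[x]

  qualifies <- function(x, parent_h) {
    node_size(x) >= min_size &&
      scatter(x) <= ms &&
      (parent_h - root_h(x)) >= mg
  }

  modules <- list()
  floating <- integer(0)
  work <- c(n - 1L)                      # root merge; leaves coded negative
  while (length(work) > 0L) {
    node <- work[[length(work)]]
    work <- work[-length(work)]
    if (node < 0) { floating <- c(floating, -node); next }
    l <- merge[node, 1L]; r <- merge[node, 2L]
    if (norm_h[node] > cut_height) {     # static part of the cut
      work <- c(work, l, r)
      next
    }
    ql <- qualifies(l, norm_h[node])
    qr <- qualifies(r, norm_h[node])
    if (ql && qr) {
      work <- c(work, l, r)
    } else if (ql || qr) {
      good <- if (ql) l else r
      other <- if (ql) r else l
      work <- c(work, good)
      if (node_size(other) < min_size) {
        floating <- c(floating, node_leaves(other))
      } else {
        work <- c(work, other)
      }
    } else {
      lv <- leaves[[node]]
      if (length(lv) >= min_size && scatter(node) <= ms) {
        modules[[length(modules) + 1L]] <- lv
      } else {
        floating <- c(floating, lv)
      }
    }
  }

  # assignment stage: attach leftover leaves to the nearest module core
  labels <- integer(n)
  for (m in seq_along(modules)) labels[modules[[m]]] <- m
  if (length(modules) > 0L && length(floating) > 0L) {
    cores <- lapply(modules, function(lv) {
      within_mean <- rowMeans(dissimilarity[lv, lv, drop = FALSE])
      lv[order(within_mean)][seq_len(min(core_size, length(lv)))]
    })
    for (g in floating) {
      d <- vapply(cores, function(co) mean(dissimilarity[g, co]), 0)
      best <- which.min(d)
      d_norm <- if (span > 0) (d[best] - q05) / span else 0
      if (d_norm <= ms) labels[g] <- best
    }
  }

  relabel_by_size(labels, rownames(dissimilarity))
}

# contiguous labels 1..m ordered by decreasing size (ties: first occurrence)
relabel_by_size <- function(labels, gene_ids = NULL) {
  pos <- which(labels > 0)
  if (length(pos) > 0L) {
    tab <- table(labels[pos])
    first_seen <- vapply(names(tab), function(l) min(which(labels == as.integer(l))), 0L)
    ord <- names(tab)[order(-as.integer(tab), first_seen)]
    map <- stats::setNames(seq_along(ord), ord)
    labels[pos] <- map[as.character(labels[pos])]
  }
  labels <- as.integer(labels)
  if (!is.null(gene_ids)) names(labels) <- gene_ids
  labels
}

#' Extract candidate subnetworks from a module partition
#'
#' Drops unassigned genes (label 0) and modules outside `[min_size,
#' max_size]`, and annotates each retained module's internal edges with TOM
#' weight and a prior (PPI) flag.
#'
#' @param partition Labels from [dynamic_tree_cut()] (named by gene).
#' @param tom TOM matrix with matching gene dimnames.
#' @param prior A [relation_network()] or binary prior matrix.
#' @param min_size,max_size Retained size range (defaults 10 and 500, the
#'   gene-set size filter used downstream).
#' @param id_prefix Prefix for subnetwork identifiers (e.g. the correlation
#'   source tag); ids are `prefix` + rank by decreasing size.
#' @return List with `sets` (named list of gene vectors, GMT-ready) and
#'   `subnetworks` (list of objects with `id`, `members`, `edges`).
#' @export
extract_subnetworks <- function(partition, tom, prior, min_size = 10,
                                max_size = 500, id_prefix = "SN") {
  stopifnot(!is.null(names(partition)), !is.null(rownames(tom)))
  if (inherits(prior, "relation_network"))
    prior <- prior_matrix(prior, rownames(tom))
  keep_labels <- names(which(table(partition[partition > 0]) >= min_size &
                               table(partition[partition > 0]) <= max_size))
  keep_labels <- keep_labels[order(as.integer(keep_labels))]
  sets <- list()
  subnetworks <- list()
  for (i in seq_along(keep_labels)) {
    lab <- as.integer(keep_labels[i])
    members <- names(partition)[partition == lab]
    id <- paste0(id_prefix, i)
    sets[[id]] <- members
    tm <- tom[members, members, drop = FALSE]
    pm <- prior[members, members, drop = FALSE]
    idx <- which(upper.tri(tm), arr.ind = TRUE)
    subnetworks[[id]] <- list(
      id = id, members = members,
      edges = data.frame(from = members[idx[, 1L]],
                         to = members[idx[, 2L]],
                         tom_weight = tm[idx],
                         is_ppi = as.integer(pm[idx]),
                         stringsAsFactors = FALSE))
  }
  list(sets = sets, subnetworks = subnetworks)
}
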