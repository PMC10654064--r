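#' Exact partition of the abundance-growth space
#'
#' Groups grid points whose qualitative vectors over the selected reactions
#' are identical.  Zone labels are deterministic: zones are numbered by the
#' lexicographically smallest (first) member point in grid order.
#'
#' @param matrix a \code{phenotype_matrix}.
#' @return an object of class \code{ag_partition}: list with \code{zone}
#'   (integer per point), \code{descriptors} (one row per zone, the shared
#'   vector) and \code{points}.
#' @export
exact_partition <- function(matrix) {
  key <- apply(matrix$states, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  levels <- key[first]               # in order of first appearance
  zone <- match(key, levels)
  desc <- matrix$states[first, , drop = FALSE]
  rownames(desc) <- paste0("zone", seq_along(levels))
  structure(list(zone = zone, descriptors = desc, points = matrix$points),
            class = "ag_partition")
}

#' @export
print.ag_partition <- function(x, ...) {
  cat("<ag_partition> ", nrow(x$descriptors), " zones over ",
      length(x$zone), " points\n", sep = "")
  invisible(x)
}

## one-hot encoding of (reaction, category) indicators per point
onehot_states <- function(states) {
  blocks <- lapply(seq_len(ncol(states)), function(j) {
    cats <- sort(unique(states[, j]))
    m <- outer(states[, j], cats, `==`) * 1L
    colnames(m) <- paste0(colnames(states)[j], "=", cats)
    m
  })
  do.call(cbind, blocks)
}

#' Cluster-partition of the abundance-growth space
#'
#' One-hot encodes each point's (reaction, category) indicators, computes
#' pairwise binary Jaccard distances, clusters them by agglomerative
#' hierarchical clustering (average linkage by default) and cuts the tree at
#' \code{k} clusters.  A consensus descriptor is attached per cluster: the
#' state held by strictly more than \code{consensus} of its points, else
#' no-consensus (\code{NA}, rendered as an empty cell in tables).
#'
#' Distances are rounded to 12 decimals before linkage so dendrogram
#' tie-breaking is deterministic across platforms.
#'
#' @param matrix a \code{phenotype_matrix}.
#' @param k number of clusters (at most the number of distinct vectors).
#' @param linkage one of "average", "single", "complete", "ward.D2".
#' @param consensus consensus threshold (default 0.80; strict inequality).
#' @return an object of class \code{ag_clustering}: list with \code{cluster}
#'   (id per point), \code{consensus} (clusters x reactions character matrix
#'   with \code{NA} for no consensus), \code{ordering} (display order, see
#'   \code{\link{order_clusters}}), \code{k}, and the inputs needed by
#'   downstream summaries.
#' @export
cluster_partition <- function(matrix, k, linkage = "average",
                              consensus = 0.80) {
  st <- matrix$states
  ndistinct <- nrow(unique(st))
  if (k > ndistinct)
    stop("k = ", k, " exceeds the number of distinct vectors (", ndistinct, ")")
  enc <- onehot_states(st)
  d <- stats::dist(enc, method = "binary")   # Jaccard distance on indicators
  d <- round(d, 12)
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = k)
  cons <- consensus_matrix(st, cl, consensus)
  ord <- order_clusters_internal(matrix$points, cl)
  structure(list(cluster = cl, consensus = cons, ordering = ord, k = k,
                 linkage = linkage, threshold = consensus,
                 points = matrix$points, states = st),
            class = "ag_clustering")
}

#' Consensus descriptor of a set of points
#'
#' For each reaction, returns the category held by strictly more than
#' \code{threshold} of the points, or \code{NA} (no consensus).
#'
#' @param states character matrix (points x reactions).
#' @param threshold consensus fraction (default 0.80).
#' @return named character vector, \code{NA} where no state dominates.
#' @export
consensus_descriptor <- function(states, threshold = 0.80) {
  if (nrow(states) == 0L) stop("empty cluster")
  out <- vapply(seq_len(ncol(states)), function(j) {
    tb <- table(states[, j])
    top <- which.max(tb)
    if (tb[top] / nrow(states) > threshold) names(tb)[top] else NA_character_
  }, character(1))
  stats::setNames(out, colnames(states))
}

consensus_matrix <- function(states, cluster, threshold) {
  ids <- sort(unique(cluster))
  out <- t(vapply(ids, function(cid)
    consensus_descriptor(states[cluster == cid, , drop = FALSE], threshold),
    character(ncol(states))))
  rownames(out) <- paste0("cluster", ids)
  out
}

order_clusters_internal <- function(points, cluster) {
  ids <- sort(unique(cluster))
  mu_mean <- vapply(ids, function(cid) mean(points$mu[cluster == cid]),
                    numeric(1))
  f_mean <- vapply(ids, function(cid) mean(points$f1[cluster == cid]),
                   numeric(1))
  ids[order(mu_mean, f_mean)]
}

#' Display order of clusters
#'
#' Clusters sorted by mean growth rate, ties broken by the mean abundance of
#' the first member — the low-growth, low-f1 cluster comes first, matching
#' the way cluster tables are laid out.
#'
#' @param partition an \code{ag_clustering}.
#' @return integer vector of cluster ids in display order.
#' @export
order_clusters <- function(partition) partition$ordering

#' Reactions whose consensus state changes between clusters
#'
#' A reaction changes if its consensus state differs between at least two
#' clusters; a no-consensus entry counts as differing from any state.
#'
#' @param partition an \code{ag_clustering}.
#' @return character vector of reaction ids.
#' @export
changing_reactions <- function(partition) {
  cons <- partition$consensus
  chg <- vapply(seq_len(ncol(cons)), function(j) {
    s <- cons[, j]
    any(is.na(s)) || length(unique(s)) > 1L
  }, logical(1))
  colnames(cons)[chg]
}

#' Select the number of clusters
#'
#' For each candidate k, each reaction is scored by the fraction of grid
#' points whose state equals the modal (plurality) state of their cluster;
#' returns the smallest k at which every reaction scores at least
#' \code{threshold}.  If no candidate reaches it, the maximum of the range is
#' returned with a warning.
#'
#' @param matrix a \code{phenotype_matrix}.
#' @param k_range candidate cluster counts (default 1 to the number of
#'   distinct vectors).
#' @param threshold required per-reaction score (default 0.80, inclusive).
#' @param linkage linkage method, as in \code{\link{cluster_partition}}.
#' @return the selected k (integer).
#' @export
select_cluster_count <- function(matrix, k_range = NULL, threshold = 0.80,
                                 linkage = "average") {
  st <- matrix$states
  ndistinct <- nrow(unique(st))
  if (is.null(k_range)) k_range <- seq_len(ndistinct)
  if (!length(k_range)) stop("empty k_range")
  k_range <- sort(unique(pmin(k_range, ndistinct)))
  enc <- onehot_states(st)
  d <- round(stats::dist(enc, method = "binary"), 12)
  hc <- stats::hclust(d, method = linkage)
  for (k in k_range) {
    cl <- stats::cutree(hc, k = k)
    sc <- reaction_scores(st, cl)
    if (all(sc >= threshold)) return(as.integer(k))
  }
  warning("no k in range reaches a score of ", threshold,
          " for every reaction; returning max(k_range)")
  as.integer(max(k_range))
}

## fraction of points matching their cluster's modal state, per reaction
reaction_scores <- function(states, cluster) {
  ids <- unique(cluster)
  hits <- matrix(0, length(ids), ncol(states))
  sizes <- vapply(ids, function(cid) sum(cluster == cid), numeric(1))
  for (a in seq_along(ids)) {
    sub <- states[cluster == ids[a], , drop = FALSE]
    hits[a, ] <- vapply(seq_len(ncol(sub)),
                        function(j) max(table(sub[, j])), numeric(1))
  }
  stats::setNames(colSums(hits) / sum(sizes), colnames(states))
}

#' @export
print.ag_clustering <- function(x, ...) {
  cat("<ag_clustering> k = ", x$k, " (", x$linkage, " linkage, consensus > ",
      x$threshold, ")\n", sep = "")
  cat("  changing reactions: ", length(changing_reactions(x)), " of ",
      ncol(x$consensus), "\n", sep = "")
  invisible(x)
}

#' Consensus table in display order
#'
#' Reactions x ordered clusters; no-consensus entries are empty cells.
#'
#' @param partition an \code{ag_clustering}.
#' @param changing_only keep only reactions that change between clusters.
#' @return character data frame (reactions as rows).
#' @export
consensus_table <- function(partition, changing_only = FALSE) {
  cons <- partition$consensus[paste0("cluster", partition$ordering), ,
                              drop = FALSE]
  tab <- t(cons)
  if (changing_only)
    tab <- tab[rownames(tab) %in% changing_reactions(partition), ,
               drop = FALSE]
  tab[is.na(tab)] <- ""
  as.data.frame(tab, stringsAsFactors = FALSE)
}

#' Plot a two-member cluster-partition
#'
#' @param x an \code{ag_clustering} over a two-member grid.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.ag_clustering <- function(x, ...) {
  pts <- x$points
  if (!"f1" %in% names(pts) || "f3" %in% names(pts))
    stop("plotting is implemented for two-member grids")
  disp <- match(x$cluster, x$ordering)
  pal <- grDevices::hcl.colors(max(disp), "Spectral")
  graphics::plot(pts$f1, pts$mu, pch = 15, cex = 0.9, col = pal[disp],
                 xlab = expression(f[1]), ylab = expression(mu ~ "(1/h)"),
                 ...)
  invisible(x)
}
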