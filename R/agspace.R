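#' Abundance-growth space analysis of a community model
#'
#' The main entry point: discretizes the abundance-growth space of a
#' community model, classifies the selected reactions' flux-variability
#' ranges into qualitative plasticity states at every feasible point, and
#' partitions the space both exactly (identical state vectors) and by
#' Jaccard/hierarchical clustering with consensus descriptors.
#'
#' @param community a \code{community_model}.
#' @param l grid resolution (values per axis, >= 2).
#' @param rxns selected reaction set R'; \code{"exchanges"} (community
#'   exchange reactions, the default), \code{"all"}, or a character vector.
#' @param k number of clusters; \code{"auto"} selects the smallest k whose
#'   per-reaction consensus scores all reach \code{threshold}.
#' @param eps zero tolerance for state classification.
#' @param linkage clustering linkage (default "average").
#' @param threshold consensus threshold (default 0.80).
#' @param efficiency_factor optional energy-efficiency factor (>= 1); when
#'   set, every point's polytope is restricted to
#'   \eqn{\sum |v| \le factor \cdot S_{min}} before classification.
#' @param progress print progress dots.
#' @return an object of class \code{agspace}: list with \code{community},
#'   \code{grid}, \code{matrix} (\code{phenotype_matrix}),
#'   \code{partition} (\code{ag_partition}), \code{clustering}
#'   (\code{ag_clustering}) and \code{call}.
#' @examples
#' cm <- make_crossfeeding_community(toy_spec())
#' res <- agspace(cm, l = 5, k = 2)
#' summary(res)
#' @export
agspace <- function(community, l = 10, rxns = "exchanges", k = "auto",
                    eps = 1e-9, linkage = "average", threshold = 0.80,
                    efficiency_factor = NULL, progress = FALSE) {
  rset <- if (identical(rxns, "exchanges")) community$exchange_ids
          else if (identical(rxns, "all")) colnames(community$S)
          else rxns
  grid <- build_grid(community, l, progress = progress)
  constrain <- NULL
  if (!is.null(efficiency_factor))
    constrain <- function(cmod)
      add_efficiency_constraint(cmod, efficiency_factor)
  mat <- phenotype_matrix(community, grid, rset, eps = eps,
                          constrain = constrain, progress = progress)
  part <- exact_partition(mat)
  if (identical(k, "auto"))
    k <- select_cluster_count(mat, threshold = threshold, linkage = linkage)
  clus <- cluster_partition(mat, k, linkage = linkage,
                            consensus = threshold)
  structure(list(community = community, grid = grid, matrix = mat,
                 partition = part, clustering = clus,
                 call = match.call()),
            class = "agspace")
}

#' @export
print.agspace <- function(x, ...) {
  cat("Abundance-growth space analysis\n")
  cat("  members    : ", paste(x$community$members, collapse = ", "),
      "\n", sep = "")
  cat("  grid       : l = ", attr(x$grid, "l"), ", ", sum(x$grid$feasible),
      " of ", nrow(x$grid), " points feasible, MAXbiomass = ",
      signif(attr(x$grid, "max_biomass"), 6), " 1/h\n", sep = "")
  cat("  reactions  : ", ncol(x$matrix$states), " analyzed\n", sep = "")
  cat("  partition  : ", nrow(x$partition$descriptors), " exact zones; ",
      x$clustering$k, " clusters (", length(changing_reactions(x$clustering)),
      " changing reactions)\n", sep = "")
  invisible(x)
}

#' @export
summary.agspace <- function(object, ...) {
  structure(list(grid = summary(object$grid),
                 matrix = summary(object$matrix),
                 k = object$clustering$k,
                 n_zones = nrow(object$partition$descriptors),
                 changing = changing_reactions(object$clustering)),
            class = "summary.agspace")
}

#' @export
print.summary.agspace <- function(x, ...) {
  print(x$grid)
  print(x$matrix)
  cat("Partitioning: ", x$n_zones, " exact zones, k = ", x$k,
      " clusters\n", sep = "")
  cat("Changing reactions (", length(x$changing), "): ",
      paste(x$changing, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot an abundance-growth space analysis
#'
#' @param x an \code{agspace} object (two-member community).
#' @param which \code{"clusters"} (default) or \code{"feasibility"}.
#' @param ... passed to the underlying plot method.
#' @export
plot.agspace <- function(x, which = c("clusters", "feasibility"), ...) {
  which <- match.arg(which)
  if (which == "feasibility") plot(x$grid, ...)
  else plot(x$clustering, ...)
  invisible(x)
}
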