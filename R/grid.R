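#' Enumerate abundance points on the simplex
#'
#' All N-tuples drawn from \code{l} equidistant values spanning \[0, 1\] that
#' sum to one (tolerance 1e-9), in lexicographic order.
#'
#' @param n_members number of community members N.
#' @param l grid resolution (number of values per coordinate, >= 2).
#' @return matrix with one row per abundance point and N columns.
#' @export
abundance_points <- function(n_members, l) {
  stopifnot(l >= 2, n_members >= 1)
  vals <- seq(0, 1, length.out = l)
  if (n_members == 1L) return(matrix(1, 1, 1))
  grid <- as.matrix(do.call(expand.grid,
                            rev(replicate(n_members, vals, simplify = FALSE))))
  grid <- grid[, rev(seq_len(n_members)), drop = FALSE]   # f1 varies slowest
  keep <- abs(rowSums(grid) - 1) <= 1e-9
  A <- grid[keep, , drop = FALSE]
  colnames(A) <- paste0("f", seq_len(n_members))
  ord <- do.call(order, as.data.frame(A))
  unname(A[ord, , drop = FALSE])
}

#' Maximal community growth over a set of abundance points
#'
#' @param community a \code{community_model}.
#' @param A matrix of abundance points (rows).
#' @return the largest \code{\link{max_growth}} over the rows of \code{A};
#'   errors if every point is infeasible.
#' @export
compute_max_biomass <- function(community, A) {
  if (nrow(A) == 0L) stop("A must contain at least one abundance point")
  mg <- apply(A, 1, function(f) max_growth(community, f))
  if (all(is.na(mg))) stop("no abundance point admits a feasible model")
  max(mg, na.rm = TRUE)
}

#' Discretize the abundance-growth space
#'
#' Builds the grid of candidate abundance-growth points: abundance points on
#' the simplex from \code{l} equidistant values per coordinate, crossed with
#' \code{l} equidistant growth values in \[0, MAXbiomass\], where MAXbiomass
#' is the maximal growth rate over the abundance points themselves.  Every
#' candidate is then tested for feasibility of its balanced-growth LP.
#'
#' @param community a \code{community_model}.
#' @param l grid resolution (>= 2).
#' @param progress print a dot per abundance column (default \code{FALSE}).
#' @return an object of class \code{ag_grid}: a data frame with abundance
#'   columns \code{f1..fN}, \code{mu} and logical \code{feasible}, plus
#'   attributes \code{l}, \code{max_biomass}, \code{abundance_values},
#'   \code{growth_values} and \code{members}.
#' @export
build_grid <- function(community, l, progress = FALSE) {
  stopifnot(l >= 2)
  N <- length(community$members)
  A <- abundance_points(N, l)
  mg <- apply(A, 1, function(f) max_growth(community, f))
  if (all(is.na(mg))) stop("no abundance point admits a feasible model")
  maxb <- max(mg, na.rm = TRUE)
  gv <- seq(0, maxb, length.out = l)
  ## candidates in deterministic lexicographic (mu, f1, ...) order
  cand <- do.call(rbind, lapply(gv, function(mu)
    cbind(A, mu = mu)))
  feasible <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ai <- ((i - 1L) %% nrow(A)) + 1L
    mu_i <- cand[i, N + 1L]
    ## no feasible point can exceed the per-abundance maximum, so prune
    ## above it; below it the LP is solved (minimal growth may be > 0)
    if (is.na(mg[ai]) || mu_i > mg[ai] + 1e-9) {
      feasible[i] <- FALSE
    } else {
      feasible[i] <- is_feasible(community, cand[i, seq_len(N)], mu_i)
    }
    if (progress && i %% nrow(A) == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- as.data.frame(cand)
  names(out) <- c(paste0("f", seq_len(N)), "mu")
  out$feasible <- feasible
  structure(out, class = c("ag_grid", "data.frame"),
            l = l, max_biomass = maxb,
            abundance_values = seq(0, 1, length.out = l),
            growth_values = gv, members = community$members)
}

#' @export
print.ag_grid <- function(x, ...) {
  cat("<ag_grid> l = ", attr(x, "l"), ", members: ",
      paste(attr(x, "members"), collapse = ", "), "\n", sep = "")
  cat("  MAXbiomass = ", signif(attr(x, "max_biomass"), 6), " 1/h\n", sep = "")
  cat("  candidates: ", nrow(x), "   feasible: ", sum(x$feasible),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.ag_grid <- function(object, ...) {
  fe <- object[object$feasible, , drop = FALSE]
  structure(list(l = attr(object, "l"),
                 members = attr(object, "members"),
                 max_biomass = attr(object, "max_biomass"),
                 n_candidates = nrow(object),
                 n_feasible = nrow(fe),
                 mu_range = if (nrow(fe)) range(fe$mu) else c(NA, NA)),
            class = "summary.ag_grid")
}

#' @export
print.summary.ag_grid <- function(x, ...) {
  cat("Abundance-growth grid (l = ", x$l, ", N = ", length(x$members),
      ")\n", sep = "")
  cat("  candidate points : ", x$n_candidates, "\n", sep = "")
  cat("  feasible points  : ", x$n_feasible, "\n", sep = "")
  cat("  MAXbiomass       : ", signif(x$max_biomass, 6), " 1/h\n", sep = "")
  invisible(x)
}

#' Plot the feasibility mask of a two-member grid
#'
#' @param x an \code{ag_grid} for a two-member community.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.ag_grid <- function(x, ...) {
  if (!"f2" %in% names(x) || "f3" %in% names(x))
    stop("plotting is implemented for two-member grids")
  graphics::plot(x$f1, x$mu, pch = 15, cex = 0.8,
                 col = ifelse(x$feasible, "steelblue4", "grey85"),
                 xlab = expression(f[1]), ylab = expression(mu ~ "(1/h)"),
                 ...)
  invisible(x)
}

#' Feasible points of a grid
#'
#' @param grid an \code{ag_grid}.
#' @return data frame of the feasible rows (abundances and \code{mu}).
#' @export
feasible_points <- function(grid) {
  out <- as.data.frame(grid)[grid$feasible,
                             setdiff(names(grid), "feasible"),
                             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a grid to TSV with a JSON sidecar
#'
#' @param grid an \code{ag_grid}.
#' @param path output TSV path; the sidecar is written to
#'   \code{<path>.json}.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(l = attr(grid, "l"),
               max_biomass = attr(grid, "max_biomass"),
               members = attr(grid, "members"),
               solver = "agspace dense simplex",
               feasibility_tol = 1e-9)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
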