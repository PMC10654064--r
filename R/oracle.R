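#' Brute-force flux ranges by vertex enumeration
#'
#' Independent oracle for flux variability analysis on small models: the flux
#' polytope is projected onto the nullspace of the mass-balance system and all
#' of its vertices are enumerated as intersections of d linearly independent
#' active bound constraints.  Per-reaction ranges are the min/max over the
#' vertex set.  Shares no code with the simplex-based FVA path.
#'
#' @param cmod a \code{constrained_model}.
#' @param rxns reaction ids to report (default: all).
#' @param max_subsets guard on the number of active-set candidates (the model
#'   is "too large" beyond it).
#' @return \code{NULL} when the polytope is empty, otherwise a data frame
#'   with columns \code{rxn}, \code{min}, \code{max}.
#' @export
brute_force_ranges <- function(cmod, rxns = NULL, max_subsets = 2e6) {
  S <- cmod$community$S
  if (is.null(rxns)) rxns <- colnames(S)
  lb <- unname(cmod$lb); ub <- unname(cmod$ub)
  n <- ncol(S)
  tol <- 1e-7

  if (any(lb > ub + 1e-12)) return(NULL)
  fixed <- (ub - lb) <= 1e-12
  xfix <- ifelse(fixed, (lb + ub) / 2, 0)
  free <- which(!fixed)
  A <- S[, free, drop = FALSE]
  b <- -as.numeric(S[, fixed, drop = FALSE] %*% xfix[fixed])

  if (length(free) == 0L) {
    if (max(abs(as.numeric(S %*% xfix))) > tol) return(NULL)
    V <- matrix(xfix, 1L, n, dimnames = list(NULL, colnames(S)))
    return(vertex_ranges(V, rxns))
  }

  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  r <- sum(sv$d > max(dim(A)) * max(sv$d, 0) * 1e-12)
  ## particular solution via pseudo-inverse; must be consistent
  x0f <- as.numeric(
    sv$v[, seq_len(r), drop = FALSE] %*%
      (as.numeric(crossprod(sv$u[, seq_len(r), drop = FALSE], b)) /
         sv$d[seq_len(r)]))
  if (length(x0f) == 0L) x0f <- numeric(ncol(A))
  if (max(abs(A %*% x0f - b)) > 1e-6) return(NULL)
  B <- sv$v[, seq_len(ncol(A)) > r, drop = FALSE]   # nullspace basis
  d <- ncol(B)
  x0 <- xfix; x0[free] <- x0f

  ## halfspaces G z <= h in nullspace coordinates
  G <- rbind(B, -B)
  h <- c(ub[free] - x0f, x0f - lb[free])
  if (length(cmod$extra)) {
    Ex <- do.call(rbind, lapply(cmod$extra, function(e) e$coef[free]))
    G <- rbind(G, Ex %*% B)
    h <- c(h, vapply(cmod$extra, `[[`, numeric(1), "rhs") -
             as.numeric(do.call(rbind, lapply(cmod$extra, `[[`, "coef")) %*% x0))
  }
  ## drop numerically null rows
  keep <- rowSums(abs(G)) > 1e-10
  G2 <- G[keep, , drop = FALSE]; h2 <- h[keep]
  if (any(h[!keep] < -tol)) return(NULL)

  if (d == 0L) {
    if (any(h2 < -tol)) return(NULL)
    V <- matrix(x0, 1L, n, dimnames = list(NULL, colnames(S)))
    return(vertex_ranges(V, rxns))
  }
  m <- nrow(G2)
  if (choose(m, d) > max_subsets)
    stop("model too large for vertex enumeration (", m, " halfspaces, ",
         d, " degrees of freedom)")
  combs <- utils::combn(m, d)
  verts <- list()
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    Gs <- G2[idx, , drop = FALSE]
    z <- tryCatch(solve(Gs, h2[idx]), error = function(e) NULL)
    if (is.null(z) || any(!is.finite(z))) next
    if (all(G2 %*% z <= h2 + tol)) verts[[length(verts) + 1L]] <- z
  }
  if (!length(verts)) return(NULL)
  Z <- do.call(rbind, verts)
  V <- matrix(rep(x0, each = nrow(Z)), nrow(Z), n)
  V[, free] <- V[, free] + Z %*% t(B)
  colnames(V) <- colnames(S)
  vertex_ranges(V, rxns)
}

vertex_ranges <- function(V, rxns) {
  data.frame(rxn = rxns,
             min = apply(V[, rxns, drop = FALSE], 2, min),
             max = apply(V[, rxns, drop = FALSE], 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Brute-force feasibility of an abundance-growth point
#'
#' Oracle counterpart of \code{\link{is_feasible}}: the point is feasible iff
#' the vertex enumeration finds at least one vertex.
#'
#' @inheritParams is_feasible
#' @return \code{TRUE} or \code{FALSE}.
#' @export
brute_force_feasible <- function(community, F, mu) {
  cmod <- apply_point(community, F, mu)
  !is.null(brute_force_ranges(cmod, rxns = colnames(community$S)[1]))
}
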