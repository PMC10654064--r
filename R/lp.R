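## Dense two-phase simplex for the small LPs arising from community models.
##
## All feasible regions handled here are boxes intersected with equality
## (mass-balance) and optional inequality rows, so every variable carries
## finite bounds and phase 2 can only be unbounded if a caller passes an
## infinite bound explicitly.

#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to \code{Aeq x = beq},
#' \code{Ain x <= bin} and \code{lb <= x <= ub}, with a deterministic
#' two-phase tableau simplex using Bland's anti-cycling rule.  The final
#' solution is re-solved from the optimal basis by QR factorization, so
#' returned fluxes are accurate to machine precision rather than to the
#' accumulated tableau error.
#'
#' @param obj numeric objective coefficients (length = number of variables).
#' @param Aeq numeric matrix of equality constraints (may have 0 rows).
#' @param beq right-hand side of the equality constraints.
#' @param lb,ub finite lower/upper variable bounds.
#' @param Ain,bin optional inequality constraints \code{Ain x <= bin}.
#' @param maximize if \code{TRUE} maximize instead of minimize.
#' @param tol pivot/feasibility tolerance.
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{objval} and the solution vector \code{x}.
#' @keywords internal
lp_solve <- function(obj, Aeq, beq, lb, ub, Ain = NULL, bin = NULL,
                     maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds; set explicit caps first")
  if (any(lb > ub + 1e-9))
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  Aeq <- as.matrix(Aeq)
  if (ncol(Aeq) != n) stop("Aeq has wrong number of columns")
  if (maximize) obj <- -obj

  ## substitute out fixed variables (lb == ub), common from the balanced
  ## growth equalities; reduces degeneracy considerably
  fixed <- (ub - lb) <= 1e-12
  xfix <- ifelse(fixed, (lb + ub) / 2, 0)
  free <- which(!fixed)
  nf <- length(free)
  beq2 <- beq - as.numeric(Aeq %*% xfix)
  A2 <- Aeq[, free, drop = FALSE]
  if (!is.null(Ain)) {
    Ain <- as.matrix(Ain)
    bin2 <- bin - as.numeric(Ain %*% xfix)
    Ai2 <- Ain[, free, drop = FALSE]
  } else {
    Ai2 <- matrix(0, 0, nf); bin2 <- numeric(0)
  }
  if (nf == 0L) {
    feas <- all(abs(beq2) <= tol * (1 + max(abs(beq), 0))) &&
      (length(bin2) == 0L || all(bin2 >= -tol * (1 + max(abs(bin), 0))))
    val <- sum(obj * xfix)
    return(list(status = if (feas) "optimal" else "infeasible",
                objval = if (feas) (if (maximize) -val else val) else NA_real_,
                x = if (feas) xfix else rep(NA_real_, n)))
  }

  l <- lb[free]; u <- ub[free]; c0 <- obj[free]
  ## shift y = x - l >= 0; add upper-bound rows y_j + t_j = u_j - l_j
  b1 <- beq2 - as.numeric(A2 %*% l)
  b2 <- bin2 - as.numeric(Ai2 %*% l)
  du <- u - l
  m1 <- nrow(A2); m2 <- nrow(Ai2); m3 <- nf
  ## columns: y (nf) | s_in (m2) | t_ub (nf)
  ncols <- nf + m2 + nf
  M <- matrix(0, m1 + m2 + m3, ncols)
  d <- c(b1, b2, du)
  if (m1) M[seq_len(m1), seq_len(nf)] <- A2
  if (m2) {
    M[m1 + seq_len(m2), seq_len(nf)] <- Ai2
    M[cbind(m1 + seq_len(m2), nf + seq_len(m2))] <- 1
  }
  M[cbind(m1 + m2 + seq_len(nf), seq_len(nf))] <- 1
  M[cbind(m1 + m2 + seq_len(nf), nf + m2 + seq_len(nf))] <- 1
  neg <- d < 0
  if (any(neg)) { M[neg, ] <- -M[neg, , drop = FALSE]; d[neg] <- -d[neg] }
  cvec <- c(c0, rep(0, m2 + nf))

  res <- simplex_two_phase(M, d, cvec, tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objval = NA_real_, x = rep(NA_real_, n)))
  }
  y <- res$x[seq_len(nf)]
  x <- xfix
  x[free] <- y + l
  val <- sum(obj * x)
  list(status = "optimal", objval = if (maximize) -val else val, x = x)
}

## Two-phase tableau simplex on standard form: min c'z, M z = d (d >= 0), z >= 0.
simplex_two_phase <- function(M, d, cvec, tol = 1e-9) {
  m <- nrow(M); nz <- ncol(M)
  M0 <- M; d0 <- d
  ## phase 1 tableau: [M | I | d], basis = artificials
  T <- cbind(M, diag(m), d)
  basis <- nz + seq_len(m)
  ## reduced costs under the all-artificial basis (cb = 1): structural
  ## columns get -colsum, artificial columns are basic (0)
  z <- c(-colSums(M), rep(0, m))
  zrhs <- -sum(d)
  ph1 <- simplex_iterate(T, basis, z, zrhs, ncols = nz + m, tol = tol,
                         allowed = seq_len(nz))
  T <- ph1$T; basis <- ph1$basis
  feas_tol <- tol * (1 + max(abs(d0), 1))
  if (-ph1$zrhs > feas_tol * max(1, m)) {
    return(list(status = "infeasible"))
  }
  ## drive remaining artificial variables out of the basis
  art <- which(basis > nz)
  for (i in rev(art)) {
    row <- i
    piv <- which(abs(T[row, seq_len(nz)]) > tol)
    if (length(piv)) {
      j <- piv[1L]
      T <- pivot_tableau(T, row, j)
      basis[row] <- j
    } else {
      ## redundant row: harmless, leave degenerate artificial at zero
      T[row, nz + m + 1] <- 0
    }
  }
  ## phase 2: restrict to structural+slack columns
  keep <- c(seq_len(nz), nz + m + 1)
  T2 <- T[, keep, drop = FALSE]
  ## recompute reduced costs from scratch for robustness
  cb <- ifelse(basis <= nz, cvec[pmin(basis, nz)], 0)
  z2 <- cvec - as.numeric(crossprod(T2[, seq_len(nz), drop = FALSE], cb))
  z2[basis[basis <= nz]] <- 0
  zrhs2 <- -sum(cb * T2[, nz + 1])
  allowed <- seq_len(nz)
  ph2 <- simplex_iterate(T2, basis, z2, zrhs2, ncols = nz, tol = tol,
                         allowed = allowed)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  basis <- ph2$basis
  ## resolve x from the basis against the original system for accuracy
  x <- numeric(nz)
  bcols <- basis[basis <= nz]
  brows <- which(basis <= nz)
  if (length(bcols)) {
    Bm <- M0[, bcols, drop = FALSE]
    sol <- tryCatch(qr.solve(Bm, d0, tol = 1e-12), error = function(e) NULL)
    if (is.null(sol)) {
      sol <- qr.coef(qr(Bm), d0)
      sol[is.na(sol)] <- 0
      x[bcols] <- sol
    } else x[bcols] <- sol
  }
  x[x < 0 & x > -1e-7] <- 0
  list(status = "optimal", x = x)
}

## Bland's-rule simplex iterations on an explicit tableau.
## T: m x (ncols_total + 1) with RHS in the last column; z: reduced costs over
## 'allowed' columns; returns updated tableau/basis or unbounded status.
simplex_iterate <- function(T, basis, z, zrhs, ncols, tol, allowed) {
  m <- nrow(T)
  rhs_col <- ncol(T)
  repeat {
    enter <- 0L
    for (j in allowed) {            # Bland: first improving index
      if (z[j] < -tol) { enter <- j; break }
    }
    if (!enter) break
    col <- T[, enter]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", T = T, basis = basis, zrhs = zrhs))
    }
    ratios <- T[pos, rhs_col] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + 1e-12]
    leave <- cand[which.min(basis[cand])]   # Bland tie-break
    T <- pivot_tableau(T, leave, enter)
    ## update reduced costs
    zc <- z[enter]
    z <- z - zc * T[leave, seq_len(length(z))]
    z[enter] <- 0
    zrhs <- zrhs - zc * T[leave, rhs_col]
    basis[leave] <- enter
  }
  list(status = "optimal", T = T, basis = basis, z = z, zrhs = zrhs)
}

pivot_tableau <- function(T, row, col) {
  T[row, ] <- T[row, ] / T[row, col]
  other <- setdiff(seq_len(nrow(T)), row)
  if (length(other)) {
    fac <- T[other, col]
    T[other, ] <- T[other, , drop = FALSE] - outer(fac, T[row, ])
    T[other, col] <- 0
  }
  T[row, col] <- 1
  T
}
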