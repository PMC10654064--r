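## Assembly of the community LPs and the standard solves on them:
## feasibility, growth maximization, FVA, and the parsimonious flux sum.

## Build lp_solve arguments for a constrained_model.  With split = TRUE each
## flux v is represented as p - m (p, m >= 0) so that sum(p + m) rows can cap
## the sum of absolute fluxes.
fba_matrices <- function(cmod, split = FALSE) {
  S <- cmod$community$S
  n <- ncol(S)
  lb <- unname(cmod$lb); ub <- unname(cmod$ub)
  if (!split && is.null(cmod$abs_sum_limit) && length(cmod$extra) == 0L) {
    return(list(Aeq = S, beq = numeric(nrow(S)), lb = lb, ub = ub,
                split = FALSE, n = n))
  }
  if (!split && is.null(cmod$abs_sum_limit)) {
    Ain <- do.call(rbind, lapply(cmod$extra, `[[`, "coef"))
    bin <- vapply(cmod$extra, `[[`, numeric(1), "rhs")
    return(list(Aeq = S, beq = numeric(nrow(S)), lb = lb, ub = ub,
                Ain = Ain, bin = bin, split = FALSE, n = n))
  }
  ## split form: variables (p_1..p_n, m_1..m_n)
  Aeq <- cbind(S, -S)
  lbp <- pmax(lb, 0); ubp <- pmax(ub, 0)
  lbm <- pmax(-ub, 0); ubm <- pmax(-lb, 0)
  Ain <- NULL; bin <- NULL
  if (!is.null(cmod$abs_sum_limit)) {
    Ain <- matrix(1, 1L, 2L * n)
    bin <- cmod$abs_sum_limit
  }
  if (length(cmod$extra)) {
    Ex <- do.call(rbind, lapply(cmod$extra, `[[`, "coef"))
    Ain <- rbind(Ain, cbind(Ex, -Ex))
    bin <- c(bin, vapply(cmod$extra, `[[`, numeric(1), "rhs"))
  }
  list(Aeq = Aeq, beq = numeric(nrow(S)), lb = c(lbp, lbm), ub = c(ubp, ubm),
       Ain = Ain, bin = bin, split = TRUE, n = n)
}

lp_on <- function(mats, obj_rxn_vec, maximize = FALSE) {
  if (mats$split) obj <- c(obj_rxn_vec, -obj_rxn_vec) else obj <- obj_rxn_vec
  lp_solve(obj, mats$Aeq, mats$beq, mats$lb, mats$ub,
           Ain = mats$Ain, bin = mats$bin, maximize = maximize)
}

#' Feasibility of an abundance-growth point
#'
#' Tests whether the community admits at least one flux distribution at the
#' given relative abundances and growth rate, i.e. whether the polytope of
#' the balanced-growth LP is non-empty.
#'
#' @param community a \code{community_model}.
#' @param F abundance vector.
#' @param mu community growth rate (1/h).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_feasible <- function(community, F, mu) {
  cmod <- apply_point(community, F, mu)
  mats <- fba_matrices(cmod)
  r <- lp_solve(numeric(length(mats$lb)), mats$Aeq, mats$beq,
                mats$lb, mats$ub, Ain = mats$Ain, bin = mats$bin)
  r$status == "optimal"
}

#' Maximal community growth rate at fixed abundances
#'
#' Solves the LP that maximizes \eqn{\mu} subject to all community
#' constraints with every member biomass flux substituted by
#' \eqn{f_i \mu}.  Returns 0 when only \eqn{\mu = 0} is feasible and
#' \code{NA} when even zero growth is infeasible at this composition.
#'
#' @inheritParams is_feasible
#' @return maximal growth rate (1/h), 0, or \code{NA_real_} if infeasible.
#' @export
max_growth <- function(community, F) {
  F <- abundance(F)
  f_of <- stats::setNames(as.numeric(F), community$members)
  S <- community$S
  bio <- community$biomass_ids
  keep <- setdiff(colnames(S), bio)
  fac <- ifelse(is.na(community$rxn_organism[keep]), 1,
                f_of[community$rxn_organism[keep]])
  lb <- unname(community$lb[keep] * fac)
  ub <- unname(community$ub[keep] * fac)
  ## mu column aggregates the biomass columns weighted by abundance
  mu_col <- as.numeric(S[, bio, drop = FALSE] %*% f_of[names(bio)])
  act <- names(bio)[f_of[names(bio)] > 0]
  mu_lb <- max(0, max(community$lb[bio[act]]))
  mu_ub <- min(community$ub[bio[act]])
  A <- cbind(S[, keep, drop = FALSE], mu = mu_col)
  obj <- c(numeric(length(keep)), 1)
  r <- lp_solve(obj, A, numeric(nrow(A)), c(lb, mu_lb), c(ub, mu_ub),
                maximize = TRUE)
  if (r$status == "infeasible") return(NA_real_)
  if (r$status != "optimal") stop("growth LP ", r$status,
                                  "; set finite substrate bounds")
  max(r$objval, 0)
}

#' Flux variability ranges at a feasible point
#'
#' Runs flux variability analysis: for each requested reaction, minimizes and
#' maximizes its flux over the polytope of the constrained model (including
#' any efficiency cap or extra linear constraints attached to it).
#'
#' @param cmod a \code{constrained_model} from \code{\link{apply_point}}.
#' @param rxns character vector of reaction ids (default: all reactions).
#' @return data frame with columns \code{rxn}, \code{min}, \code{max}.
#' @export
flux_ranges <- function(cmod, rxns = NULL) {
  S <- cmod$community$S
  if (is.null(rxns)) rxns <- colnames(S)
  miss <- setdiff(rxns, colnames(S))
  if (length(miss)) stop("unknown reactions: ", paste(miss, collapse = ", "))
  mats <- fba_matrices(cmod, split = !is.null(cmod$abs_sum_limit))
  ## feasibility check first so callers get a clear error
  f0 <- lp_solve(numeric(length(mats$lb)), mats$Aeq, mats$beq, mats$lb,
                 mats$ub, Ain = mats$Ain, bin = mats$bin)
  if (f0$status != "optimal")
    stop("point F = (", paste(signif(cmod$f, 4), collapse = ", "),
         "), mu = ", signif(cmod$mu, 6),
         " is infeasible; consult the grid feasibility mask")
  n <- mats$n
  res <- matrix(NA_real_, length(rxns), 2L,
                dimnames = list(rxns, c("min", "max")))
  for (r in rxns) {
    ev <- numeric(n); ev[match(r, colnames(S))] <- 1
    lo <- lp_on(mats, ev, maximize = FALSE)
    hi <- lp_on(mats, ev, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA solve failed for ", r, " (", lo$status, "/", hi$status, ")")
    res[r, ] <- c(lo$objval, hi$objval)
  }
  data.frame(rxn = rxns, min = unname(res[, 1]), max = unname(res[, 2]),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Minimal sum of absolute fluxes at a point (parsimonious optimum).
min_abs_flux_sum <- function(cmod) {
  mats <- fba_matrices(cmod, split = TRUE)
  obj <- rep(1, length(mats$lb))
  r <- lp_solve(obj, mats$Aeq, mats$beq, mats$lb, mats$ub,
                Ain = mats$Ain, bin = mats$bin)
  if (r$status != "optimal")
    stop("parsimonious LP ", r$status, " at F = (",
         paste(signif(cmod$f, 4), collapse = ", "), "), mu = ",
         signif(cmod$mu, 6))
  r$objval
}

#' Pick one feasible flux distribution at a point
#'
#' Returns an arbitrary vertex of the flux polytope (the solution of the
#' feasibility LP), mainly for inspection and tests.
#'
#' @inheritParams flux_ranges
#' @return named numeric vector of fluxes (mmol/gDW_com/h).
#' @export
flux_sample <- function(cmod) {
  mats <- fba_matrices(cmod, split = !is.null(cmod$abs_sum_limit))
  r <- lp_solve(numeric(length(mats$lb)), mats$Aeq, mats$beq, mats$lb,
                mats$ub, Ain = mats$Ain, bin = mats$bin)
  if (r$status != "optimal") stop("infeasible point")
  v <- if (mats$split) r$x[seq_len(mats$n)] - r$x[mats$n + seq_len(mats$n)]
       else r$x
  stats::setNames(v, colnames(cmod$community$S))
}
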