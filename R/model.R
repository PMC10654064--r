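#' Construct a single-organism metabolic model
#'
#' A light container for a genome-scale (or toy) metabolic model: a
#' stoichiometric matrix, flux bounds, metabolite compartments and a biomass
#' reaction.  Exchange reactions are auto-detected as boundary reactions
#' touching exactly one metabolite of the extracellular compartment.
#'
#' @param organism_id short identifier used to tag reactions in a community.
#' @param S stoichiometric matrix (metabolites x reactions) with dimnames.
#' @param lb,ub lower/upper flux bounds in mmol/gDW/h, named by reaction or in
#'   column order of \code{S}.
#' @param met_compartment character vector of compartment ids, named by
#'   metabolite or in row order of \code{S}.
#' @param biomass_id id of the biomass reaction.
#' @param extracellular id of the extracellular compartment (default "e").
#' @return an object of class \code{organism_model}.
#' @export
organism_model <- function(organism_id, S, lb, ub, met_compartment,
                           biomass_id, extracellular = "e") {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S must carry metabolite row names and reaction column names")
  rxns <- colnames(S); mets <- rownames(S)
  lb <- resolve_named(lb, rxns, "lb"); ub <- resolve_named(ub, rxns, "ub")
  met_compartment <- resolve_named(met_compartment, mets, "met_compartment")
  if (any(!is.finite(S))) stop("stoichiometric coefficients must be finite")
  ## infinite bounds take the conventional +/-1000 caps so every LP is a
  ## bounded polytope; ranges hitting these sentinels mean "no finite bound"
  lb[lb == -Inf] <- -1000
  ub[ub == Inf] <- 1000
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("flux bounds must not be NA/NaN")
  if (any(lb > ub + 1e-12))
    stop("lower bound exceeds upper bound for: ",
         paste(rxns[lb > ub + 1e-12], collapse = ", "))
  if (!biomass_id %in% rxns)
    stop("biomass reaction '", biomass_id, "' not found in model")
  exch <- detect_exchanges(S, met_compartment, extracellular)
  obj <- structure(list(
    organism_id = organism_id,
    S = S, lb = lb, ub = ub,
    met_compartment = met_compartment,
    biomass_id = biomass_id,
    exchange_ids = exch,
    extracellular = extracellular
  ), class = "organism_model")
  obj
}

resolve_named <- function(x, ids, what) {
  if (!is.null(names(x))) {
    miss <- setdiff(ids, names(x))
    if (length(miss)) stop(what, " missing entries for: ",
                           paste(miss, collapse = ", "))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop(what, " must be named or match length ", length(ids))
  } else names(x) <- ids
  x
}

## boundary reactions with exactly one (extracellular) metabolite
detect_exchanges <- function(S, met_compartment, extracellular) {
  nmet <- colSums(S != 0)
  cand <- which(nmet == 1L)
  keep <- vapply(cand, function(j) {
    m <- rownames(S)[which(S[, j] != 0)]
    met_compartment[[m]] == extracellular
  }, logical(1))
  colnames(S)[cand[keep]]
}

#' Relative abundance vector
#'
#' Validates a vector of relative abundances: entries in \[0, 1\] summing to 1
#' (tolerance 1e-9).
#'
#' @param f numeric vector of length N (one entry per community member).
#' @return the validated vector, classed \code{abundance}.
#' @export
abundance <- function(f) {
  f <- as.numeric(f)
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("abundances must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", format(sum(f)), ")")
  structure(pmin(pmax(f, 0), 1), class = "abundance")
}

#' @export
print.organism_model <- function(x, ...) {
  cat("<organism_model> ", x$organism_id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$S), "   reactions: ", ncol(x$S), "\n", sep = "")
  cat("  biomass: ", x$biomass_id,
      "   exchanges: ", length(x$exchange_ids), "\n", sep = "")
  invisible(x)
}
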