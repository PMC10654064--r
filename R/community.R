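#' Merge single-organism models into a compartmentalized community model
#'
#' Each member becomes a meta-compartment; a shared pool compartment holds
#' every metabolite present in the extracellular compartment of at least one
#' member.  Former member exchange reactions are rewired into transports
#' between the member's extracellular compartment and the pool, and one new
#' community exchange reaction per pool metabolite (\code{EX_<met>_e})
#' controls external availability.  Member reactions are renamed
#' \code{<organism_id>_<reaction_id>} so the owner of any flux is recoverable
#' from its id.
#'
#' Community exchange bounds default to the most permissive bounds found among
#' the members' original exchanges for that metabolite; individual reactions
#' can be overridden through \code{exchange_bounds}.
#'
#' @param models list of at least two \code{\link{organism_model}} objects
#'   with distinct \code{organism_id}s.
#' @param exchange_bounds optional named list; each entry
#'   \code{EX_<met>_e = c(lb, ub)} overrides a community exchange bound.
#' @return an object of class \code{community_model}.
#' @export
build_community <- function(models, exchange_bounds = NULL) {
  if (length(models) < 2L) stop("a community needs at least two members")
  ids <- vapply(models, function(m) m$organism_id, character(1))
  if (anyDuplicated(ids)) stop("organism ids must be distinct")

  pool_base <- character(0)       # base metabolite names (compartment-free)
  pool_lb <- pool_ub <- numeric(0)
  blocks <- list()

  for (m in models) {
    org <- m$organism_id
    S <- m$S
    mets <- paste0(org, "_", rownames(S))
    rxns <- paste0(org, "_", colnames(S))
    comp <- stats::setNames(paste0(org, ":", m$met_compartment), mets)
    ## rewire exchanges into organism<->pool transports
    extra <- list()   # pool-metabolite rows to append: list(rxn, base, coef)
    for (ex in m$exchange_ids) {
      j <- match(ex, colnames(S))
      i <- which(S[, j] != 0)
      met <- rownames(S)[i]
      base <- sub(paste0("_", m$extracellular, "$"), "", met)
      coef <- S[i, j]
      extra[[length(extra) + 1L]] <- list(rxn = paste0(org, "_", ex),
                                          base = base, coef = -coef)
      if (!base %in% pool_base) {
        pool_base <- c(pool_base, base)
        pool_lb[base] <- m$lb[[ex]]
        pool_ub[base] <- m$ub[[ex]]
      } else {
        pool_lb[base] <- min(pool_lb[base], m$lb[[ex]])
        pool_ub[base] <- max(pool_ub[base], m$ub[[ex]])
      }
    }
    blocks[[org]] <- list(
      S = S, mets = mets, rxns = rxns, comp = comp,
      lb = stats::setNames(m$lb, rxns), ub = stats::setNames(m$ub, rxns),
      biomass = paste0(org, "_", m$biomass_id),
      original = stats::setNames(colnames(S), rxns),
      pool_links = extra
    )
  }

  pool_mets <- paste0(pool_base, "_pool")
  ex_ids <- paste0("EX_", pool_base, "_e")
  all_mets <- c(unlist(lapply(blocks, `[[`, "mets"), use.names = FALSE), pool_mets)
  all_rxns <- c(unlist(lapply(blocks, `[[`, "rxns"), use.names = FALSE), ex_ids)
  if (anyDuplicated(all_rxns)) stop("reaction id collision after renaming")

  S <- matrix(0, length(all_mets), length(all_rxns),
              dimnames = list(all_mets, all_rxns))
  lb <- stats::setNames(numeric(length(all_rxns)), all_rxns)
  ub <- lb
  rxn_organism <- stats::setNames(rep(NA_character_, length(all_rxns)), all_rxns)
  rxn_original <- stats::setNames(all_rxns, all_rxns)
  comp <- stats::setNames(rep("pool", length(all_mets)), all_mets)

  for (org in names(blocks)) {
    bl <- blocks[[org]]
    S[bl$mets, bl$rxns] <- bl$S
    lb[bl$rxns] <- bl$lb; ub[bl$rxns] <- bl$ub
    rxn_organism[bl$rxns] <- org
    rxn_original[bl$rxns] <- bl$original
    comp[bl$mets] <- bl$comp
    for (lk in bl$pool_links)
      S[paste0(lk$base, "_pool"), lk$rxn] <- lk$coef
  }
  ## community exchanges: pool metabolite -> exterior (coef -1; uptake < 0)
  for (k in seq_along(pool_base)) {
    S[pool_mets[k], ex_ids[k]] <- -1
    lb[ex_ids[k]] <- pool_lb[[pool_base[k]]]
    ub[ex_ids[k]] <- pool_ub[[pool_base[k]]]
  }
  if (!is.null(exchange_bounds)) {
    for (nm in names(exchange_bounds)) {
      if (!nm %in% ex_ids) stop("no community exchange named ", nm)
      lb[nm] <- exchange_bounds[[nm]][1]
      ub[nm] <- exchange_bounds[[nm]][2]
    }
  }

  structure(list(
    members = ids,
    S = S, lb = lb, ub = ub,
    rxn_organism = rxn_organism,
    rxn_original = rxn_original,
    biomass_ids = stats::setNames(
      vapply(blocks, `[[`, character(1), "biomass"), names(blocks)),
    met_compartment = comp,
    pool_mets = pool_mets,
    exchange_ids = ex_ids,
    recycling = NULL
  ), class = "community_model")
}

#' Add biomass-recycling pseudo-reactions
#'
#' Models death and degradation of community biomass into reusable organic
#' carbon.  Every member biomass reaction additionally produces one unit of a
#' community-biomass pseudo-metabolite per gDW; pseudo-reactions then split it
#' into a degraded fraction \code{alpha} converted to glucose equivalents in
#' the pool and a net fraction removed through a sink:
#' \deqn{Biomass_{community} \to \alpha\, Biomass_{degraded} +
#'   (1-\alpha)\, Biomass_{net}}
#' \deqn{Biomass_{degraded} \to g \cdot glc_{pool}}
#' with \code{g = glucose_coefficient} carbon-equivalent mmol of glucose per
#' gDW of degraded biomass.  The community growth rate stays gross
#' (\eqn{\mu = \sum_i v_{biom,i}}); recycling is pure mass bookkeeping.
#'
#' @param community a \code{community_model}.
#' @param alpha fraction of produced biomass that is degraded, in \[0, 1).
#' @param glucose_coefficient mmol glucose released per gDW degraded biomass
#'   (default 6.169).
#' @param glucose_met id of the pool glucose metabolite (default
#'   \code{"glc_pool"}).
#' @return the augmented \code{community_model}.
#' @export
add_biomass_recycling <- function(community, alpha,
                                  glucose_coefficient = 6.169,
                                  glucose_met = "glc_pool") {
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  if (!glucose_met %in% rownames(community$S))
    stop("pool metabolite '", glucose_met, "' not present; ",
         "recycling needs a glucose sink in the pool")
  S <- community$S
  new_mets <- c("Biomass_community", "Biomass_degraded", "Biomass_net")
  new_rxns <- c("BIOMASS_RECYCLING", "BIOMASS_DEGRADATION", "SINK_Biomass_net")
  if (any(new_rxns %in% colnames(S))) stop("recycling block already present")
  S2 <- matrix(0, nrow(S) + 3L, ncol(S) + 3L,
               dimnames = list(c(rownames(S), new_mets),
                               c(colnames(S), new_rxns)))
  S2[rownames(S), colnames(S)] <- S
  for (b in community$biomass_ids) S2["Biomass_community", b] <- 1
  S2["Biomass_community", "BIOMASS_RECYCLING"] <- -1
  S2["Biomass_degraded", "BIOMASS_RECYCLING"] <- alpha
  S2["Biomass_net", "BIOMASS_RECYCLING"] <- 1 - alpha
  S2["Biomass_degraded", "BIOMASS_DEGRADATION"] <- -1
  S2[glucose_met, "BIOMASS_DEGRADATION"] <- glucose_coefficient
  S2["Biomass_net", "SINK_Biomass_net"] <- -1

  community$S <- S2
  add <- stats::setNames(c(0, 0, 0), new_rxns)
  community$lb <- c(community$lb, add)
  community$ub <- c(community$ub, add + 1000)
  community$rxn_organism <- c(community$rxn_organism,
                              stats::setNames(rep(NA_character_, 3L), new_rxns))
  community$rxn_original <- c(community$rxn_original,
                              stats::setNames(new_rxns, new_rxns))
  community$met_compartment <- c(community$met_compartment,
                                 stats::setNames(rep("pool", 3L), new_mets))
  community$recycling <- list(alpha = alpha,
                              glucose_coefficient = glucose_coefficient,
                              glucose_met = glucose_met)
  community
}

#' Constrain a community model at an abundance-growth point
#'
#' Produces the linear program describing the flux polytope at fixed relative
#' abundances \code{F} and community growth rate \code{mu}: every reaction of
#' member i gets bounds \code{[f_i * lb, f_i * ub]}, each member's biomass
#' flux is pinned to \code{f_i * mu} (balanced growth), and pool exchange
#' bounds are left untouched (they cap the community, not a member).
#' Infeasibility is a property of the resulting polytope, not an error here.
#'
#' @param community a \code{community_model}.
#' @param F an \code{\link{abundance}} vector (or coercible numeric), ordered
#'   as \code{community$members}.
#' @param mu community growth rate (1/h), non-negative.
#' @return an object of class \code{constrained_model}.
#' @export
apply_point <- function(community, F, mu) {
  F <- abundance(F)
  if (length(F) != length(community$members))
    stop("abundance vector length must equal the number of members")
  if (mu < 0) stop("mu must be non-negative")
  f_of <- stats::setNames(as.numeric(F), community$members)
  fac <- ifelse(is.na(community$rxn_organism), 1,
                f_of[community$rxn_organism])
  lb <- community$lb * fac
  ub <- community$ub * fac
  for (org in community$members) {
    b <- community$biomass_ids[[org]]
    target <- f_of[[org]] * mu
    ## pinning must respect the (scaled) original biomass bounds: an
    ## out-of-range target makes the point infeasible via lb > ub
    lb[b] <- max(lb[b], target)
    ub[b] <- min(ub[b], target)
  }
  structure(list(
    community = community, f = f_of, mu = mu,
    lb = lb, ub = ub,
    extra = list(),           # rows a'v <= rhs on plain fluxes
    abs_sum_limit = NULL      # cap on sum of |v| (efficiency scenarios)
  ), class = "constrained_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> members: ", paste(x$members, collapse = ", "),
      "\n", sep = "")
  cat("  metabolites: ", nrow(x$S), " (", length(x$pool_mets),
      " pool)   reactions: ", ncol(x$S), " (", length(x$exchange_ids),
      " community exchanges)\n", sep = "")
  if (!is.null(x$recycling))
    cat("  biomass recycling: alpha = ", x$recycling$alpha,
        ", ", x$recycling$glucose_coefficient, " glc/gDW\n", sep = "")
  invisible(x)
}

#' @export
print.constrained_model <- function(x, ...) {
  cat("<constrained_model> F = (", paste(signif(x$f, 4), collapse = ", "),
      "), mu = ", signif(x$mu, 6), "\n", sep = "")
  if (!is.null(x$abs_sum_limit))
    cat("  efficiency cap: sum|v| <= ", signif(x$abs_sum_limit, 6), "\n",
        sep = "")
  invisible(x)
}
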