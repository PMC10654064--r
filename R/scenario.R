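#' Scenario configuration
#'
#' Collects the environmental and objective parameters of an analysis
#' scenario: the biomass-recycling fraction \code{alpha}, the substrate
#' availability split \code{lambda} between the iron-like and
#' thiosulfate-like energy sources, their reference caps, an optional
#' energy-efficiency factor, amino-acid supplementation fluxes, and the
#' cross-feeding case constants.
#'
#' Reference values: \code{max_fe2 = 150} and \code{max_tsul = 10}
#' mmol/gDW_com/h, the uptakes that produce maximal biomass on each single
#' model; \code{glucose_availability = 10} and \code{aa_production_cap = 0.2}
#' mmol/gDW_org/h for the cross-feeding case; supplementation flux 0.01.
#'
#' @param alpha biomass-recycling fraction in \[0, 1).
#' @param lambda fraction of the energy supply delivered as Fe(II)-equivalent
#'   substrate, in \[0, 1\].
#' @param max_fe2,max_tsul reference substrate caps (mmol/gDW_com/h).
#' @param efficiency_factor factor >= 1 bounding the sum of absolute fluxes
#'   relative to its minimum, or \code{NULL} for none.
#' @param supplementation named numeric: pool exchange uptake fluxes, e.g.
#'   \code{c(leu = 0.01, lys = 0.01)}.
#' @param glucose_availability glucose uptake cap per organism.
#' @param aa_production_cap amino-acid export cap per organism.
#' @return a list of class \code{scenario_config}.
#' @export
scenario_config <- function(alpha = 0.2, lambda = 0.5, max_fe2 = 150,
                            max_tsul = 10, efficiency_factor = NULL,
                            supplementation = NULL,
                            glucose_availability = 10,
                            aa_production_cap = 0.2) {
  stopifnot(lambda >= 0, lambda <= 1, alpha >= 0, alpha < 1)
  if (!is.null(efficiency_factor) && efficiency_factor < 1)
    stop("efficiency_factor must be >= 1")
  structure(list(alpha = alpha, lambda = lambda, max_fe2 = max_fe2,
                 max_tsul = max_tsul, efficiency_factor = efficiency_factor,
                 supplementation = supplementation,
                 glucose_availability = glucose_availability,
                 aa_production_cap = aa_production_cap),
            class = "scenario_config")
}

#' Split the energy supply between two substrates
#'
#' Sets the community exchange lower bounds (uptake is negative) to
#' \code{-lambda * max_fe2} for the iron-like source and
#' \code{-(1 - lambda) * max_tsul} for the thiosulfate-like source, modeling
#' energetically equivalent convex combinations of the two substrates.
#'
#' @param community a \code{community_model}.
#' @param config a \code{\link{scenario_config}}.
#' @param fe2_id,tsul_id community exchange ids.
#' @return the modified \code{community_model}.
#' @export
set_substrate_ratio <- function(community, config,
                                fe2_id = "EX_fe2_e", tsul_id = "EX_tsul_e") {
  miss <- setdiff(c(fe2_id, tsul_id), colnames(community$S))
  if (length(miss))
    stop("community exchanges not found: ", paste(miss, collapse = ", "))
  community$lb[fe2_id] <- -config$lambda * config$max_fe2
  community$lb[tsul_id] <- -(1 - config$lambda) * config$max_tsul
  community
}

#' Constrain the sum of absolute fluxes (energy efficiency)
#'
#' Computes the parsimonious optimum \eqn{S_{min} = \min \sum_r |v_r|} at
#' the model's abundance-growth point and attaches the constraint
#' \eqn{\sum_r |v_r| \le factor \cdot S_{min}} (internally via non-negative
#' forward/reverse flux splitting).  Subsequent FVA and categorization on the
#' returned model operate on the restricted polytope.
#'
#' @param cmod a feasible \code{constrained_model}.
#' @param factor allowed deviation from the parsimonious optimum (>= 1);
#'   1.1, 1.2 and 1.5 correspond to 10/20/50 percent deviation.
#' @return the \code{constrained_model} with the efficiency cap attached.
#' @export
add_efficiency_constraint <- function(cmod, factor) {
  if (factor < 1) stop("factor must be >= 1")
  s_min <- min_abs_flux_sum(cmod)   # errors if the base point is infeasible
  cmod$abs_sum_limit <- factor * s_min
  cmod$efficiency_factor <- factor
  cmod
}

#' Configure the cross-feeding community case
#'
#' Applies the synthetic cross-feeding study conditions to a community
#' carrying glucose, leucine and lysine exchanges: member glucose uptake
#' capped at \code{glucose_availability} and member amino-acid export capped
#' at \code{aa_production_cap} (both per gDW of the organism, i.e. before
#' abundance scaling), and community amino-acid exchanges closed (lower
#' bound 0) unless a supplementation flux opens them
#' (lower bound \code{-supplementation}).
#'
#' @param community a \code{community_model} whose members have
#'   \code{EX_glc_e}-, \code{EX_leu_e}- and \code{EX_lys_e}-style exchanges.
#' @param config a \code{\link{scenario_config}}; supplementation entries
#'   must be named by the pool metabolite base name (\code{leu}, \code{lys}).
#' @param aa base names of the cross-fed metabolites.
#' @return the modified \code{community_model}.
#' @export
configure_ecoli_case <- function(community, config = scenario_config(),
                                 aa = c("leu", "lys")) {
  rxns <- colnames(community$S)
  glc_member <- rxns[!is.na(community$rxn_organism) &
                       community$rxn_original == "EX_glc_e"]
  if (!length(glc_member)) stop("no member glucose exchange found")
  community$lb[glc_member] <- -config$glucose_availability
  for (a in aa) {
    ex_comm <- paste0("EX_", a, "_e")
    if (!ex_comm %in% rxns) stop("missing community exchange ", ex_comm)
    member_ex <- rxns[!is.na(community$rxn_organism) &
                        community$rxn_original == ex_comm]
    for (mex in member_ex)      # producer export caps, uptake untouched
      if (community$ub[mex] > 0)
        community$ub[mex] <- config$aa_production_cap
    supp <- 0
    if (!is.null(config$supplementation) && a %in% names(config$supplementation))
      supp <- config$supplementation[[a]]
    community$lb[ex_comm] <- -supp
  }
  community
}

#' Run a sweep of scenarios
#'
#' Builds grid, phenotype matrix and partitions independently for each
#' scenario; failures are collected per scenario without aborting the sweep.
#'
#' @param community_fn function(scenario_config) returning the configured
#'   \code{community_model} for one scenario.
#' @param scenarios named list of \code{\link{scenario_config}} objects.
#' @param l grid resolution.
#' @param rxns selected reaction set R' (default: community exchanges).
#' @param k number of clusters for the cluster-partition, or \code{NULL} to
#'   skip clustering.
#' @return named list per scenario with elements \code{grid},
#'   \code{matrix}, \code{partition}, \code{clustering} (or \code{error}).
#' @export
run_sweep <- function(community_fn, scenarios, l = 10, rxns = NULL,
                      k = NULL) {
  out <- vector("list", length(scenarios))
  names(out) <- names(scenarios)
  for (nm in names(scenarios)) {
    out[[nm]] <- tryCatch({
      cfg <- scenarios[[nm]]
      cm <- community_fn(cfg)
      grid <- build_grid(cm, l)
      constrain <- NULL
      if (!is.null(cfg$efficiency_factor)) {
        fac <- cfg$efficiency_factor
        constrain <- function(cmod) add_efficiency_constraint(cmod, fac)
      }
      pm <- phenotype_matrix(cm, grid, rxns, constrain = constrain)
      res <- list(grid = grid, matrix = pm, partition = exact_partition(pm))
      if (!is.null(k)) res$clustering <- cluster_partition(pm, k)
      res
    }, error = function(e) list(error = conditionMessage(e)))
  }
  out
}
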