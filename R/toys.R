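#' Specification of the built-in toy communities
#'
#' Parameters of the small, fully analyzable two-organism fixtures used for
#' testing and demonstration: a mandatory cross-feeding pair (two auxotrophs
#' exchanging amino acids) and a chemolithotroph pair (two members oxidizing
#' inorganic substrates, one of which can also consume recycled organic
#' matter).
#'
#' Defaults mirror the study conditions of the corresponding analyses:
#' amino-acid export cap 0.2 mmol/gDW/h, substrate availability
#' 10 mmol/gDW/h, one mmol of the partner's metabolite required per gDW of
#' biomass, and inorganic substrate caps of 150 (iron-like source "fe2") and
#' 10 (thiosulfate-like source "tsul") calibrated so either source alone
#' sustains a maximal growth rate of 0.15 1/h.
#'
#' @param crossfeed_cap p, maximal export flux of each cross-fed metabolite
#'   (mmol/gDW/h).
#' @param substrate_cap maximal glucose uptake per organism (mmol/gDW/h).
#' @param biomass_requirement mmol of the partner metabolite needed per gDW
#'   of biomass.
#' @param mu_cap optional hard cap on each member's growth rate (1/h);
#'   \code{NULL} leaves the default biomass bound of 1000.
#' @param fe2_yield,tsul_yield,glc_yield gDW of biomass precursor per mmol of
#'   each energy source in the chemolithotroph pair.
#' @return a list of class \code{toy_spec}.
#' @export
toy_spec <- function(crossfeed_cap = 0.2, substrate_cap = 10,
                     biomass_requirement = 1, mu_cap = NULL,
                     fe2_yield = 0.001, tsul_yield = 0.015,
                     glc_yield = 0.05) {
  stopifnot(crossfeed_cap > 0, substrate_cap > 0, biomass_requirement > 0,
            fe2_yield > 0, tsul_yield > 0, glc_yield > 0)
  structure(list(crossfeed_cap = crossfeed_cap,
                 substrate_cap = substrate_cap,
                 biomass_requirement = biomass_requirement,
                 mu_cap = mu_cap,
                 fe2_yield = fe2_yield, tsul_yield = tsul_yield,
                 glc_yield = glc_yield),
            class = "toy_spec")
}

toy_member <- function(org, makes, needs, spec) {
  p <- spec$crossfeed_cap; req <- spec$biomass_requirement
  mu_ub <- if (is.null(spec$mu_cap)) 1000 else spec$mu_cap
  mets <- c("glc_e", "glc_c",
            paste0(makes, c("_e", "_c")), paste0(needs, c("_e", "_c")))
  comp <- ifelse(grepl("_e$", mets), "e", "c")
  rxns <- c("EX_glc_e", "GLCt", paste0(toupper(makes), "S"),
            paste0(toupper(makes), "t"), paste0("EX_", makes, "_e"),
            paste0(toupper(needs), "t"), paste0("EX_", needs, "_e"),
            "BIOMASS")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["glc_e", "EX_glc_e"] <- -1
  S["glc_e", "GLCt"] <- -1; S["glc_c", "GLCt"] <- 1
  S["glc_c", paste0(toupper(makes), "S")] <- -1
  S[paste0(makes, "_c"), paste0(toupper(makes), "S")] <- 1
  S[paste0(makes, "_c"), paste0(toupper(makes), "t")] <- -1
  S[paste0(makes, "_e"), paste0(toupper(makes), "t")] <- 1
  S[paste0(makes, "_e"), paste0("EX_", makes, "_e")] <- -1
  S[paste0(needs, "_e"), paste0(toupper(needs), "t")] <- -1
  S[paste0(needs, "_c"), paste0(toupper(needs), "t")] <- 1
  S[paste0(needs, "_e"), paste0("EX_", needs, "_e")] <- -1
  S["glc_c", "BIOMASS"] <- -1
  S[paste0(needs, "_c"), "BIOMASS"] <- -req
  lb <- c(-spec$substrate_cap, -1000, 0, 0, 0, 0, -1000, 0)
  ub <- c(1000, 1000, 1000, 1000, p, 1000, 0, mu_ub)
  organism_model(org, S, lb, ub, comp, "BIOMASS")
}

#' Two-member mandatory cross-feeding toy
#'
#' Builds two auxotrophic organisms on glucose: \code{eco_K} synthesizes and
#' exports leucine but must import lysine, \code{eco_L} the converse.  Export
#' of the cross-fed metabolite is capped at \code{crossfeed_cap} per gDW, so
#' the maximal community growth rate has the closed form
#' \deqn{\mu_{max}(F) = \min\left(\frac{f_2\,p}{q f_1},
#'   \frac{f_1\,p}{q f_2}, \mu_{cap}\right)}
#' with p the export cap and q the biomass requirement — a concave triangle
#' over abundance with its peak at the balanced composition.
#'
#' @param spec a \code{\link{toy_spec}}.
#' @return list of two \code{\link{organism_model}} objects.
#' @export
make_crossfeeding_pair <- function(spec = toy_spec()) {
  list(make = toy_member("eco_K", makes = "leu", needs = "lys", spec),
       partner = toy_member("eco_L", makes = "lys", needs = "leu", spec))
}

#' Cross-feeding toy community (no external amino acids)
#'
#' Merges the cross-feeding pair and closes the community amino-acid
#' exchanges (lower bound 0), making the cross-feeding mandatory; use
#' \code{\link{configure_ecoli_case}} to reopen them for supplementation.
#'
#' @inheritParams make_crossfeeding_pair
#' @return a \code{community_model}.
#' @export
make_crossfeeding_community <- function(spec = toy_spec()) {
  pair <- make_crossfeeding_pair(spec)
  build_community(unname(pair),
                  exchange_bounds = list(EX_leu_e = c(0, 1000),
                                         EX_lys_e = c(0, 1000)))
}

#' Closed-form maximal growth of the cross-feeding toy
#'
#' @param spec a \code{\link{toy_spec}}.
#' @param f1 abundance of the first member (scalar or vector).
#' @return \eqn{\mu_{max}} for each \code{f1}.
#' @export
crossfeeding_mu_max <- function(spec, f1) {
  p <- spec$crossfeed_cap; q <- spec$biomass_requirement
  cap <- if (is.null(spec$mu_cap)) Inf else spec$mu_cap
  f2 <- 1 - f1
  a <- ifelse(f1 > 0, f2 * p / (q * f1), Inf)
  b <- ifelse(f2 > 0, f1 * p / (q * f2), Inf)
  res <- pmin(a, b, cap)
  ifelse(f1 %in% c(0, 1), 0, res)
}

chemo_member <- function(org, spec, heterotroph = FALSE) {
  mets <- c("fe2_e", "fe2_c", "tsul_e", "tsul_c", "prec_c")
  rxns <- c("EX_fe2_e", "FE2t", "FEOX", "EX_tsul_e", "TSULt", "TSOX",
            "BIOMASS")
  if (heterotroph) {
    mets <- c(mets, "glc_e", "glc_c")
    rxns <- c(rxns, "EX_glc_e", "GLCt", "GLCOX")
  }
  comp <- ifelse(grepl("_e$", mets), "e", "c")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["fe2_e", "EX_fe2_e"] <- -1
  S["fe2_e", "FE2t"] <- -1; S["fe2_c", "FE2t"] <- 1
  S["fe2_c", "FEOX"] <- -1; S["prec_c", "FEOX"] <- spec$fe2_yield
  S["tsul_e", "EX_tsul_e"] <- -1
  S["tsul_e", "TSULt"] <- -1; S["tsul_c", "TSULt"] <- 1
  S["tsul_c", "TSOX"] <- -1; S["prec_c", "TSOX"] <- spec$tsul_yield
  S["prec_c", "BIOMASS"] <- -1
  lb <- stats::setNames(rep(0, length(rxns)), rxns)
  ub <- stats::setNames(rep(1000, length(rxns)), rxns)
  lb[c("EX_fe2_e", "EX_tsul_e")] <- -1000
  ub[c("EX_fe2_e", "EX_tsul_e")] <- 0
  if (heterotroph) {
    S["glc_e", "EX_glc_e"] <- -1
    S["glc_e", "GLCt"] <- -1; S["glc_c", "GLCt"] <- 1
    S["glc_c", "GLCOX"] <- -1; S["prec_c", "GLCOX"] <- spec$glc_yield
    lb["EX_glc_e"] <- -1000; ub["EX_glc_e"] <- 0
  }
  organism_model(org, S, lb, ub, comp, "BIOMASS")
}

#' Two-member chemolithotroph toy
#'
#' Two organisms oxidizing an iron-like ("fe2") and a thiosulfate-like
#' ("tsul") energy source into a biomass precursor; the second member
#' ("cut") can additionally assimilate pool glucose, the currency of the
#' biomass-recycling block, mimicking a bioleaching autotroph/facultative
#' heterotroph pair.
#'
#' @param spec a \code{\link{toy_spec}}.
#' @return list of two \code{\link{organism_model}} objects (\code{wen},
#'   \code{cut}).
#' @export
make_chemolithotroph_pair <- function(spec = toy_spec()) {
  list(wen = chemo_member("wen", spec, heterotroph = FALSE),
       cut = chemo_member("cut", spec, heterotroph = TRUE))
}

#' Chemolithotroph toy community
#'
#' Merges the chemolithotroph pair, closes external glucose (organic matter
#' enters only through biomass recycling) and optionally installs the
#' recycling block with fraction \code{alpha}.
#'
#' @param spec a \code{\link{toy_spec}}.
#' @param alpha biomass-recycling fraction in \[0, 1); \code{NULL} for none.
#' @param glucose_coefficient mmol glucose per gDW degraded biomass.
#' @return a \code{community_model}.
#' @export
make_chemolithotroph_community <- function(spec = toy_spec(), alpha = NULL,
                                           glucose_coefficient = 6.169) {
  pair <- make_chemolithotroph_pair(spec)
  cm <- build_community(unname(pair),
                        exchange_bounds = list(EX_glc_e = c(0, 1000)))
  if (!is.null(alpha))
    cm <- add_biomass_recycling(cm, alpha, glucose_coefficient)
  cm
}
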