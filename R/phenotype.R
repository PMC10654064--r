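## Qualitative flux states.  A reaction's feasible flux range [min, max] at a
## point of the abundance-growth space is reduced to one of eight categories
## combining flux sign, variability and requirement:
##   0            min = max = 0                    off, no plasticity
##   -  / +       fixed nonzero                    mandatory, no plasticity
##   -- / ++      variable, sign-definite          mandatory, flux plasticity
##   -0 / 0+ / -+ variable, range touches/spans 0  optional, structural plasticity

flux_categories <- c("0", "-", "+", "--", "++", "-0", "0+", "-+")

#' Classify a flux range into a qualitative state
#'
#' Values within \code{eps} of zero are snapped to zero first, so the eight
#' predicates are total and mutually exclusive.
#'
#' @param min,max range endpoints (vectors allowed, recycled jointly).
#' @param eps zero tolerance (default 1e-9, matching the solver's
#'   feasibility tolerance so categories are stable).
#' @return character vector of categories among
#'   \code{c("0","-","+","--","++","-0","0+","-+")}.
#' @export
categorize <- function(min, max, eps = 1e-9) {
  if (any(min > max + 1e-9)) stop("invalid range: min > max")
  ## collapse numerically equal endpoints before sign snapping, so solver
  ## noise cannot turn a pinned flux into a "variable" state
  pt <- (max - min) <= eps
  mid <- (min + max) / 2
  lo <- ifelse(pt, mid, min)
  hi <- ifelse(pt, mid, max)
  lo <- ifelse(abs(lo) <= eps, 0, lo)
  hi <- ifelse(abs(hi) <= eps, 0, hi)
  hi <- pmax(lo, hi)   # snapping cannot invert a legal range
  out <- character(length(lo))
  same <- lo == hi
  out[same & lo == 0] <- "0"
  out[same & lo < 0] <- "-"
  out[same & lo > 0] <- "+"
  out[!same & hi < 0] <- "--"
  out[!same & lo > 0] <- "++"
  out[!same & lo < 0 & hi == 0] <- "-0"
  out[!same & lo == 0 & hi > 0] <- "0+"
  out[!same & lo < 0 & hi > 0] <- "-+"
  out
}

#' Plasticity class of a qualitative state
#'
#' @param category vector of categories from \code{\link{categorize}}.
#' @return \code{"none"} (0, -, +), \code{"flux"} (--, ++) or
#'   \code{"structural"} (-0, 0+, -+).
#' @export
plasticity_class <- function(category) {
  out <- rep(NA_character_, length(category))
  out[category %in% c("0", "-", "+")] <- "none"
  out[category %in% c("--", "++")] <- "flux"
  out[category %in% c("-0", "0+", "-+")] <- "structural"
  out
}

#' Qualitative phenotype matrix over the abundance-growth grid
#'
#' Runs flux variability analysis at every feasible grid point and classifies
#' each selected reaction's range into its qualitative state.  Points are
#' processed in the grid's deterministic order.
#'
#' @param community a \code{community_model}.
#' @param grid an \code{ag_grid} from \code{\link{build_grid}}.
#' @param rxns selected reaction set R' (default: community exchange
#'   reactions).
#' @param eps zero tolerance passed to \code{\link{categorize}}.
#' @param constrain optional function \code{f(cmod)} returning a modified
#'   \code{constrained_model} (used for efficiency-constrained scenarios).
#' @param progress print a dot every 25 points.
#' @return an object of class \code{phenotype_matrix}: list with
#'   \code{points} (feasible grid points), \code{states} (character matrix,
#'   points x reactions), \code{min}/\code{max} (numeric matrices of raw
#'   ranges) and \code{eps}.
#' @export
phenotype_matrix <- function(community, grid, rxns = NULL, eps = 1e-9,
                             constrain = NULL, progress = FALSE) {
  if (is.null(rxns)) rxns <- community$exchange_ids
  pts <- feasible_points(grid)
  N <- length(community$members)
  states <- matrix(NA_character_, nrow(pts), length(rxns),
                   dimnames = list(NULL, rxns))
  mn <- mx <- matrix(NA_real_, nrow(pts), length(rxns),
                     dimnames = list(NULL, rxns))
  for (i in seq_len(nrow(pts))) {
    cmod <- apply_point(community, as.numeric(pts[i, seq_len(N)]),
                        pts$mu[i])
    if (!is.null(constrain)) cmod <- constrain(cmod)
    fr <- tryCatch(flux_ranges(cmod, rxns), error = function(e)
      stop("FVA failed at F = (",
           paste(signif(as.numeric(pts[i, seq_len(N)]), 4), collapse = ", "),
           "), mu = ", signif(pts$mu[i], 6), ": ", conditionMessage(e)))
    mn[i, ] <- fr$min; mx[i, ] <- fr$max
    states[i, ] <- categorize(fr$min, fr$max, eps)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(list(points = pts, states = states, min = mn, max = mx,
                 eps = eps, members = attr(grid, "members")),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat("<phenotype_matrix> ", nrow(x$states), " feasible points x ",
      ncol(x$states), " reactions\n", sep = "")
  tb <- table(factor(x$states, levels = flux_categories))
  cat("  states: ", paste(names(tb), tb, sep = ":", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Per-reaction plasticity summary
#'
#' Labels each reaction of a phenotype matrix as \code{blocked} (state "0" at
#' every point), \code{fixed} (a no-plasticity state everywhere, nonzero
#' somewhere) or \code{variable} (any plasticity somewhere).
#'
#' @param matrix a \code{phenotype_matrix}.
#' @return data frame with columns \code{rxn}, \code{label},
#'   \code{n_states}.
#' @export
plasticity_summary <- function(matrix) {
  st <- matrix$states
  lab <- vapply(seq_len(ncol(st)), function(j) {
    s <- st[, j]
    if (all(s == "0")) "blocked"
    else if (all(s %in% c("0", "-", "+"))) "fixed"
    else "variable"
  }, character(1))
  data.frame(rxn = colnames(st), label = lab,
             n_states = apply(st, 2, function(s) length(unique(s))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
summary.phenotype_matrix <- function(object, ...) {
  ps <- plasticity_summary(object)
  structure(list(n_points = nrow(object$states),
                 n_rxns = ncol(object$states),
                 labels = table(ps$label),
                 state_table = table(factor(object$states,
                                            levels = flux_categories))),
            class = "summary.phenotype_matrix")
}

#' @export
print.summary.phenotype_matrix <- function(x, ...) {
  cat("Phenotype matrix: ", x$n_points, " points x ", x$n_rxns,
      " reactions\n", sep = "")
  cat("  reactions: ",
      paste(names(x$labels), x$labels, sep = " = ", collapse = ", "),
      "\n  state counts:\n", sep = "")
  print(x$state_table)
  invisible(x)
}

#' Write a phenotype matrix to TSV
#'
#' Writes the categorical matrix (one row per point) and, optionally, a
#' companion TSV with the raw min/max ranges.
#'
#' @param matrix a \code{phenotype_matrix}.
#' @param path TSV path for the states; ranges go to \code{<path>.ranges.tsv}
#'   when \code{ranges = TRUE}.
#' @param ranges also write raw ranges (default \code{TRUE}).
#' @export
write_phenotypes <- function(matrix, path, ranges = TRUE) {
  df <- cbind(matrix$points, as.data.frame(matrix$states,
                                           stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (ranges) {
    long <- data.frame(matrix$points[rep(seq_len(nrow(matrix$points)),
                                         ncol(matrix$states)), ],
                       rxn = rep(colnames(matrix$states),
                                 each = nrow(matrix$states)),
                       min = as.numeric(matrix$min),
                       max = as.numeric(matrix$max))
    utils::write.table(long, paste0(path, ".ranges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
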