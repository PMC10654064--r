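#' Quantitative flux-coupling envelope of two reactions
#'
#' At a fixed abundance-growth point, spans the FVA range of reaction
#' \code{r1} with \code{n} homogeneous values (both extremes included); at
#' each value, \code{r1} is pinned and FVA is run on \code{r2}, giving the
#' feasible interval of \code{r2} conditional on \code{r1}.  Fluxes of
#' organism-owned reactions are divided by the owner's relative abundance to
#' express them in mmol/gDW of that organism per hour; community-level
#' reactions (owned by no organism) are reported unnormalized.
#'
#' A degenerate \code{r1} range (min = max) yields a single-sample envelope.
#' Pinning exactly at a range endpoint can be infeasible at solver precision;
#' such endpoints are nudged inward by 1e-9 with a warning.
#'
#' @param community a \code{community_model}.
#' @param F abundance vector.
#' @param mu community growth rate.
#' @param r1,r2 reaction ids.
#' @param n number of samples across the range of \code{r1} (default 50).
#' @param normalize divide organism fluxes by the owner's abundance
#'   (default \code{TRUE}).
#' @param constrain optional function transforming the
#'   \code{constrained_model} before analysis.
#' @return an object of class \code{coupling_envelope}: data frame with
#'   columns \code{v1}, \code{min2}, \code{max2}; attributes record the
#'   point, reactions, units and n.
#' @export
coupling_envelope <- function(community, F, mu, r1, r2, n = 50,
                              normalize = TRUE, constrain = NULL) {
  F <- abundance(F)
  stopifnot(r1 %in% colnames(community$S), r2 %in% colnames(community$S))
  cmod <- apply_point(community, F, mu)
  if (!is.null(constrain)) cmod <- constrain(cmod)
  own <- community$rxn_organism[c(r1, r2)]
  f_of <- stats::setNames(as.numeric(F), community$members)
  norm_fac <- function(rxn) {
    org <- community$rxn_organism[[rxn]]
    if (!normalize || is.na(org)) return(1)
    if (f_of[[org]] <= 0)
      stop("abundance of ", org, " is zero; per-organism normalization is ",
           "undefined - rerun with normalize = FALSE for raw units")
    f_of[[org]]
  }
  n1 <- norm_fac(r1); n2 <- norm_fac(r2)

  base <- flux_ranges(cmod, r1)
  lo <- base$min; hi <- base$max
  if (hi - lo <= 1e-12) {
    v1s <- lo
  } else {
    v1s <- seq(lo, hi, length.out = n)
  }
  min2 <- max2 <- numeric(length(v1s))
  j1 <- match(r1, colnames(community$S))
  for (i in seq_along(v1s)) {
    v <- v1s[i]
    cm2 <- cmod
    cm2$lb[j1] <- v; cm2$ub[j1] <- v
    fr <- tryCatch(flux_ranges(cm2, r2), error = function(e) NULL)
    if (is.null(fr) && (i == 1L || i == length(v1s))) {
      ## numerical edge at a range endpoint: nudge inward
      warning("endpoint of ", r1, " infeasible at solver precision; ",
              "nudged inward by 1e-9")
      v <- v + if (i == 1L) 1e-9 else -1e-9
      cm2$lb[j1] <- v; cm2$ub[j1] <- v
      fr <- flux_ranges(cm2, r2)
      v1s[i] <- v
    }
    if (is.null(fr)) stop("pinning ", r1, " = ", v, " is infeasible")
    min2[i] <- fr$min; max2[i] <- fr$max
  }
  out <- data.frame(v1 = v1s / n1, min2 = min2 / n2, max2 = max2 / n2)
  structure(out, class = c("coupling_envelope", "data.frame"),
            point = list(F = as.numeric(F), mu = mu),
            reactions = c(r1 = r1, r2 = r2), n = length(v1s),
            units = c(r1 = if (normalize && !is.na(own[1]))
                        "mmol/gDW_org/h" else "mmol/gDW_com/h",
                      r2 = if (normalize && !is.na(own[2]))
                        "mmol/gDW_org/h" else "mmol/gDW_com/h"))
}

#' @export
print.coupling_envelope <- function(x, ...) {
  rx <- attr(x, "reactions"); pt <- attr(x, "point")
  cat("<coupling_envelope> ", rx[["r1"]], " vs ", rx[["r2"]], " at F = (",
      paste(signif(pt$F, 4), collapse = ", "), "), mu = ",
      signif(pt$mu, 6), "\n", sep = "")
  cat("  ", attr(x, "n"), " samples; v1 in [",
      signif(min(x$v1), 6), ", ", signif(max(x$v1), 6), "]\n", sep = "")
  invisible(x)
}

#' Plot a coupling envelope
#'
#' @param x a \code{coupling_envelope}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.coupling_envelope <- function(x, ...) {
  rx <- attr(x, "reactions")
  graphics::plot(range(x$v1), range(c(x$min2, x$max2)), type = "n",
                 xlab = rx[["r1"]], ylab = rx[["r2"]], ...)
  graphics::polygon(c(x$v1, rev(x$v1)), c(x$min2, rev(x$max2)),
                    col = grDevices::adjustcolor("steelblue4", 0.4),
                    border = "steelblue4")
  invisible(x)
}

#' Write a coupling envelope to TSV with a JSON header sidecar
#'
#' @param envelope a \code{coupling_envelope}.
#' @param path output TSV path; metadata goes to \code{<path>.json}.
#' @export
write_envelope <- function(envelope, path) {
  utils::write.table(as.data.frame(envelope), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(point = attr(envelope, "point"),
               reactions = as.list(attr(envelope, "reactions")),
               units = as.list(attr(envelope, "units")),
               n = attr(envelope, "n"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
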