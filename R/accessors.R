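#' Accessors for EDNADataset objects
#'
#' \code{nSites} returns I, the total number of sites; \code{nDualSites}
#' returns J, the number of calibration sites with a known density;
#' \code{replicateCounts} returns the named vector of per-site replicate
#' counts K_i (ragged counts are allowed); \code{siteDensities} returns the
#' named density vector of the dual sites; \code{edna} returns the
#' replicate-level table; \code{ednaUnit} the shared measurement unit.
#'
#' @param x an \code{\linkS4class{EDNADataset}}.
#' @return see individual descriptions; site ids are kept in first-appearance
#'   order of the eDNA table.
#' @name EDNADataset-accessors
#' @aliases nSites nDualSites siteIDs dualSiteIDs ednaOnlyIDs replicateCounts
#'   siteDensities edna ednaUnit
NULL

#' @rdname EDNADataset-accessors
#' @export
setMethod("siteIDs", "EDNADataset", function(x) unique(x@edna$site_id))

#' @rdname EDNADataset-accessors
#' @export
setMethod("nSites", "EDNADataset", function(x) length(siteIDs(x)))

#' @rdname EDNADataset-accessors
#' @export
setMethod("nDualSites", "EDNADataset", function(x) length(x@density))

#' @rdname EDNADataset-accessors
#' @export
setMethod("dualSiteIDs", "EDNADataset", function(x) names(x@density))

#' @rdname EDNADataset-accessors
#' @export
setMethod("ednaOnlyIDs", "EDNADataset",
          function(x) setdiff(siteIDs(x), names(x@density)))

#' @rdname EDNADataset-accessors
#' @export
setMethod("replicateCounts", "EDNADataset", function(x) {
  ids <- siteIDs(x)
  k <- vapply(ids, function(s) sum(x@edna$site_id == s), integer(1))
  setNames(k, ids)
})

#' @rdname EDNADataset-accessors
#' @export
setMethod("siteDensities", "EDNADataset", function(x) x@density)

#' @rdname EDNADataset-accessors
#' @export
setMethod("edna", "EDNADataset", function(x) x@edna)

#' @rdname EDNADataset-accessors
#' @export
setMethod("ednaUnit", "EDNADataset", function(x) x@unit)

#' Model family of a ModelSpec, EDNAFit or EDNACV
#'
#' @param x object with an observation-model family.
#' @return one of \code{"normal"}, \code{"poisson"}, \code{"negbin"}.
#' @name modelFamily
NULL

#' @rdname modelFamily
#' @export
setMethod("modelFamily", "ModelSpec", function(x) x@family)

#' @rdname modelFamily
#' @export
setMethod("modelFamily", "EDNAFit", function(x) x@model@family)

#' @rdname modelFamily
#' @export
setMethod("modelFamily", "EDNACV", function(x) x@family)

#' Coefficients, log-likelihood and working-scale covariance of a fit
#'
#' \code{coef} returns all natural-scale MLEs as a named vector (beta0, the
#' dispersion where the family has one, then \code{D[<site>]} latent
#' densities); \code{logLik} the maximized log-likelihood with \code{df}
#' attribute; \code{vcov} the covariance of the working (log-transformed)
#' parameters from the inverse negative Hessian.
#'
#' @param object an \code{\linkS4class{EDNAFit}}.
#' @param ... unused.
#' @return see description.
#' @name EDNAFit-accessors
#' @aliases coef,EDNAFit-method logLik,EDNAFit-method vcov,EDNAFit-method
NULL

#' @rdname EDNAFit-accessors
#' @export
setMethod("coef", "EDNAFit", function(object, ...) {
  p <- object@estimates
  out <- c(beta0 = p@beta0)
  if (length(p@dispersion))
    out <- c(out, setNames(p@dispersion, dispersionName(object@model@family)))
  if (length(p@latentDensities))
    out <- c(out, setNames(p@latentDensities,
                           paste0("D[", names(p@latentDensities), "]")))
  out
})

#' @rdname EDNAFit-accessors
#' @export
setMethod("logLik", "EDNAFit", function(object, ...) {
  structure(object@loglik, df = length(coef(object)), class = "logLik")
})

#' @rdname EDNAFit-accessors
#' @export
setMethod("vcov", "EDNAFit", function(object, ...) object@vcov)

#' Standard errors and confidence intervals of a fit
#'
#' @param fit an \code{\linkS4class{EDNAFit}}.
#' @return \code{stdErrors}: named natural-scale SEs; \code{confIntervals}:
#'   matrix with columns \code{lower}, \code{upper} at the fit's CI level.
#' @export
stdErrors <- function(fit) {
  stopifnot(is(fit, "EDNAFit"))
  fit@se
}

#' @rdname stdErrors
#' @export
confIntervals <- function(fit) {
  stopifnot(is(fit, "EDNAFit"))
  fit@ci95
}

#' @rdname stdErrors
#' @export
isConverged <- function(fit) {
  stopifnot(is(fit, "EDNAFit"))
  fit@converged
}

#' Accessors for cross-validation results
#'
#' \code{cvRecords} returns the per-held-out-site data.frame (one row per
#' site per split); \code{cvSummary} a one-row data.frame of the pooled
#' summaries.
#'
#' @param x an \code{\linkS4class{EDNACV}}.
#' @name EDNACV-accessors
#' @aliases cvRecords cvSummary
NULL

#' @rdname EDNACV-accessors
#' @export
setMethod("cvRecords", "EDNACV", function(x) x@records)

#' @rdname EDNACV-accessors
#' @export
setMethod("cvSummary", "EDNACV", function(x) {
  data.frame(family = x@family, J = x@J, n_splits = x@nSplits,
             n_failed = x@nFailed, rmse = x@rmse, coverage = x@coverage,
             rank_accuracy = x@rankAccuracy, stringsAsFactors = FALSE)
})

setMethod("show", "EDNADataset", function(object) {
  k <- replicateCounts(object)
  cat("EDNADataset:", nSites(object), "sites (", nDualSites(object),
      "dual,", nSites(object) - nDualSites(object), "eDNA-only ),",
      nrow(object@edna), "observations [", object@unit, "]\n")
  cat("  replicates per site:", if (length(k)) paste(range(k), collapse = "-")
      else "none", "\n")
  if (nDualSites(object))
    cat("  known densities:",
        paste(sprintf("%s=%.4g", names(object@density), object@density),
              collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@family,
      "family, mean link mu_i = beta0 * D_i (through origin)\n")
})

setMethod("show", "ParameterVector", function(object) {
  cat("ParameterVector: beta0 =", format(object@beta0), "\n")
  if (length(object@dispersion))
    cat("  dispersion =", format(object@dispersion), "\n")
  if (length(object@latentDensities))
    cat("  latent densities:",
        paste(sprintf("%s=%.4g", names(object@latentDensities),
                      object@latentDensities), collapse = ", "), "\n")
})

setMethod("show", "EDNAFit", function(object) {
  cat("EDNAFit (", object@model@family, " family): ",
      if (object@converged) "converged" else "NOT converged", "\n", sep = "")
  cat("  sites: I =", object@I, ", dual J =", object@J,
      "; observations:", object@nobs, "\n")
  cat("  log-likelihood:", format(object@loglik), "\n")
  est <- coef(object)
  tab <- data.frame(estimate = est, se = object@se[names(est)],
                    lower = object@ci95[names(est), "lower"],
                    upper = object@ci95[names(est), "upper"])
  print(round(tab, 4))
})

setMethod("show", "EDNACV", function(object) {
  cat("EDNACV (", object@family, " family): exhaustive leave-p-out, J = ",
      object@J, " calibration sites\n", sep = "")
  cat("  splits:", object@nSplits, "( failed:", object@nFailed, ")\n")
  cat(sprintf("  RMSE = %.4g, realized coverage = %.3f, rank accuracy = %.3f\n",
              object@rmse, object@coverage, object@rankAccuracy))
})
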