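#' @import methods
#' @importFrom stats coef logLik vcov
NULL

VALID_UNITS <- c("copies_per_ml", "ng_per_l", "integerized")
VALID_FAMILIES <- c("normal", "poisson", "negbin")

#' EDNADataset: replicate-level eDNA measurements with optional site densities
#'
#' The central data container. One row of \code{edna(x)} per site x replicate
#' holds the measured eDNA quantity \eqn{w_{ik}}. Sites listed in
#' \code{siteDensities(x)} carry an independently measured animal density
#' (animals per square metre) and act as "dual data" calibration sites; the
#' remaining sites are "eDNA-only" and their densities are latent parameters
#' estimated by \code{\link{fitDensityModel}}.
#'
#' @slot edna data.frame with columns \code{site_id} (character),
#'   \code{replicate} (integer, 1..K_i within site) and \code{value}
#'   (non-negative numeric; integral when the unit is counts).
#' @slot unit single string, one of \code{"copies_per_ml"}, \code{"ng_per_l"},
#'   \code{"integerized"}. All observations in a dataset share one unit;
#'   mixed-unit tables are rejected rather than converted.
#' @slot density named numeric vector of known densities for the dual-data
#'   sites; names are site ids present in \code{edna}.
#'
#' @seealso \code{\link{EDNADataset}} (constructor),
#'   \code{\link{readEDNADataset}}, \code{\link{simulateDataset}}
#' @name EDNADataset-class
#' @rdname EDNADataset-class
#' @exportClass EDNADataset
setClass("EDNADataset",
  representation(edna = "data.frame", unit = "character", density = "numeric"),
  prototype(
    edna = data.frame(site_id = character(), replicate = integer(),
                      value = numeric()),
    unit = "copies_per_ml",
    density = setNames(numeric(0), character(0))
  )
)

setValidity("EDNADataset", function(object) {
  msg <- character(0)
  ed <- object@edna
  need <- c("site_id", "replicate", "value")
  if (!all(need %in% names(ed)))
    return(sprintf("edna table must have columns %s", paste(need, collapse = ", ")))
  if (length(object@unit) != 1L || !object@unit %in% VALID_UNITS)
    msg <- c(msg, sprintf("unit must be one of: %s", paste(VALID_UNITS, collapse = ", ")))
  if (any(!is.finite(ed$value)) || any(ed$value < 0))
    msg <- c(msg, "eDNA values must be finite and non-negative")
  if (length(object@unit) == 1L && object@unit %in% c("copies_per_ml", "integerized") &&
      nrow(ed) > 0 && any(abs(ed$value - round(ed$value)) > 1e-9))
    msg <- c(msg, sprintf("unit '%s' requires integer eDNA values", object@unit))
  key <- paste(ed$site_id, ed$replicate, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (site_id, replicate) rows")
  dn <- names(object@density)
  if (length(object@density) > 0) {
    if (is.null(dn) || anyDuplicated(dn))
      msg <- c(msg, "density vector must have unique site_id names")
    else if (!all(dn %in% ed$site_id))
      msg <- c(msg, sprintf("density given for unknown site(s): %s",
                            paste(setdiff(dn, ed$site_id), collapse = ", ")))
    if (any(!is.finite(object@density)) || any(object@density < 0))
      msg <- c(msg, "densities must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' ModelSpec: observation-model family for replicate eDNA values
#'
#' Fixes the distribution family used for the replicate eDNA quantities and
#' (implicitly) the mean link, which is always linear through the origin:
#' \eqn{\mu_i = \beta_0 D_i}. Zero animals must imply zero expected eDNA, so
#' no intercept is offered.
#'
#' @slot family one of \code{"normal"} (dispersion \eqn{\sigma^2}),
#'   \code{"poisson"} (no dispersion parameter) or \code{"negbin"}
#'   (dispersion \eqn{r}; smaller \eqn{r} = more overdispersion).
#' @name ModelSpec-class
#' @rdname ModelSpec-class
#' @exportClass ModelSpec
setClass("ModelSpec", representation(family = "character"),
         prototype(family = "negbin"))

setValidity("ModelSpec", function(object) {
  if (length(object@family) != 1L || !object@family %in% VALID_FAMILIES)
    sprintf("family must be one of: %s", paste(VALID_FAMILIES, collapse = ", "))
  else TRUE
})

#' ParameterVector: one point in the joint parameter space
#'
#' Holds the scaling coefficient \eqn{\beta_0} (expected eDNA units per unit
#' animal density), the family-specific dispersion (\eqn{\sigma^2} for the
#' normal family, \eqn{r} for the negative binomial, absent for Poisson), and
#' the latent densities of the eDNA-only sites.
#'
#' @slot beta0 positive scalar.
#' @slot dispersion positive scalar, or length-0 for the Poisson family.
#' @slot latentDensities named non-negative numeric vector, one entry per
#'   eDNA-only site of the dataset being analysed.
#' @name ParameterVector-class
#' @rdname ParameterVector-class
#' @exportClass ParameterVector
setClass("ParameterVector",
  representation(beta0 = "numeric", dispersion = "numeric",
                 latentDensities = "numeric"),
  prototype(beta0 = 1, dispersion = numeric(0),
            latentDensities = setNames(numeric(0), character(0)))
)

setValidity("ParameterVector", function(object) {
  msg <- character(0)
  if (length(object@beta0) != 1L || !is.finite(object@beta0) || object@beta0 <= 0)
    msg <- c(msg, "beta0 must be a positive finite scalar")
  if (length(object@dispersion) > 1L)
    msg <- c(msg, "dispersion must be length 0 or 1")
  if (length(object@dispersion) == 1L &&
      (!is.finite(object@dispersion) || object@dispersion <= 0))
    msg <- c(msg, "dispersion must be positive and finite")
  ld <- object@latentDensities
  if (length(ld) > 0 && (is.null(names(ld)) || anyDuplicated(names(ld))))
    msg <- c(msg, "latentDensities must have unique site_id names")
  if (any(!is.finite(ld)) || any(ld < 0))
    msg <- c(msg, "latent densities must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' EDNAFit: joint maximum-likelihood fit of an eDNA density model
#'
#' Result of \code{\link{fitDensityModel}}. Standard errors are on the
#' natural scale (delta method from the log-scale working covariance);
#' confidence intervals are Wald intervals floored at zero.
#'
#' @slot model the \code{ModelSpec} that was fit.
#' @slot estimates \code{ParameterVector} at the maximum.
#' @slot loglik maximized log-likelihood.
#' @slot vcov variance-covariance matrix over the working (log) parameters.
#' @slot se named numeric, natural-scale standard errors.
#' @slot ci95 matrix with columns \code{lower}, \code{upper}, one row per
#'   parameter, at the level recorded in \code{ciLevel}.
#' @slot ciLevel confidence level used (default 0.95).
#' @slot converged logical; FALSE when optimization or curvature extraction
#'   failed (never an exception).
#' @slot nobs total number of replicate observations.
#' @slot I,J site counts (total, dual).
#' @slot K named integer vector of per-site replicate counts.
#' @slot dualSites character vector of calibration site ids.
#' @name EDNAFit-class
#' @rdname EDNAFit-class
#' @exportClass EDNAFit
setClass("EDNAFit",
  representation(model = "ModelSpec", estimates = "ParameterVector",
                 loglik = "numeric", vcov = "matrix", se = "numeric",
                 ci95 = "matrix", ciLevel = "numeric", converged = "logical",
                 nobs = "integer", I = "integer", J = "integer",
                 K = "integer", dualSites = "character")
)

setValidity("EDNAFit", function(object) {
  msg <- character(0)
  if (length(object@se) && any(object@se < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be non-negative")
  if (nrow(object@ci95) > 0 &&
      !identical(colnames(object@ci95), c("lower", "upper")))
    msg <- c(msg, "ci95 must have columns lower, upper")
  if (length(msg)) msg else TRUE
})

#' EDNACV: exhaustive leave-p-out cross-validation result
#'
#' One row of \code{cvRecords(x)} per held-out site per split, with the
#' density estimate, its Wald interval, the signed error
#' \eqn{\epsilon_i = \hat D_i - D_i} and the coverage indicator. Aggregates
#' (RMSE, realized coverage, rank accuracy) pool all held-out records of all
#' converged splits.
#'
#' @slot family model family used.
#' @slot J number of calibration sites kept per split.
#' @slot nSplits number of splits enumerated, \eqn{C(I, J)}.
#' @slot records data.frame: split, site_id, true_density, estimate, se,
#'   ci_lower, ci_upper, error, covered.
#' @slot rmse,coverage,rankAccuracy pooled performance summaries.
#' @slot nFailed number of non-converged splits (excluded from aggregates).
#' @name EDNACV-class
#' @rdname EDNACV-class
#' @exportClass EDNACV
setClass("EDNACV",
  representation(family = "character", J = "integer", nSplits = "integer",
                 records = "data.frame", rmse = "numeric", coverage = "numeric",
                 rankAccuracy = "numeric", nFailed = "integer")
)

#' Construct an EDNADataset
#'
#' @param edna data.frame with columns \code{site_id}, \code{replicate},
#'   \code{value} (a \code{unit} column is also accepted and checked).
#' @param density optional named numeric vector, or data.frame with columns
#'   \code{site_id} and \code{density}, giving known animal densities for
#'   the dual-data sites.
#' @param unit measurement unit shared by all observations. Defaults to the
#'   table's \code{unit} column when present, else \code{"copies_per_ml"}.
#' @return validated \code{\linkS4class{EDNADataset}}.
#' @examples
#' d <- EDNADataset(
#'   data.frame(site_id = rep(c("a", "b"), each = 2),
#'              replicate = c(1, 2, 1, 2), value = c(10, 12, 3, 5)),
#'   density = c(a = 2.5))
#' nSites(d); nDualSites(d)
#' @export
EDNADataset <- function(edna, density = NULL, unit = NULL) {
  edna <- as.data.frame(edna)
  if ("unit" %in% names(edna)) {
    u <- unique(as.character(edna$unit))
    if (length(u) > 1L)
      stop("mixed units within one dataset are not supported: ",
           paste(u, collapse = ", "))
    if (is.null(unit)) unit <- u
    else if (length(u) == 1L && !identical(unit, u))
      stop("'unit' argument disagrees with the table's unit column")
  }
  if (is.null(unit)) unit <- "copies_per_ml"
  if (is.data.frame(density)) {
    if (!all(c("site_id", "density") %in% names(density)))
      stop("density table must have columns site_id, density")
    if (anyDuplicated(density$site_id))
      stop("duplicate site_id in density table")
    density <- setNames(as.numeric(density$density),
                        as.character(density$site_id))
  }
  if (is.null(density)) density <- setNames(numeric(0), character(0))
  edna <- data.frame(site_id = as.character(edna$site_id),
                     replicate = as.integer(edna$replicate),
                     value = as.numeric(edna$value),
                     stringsAsFactors = FALSE)
  new("EDNADataset", edna = edna, unit = unit, density = density)
}

#' Construct a ModelSpec
#'
#' @param family \code{"normal"}, \code{"poisson"} or \code{"negbin"}.
#' @return a \code{\linkS4class{ModelSpec}}.
#' @export
ModelSpec <- function(family = c("negbin", "normal", "poisson")) {
  new("ModelSpec", family = match.arg(family))
}

#' Construct a ParameterVector
#'
#' @param beta0 positive scaling coefficient (eDNA units per unit density).
#' @param dispersion \eqn{\sigma^2} (normal) or \eqn{r} (negbin); omit for
#'   Poisson.
#' @param latentDensities named non-negative vector of densities for the
#'   eDNA-only sites.
#' @return a \code{\linkS4class{ParameterVector}}.
#' @export
ParameterVector <- function(beta0, dispersion = numeric(0),
                            latentDensities = setNames(numeric(0), character(0))) {
  new("ParameterVector", beta0 = as.numeric(beta0),
      dispersion = as.numeric(dispersion),
      latentDensities = latentDensities)
}
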