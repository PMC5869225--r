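# Exact log-likelihoods for the three observation families under the
# linear-through-origin mean link. All count arithmetic goes through lgamma;
# Gamma itself is never evaluated (copy numbers in the tens of thousands
# would overflow it).

dispersionName <- function(family) {
  switch(family, normal = "sigma2", negbin = "r",
         poisson = character(0))
}

#' Expected eDNA quantity at a given animal density
#'
#' The mean link is linear through the origin: \eqn{\mu = \beta_0 D}. Zero
#' animals imply zero expected eDNA; no intercept is available.
#'
#' @param beta0 positive scaling coefficient (eDNA units per unit density).
#' @param density non-negative animal density (animals per square metre).
#' @return \code{beta0 * density}, vectorized over \code{density}.
#' @examples
#' meanFunction(2, 3)    # 6
#' meanFunction(5, 0)    # 0
#' @export
meanFunction <- function(beta0, density) {
  if (any(!is.finite(beta0)) || any(beta0 <= 0))
    stop("beta0 must be positive")
  if (any(!is.finite(density)) || any(density < 0))
    stop("density must be non-negative")
  beta0 * density
}

#' Negative-binomial success probability at a given mean
#'
#' Under the (mu, r) parameterization the per-trial success probability is
#' \eqn{p = r / (\mu + r)}; it equals 1 when the mean is zero and decreases
#' towards 0 as the mean grows.
#'
#' @param mu non-negative expected count.
#' @param r positive dispersion ("target number of successful trials";
#'   smaller r = more overdispersion, variance \eqn{\mu + \mu^2/r}).
#' @return value(s) in (0, 1].
#' @examples
#' nbSuccessProb(1, 1)  # 0.5
#' nbSuccessProb(0, 5)  # 1
#' @export
nbSuccessProb <- function(mu, r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive")
  if (any(!is.finite(mu)) || any(mu < 0)) stop("mu must be non-negative")
  r / (mu + r)
}

# Resolve one density per site: known for dual sites, latent otherwise.
# Returns the vector aligned with siteIDs(dataset).
siteDensityVector <- function(dataset, params) {
  ids <- siteIDs(dataset)
  known <- siteDensities(dataset)
  lat <- params@latentDensities
  d <- setNames(rep(NA_real_, length(ids)), ids)
  d[names(known)] <- known
  hit <- intersect(names(lat), ids[is.na(d)])
  d[hit] <- lat[hit]
  if (anyNA(d))
    stop("no density (known or latent) for site(s): ",
         paste(ids[is.na(d)], collapse = ", "))
  d
}

checkCountData <- function(w, family) {
  if (any(abs(w - round(w)) > 1e-9))
    stop("the ", family, " family requires integer eDNA values; ",
         "integerize() continuous concentrations first")
}

# Per-observation log-density vectors; mu recycled per observation.
normalLogTerms <- function(w, mu, sigma2) {
  -0.5 * log(2 * pi * sigma2) - (w - mu)^2 / (2 * sigma2)
}

poissonLogTerms <- function(w, mu) {
  out <- numeric(length(w))
  z <- mu == 0
  # point mass at 0 when the mean is 0
  out[z] <- ifelse(w[z] == 0, 0, -Inf)
  if (any(!z))
    out[!z] <- w[!z] * log(mu[!z]) - mu[!z] - lgamma(w[!z] + 1)
  out
}

negbinLogTerms <- function(w, mu, r) {
  out <- numeric(length(w))
  z <- mu == 0
  out[z] <- ifelse(w[z] == 0, 0, -Inf)
  if (any(!z)) {
    p <- r / (mu[!z] + r)
    wi <- w[!z]
    out[!z] <- lgamma(wi + r) - lgamma(wi + 1) - lgamma(r) +
      r * log(p) + wi * log1p(-p)
  }
  out
}

#' Log-likelihood of an eDNA dataset under one observation family
#'
#' The joint log-likelihood over all sites and replicates,
#' \eqn{\sum_i \sum_k \log f(w_{ik} \mid \mu_i, \theta)} with
#' \eqn{\mu_i = \beta_0 D_i}, where \eqn{D_i} is the known density at dual
#' sites and the latent density from \code{params} elsewhere.
#'
#' For the count families a site mean of exactly zero is treated as a point
#' mass at zero: a zero count contributes 0, a positive count \code{-Inf}.
#'
#' @param dataset an \code{\linkS4class{EDNADataset}}; every site must have a
#'   known or latent density.
#' @param params a \code{\linkS4class{ParameterVector}} with the appropriate
#'   dispersion slot (\eqn{\sigma^2} for normal, \eqn{r} for negbin, empty
#'   for Poisson).
#' @return scalar log-likelihood.
#' @seealso \code{\link{fitDensityModel}} which maximizes these.
#' @examples
#' d <- EDNADataset(data.frame(site_id = "a", replicate = 1:2,
#'                             value = c(3, 5)), density = c(a = 2))
#' negbinLogLik(d, ParameterVector(beta0 = 2, dispersion = 1))
#' @export
normalLogLik <- function(dataset, params) {
  if (length(params@dispersion) != 1L || params@dispersion <= 0)
    stop("normal family requires dispersion sigma2 > 0")
  d <- siteDensityVector(dataset, params)
  ed <- edna(dataset)
  mu <- meanFunction(params@beta0, d)[ed$site_id]
  sum(normalLogTerms(ed$value, mu, params@dispersion))
}

#' @rdname normalLogLik
#' @export
poissonLogLik <- function(dataset, params) {
  ed <- edna(dataset)
  checkCountData(ed$value, "poisson")
  d <- siteDensityVector(dataset, params)
  mu <- meanFunction(params@beta0, d)[ed$site_id]
  sum(poissonLogTerms(ed$value, mu))
}

#' @rdname normalLogLik
#' @export
negbinLogLik <- function(dataset, params) {
  if (length(params@dispersion) != 1L || params@dispersion <= 0)
    stop("negbin family requires dispersion r > 0")
  ed <- edna(dataset)
  checkCountData(ed$value, "negbin")
  d <- siteDensityVector(dataset, params)
  mu <- meanFunction(params@beta0, d)[ed$site_id]
  sum(negbinLogTerms(ed$value, mu, params@dispersion))
}

#' @rdname normalLogLik
#' @param model a \code{\linkS4class{ModelSpec}} selecting the family.
#' @export
ednaLogLik <- function(dataset, params, model) {
  switch(modelFamily(model),
         normal = normalLogLik(dataset, params),
         poisson = poissonLogLik(dataset, params),
         negbin = negbinLogLik(dataset, params))
}
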