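# Joint ML estimation of (beta0, dispersion, latent densities) with Wald
# uncertainty. Optimization is unconstrained over the working coordinates
# ln(beta0), ln(dispersion), ln(D_i + 1e-12); natural-scale SEs follow by
# the delta method from the inverse negative Hessian.

LOG_EPS <- 1e-12

#' Wald confidence interval
#'
#' \code{estimate +/- z * se} with \code{z} the standard-normal quantile for
#' the requested two-sided level (1.959964 at 0.95). A lower floor (0 for
#' densities, which cannot be negative) may be applied.
#'
#' @param estimate point estimate.
#' @param se non-negative standard error.
#' @param level confidence level in (0, 1).
#' @param floor optional lower bound imposed on the interval (use 0 for
#'   non-negative quantities); \code{NULL} for none.
#' @return numeric c(lower, upper).
#' @examples
#' confidenceInterval(10, 1)            # 8.04, 11.96
#' confidenceInterval(0, 2, floor = 0)  # 0, 3.92
#' @export
confidenceInterval <- function(estimate, se, level = 0.95, floor = NULL) {
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  if (any(!is.finite(se)) || any(se < 0)) stop("se must be non-negative")
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- estimate - z * se
  hi <- estimate + z * se
  if (!is.null(floor)) {
    lo <- pmax(lo, floor)
    hi <- pmax(hi, floor)
  }
  c(lower = lo, upper = hi)
}

# Deterministic, data-driven starting values in working coordinates.
startingValues <- function(ed, knownD, freeIds, family) {
  dual <- ed[!is.na(knownD[ed$site_id]), , drop = FALSE]
  Dd <- knownD[dual$site_id]
  wbar <- tapply(dual$value, dual$site_id, mean)
  Dsite <- knownD[names(wbar)]
  beta0 <- sum(wbar * Dsite) / sum(Dsite^2)   # LS through origin on site means
  if (!is.finite(beta0) || beta0 <= 0) {
    beta0 <- sum(dual$value) / sum(Dd)
    if (!is.finite(beta0) || beta0 <= 0) beta0 <- 1
  }
  x <- log(beta0)
  if (family == "negbin") {
    # per-site method of moments r = m^2 / (s^2 - m), median over dual sites
    rs <- vapply(split(dual$value, dual$site_id), function(w) {
      if (length(w) < 2) return(NA_real_)
      m <- mean(w); v <- stats::var(w)
      if (v > m && m > 0) m^2 / (v - m) else NA_real_
    }, numeric(1))
    r0 <- stats::median(rs, na.rm = TRUE)
    if (!is.finite(r0)) r0 <- 1
    x <- c(x, log(min(max(r0, 0.01), 1e6)))
  }
  if (length(freeIds)) {
    wfree <- tapply(ed$value[ed$site_id %in% freeIds],
                    ed$site_id[ed$site_id %in% freeIds], mean)[freeIds]
    x <- c(x, log(wfree / beta0 + LOG_EPS))
  }
  x
}

# Cox-Reid adjusted profile likelihood for the negative-binomial dispersion.
# For each candidate log(r), the mean parameters (log beta0, log latent D)
# are re-maximized and the profile deviance is penalized by half the
# log-determinant of their observed information, removing the O(p/n) upward
# bias of the ML dispersion. x is the working vector c(log beta0, log r,
# log D...); returns the updated working vector.
crAdjustNegbin <- function(negll, x, nPar, maxit = 10000) {
  meanIdx <- setdiff(seq_len(nPar), 2L)
  warm <- x[meanIdx]                       # warm start across outer steps
  innerFit <- function(fm, xm0) {
    inner <- tryCatch(
      stats::optim(xm0, fm,
                   method = if (length(xm0) == 1L) "BFGS" else "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(inner) || !is.finite(inner$value)) return(NULL)
    if (length(xm0) > 1L) {
      for (m in c("BFGS", "Nelder-Mead", "BFGS")) {
        pol <- tryCatch(
          stats::optim(inner$par, fm, method = m,
                       control = list(maxit = 1000, reltol = 1e-14)),
          error = function(e) NULL)
        if (!is.null(pol) && is.finite(pol$value) && pol$value < inner$value)
          inner <- pol
      }
    }
    inner
  }
  profileAdj <- function(logr) {
    fm <- function(xm) negll(append(xm, logr, after = 1L))
    inner <- innerFit(fm, warm)
    if (is.null(inner)) return(list(val = Inf))
    warm <<- inner$par
    Hm <- tryCatch(numericHessian(fm, inner$par), error = function(e) NULL)
    if (is.null(Hm) || !all(is.finite(Hm))) return(list(val = Inf))
    ld <- determinant(Hm, logarithm = TRUE)
    if (ld$sign <= 0) return(list(val = Inf))
    list(val = inner$value + 0.5 * as.numeric(ld$modulus), par = inner$par)
  }
  opt <- tryCatch(
    stats::optimize(function(lr) profileAdj(lr)$val,
                    interval = c(x[2] - 6, x[2] + 3), tol = 1e-6),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) return(x)
  warm <- x[meanIdx]                       # refit cleanly at the optimum
  best <- profileAdj(opt$minimum)
  if (!is.finite(best$val) || is.null(best$par)) return(x)
  append(best$par, opt$minimum, after = 1L)
}

# Central-difference Hessian with relative step.
numericHessian <- function(fn, x, rel = 1e-5) {
  n <- length(x)
  h <- rel * pmax(abs(x), 1)
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(n), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) -
         fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit the joint eDNA-density model by maximum likelihood
#'
#' Maximizes the chosen family's log-likelihood jointly over the scaling
#' coefficient beta0, the family dispersion (sigma2 or r) and the latent
#' densities of every eDNA-only site. Dual-data sites (those with a known
#' density) identify beta0; at least one is required. Optimization works on
#' log-transformed parameters (positivity for free), the covariance comes
#' from a central-finite-difference Hessian, and natural-scale standard
#' errors follow by the delta method. Optimizer failure is reported through
#' \code{isConverged(fit) == FALSE}, never as an exception.
#'
#' @param dataset an \code{\linkS4class{EDNADataset}} with J >= 1 dual sites.
#' @param model a \code{\linkS4class{ModelSpec}} (or family string).
#' @param ciLevel two-sided confidence level for the Wald intervals.
#' @param ciScale \code{"log"} (default) builds intervals in the working
#'   coordinates and back-transforms, \code{exp(log estimate +/- z * se_log)}
#'   — the standard construction for positive parameters, asymmetric and
#'   strictly positive; \code{"natural"} uses the symmetric
#'   \code{estimate +/- z * se} floored at 0. For the strongly right-skewed
#'   latent-density estimators that arise from few, overdispersed replicates
#'   the log-scale interval holds its nominal coverage markedly better (the
#'   methods vignette quantifies this).
#' @param adjustDispersion apply the standard small-sample correction to the
#'   dispersion estimate (default TRUE): REML-type rescaling of
#'   \eqn{\hat\sigma^2} by n/(n - p) for the normal family, Cox-Reid
#'   adjusted profile likelihood for the negative binomial r. With few
#'   replicates and several estimated mean parameters (beta0 plus one latent
#'   density per eDNA-only site) the plain ML dispersion is biased towards
#'   "too little dispersion", which narrows every interval below nominal
#'   coverage; the adjustment removes most of that bias. Set FALSE for the
#'   uncorrected joint MLE. Poisson fits are unaffected.
#' @param reltol optimizer relative tolerance.
#' @param maxit maximum optimizer iterations.
#' @param nRestarts jittered restarts attempted when the first optimization
#'   fails (deterministic jitter; the global RNG stream is left untouched).
#' @return an \code{\linkS4class{EDNAFit}}.
#' @examples
#' sim <- simulateDataset(I = 6, J = 3, K = 3, beta0 = 50, family = "negbin",
#'                        dispersion = 1, densityRange = c(2, 40), seed = 1)
#' fit <- fitDensityModel(sim$dataset, ModelSpec("negbin"))
#' predictDensities(fit)
#' @export
fitDensityModel <- function(dataset, model = ModelSpec("negbin"),
                            ciLevel = 0.95, ciScale = c("log", "natural"),
                            adjustDispersion = TRUE, reltol = 1e-8,
                            maxit = 10000, nRestarts = 5) {
  ciScale <- match.arg(ciScale)
  stopifnot(is(dataset, "EDNADataset"))
  if (is.character(model)) model <- ModelSpec(model)
  family <- modelFamily(model)
  if (nDualSites(dataset) < 1L)
    stop("beta0 is unidentifiable without at least one dual-data site ",
         "(a site with known density)")
  ed <- edna(dataset)
  if (family %in% c("poisson", "negbin")) checkCountData(ed$value, family)
  ids <- siteIDs(dataset)
  known <- siteDensities(dataset)
  knownD <- setNames(rep(NA_real_, length(ids)), ids)
  knownD[names(known)] <- known
  if (all(ed$value[ed$site_id %in% names(known)] == 0))
    stop("degenerate data: every replicate at every dual site is zero, ",
         "so beta0 collapses to the boundary")
  freeIds <- ids[is.na(knownD)]
  hasDisp <- family != "poisson"       # sigma2 / r reported
  dispInWork <- family == "negbin"     # sigma2 is concentrated out, r is not
  # under a count family, an eDNA-only site whose replicates are all zero
  # has its MLE on the D = 0 boundary: fix it there instead of letting the
  # optimizer chase log(D) to -Inf; it gets an exact one-sided upper bound
  zeroIds <- character(0)
  if (family %in% c("poisson", "negbin") && length(freeIds))
    zeroIds <- freeIds[vapply(freeIds, function(s)
      all(ed$value[ed$site_id == s] == 0), logical(1))]
  optIds <- setdiff(freeIds, zeroIds)
  nFree <- length(optIds)
  nWork <- 1L + as.integer(dispInWork) + nFree
  obsSite <- match(ed$site_id, ids)
  w <- ed$value
  n <- length(w)
  freeIdx <- match(optIds, ids)
  Dbase <- knownD
  Dbase[match(zeroIds, ids)] <- 0
  # profile sigma2 = RSS/n, floored so an exact (noiseless) fit stays finite
  s2floor <- 1e-12 * mean(w^2) + 1e-300

  muOf <- function(x) {
    D <- Dbase
    if (nFree) D[freeIdx] <- exp(x[(nWork - nFree + 1):nWork])
    exp(x[1]) * D[obsSite]
  }
  negll <- function(x) {
    mu <- muOf(x)
    ll <- switch(family,
      normal = {
        s2 <- max(mean((w - mu)^2), s2floor)
        sum(normalLogTerms(w, mu, s2))
      },
      poisson = sum(poissonLogTerms(w, mu)),
      negbin = sum(negbinLogTerms(w, mu, exp(x[2]))))
    if (!is.finite(ll)) 1e12 else -ll
  }

  x0 <- startingValues(ed, knownD, optIds, family)
  runOpt <- function(x) {
    method <- if (length(x) == 1L) "BFGS" else "Nelder-Mead"
    tryCatch(stats::optim(x, negll, method = method,
                          control = list(maxit = maxit, reltol = reltol)),
             error = function(e) NULL)
  }
  polish <- function(opt) {
    if (length(opt$par) == 1L) {
      p <- tryCatch(stats::optimize(function(v) negll(v),
                                    interval = opt$par + c(-2, 2),
                                    tol = 1e-12),
                    error = function(e) NULL)
      if (!is.null(p) && is.finite(p$objective) && p$objective <= opt$value)
        return(list(par = p$minimum, value = p$objective,
                    convergence = opt$convergence))
      return(opt)
    }
    for (m in c("BFGS", "Nelder-Mead")) {
      p <- tryCatch(
        stats::optim(opt$par, negll, method = m,
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(p) && is.finite(p$value) && p$value < opt$value)
        opt <- list(par = p$par, value = p$value,
                    convergence = opt$convergence)
    }
    opt
  }
  okOpt <- function(o) !is.null(o) && is.finite(o$value) && o$value < 1e12

  opt <- runOpt(x0)
  optConverged <- okOpt(opt) && opt$convergence == 0
  if (!optConverged) {
    # deterministic jitter; protect the caller's RNG stream
    seedState <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(seedState))
      assign(".Random.seed", seedState, envir = globalenv()), add = TRUE)
    for (s in seq_len(nRestarts)) {
      set.seed(1000L + s)
      cand <- runOpt(x0 + stats::rnorm(length(x0), sd = 0.5))
      if (okOpt(cand) && cand$convergence == 0 &&
          (!okOpt(opt) || cand$value < opt$value)) {
        opt <- cand
        optConverged <- TRUE
        break
      }
      if (okOpt(cand) && (!okOpt(opt) || cand$value < opt$value)) opt <- cand
    }
  }
  if (!okOpt(opt)) {
    opt <- list(par = x0, value = negll(x0), convergence = 1L)
    optConverged <- FALSE
  }
  opt <- polish(opt)

  xhat <- opt$par
  pMean <- 1L + nFree                   # mean parameters: beta0 + latent D

  if (adjustDispersion && family == "negbin" && n > pMean)
    xhat <- crAdjustNegbin(negll, xhat, nWork, maxit = maxit)

  # working-coordinate covariance from the observed information
  H <- tryCatch(numericHessian(negll, xhat), error = function(e) NULL)
  vc <- NULL
  hessOK <- FALSE
  if (!is.null(H) && all(is.finite(H))) {
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (!is.null(ch)) {
      vc <- chol2inv(ch)
      hessOK <- TRUE
    }
  }
  if (!hessOK) {
    dH <- if (!is.null(H)) diag(as.matrix(H)) else rep(NA_real_, nWork)
    dH[!is.finite(dH) | dH <= 0] <- 1e12   # near-flat direction: huge SE
    vc <- diag(1 / dH, nrow = nWork)
  }

  repNames <- c("beta0", if (dispInWork) "r",
                if (nFree) paste0("D[", optIds, "]"))
  xRep <- xhat
  if (family == "normal") {
    # sigma2 was concentrated out; reinstate it for reporting with its
    # classical variance 2*sigma4/df on the log scale
    df <- if (adjustDispersion) max(n - pMean, 1L) else n
    s2 <- max(mean((w - muOf(xhat))^2), s2floor) * n / df
    xRep <- append(xhat, log(s2), after = 1L)
    repNames <- append(repNames, "sigma2", after = 1L)
    vcFull <- matrix(0, nWork + 1L, nWork + 1L)
    vcFull[-2L, -2L] <- vc
    vcFull[2L, 2L] <- 2 / df
    vc <- vcFull
  }
  natural <- setNames(exp(xRep), repNames)
  dimnames(vc) <- list(repNames, repNames)

  seLog <- setNames(sqrt(pmax(diag(vc), 0)), repNames)
  seNat <- natural * seLog            # delta method for exp()
  z <- stats::qnorm(1 - (1 - ciLevel) / 2)
  ci <- if (ciScale == "log") {
    cbind(lower = exp(xRep - z * seLog), upper = exp(xRep + z * seLog))
  } else {
    t(vapply(repNames, function(p)
      confidenceInterval(natural[p], seNat[p], level = ciLevel, floor = 0),
      numeric(2)))
  }
  dimnames(ci) <- list(repNames, c("lower", "upper"))

  if (length(zeroIds)) {
    # boundary estimates: D = 0 exactly, with the exact one-sided upper
    # bound solving P(all K_i replicates are zero | mu) = 1 - ciLevel
    alpha <- 1 - ciLevel
    b0 <- unname(natural["beta0"])
    zn <- paste0("D[", zeroIds, "]")
    zUp <- vapply(zeroIds, function(s) {
      k <- sum(ed$site_id == s)
      mu <- if (family == "poisson") -log(alpha) / k
            else {
              r <- unname(natural["r"])
              r * (alpha^(-1 / (r * k)) - 1)
            }
      mu / b0
    }, numeric(1))
    allNames <- c(repNames[!grepl("^D\\[", repNames)],
                  paste0("D[", freeIds, "]"))
    natural <- c(natural, setNames(numeric(length(zn)), zn))[allNames]
    seNat <- c(seNat, setNames(numeric(length(zn)), zn))[allNames]
    ciZ <- rbind(ci, matrix(c(numeric(length(zn)), zUp), ncol = 2,
                            dimnames = list(zn, c("lower", "upper"))))
    ci <- ciZ[allNames, , drop = FALSE]
    vcFull <- matrix(0, length(allNames), length(allNames),
                     dimnames = list(allNames, allNames))
    vcFull[repNames, repNames] <- vc
    vc <- vcFull
    repNames <- allNames
  }

  latent <- setNames(natural[grepl("^D\\[", repNames)], freeIds)
  est <- new("ParameterVector", beta0 = unname(natural["beta0"]),
             dispersion = if (hasDisp) unname(natural[dispersionName(family)])
                          else numeric(0),
             latentDensities = latent)
  llFinal <- if (family == "normal")
    sum(normalLogTerms(w, muOf(xhat), unname(natural["sigma2"])))
  else -negll(xhat)

  new("EDNAFit", model = model, estimates = est, loglik = llFinal,
      vcov = vc, se = seNat, ci95 = ci, ciLevel = ciLevel,
      converged = isTRUE(optConverged) && hessOK,
      nobs = nrow(ed), I = nSites(dataset), J = nDualSites(dataset),
      K = replicateCounts(dataset), dualSites = dualSiteIDs(dataset))
}

#' Density estimates for the eDNA-only sites of a fit
#'
#' One record per eDNA-only site with its estimated density, natural-scale
#' SE, and Wald interval floored at zero. Refuses non-converged fits.
#'
#' @param object a converged \code{\linkS4class{EDNAFit}}.
#' @param ... unused.
#' @return data.frame: site_id, estimate, se, ci_lower, ci_upper.
#' @rdname predictDensities
#' @export
setMethod("predictDensities", "EDNAFit", function(object, ...) {
  if (!object@converged)
    stop("fit did not converge; density predictions would be unreliable ",
         "(inspect the data or increase restarts)")
  lat <- object@estimates@latentDensities
  ids <- names(lat)
  pn <- paste0("D[", ids, "]")
  data.frame(site_id = ids,
             estimate = unname(lat),
             se = unname(object@se[pn]),
             ci_lower = unname(object@ci95[pn, "lower"]),
             ci_upper = unname(object@ci95[pn, "upper"]),
             stringsAsFactors = FALSE, row.names = NULL)
})
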