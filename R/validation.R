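# Exhaustive leave-p-out cross-validation: every C(I, J) choice of J
# calibration sites is fit once; the held-out sites' known densities are
# scored against the model's latent-density estimates.

#' Enumerate all calibration subsets of size J
#'
#' All \eqn{C(I, J)} ways of keeping J of I sites as dual-data calibration
#' sites, in deterministic lexicographic order (column order of
#' \code{utils::combn}).
#'
#' @param I total number of sites (or a character vector of site ids).
#' @param J subset size, 1 <= J <= I.
#' @return list of length \eqn{C(I, J)}; each element an index (or id)
#'   vector of length J.
#' @examples
#' length(enumerateSplits(11, 3))  # 165
#' @export
enumerateSplits <- function(I, J) {
  ids <- if (is.character(I)) I else seq_len(I)
  n <- length(ids)
  if (!is.numeric(J) || length(J) != 1L || J < 1 || J > n)
    stop("J must satisfy 1 <= J <= I")
  cmb <- utils::combn(ids, as.integer(J), simplify = FALSE)
  cmb
}

#' Root mean squared error
#'
#' \code{sqrt(mean(errors^2))} over all cross-validation errors
#' \eqn{\epsilon_i = \hat D_i - D_i}.
#'
#' @param errors non-empty numeric vector of signed errors.
#' @return non-negative scalar.
#' @examples
#' rmse(c(3, -4))  # 3.535534
#' @export
rmse <- function(errors) {
  if (length(errors) == 0) stop("rmse of an empty error vector is undefined")
  sqrt(mean(errors^2))
}

#' Realized coverage of the confidence intervals
#'
#' The fraction of held-out records whose known density fell inside its
#' interval, pooled over all records of all (converged) repetitions. For a
#' well-behaved 95\% interval this should be very close to 0.95.
#'
#' @param records data.frame of held-out records with a logical
#'   \code{covered} column (as in \code{cvRecords}), or an
#'   \code{\linkS4class{EDNACV}}.
#' @return proportion in [0, 1].
#' @export
realizedCoverage <- function(records) {
  if (is(records, "EDNACV")) records <- cvRecords(records)
  if (NROW(records) == 0) stop("no held-out records")
  mean(records$covered)
}

#' Rate of correct relative rank assignment
#'
#' Pairwise concordance: within each repetition, over all unordered pairs of
#' held-out sites, a pair scores 1 when the estimates order the two sites the
#' same way their true densities do, 0 when they reverse it, and 1/2 when
#' either the truths or the estimates are tied. The rate is the mean score
#' over all pairs of all repetitions (a Kendall-type statistic: 1 = every
#' pair ranked correctly, 0 = every pair reversed).
#'
#' @param records as in \code{\link{realizedCoverage}}; needs columns
#'   \code{split}, \code{true_density}, \code{estimate}, and every split must
#'   hold out at least 2 sites.
#' @return proportion in [0, 1].
#' @export
rankAccuracy <- function(records) {
  if (is(records, "EDNACV")) records <- cvRecords(records)
  if (NROW(records) == 0) stop("no held-out records")
  scores <- unlist(lapply(split(records, records$split), function(rep) {
    n <- nrow(rep)
    if (n < 2)
      stop("rank accuracy needs at least 2 held-out sites per repetition")
    out <- numeric(0)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      st <- sign(rep$true_density[a] - rep$true_density[b])
      se <- sign(rep$estimate[a] - rep$estimate[b])
      out <- c(out, if (st == 0 || se == 0) 0.5 else as.numeric(st == se))
    }
    out
  }), use.names = FALSE)
  mean(scores)
}

#' Exhaustive leave-p-out cross-validation
#'
#' Requires a dataset whose density is known at every site (so held-out
#' truths exist). For each of the \eqn{C(I, J)} subsets of J calibration
#' sites, the remaining p = I - J sites are masked to eDNA-only, the model is
#' fit, and each masked site's estimate, Wald interval, signed error and
#' coverage indicator are recorded. RMSE, realized coverage and rank
#' accuracy pool every held-out record of every converged split;
#' non-converged splits are counted in \code{nFailed} and excluded.
#'
#' @param dataset an \code{\linkS4class{EDNADataset}} with a known density at
#'   all I sites.
#' @param J number of calibration sites kept per split, 1 <= J < I.
#' @param model a \code{\linkS4class{ModelSpec}} or family string.
#' @param ciLevel confidence level of the recorded intervals.
#' @param verbose print per-split progress to stderr.
#' @param ... passed on to \code{\link{fitDensityModel}}.
#' @return an \code{\linkS4class{EDNACV}}.
#' @examples
#' sim <- simulateDataset(I = 5, J = 5, K = 3, beta0 = 50, family = "negbin",
#'                        dispersion = 1, densityRange = c(2, 40), seed = 1)
#' cv <- crossValidate(sim$dataset, J = 3, model = "negbin")
#' cvSummary(cv)
#' @export
crossValidate <- function(dataset, J, model = ModelSpec("negbin"),
                          ciLevel = 0.95, verbose = FALSE, ...) {
  stopifnot(is(dataset, "EDNADataset"))
  if (is.character(model)) model <- ModelSpec(model)
  ids <- siteIDs(dataset)
  I <- length(ids)
  if (nDualSites(dataset) != I)
    stop("cross-validation requires a known density at every site")
  if (J < 1 || J >= I) stop("J must satisfy 1 <= J < I")
  truth <- siteDensities(dataset)
  splits <- enumerateSplits(ids, J)
  ed <- edna(dataset)
  unit <- ednaUnit(dataset)

  recs <- vector("list", length(splits))
  nFailed <- 0L
  for (s in seq_along(splits)) {
    keep <- splits[[s]]
    masked <- EDNADataset(ed, density = truth[keep], unit = unit)
    fit <- tryCatch(fitDensityModel(masked, model, ciLevel = ciLevel, ...),
                    error = function(e) NULL)
    if (is.null(fit) || !isConverged(fit)) {
      nFailed <- nFailed + 1L
      if (verbose) message(sprintf("split %d/%d: fit failed", s, length(splits)))
      next
    }
    pred <- predictDensities(fit)
    tr <- truth[pred$site_id]
    recs[[s]] <- data.frame(
      split = s, site_id = pred$site_id, true_density = unname(tr),
      estimate = pred$estimate, se = pred$se,
      ci_lower = pred$ci_lower, ci_upper = pred$ci_upper,
      error = pred$estimate - unname(tr),
      covered = pred$ci_lower <= tr & tr <= pred$ci_upper,
      stringsAsFactors = FALSE)
    if (verbose && s %% 25 == 0)
      message(sprintf("split %d/%d done", s, length(splits)))
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records))
    records <- data.frame(split = integer(), site_id = character(),
                          true_density = numeric(), estimate = numeric(),
                          se = numeric(), ci_lower = numeric(),
                          ci_upper = numeric(), error = numeric(),
                          covered = logical(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  hasRecs <- nrow(records) > 0
  new("EDNACV", family = modelFamily(model), J = as.integer(J),
      nSplits = length(splits), records = records,
      rmse = if (hasRecs) rmse(records$error) else NA_real_,
      coverage = if (hasRecs) realizedCoverage(records) else NA_real_,
      rankAccuracy = if (hasRecs && I - J >= 2) rankAccuracy(records)
                     else NA_real_,
      nFailed = nFailed)
}
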