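# Pre-analysis data characterization: overdispersion (per-site VMR),
# strength of the eDNA-density relationship, and the integerization
# transform continuous (ng/L) concentrations need before count models.

#' Per-site variance-to-mean ratios
#'
#' For each site, VMR = s^2 / wbar with s^2 the sample variance (K_i - 1
#' denominator) of the replicate eDNA values. VMR > 1 indicates
#' overdispersion relative to Poisson, VMR < 1 underdispersion; the
#' unweighted mean over sites summarizes the dataset. Sites whose replicate
#' mean is zero get VMR = 0 (all replicates are then zero).
#'
#' @param dataset an \code{\linkS4class{EDNADataset}} with K_i >= 2
#'   replicates at every site.
#' @return list with \code{per_site} (named vector) and \code{mean_vmr}.
#' @examples
#' d <- EDNADataset(data.frame(site_id = "a", replicate = 1:3, value = 1:3))
#' perSiteVMR(d)$per_site  # 0.5
#' @export
perSiteVMR <- function(dataset) {
  stopifnot(is(dataset, "EDNADataset"))
  k <- replicateCounts(dataset)
  if (any(k < 2))
    stop("VMR needs K_i >= 2 replicates at every site; offending site(s): ",
         paste(names(k)[k < 2], collapse = ", "))
  ed <- edna(dataset)
  vmr <- vapply(split(ed$value, factor(ed$site_id, levels = siteIDs(dataset))),
                function(w) {
                  m <- mean(w)
                  if (m == 0) 0 else stats::var(w) / m
                }, numeric(1))
  list(per_site = vmr, mean_vmr = mean(vmr))
}

#' Replicate-level correlation between eDNA and density
#'
#' Pearson correlation between each dual-site replicate value w_jk and its
#' site's known density D_j, over all dual-site observations, plus the
#' derived R^2 and the least-squares slope through the origin. A strong
#' correlation indicates the calibration information needed for density
#' inference is present.
#'
#' @param dataset an \code{\linkS4class{EDNADataset}} with at least 3 dual
#'   sites.
#' @return list: \code{pearson_r}, \code{r_squared},
#'   \code{slope_through_origin}.
#' @export
ednaDensityCorrelation <- function(dataset) {
  stopifnot(is(dataset, "EDNADataset"))
  if (nDualSites(dataset) < 3)
    stop("correlation needs at least 3 dual-data sites")
  ed <- edna(dataset)
  dens <- siteDensities(dataset)
  dual <- ed[ed$site_id %in% names(dens), , drop = FALSE]
  w <- dual$value
  D <- unname(dens[dual$site_id])
  if (stats::sd(w) == 0 || stats::sd(D) == 0)
    stop("correlation undefined: zero variance in eDNA values or densities")
  r <- stats::cor(w, D)
  list(pearson_r = r, r_squared = r^2,
       slope_through_origin = sum(w * D) / sum(D^2))
}

#' Integerize continuous eDNA concentrations for count models
#'
#' Count families require integer inputs. Continuous concentrations (ng/L
#' from qPCR) are scaled to the measurement precision and rounded
#' half-away-from-zero: \code{round(value * scale)}. By default the scale is
#' the smallest power of ten that maps the smallest positive value to at
#' least 1, so no positive detection collapses to zero.
#'
#' @param values non-negative numeric vector, or an
#'   \code{\linkS4class{EDNADataset}} (whose unit then becomes
#'   \code{"integerized"}).
#' @param scale positive multiplier applied before rounding; \code{NULL}
#'   selects the automatic power of ten.
#' @return integer vector, or a new \code{EDNADataset}, matching the input.
#' @examples
#' integerize(c(1.23, 0.07), scale = 100)  # 123 7
#' @export
integerize <- function(values, scale = NULL) {
  if (is(values, "EDNADataset")) {
    ed <- edna(values)
    ed$value <- integerize(ed$value, scale = scale)
    return(EDNADataset(ed, density = siteDensities(values),
                       unit = "integerized"))
  }
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and non-negative")
  if (is.null(scale)) {
    pos <- values[values > 0]
    scale <- if (length(pos)) 10^ceiling(-log10(min(pos))) else 1
    scale <- max(scale, 1)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive scalar")
  x <- values * scale
  # round half away from zero (values are non-negative)
  as.integer(floor(x + 0.5))
}

#' One-call diagnostics report
#'
#' Bundles \code{\link{perSiteVMR}} and (when J >= 3)
#' \code{\link{ednaDensityCorrelation}} into a single list, the pre-analysis
#' look at overdispersion and calibration quality.
#'
#' @param dataset an \code{\linkS4class{EDNADataset}}.
#' @return list: \code{per_site_vmr}, \code{mean_vmr}, and when computable
#'   \code{pearson_r}, \code{r_squared}, \code{slope_through_origin}.
#' @export
diagnosticsReport <- function(dataset) {
  v <- perSiteVMR(dataset)
  out <- list(per_site_vmr = v$per_site, mean_vmr = v$mean_vmr)
  if (nDualSites(dataset) >= 3) {
    cc <- tryCatch(ednaDensityCorrelation(dataset), error = function(e) NULL)
    if (!is.null(cc)) out <- c(out, cc)
  }
  out
}
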