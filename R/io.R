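# Delimited-text readers/writers. eDNA tables are CSVs with a header row
# (site_id, replicate, value[, unit]); density tables are (site_id, density).
# site_id is treated as an opaque string throughout. All floats are written
# with full precision (>= 10 significant digits) so round-trips are lossless
# to working precision.

#' Read a replicate-level eDNA dataset from CSV
#'
#' \code{ednaFile} must have columns \code{site_id}, \code{replicate},
#' \code{value}, optionally \code{unit} (one shared unit; mixed units are
#' rejected). \code{densityFile}, when given, must have \code{site_id},
#' \code{density} and lists the dual-data calibration sites; every site it
#' names must appear in the eDNA table. Missing replicates are simply absent
#' rows, so ragged K_i designs are read as-is.
#'
#' @param ednaFile path to the replicate-level eDNA CSV.
#' @param densityFile optional path to the site-density CSV.
#' @param unit unit override when the eDNA table has no unit column.
#' @return a validated \code{\linkS4class{EDNADataset}}.
#' @examples
#' # a small simulated mesocosm-style dataset ships with the package
#' d <- readEDNADataset(
#'   system.file("extdata", "synthetic_mesocosm_edna.csv",
#'               package = "ednaDensity"),
#'   system.file("extdata", "synthetic_mesocosm_density.csv",
#'               package = "ednaDensity"))
#' d
#' @export
readEDNADataset <- function(ednaFile, densityFile = NULL, unit = NULL) {
  ed <- utils::read.csv(ednaFile, stringsAsFactors = FALSE)
  need <- c("site_id", "replicate", "value")
  if (!all(need %in% names(ed)))
    stop("eDNA table must have columns: ", paste(need, collapse = ", "))
  dens <- NULL
  if (!is.null(densityFile)) {
    dens <- utils::read.csv(densityFile, stringsAsFactors = FALSE)
    if (!all(c("site_id", "density") %in% names(dens)))
      stop("density table must have columns: site_id, density")
    missing <- setdiff(as.character(dens$site_id), as.character(ed$site_id))
    if (length(missing))
      stop("density table names site(s) absent from the eDNA table: ",
           paste(missing, collapse = ", "))
  }
  EDNADataset(ed, density = dens, unit = unit)
}

#' Write an EDNADataset back to CSV
#'
#' Writes the replicate table (with its unit column) and, when the dataset
#' has dual sites and \code{densityFile} is given, the density table.
#' \code{readEDNADataset} on the written files reproduces the dataset.
#'
#' @param dataset an \code{\linkS4class{EDNADataset}}.
#' @param ednaFile output path for the replicate-level CSV.
#' @param densityFile optional output path for the density CSV.
#' @return invisibly, the paths written.
#' @export
writeEDNADataset <- function(dataset, ednaFile, densityFile = NULL) {
  stopifnot(is(dataset, "EDNADataset"))
  ed <- edna(dataset)
  ed$unit <- ednaUnit(dataset)
  ed$value <- formatFull(ed$value)
  utils::write.csv(ed, ednaFile, row.names = FALSE, quote = FALSE)
  paths <- ednaFile
  if (!is.null(densityFile) && nDualSites(dataset) > 0) {
    dens <- siteDensities(dataset)
    utils::write.csv(
      data.frame(site_id = names(dens), density = formatFull(unname(dens))),
      densityFile, row.names = FALSE, quote = FALSE)
    paths <- c(paths, densityFile)
  }
  invisible(paths)
}

formatFull <- function(x) {
  vapply(x, function(v)
    if (is.finite(v) && v == round(v) && abs(v) < 1e15)
      sprintf("%.0f", v)
    else format(v, digits = 15, scientific = FALSE, trim = TRUE),
    character(1))
}

#' Write and read a machine-readable fit report
#'
#' One record per estimated quantity (name, estimate, SE, CI bounds) plus
#' the log-likelihood, the convergence flag and the model family. JSON
#' (default) keeps full double precision; CSV writes >= 15 significant
#' digits. A written report read back reproduces the fit's numbers.
#'
#' @param fit an \code{\linkS4class{EDNAFit}} (converged or not; the flag is
#'   passed through).
#' @param file destination path; format follows the extension unless
#'   \code{format} is given.
#' @param format \code{"json"} or \code{"csv"}.
#' @return invisibly, \code{file}.
#' @export
writeFitReport <- function(fit, file, format = c("auto", "json", "csv")) {
  stopifnot(is(fit, "EDNAFit"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "csv" else "json"
  est <- coef(fit)
  tab <- data.frame(name = names(est), estimate = unname(est),
                    se = unname(fit@se[names(est)]),
                    ci_lower = unname(fit@ci95[names(est), "lower"]),
                    ci_upper = unname(fit@ci95[names(est), "upper"]),
                    stringsAsFactors = FALSE)
  if (format == "json") {
    jsonlite::write_json(
      list(family = modelFamily(fit), converged = fit@converged,
           loglik = fit@loglik, ci_level = fit@ciLevel,
           n_obs = fit@nobs, I = fit@I, J = fit@J, parameters = tab),
      file, auto_unbox = TRUE, digits = NA)
  } else {
    hdr <- sprintf("# family=%s converged=%s loglik=%s ci_level=%s",
                   modelFamily(fit), fit@converged, formatFull(fit@loglik),
                   formatFull(fit@ciLevel))
    num <- vapply(tab[-1], formatFull, character(nrow(tab)))
    out <- cbind(name = tab$name, num)
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname writeFitReport
#' @return \code{readFitReport}: list with \code{family}, \code{converged},
#'   \code{loglik}, \code{ci_level} and the \code{parameters} data.frame.
#' @export
readFitReport <- function(file, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    rep <- jsonlite::read_json(file, simplifyVector = TRUE)
    rep$parameters <- as.data.frame(rep$parameters)
    return(rep)
  }
  lines <- readLines(file)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- strsplit(hdr, "=")
  meta <- setNames(vapply(kv, `[`, character(1), 2),
                   vapply(kv, `[`, character(1), 1))
  tab <- utils::read.csv(text = lines[-1], stringsAsFactors = FALSE)
  list(family = meta[["family"]],
       converged = as.logical(meta[["converged"]]),
       loglik = as.numeric(meta[["loglik"]]),
       ci_level = as.numeric(meta[["ci_level"]]),
       parameters = tab)
}

#' Write cross-validation outputs
#'
#' The per-repetition records go to CSV (one row per held-out site per
#' split); the pooled summary (rmse, coverage, rank accuracy, split counts)
#' to JSON.
#'
#' @param cv an \code{\linkS4class{EDNACV}}.
#' @param recordsFile path for the per-repetition CSV.
#' @param summaryFile path for the summary JSON.
#' @return invisibly, the paths written.
#' @export
writeCVReport <- function(cv, recordsFile, summaryFile) {
  stopifnot(is(cv, "EDNACV"))
  utils::write.csv(cvRecords(cv), recordsFile, row.names = FALSE)
  s <- cvSummary(cv)
  jsonlite::write_json(as.list(s), summaryFile, auto_unbox = TRUE, digits = NA)
  invisible(c(recordsFile, summaryFile))
}
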