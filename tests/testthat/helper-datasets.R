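# Small programmatic fixtures shared across test files.

# Deterministic two-site dataset with known densities at both sites.
makeTinyDual <- function(values = list(a = c(3, 5, 4), b = c(10, 8, 12)),
                         density = c(a = 2, b = 5),
                         unit = "copies_per_ml") {
  ed <- data.frame(
    site_id = rep(names(values), lengths(values)),
    replicate = unlist(lapply(lengths(values), seq_len), use.names = FALSE),
    value = unlist(values, use.names = FALSE))
  EDNADataset(ed, density = density, unit = unit)
}

# Mesocosm-like design: I sites, K replicates, noiseless w = beta0 * D.
makeNoiseless <- function(I = 6, K = 3, beta0 = 10,
                          densities = seq(2, 12, length.out = I),
                          dual = seq_len(I)) {
  ids <- sprintf("m%02d", seq_len(I))
  names(densities) <- ids
  ed <- data.frame(site_id = rep(ids, each = K),
                   replicate = rep(seq_len(K), I),
                   value = rep(beta0 * densities, each = K))
  EDNADataset(ed, density = densities[ids[dual]], unit = "ng_per_l")
}

# Independent per-observation log-density oracles built on base R d*
# functions -- never on the package's own likelihood code.
oracleLogLik <- function(dataset, params, family) {
  ed <- edna(dataset)
  dens <- siteDensities(dataset)
  D <- c(dens, params@latentDensities)
  mu <- params@beta0 * D[ed$site_id]
  per <- switch(family,
    normal = dnorm(ed$value, mu, sqrt(params@dispersion), log = TRUE),
    poisson = dpois(ed$value, mu, log = TRUE),
    negbin = dnbinom(ed$value, size = params@dispersion, mu = mu, log = TRUE))
  sum(per)
}

# Random small dataset generator for property-style loops (count-valued).
randomCountDataset <- function(seed, I = 4, Kmax = 4, allDual = FALSE) {
  set.seed(seed)
  ids <- paste0("s", seq_len(I))
  K <- sample(2:Kmax, I, replace = TRUE)
  ed <- data.frame(site_id = rep(ids, K),
                   replicate = unlist(lapply(K, seq_len)),
                   value = rpois(sum(K), lambda = 20))
  dens <- setNames(runif(I, 0.5, 10), ids)
  J <- if (allDual) I else sample(seq_len(I - 1), 1)
  dual <- sample(ids, J)
  list(dataset = EDNADataset(ed, density = dens[dual]),
       densities = dens,
       params = ParameterVector(beta0 = runif(1, 1, 5),
                                dispersion = runif(1, 0.5, 5),
                                latentDensities = dens[setdiff(ids, dual)]))
}
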