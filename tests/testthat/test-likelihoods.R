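test_that("mean link and success probability follow their closed forms", {
  expect_identical(meanFunction(2, 3), 6)
  expect_identical(meanFunction(5, 0), 0)
  expect_identical(meanFunction(1, 47.2), 47.2)
  expect_error(meanFunction(-1, 2), "positive")
  expect_error(meanFunction(2, -1), "non-negative")

  expect_identical(nbSuccessProb(1, 1), 0.5)
  expect_identical(nbSuccessProb(0, 5), 1)
  expect_identical(nbSuccessProb(3, 1), 0.25)
  expect_error(nbSuccessProb(1, 0), "positive")
})

oneObs <- function(w, D = 1, unit = "copies_per_ml")
  EDNADataset(data.frame(site_id = "s", replicate = 1, value = w),
              density = c(s = D), unit = unit)

test_that("single-observation log-likelihoods match hand-computed values", {
  # normal: w at the mean, then one unit away, sigma2 = 1
  expect_equal(normalLogLik(oneObs(3, D = 3, unit = "ng_per_l"),
                            ParameterVector(1, dispersion = 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(normalLogLik(oneObs(4, D = 3, unit = "ng_per_l"),
                            ParameterVector(1, dispersion = 1)),
               -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)
  # poisson at mu = 1: P(0) = P(1) = exp(-1)
  expect_equal(poissonLogLik(oneObs(0), ParameterVector(1)), -1,
               tolerance = 1e-12)
  expect_equal(poissonLogLik(oneObs(1), ParameterVector(1)), -1,
               tolerance = 1e-12)
  expect_equal(poissonLogLik(oneObs(3, D = 2), ParameterVector(1)),
               3 * log(2) - 2 - log(6), tolerance = 1e-12)
  # negbin pmf evaluated directly: w=0 -> p^r; w=2, mu=r=2 -> 0.1875
  expect_equal(negbinLogLik(oneObs(0), ParameterVector(1, dispersion = 1)),
               log(0.5), tolerance = 1e-12)
  expect_equal(negbinLogLik(oneObs(2, D = 2),
                            ParameterVector(1, dispersion = 2)),
               log(0.1875), tolerance = 1e-12)
})

test_that("log-likelihoods equal summed independent per-observation oracles", {
  for (seed in 1:25) {
    rc <- randomCountDataset(seed)
    for (fam in c("poisson", "negbin")) {
      fn <- switch(fam, poisson = poissonLogLik, negbin = negbinLogLik)
      p <- rc$params
      if (fam == "poisson") p@dispersion <- numeric(0)
      expect_equal(fn(rc$dataset, p), oracleLogLik(rc$dataset, p, fam),
                   tolerance = 1e-8, label = sprintf("%s seed %d", fam, seed))
    }
    # same structure, continuous values, for the normal family
    edn <- edna(rc$dataset); edn$value <- edn$value + 0.37
    dn <- EDNADataset(edn, density = siteDensities(rc$dataset),
                      unit = "ng_per_l")
    expect_equal(normalLogLik(dn, rc$params),
                 oracleLogLik(dn, rc$params, "normal"), tolerance = 1e-8)
  }
})

test_that("negative binomial approaches poisson as r grows", {
  for (seed in 1:5) {
    rc <- randomCountDataset(seed)
    pPois <- rc$params; pPois@dispersion <- numeric(0)
    ll_pois <- poissonLogLik(rc$dataset, pPois)
    n <- nrow(edna(rc$dataset))
    for (r in c(1e6, 1e8)) {
      pNB <- rc$params; pNB@dispersion <- r
      expect_lt(abs(negbinLogLik(rc$dataset, pNB) - ll_pois) / n, 1e-4)
    }
  }
})

test_that("log-likelihood is invariant to row order", {
  rc <- randomCountDataset(7)
  ed <- edna(rc$dataset)
  set.seed(1); perm <- sample(nrow(ed))
  shuffled <- EDNADataset(ed[perm, ], density = siteDensities(rc$dataset))
  for (fn in list(poissonLogLik, negbinLogLik)) {
    p <- rc$params
    if (identical(fn, poissonLogLik)) p@dispersion <- numeric(0)
    expect_equal(fn(shuffled, p), fn(rc$dataset, p), tolerance = 1e-12)
  }
})

test_that("zero-mean conventions give a point mass at zero", {
  z <- oneObs(0, D = 0)
  expect_identical(poissonLogLik(z, ParameterVector(2)), 0)
  expect_identical(negbinLogLik(z, ParameterVector(2, dispersion = 1)), 0)
  pos <- oneObs(3, D = 0)
  expect_identical(poissonLogLik(pos, ParameterVector(2)), -Inf)
  expect_identical(negbinLogLik(pos, ParameterVector(2, dispersion = 1)), -Inf)
})

test_that("count families reject non-integer data and missing densities", {
  cont <- oneObs(2.5, unit = "ng_per_l")
  expect_error(poissonLogLik(cont, ParameterVector(1)), "integer")
  expect_error(negbinLogLik(cont, ParameterVector(1, dispersion = 1)),
               "integer")
  noDens <- EDNADataset(data.frame(site_id = "q", replicate = 1, value = 1))
  expect_error(poissonLogLik(noDens, ParameterVector(1)), "no density")
  expect_error(normalLogLik(oneObs(1, unit = "ng_per_l"),
                            ParameterVector(1, dispersion = -1)), "sigma2|positive")
})

test_that("negbin (mu, r) parameterization has variance mu + mu^2/r", {
  set.seed(404)
  for (cfg in list(c(mu = 20, r = 0.8), c(mu = 120, r = 5))) {
    x <- rnbinom(2e4, size = cfg["r"], mu = cfg["mu"])
    expect_equal(var(x), cfg[["mu"]] + cfg[["mu"]]^2 / cfg[["r"]],
                 tolerance = 0.1)
  }
})
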