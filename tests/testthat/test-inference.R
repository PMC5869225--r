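test_that("Wald interval helper matches its closed form", {
  expect_equal(confidenceInterval(10, 1),
               c(lower = 10 - qnorm(0.975), upper = 10 + qnorm(0.975)),
               tolerance = 1e-9)
  expect_equal(unname(confidenceInterval(10, 0)), c(10, 10))
  expect_equal(confidenceInterval(0, 2, floor = 0),
               c(lower = 0, upper = 2 * qnorm(0.975)), tolerance = 1e-9)
  expect_error(confidenceInterval(1, 1, level = 1.2), "level")
  expect_error(confidenceInterval(1, -1), "non-negative")
})

test_that("noiseless data are recovered exactly (zero-residual optimum)", {
  beta0 <- 10
  d <- makeNoiseless(I = 6, K = 3, beta0 = beta0, dual = 1:3)
  fit <- fitDensityModel(d, ModelSpec("normal"))
  est <- coef(fit)
  expect_equal(unname(est["beta0"]), beta0, tolerance = 1e-6)
  wbar <- tapply(edna(d)$value, edna(d)$site_id, mean)
  for (s in ednaOnlyIDs(d))
    expect_equal(unname(est[paste0("D[", s, "]")]),
                 unname(wbar[s] / beta0), tolerance = 1e-6)
})

test_that("all-dual poisson fit equals the closed-form MLE", {
  # score of the poisson log-likelihood in beta0 vanishes at
  # sum(w) / sum(K_i * D_i) when every density is known
  for (seed in c(2, 5, 9)) {
    rc <- randomCountDataset(seed, I = 5, allDual = TRUE)
    d <- rc$dataset
    fit <- fitDensityModel(d, ModelSpec("poisson"))
    k <- replicateCounts(d)
    dens <- siteDensities(d)
    closed <- sum(edna(d)$value) / sum(k * dens[names(k)])
    expect_equal(unname(coef(fit)["beta0"]), closed, tolerance = 1e-6)
  }
})

test_that("identifiability and degeneracy preconditions are enforced", {
  noDual <- EDNADataset(data.frame(site_id = rep("a", 3), replicate = 1:3,
                                   value = c(1, 2, 3)))
  expect_error(fitDensityModel(noDual, ModelSpec("poisson")),
               "unidentifiable")
  allZero <- EDNADataset(data.frame(site_id = rep(c("a", "b"), each = 2),
                                    replicate = rep(1:2, 2),
                                    value = c(0, 0, 5, 6)),
                         density = c(a = 3))
  expect_error(fitDensityModel(allZero, ModelSpec("poisson")), "degenerate")
})

test_that("fit output is internally consistent", {
  sim <- simulateDataset(I = 8, J = 4, K = 3, beta0 = 40, family = "negbin",
                         dispersion = 1.5, densityRange = c(2, 30), seed = 21)
  fit <- fitDensityModel(sim$dataset, ModelSpec("negbin"))
  expect_true(isConverged(fit))
  est <- coef(fit)
  ci <- confIntervals(fit)
  # every estimate sits inside its own interval; SEs non-negative
  expect_true(all(ci[names(est), "lower"] <= est + 1e-12))
  expect_true(all(est <= ci[names(est), "upper"] + 1e-12))
  expect_true(all(stdErrors(fit) >= 0))
  # vcov symmetric, non-negative diagonal
  expect_equal(vcov(fit), t(vcov(fit)), tolerance = 1e-10)
  expect_true(all(diag(vcov(fit)) >= 0))
  # stored loglik is the family log-likelihood re-evaluated at the estimates
  expect_equal(fit@loglik, negbinLogLik(sim$dataset, fit@estimates),
               tolerance = 1e-8)
  # and beats 50 random admissible parameter vectors
  set.seed(99)
  for (i in 1:50) {
    p <- ParameterVector(
      beta0 = runif(1, 1, 100), dispersion = runif(1, 0.1, 10),
      latentDensities = setNames(
        runif(length(ednaOnlyIDs(sim$dataset)), 0.1, 60),
        ednaOnlyIDs(sim$dataset)))
    expect_gte(fit@loglik, negbinLogLik(sim$dataset, p))
  }
})

test_that("fit is invariant under permutation of site order", {
  sim <- simulateDataset(I = 7, J = 4, K = 3, beta0 = 30, family = "negbin",
                         dispersion = 2, densityRange = c(2, 30), seed = 31)
  d <- sim$dataset
  ed <- edna(d)
  set.seed(8); perm <- sample(nrow(ed))
  d2 <- EDNADataset(ed[perm, ], density = siteDensities(d),
                    unit = ednaUnit(d))
  # the joint MLE itself is invariant to numerical precision
  f1 <- fitDensityModel(d, ModelSpec("negbin"), adjustDispersion = FALSE)
  f2 <- fitDensityModel(d2, ModelSpec("negbin"), adjustDispersion = FALSE)
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-6)
  expect_equal(coef(f1), coef(f2)[names(coef(f1))], tolerance = 1e-5)
  # the dispersion-adjusted fit adds a numerically profiled 1-D search whose
  # argmin is reproducible to the profile's numerical noise, not to 1e-6
  a1 <- fitDensityModel(d, ModelSpec("negbin"))
  a2 <- fitDensityModel(d2, ModelSpec("negbin"))
  expect_equal(a1@loglik, a2@loglik, tolerance = 1e-4)
  expect_equal(coef(a1), coef(a2)[names(coef(a1))], tolerance = 5e-3)
})

test_that("doubling eDNA values doubles beta0 and leaves densities alone", {
  for (seed in c(3, 12)) {
    rc <- randomCountDataset(seed, I = 5)
    d <- rc$dataset
    ed2 <- edna(d); ed2$value <- 2 * ed2$value
    d2 <- EDNADataset(ed2, density = siteDensities(d))
    f1 <- fitDensityModel(d, ModelSpec("poisson"))
    f2 <- fitDensityModel(d2, ModelSpec("poisson"))
    expect_equal(unname(coef(f2)["beta0"]), 2 * unname(coef(f1)["beta0"]),
                 tolerance = 1e-5)
    lat <- paste0("D[", ednaOnlyIDs(d), "]")
    expect_equal(coef(f2)[lat], coef(f1)[lat], tolerance = 1e-4)
  }
})

test_that("predictDensities returns one bounded record per eDNA-only site", {
  sim <- simulateDataset(I = 11, J = 3, K = 3, beta0 = 50, family = "negbin",
                         dispersion = 1, densityRange = c(1.7, 47.2),
                         seed = 77)
  fit <- fitDensityModel(sim$dataset, ModelSpec("negbin"))
  pred <- predictDensities(fit)
  expect_identical(nrow(pred), 8L)           # p = I - J held-out sites
  expect_setequal(pred$site_id, ednaOnlyIDs(sim$dataset))
  expect_true(all(pred$ci_lower >= 0))
  expect_true(all(pred$ci_lower <= pred$estimate & pred$estimate <= pred$ci_upper))

  bad <- fit; bad@converged <- FALSE
  expect_error(predictDensities(bad), "converge")
})

test_that("an all-zero eDNA-only site gets a zero density estimate", {
  ed <- data.frame(site_id = rep(c("a", "b"), each = 3), replicate = rep(1:3, 2),
                   value = c(8, 12, 10, 0, 0, 0))
  d <- EDNADataset(ed, density = c(a = 2))
  fit <- fitDensityModel(d, ModelSpec("poisson"))
  pred <- predictDensities(fit)
  expect_equal(pred$estimate[pred$site_id == "b"], 0, tolerance = 1e-6)
  expect_equal(pred$ci_lower[pred$site_id == "b"], 0, tolerance = 1e-6)
})

test_that("interval construction ranks as documented: symmetric natural-scale
           under-covers, log-scale Wald with adjusted dispersion does best", {
  z <- qnorm(0.975)
  cov <- c(nat_ml = 0, log_ml = 0, log_adj = 0); tot <- 0
  for (d in 1:80) {
    sim <- simulateDataset(I = 11, J = 5, K = 3, beta0 = 50,
                           family = "negbin", dispersion = 1,
                           densityRange = c(1.7, 47.2), seed = 640000 + d)
    ml <- tryCatch(fitDensityModel(sim$dataset, ModelSpec("negbin"),
                                   adjustDispersion = FALSE),
                   error = function(e) NULL)
    adj <- tryCatch(fitDensityModel(sim$dataset, ModelSpec("negbin")),
                    error = function(e) NULL)
    if (is.null(ml) || is.null(adj) || !isConverged(ml) || !isConverged(adj))
      next
    pm <- predictDensities(ml); pa <- predictDensities(adj)
    tr <- sim$truth[pm$site_id]
    cov["nat_ml"] <- cov["nat_ml"] +
      sum(pmax(pm$estimate - z * pm$se, 0) <= tr & tr <= pm$estimate + z * pm$se)
    cov["log_ml"] <- cov["log_ml"] +
      sum(pm$ci_lower <= tr & tr <= pm$ci_upper)
    tra <- sim$truth[pa$site_id]
    cov["log_adj"] <- cov["log_adj"] +
      sum(pa$ci_lower <= tra & tra <= pa$ci_upper)
    tot <- tot + nrow(pm)
  }
  cov <- cov / tot
  expect_gte(tot, 400)
  expect_lt(cov[["nat_ml"]], 0.90)
  expect_gt(cov[["log_ml"]], cov[["nat_ml"]])
  expect_gte(cov[["log_adj"]], cov[["log_ml"]])
})

test_that("median beta0 recovery bias is small at the mesocosm-like design", {
  r <- recoveryExperiment(60, I = 11, J = 5, K = 3, beta0 = 50,
                          family = "negbin", dispersion = 1,
                          densityRange = c(1.7, 47.2), seed = 2024)
  expect_lt(abs(r$beta0$median_rel_bias), 0.10)
  expect_lte(r$n_failed, 3)
})
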