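test_that("fit_ols matches the normal-equations solution on a hand dataset", {
  y <- c(1.2, 0.7, -0.3, 2.1, 1.5, -0.8)
  x <- c(0.5, 0.1, -1.0, 1.4, 0.8, -1.2)
  z <- c(1, 0, 1, 0, 1, 0)
  X <- cbind(1, x, z)
  b_hand <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b_hand
  s2 <- sum(res^2) / (6 - 3)
  se_hand <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  fit <- fit_ols(y, x, cbind(z = z))
  expect_equal(fit$beta, b_hand[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$se, se_hand, tolerance = 1e-10)
})

test_that("fit_ols recovers identity and null relationships", {
  x <- rnorm(100)
  fit <- fit_ols(x, x)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_lt(fit$se, 1e-8)

  set.seed(10)
  x <- rnorm(5000); y <- rnorm(5000)
  expect_lt(abs(fit_ols(y, x)$beta), 0.05)

  expect_error(fit_ols(rnorm(20), rep(1, 20) * 2,
                       cbind(k = rep(1, 20))), "collinear")
})

test_that("the vectorized model series equals per-fit lm on each cell", {
  set.seed(21)
  n <- 80
  cov <- toy_covariates(n, seed = 4)
  P <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  out <- data.frame(y1 = rnorm(n), y2 = rnorm(n))
  res <- run_model_series(P, out, cov, models = c(1, 2), n_eff_tests = 3)
  for (i in sample(nrow(res), 6)) {
    r <- res[i, ]
    X <- metacourse:::covariate_design(cov, model_covariates(r$model))
    y <- scale(out[[r$outcome]])[, 1]
    fit <- stats::lm(y ~ P[, r$predictor] + X - 1)
    sm <- summary(fit)$coefficients
    expect_equal(r$beta, sm[1, 1], tolerance = 1e-10)
    expect_equal(r$se, sm[1, 2], tolerance = 1e-10)
  }
})

test_that("model covariate sets are strictly nested", {
  for (k in 2:4)
    expect_true(all(model_covariates(k - 1) %in% model_covariates(k)))
  expect_setequal(model_covariates(1),
                  c("sex", "clinic", "age_at_clinic", "fasting"))
})

test_that("effective tests counts principal components explaining >95% variance", {
  set.seed(3)
  x <- rnorm(50)
  two <- zscored_matrix(cbind(a = x, b = x * 2 + 1e-12))
  eff <- effective_tests(two)
  expect_equal(eff$n_components, 1L)
  expect_equal(eff$threshold, 0.05)

  ind <- zscored_matrix(matrix(rnorm(10000 * 10), 10000, 10))
  expect_true(effective_tests(ind)$n_components %in% 9:10)

  expect_error(effective_tests(zscored_matrix(matrix(rnorm(4), 2, 2))),
               "3 samples")
})

test_that("Bonferroni thresholds reproduce the printed analytic values", {
  expect_equal(attr(bonferroni_threshold(0.05, 435), "signif3"), 1.15e-4)
  expect_equal(attr(bonferroni_threshold(0.05, 53), "signif3"), 9.43e-4)
  expect_equal(attr(bonferroni_threshold(0.05, 14), "signif3"), 3.57e-3)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("attenuation reports signed magnitude change", {
  a <- attenuation(-0.14, -0.11)
  expect_equal(a$signed_pct, -21.4, tolerance = 1e-2)
  expect_equal(a$shrink_pct, 21.4, tolerance = 1e-2)
  expect_equal(attenuation(-0.067, -0.095)$signed_pct, 41.8, tolerance = 0.1)
  expect_equal(attenuation(0.3, 0.3)$signed_pct, 0)
  expect_equal(attenuation(0.3, 0)$signed_pct, -100)
  expect_warning(a0 <- attenuation(0, 0.1), "zero reference")
  expect_true(is.na(a0$signed_pct))
})

test_that("pathway scores are member means and small pathways are excluded", {
  x <- matrix(rnorm(15), 3, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  m5 <- zscored_matrix(cbind(x[, rep(1, 5)]))
  colnames(m5$values) <- paste0("m", 1:5)
  ann <- data.frame(metabolite = paste0("m", 1:5), pathway = "pw1")
  sc <- pathway_scores(m5, ann)
  expect_equal(as.vector(sc[, "pw1"]), as.vector(m5$values[, 1]))

  ann4 <- data.frame(metabolite = paste0("m", 1:4),
                     pathway = rep("small", 4))
  m <- zscored_matrix(matrix(rnorm(40), 10, 4,
                             dimnames = list(NULL, paste0("m", 1:4))))
  sc4 <- suppressWarnings(pathway_scores(m, ann4))
  expect_equal(ncol(sc4), 0)
  expect_identical(attr(sc4, "excluded"), "small")

  # hand-computed row means on a 3-sample, 5-member pathway
  mz <- zscored_matrix(matrix(rnorm(15), 3, 5,
                              dimnames = list(NULL, paste0("m", 1:5))))
  sc5 <- pathway_scores(mz, ann)
  expect_equal(as.vector(sc5[, "pw1"]), unname(rowMeans(mz$values)))
})

test_that("residualized change scores are standardized and orthogonal to wave 1", {
  set.seed(30)
  w1 <- rnorm(5000)
  w2 <- w1 + rnorm(5000)
  cs <- residual_change_score(w1, w2)
  expect_lt(abs(stats::cor(cs, w1)), 0.05)
  expect_equal(mean(cs), 0, tolerance = 1e-12)
  expect_equal(stats::sd(cs), 1, tolerance = 1e-12)
  expect_error(residual_change_score(w1, 2 * w1 + 1), "residual variance")
  w1m <- w1; w1m[1:10] <- NA
  csm <- residual_change_score(w1m, w2)
  expect_equal(attr(csm, "n_excluded"), 10)
  expect_true(all(is.na(csm[1:10])))
})

test_that("a planted direct effect is stable across models and a confounded one attenuates", {
  spec <- cohort_spec(
    n_samples = 1500, missing_rate_range = c(0, 0),
    covariate_missing_rate = 0, seed = 17)
  sim <- simulate_metabolome(spec)
  co <- generate_covariates_outcomes(sim$metabolome, sim$truth, spec)
  P <- cbind(mod1 = sim$truth$factors[, 1], mod2 = sim$truth$factors[, 2])
  res <- run_model_series(P, co$outcomes[c("PS_64", "STM_69")],
                          co$covariates, models = c(1, 3, 4),
                          n_eff_tests = 2)
  direct <- res[res$predictor == "mod1" & res$outcome == "PS_64", ]
  expect_lt(abs(direct$beta[direct$model == 1] -
                direct$beta[direct$model == 4]), 0.05)
  conf <- res[res$predictor == "mod2" & res$outcome == "STM_69", ]
  expect_lt(abs(conf$beta[conf$model == 3]), 0.05)
  expect_lt(conf$atten_pct[conf$model == 3], -50)
})

test_that("the single-addition ledger points to the planted confounder", {
  spec <- cohort_spec(
    n_samples = 1200, missing_rate_range = c(0, 0),
    covariate_missing_rate = 0, seed = 19)
  sim <- simulate_metabolome(spec)
  co <- generate_covariates_outcomes(sim$metabolome, sim$truth, spec)
  led <- attenuation_ledger(sim$truth$factors[, 2], co$outcomes$STM_69,
                            co$covariates)
  expect_equal(led$covariate[1], "childhood_cognition")
  expect_lt(led$atten_pct[1], -30)
})
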