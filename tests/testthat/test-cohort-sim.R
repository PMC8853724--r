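test_that("planted within-module correlations are recovered at large n", {
  spec <- cohort_spec(n_samples = 5000, module_sizes = 3,
                      within_module_cor = 0.99, background_cor = 0,
                      n_noise_metabolites = 0, effect_map = list(),
                      confounder_map = list(), seed = 4)
  sim <- simulate_metabolome(spec)
  cc <- stats::cor(log10(sim$metabolome$values))
  expect_true(all(cc[upper.tri(cc)] > 0.95))
  expect_true(all(abs(cc[upper.tri(cc)] - 0.99) < 0.03))
})

test_that("noise-only metabolomes are near-independent", {
  spec <- cohort_spec(n_samples = 5000, module_sizes = integer(0),
                      background_cor = 0, n_noise_metabolites = 10,
                      effect_map = list(), confounder_map = list(), seed = 5)
  sim <- simulate_metabolome(spec)
  cc <- stats::cor(log10(sim$metabolome$values))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("generation is deterministic under a fixed seed", {
  spec <- cohort_spec(seed = 9, n_samples = 80)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$metabolome$values, b$metabolome$values)
  expect_identical(missing_mask(a$metabolome), missing_mask(b$metabolome))
  expect_identical(as.data.frame(a$covariates), as.data.frame(b$covariates))
  expect_identical(a$outcomes, b$outcomes)
})

test_that("ground truth covers every metabolite exactly once", {
  fx <- modular_fixture(seed = 2)
  asg <- fx$sim$truth$module_assignment
  expect_setequal(names(asg), colnames(fx$sim$metabolome$values))
  expect_true(all(asg %in% 0:length(fx$spec$module_sizes)))
  expect_equal(sum(asg == 0), fx$spec$n_noise_metabolites)
})

test_that("non-PSD or invalid correlation targets are rejected with the block named", {
  expect_error(cohort_spec(module_sizes = c(10, 10),
                           within_module_cor = c(0.5, 1.0)), "block 2")
  expect_error(cohort_spec(module_sizes = 10, within_module_cor = 0.02,
                           background_cor = 0.05), "block 1")
})

test_that("planted module effects are recovered by regression on the eigen-signal", {
  spec <- cohort_spec(
    n_samples = 5000, missing_rate_range = c(0, 0),
    covariate_missing_rate = 0,
    effect_map = list(list(source = 1L, outcome = "STM_64", beta = -0.3)),
    confounder_map = list(), seed = 6)
  sim <- simulate_metabolome(spec)
  co <- generate_covariates_outcomes(sim$metabolome, sim$truth, spec)
  b <- stats::coef(stats::lm(scale(co$outcomes$STM_64) ~
                               scale(sim$truth$factors[, 1])))[2]
  expect_lt(abs(b - (-0.3)), 0.05)
})

test_that("an empty effect map yields null metabolite-outcome associations", {
  spec <- cohort_spec(n_samples = 5000, module_sizes = c(30, 20),
                      n_noise_metabolites = 10, missing_rate_range = c(0, 0),
                      effect_map = list(), confounder_map = list(), seed = 7)
  sim <- simulate_metabolome(spec)
  co <- generate_covariates_outcomes(sim$metabolome, sim$truth, spec)
  z <- scale(log10(sim$metabolome$values[, seq(1, 60, by = 3)]))
  bmax <- max(abs(stats::cor(z, as.matrix(co$outcomes[outcome_names()]))))
  expect_lt(bmax, 0.05)
})

test_that("confounder loadings give the stated covariate-module correlation", {
  spec <- cohort_spec(
    n_samples = 5000, missing_rate_range = c(0, 0),
    covariate_missing_rate = 0, effect_map = list(),
    confounder_map = list(list(covariate = "childhood_cognition",
                               module = 2L, loading = 0.5)), seed = 8)
  sim <- simulate_metabolome(spec)
  co <- generate_covariates_outcomes(sim$metabolome, sim$truth, spec)
  r <- stats::cor(co$covariates$childhood_cognition, sim$truth$factors[, 2])
  expect_lt(abs(r - 0.5), 0.05)
})

test_that("effect and confounder maps referencing unknowns are rejected", {
  spec <- cohort_spec(seed = 1, n_samples = 50,
                      effect_map = list(list(source = 1L, outcome = "nope",
                                             beta = 0.1)))
  sim <- simulate_metabolome(spec)
  expect_error(generate_covariates_outcomes(sim$metabolome, sim$truth, spec),
               "unknown outcome")
  spec2 <- cohort_spec(seed = 1, n_samples = 50,
                       effect_map = list(list(source = "bogus",
                                              outcome = "STM_64", beta = 0.1)))
  sim2 <- simulate_metabolome(spec2)
  expect_error(generate_covariates_outcomes(sim2$metabolome, sim2$truth, spec2),
               "unknown source")
})

test_that("missingness injection is MCAR at the stated rate and seeded", {
  spec0 <- cohort_spec(missing_rate_range = c(0, 0), seed = 3,
                       n_samples = 100)
  sim <- simulate_metabolome(spec0)
  expect_identical(inject_missingness(sim$metabolome, spec0)$values,
                   sim$metabolome$values)

  spec <- cohort_spec(module_sizes = 10, n_noise_metabolites = 0,
                      n_samples = 100, missing_rate_range = c(0.25, 0.25),
                      seed = 3)
  sim <- simulate_metabolome(spec)
  mm <- inject_missingness(sim$metabolome, spec)
  n_miss <- sum(is.na(mm$values))          # 1000 cells at rate 0.25
  ci <- stats::qbinom(c(0.0005, 0.9995), 1000, 0.25)
  expect_gte(n_miss, ci[1]); expect_lte(n_miss, ci[2])
  mm2 <- inject_missingness(sim$metabolome, spec)
  expect_identical(is.na(mm$values), is.na(mm2$values))
  expect_error(cohort_spec(missing_rate_range = c(0.2, 1.0)), "rate")
})

test_that("cohort files round-trip through the CSV dialect", {
  spec <- cohort_spec(seed = 12, n_samples = 40, module_sizes = c(8, 6),
                      n_noise_metabolites = 4)
  cohort <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_metabolome_csv(file.path(dir, "metabolome.csv"))
  expect_equal(back$values, cohort$metabolome$values)
  expect_identical(is.na(back$values), is.na(cohort$metabolome$values))
  ann <- utils::read.csv(file.path(dir, "annotation.csv"))
  expect_setequal(ann$metabolite, colnames(back$values))
})
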