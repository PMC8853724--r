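test_that("residualization produces standardized residuals orthogonal to the design", {
  fx <- modular_fixture(seed = 23, n_samples = 120)
  spec <- fx$spec
  co <- generate_covariates_outcomes(fx$sim$metabolome, fx$sim$truth, spec)
  r <- residualize_model1(fx$m, co$covariates)
  X <- metacourse:::covariate_design(co$covariates, model_covariates(1))
  expect_lt(max(abs(stats::cor(X[, -1], r$values))), 1e-10)
  expect_equal(colMeans(r$values), rep(0, ncol(r$values)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(r$values, 2, stats::sd), rep(1, ncol(r$values)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # metabolite exactly linear in a design column -> zero residual variance
  bad <- fx$m
  bad$values[, 1] <- co$covariates$sex * 3 + 1
  bad$values <- scale(bad$values)
  expect_error(residualize_model1(bad, co$covariates), "residual variance")
})

test_that("Z.k flags a decorrelated sample as the strongest outlier", {
  fx <- modular_fixture(seed = 31, n_samples = 100)
  out <- sample_outliers_zk(fx$m)
  expect_equal(mean(out$zk), 0, tolerance = 1e-12)
  expect_equal(stats::sd(out$zk), 1, tolerance = 1e-12)
  expect_length(out$excluded, 0)    # homogeneous cohort, cut -4

  # a sample replaced by independent noise loses the shared abundance
  # profile and drops to the bottom of the connectivity distribution
  x <- fx$sim$metabolome; x$state <- "imputed"
  logm <- log10_transform(x)
  set.seed(99)
  logm$values[7, ] <- rnorm(ncol(logm$values), mean = 5)
  out2 <- sample_outliers_zk(logm)
  expect_equal(names(which.min(out2$zk)), rownames(logm$values)[7])
})

test_that("biweight midcorrelation agrees with Pearson on clean Gaussian data", {
  set.seed(12)
  x <- matrix(rnorm(1000 * 6), 1000, 6)
  x[, 2] <- 0.6 * x[, 1] + sqrt(1 - 0.36) * x[, 2]
  bc <- bicor_matrix(x)
  pc <- stats::cor(x)
  expect_lt(max(abs(bc - pc)), 0.05)
  expect_equal(diag(bc), rep(1, 6), ignore_attr = TRUE)
  expect_equal(bc, t(bc))

  y <- cbind(a = rnorm(50), b = rnorm(50))
  y <- cbind(y, c = -y[, "a"])
  bc2 <- bicor_matrix(y)
  expect_equal(bc2["a", "a"], 1)
  expect_equal(bc2["a", "c"], -1)

  z <- cbind(a = rnorm(30), spike = c(rep(0, 29), 5))  # MAD = 0 column
  expect_warning(bz <- bicor_matrix(z), "Pearson fallback")
  expect_error(bicor_matrix(cbind(a = rnorm(30), k = rep(2, 30))),
               "constant")
})

test_that("bicor downweights a gross outlier that inflates Pearson", {
  set.seed(7)
  x <- rnorm(60); y <- rnorm(60)
  x[1] <- 25; y[1] <- 25
  pc <- stats::cor(x, y)
  bc <- bicor_matrix(cbind(x, y))["x", "y"]
  expect_gt(pc, 0.8)
  expect_lt(abs(bc), 0.35)
})

test_that("signed adjacency follows the (1+cor)/2 power rule", {
  cc <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(signed_adjacency(cc, 9)[1, 2], 1)
  cc[1, 2] <- cc[2, 1] <- -1
  expect_equal(signed_adjacency(cc, 9)[1, 2], 0)
  cc[1, 2] <- cc[2, 1] <- 0
  expect_equal(signed_adjacency(cc, 9)[1, 2], 0.5^9)
  expect_equal(diag(signed_adjacency(cc, 9)), c(0, 0))
  expect_equal(signed_adjacency(cc, 2, type = "unsigned")[1, 2], 0)
})

test_that("TOM matches hand arithmetic and the brute-force oracle", {
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  tom3 <- tom_matrix(a3)
  expect_equal(tom3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))
  expect_equal(diag(tom3), rep(1, 3))

  z <- matrix(0, 4, 4)
  expect_equal(tom_matrix(z), diag(4))

  set.seed(8)
  a6 <- rand_adjacency(6)
  expect_lt(max(abs(tom_matrix(a6) - brute_tom(a6))), 1e-12)
  expect_error(tom_matrix(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("mean connectivity decreases with power and the minimal qualifying power is chosen", {
  fx <- modular_fixture(seed = 41, n_samples = 400,
                        module_sizes = c(40, 30, 25, 20),
                        within_module_cor = c(0.7, 0.6, 0.6, 0.5),
                        n_noise_metabolites = 150)
  cc <- bicor_matrix(fx$m)
  ps <- pick_soft_threshold(cc, powers = 1:20)
  expect_true(all(diff(ps$scan$mean_k) < 0))
  qual <- ps$scan$power[!is.na(ps$scan$signed_r2) & ps$scan$signed_r2 >= 0.85]
  expect_gt(length(qual), 0)          # some power <= 20 qualifies
  expect_equal(ps$power, min(qual))   # selection rule: minimal qualifying
})

test_that("planted modules are recovered and noise stays grey", {
  fx <- modular_fixture(seed = 2)
  cc <- bicor_matrix(fx$m)
  diss <- 1 - tom_matrix(signed_adjacency(cc, 9))
  asg <- cluster_modules(diss, metabolites = fx$m)
  truth <- fx$sim$truth$module_assignment[names(asg)]
  expect_gte(mclust::adjustedRandIndex(asg, truth), 0.8)
  expect_equal(length(setdiff(unique(asg), "grey")), 4)
})

test_that("modules with highly correlated eigenvalues merge", {
  set.seed(55)
  n <- 500
  f1 <- rnorm(n)
  f2 <- 0.92 * f1 + sqrt(1 - 0.92^2) * rnorm(n)   # 1 - cor < merge_height
  g <- rnorm(n)                                    # distinct third module
  blk <- function(f, s, rho = 0.7)
    sapply(seq_len(s), function(i) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
  x <- cbind(blk(f1, 30), blk(f2, 25), blk(g, 25))
  colnames(x) <- sprintf("m%02d", seq_len(ncol(x)))
  m <- zscored_matrix(x)
  diss <- 1 - tom_matrix(signed_adjacency(bicor_matrix(m), 9))
  asg <- cluster_modules(diss, metabolites = m)
  mods <- setdiff(unique(asg), "grey")
  expect_equal(length(mods), 2)
  expect_equal(length(unique(asg[1:55])), 1)   # f1/f2 blocks share a label
})

test_that("a pure-noise matrix stays almost entirely grey", {
  set.seed(61)
  x <- matrix(rnorm(300 * 100), 300, 100,
              dimnames = list(NULL, sprintf("m%03d", 1:100)))
  m <- zscored_matrix(x)
  diss <- 1 - tom_matrix(signed_adjacency(bicor_matrix(m), 9))
  asg <- suppressWarnings(cluster_modules(diss, metabolites = m))
  expect_gte(mean(asg == "grey"), 0.9)
})

test_that("module eigenvalues maximize explained member variance", {
  set.seed(71)
  n <- 200
  f <- rnorm(n)
  x <- sapply(1:8, function(i) sqrt(0.6) * f + sqrt(0.4) * rnorm(n))
  colnames(x) <- paste0("m", 1:8)
  m <- zscored_matrix(x)
  asg <- stats::setNames(rep("blue", 8), paste0("m", 1:8))
  e <- module_eigenvalues(m, asg)
  expect_equal(stats::sd(e[, "blue"]), 1, tolerance = 1e-12)
  expect_gt(stats::cor(e[, "blue"], rowMeans(m$values)), 0)

  # variance explained equals the leading singular value's share (SVD oracle)
  sv <- svd(scale(m$values, scale = FALSE))
  var_e <- mean(stats::cor(m$values, e[, "blue"])^2)
  var_svd <- mean(stats::cor(m$values, sv$u[, 1])^2)
  expect_equal(var_e, var_svd, tolerance = 1e-10)

  # identical columns: eigenvalue equals the common column z-scored
  xx <- x[, c(1, 1, 1)]; colnames(xx) <- paste0("m", 1:3)
  mi <- zscored_matrix(xx)
  ei <- module_eigenvalues(mi, stats::setNames(rep("red", 3), paste0("m", 1:3)))
  expect_equal(abs(stats::cor(ei[, "red"], x[, 1])), 1, tolerance = 1e-12)

  # sign flip of all members flips the eigenvalue
  mf <- zscored_matrix(-x)
  ef <- module_eigenvalues(mf, asg)
  expect_equal(ef[, "blue"], -e[, "blue"], tolerance = 1e-8)
})

test_that("kME is the metabolite-eigenvalue correlation", {
  fx <- modular_fixture(seed = 81)
  cc <- bicor_matrix(fx$m)
  diss <- 1 - tom_matrix(signed_adjacency(cc, 9))
  asg <- cluster_modules(diss, metabolites = fx$m)
  e <- module_eigenvalues(fx$m, asg)
  km <- module_kme(fx$m, e)
  truth <- fx$sim$truth$module_assignment[rownames(km)]
  noise <- truth == 0
  expect_lt(max(abs(km[noise, ])), 0.2)
  own <- km[cbind(seq_len(nrow(km)), match(asg[rownames(km)],
                                           colnames(km)))]
  expect_gt(stats::median(own[!noise]), 0.65)
})

test_that("hub identification enforces the strict kME cut and significance filter", {
  km <- matrix(c(0.73, 0.65, 0.9), 3, 1,
               dimnames = list(c("a", "b", "c"), "purple"))
  asg <- c(a = "purple", b = "purple", c = "purple")
  hubs <- identify_hubs(km, asg, significant = c("a", "b"))
  expect_identical(hubs$metabolite, "a")    # 0.65 exactly is not a hub
  expect_equal(hubs$kme_own, 0.73)
  hubs2 <- identify_hubs(km, asg, significant = character(0))
  expect_equal(nrow(hubs2), 0)              # kME 0.9 but not significant
})
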