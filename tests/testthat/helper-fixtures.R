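# Fixture builders and independent oracles used across test files.

# Push a raw simulated metabolome through log10 + zscore without the
# missingness stages (the simulated matrix is complete).
clean_metabolome <- function(sim) {
  x <- sim$metabolome
  x$state <- "imputed"
  zscore(log10_transform(x))
}

modular_fixture <- function(seed = 1, ...) {
  spec <- cohort_spec(missing_rate_range = c(0, 0),
                      covariate_missing_rate = 0, seed = seed, ...)
  sim <- simulate_metabolome(spec)
  list(spec = spec, sim = sim, m = clean_metabolome(sim))
}

# Triple-loop TOM oracle, independent of the matrix implementation.
brute_tom <- function(a) {
  p <- ncol(a)
  diag(a) <- 0
  k <- colSums(a)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) { out[i, j] <- 1; next }
      s <- 0
      for (u in seq_len(p)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

rand_adjacency <- function(p) {
  a <- matrix(stats::runif(p * p), p, p)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# Exact upper-tail hypergeometric by enumeration of the overlap count.
brute_hyper_upper <- function(N, K, n, k) {
  js <- max(k, 0):min(K, n)
  if (!length(js) || k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Tiny complete covariate table for regression tests.
toy_covariates <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    sex = rbinom(n, 1, 0.5),
    age_at_clinic = rnorm(n, 63, 1),
    fasting = rbinom(n, 1, 0.95),
    clinic = sample(1:3, n, replace = TRUE),
    BMI = rnorm(n, 27, 4),
    lipid_med = rbinom(n, 1, 0.15),
    childhood_cognition = rnorm(n),
    education = sample(1:3, n, replace = TRUE),
    SEP_child = sample(1:6, n, replace = TRUE),
    SEP_mid = sample(1:6, n, replace = TRUE),
    smoking_packyears = rgamma(n, 1, 0.1),
    alcohol = sample(1:3, n, replace = TRUE),
    sys_bp = rnorm(n, 136, 15),
    activity = sample(1:3, n, replace = TRUE),
    diet_quintile = sample(1:5, n, replace = TRUE),
    apoe_dose = sample(0:2, n, replace = TRUE, prob = c(.7, .25, .05))
  )
  covariate_table(df, c(
    sex = "binary", age_at_clinic = "continuous", fasting = "binary",
    clinic = "nominal", BMI = "continuous", lipid_med = "binary",
    childhood_cognition = "continuous", education = "ordered",
    SEP_child = "ordered", SEP_mid = "ordered",
    smoking_packyears = "continuous", alcohol = "ordered",
    sys_bp = "continuous", activity = "ordered", diet_quintile = "ordered",
    apoe_dose = "continuous"))
}

zscored_matrix <- function(x) {
  m <- metab_matrix(x)
  m$values <- scale(m$values)
  m$state <- "zscored"
  m
}
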