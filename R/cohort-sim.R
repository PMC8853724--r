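#' Specification of a synthetic cohort
#'
#' Describes a cohort with planted metabolite modules, pathway labels,
#' confounded covariates and outcome effects, so that every downstream stage
#' of the pipeline (QC, imputation, regression models, network construction,
#' enrichment) has a recoverable ground truth.
#'
#' Metabolite abundances are generated as 10^z of a latent multivariate
#' normal z with block-constant ("compound symmetry") within-module
#' correlation, a common background correlation across all metabolites, and
#' unit latent variance, so the log10 transform exactly recovers normality.
#'
#' @param n_samples number of participants.
#' @param module_sizes integer vector of planted module sizes.
#' @param within_module_cor correlation within each module, recycled to the
#'   number of modules; each in `[0, 1)` and at least `background_cor`.
#' @param background_cor correlation between any two metabolites not in the
#'   same module, in `[0, min(within_module_cor))`.
#' @param n_noise_metabolites number of metabolites in no module.
#' @param pathway_fidelity fraction of a module's metabolites sharing the
#'   module's dominant pathway label.
#' @param effect_map list of effects, each `list(source=, outcome=, beta=)`.
#'   `source` is a module index (integer), a metabolite id (character) or a
#'   covariate name (character); `beta` is a standardized effect.
#' @param confounder_map list of `list(covariate=, module=, loading=)`:
#'   the named covariate's latent loads on the module's eigen-signal with the
#'   given correlation.
#' @param missing_rate_range length-2 vector; per-metabolite MCAR rates are
#'   drawn uniformly from this range, each in `[0, 1)`.
#' @param covariate_missing_rate MCAR rate applied to covariates other than
#'   the basic blood-clinic set (sex, clinic, age, fasting stay complete,
#'   mirroring a cohort where clinic data are required for inclusion).
#' @param seed master integer seed; one derived stream per component
#'   (metabolome / covariates / missingness) for stage-level reproducibility.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 600,
                        module_sizes = c(60, 45, 35, 25),
                        within_module_cor = 0.6,
                        background_cor = 0.05,
                        n_noise_metabolites = 40,
                        pathway_fidelity = 0.8,
                        effect_map = list(
                          list(source = 1L, outcome = "PS_64", beta = -0.3),
                          list(source = "childhood_cognition",
                               outcome = "STM_69", beta = 0.4)
                        ),
                        confounder_map = list(
                          list(covariate = "childhood_cognition",
                               module = 2L, loading = 0.5)
                        ),
                        missing_rate_range = c(0, 0.05),
                        covariate_missing_rate = 0.10,
                        seed = 1L) {
  n_mod <- length(module_sizes)
  within <- rep_len(within_module_cor, max(n_mod, 1L))
  spec <- structure(list(
    n_samples = as.integer(n_samples),
    module_sizes = as.integer(module_sizes),
    within_module_cor = if (n_mod) within[seq_len(n_mod)] else numeric(0),
    background_cor = background_cor,
    n_noise_metabolites = as.integer(n_noise_metabolites),
    pathway_fidelity = pathway_fidelity,
    effect_map = effect_map,
    confounder_map = confounder_map,
    missing_rate_range = missing_rate_range,
    covariate_missing_rate = covariate_missing_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_samples < 1) stop("n_samples must be positive")
    if (any(module_sizes < 1)) stop("module sizes must be positive")
    bad <- which(within_module_cor >= 1 | within_module_cor < 0)
    if (length(bad))
      stop(sprintf(paste("block %d: within-module correlation %.3f does not",
                         "give a positive semi-definite block (need [0, 1))"),
                   bad[1], within_module_cor[bad[1]]))
    if (background_cor < 0)
      stop("background_cor must be non-negative")
    low <- which(within_module_cor < background_cor)
    if (length(low))
      stop(sprintf(paste("block %d: within-module correlation %.3f below",
                         "background %.3f makes the target non-PSD under the",
                         "shared-factor construction"),
                   low[1], within_module_cor[low[1]], background_cor))
    if (length(module_sizes) == 0 && background_cor >= 1)
      stop("background_cor must be < 1")
    if (n_noise_metabolites < 0) stop("n_noise_metabolites must be >= 0")
    if (pathway_fidelity < 0 || pathway_fidelity > 1)
      stop("pathway_fidelity must be in [0, 1]")
    if (length(missing_rate_range) != 2 ||
        any(missing_rate_range < 0) || any(missing_rate_range >= 1) ||
        missing_rate_range[1] > missing_rate_range[2])
      stop("missing_rate_range must be an increasing pair in [0, 1)")
    if (covariate_missing_rate < 0 || covariate_missing_rate >= 1)
      stop("covariate_missing_rate must be in [0, 1)")
  })
  invisible(spec)
}

## One RNG stream per logical component, derived from the master seed.
derive_seed <- function(seed, component) {
  offset <- c(metabolome = 1L, covariates = 2L,
              missingness = 3L, covariate_missingness = 4L)[[component]]
  (abs(seed) %% 214748L) * 9973L + offset
}

outcome_names <- function() {
  c("STM_64", "STM_69", "PS_64", "PS_69", "DM_64", "ACE_69")
}

metabolite_families <- function() {
  c("Lipid", "Amino acid", "Nucleotide", "Carbohydrate", "Peptide",
    "Cofactors and vitamins", "Energy", "Xenobiotics",
    "Partially characterized molecules")
}

#' Generate the synthetic metabolome
#'
#' Draws a samples x metabolites abundance matrix with the planted block
#' correlation structure of `spec`, plus a pathway annotation table whose
#' labels agree with the planted modules at rate `pathway_fidelity`.
#'
#' Latent construction per module j with within-correlation rho_j and
#' background b: z = sqrt(b) g + sqrt(rho_j - b) f_j + sqrt(1 - rho_j) e,
#' where g is a cohort-wide factor, f_j the module factor and e independent
#' noise; abundances are 10^(mu + z) with metabolite-specific means mu.
#'
#' @param spec a [cohort_spec()].
#' @return list with `metabolome` (a raw-state [metab_matrix()]),
#'   `truth` (module assignment, effect map echo, confounded pairs, plus the
#'   latent matrix and the per-module eigen-signals `factors` — each module's
#'   unit-variance common component, the quantity a module eigenvalue
#'   estimates), and
#'   `annotation` (data.frame metabolite/family/pathway; unknown metabolites
#'   carry ids prefixed "X-" and no family).
#' @export
simulate_metabolome <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(derive_seed(spec$seed, "metabolome"))
  n <- spec$n_samples
  sizes <- spec$module_sizes
  K <- length(sizes)
  p <- sum(sizes) + spec$n_noise_metabolites
  if (p < 1) stop("spec describes zero metabolites")
  b <- spec$background_cor

  g <- rnorm(n)
  factors <- if (K) matrix(rnorm(n * K), n, K) else matrix(0, n, 0)
  z <- matrix(rnorm(n * p), n, p)

  assignment <- integer(p)
  eig_signal <- matrix(0, n, K)   # per-module common component, unit variance
  col <- 1L
  for (j in seq_len(K)) {
    rho <- spec$within_module_cor[j]
    idx <- col:(col + sizes[j] - 1L)
    common <- sqrt(b) * g + sqrt(rho - b) * factors[, j]
    z[, idx] <- common + sqrt(1 - rho) * z[, idx]
    eig_signal[, j] <- common / sqrt(rho)
    assignment[idx] <- j
    col <- col + sizes[j]
  }
  if (spec$n_noise_metabolites > 0) {
    idx <- col:p
    z[, idx] <- sqrt(b) * g + sqrt(1 - b) * z[, idx]
  }

  ids <- character(p)
  ids[assignment > 0] <- sprintf("M%04d", which(assignment > 0))
  noise_idx <- which(assignment == 0)
  if (length(noise_idx)) {
    # half of the noise metabolites are chemically unidentified ("X-" ids)
    n_unknown <- floor(length(noise_idx) / 2)
    unk <- noise_idx[seq_len(n_unknown)]
    ids[unk] <- sprintf("X-1%04d", seq_along(unk))
    known <- setdiff(noise_idx, unk)
    ids[known] <- sprintf("M%04d", known)
  }

  mu <- rnorm(p, mean = 5, sd = 0.5)
  latent <- sweep(z, 2, mu, "+")
  values <- 10^latent
  dimnames(values) <- list(sprintf("S%04d", seq_len(n)), ids)
  dimnames(latent) <- dimnames(values)
  rownames(eig_signal) <- rownames(values)

  annotation <- build_annotation(ids, assignment, spec)
  truth <- list(
    module_assignment = stats::setNames(assignment, ids),
    true_betas = spec$effect_map,
    confounded_pairs = spec$confounder_map,
    factors = eig_signal,
    latent = latent
  )
  list(metabolome = metab_matrix(values, state = "raw"),
       truth = truth, annotation = annotation)
}

build_annotation <- function(ids, assignment, spec) {
  p <- length(ids)
  K <- length(spec$module_sizes)
  fams <- metabolite_families()
  module_pathway <- if (K) sprintf("pathway_mod%02d", seq_len(K)) else character(0)
  module_family <- if (K) fams[((seq_len(K) - 1L) %% length(fams)) + 1L] else character(0)
  bg_pathway <- sprintf("pathway_bg%02d", 1:6)
  bg_family <- fams[((seq_along(bg_pathway) - 1L) %% length(fams)) + 1L]

  family <- character(p); pathway <- character(p)
  for (j in seq_len(K)) {
    idx <- which(assignment == j)
    faithful <- idx[stats::runif(length(idx)) < spec$pathway_fidelity]
    stray <- setdiff(idx, faithful)
    pathway[faithful] <- module_pathway[j]
    family[faithful] <- module_family[j]
    if (length(stray)) {
      pick <- sample.int(length(bg_pathway), length(stray), replace = TRUE)
      pathway[stray] <- bg_pathway[pick]
      family[stray] <- bg_family[pick]
    }
  }
  noise <- which(assignment == 0)
  for (i in noise) {
    if (startsWith(ids[i], "X-")) {
      pathway[i] <- "Unknown"; family[i] <- NA_character_
    } else {
      pick <- sample.int(length(bg_pathway), 1)
      pathway[i] <- bg_pathway[pick]; family[i] <- bg_family[pick]
    }
  }
  data.frame(metabolite = ids, family = family, pathway = pathway,
             stringsAsFactors = FALSE)
}

#' Covariate table constructor
#'
#' A data.frame of per-sample covariates carrying a named `cov_types`
#' attribute with levels `continuous`, `binary`, `ordered` or `nominal`.
#'
#' @param df data.frame of covariates.
#' @param types named character vector of types, one per column of `df`.
#' @return object of class `covariate_table` (a data.frame).
#' @export
covariate_table <- function(df, types) {
  stopifnot(is.data.frame(df), all(names(types) == names(df)))
  bad <- setdiff(unique(types), c("continuous", "binary", "ordered", "nominal"))
  if (length(bad)) stop("unknown covariate type(s): ", paste(bad, collapse = ", "))
  structure(df, cov_types = types, class = c("covariate_table", "data.frame"))
}

#' @export
#' @rdname covariate_table
cov_types <- function(df) attr(df, "cov_types")

## thresholds a standard-normal latent into integer categories with the
## given marginal probabilities, preserving its correlation structure
categorize <- function(latent, probs) {
  br <- c(-Inf, stats::qnorm(cumsum(probs)[-length(probs)]), Inf)
  as.integer(cut(latent, breaks = br, labels = FALSE))
}

#' Generate covariates and cognitive outcomes for a synthetic cohort
#'
#' Covariates emulate a life-course battery: sex, blood-clinic variables,
#' BMI and lipid medication, childhood cognition, education, childhood and
#' midlife socioeconomic position, smoking pack-years, alcohol band,
#' systolic blood pressure, physical activity, diet quintile and APOE e4
#' dose. Covariates named in `spec$confounder_map` are built from latents
#' loading on the planted module factors with the stated loading; social
#' and lifestyle covariates share mild common factors so the table is
#' realistically intercorrelated. Categorical covariates threshold latent
#' normals, preserving the stated correlations.
#'
#' Outcomes are the sum of the standardized sources in `spec$effect_map`
#' weighted by their betas plus Gaussian noise with variance `1 - sum(beta^2)`
#' (floored at 0.05), so each stated beta is on the standardized scale.
#'
#' @param metabolome raw-state [metab_matrix()] from [simulate_metabolome()].
#' @param truth ground-truth list from [simulate_metabolome()].
#' @param spec the [cohort_spec()].
#' @return list with `covariates` (a [covariate_table()]) and `outcomes`
#'   (data.frame of the six cognitive outcomes plus `ACE_total`, a bounded
#'   0-100 rescaling of `ACE_69` used for clinical-threshold exclusions).
#' @export
generate_covariates_outcomes <- function(metabolome, truth, spec) {
  assert_state(metabolome, "raw", "generate_covariates_outcomes")
  set.seed(derive_seed(spec$seed, "covariates"))
  n <- nrow(metabolome$values)
  K <- ncol(truth$factors)

  ## shared latent factors inducing covariate intercorrelation
  social <- rnorm(n); lifestyle <- rnorm(n); cardio <- rnorm(n)
  base_load <- list(
    sex = NULL, age_at_clinic = NULL, fasting = NULL, clinic = NULL,
    BMI = list(cardio = 0.4), lipid_med = list(cardio = 0.4),
    childhood_cognition = list(social = 0.4),
    education = list(social = 0.5), SEP_child = list(social = 0.4),
    SEP_mid = list(social = 0.4),
    smoking_packyears = list(lifestyle = 0.4),
    alcohol = list(lifestyle = 0.3), sys_bp = list(cardio = 0.4),
    activity = list(lifestyle = -0.3), diet_quintile = list(lifestyle = -0.3),
    apoe_dose = NULL
  )
  shared <- list(social = social, lifestyle = lifestyle, cardio = cardio)

  ## module loadings from the confounder map
  mod_load <- lapply(base_load, function(x) numeric(K))
  for (cm in spec$confounder_map) {
    nm <- cm$covariate
    if (!nm %in% names(base_load))
      stop("confounder_map references unknown covariate: ", nm)
    if (cm$module < 1 || cm$module > K)
      stop("confounder_map references unknown module index: ", cm$module)
    mod_load[[nm]][cm$module] <- cm$loading
  }

  latent_for <- function(nm) {
    lam <- mod_load[[nm]]
    contrib <- if (K) as.vector(truth$factors %*% lam) else 0
    v <- sum(lam^2)
    for (s in names(base_load[[nm]])) {
      w <- base_load[[nm]][[s]]
      contrib <- contrib + w * shared[[s]]
      v <- v + w^2
    }
    if (v >= 1)
      stop(sprintf("covariate %s: total squared loading %.2f >= 1", nm, v))
    contrib + sqrt(1 - v) * rnorm(n)
  }

  lat <- lapply(stats::setNames(names(base_load), names(base_load)), latent_for)

  covs <- data.frame(
    sex = categorize(lat$sex, c(0.491, 0.509)) - 1L,
    age_at_clinic = 63.2 + 1.1 * lat$age_at_clinic,
    fasting = categorize(lat$fasting, c(0.04, 0.96)) - 1L,
    clinic = categorize(lat$clinic, c(1, 1, 1) / 3),
    BMI = 27.6 + 4.4 * lat$BMI,
    lipid_med = categorize(lat$lipid_med, c(0.85, 0.15)) - 1L,
    childhood_cognition = lat$childhood_cognition,
    education = categorize(lat$education, c(0.30, 0.40, 0.30)),
    SEP_child = categorize(lat$SEP_child, c(0.08, 0.17, 0.30, 0.20, 0.15, 0.10)),
    SEP_mid = categorize(lat$SEP_mid, c(0.05, 0.12, 0.28, 0.22, 0.20, 0.13)),
    smoking_packyears = stats::qgamma(stats::pnorm(lat$smoking_packyears),
                                      shape = 0.8, scale = 15),
    alcohol = categorize(lat$alcohol, c(0.15, 0.70, 0.15)),
    sys_bp = 136 + 16 * lat$sys_bp,
    activity = categorize(lat$activity, c(0.45, 0.35, 0.20)),
    diet_quintile = categorize(lat$diet_quintile, rep(0.2, 5)),
    apoe_dose = categorize(lat$apoe_dose, c(0.724, 0.245, 0.031)) - 1L,
    row.names = rownames(metabolome$values)
  )
  types <- c(sex = "binary", age_at_clinic = "continuous", fasting = "binary",
             clinic = "nominal", BMI = "continuous", lipid_med = "binary",
             childhood_cognition = "continuous", education = "ordered",
             SEP_child = "ordered", SEP_mid = "ordered",
             smoking_packyears = "continuous", alcohol = "ordered",
             sys_bp = "continuous", activity = "ordered",
             diet_quintile = "ordered", apoe_dose = "continuous")
  covariates <- covariate_table(covs, types)

  ## outcomes: linear combinations of standardized sources + Gaussian noise
  resolve_source <- function(src) {
    if (is.numeric(src)) {
      if (src < 1 || src > K) stop("effect_map: unknown module index ", src)
      return(as.vector(scale(truth$factors[, src])))
    }
    if (src %in% colnames(truth$latent))
      return(as.vector(scale(truth$latent[, src])))
    if (src %in% names(covs))
      return(as.vector(scale(as.numeric(covs[[src]]))))
    stop("effect_map: unknown source '", src, "'")
  }
  outcomes <- as.data.frame(
    matrix(0, n, length(outcome_names()),
           dimnames = list(rownames(covs), outcome_names()))
  )
  var_used <- stats::setNames(numeric(length(outcome_names())), outcome_names())
  for (ef in spec$effect_map) {
    if (!ef$outcome %in% outcome_names())
      stop("effect_map: unknown outcome '", ef$outcome, "'")
    outcomes[[ef$outcome]] <- outcomes[[ef$outcome]] +
      ef$beta * resolve_source(ef$source)
    var_used[ef$outcome] <- var_used[ef$outcome] + ef$beta^2
  }
  for (o in outcome_names()) {
    sigma <- sqrt(max(0.05, 1 - var_used[[o]]))
    outcomes[[o]] <- outcomes[[o]] + rnorm(n, sd = sigma)
  }
  outcomes$ACE_total <- pmin(100, pmax(0, round(89 + 5.5 * outcomes$ACE_69)))
  list(covariates = covariates, outcomes = outcomes)
}

#' Inject missing-completely-at-random cells
#'
#' For a metabolite matrix, each metabolite receives its own MCAR rate drawn
#' uniformly from `spec$missing_rate_range`. For a covariate table, the rate
#' `spec$covariate_missing_rate` is applied to every covariate except the
#' basic blood-clinic set (sex, age_at_clinic, fasting, clinic), which stays
#' complete. Deterministic under the spec seed.
#'
#' @param x a raw-state [metab_matrix()] with no missing cells, or a
#'   complete [covariate_table()].
#' @param spec the [cohort_spec()].
#' @return the same type of object with `NA`s injected.
#' @export
inject_missingness <- function(x, spec) UseMethod("inject_missingness")

#' @export
inject_missingness.metab_matrix <- function(x, spec) {
  validate_cohort_spec(spec)
  assert_state(x, "raw", "inject_missingness")
  if (anyNA(x$values)) stop("matrix already has missing cells")
  set.seed(derive_seed(spec$seed, "missingness"))
  r <- spec$missing_rate_range
  rates <- stats::runif(ncol(x$values), r[1], r[2])
  for (j in seq_len(ncol(x$values))) {
    hit <- stats::runif(nrow(x$values)) < rates[j]
    x$values[hit, j] <- NA_real_
  }
  x
}

#' @export
inject_missingness.data.frame <- function(x, spec) {
  validate_cohort_spec(spec)
  if (anyNA(x)) stop("table already has missing cells")
  set.seed(derive_seed(spec$seed, "covariate_missingness"))
  protected <- c("sex", "age_at_clinic", "fasting", "clinic")
  rate <- spec$covariate_missing_rate
  for (nm in setdiff(names(x), protected)) {
    hit <- stats::runif(nrow(x)) < rate
    x[[nm]][hit] <- NA
  }
  x
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_metabolome()],
#' [generate_covariates_outcomes()] and [inject_missingness()] (on both the
#' metabolome and the covariates).
#'
#' @param spec a [cohort_spec()].
#' @return list with `metabolome`, `annotation`, `covariates`, `outcomes`,
#'   `truth` and the `spec` itself.
#' @export
simulate_cohort <- function(spec) {
  met <- simulate_metabolome(spec)
  co <- generate_covariates_outcomes(met$metabolome, met$truth, spec)
  metabolome <- inject_missingness(met$metabolome, spec)
  covariates <- inject_missingness(co$covariates, spec)
  list(metabolome = metabolome, annotation = met$annotation,
       covariates = covariates, outcomes = co$outcomes,
       truth = met$truth, spec = spec)
}

#' Write a synthetic cohort to disk
#'
#' Writes `metabolome.csv` (samples x metabolites, empty cell = missing),
#' `annotation.csv`, `covariates.csv`, `outcomes.csv` and
#' `ground_truth.json` under `dir`.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory, created if absent.
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("metabolome.csv", "annotation.csv",
                            "covariates.csv", "outcomes.csv",
                            "ground_truth.json"))
  utils::write.csv(cohort$metabolome$values, paths[1], na = "")
  utils::write.csv(cohort$annotation, paths[2], row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$covariates), paths[3], na = "")
  utils::write.csv(cohort$outcomes, paths[4], na = "")
  gt <- list(
    module_assignment = as.list(cohort$truth$module_assignment),
    true_betas = cohort$truth$true_betas,
    confounded_pairs = cohort$truth$confounded_pairs
  )
  jsonlite::write_json(gt, paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a metabolite matrix from the cohort CSV dialect
#'
#' @param path CSV with sample ids in the first column, metabolites in the
#'   remaining columns; empty cells are missing.
#' @param state processing state to stamp on the result.
#' @return a [metab_matrix()].
#' @export
read_metabolome_csv <- function(path, state = "raw") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  metab_matrix(as.matrix(df), state = state)
}
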