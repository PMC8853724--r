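#' Subset an imputation stack to a set of samples
#'
#' Applies the same row selection to every completed table of an `mi_stack`
#' (e.g. to align the stack with the samples kept after network outlier
#' exclusion).
#'
#' @param stack an `mi_stack` from [mice_impute()].
#' @param idx sample ids or logical/integer row index.
#' @return an `mi_stack` over the selected samples.
#' @export
subset_stack <- function(stack, idx) {
  tabs <- lapply(stack$tables, function(tb)
    covariate_table(as.data.frame(tb)[idx, , drop = FALSE], cov_types(tb)))
  structure(list(tables = tabs, m = stack$m, iters = stack$iters,
                 seed = stack$seed, chain_means = stack$chain_means),
            class = "mi_stack")
}

#' Default pipeline configuration
#'
#' @param ... overrides for any configuration field.
#' @return named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    spec = NULL,            # cohort_spec for simulation, or NULL
    metabolome = NULL,      # CSV paths when not simulating
    annotation = NULL,
    covariates = NULL,
    outcomes = NULL,
    max_missing = 0.20, knn_k = 10,
    m_imputations = 50, mi_iters = 10,
    models = 1:4, alpha = 0.05,
    power = "auto", r2_min = 0.85,
    min_module_size = 20, deep_split = 4, merge_height = 0.25,
    zk_cut = -4, kme_threshold = 0.65, min_pathway_size = 5,
    adjust_apoe = FALSE, exclude_below_ace = NULL,
    attenuation_ledger = TRUE,
    seed = 1L, out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the complete metabolome-cognition pipeline
#'
#' Orchestrates every stage: cohort loading (or simulation from
#' `config$spec`), metabolite QC, covariate multiple imputation,
#' single-metabolite and pathway model series with residualized change
#' scores, network construction, module regressions, hub identification,
#' pathway overrepresentation, the per-covariable attenuation ledger for
#' Bonferroni-significant module results, and optional sensitivity reruns
#' (APOE-dose adjustment; exclusion of participants below a clinical
#' cognition-screen threshold). Every random stage records its seed in the
#' report; a rerun with the same configuration reproduces the report.
#'
#' @param config list from [pipeline_config()], or a path to a YAML file of
#'   overrides.
#' @return object of class `pipeline_report`: list of per-stage parameters,
#'   thresholds, result tables and the hub list. When `config$out_dir` is
#'   set, `report.json` and the result CSVs are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  cfg <- config

  ## ---- inputs ----
  if (!is.null(cfg$spec)) {
    cohort <- simulate_cohort(cfg$spec)
  } else {
    if (is.null(cfg$metabolome)) stop("config names neither a spec nor input files")
    cohort <- list(
      metabolome = read_metabolome_csv(cfg$metabolome),
      annotation = utils::read.csv(cfg$annotation, stringsAsFactors = FALSE),
      covariates = read_covariates_csv(cfg$covariates),
      outcomes = utils::read.csv(cfg$outcomes, row.names = 1)
    )
  }

  ## ---- preprocess ----
  prep <- run_preprocess(cohort$metabolome, max_missing = cfg$max_missing,
                         k = cfg$knn_k)
  clean <- prep$matrix

  ## ---- covariate multiple imputation ----
  stack <- mice_impute(cohort$covariates, m = cfg$m_imputations,
                       iters = cfg$mi_iters, seed = cfg$seed)

  ## ---- outcomes incl. residualized change scores ----
  outcomes <- cohort$outcomes[outcome_names()]
  outcomes$STM_change <- residual_change_score(outcomes$STM_64,
                                               outcomes$STM_69)
  outcomes$PS_change <- residual_change_score(outcomes$PS_64,
                                              outcomes$PS_69)

  ## ---- single-metabolite series ----
  eff <- effective_tests(clean)
  single <- run_model_series(clean, outcomes, stack, models = cfg$models,
                             n_eff_tests = eff$n_components,
                             alpha = cfg$alpha)

  ## ---- pathway series (basic-model adjustment only) ----
  scores <- pathway_scores(clean, cohort$annotation,
                           min_size = cfg$min_pathway_size)
  pathway <- if (ncol(scores))
    run_model_series(scores, outcomes, stack, models = 1,
                     n_eff_tests = ncol(scores), alpha = cfg$alpha)
  else NULL

  ## ---- network ----
  net <- build_network(clean, covariates = complete_basic(cohort$covariates),
                       power = cfg$power, r2_min = cfg$r2_min,
                       min_module_size = cfg$min_module_size,
                       deep_split = cfg$deep_split,
                       merge_height = cfg$merge_height, zk_cut = cfg$zk_cut)
  kept <- rownames(net$metabolites$values)
  modules <- if (!is.null(net$eigenvalues)) {
    run_model_series(net$eigenvalues, outcomes[kept, , drop = FALSE],
                     subset_stack(stack, kept), models = cfg$models,
                     n_eff_tests = ncol(net$eigenvalues),
                     alpha = cfg$alpha, exclude_model1 = TRUE)
  } else NULL

  ## ---- enrichment and hubs ----
  enrichment <- if (!is.null(net$eigenvalues))
    hypergeom_ora(net$assignment, cohort$annotation, alpha = cfg$alpha)
  else NULL
  significant <- unique(single$predictor[single$tier == "bonferroni"])
  hubs <- if (!is.null(net$kme))
    identify_hubs(net$kme, net$assignment, significant,
                  threshold = cfg$kme_threshold)
  else data.frame(metabolite = character(0), module = character(0),
                  kme_own = numeric(0))

  ## ---- attenuation ledger for significant module results ----
  ledger <- NULL
  if (isTRUE(cfg$attenuation_ledger) && !is.null(modules)) {
    sig <- modules[modules$model == 1 & modules$tier == "bonferroni", ]
    rows <- lapply(seq_len(nrow(sig)), function(i) {
      al <- attenuation_ledger(net$eigenvalues[, sig$predictor[i]],
                               outcomes[kept, sig$outcome[i]],
                               subset_stack(stack, kept))
      cbind(module = sig$predictor[i], outcome = sig$outcome[i], al)
    })
    ledger <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  ## ---- sensitivity reruns ----
  sensitivity <- list()
  if (isTRUE(cfg$adjust_apoe)) {
    sensitivity$apoe_single <- run_model_series(
      clean, outcomes, stack, models = cfg$models,
      n_eff_tests = eff$n_components, alpha = cfg$alpha,
      extra_covariates = "apoe_dose")
    if (!is.null(net$eigenvalues))
      sensitivity$apoe_modules <- run_model_series(
        net$eigenvalues, outcomes[kept, , drop = FALSE],
        subset_stack(stack, kept), models = cfg$models,
        n_eff_tests = ncol(net$eigenvalues), alpha = cfg$alpha,
        exclude_model1 = TRUE, extra_covariates = "apoe_dose")
  }
  if (!is.null(cfg$exclude_below_ace) && "ACE_total" %in% names(cohort$outcomes)) {
    keep_ace <- which(is.na(cohort$outcomes$ACE_total) |
                      cohort$outcomes$ACE_total >= cfg$exclude_below_ace)
    sensitivity$ace_single <- run_model_series(
      subset_samples(clean, keep_ace),
      outcomes[keep_ace, , drop = FALSE],
      subset_stack(stack, keep_ace), models = cfg$models,
      n_eff_tests = eff$n_components, alpha = cfg$alpha)
  }

  report <- structure(list(
    params = cfg[setdiff(names(cfg), "spec")],
    seed = cfg$seed,
    qc = prep$report,
    thresholds = list(
      metabolite = as.numeric(bonferroni_threshold(cfg$alpha,
                                                   eff$n_components)),
      n_effective_tests = eff$n_components,
      pathway = if (ncol(scores))
        as.numeric(bonferroni_threshold(cfg$alpha, ncol(scores))) else NA,
      n_pathways = ncol(scores),
      module = if (!is.null(net$eigenvalues))
        as.numeric(bonferroni_threshold(cfg$alpha,
                                        ncol(net$eigenvalues))) else NA,
      n_modules = if (!is.null(net$eigenvalues)) ncol(net$eigenvalues) else 0
    ),
    network = list(power = net$power,
                   excluded_samples = net$excluded_samples,
                   module_sizes = as.list(table(
                     net$assignment[net$assignment != "grey"]))),
    single = single, pathway = pathway, modules = modules,
    enrichment = enrichment, hubs = hubs,
    attenuation_ledger = ledger,
    sensitivity = sensitivity,
    net = net
  ), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

read_covariates_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  types <- c(sex = "binary", age_at_clinic = "continuous", fasting = "binary",
             clinic = "nominal", BMI = "continuous", lipid_med = "binary",
             childhood_cognition = "continuous", education = "ordered",
             SEP_child = "ordered", SEP_mid = "ordered",
             smoking_packyears = "continuous", alcohol = "ordered",
             sys_bp = "continuous", activity = "ordered",
             diet_quintile = "ordered", apoe_dose = "continuous")
  covariate_table(df, types[names(df)])
}

## basic (Model-1) covariates are required complete; return the table with
## any incomplete later-model covariates untouched (they are not used)
complete_basic <- function(covariates) covariates

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("single", "pathway", "modules", "enrichment", "hubs",
               "attenuation_ledger")) {
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(report$net$assignment)) {
    utils::write.csv(
      data.frame(metabolite = names(report$net$assignment),
                 module = unname(report$net$assignment)),
      file.path(dir, "assignment.csv"), row.names = FALSE)
  }
  slim <- report[c("params", "seed", "qc", "thresholds", "network")]
  slim$n_hubs <- nrow(report$hubs)
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  metabolites kept: %d; effective tests: %d (threshold %.3g)\n",
              x$qc$n_metabolites_kept, x$thresholds$n_effective_tests,
              x$thresholds$metabolite))
  cat(sprintf("  modules: %d (power %d); pathways scored: %d\n",
              x$thresholds$n_modules, x$network$power,
              x$thresholds$n_pathways))
  cat(sprintf("  hubs: %d\n", nrow(x$hubs)))
  invisible(x)
}
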