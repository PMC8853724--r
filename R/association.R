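#' Covariate sets of the nested life-course models
#'
#' Model 1 holds the basic blood-clinic covariates (sex, clinic, age at
#' clinic, fasting); Model 2 adds BMI and lipid medication; Model 3 adds
#' childhood cognition, education and childhood/midlife socioeconomic
#' position; Model 4 adds blood pressure, activity, alcohol, smoking and
#' diet. Each model's set strictly contains the previous one.
#'
#' @param model_id integer in 1..4.
#' @return character vector of covariate names.
#' @export
model_covariates <- function(model_id) {
  stopifnot(model_id %in% 1:4)
  sets <- list(
    c("sex", "clinic", "age_at_clinic", "fasting"),
    c("BMI", "lipid_med"),
    c("childhood_cognition", "education", "SEP_child", "SEP_mid"),
    c("sys_bp", "activity", "alcohol", "smoking_packyears", "diet_quintile")
  )
  unlist(sets[seq_len(model_id)], use.names = FALSE)
}

## Numeric design matrix for a covariate subset: intercept, standardized
## continuous columns, 0/1 binaries, dummy-coded categoricals (first level
## as reference). APOE dose is treated as continuous.
covariate_design <- function(covariates, names, types = cov_types(covariates)) {
  if (!length(names)) {
    X <- matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  d <- as.data.frame(covariates)[names]
  for (v in names) {
    ty <- types[[v]]
    if (ty %in% c("nominal", "ordered") && length(unique(d[[v]])) > 1) {
      d[[v]] <- factor(d[[v]])
    } else if (ty == "continuous") {
      s <- stats::sd(d[[v]])
      d[[v]] <- if (s > 0) (d[[v]] - mean(d[[v]])) / s else d[[v]] * 0
    }
  }
  X <- stats::model.matrix(~ ., data = d)
  if (qr(X)$rank < ncol(X)) {
    qx <- qr(X)
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  X
}

#' Least-squares fit of one predictor with covariate adjustment
#'
#' Ordinary least squares of `y` on `x` plus optional covariate columns
#' (intercept always included), returning the coefficient and standard error
#' of `x`. A residual-based linearity diagnostic (correlations of residuals
#' with fitted values and squared fitted values) is attached as attribute
#' `"diagnostic"`.
#'
#' @param y outcome vector.
#' @param x predictor vector.
#' @param covariates optional numeric matrix of covariate columns (no
#'   intercept column).
#' @return list with `beta`, `se`, `p`, `df` for the predictor term.
#' @export
fit_ols <- function(y, x, covariates = NULL) {
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x = x, covariates)
  if (n <= ncol(X) + 1) stop("too few observations for the design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  b <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- b[["x"]] / se
  fitted <- y - res
  diag <- list(
    resid_fitted_cor = if (stats::sd(fitted) > 0 && stats::sd(res) > 0)
      stats::cor(res, fitted) else 0,
    resid_curvature_cor = if (stats::sd(fitted^2) > 0 && stats::sd(res) > 0)
      stats::cor(res, fitted^2) else 0
  )
  out <- list(beta = b[["x"]], se = se,
              p = 2 * stats::pt(-abs(tval), df), df = df)
  attr(out, "diagnostic") <- diag
  out
}

#' Effective number of independent tests
#'
#' Number of principal components of the metabolite correlation matrix
#' needed to explain strictly more than `variance_threshold` of the total
#' variance; the per-test significance threshold is `alpha` divided by that
#' count.
#'
#' @param m a zscored [metab_matrix()] or numeric matrix.
#' @param variance_threshold cumulative explained-variance target (strict >).
#' @param alpha family-wise error rate.
#' @return object of class `effective_tests`: list with `n_components`,
#'   `variance_threshold`, `alpha`, `threshold`.
#' @export
effective_tests <- function(m, variance_threshold = 0.95, alpha = 0.05) {
  x <- if (inherits(m, "metab_matrix")) {
    assert_state(m, "zscored", "effective_tests")
    m$values
  } else as.matrix(m)
  if (nrow(x) < 3) stop("effective_tests needs at least 3 samples")
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cumvar <- cumsum(ev) / sum(ev)
  q <- which(cumvar > variance_threshold)[1]
  structure(list(n_components = as.integer(q),
                 variance_threshold = variance_threshold,
                 alpha = alpha, threshold = alpha / q),
            class = "effective_tests")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of (effective) tests, >= 1.
#' @return `alpha / n_tests` at full precision, with the 3-significant-figure
#'   rendering attached as attribute `"signif3"`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  out <- alpha / n_tests
  attr(out, "signif3") <- signif(out, 3)
  out
}

#' Percent change of a coefficient under added adjustment
#'
#' The primary, signed form is the percent change in coefficient magnitude,
#' `100 (|beta_adj| - |beta_ref|) / |beta_ref|`: attenuation toward zero is
#' negative regardless of the coefficient's sign, and a coefficient growing
#' in magnitude is positive — the convention used when reporting a "beta
#' change" column across adjustment models. The complementary
#' "% attenuation" form `100 (1 - |beta_adj| / |beta_ref|)` is also
#' returned.
#'
#' @param beta_ref reference-model coefficient (nonzero).
#' @param beta_adj adjusted-model coefficient.
#' @return list with `signed_pct` and `shrink_pct`; both `NA` with a warning
#'   when `beta_ref` is 0.
#' @export
attenuation <- function(beta_ref, beta_adj) {
  if (is.na(beta_ref) || beta_ref == 0) {
    warning("attenuation undefined for a zero reference coefficient")
    return(list(signed_pct = NA_real_, shrink_pct = NA_real_))
  }
  list(signed_pct = 100 * (abs(beta_adj) - abs(beta_ref)) / abs(beta_ref),
       shrink_pct = 100 * (1 - abs(beta_adj) / abs(beta_ref)))
}

#' Run the nested model series for a set of predictors
#'
#' Fits every (predictor, outcome, model) linear regression, once per imputed
#' covariate dataset when a [mice_impute()] stack is supplied, pooling with
#' [pool_rubin()]. Outcomes are standardized; samples missing an outcome are
#' dropped for that outcome. Each result is tiered against the
#' effective-tests Bonferroni threshold (`bonferroni` / `nominal` / `ns`)
#' and annotated with the signed percent change relative to its Model-1
#' coefficient.
#'
#' Internally the covariates are projected out of predictors and outcome
#' once per (outcome, model, imputation), so all predictors share one QR
#' decomposition; coefficients and standard errors equal the full OLS fit.
#'
#' @param predictors a zscored [metab_matrix()], or a numeric matrix whose
#'   columns are predictors (e.g. module eigenvalues, pathway scores).
#' @param outcomes data.frame of outcome columns.
#' @param covariates a [covariate_table()] (complete) or `mi_stack`.
#' @param models integer vector of model ids to run (subset of 1..4).
#' @param n_eff_tests Bonferroni denominator; defaults to the effective-tests
#'   count of the predictor matrix when it is a `metab_matrix`, else the
#'   number of predictors.
#' @param alpha family-wise error rate for the tiers.
#' @param exclude_model1 drop the Model-1 covariates from every design (used
#'   for predictors already residualized on them, e.g. module eigenvalues).
#' @param extra_covariates names of additional covariates appended to every
#'   model (e.g. `"apoe_dose"` for the APOE-adjusted sensitivity rerun).
#' @param subset optional logical/character/integer row selector (e.g. to
#'   exclude participants below a clinical cognition threshold).
#' @return data.frame in long format: predictor, outcome, model, beta, se,
#'   ci_low, ci_high, p, df, tier, atten_pct.
#' @export
run_model_series <- function(predictors, outcomes, covariates, models = 1:4,
                             n_eff_tests = NULL, alpha = 0.05,
                             exclude_model1 = FALSE,
                             extra_covariates = character(0),
                             subset = NULL) {
  P <- if (inherits(predictors, "metab_matrix")) {
    assert_state(predictors, "zscored", "run_model_series")
    predictors$values
  } else as.matrix(predictors)
  stopifnot(all(models %in% 1:4))
  tabs <- if (inherits(covariates, "mi_stack")) covariates$tables
          else list(covariates)
  m_imp <- length(tabs)
  stopifnot(inherits(tabs[[1]], "covariate_table"))
  if (nrow(P) != nrow(outcomes) || nrow(P) != nrow(tabs[[1]]))
    stop("predictors, outcomes and covariates must cover the same samples")

  if (!is.null(subset)) {
    P <- P[subset, , drop = FALSE]
    outcomes <- outcomes[subset, , drop = FALSE]
    tabs <- lapply(tabs, function(tb)
      covariate_table(as.data.frame(tb)[subset, , drop = FALSE], cov_types(tb)))
  }
  if (is.null(n_eff_tests)) {
    n_eff_tests <- if (inherits(predictors, "metab_matrix"))
      effective_tests(predictors)$n_components else ncol(P)
  }
  thr <- bonferroni_threshold(alpha, n_eff_tests)

  rows <- list()
  for (o in names(outcomes)) {
    yo <- outcomes[[o]]
    ok <- !is.na(yo)
    if (sum(ok) < 10) next
    y <- zscore.numeric(yo[ok])
    Po <- P[ok, , drop = FALSE]
    for (mod in models) {
      covs <- model_covariates(mod)
      if (exclude_model1) covs <- setdiff(covs, model_covariates(1))
      covs <- union(covs, extra_covariates)
      est <- array(NA_real_, c(ncol(P), m_imp, 2))
      dfcom <- NA_integer_
      for (d in seq_len(m_imp)) {
        tb <- as.data.frame(tabs[[d]])[ok, , drop = FALSE]
        X <- covariate_design(
          covariate_table(tb, cov_types(tabs[[d]])), covs)
        fit <- fwl_fit(y, Po, X)
        est[, d, 1] <- fit$beta
        est[, d, 2] <- fit$se
        dfcom <- fit$df
      }
      for (j in seq_len(ncol(P))) {
        if (m_imp > 1) {
          pe <- pool_rubin(est[j, , 1], est[j, , 2], dfcom = dfcom)
        } else {
          b <- est[j, 1, 1]; s <- est[j, 1, 2]
          tcrit <- stats::qt(0.975, dfcom)
          pe <- list(beta = b, se = s, ci_low = b - tcrit * s,
                     ci_high = b + tcrit * s,
                     p = 2 * stats::pt(-abs(b / s), dfcom), df = dfcom)
        }
        rows[[length(rows) + 1]] <- data.frame(
          predictor = colnames(P)[j] %||% sprintf("P%03d", j),
          outcome = o, model = mod, beta = pe$beta, se = pe$se,
          ci_low = pe$ci_low, ci_high = pe$ci_high, p = pe$p, df = pe$df,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$tier <- ifelse(res$p < thr, "bonferroni",
                     ifelse(res$p < 0.05, "nominal", "ns"))
  res$atten_pct <- NA_real_
  if (1 %in% models) {
    key <- paste(res$predictor, res$outcome)
    ref <- res$beta[res$model == 1][match(key, key[res$model == 1])]
    nz <- !is.na(ref) & ref != 0
    res$atten_pct[nz] <- 100 * (abs(res$beta[nz]) - abs(ref[nz])) / abs(ref[nz])
  }
  attr(res, "threshold") <- thr
  attr(res, "n_eff_tests") <- n_eff_tests
  res
}

## Frisch-Waugh-Lovell: project the covariate design X (with intercept) out
## of the outcome and every predictor column, then fit simple regressions.
## Coefficients and SEs match the full OLS fit with df = n - ncol(X) - 1.
fwl_fit <- function(y, P, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  ry <- qr.resid(qx, y)
  RP <- qr.resid(qx, P)
  sxx <- colSums(RP^2)
  if (any(sxx < 1e-12))
    stop("predictor collinear with covariates: ",
         paste(colnames(P)[sxx < 1e-12], collapse = ", "))
  sxy <- as.vector(crossprod(RP, ry))
  beta <- sxy / sxx
  df <- length(y) - ncol(X) - 1
  rss <- sum(ry^2) - beta * sxy
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / sxx)
  list(beta = beta, se = se, df = df)
}

#' Quantitative pathway scores
#'
#' Per pathway with at least `min_size` annotated metabolites present in the
#' matrix, the score is the row-wise mean of the member columns of the
#' z-scored metabolite matrix. Smaller pathways are dropped and reported in
#' attribute `"excluded"`; matrix metabolites absent from the annotation are
#' treated as unannotated with a warning.
#'
#' @param m a zscored [metab_matrix()].
#' @param annotation data.frame with columns `metabolite` and `pathway`.
#' @param min_size minimum pathway size.
#' @return samples x pathways numeric matrix of scores.
#' @export
pathway_scores <- function(m, annotation, min_size = 5) {
  assert_state(m, "zscored", "pathway_scores")
  ids <- colnames(m$values)
  unknown <- setdiff(ids, annotation$metabolite)
  if (length(unknown))
    warning(length(unknown), " metabolites missing from the annotation; ",
            "treated as unannotated")
  ann <- annotation[annotation$metabolite %in% ids &
                    !is.na(annotation$pathway) &
                    annotation$pathway != "Unknown", ]
  members <- split(ann$metabolite, ann$pathway)
  sizes <- lengths(members)
  excluded <- names(members)[sizes < min_size]
  members <- members[sizes >= min_size]
  if (!length(members)) {
    out <- matrix(0, nrow(m$values), 0,
                  dimnames = list(rownames(m$values), NULL))
  } else {
    out <- vapply(members, function(ms)
      rowMeans(m$values[, ms, drop = FALSE]), numeric(nrow(m$values)))
    rownames(out) <- rownames(m$values)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Residualized change score between two waves
#'
#' Regresses the later score on the earlier score (with intercept) over
#' samples observed at both waves, and returns the z-standardized residuals
#' (`NA` where either wave is missing; the count of excluded samples is
#' attached as attribute `"n_excluded"`).
#'
#' @param score_w1 earlier-wave score.
#' @param score_w2 later-wave score.
#' @return numeric vector of standardized residuals.
#' @export
residual_change_score <- function(score_w1, score_w2) {
  stopifnot(length(score_w1) == length(score_w2))
  ok <- !is.na(score_w1) & !is.na(score_w2)
  if (sum(ok) < 3) stop("too few samples observed at both waves")
  fit <- stats::lm.fit(cbind(1, score_w1[ok]), score_w2[ok])
  res <- fit$residuals
  if (stats::sd(res) < 1e-12)
    stop("zero residual variance: the later wave is an exact linear ",
         "function of the earlier wave")
  out <- rep(NA_real_, length(score_w1))
  out[ok] <- zscore.numeric(res)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Single-addition attenuation ledger
#'
#' For a given predictor and outcome, reruns the Model-1 regression adding
#' each later-model covariate one at a time, and reports the signed percent
#' change of the predictor coefficient relative to plain Model 1 — used to
#' attribute attenuation to individual life-course factors.
#'
#' @param predictor numeric vector (standardized predictor).
#' @param outcome numeric outcome vector.
#' @param covariates a [covariate_table()] (complete) or `mi_stack`.
#' @param candidates covariates to add singly; defaults to all non-Model-1
#'   model covariates.
#' @return data.frame with columns covariate, beta, atten_pct, ordered by
#'   decreasing absolute attenuation; the Model-1 beta is attribute
#'   `"beta_model1"`.
#' @export
attenuation_ledger <- function(predictor, outcome, covariates,
                               candidates = setdiff(model_covariates(4),
                                                    model_covariates(1))) {
  out <- data.frame(outcome = outcome)
  P <- matrix(predictor, ncol = 1, dimnames = list(NULL, "predictor"))
  base <- run_model_series(P, out, covariates, models = 1,
                           n_eff_tests = 1)
  b1 <- base$beta[1]
  rows <- lapply(candidates, function(cv) {
    r <- run_model_series(P, out, covariates, models = 1, n_eff_tests = 1,
                          extra_covariates = cv)
    data.frame(covariate = cv, beta = r$beta[1],
               atten_pct = attenuation(b1, r$beta[1])$signed_pct,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-abs(res$atten_pct)), ]
  rownames(res) <- NULL
  attr(res, "beta_model1") <- b1
  res
}
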