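#' Multiple imputation of covariates by chained equations
#'
#' Fills missing covariate cells with `m` stochastic completions. Variables
#' are visited in fixed column order for `iters` cycles; at each visit the
#' variable is re-imputed from all other covariates (current working values):
#' continuous variables by predictive mean matching (donor pool of 5),
#' binary variables by a logistic-regression posterior draw, and categorical
#' variables by a multinomial draw. A conditional model that fails to
#' converge falls back to a draw from the observed margin, with a warning.
#'
#' @param covariates a [covariate_table()] with missing cells.
#' @param m number of imputed datasets (>= 2).
#' @param iters chained-equation cycles per dataset.
#' @param seed integer seed; the whole stack is deterministic under it.
#' @return an object of class `mi_stack`: list with `tables` (list of `m`
#'   complete [covariate_table()]s), `m`, `iters`, `seed`, and `chain_means`
#'   (per dataset x iteration x variable mean of imputed values, for
#'   convergence monitoring).
#' @export
mice_impute <- function(covariates, m = 50, iters = 10, seed = 1L) {
  stopifnot(inherits(covariates, "covariate_table"))
  if (m < 2) stop("m must be >= 2")
  types <- cov_types(covariates)
  df <- as.data.frame(covariates)
  miss_vars <- names(df)[colSums(is.na(df)) > 0]
  complete_vars <- setdiff(names(df), miss_vars)
  if (length(miss_vars) && !length(complete_vars))
    stop("chained equations need at least one fully observed covariate")

  set.seed(as.integer(seed))
  chain_means <- array(
    NA_real_, c(m, iters, length(miss_vars)),
    dimnames = list(NULL, NULL, miss_vars)
  )
  tables <- vector("list", m)
  for (d in seq_len(m)) {
    work <- init_impute(df)
    if (length(miss_vars)) {
      for (it in seq_len(iters)) {
        for (v in miss_vars) {
          ry <- !is.na(df[[v]])
          X <- impute_design(work, exclude = v, types = types)
          work[[v]][!ry] <- draw_imputations(df[[v]], ry, X, types[[v]])
          chain_means[d, it, v] <- mean(as.numeric(work[[v]][!ry]))
        }
      }
    }
    tables[[d]] <- covariate_table(work, types)
  }
  structure(list(tables = tables, m = m, iters = iters, seed = seed,
                 chain_means = chain_means),
            class = "mi_stack")
}

#' @export
print.mi_stack <- function(x, ...) {
  cat(sprintf("mi_stack: %d imputed datasets (%d iterations, seed %d)\n",
              x$m, x$iters, x$seed))
  invisible(x)
}

## starting values: random draws from each variable's observed margin
init_impute <- function(df) {
  for (v in names(df)) {
    nas <- is.na(df[[v]])
    if (any(nas))
      df[[v]][nas] <- sample(df[[v]][!nas], sum(nas), replace = TRUE)
  }
  df
}

## numeric design matrix (intercept + dummy-coded categoricals) from all
## covariates except the one being imputed
impute_design <- function(work, exclude, types) {
  preds <- setdiff(names(work), exclude)
  d <- work[preds]
  for (v in preds) {
    if (types[[v]] %in% c("nominal", "ordered") &&
        length(unique(d[[v]])) > 1)
      d[[v]] <- factor(d[[v]])
  }
  stats::model.matrix(~ ., data = d)
}

draw_imputations <- function(y, ry, X, type) {
  switch(type,
    continuous = pmm_draw(y, ry, X, donors = 5),
    binary = logistic_draw(y, ry, X),
    margin_or_multinom(y, ry, X)
  )
}

## predictive mean matching with a Bayesian parameter draw (donor pool 5)
pmm_draw <- function(y, ry, X, donors = 5) {
  Xo <- X[ry, , drop = FALSE]; yo <- y[ry]
  Xm <- X[!ry, , drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  b <- fit$coefficients
  keep <- !is.na(b)
  b <- b[keep]
  Xo <- Xo[, keep, drop = FALSE]; Xm <- Xm[, keep, drop = FALSE]
  dfres <- max(1, length(yo) - length(b))
  res <- yo - as.vector(Xo %*% b)
  sigma2 <- sum(res^2) / stats::rchisq(1, dfres)
  xtx <- crossprod(Xo)
  V <- tryCatch(chol2inv(chol(xtx + diag(1e-8, ncol(xtx)))),
                error = function(e) NULL)
  bstar <- if (is.null(V)) b
           else b + as.vector(chol(sigma2 * (V + t(V)) / 2 +
                                   diag(1e-12, ncol(V))) %*%
                              stats::rnorm(length(b)))
  yhat_obs <- as.vector(Xo %*% b)
  yhat_mis <- as.vector(Xm %*% bstar)
  vapply(yhat_mis, function(h) {
    nb <- order(abs(yhat_obs - h))[seq_len(min(donors, length(yo)))]
    yo[sample(nb, 1)]
  }, numeric(1))
}

logistic_draw <- function(y, ry, X) {
  yo <- y[ry]
  fit <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X[ry, , drop = FALSE], yo,
                     family = stats::binomial())
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
    warning("logistic imputation model did not converge; drawing from the observed margin")
    return(sample(yo, sum(!ry), replace = TRUE))
  }
  b <- fit$coefficients
  W <- fit$weights
  xtwx <- crossprod(X[ry, , drop = FALSE] * sqrt(W))
  V <- tryCatch(chol2inv(chol(xtwx + diag(1e-8, ncol(xtwx)))),
                error = function(e) NULL)
  bstar <- if (is.null(V)) b
           else b + as.vector(chol((V + t(V)) / 2 + diag(1e-12, ncol(V))) %*%
                              stats::rnorm(length(b)))
  p <- stats::plogis(as.vector(X[!ry, , drop = FALSE] %*% bstar))
  stats::rbinom(sum(!ry), 1, p)
}

margin_or_multinom <- function(y, ry, X) {
  yo <- y[ry]
  lev <- sort(unique(yo))
  if (length(lev) < 2) return(rep(lev, sum(!ry)))
  dat <- data.frame(.y = factor(yo, levels = lev))
  fit <- tryCatch({
    utils::capture.output(
      f <- nnet::multinom(
        .y ~ . - 1,
        data = cbind(dat, as.data.frame(X[ry, , drop = FALSE])),
        maxit = 200
      )
    )
    f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("multinomial imputation model failed; drawing from the observed margin")
    return(sample(yo, sum(!ry), replace = TRUE))
  }
  pr <- stats::predict(fit, newdata = as.data.frame(X[!ry, , drop = FALSE]),
                       type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)   # 2-level case
  idx <- apply(pr, 1, function(p) sample.int(length(lev), 1, prob = p))
  as.integer(as.character(lev[idx]))
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Combines per-imputation coefficients and standard errors: the pooled
#' coefficient is the mean of the betas; total variance
#' `T = W + (1 + 1/m) B` where `W` is the mean squared standard error and
#' `B` the between-imputation variance of the betas (n-1 denominator).
#' Degrees of freedom follow the Barnard-Rubin small-sample formula given the
#' complete-data degrees of freedom `dfcom`; the p-value and 95% interval
#' come from the corresponding t distribution.
#'
#' @param betas numeric vector of per-imputation coefficients (length m >= 2).
#' @param ses numeric vector of per-imputation standard errors (all > 0).
#' @param dfcom complete-data degrees of freedom (e.g. n - p - 1);
#'   `Inf` gives the asymptotic (normal-based) interval.
#' @return object of class `pooled_estimate`: list with `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `df`, `within_var`, `between_var`, `m`.
#' @export
pool_rubin <- function(betas, ses, dfcom = Inf) {
  m <- length(betas)
  if (m < 2) stop("Rubin pooling requires m >= 2 estimates")
  if (length(ses) != m) stop("betas and ses must have equal length")
  if (any(ses <= 0)) stop("all standard errors must be positive")
  qbar <- mean(betas)
  within <- mean(ses^2)
  between <- stats::var(betas)
  total <- within + (1 + 1 / m) * between
  se <- sqrt(total)

  lambda <- (1 + 1 / m) * between / total
  if (lambda < .Machine$double.eps) {
    df <- dfcom
  } else {
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else df <- df_old
  }
  tcrit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  tstat <- qbar / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(tstat), df)
       else 2 * stats::pnorm(-abs(tstat))
  structure(list(beta = qbar, se = se,
                 ci_low = qbar - tcrit * se, ci_high = qbar + tcrit * se,
                 p = p, df = df, within_var = within, between_var = between,
                 m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled beta %.4f (se %.4f, 95%% CI %.4f to %.4f, p %.3g, df %.1f)\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$p, x$df))
  invisible(x)
}
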