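#' Exclude metabolites with excessive missingness
#'
#' Drops every metabolite whose fraction of missing samples is strictly
#' greater than `max_frac` (a column at exactly the threshold is kept).
#'
#' @param m a raw-state [metab_matrix()].
#' @param max_frac maximum tolerated missing fraction per metabolite.
#' @return a filtered-state `metab_matrix`; the ids of dropped metabolites
#'   are attached as attribute `"dropped"`.
#' @export
filter_missingness <- function(m, max_frac = 0.20) {
  assert_state(m, "raw", "filter_missingness")
  frac <- colMeans(is.na(m$values))
  keep <- frac <= max_frac
  if (!any(keep))
    stop("all metabolites exceed the missingness threshold; review max_frac")
  dropped <- colnames(m$values)[!keep]
  m$values <- m$values[, keep, drop = FALSE]
  m <- advance_state(m, "filtered")
  attr(m, "dropped") <- dropped
  m
}

#' k-nearest-neighbour imputation of missing abundances
#'
#' Each missing cell of a metabolite is replaced by the mean value, in that
#' sample, of the k metabolites with the most similar profiles. Similarity
#' is Euclidean distance between metabolite profiles computed over mutually
#' observed samples and rescaled by the fraction of samples observed (so
#' profiles with few overlapping observations are not spuriously close).
#' Distance ties are broken by metabolite column order. A metabolite sharing
#' no observed sample with any other falls back to its column mean, with a
#' warning. Observed cells are never touched.
#'
#' @param m a filtered-state [metab_matrix()].
#' @param k number of neighbours (must be < number of metabolites).
#' @return an imputed-state `metab_matrix` with no missing cells.
#' @export
knn_impute <- function(m, k = 10) {
  assert_state(m, "filtered", "knn_impute")
  x <- m$values
  p <- ncol(x)
  if (k >= p) stop("k must be smaller than the number of metabolites")
  miss_cols <- which(colSums(is.na(x)) > 0)
  if (length(miss_cols)) {
    obs <- !is.na(x)
    for (j in miss_cols) {
      d <- knn_profile_dist(x, obs, j)
      ord <- order(d, seq_len(p))           # index order breaks ties
      ord <- ord[is.finite(d[ord])]
      miss_rows <- which(!obs[, j])
      if (!length(ord)) {
        warning(sprintf("metabolite %s has no overlapping observations; %s",
                        colnames(x)[j], "falling back to column mean"))
        x[miss_rows, j] <- mean(x[, j], na.rm = TRUE)
        next
      }
      nb <- ord[seq_len(min(k, length(ord)))]
      for (i in miss_rows) {
        v <- x[i, nb]
        v <- v[!is.na(v)]
        x[i, j] <- if (length(v)) mean(v)
                   else mean(x[, j], na.rm = TRUE)
      }
    }
  }
  m$values <- x
  advance_state(m, "imputed")
}

## distances from metabolite j to all others over mutually observed samples,
## rescaled by the fraction observed; Inf where there is no overlap
knn_profile_dist <- function(x, obs, j) {
  n <- nrow(x)
  p <- ncol(x)
  d <- rep(Inf, p)
  xj <- x[, j]; oj <- obs[, j]
  for (l in seq_len(p)) {
    if (l == j) next
    both <- oj & obs[, l]
    nb <- sum(both)
    if (nb == 0) next
    d[l] <- sqrt(sum((xj[both] - x[both, l])^2) * n / nb)
  }
  d[j] <- Inf
  d
}

#' Log10 transform of imputed abundances
#'
#' @param m an imputed-state [metab_matrix()]; all values must be positive.
#' @return a log10-state `metab_matrix`.
#' @export
log10_transform <- function(m) {
  assert_state(m, "imputed", "log10_transform")
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive abundance at sample %s, metabolite %s",
                 rownames(m$values)[bad[1, 1]], colnames(m$values)[bad[1, 2]]))
  m$values <- log10(m$values)
  advance_state(m, "log10")
}

#' Column-wise z-standardization
#'
#' Centres each column to mean 0 and scales to standard deviation 1
#' (denominator n - 1). Works on a log10-state [metab_matrix()] or on any
#' numeric matrix / data.frame of complete columns.
#'
#' @param x a [metab_matrix()], numeric matrix or data.frame.
#' @return same type, standardized; a `metab_matrix` advances to state
#'   `zscored`.
#' @export
zscore <- function(x) UseMethod("zscore")

#' @export
zscore.metab_matrix <- function(x) {
  assert_state(x, c("log10", "zscored"), "zscore")
  x$values <- zscore.matrix(x$values)
  advance_state(x, "zscored")
}

#' @export
zscore.matrix <- function(x) {
  sds <- apply(x, 2, stats::sd)
  zero <- which(sds == 0 | is.na(sds))
  if (length(zero))
    stop("zero-variance column: ",
         paste(colnames(x)[zero] %||% zero, collapse = ", "))
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' @export
zscore.data.frame <- function(x) {
  as.data.frame(zscore.matrix(as.matrix(x)))
}

#' @export
zscore.numeric <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("zero-variance vector")
  as.vector(x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full metabolite QC pipeline
#'
#' Missingness filter, kNN imputation, log10 transform and z-standardization
#' in order, returning the cleaned matrix together with a QC report.
#'
#' @param m a raw-state [metab_matrix()].
#' @param max_missing missingness threshold for [filter_missingness()].
#' @param k neighbours for [knn_impute()].
#' @return list with `matrix` (zscored `metab_matrix`) and `report` (counts,
#'   dropped metabolite ids, number of imputed cells).
#' @export
run_preprocess <- function(m, max_missing = 0.20, k = 10) {
  n_missing <- sum(is.na(m$values))
  filt <- filter_missingness(m, max_frac = max_missing)
  imputed_cells <- sum(is.na(filt$values))
  imp <- knn_impute(filt, k = k)
  z <- zscore(log10_transform(imp))
  list(
    matrix = z,
    report = list(
      n_metabolites_in = ncol(m$values),
      n_metabolites_kept = ncol(z$values),
      dropped = attr(filt, "dropped"),
      missing_cells_in = n_missing,
      imputed_cells = imputed_cells,
      max_missing = max_missing, k = k
    )
  )
}
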