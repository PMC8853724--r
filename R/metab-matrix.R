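#' Metabolite abundance matrix with processing state
#'
#' Container for a samples x metabolites abundance matrix. Missing cells are
#' `NA`; the missingness mask is derived from them. The object carries a
#' processing `state` that advances monotonically through
#' `raw -> filtered -> imputed -> log10 -> zscored`, so that each pipeline
#' stage can assert it receives data at the right point.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns.
#'   Dimnames are used as sample/metabolite identifiers; defaults are
#'   generated when absent.
#' @param state processing state, one of `"raw"`, `"filtered"`, `"imputed"`,
#'   `"log10"`, `"zscored"`.
#' @return an object of class `metab_matrix`.
#' @export
metab_matrix <- function(values, state = "raw") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  state <- match.arg(state, metab_states())
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%04d", seq_len(ncol(values)))
  structure(
    list(values = values, state = state),
    class = "metab_matrix"
  )
}

metab_states <- function() c("raw", "filtered", "imputed", "log10", "zscored")

state_index <- function(state) match(state, metab_states())

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("metab_matrix: %d samples x %d metabolites [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  nmiss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
as.matrix.metab_matrix <- function(x, ...) x$values

#' @export
dim.metab_matrix <- function(x) dim(x$values)

#' Missingness mask of a metabolite matrix
#'
#' @param m a [metab_matrix()].
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(m) {
  stopifnot(inherits(m, "metab_matrix"))
  is.na(m$values)
}

sample_ids <- function(m) rownames(m$values)
metabolite_ids <- function(m) colnames(m$values)

## Enforce the raw -> filtered -> imputed -> log10 -> zscored ordering.
## `from` may list several admissible source states.
assert_state <- function(m, from, op) {
  stopifnot(inherits(m, "metab_matrix"))
  if (!m$state %in% from)
    stop(sprintf("%s expects state %s, got '%s'", op,
                 paste(sQuote(from), collapse = " or "), m$state))
  invisible(m)
}

advance_state <- function(m, to) {
  if (state_index(to) < state_index(m$state))
    stop(sprintf("state cannot move backwards (%s -> %s)", m$state, to))
  m$state <- to
  m
}

#' Subset samples of a metabolite matrix
#'
#' Row subsetting that preserves the processing state; used e.g. after
#' sample-outlier exclusion.
#'
#' @param m a [metab_matrix()].
#' @param keep sample identifiers or logical/integer row index.
#' @return a `metab_matrix` with the selected samples.
#' @export
subset_samples <- function(m, keep) {
  stopifnot(inherits(m, "metab_matrix"))
  m$values <- m$values[keep, , drop = FALSE]
  m
}
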