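#' Hypergeometric pathway overrepresentation within modules
#'
#' For every (module, pathway) pair, tests whether the pathway is
#' overrepresented among the module's metabolites. The universe is the set
#' of metabolites that are both module-assigned (non-grey) and
#' pathway-annotated; unknown ("X-") metabolites without a pathway are
#' excluded. With `N` the universe size, `K` the pathway size, `n` the
#' module size and `k` their overlap, the upper-tail probability is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, the standard
#' overrepresentation convention including the observed overlap. Results
#' are tiered against `alpha /` (number of modules).
#'
#' @param assignment named character vector metabolite -> module ("grey" =
#'   unassigned).
#' @param annotation data.frame with columns `metabolite` and `pathway`
#'   (`NA` or `"Unknown"` = unannotated).
#' @param alpha family-wise error rate for the module-count Bonferroni tier.
#' @param include_grey include grey metabolites in the universe (off by
#'   default).
#' @return data.frame with columns module, pathway, N, K, n, k, p_upper,
#'   tier; the threshold is attached as attribute `"threshold"`.
#' @export
hypergeom_ora <- function(assignment, annotation, alpha = 0.05,
                          include_grey = FALSE) {
  ann <- annotation[!is.na(annotation$pathway) &
                    annotation$pathway != "Unknown", ]
  ids <- names(assignment)
  keep <- ids %in% ann$metabolite &
    (include_grey | assignment != "grey")
  universe <- ids[keep]
  if (!length(universe)) stop("empty overlap universe")
  pw <- ann$pathway[match(universe, ann$metabolite)]
  mod <- assignment[universe]
  modules <- setdiff(unique(mod), "grey")
  if (!length(modules)) stop("no non-grey module in the universe")
  pathways <- unique(pw)
  N <- length(universe)
  thr <- bonferroni_threshold(alpha, length(modules))

  rows <- list()
  for (md in modules) {
    inmod <- mod == md
    n <- sum(inmod)
    for (pp in pathways) {
      inpw <- pw == pp
      K <- sum(inpw)
      k <- sum(inmod & inpw)
      p_upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = md, pathway = pp, N = N, K = K, n = n, k = k,
        p_upper = p_upper, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$tier <- ifelse(res$p_upper < thr, "bonferroni",
                     ifelse(res$p_upper < 0.05, "nominal", "ns"))
  attr(res, "threshold") <- thr
  res
}
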