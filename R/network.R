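#' Residualize metabolites on the basic covariates
#'
#' Replaces each metabolite column by the z-standardized residuals of its
#' OLS regression on the Model-1 design (sex, clinic, age at clinic,
#' fasting). The basic covariates must be complete; network construction
#' then proceeds on covariate-adjusted abundances.
#'
#' @param m a zscored [metab_matrix()].
#' @param covariates a complete [covariate_table()].
#' @return a zscored `metab_matrix` of residuals.
#' @export
residualize_model1 <- function(m, covariates) {
  assert_state(m, "zscored", "residualize_model1")
  covs <- model_covariates(1)
  if (anyNA(as.data.frame(covariates)[covs]))
    stop("Model-1 covariates must be complete for residualization")
  X <- covariate_design(covariates, covs)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient Model-1 design")
  R <- qr.resid(qx, m$values)
  sds <- apply(R, 2, stats::sd)
  zero <- which(sds < 1e-12)
  if (length(zero))
    stop("zero residual variance for metabolite(s): ",
         paste(colnames(m$values)[zero], collapse = ", "))
  m$values <- scale(R, center = TRUE, scale = sds)[, , drop = FALSE]
  dimnames(m$values) <- dimnames(R)
  m
}

#' Sample outlier detection by standardized connectivity
#'
#' Builds the sample-sample network with adjacency
#' `A_st = (1 + cor(sample_s, sample_t)) / 2`, computes each sample's
#' connectivity `k_s = sum_{t != s} A_st`, standardizes it to `Z.k`, and
#' flags samples with `Z.k < cut` as outliers.
#'
#' @param m a [metab_matrix()] (typically residualized).
#' @param cut exclusion threshold on Z.k.
#' @return list with `kept` and `excluded` sample ids and the named `zk`
#'   vector.
#' @export
sample_outliers_zk <- function(m, cut = -4) {
  stopifnot(inherits(m, "metab_matrix"))
  if (nrow(m$values) < 10) stop("need at least 10 samples")
  A <- (1 + stats::cor(t(m$values))) / 2
  k <- rowSums(A) - diag(A)
  if (stats::sd(k) < 1e-12) stop("zero variance in sample connectivity")
  zk <- (k - mean(k)) / stats::sd(k)
  names(zk) <- rownames(m$values)
  excluded <- names(zk)[zk < cut]
  list(kept = setdiff(names(zk), excluded), excluded = excluded, zk = zk)
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation for every metabolite pair. For a column x with median
#' med and median absolute deviation MAD (unscaled), `u_i = (x_i - med) /
#' (9 MAD)` and weights `w_i = (1 - u_i^2)^2 I(|u_i| < 1)`; the correlation
#' is the weighted centred cross-product normalized by the weighted norms.
#' A column with MAD = 0 (but nonzero variance) falls back to its Pearson
#' standardization with a warning; a constant column is an error.
#'
#' @param m a [metab_matrix()] or numeric matrix (samples x metabolites).
#' @return symmetric correlation matrix, unit diagonal, entries in [-1, 1].
#' @export
bicor_matrix <- function(m) {
  x <- if (inherits(m, "metab_matrix")) m$values else as.matrix(m)
  if (nrow(x) < 10) stop("need at least 10 samples")
  p <- ncol(x)
  U <- matrix(0, nrow(x), p, dimnames = dimnames(x))
  fallback <- character(0)
  for (j in seq_len(p)) {
    xj <- x[, j]
    if (stats::sd(xj) == 0)
      stop("constant column: ", colnames(x)[j] %||% j)
    med <- stats::median(xj)
    madj <- stats::mad(xj, constant = 1)
    if (madj == 0) {
      fallback <- c(fallback, colnames(x)[j] %||% as.character(j))
      cj <- xj - mean(xj)
    } else {
      u <- (xj - med) / (9 * madj)
      w <- (1 - u^2)^2 * (abs(u) < 1)
      cj <- (xj - med) * w
    }
    U[, j] <- cj / sqrt(sum(cj^2))
  }
  if (length(fallback))
    warning("MAD = 0, Pearson fallback for: ",
            paste(fallback, collapse = ", "))
  cc <- crossprod(U)
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^power` for the signed network (the default;
#' anticorrelated metabolites get near-zero adjacency) or `|cor_ij|^power`
#' for the unsigned variant. The diagonal is set to 0 so connectivity sums
#' exclude self-adjacency.
#'
#' @param cor correlation matrix.
#' @param power soft-thresholding exponent (>= 1).
#' @param type `"signed"` (default) or `"unsigned"`.
#' @return adjacency matrix with entries in [0, 1] and zero diagonal.
#' @export
signed_adjacency <- function(cor, power, type = c("signed", "unsigned")) {
  type <- match.arg(type)
  if (power < 1) stop("power must be >= 1")
  a <- if (type == "signed") ((1 + cor) / 2)^power else abs(cor)^power
  diag(a) <- 0
  a
}

## scale-free fit: bin connectivities into equal-occupancy bins, estimate
## log-density per bin, regress on log mean connectivity; the fit index is
## R^2 signed by the negative slope (scale-free networks slope downwards)
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < nbins) nbins <- max(2, length(unique(k)) %/% 2)
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = nbins + 1)))
  if (length(br) < 3) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  width <- diff(br)
  dens <- as.vector(table(bin)) / (length(k) * width)
  ok <- dens > 0 & !is.na(dk)
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(dens[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power, builds the signed adjacency, computes
#' connectivities and the signed scale-free fit index R^2, and picks the
#' smallest power whose fit reaches `r2_min` — which, since mean
#' connectivity decreases monotonically with power, also maximizes mean
#' connectivity among qualifying powers. If no power qualifies, the power
#' with the best fit is returned with a warning.
#'
#' @param cor correlation matrix.
#' @param powers candidate integer powers.
#' @param r2_min scale-free topology threshold.
#' @param type network type, passed to [signed_adjacency()].
#' @return list with `power` (chosen) and `scan`, a data.frame with columns
#'   power, signed_r2, mean_k, median_k.
#' @export
pick_soft_threshold <- function(cor, powers = 1:20, r2_min = 0.85,
                                type = "signed") {
  scan <- data.frame(power = powers, signed_r2 = NA_real_,
                     mean_k = NA_real_, median_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- signed_adjacency(cor, powers[i], type = type)
    k <- colSums(a)
    scan$signed_r2[i] <- scale_free_fit(k)
    scan$mean_k[i] <- mean(k)
    scan$median_k[i] <- stats::median(k)
  }
  ok <- which(!is.na(scan$signed_r2) & scan$signed_r2 >= r2_min)
  if (length(ok)) {
    power <- powers[min(ok)]
  } else {
    power <- powers[which.max(scan$signed_r2)]
    warning(sprintf(
      "no candidate power reaches signed R^2 >= %.2f; using power %d (best fit %.3f)",
      r2_min, power, max(scan$signed_r2, na.rm = TRUE)))
  }
  list(power = power, scan = scan)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{u != i} a_iu` and unit diagonal; the clustering
#' dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric matrix with entries in [0, 1] (diagonal
#'   ignored, treated as 0).
#' @return TOM matrix, symmetric, entries in [0, 1], unit diagonal.
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  if (any(den <= 0)) stop("non-positive TOM denominator; invalid adjacency")
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  tom[tom > 1] <- 1
  tom
}

## standard module colour sequence, largest module first
module_colours <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}

#' Module detection by dynamic hybrid cutting of the TOM dendrogram
#'
#' Average-linkage clustering of the `1 - TOM` dissimilarity followed by a
#' three-stage cut. Stage 1 traverses the dendrogram top-down: a branch is
#' split where the joining height leaves a clear gap to both sub-branches;
#' a terminal branch becomes a module candidate when it has at least
#' `min_module_size` members, its core scatter (mean internal merge height)
#' is below a threshold, and it attaches to the rest of the tree with a
#' clear gap. `deep_split` (0-4) relaxes the scatter threshold and shrinks
#' the required gap, so higher values yield more granular modules. Stage 2
#' assigns each unlabelled metabolite to its nearest module (by average
#' dissimilarity) when it lies within that module's own radius — the
#' maximum average within-module dissimilarity of the module's members —
#' otherwise it stays "grey". Stage 3 computes module eigenvalues, clusters
#' modules on `1 - cor(eigenvalues)` and merges groups joined below
#' `merge_height`. Labels are colour strings in descending module size
#' (largest = "turquoise").
#'
#' @param dissimilarity `1 - TOM` matrix.
#' @param min_module_size smallest allowed module.
#' @param deep_split granularity, integer 0-4 (4 = most granular).
#' @param merge_height eigenvalue-correlation cut for merging (modules whose
#'   eigenvalues correlate above `1 - merge_height` merge).
#' @param metabolites the zscored/residualized [metab_matrix()] behind the
#'   dissimilarity; required for eigenvalue merging.
#' @return named character vector metabolite -> colour ("grey" =
#'   unassigned), with a warning when no module is found.
#' @export
cluster_modules <- function(dissimilarity, min_module_size = 20,
                            deep_split = 4, merge_height = 0.25,
                            metabolites = NULL) {
  d <- as.matrix(dissimilarity)
  p <- ncol(d)
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  ids <- colnames(d) %||% sprintf("M%04d", seq_len(p))
  hc <- stats::hclust(stats::as.dist(d), method = "average")

  lab <- dynamic_branch_cut(hc, min_module_size, deep_split, d)
  lab <- reassign_near_modules(lab, d)

  if (!any(lab > 0)) {
    warning("no module found; all metabolites are grey")
    return(stats::setNames(rep("grey", p), ids))
  }

  ## stage 3: merge modules with highly correlated eigenvalues
  if (!is.null(metabolites) && length(unique(lab[lab > 0])) > 1) {
    lab <- merge_close_modules(lab, metabolites, merge_height, ids)
  }

  ## colour labels by descending size
  sizes <- sort(table(lab[lab > 0]), decreasing = TRUE)
  pal <- module_colours()
  if (length(sizes) > length(pal))
    pal <- c(pal, sprintf("module%03d", seq_len(length(sizes) - length(pal))))
  colour_of <- stats::setNames(pal[seq_along(sizes)], names(sizes))
  out <- rep("grey", p)
  nz <- lab > 0
  out[nz] <- colour_of[as.character(lab[nz])]
  stats::setNames(out, ids)
}

## Stage-1 branch identification on an hclust tree. The dendrogram is first
## cut statically just below its top (0.99 of the maximum joining height),
## severing the loosely-joined upper ladder; each resulting component is
## then refined top-down: a node splits where the joining height leaves a
## gap >= gap_abs to both sub-branches, a small side chained on with a clear
## gap is peeled off, and a terminal branch becomes a module when its core
## scatter (mean internal merge height) stays below cs_abs. deep_split
## relaxes cs_abs and shrinks gap_abs, giving more granular modules. Before
## labelling, a terminal branch is trimmed to its core: members whose
## average dissimilarity to the rest of the branch is a robust outlier
## (above median + 3 MAD) are left unassigned — stragglers chained onto the
## branch just below the static cut.
## Returns integer labels (0 = unassigned).
dynamic_branch_cut <- function(hc, min_size, deep_split, d) {
  merge <- hc$merge
  height <- hc$height
  n <- length(hc$order)
  n_nodes <- nrow(merge)

  members <- vector("list", n_nodes)
  subtree_hsum <- numeric(n_nodes)   # sum of merge heights within subtree
  subtree_hcnt <- integer(n_nodes)
  parent <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    mem <- integer(0); hs <- height[i]; cnt <- 1L
    for (ch in merge[i, ]) {
      if (ch < 0) mem <- c(mem, -ch)
      else {
        mem <- c(mem, members[[ch]])
        hs <- hs + subtree_hsum[ch]
        cnt <- cnt + subtree_hcnt[ch]
        parent[ch] <- i
      }
    }
    members[[i]] <- mem
    subtree_hsum[i] <- hs
    subtree_hcnt[i] <- cnt
  }
  node_size <- lengths(members)
  node_h <- function(ch) if (ch < 0) 0 else height[ch]
  node_n <- function(ch) if (ch < 0) 1L else node_size[ch]
  scatter <- subtree_hsum / subtree_hcnt

  cut_height <- 0.99 * max(height)
  hlo <- stats::quantile(height, 0.05, names = FALSE)
  rng <- max(cut_height - hlo, .Machine$double.eps)
  cs_abs <- hlo + (0.64 + 0.08 * deep_split) * rng
  gap_abs <- (0.25 - 0.05 * deep_split) * rng

  labels <- integer(n)
  n_modules <- 0L
  label_node <- function(node) {
    mem <- members[[node]]
    repeat {
      avg <- colSums(d[mem, mem, drop = FALSE]) / (length(mem) - 1)
      thr <- stats::median(avg) + 3 * stats::mad(avg) + 1e-8
      core <- mem[avg <= thr]
      if (length(core) < min_size || length(core) == length(mem)) break
      mem <- core
    }
    if (length(mem) < min_size) return(invisible())
    n_modules <<- n_modules + 1L
    labels[mem] <<- n_modules
  }

  recurse <- function(node) {
    if (node < 0 || node_size[node] < min_size) return(invisible())
    ch <- merge[node, ]
    sz <- vapply(ch, node_n, integer(1))
    hh <- vapply(ch, node_h, numeric(1))
    h <- height[node]
    if (all(sz >= min_size) && h - max(hh) >= gap_abs) {
      recurse(ch[1]); recurse(ch[2])
      return(invisible())
    }
    if (xor(sz[1] < min_size, sz[2] < min_size)) {
      big <- ch[which.max(sz)]
      if (h - node_h(big) >= gap_abs) {
        recurse(big)             # small side peeled off, stays unassigned
        return(invisible())
      }
    }
    if (scatter[node] <= cs_abs) {
      label_node(node)
    } else {
      recurse(ch[1]); recurse(ch[2])
    }
  }

  ## component roots: maximal internal nodes at or below the static cut
  roots <- which(height <= cut_height &
                 (parent == 0 | height[pmax(parent, 1)] > cut_height))
  roots <- roots[vapply(roots, function(i)
    parent[i] == 0 || height[parent[i]] > cut_height, logical(1))]
  for (r in roots) recurse(r)
  labels
}

## Stage-2 hybrid assignment: attach an unlabelled metabolite to the module
## with smallest average dissimilarity, provided it lies within that
## module's own radius (max average within-module dissimilarity).
reassign_near_modules <- function(lab, d) {
  mods <- sort(unique(lab[lab > 0]))
  if (!length(mods)) return(lab)
  unas <- which(lab == 0)
  if (!length(unas)) return(lab)
  radius <- numeric(length(mods))
  avg_to <- matrix(NA_real_, length(unas), length(mods))
  for (mi in seq_along(mods)) {
    mem <- which(lab == mods[mi])
    within <- d[mem, mem, drop = FALSE]
    radius[mi] <- max(colSums(within) / (length(mem) - 1))
    avg_to[, mi] <- rowMeans(d[unas, mem, drop = FALSE])
  }
  best <- apply(avg_to, 1, which.min)
  dmin <- avg_to[cbind(seq_along(unas), best)]
  take <- dmin <= radius[best]
  lab[unas[take]] <- mods[best[take]]
  lab
}

merge_close_modules <- function(lab, metabolites, merge_height, ids) {
  repeat {
    mods <- sort(unique(lab[lab > 0]))
    if (length(mods) < 2) break
    assign_chr <- stats::setNames(ifelse(lab > 0, as.character(lab), "grey"),
                                  ids)
    me <- module_eigenvalues(metabolites, assign_chr)
    dme <- 1 - stats::cor(me)
    hcm <- stats::hclust(stats::as.dist(dme), method = "average")
    grp <- stats::cutree(hcm, h = merge_height)
    if (max(grp) == length(mods)) break
    remap <- stats::setNames(as.integer(grp), colnames(me))
    lab[lab > 0] <- remap[as.character(lab[lab > 0])]
  }
  lab
}

#' Module eigenvalues (eigengenes)
#'
#' For every non-grey module, the first principal-component score of the
#' member submatrix, scaled to unit variance and sign-aligned so that its
#' correlation with the module's average member profile is positive. A
#' single-metabolite module degenerates to that column standardized.
#'
#' @param m zscored/residualized [metab_matrix()].
#' @param assignment named character vector metabolite -> module label.
#' @return samples x modules numeric matrix (module labels as column names).
#' @export
module_eigenvalues <- function(m, assignment) {
  stopifnot(inherits(m, "metab_matrix"))
  ids <- colnames(m$values)
  assignment <- assignment[ids]
  mods <- setdiff(unique(assignment), "grey")
  mods <- mods[!is.na(mods)]
  if (!length(mods)) stop("no non-grey module to summarize")
  out <- matrix(NA_real_, nrow(m$values), length(mods),
                dimnames = list(rownames(m$values), mods))
  for (md in mods) {
    X <- m$values[, assignment == md, drop = FALSE]
    if (ncol(X) == 1) {
      e <- zscore.numeric(as.vector(X))
    } else {
      sv <- svd(scale(X, center = TRUE, scale = FALSE), nu = 1, nv = 0)
      e <- zscore.numeric(sv$u[, 1])
      if (stats::cor(e, rowMeans(X)) < 0) e <- -e
    }
    out[, md] <- e
  }
  out
}

#' Module membership (kME) table
#'
#' Pearson correlation of every metabolite with every module eigenvalue;
#' both own-module and cross-module memberships are retained.
#'
#' @param m zscored/residualized [metab_matrix()].
#' @param eigenvalues samples x modules matrix from [module_eigenvalues()].
#' @return metabolites x modules correlation matrix.
#' @export
module_kme <- function(m, eigenvalues) {
  stopifnot(inherits(m, "metab_matrix"))
  if (nrow(eigenvalues) != nrow(m$values))
    stop("eigenvalues and metabolites must cover the same samples")
  stats::cor(m$values, eigenvalues)
}

#' Hub metabolites
#'
#' Hubs are metabolites whose own-module kME strictly exceeds `threshold`
#' and that were independently significant in the single-metabolite
#' analyses.
#'
#' @param kme metabolites x modules kME matrix from [module_kme()].
#' @param assignment named character vector metabolite -> module label.
#' @param significant character vector of metabolite ids significant in the
#'   single-metabolite analyses.
#' @param threshold own-module kME cut (strict >).
#' @return data.frame with columns metabolite, module, kme_own for the hubs.
#' @export
identify_hubs <- function(kme, assignment, significant, threshold = 0.65) {
  ids <- rownames(kme)
  assignment <- assignment[ids]
  own <- rep(NA_real_, length(ids))
  inmod <- !is.na(assignment) & assignment != "grey" &
    assignment %in% colnames(kme)
  own[inmod] <- kme[cbind(which(inmod), match(assignment[inmod],
                                              colnames(kme)))]
  hub <- inmod & !is.na(own) & own > threshold & ids %in% significant
  data.frame(metabolite = ids[hub], module = assignment[hub],
             kme_own = own[hub], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Build the full weighted signed correlation network
#'
#' End-to-end network construction: optional residualization on the Model-1
#' covariates, sample-outlier exclusion by Z.k (residuals rebuilt on the
#' kept samples), biweight midcorrelation, soft-threshold selection (or a
#' fixed power), signed adjacency, TOM, dynamic hybrid module detection,
#' module eigenvalues and kME.
#'
#' @param m a zscored [metab_matrix()].
#' @param covariates complete [covariate_table()] for Model-1
#'   residualization, or `NULL` to skip.
#' @param power `"auto"` for scale-free selection or a fixed integer.
#' @param powers,r2_min passed to [pick_soft_threshold()].
#' @param min_module_size,deep_split,merge_height passed to
#'   [cluster_modules()].
#' @param zk_cut sample-outlier threshold, or `NULL` to skip exclusion.
#' @param type network type, see [signed_adjacency()].
#' @return object of class `network_model`: list with `cor`, `power`,
#'   `scan`, `adjacency`, `tom`, `dissimilarity`, `assignment`,
#'   `eigenvalues`, `kme`, `zk`, `excluded_samples`, `metabolites` (the
#'   matrix the network was built on).
#' @export
build_network <- function(m, covariates = NULL, power = "auto",
                          powers = 1:20, r2_min = 0.85,
                          min_module_size = 20, deep_split = 4,
                          merge_height = 0.25, zk_cut = -4,
                          type = "signed") {
  if (!is.null(covariates)) m <- residualize_model1(m, covariates)
  zk <- NULL; excluded <- character(0)
  if (!is.null(zk_cut)) {
    out <- sample_outliers_zk(m, cut = zk_cut)
    zk <- out$zk
    excluded <- out$excluded
    if (length(excluded)) {
      m <- subset_samples(m, out$kept)
      if (!is.null(covariates)) {
        covariates <- covariate_table(
          as.data.frame(covariates)[out$kept, , drop = FALSE],
          cov_types(covariates))
        m$values <- scale(m$values)   # re-centre before re-residualizing
        m <- residualize_model1(m, covariates)
      } else {
        m$values <- scale(m$values)
      }
    }
  }
  cc <- bicor_matrix(m)
  scan <- NULL
  if (identical(power, "auto")) {
    ps <- pick_soft_threshold(cc, powers = powers, r2_min = r2_min,
                              type = type)
    power <- ps$power
    scan <- ps$scan
  }
  adj <- signed_adjacency(cc, power, type = type)
  tom <- tom_matrix(adj)
  diss <- 1 - tom
  assignment <- cluster_modules(diss, min_module_size = min_module_size,
                                deep_split = deep_split,
                                merge_height = merge_height,
                                metabolites = m)
  has_mod <- any(assignment != "grey")
  eig <- if (has_mod) module_eigenvalues(m, assignment) else NULL
  kme <- if (has_mod) module_kme(m, eig) else NULL
  structure(list(cor = cc, power = power, scan = scan, adjacency = adj,
                 tom = tom, dissimilarity = diss, assignment = assignment,
                 eigenvalues = eig, kme = kme, zk = zk,
                 excluded_samples = excluded, metabolites = m),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  sizes <- table(x$assignment[x$assignment != "grey"])
  cat(sprintf("network_model: %d metabolites, power %d, %d modules (+%d grey)\n",
              length(x$assignment), x$power, length(sizes),
              sum(x$assignment == "grey")))
  if (length(sizes)) {
    s <- sort(sizes, decreasing = TRUE)
    cat("  modules:", paste(sprintf("%s(%d)", names(s), s), collapse = " "),
        "\n")
  }
  invisible(x)
}
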