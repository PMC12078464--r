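# 4x4 component correlation matrices across indicators and their
# dimensionality: PCA, Horn's parallel analysis, permutation tests,
# bootstrap confidence intervals.

#' Assemble a component correlation matrix from pairwise estimates
#'
#' Fills a symmetric indicator-by-indicator correlation matrix from pairwise
#' estimates (e.g. the `r_A` rows of bivariate fits, or SNP genetic
#' correlations). Pairwise fits need not produce a coherent joint matrix; if
#' the assembled matrix is not positive semi-definite it is projected to the
#' nearest PSD correlation matrix by eigenvalue clipping and unit-diagonal
#' rescaling, and the largest entry change is recorded.
#'
#' @param tbl A tibble with columns `trait1`, `trait2`, `estimate` and
#'   optionally `se`, one row per unordered indicator pair.
#' @param traits Indicator names fixing the matrix order; default: the names
#'   appearing in `tbl`.
#' @param source Label for the variance source (`"phenotypic"`, `"A"`, `"C"`,
#'   `"E"`), kept as an attribute.
#' @param n_effective Effective sample size behind the estimates (used by the
#'   bootstrap); kept as an attribute.
#' @return A correlation matrix of class `component_corr` with attributes
#'   `source`, `n_effective`, `se` (matrix), `psd_adjustment` (max absolute
#'   entry change, 0 if none).
#' @export
assemble_corr_matrix <- function(tbl, traits = NULL, source = "A",
                                 n_effective = NA_real_) {
  stopifnot(all(c("trait1", "trait2", "estimate") %in% names(tbl)))
  if (anyNA(tbl$estimate)) stop("unestimable entries in input")
  if (is.null(traits)) traits <- unique(c(tbl$trait1, tbl$trait2))
  k <- length(traits)
  need <- utils::combn(traits, 2)
  have <- paste(pmin(tbl$trait1, tbl$trait2), pmax(tbl$trait1, tbl$trait2))
  want <- paste(pmin(need[1, ], need[2, ]), pmax(need[1, ], need[2, ]))
  if (!all(want %in% have)) {
    stop("missing pair(s): ", paste(setdiff(want, have), collapse = ", "))
  }
  R <- diag(k); dimnames(R) <- list(traits, traits)
  SE <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(nrow(tbl))) {
    a <- tbl$trait1[i]; b <- tbl$trait2[i]
    R[a, b] <- R[b, a] <- tbl$estimate[i]
    if ("se" %in% names(tbl)) SE[a, b] <- SE[b, a] <- tbl$se[i]
  }
  adj <- 0
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    R_psd <- project_psd_corr(R)
    adj <- max(abs(R_psd - R))
    R <- R_psd
  }
  structure(R, class = c("component_corr", "matrix"),
            source = source, n_effective = n_effective, se = SE,
            psd_adjustment = adj)
}

# nearest PSD correlation matrix by eigenvalue clipping + rescaling
project_psd_corr <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  S <- e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
  D <- 1 / sqrt(diag(S))
  out <- S * outer(D, D)
  dimnames(out) <- dimnames(R)
  out
}

corr_matrix_of <- function(mat) {
  m <- unclass(mat)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  m
}

#' PCA of a correlation matrix
#'
#' Eigendecomposition of a correlation matrix; explained-variance fractions
#' are `lambda_i / sum(lambda)`, and each component's loadings are sign-fixed
#' so the largest-magnitude loading is positive.
#'
#' @param mat A correlation matrix (plain or from [assemble_corr_matrix()]).
#' @return Object of class `ses_pca`: list with `eigenvalues`,
#'   `explained` (fractions), `loadings` (variables x components), `source`.
#' @export
pca_corr <- function(mat) {
  R <- corr_matrix_of(mat)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) stop("matrix must be symmetric")
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(rownames(R), paste0("PC", seq_len(ncol(L))))
  structure(list(eigenvalues = e$values,
                 explained = e$values / sum(e$values),
                 loadings = L,
                 source = attr(mat, "source", exact = TRUE)),
            class = "ses_pca")
}

#' Horn's parallel analysis
#'
#' Retains the leading components whose observed eigenvalues exceed the
#' chosen quantile (default 95th) of eigenvalues of uncorrelated normal data
#' of the same shape (n observations x k variables); retention stops at the
#' first component that fails.
#'
#' @param data Observation-level data (n x k); or supply `corr` + `n`.
#' @param corr Correlation matrix (used with `n` when raw data are absent).
#' @param n Number of observations behind `corr`.
#' @param n_sims Number of null simulations (>= 100).
#' @param quantile Null quantile used as the retention threshold.
#' @param seed Integer seed.
#' @return A list with `n_retained`, `observed` eigenvalues, and `threshold`
#'   (null quantile per component).
#' @export
parallel_analysis <- function(data = NULL, corr = NULL, n = NULL,
                              n_sims = 1000, quantile = 0.95, seed = NULL) {
  if (n_sims < 100) stop("n_sims must be at least 100")
  if (!is.null(data)) {
    data <- as.matrix(data)
    n <- nrow(data)
    corr <- stats::cor(data)
  } else if (is.null(corr) || is.null(n)) {
    stop("supply either raw data or a correlation matrix with n")
  }
  corr <- corr_matrix_of(corr)
  k <- ncol(corr)
  if (n <= k) stop("need more observations than variables")
  obs <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  with_seed(seed, {
    null_eig <- matrix(NA_real_, n_sims, k)
    for (s in seq_len(n_sims)) {
      Z <- matrix(stats::rnorm(n * k), n, k)
      null_eig[s, ] <- eigen(stats::cor(Z), symmetric = TRUE,
                             only.values = TRUE)$values
    }
    thr <- apply(null_eig, 2, stats::quantile, probs = quantile)
    pass <- obs > thr
    n_ret <- if (pass[1]) {
      which(c(!pass, TRUE))[1] - 1L
    } else 0L
    list(n_retained = as.integer(n_ret), observed = obs, threshold = thr)
  })
}

#' Permutation test of PCA axes and variable contributions
#'
#' Builds a null distribution by independently permuting each variable's
#' values (destroying between-variable correlation while preserving
#' marginals) and compares observed eigenvalues and squared loadings against
#' it. An axis is significant when its observed eigenvalue exceeds the
#' `1 - alpha` null quantile; a variable contributes significantly to a
#' significant axis when its squared loading exceeds the corresponding null
#' quantile.
#'
#' @param data Observation-level data (n x k).
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return A list with `axes` (tibble: axis, eigenvalue, p_value,
#'   significant) and `contributions` (tibble: axis, variable, loading2,
#'   threshold, significant; significant axes only).
#' @export
pca_permutation_test <- function(data, n_perm = 1000, alpha = 0.05, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(k))
  obs_pca <- pca_corr(stats::cor(data))
  obs <- obs_pca$eigenvalues
  obs_l2 <- obs_pca$loadings^2
  with_seed(seed, {
    null_eig <- matrix(NA_real_, n_perm, k)
    null_l2 <- array(NA_real_, c(n_perm, k, k))
    for (s in seq_len(n_perm)) {
      P <- apply(data, 2, sample)
      e <- eigen(stats::cor(P), symmetric = TRUE)
      null_eig[s, ] <- e$values
      null_l2[s, , ] <- e$vectors^2
    }
    pval <- vapply(seq_len(k), function(j) mean(null_eig[, j] >= obs[j]),
                   numeric(1))
    axes <- tibble::tibble(axis = seq_len(k), eigenvalue = obs,
                           p_value = pval, significant = pval < alpha)
    sig_axes <- axes$axis[axes$significant]
    contrib <- purrr::map(sig_axes, function(j) {
      thr <- apply(null_l2[, , j, drop = FALSE], 2, stats::quantile,
                   probs = 1 - alpha)
      tibble::tibble(axis = j, variable = colnames(data),
                     loading2 = obs_l2[, j], threshold = as.numeric(thr),
                     significant = obs_l2[, j] > as.numeric(thr))
    })
    list(axes = axes, contributions = dplyr::bind_rows(contrib))
  })
}

#' Bootstrap confidence intervals for component-matrix PCA
#'
#' Parametric bootstrap (default): draws `n` observations from a zero-mean
#' multivariate normal with the estimated correlation matrix (via a Wishart
#' draw of the sample covariance), recomputes the PCA per replicate, and
#' returns percentile confidence intervals for explained-variance fractions
#' and loadings (sign-aligned to the point estimate). With
#' `mode = "resample"` and raw `data`, rows are resampled with replacement
#' instead.
#'
#' @param mat Correlation matrix ([assemble_corr_matrix()] output or plain).
#' @param n Effective sample size; defaults to the matrix's `n_effective`.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param mode `"parametric"` or `"resample"`.
#' @param data Raw data for `mode = "resample"`.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return A list with `explained` (tibble: component, estimate, lo, hi) and
#'   `loadings` (tibble: component, variable, estimate, lo, hi).
#' @export
bootstrap_pca <- function(mat, n = NULL, n_boot = 10000,
                          mode = c("parametric", "resample"), data = NULL,
                          level = 0.95, seed = NULL) {
  mode <- match.arg(mode)
  R <- corr_matrix_of(mat)
  k <- ncol(R)
  if (is.null(n)) n <- attr(mat, "n_effective", exact = TRUE)
  if (mode == "parametric" && (is.null(n) || is.na(n))) {
    stop("effective sample size n is required for the parametric bootstrap")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("matrix is not positive semi-definite; project it first")
  point <- pca_corr(R)
  a <- (1 - level) / 2
  with_seed(seed, {
    expl <- matrix(NA_real_, n_boot, k)
    lods <- array(NA_real_, c(n_boot, k, k))
    if (mode == "parametric") {
      Rpd <- project_psd_corr(R)       # strictly PD for the Wishart draw
      Ws <- stats::rWishart(n_boot, df = n - 1, Sigma = Rpd)
      for (s in seq_len(n_boot)) {
        S <- Ws[, , s]
        Ds <- 1 / sqrt(diag(S))
        e <- eigen(S * outer(Ds, Ds), symmetric = TRUE)
        expl[s, ] <- e$values / sum(e$values)
        L <- e$vectors
        # align signs with the point estimate
        sgn <- sign(colSums(L * point$loadings))
        sgn[sgn == 0] <- 1
        lods[s, , ] <- sweep(L, 2, sgn, "*")
      }
    } else {
      if (is.null(data)) stop("mode = 'resample' requires raw data")
      data <- as.matrix(data)
      for (s in seq_len(n_boot)) {
        idx <- sample.int(nrow(data), replace = TRUE)
        e <- eigen(stats::cor(data[idx, , drop = FALSE]), symmetric = TRUE)
        expl[s, ] <- e$values / sum(e$values)
        L <- e$vectors
        sgn <- sign(colSums(L * point$loadings))
        sgn[sgn == 0] <- 1
        lods[s, , ] <- sweep(L, 2, sgn, "*")
      }
    }
    expl_ci <- tibble::tibble(
      component = paste0("PC", seq_len(k)),
      estimate = point$explained,
      lo = apply(expl, 2, stats::quantile, probs = a),
      hi = apply(expl, 2, stats::quantile, probs = 1 - a))
    load_ci <- purrr::map(seq_len(k), function(j) {
      tibble::tibble(component = paste0("PC", j),
                     variable = rownames(point$loadings),
                     estimate = point$loadings[, j],
                     lo = apply(lods[, , j, drop = FALSE], 2, stats::quantile, probs = a),
                     hi = apply(lods[, , j, drop = FALSE], 2, stats::quantile, probs = 1 - a))
    })
    list(explained = expl_ci, loadings = dplyr::bind_rows(load_ci))
  })
}

#' @export
tidy.ses_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$eigenvalues)),
                 eigenvalue = x$eigenvalues,
                 explained = x$explained)
}

#' @export
print.ses_pca <- function(x, ...) {
  src <- if (!is.null(x$source)) paste0(" (", x$source, ")") else ""
  cat("PCA of correlation matrix", src, "\n", sep = "")
  print(tidy.ses_pca(x))
  invisible(x)
}
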