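# SNP-based heritability: GRM construction, REML variance components,
# association scan, LD scores and LD-score regression.

#' Standardize a dosage matrix
#'
#' Drops SNPs with minor-allele frequency below `maf_min` (frequency computed
#' from the sample) and zero-variance SNPs, then centres and scales each
#' remaining column to `(x - 2p) / sqrt(2p(1 - p))`.
#'
#' @param genos Genotype object or dosage matrix (individuals x SNPs, 0/1/2).
#' @param maf_min Minor-allele-frequency cutoff (default 0.01).
#' @return A numeric matrix `W` with attribute `"freq"` (the estimated allele
#'   frequencies of the retained SNPs).
#' @export
standardize_genotypes <- function(genos, maf_min = 0.01) {
  X <- dosage_matrix(genos)
  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  v <- matrixStats_colVars(X)
  keep <- maf >= maf_min & v > 0
  if (!any(keep)) stop("no SNPs survive MAF filter")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  W <- sweep(sweep(X, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  attr(W, "freq") <- p
  W
}

# column variances without extra dependencies
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' Genomic relatedness matrix
#'
#' `A = W W' / N` from a standardized genotype matrix `W` with `N` SNPs.
#'
#' @param W Standardized genotype matrix from [standardize_genotypes()].
#' @return Object of class `ses_grm`: list with `matrix` (n x n, dimnames =
#'   sample ids) and `n_snps`.
#' @export
compute_grm <- function(W) {
  if (ncol(W) == 0) stop("no SNPs in W")
  A <- tcrossprod(W) / ncol(W)
  structure(list(matrix = A, n_snps = ncol(W), sample_ids = rownames(W)),
            class = "ses_grm")
}

grm_matrix <- function(grm) {
  if (inherits(grm, "ses_grm")) grm$matrix else as.matrix(grm)
}

#' Prune close relatives from a GRM
#'
#' Greedy removal: while any off-diagonal relatedness exceeds `cutoff`, drop
#' the individual with the most above-cutoff partners (ties broken by sample
#' order), so the retained set has all pairwise relatedness below the cutoff.
#'
#' @param grm A `ses_grm` or relatedness matrix.
#' @param cutoff Relatedness threshold (default 0.025).
#' @return Character vector (or integer indices if unnamed) of retained ids.
#' @export
prune_relatives <- function(grm, cutoff = 0.025) {
  A <- grm_matrix(grm)
  n <- nrow(A)
  adj <- abs(A) > cutoff
  diag(adj) <- FALSE
  keep <- rep(TRUE, n)
  deg <- rowSums(adj)
  while (any(deg[keep] > 0)) {
    cand <- which(keep)
    worst <- cand[which.max(deg[cand])]
    keep[worst] <- FALSE
    nb <- which(adj[worst, ] & keep)
    deg[nb] <- deg[nb] - 1L
    deg[worst] <- 0L
  }
  ids <- rownames(A)
  if (is.null(ids)) which(keep) else ids[keep]
}

#' GREML: REML variance components from a GRM
#'
#' Fits `y = X beta + g + e` with `g ~ N(0, A sigma_g2)`,
#' `e ~ N(0, I sigma_e2)` by restricted maximum likelihood. The GRM is
#' eigendecomposed once; rotating `y` and `X` by the eigenvectors makes the
#' covariance diagonal, so the REML criterion reduces to a one-dimensional
#' profile optimization over the heritability ratio. The SE of
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)` comes from the observed
#' information of the two variance components (delta method).
#'
#' @param y Numeric response (names or order matching the GRM ids).
#' @param X Covariate matrix or data frame (an intercept is added); `NULL`
#'   for intercept only.
#' @param grm A `ses_grm` (ideally pruned with [prune_relatives()]).
#' @return Object of class `greml_fit` with `sigma_g2`, `sigma_e2`, `h2`,
#'   `se_h2`, `loglik`, `n_used`.
#' @export
fit_greml <- function(y, X = NULL, grm) {
  A <- grm_matrix(grm)
  n <- length(y)
  stopifnot(nrow(A) == n)
  X <- build_design(X, n)
  p <- ncol(X)
  eg <- eigen(A, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-8) {
    warning("GRM is not positive semi-definite; shifting eigenvalues")
  }
  d <- pmax(d, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  # REML log-likelihood for V = s * (h*D + (1-h)*I), with s profiled out
  reml_parts <- function(h) {
    w <- h * d + (1 - h)           # V / s
    if (any(w <= 0)) return(NULL)
    wi <- 1 / w
    XtWX <- crossprod(Xs, Xs * wi)
    XtWy <- crossprod(Xs, ys * wi)
    bh <- solve(XtWX, XtWy)
    r <- ys - Xs %*% bh
    q <- sum(r^2 * wi)
    list(w = w, XtWX = XtWX, q = q)
  }
  nre <- function(h) {
    pr <- reml_parts(h)
    if (is.null(pr)) return(1e10)
    s <- pr$q / (n - p)
    0.5 * ((n - p) * log(s) + sum(log(pr$w)) +
             determinant(pr$XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(nre, interval = c(1e-6, 1 - 1e-6), tol = 1e-8)
  h <- opt$minimum
  pr <- reml_parts(h)
  s <- pr$q / (n - p)
  sg <- h * s; se_ <- (1 - h) * s
  # observed information in (sigma_g2, sigma_e2)
  nll2 <- function(th) {
    a <- th[1]; b <- th[2]
    if (a < 0 || b <= 0) return(1e10)
    w <- a * d + b
    wi <- 1 / w
    XtWX <- crossprod(Xs, Xs * wi)
    bh <- solve(XtWX, crossprod(Xs, ys * wi))
    r <- ys - Xs %*% bh
    0.5 * (sum(log(w)) + determinant(XtWX, logarithm = TRUE)$modulus +
             sum(r^2 * wi))
  }
  H <- stats::optimHess(c(sg, se_), nll2)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  tot <- sg + se_
  grad <- c(se_, -sg) / tot^2
  se_h2 <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
  structure(list(sigma_g2 = sg, sigma_e2 = se_, h2 = h, se_h2 = se_h2,
                 loglik = -nre(h), n_used = n,
                 vcov_sigma = V),
            class = "greml_fit")
}

build_design <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == n)
  if (!any(apply(X, 2, function(v) all(v == v[1])))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  X
}

#' Bivariate GREML: genetic correlation between two traits
#'
#' Residualizes both traits on the covariates, rotates by the GRM
#' eigenvectors, and maximizes the likelihood of independent 2x2 normal
#' blocks with covariance `d_i * G + R` (G = genetic, R = residual 2x2
#' covariance matrices, log-Cholesky parameterized). Returns the genetic
#' correlation `r_g = g12 / sqrt(g11 g22)` with a delta-method SE.
#'
#' @inheritParams fit_greml
#' @param y1,y2 The two traits.
#' @return Object of class `greml_rg` with `r_g`, `se_rg`, component
#'   matrices, `loglik`.
#' @export
fit_greml_biv <- function(y1, y2, X = NULL, grm) {
  A <- grm_matrix(grm)
  n <- length(y1)
  stopifnot(length(y2) == n, nrow(A) == n)
  X <- build_design(X, n)
  r1 <- stats::lm.fit(X, y1)$residuals
  r2 <- stats::lm.fit(X, y2)$residuals
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  z1 <- drop(crossprod(U, r1))
  z2 <- drop(crossprod(U, r2))
  # theta: log-chol of G (l11, l21, l22-log) and of R
  unpack2 <- function(th) {
    Lg <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
    Lr <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2, 2)
    list(G = tcrossprod(Lg), R = tcrossprod(Lr))
  }
  v1 <- stats::var(z1); v2 <- stats::var(z2)
  start <- c(0.5 * log(0.3 * v1), 0, 0.5 * log(0.3 * v2),
             0.5 * log(0.7 * v1), 0, 0.5 * log(0.7 * v2))
  nll <- function(th) {
    m <- unpack2(th)
    if (any(!is.finite(unlist(m)))) return(1e10)
    s11 <- d * m$G[1, 1] + m$R[1, 1]
    s22 <- d * m$G[2, 2] + m$R[2, 2]
    s12 <- d * m$G[1, 2] + m$R[1, 2]
    out <- nll_biv2(z1, z2, s11, s22, s12)
    if (is.na(out)) 1e10 else out
  }
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-15, -20, -15, -15, -20, -15),
                      upper = c(6, 20, 6, 6, 20, 6),
                      control = list(maxit = 500))
  m <- unpack2(opt$par)
  if (m$G[1, 1] / (m$G[1, 1] + m$R[1, 1]) < 1e-4 ||
      m$G[2, 2] / (m$G[2, 2] + m$R[2, 2]) < 1e-4) {
    return(structure(list(r_g = NA_real_, se_rg = NA_real_, G = m$G, R = m$R,
                          loglik = -opt$value, n_used = n,
                          note = "genetic variance approximately zero; r_g unestimable"),
                     class = "greml_rg"))
  }
  H <- stats::optimHess(opt$par, nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 6, 6))
  gfun <- function(th) {
    mm <- unpack2(th)
    mm$G[1, 2] / sqrt(mm$G[1, 1] * mm$G[2, 2])
  }
  rg <- gfun(opt$par)
  J <- num_jacobian(gfun, opt$par)
  se <- sqrt(max(0, drop(J %*% V %*% t(J))))
  structure(list(r_g = rg, se_rg = se, G = m$G, R = m$R,
                 loglik = -opt$value, n_used = n, note = NULL),
            class = "greml_rg")
}

#' Per-SNP association scan (OLS)
#'
#' Linear regression of the trait on each SNP dosage with covariates
#' projected out of both sides. This is an ordinary-least-squares scan at
#' desk scale; run metadata records that it stands in for a sparse-GRM mixed
#' model, which matters only when close relatives remain in the sample.
#' Zero-variance SNPs are skipped.
#'
#' @param y Trait values.
#' @param genos Genotype object or dosage matrix.
#' @param X Covariates (see [fit_greml()]); intercept added.
#' @return A summary-statistics tibble: `snp`, `a1`, `a2`, `n`, `beta`, `se`,
#'   `z`, `chisq`, with attribute `"method" = "ols"`.
#' @export
run_gwas <- function(y, genos, X = NULL) {
  G <- dosage_matrix(genos)
  n <- length(y)
  stopifnot(nrow(G) == n)
  X <- build_design(X, n)
  p <- ncol(X)
  qr_x <- qr(X)
  yr <- stats::lm.fit(X, y)$residuals
  # residualize dosages in chunks
  m <- ncol(G)
  keep <- matrixStats_colVars(G) > 0
  beta <- se <- rep(NA_real_, m)
  idx <- which(keep)
  chunk <- max(1L, floor(5e7 / n))
  yss <- sum(yr^2)
  for (s in seq(1, length(idx), by = chunk)) {
    jj <- idx[s:min(length(idx), s + chunk - 1L)]
    Gc <- G[, jj, drop = FALSE]
    Gr <- Gc - X %*% qr.coef(qr_x, Gc)
    gss <- colSums(Gr^2)
    b <- colSums(Gr * yr) / gss
    rss <- yss - b^2 * gss
    s2 <- rss / (n - p - 1)
    beta[jj] <- b
    se[jj] <- sqrt(s2 / gss)
  }
  snp <- colnames(G)
  if (is.null(snp)) snp <- paste0("snp", seq_len(m))
  out <- tibble::tibble(snp = snp[keep], a1 = "A", a2 = "B", n = n,
                        beta = beta[keep], se = se[keep]) |>
    dplyr::mutate(z = .data$beta / .data$se, chisq = .data$z^2)
  attr(out, "method") <- "ols"
  out
}

#' LD scores from a reference panel
#'
#' For each SNP j, `l_j = sum_k r2_adj(j, k)` over SNPs k within `window`
#' positions, including the self pair, with the small-sample bias adjustment
#' `r2_adj = r2 - (1 - r2) / (n - 2)`.
#'
#' @param ref_genos Reference-panel genotypes (object or dosage matrix) with
#'   at least 50 samples.
#' @param window Half-window width in SNP positions (default 200).
#' @return A tibble `snp`, `ld` with attribute `"m_total"`.
#' @export
ld_scores <- function(ref_genos, window = 200) {
  G <- dosage_matrix(ref_genos)
  n <- nrow(G)
  if (n < 50) stop("reference panel must have at least 50 samples")
  m <- ncol(G)
  if (window >= m) {
    warning("window larger than SNP count; truncated")
    window <- m - 1L
  }
  v <- matrixStats_colVars(G)
  if (any(v == 0)) stop("reference panel contains monomorphic SNPs")
  S <- scale(G)                      # n x m, unit variance columns
  ld <- numeric(m)
  chunk <- max(window + 1L, 512L)
  for (s in seq(1, m, by = chunk)) {
    e <- min(m, s + chunk - 1L)
    lo <- max(1L, s - window)
    hi <- min(m, e + window)
    R <- crossprod(S[, s:e, drop = FALSE], S[, lo:hi, drop = FALSE]) / (n - 1)
    r2 <- R^2
    r2 <- r2 - (1 - r2) / (n - 2)
    # zero out entries beyond the window
    dpos <- abs(outer(s:e, lo:hi, "-")) <= window
    ld[s:e] <- rowSums(r2 * dpos)
  }
  snp <- colnames(G)
  if (is.null(snp)) snp <- paste0("snp", seq_len(m))
  out <- tibble::tibble(snp = snp, ld = ld)
  attr(out, "m_total") <- m
  out
}

# weighted simple linear regression y ~ a + b x; returns c(a, b)
wls2 <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  den <- sw * sxx - sx^2
  b <- (sw * sxy - sx * sy) / den
  a <- (sy - b * sx) / sw
  c(a, b)
}

#' LD-score regression: SNP heritability and confounding intercept
#'
#' Iteratively reweighted regression of GWAS chi-square statistics on
#' `N * l_j / M`: the slope estimates the SNP heritability and the intercept
#' the confounding bias (1 in the absence of stratification and cryptic
#' relatedness). Weights are proportional to `1 / (l_j * (1 + N h2 l_j / M)^2)`;
#' standard errors come from a delete-one block jackknife over contiguous SNP
#' blocks. A negative fitted h2 is reported as is, with a flag.
#'
#' @param ss Summary-statistics tibble from [run_gwas()] (needs `snp`,
#'   `chisq`, `n`).
#' @param ld LD-score tibble from [ld_scores()].
#' @param M Number of SNPs the heritability refers to (default: number of
#'   matched SNPs).
#' @param n_blocks Jackknife block count (default 200).
#' @return Object of class `ldsc_fit` with `h2`, `se_h2`, `intercept`,
#'   `se_intercept`, jackknife CIs and the number of SNPs used.
#' @export
ldsc_h2 <- function(ss, ld, M = NULL, n_blocks = 200) {
  dat <- dplyr::inner_join(ss, ld, by = "snp")
  m <- nrow(dat)
  if (m < 10) stop("too few matched SNPs")
  if (is.null(M)) M <- m
  if (n_blocks < 2) stop("need at least 2 jackknife blocks")
  n_blocks <- min(n_blocks, m)
  x <- dat$n * dat$ld / M
  y <- dat$chisq
  w <- rep(1, m)
  fit <- c(1, 0)
  for (it in 1:3) {
    fit <- wls2(x, y, w)
    h2 <- fit[2]
    w <- 1 / (pmax(dat$ld, 1) * pmax(1 + dat$n * max(h2, 0) * dat$ld / M, 0.1)^2)
  }
  blocks <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  jk <- vapply(seq_len(n_blocks), function(b) {
    s <- blocks != b
    wls2(x[s], y[s], w[s])
  }, numeric(2))
  nb <- n_blocks
  jk_mean <- rowMeans(jk)
  se <- sqrt((nb - 1) / nb * rowSums((jk - jk_mean)^2))
  structure(list(h2 = fit[2], se_h2 = se[2],
                 intercept = fit[1], se_intercept = se[1],
                 h2_ci = fit[2] + c(-1.96, 1.96) * se[2],
                 intercept_ci = fit[1] + c(-1.96, 1.96) * se[1],
                 negative_h2 = fit[2] < 0,
                 m_used = m, M = M, n_blocks = n_blocks),
            class = "ldsc_fit")
}

#' Cross-trait LD-score regression: genetic correlation
#'
#' Regresses the product of the two traits' Z statistics on
#' `sqrt(N1 N2) * l_j / M` to estimate the genetic covariance, divides by the
#' square root of the product of the univariate LDSC heritabilities, and
#' jackknifes the whole ratio over contiguous SNP blocks.
#'
#' @param ss1,ss2 Summary statistics for the two traits (matched alleles).
#' @param ld LD scores.
#' @inheritParams ldsc_h2
#' @return Object of class `ldsc_rg` with `r_g`, `se_rg`, `gencov`, the two
#'   univariate fits, and block count.
#' @export
ldsc_rg <- function(ss1, ss2, ld, M = NULL, n_blocks = 200) {
  dat <- dplyr::inner_join(
    dplyr::inner_join(
      dplyr::select(ss1, "snp", z1 = "z", chisq1 = "chisq", n1 = "n"),
      dplyr::select(ss2, "snp", z2 = "z", chisq2 = "chisq", n2 = "n"),
      by = "snp"),
    ld, by = "snp")
  m <- nrow(dat)
  if (is.null(M)) M <- m
  n_blocks <- min(n_blocks, m)
  x_g <- sqrt(dat$n1 * dat$n2) * dat$ld / M
  x_1 <- dat$n1 * dat$ld / M
  x_2 <- dat$n2 * dat$ld / M
  w <- 1 / pmax(dat$ld, 1)
  est_all <- function(s) {
    h1 <- wls2(x_1[s], dat$chisq1[s], w[s])[2]
    h2 <- wls2(x_2[s], dat$chisq2[s], w[s])[2]
    gc <- wls2(x_g[s], (dat$z1 * dat$z2)[s], w[s])[2]
    c(h1 = h1, h2 = h2, gencov = gc,
      rg = if (h1 > 0 && h2 > 0) gc / sqrt(h1 * h2) else NA_real_)
  }
  full <- est_all(rep(TRUE, m))
  if (is.na(full["rg"])) {
    stop("a univariate LDSC heritability is not positive; genetic correlation unestimable")
  }
  blocks <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  jk <- vapply(seq_len(n_blocks), function(b) est_all(blocks != b)["rg"],
               numeric(1))
  ok <- !is.na(jk)
  nb <- sum(ok)
  se <- sqrt((nb - 1) / nb * sum((jk[ok] - mean(jk[ok]))^2))
  structure(list(r_g = unname(full["rg"]), se_rg = se,
                 gencov = unname(full["gencov"]),
                 h2_1 = unname(full["h1"]), h2_2 = unname(full["h2"]),
                 m_used = m, n_blocks = n_blocks),
            class = "ldsc_rg")
}

#' @export
tidy.greml_fit <- function(x, ...) {
  tibble::tibble(component = c("sigma_g2", "sigma_e2", "h2"),
                 estimate = c(x$sigma_g2, x$sigma_e2, x$h2),
                 se = c(sqrt(pmax(0, diag(x$vcov_sigma))), x$se_h2))
}

#' @export
glance.greml_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se_h2 = x$se_h2, loglik = x$loglik, n = x$n_used)
}

#' @export
tidy.ldsc_fit <- function(x, ...) {
  tibble::tibble(term = c("h2", "intercept"),
                 estimate = c(x$h2, x$intercept),
                 se = c(x$se_h2, x$se_intercept),
                 lo95 = c(x$h2_ci[1], x$intercept_ci[1]),
                 hi95 = c(x$h2_ci[2], x$intercept_ci[2]))
}

#' @export
print.greml_fit <- function(x, ...) {
  cat("GREML fit: h2 =", format(x$h2, digits = 3),
      "(SE", format(x$se_h2, digits = 3), "), n =", x$n_used, "\n")
  invisible(x)
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("LD-score regression: h2 =", format(x$h2, digits = 3),
      "(SE", format(x$se_h2, digits = 3), "), intercept =",
      format(x$intercept, digits = 3),
      "(SE", format(x$se_intercept, digits = 3), ")\n")
  if (x$negative_h2) cat("  note: fitted h2 is negative\n")
  invisible(x)
}

#' @export
print.ldsc_rg <- function(x, ...) {
  cat("Cross-trait LDSC: r_g =", format(x$r_g, digits = 3),
      "(jackknife SE", format(x$se_rg, digits = 3), ")\n")
  invisible(x)
}

#' @export
print.greml_rg <- function(x, ...) {
  cat("Bivariate GREML: r_g =", format(x$r_g, digits = 3),
      "(SE", format(x$se_rg, digits = 3), ")\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Write / read summary statistics TSV
#'
#' LDSC-style TSV with columns SNP, A1, A2, N, BETA, SE, Z, CHISQ.
#' @param ss Summary statistics tibble from [run_gwas()].
#' @param path File path.
#' @export
write_sumstats <- function(ss, path) {
  out <- dplyr::rename(ss, SNP = "snp", A1 = "a1", A2 = "a2", N = "n",
                       BETA = "beta", SE = "se", Z = "z", CHISQ = "chisq")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols())
  names(raw) <- tolower(names(raw))
  if (!"chisq" %in% names(raw) && "z" %in% names(raw)) raw$chisq <- raw$z^2
  if (!"z" %in% names(raw) && all(c("beta", "se") %in% names(raw))) {
    raw$z <- raw$beta / raw$se
  }
  raw
}
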