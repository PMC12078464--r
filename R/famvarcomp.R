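# Pairwise maximum-likelihood ACE / AE variance-component models.
#
# Every fit works on a "pair table": one row per relative pair with the two
# members' trait values and the pair's genetic correlation r_g (expected from
# the pedigree, or empirical IBD sharing) and environment-sharing class.
# Pairs are treated as independent in the likelihood (pseudo-likelihood);
# overlapping pairs within extended families are ignored at the likelihood
# level, which leaves point estimates consistent but can understate SEs
# slightly when many pairs share members.

# negative log-likelihood of bivariate normals with common variance v,
# per-pair covariance cv, and per-member means m1, m2
nll_pair_normal <- function(y1, y2, m1, m2, v, cv, vec = FALSE) {
  d1 <- y1 - m1; d2 <- y2 - m2
  det <- v^2 - cv^2
  if (any(det <= 0) || v <= 0) {
    return(if (vec) rep(1e10 / length(y1), length(y1)) else 1e10)
  }
  ll <- log(2 * pi) + 0.5 * log(det) +
    0.5 * (v * (d1^2 + d2^2) - 2 * cv * d1 * d2) / det
  if (vec) ll else sum(ll)
}

# Cluster-robust (sandwich) parameter covariance for an M-estimator:
# H^-1 (sum_c s_c s_c') H^-1, with per-observation scores obtained by
# central differences of the per-pair negative log-likelihood.
sandwich_vcov <- function(nll_vec, theta, H, cluster, eps = 1e-5) {
  k <- length(theta)
  G <- matrix(0, length(cluster), k)
  for (j in seq_len(k)) {
    tp <- theta; tm <- theta
    tp[j] <- theta[j] + eps; tm[j] <- theta[j] - eps
    G[, j] <- (nll_vec(tp) - nll_vec(tm)) / (2 * eps)
  }
  S <- rowsum(G, cluster)
  Hi <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  Hi %*% crossprod(S) %*% Hi
}

# Attach per-pair trait values from a phenotype table.
#' Join a trait onto a pair table
#'
#' @param pairs Pair tibble (columns `id1`, `id2`).
#' @param pheno Phenotype tibble with `id` and the trait column.
#' @param trait Trait column name (string).
#' @param sex Also join the `sex` column as `sex1`/`sex2`? Default `TRUE`
#'   when present.
#' @return `pairs` with columns `y1`, `y2` (and `sex1`, `sex2`).
#' @export
pair_trait <- function(pairs, pheno, trait, sex = "sex" %in% names(pheno)) {
  i1 <- match(pairs$id1, pheno$id)
  i2 <- match(pairs$id2, pheno$id)
  out <- dplyr::mutate(pairs, y1 = pheno[[trait]][i1], y2 = pheno[[trait]][i2])
  if (isTRUE(sex)) out <- dplyr::mutate(out, sex1 = pheno$sex[i1], sex2 = pheno$sex[i2])
  dplyr::filter(out, !is.na(.data$y1) & !is.na(.data$y2))
}

# numerical jacobian by central differences
num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + eps; xm[j] <- x[j] - eps
    J[, j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  J
}

new_ace_fit <- function(estimates, loglik, n_pairs, model, assumptions,
                        converged, boundary, theta, vcov_theta, notes = character()) {
  structure(list(estimates = estimates, loglik = loglik, n_pairs = n_pairs,
                 model = model, assumptions = assumptions,
                 converged = converged, boundary = boundary,
                 theta = theta, vcov_theta = vcov_theta, notes = notes),
            class = "ace_fit")
}

#' Fit a univariate ACE or AE model to relative pairs
#'
#' Maximizes the pairwise bivariate-normal likelihood in which each pair's
#' cross-member covariance is `a2 * r_g + c2 * r_c` and the common variance is
#' `a2 + c2 + e2`. The shared-environment correlation is `rc_sib` (default 1)
#' for twin/sibling pairs and either a fixed `rc_cousin` or a free parameter
#' (`rc_cousin = "free"`, bounded to `[0, 1]`) for first-cousin pairs.
#' Variance components are parameterized on the log scale, so they are
#' non-negative by construction; fits pinned near zero are flagged as
#' boundary solutions. Estimates are reported standardized to total variance
#' 1 (so `a2` is the heritability), with observed-information (delta-method)
#' standard errors.
#'
#' @param pairs Pair tibble with columns `y1`, `y2`, `r_g`, `r_c_label`
#'   (see [pair_trait()]); optionally `sex1`, `sex2` for a sex mean effect.
#' @param components `"ACE"` or `"AE"`.
#' @param rc_sib Shared-environment correlation for sibling-class pairs.
#' @param rc_cousin Fixed cousin shared-environment correlation, or `"free"`.
#' @param r_g_col Column holding the genetic correlation (use `"r_g_hat"`
#'   for empirical IBD sharing).
#' @param sex_effect Include a sex covariate on the mean (requires `sex1`,
#'   `sex2`)? Default: `TRUE` when the columns are present.
#' @param cluster Optional cluster labels (one per pair, e.g. the extended
#'   family), switching the SEs to the family-level sandwich estimator.
#'   Recommended whenever pairs within a family share members, since the
#'   pseudo-likelihood otherwise understates uncertainty.
#' @return An object of class `ace_fit`; see [tidy.ace_fit()].
#' @export
fit_pair_ace <- function(pairs, components = c("ACE", "AE"),
                         rc_sib = 1, rc_cousin = 0, r_g_col = "r_g",
                         sex_effect = all(c("sex1", "sex2") %in% names(pairs)),
                         cluster = NULL) {
  components <- match.arg(components)
  stopifnot(all(c("y1", "y2", r_g_col) %in% names(pairs)))
  ok <- !is.na(pairs$y1) & !is.na(pairs$y2) & !is.na(pairs[[r_g_col]])
  if (!is.null(cluster)) {
    stopifnot(length(cluster) == length(ok))
    cluster <- cluster[ok]
  }
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 3) stop("too few complete pairs to fit")
  rg <- pairs[[r_g_col]]
  ace <- components == "ACE"
  rc_free <- identical(rc_cousin, "free")
  lab <- if ("r_c_label" %in% names(pairs)) pairs$r_c_label else rep("sib", nrow(pairs))
  is_cousin <- lab == "cousin"
  if (ace) {
    # identifiability: need distinct (r_g, r_c) configurations
    n_cfg <- nrow(unique(cbind(round(rg, 6), is_cousin)))
    if (n_cfg < 2 + rc_free) {
      stop("model not identifiable: need at least ", 2 + rc_free,
           " distinct relationship configurations, found ", n_cfg)
    }
    if (rc_free && !any(is_cousin)) stop("free cousin r_c requires cousin pairs")
  }
  sexed <- isTRUE(sex_effect)
  s1 <- if (sexed) as.numeric(pairs$sex1 == 1L) else 0
  s2 <- if (sexed) as.numeric(pairs$sex2 == 1L) else 0
  y1 <- pairs$y1; y2 <- pairs$y2

  # theta layout: log a2, [log c2], log e2, [qlogis rho_c], mu, [beta_sex]
  nm <- c("log_a2", if (ace) "log_c2", "log_e2",
          if (rc_free) "logit_rho_c", "mu", if (sexed) "beta_sex")
  vy <- stats::var(c(y1, y2))
  start <- c(log(0.3 * vy), if (ace) log(0.2 * vy), log(0.5 * vy),
             if (rc_free) 0, mean(c(y1, y2)), if (sexed) 0)
  unpack <- function(th) {
    i <- 1
    a2 <- exp(th[i]); i <- i + 1
    c2 <- if (ace) { v <- exp(th[i]); i <- i + 1; v } else 0
    e2 <- exp(th[i]); i <- i + 1
    rho <- if (rc_free) { v <- stats::plogis(th[i]); i <- i + 1; v } else rc_cousin
    mu <- th[i]; i <- i + 1
    bs <- if (sexed) th[i] else 0
    list(a2 = a2, c2 = c2, e2 = e2, rho = as.numeric(rho), mu = mu, bs = bs)
  }
  nll_gen <- function(th, vec = FALSE) {
    p <- unpack(th)
    rc <- ifelse(is_cousin, p$rho, rc_sib)
    v <- p$a2 + p$c2 + p$e2
    cv <- p$a2 * rg + p$c2 * rc
    nll_pair_normal(y1, y2, p$mu + p$bs * s1, p$mu + p$bs * s2, v, cv, vec)
  }
  nll <- function(th) nll_gen(th)
  lower <- rep(-Inf, length(start)); upper <- rep(Inf, length(start))
  k_var <- if (ace) 3 else 2
  lower[seq_len(k_var)] <- -15; upper[seq_len(k_var)] <- 6
  if (rc_free) { lower[k_var + 1] <- -10; upper[k_var + 1] <- 10 }
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
  H <- stats::optimHess(opt$par, nll)
  V <- if (is.null(cluster)) {
    tryCatch(solve(H), error = function(e) matrix(NA_real_, length(start), length(start)))
  } else {
    sandwich_vcov(function(th) nll_gen(th, vec = TRUE), opt$par, H, cluster)
  }
  p <- unpack(opt$par)
  vtot <- p$a2 + p$c2 + p$e2
  g <- function(th) {
    q <- unpack(th)
    v <- q$a2 + q$c2 + q$e2
    c(a2 = q$a2 / v, c2 = if (ace) q$c2 / v else NULL, e2 = q$e2 / v,
      rho_c = if (rc_free) q$rho else NULL,
      mu = q$mu, beta_sex = if (sexed) q$bs else NULL)
  }
  est <- g(opt$par)
  J <- num_jacobian(g, opt$par)
  se <- sqrt(pmax(0, diag(J %*% V %*% t(J))))
  frac <- names(est) %in% c("a2", "c2", "e2", "rho_c")
  lo <- est - 1.96 * se; hi <- est + 1.96 * se
  lo[frac] <- pmax(0, lo[frac]); hi[frac] <- pmin(1, hi[frac])
  estimates <- tibble::tibble(component = names(est), estimate = unname(est),
                              se = unname(se), lo95 = unname(lo), hi95 = unname(hi))
  boundary <- any(c(p$a2, p$c2[ace], p$e2) / vtot < 1e-3) ||
    (rc_free && (p$rho < 1e-3 || p$rho > 1 - 1e-3))
  n_pairs <- if ("relationship" %in% names(pairs)) {
    dplyr::count(pairs, .data$relationship, name = "n")
  } else tibble::tibble(relationship = "all", n = nrow(pairs))
  new_ace_fit(estimates, -opt$value, n_pairs, components,
              list(rc_sib = rc_sib, rc_cousin = rc_cousin, r_g_col = r_g_col),
              opt$convergence == 0, boundary, opt$par, V)
}

#' Sibling AE model with empirical IBD sharing
#'
#' Fits the AE model in which each sibling pair's genetic correlation is its
#' estimated realised genome sharing (`r_g_hat` from
#' [estimate_ibd_sharing()]): `Cov(P1, P2) = a2 * r_g_hat`,
#' `Var(P) = a2 + e2`. Identification comes from variation in realised
#' sharing around 0.5, so the fit refuses degenerate input where all pairs
#' share equally.
#'
#' @param pairs Pair tibble with `y1`, `y2`, `r_g_hat` (and optional sex).
#' @inheritParams fit_pair_ace
#' @return An `ace_fit` with components `a2` (= h2) and `e2`.
#' @export
fit_ibd_ae <- function(pairs, sex_effect = all(c("sex1", "sex2") %in% names(pairs)),
                       cluster = NULL) {
  stopifnot("r_g_hat" %in% names(pairs))
  ok <- !is.na(pairs$r_g_hat)
  if (!is.null(cluster)) cluster <- cluster[ok]
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 3) stop("too few pairs with a usable sharing estimate")
  if (stats::sd(pairs$r_g_hat) < 1e-8) {
    stop("IBD variance zero: realised sharing is constant across pairs, AE model unidentifiable")
  }
  fit <- fit_pair_ace(pairs, components = "AE", r_g_col = "r_g_hat",
                      sex_effect = sex_effect, cluster = cluster)
  fit$model <- "IBD-AE"
  fit
}

#' Sensitivity of ACE estimates to the assumed cousin environment correlation
#'
#' Refits the ACE model across a grid of assumed cousin shared-environment
#' correlations (sibling correlation held at `rc_sib`), returning one row per
#' grid point and component.
#'
#' @inheritParams fit_pair_ace
#' @param rc_grid Grid of assumed cousin correlations in `[0, 1]`.
#' @return A tibble of class `ace_sweep` with columns `rho_c_assumed`,
#'   `component`, `estimate`, `se`, `lo95`, `hi95`.
#' @export
sensitivity_sweep <- function(pairs, rc_grid = seq(0, 1, by = 0.05), rc_sib = 1,
                              sex_effect = all(c("sex1", "sex2") %in% names(pairs)),
                              cluster = NULL) {
  if (length(rc_grid) == 0) stop("rc_grid is empty")
  if (any(rc_grid < 0 | rc_grid > 1)) stop("rc_grid values must lie in [0, 1]")
  rows <- purrr::map(rc_grid, function(rc) {
    fit <- fit_pair_ace(pairs, components = "ACE", rc_sib = rc_sib,
                        rc_cousin = rc, sex_effect = sex_effect,
                        cluster = cluster)
    dplyr::mutate(
      dplyr::filter(fit$estimates, .data$component %in% c("a2", "c2", "e2")),
      rho_c_assumed = rc, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ace_sweep", class(out))
  out
}

# vectorized bivariate-normal nll with per-observation 2x2 covariance
nll_biv2 <- function(u1, u2, s11, s22, s12, vec = FALSE) {
  det <- s11 * s22 - s12^2
  if (anyNA(det) || any(det <= 0) || any(s11 <= 0)) return(NA_real_)
  ll <- log(2 * pi) + 0.5 * log(det) +
    0.5 * (s22 * u1^2 - 2 * s12 * u1 * u2 + s11 * u2^2) / det
  if (vec) ll else sum(ll)
}

#' Bivariate ACE/AE model: cross-trait component correlations
#'
#' Fits a 4-variate normal model to pairs measured on two traits, with
#' per-trait A/C/E variances and first-class component correlations r_A, r_C,
#' r_E: within a member, `Cov(X, Y) = ax*ay*rA + cx*cy*rC + ex*ey*rE` (a, c, e
#' on the SD scale); across members, the genetic part is multiplied by the
#' pair's `r_g` and the shared-environment part by its `r_c`. The likelihood
#' is evaluated through the sum/difference transform of the two members'
#' trait vectors, which block-diagonalizes the 4x4 covariance into two 2x2
#' matrices and permits a continuous per-pair `r_g` (empirical IBD sharing).
#' Correlations are parameterized via the inverse hyperbolic tangent, so they
#' stay inside (-1, 1); standard errors are delta-method from the observed
#' information. If a component's variance is estimated at (numerically) zero
#' for either trait, its correlation is reported as `NA` (unestimable).
#'
#' @param pairs Pair tibble with columns `x1`, `x2`, `y1`, `y2` (trait X and
#'   Y for members 1 and 2) plus `r_g` (or `r_g_hat`) and `r_c_label`.
#' @param components `"ACE"` or `"AE"`.
#' @param rc_sib,rc_cousin Shared-environment correlations by class (ACE
#'   only; no free cousin parameter in the bivariate model).
#' @param r_g_col Genetic-correlation column, e.g. `"r_g_hat"` for IBD pairs.
#' @param cluster Optional cluster labels (one per pair) for family-level
#'   sandwich SEs; see [fit_pair_ace()].
#' @return An object of class `biv_fit`.
#' @export
fit_pair_biv <- function(pairs, components = c("ACE", "AE"),
                         rc_sib = 1, rc_cousin = 0, r_g_col = "r_g",
                         cluster = NULL) {
  components <- match.arg(components)
  need <- c("x1", "x2", "y1", "y2", r_g_col)
  stopifnot(all(need %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, need])
  if (!is.null(cluster)) {
    stopifnot(length(cluster) == length(ok))
    cluster <- cluster[ok]
  }
  pairs <- pairs[ok, , drop = FALSE]
  ace <- components == "ACE"
  rg <- pairs[[r_g_col]]
  lab <- if ("r_c_label" %in% names(pairs)) pairs$r_c_label else rep("sib", nrow(pairs))
  rc <- ifelse(lab == "cousin", rc_cousin, rc_sib)
  if (!ace) rc <- rep(0, nrow(pairs))
  x1 <- pairs$x1; x2 <- pairs$x2; y1 <- pairs$y1; y2 <- pairs$y2

  # theta: log variances (ax, [cx], ex, ay, [cy], ey), atanh(rA), [atanh(rC)], atanh(rE), mux, muy
  nm <- c("log_a2_x", if (ace) "log_c2_x", "log_e2_x",
          "log_a2_y", if (ace) "log_c2_y", "log_e2_y",
          "z_rA", if (ace) "z_rC", "z_rE", "mu_x", "mu_y")
  vx <- stats::var(c(x1, x2)); vyv <- stats::var(c(y1, y2))
  start <- c(log(0.3 * vx), if (ace) log(0.2 * vx), log(0.5 * vx),
             log(0.3 * vyv), if (ace) log(0.2 * vyv), log(0.5 * vyv),
             atanh(0.4), if (ace) atanh(0.4), atanh(0.05),
             mean(c(x1, x2)), mean(c(y1, y2)))
  unpack <- function(th) {
    i <- 1
    ax <- exp(th[i]); i <- i + 1
    cx <- if (ace) { v <- exp(th[i]); i <- i + 1; v } else 0
    ex <- exp(th[i]); i <- i + 1
    ay <- exp(th[i]); i <- i + 1
    cy <- if (ace) { v <- exp(th[i]); i <- i + 1; v } else 0
    ey <- exp(th[i]); i <- i + 1
    rA <- tanh(th[i]); i <- i + 1
    rC <- if (ace) { v <- tanh(th[i]); i <- i + 1; v } else 0
    rE <- tanh(th[i]); i <- i + 1
    list(ax = ax, cx = cx, ex = ex, ay = ay, cy = cy, ey = ey,
         rA = rA, rC = rC, rE = rE, mux = th[i], muy = th[i + 1])
  }
  nll_gen <- function(th, vec = FALSE) {
    p <- unpack(th)
    vxx <- p$ax + p$cx + p$ex
    vyy <- p$ay + p$cy + p$ey
    cw <- sqrt(p$ax * p$ay) * p$rA + sqrt(p$cx * p$cy) * p$rC +
      sqrt(p$ex * p$ey) * p$rE
    cxx <- p$ax * rg + p$cx * rc
    cyy <- p$ay * rg + p$cy * rc
    cxy <- sqrt(p$ax * p$ay) * p$rA * rg + sqrt(p$cx * p$cy) * p$rC * rc
    # sum/difference transform: independent 2x2 normals
    sq <- 1 / sqrt(2)
    u1 <- (x1 - p$mux + x2 - p$mux) * sq; u2 <- (y1 - p$muy + y2 - p$muy) * sq
    w1 <- (x1 - x2) * sq; w2 <- (y1 - y2) * sq
    l1 <- nll_biv2(u1, u2, vxx + cxx, vyy + cyy, cw + cxy, vec)
    l2 <- nll_biv2(w1, w2, vxx - cxx, vyy - cyy, cw - cxy, vec)
    if (anyNA(l1) || anyNA(l2)) {
      return(if (vec) rep(1e10 / length(x1), length(x1)) else 1e10)
    }
    l1 + l2
  }
  nll <- function(th) nll_gen(th)
  k <- length(start)
  lower <- rep(-Inf, k); upper <- rep(Inf, k)
  nv <- if (ace) 6 else 4
  lower[seq_len(nv)] <- -15; upper[seq_len(nv)] <- 6
  ncor <- if (ace) 3 else 2
  lower[nv + seq_len(ncor)] <- -7; upper[nv + seq_len(ncor)] <- 7
  opt <- stats::optim(start, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 1000))
  H <- stats::optimHess(opt$par, nll)
  V <- if (is.null(cluster)) {
    tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  } else {
    sandwich_vcov(function(th) nll_gen(th, vec = TRUE), opt$par, H, cluster)
  }
  p <- unpack(opt$par)
  g <- function(th) {
    q <- unpack(th)
    vxx <- q$ax + q$cx + q$ex; vyy <- q$ay + q$cy + q$ey
    cw <- sqrt(q$ax * q$ay) * q$rA + sqrt(q$cx * q$cy) * q$rC +
      sqrt(q$ex * q$ey) * q$rE
    c(r_A = q$rA, r_C = if (ace) q$rC else NULL, r_E = q$rE,
      r_P = cw / sqrt(vxx * vyy),
      a2_x = q$ax / vxx, c2_x = if (ace) q$cx / vxx else NULL, e2_x = q$ex / vxx,
      a2_y = q$ay / vyy, c2_y = if (ace) q$cy / vyy else NULL, e2_y = q$ey / vyy)
  }
  est <- g(opt$par)
  J <- num_jacobian(g, opt$par)
  se <- sqrt(pmax(0, diag(J %*% V %*% t(J))))
  names(se) <- names(est)
  # component correlations are unestimable when a component variance is ~ 0
  vxx <- p$ax + p$cx + p$ex; vyy <- p$ay + p$cy + p$ey
  notes <- character()
  kill <- function(which_r, fr_x, fr_y) {
    if (fr_x < 1e-4 || fr_y < 1e-4) {
      est[which_r] <<- NA_real_; se[which_r] <<- NA_real_
      notes <<- c(notes, paste0(which_r,
        " unestimable: component variance approximately zero"))
    }
  }
  kill("r_A", p$ax / vxx, p$ay / vyy)
  if (ace) kill("r_C", p$cx / vxx, p$cy / vyy)
  kill("r_E", p$ex / vxx, p$ey / vyy)
  estimates <- tibble::tibble(component = names(est), estimate = unname(est),
                              se = unname(se),
                              lo95 = unname(est - 1.96 * se),
                              hi95 = unname(est + 1.96 * se))
  cor_rows <- grepl("^r_", estimates$component)
  estimates$lo95[cor_rows] <- pmax(-1, estimates$lo95[cor_rows])
  estimates$hi95[cor_rows] <- pmin(1, estimates$hi95[cor_rows])
  structure(list(estimates = estimates, loglik = -opt$value,
                 n_pairs = nrow(pairs), model = components,
                 assumptions = list(rc_sib = rc_sib, rc_cousin = rc_cousin,
                                    r_g_col = r_g_col),
                 converged = opt$convergence == 0, theta = opt$par,
                 vcov_theta = V, notes = notes),
            class = "biv_fit")
}

#' @export
tidy.ace_fit <- function(x, ...) x$estimates

#' @export
glance.ace_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik,
                 n_pairs = sum(x$n_pairs$n),
                 converged = x$converged, boundary = x$boundary)
}

#' @export
tidy.biv_fit <- function(x, ...) x$estimates

#' @export
glance.biv_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik, n_pairs = x$n_pairs,
                 converged = x$converged,
                 notes = paste(x$notes, collapse = "; "))
}

#' @export
print.ace_fit <- function(x, ...) {
  cat("Pairwise", x$model, "variance-component fit\n")
  cat("  log-likelihood:", format(x$loglik), " pairs:", sum(x$n_pairs$n), "\n")
  if (x$boundary) cat("  note: estimate at or near a boundary\n")
  print(x$estimates)
  invisible(x)
}

#' @export
print.biv_fit <- function(x, ...) {
  cat("Bivariate", x$model, "component-correlation fit\n")
  cat("  log-likelihood:", format(x$loglik), " pairs:", x$n_pairs, "\n")
  for (nt in x$notes) cat("  note:", nt, "\n")
  print(x$estimates)
  invisible(x)
}
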