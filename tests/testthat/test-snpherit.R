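make_founder_geno <- function(n, m, seed, block_len = 50, ld = 0) {
  ped <- tibble::tibble(id = paste0("i", seq_len(n)), father = NA_character_,
                        mother = NA_character_,
                        sex = rep(1:2, length.out = n),
                        zygosity = NA_character_)
  list(ped = ped,
       genos = sim_genotypes(ped, m_snps = m, block_len = block_len,
                             ld_rho = ld, seed = seed))
}

test_that("genotype standardization applies the MAF filter and the
           (x - 2p)/sqrt(2p(1-p)) transform", {
  X <- cbind(s1 = c(0, 1, 2, 0, 1, 2), # p = 0.5
             s2 = c(0, 0, 0, 0, 0, 1), # maf = 1/12 < 0.1
             s3 = c(1, 1, 1, 1, 1, 1)) # zero variance
  rownames(X) <- paste0("i", 1:6)
  W <- standardize_genotypes(X, maf_min = 0.1)
  expect_equal(colnames(W), "s1")
  expect_equal(unname(W[1:3, 1]), c(-1, 0, 1) / sqrt(0.5), tolerance = 1e-12)
  expect_error(standardize_genotypes(X[, 3, drop = FALSE], maf_min = 0.01),
               "no SNPs survive")
  # kept SNP with MAF 0.005 dropped at the 0.01 cutoff
  X2 <- cbind(rare = c(rep(0, 99), 1), common = rbinom(100, 2, 0.3))
  W2 <- standardize_genotypes(X2, maf_min = 0.01)
  expect_false("rare" %in% colnames(W2))
})

test_that("GRM has unit diagonal in expectation, 1/sqrt(N) off-diagonal noise,
           and detects duplicates", {
  fg <- make_founder_geno(300, 5000, seed = 61)
  W <- standardize_genotypes(fg$genos, maf_min = 0.01)
  W <- rbind(W, dup = W["i1", ])
  grm <- compute_grm(W)
  A <- grm$matrix
  expect_equal(A, t(A))
  expect_lt(abs(mean(diag(A)) - 1), 0.02)
  expect_gt(A["i1", "dup"], 0.9)
  off <- A[upper.tri(A)]
  off <- off[abs(off) < 0.5]          # exclude the planted duplicate
  expect_lt(abs(sd(off) - 1 / sqrt(grm$n_snps)), 0.005)
})

test_that("relative pruning removes the minimum greedy set", {
  A <- diag(4)
  rownames(A) <- colnames(A) <- c("a", "b", "c", "d")
  A["a", "b"] <- A["b", "a"] <- 0.5        # one sib pair
  kept <- prune_relatives(A, cutoff = 0.025)
  expect_setequal(setdiff(c("a", "b", "c", "d"), kept), "a")
  expect_length(kept, 3)
  # all-unrelated: everyone retained
  expect_length(prune_relatives(diag(5) + 0, cutoff = 0.025), 5)
  # clique of three relatives: exactly two removed
  B <- matrix(0.6, 3, 3); diag(B) <- 1
  rownames(B) <- colnames(B) <- c("x", "y", "z")
  expect_length(prune_relatives(B, cutoff = 0.025), 1)
})

test_that("GREML recovers boundary cases and matches the Haseman-Elston
           oracle on simulated data", {
  fg <- make_founder_geno(800, 2000, seed = 71)
  W <- standardize_genotypes(fg$genos, maf_min = 0.01)
  grm <- compute_grm(W)
  set.seed(72)
  # pure noise: h2 within 2 SE of zero
  y0 <- rnorm(800)
  f0 <- fit_greml(y0, NULL, grm)
  expect_lt(f0$h2, 2 * f0$se_h2 + 0.02)
  # noiseless genetic trait: h2 near 1
  b <- rnorm(ncol(W), 0, 1 / sqrt(ncol(W)))
  yg <- drop(W %*% b)
  f1 <- fit_greml(yg, NULL, grm)
  expect_gt(f1$h2, 0.95)
  # h2 = 0.4: REML within 2 SE and consistent with HE regression
  y <- sqrt(0.4) * yg / sd(yg) + rnorm(800, 0, sqrt(0.6))
  fit <- fit_greml(y, NULL, grm)
  expect_lt(abs(fit$h2 - 0.4), 2 * fit$se_h2)
  A <- grm$matrix; ut <- upper.tri(A)
  ys <- drop(scale(y))
  he <- coef(stats::lm(tcrossprod(ys)[ut] ~ A[ut]))[2]
  expect_lt(abs(fit$h2 - he), 0.1)
})

test_that("bivariate GREML handles identical, independent, and correlated
           architectures", {
  fg <- make_founder_geno(700, 1500, seed = 81)
  W <- standardize_genotypes(fg$genos, maf_min = 0.01)
  grm <- compute_grm(W)
  set.seed(82)
  b1 <- rnorm(ncol(W), 0, sqrt(0.4 / ncol(W)))
  y1 <- drop(W %*% b1) + rnorm(700, 0, sqrt(0.6))
  same <- fit_greml_biv(y1, y1, NULL, grm)
  expect_gt(same$r_g, 0.98)
  b2 <- rnorm(ncol(W), 0, sqrt(0.4 / ncol(W)))
  y2 <- drop(W %*% b2) + rnorm(700, 0, sqrt(0.6))
  ind <- fit_greml_biv(y1, y2, NULL, grm)
  expect_lt(abs(ind$r_g), 3 * ind$se_rg + 0.05)
  # no genetic variance: unestimable, not NaN
  null <- fit_greml_biv(rnorm(700), y2, NULL, grm)
  if (is.na(null$r_g)) expect_match(null$note, "unestimable")
})

test_that("the association scan is calibrated under the null and picks up a
           planted effect", {
  fg <- make_founder_geno(1000, 3000, seed = 91)
  X <- fg$genos$dosage
  set.seed(92)
  y0 <- rnorm(1000)
  ss0 <- run_gwas(y0, X)
  expect_lt(abs(mean(ss0$chisq) - 1), 0.08)
  # one SNP explaining 5% of variance: chi2 near n * 0.05
  w1 <- drop(scale(X[, 1]))
  y1 <- sqrt(0.05) * w1 + rnorm(1000, 0, sqrt(0.95))
  ss1 <- run_gwas(y1, X)
  expect_gt(ss1$chisq[ss1$snp == "snp1"], 25)
  # constant SNP dropped from the output
  Xc <- cbind(X, mono = rep(2L, 1000))
  ssc <- run_gwas(y0, Xc)
  expect_false("mono" %in% ssc$snp)
  # covariate projection: regressing out y itself errors usefully downstream,
  # regressing out noise leaves the scan unchanged in expectation
  ssx <- run_gwas(y0, X, X = data.frame(z = rnorm(1000)))
  expect_lt(abs(mean(ssx$chisq) - 1), 0.08)
})

test_that("LD scores equal the local redundancy of each SNP", {
  fg <- make_founder_geno(400, 300, seed = 93, ld = 0)
  X <- fg$genos$dosage
  # duplicate one SNP, make a perfectly correlated block of 4
  X2 <- cbind(X, dup = X[, 1])
  blk <- X[, 2]
  X3 <- cbind(X2, b1 = blk, b2 = blk, b3 = blk)
  ld <- ld_scores(X3, window = ncol(X3) - 1)
  tb <- ld$ld[ld$snp == "snp100"]
  expect_lt(abs(tb - 1), 0.15)                      # uncorrelated SNP: ~1
  expect_lt(abs(ld$ld[ld$snp == "dup"] - 2), 0.2)   # duplicated: ~2
  expect_lt(abs(ld$ld[ld$snp == "b1"] - 4), 0.3)    # block of 4: ~4
  expect_error(ld_scores(X[1:10, ]), "at least 50")
  expect_warning(ld_scores(X[, 1:20], window = 50), "window")
})

test_that("LDSC is null-calibrated, permutation-invariant, and flags a
           negative fit", {
  m <- 3000
  set.seed(94)
  ld <- tibble::tibble(snp = paste0("s", 1:m),
                       ld = 1 + rexp(m, 1 / 3))
  # chi2 identically 1: h2 ~ 0, intercept ~ 1
  ss <- tibble::tibble(snp = ld$snp, n = 5000, chisq = 1)
  f <- ldsc_h2(ss, ld)
  expect_lt(abs(f$h2), 1e-8)
  expect_equal(f$intercept, 1, tolerance = 1e-8)
  # joint permutation invariance of the point estimate
  chi <- 1 + 0.3 * ld$ld + rnorm(m, 0, 0.2)
  ss2 <- tibble::tibble(snp = ld$snp, n = 5000, chisq = chi)
  f2 <- ldsc_h2(ss2, ld)
  perm <- sample(m)
  f2p <- ldsc_h2(ss2[perm, ], ld)
  expect_equal(f2$h2, f2p$h2, tolerance = 1e-10)
  # downward-sloping chi2: negative h2 reported with the flag, not clipped
  ss3 <- tibble::tibble(snp = ld$snp, n = 5000,
                        chisq = pmax(0, 2 - 0.2 * ld$ld + rnorm(m, 0, 0.1)))
  f3 <- ldsc_h2(ss3, ld)
  expect_lt(f3$h2, 0)
  expect_true(f3$negative_h2)
  expect_error(ldsc_h2(ss, ld, n_blocks = 1), "blocks")
})

test_that("allele flips leave GRM, LD scores, GWAS chi2 and LDSC unchanged", {
  fg <- make_founder_geno(300, 800, seed = 95, ld = c(0.3, 0.9))
  X <- fg$genos$dosage
  set.seed(96)
  flip <- sample(800, 300)
  Xf <- X
  Xf[, flip] <- 2L - Xf[, flip]
  W <- standardize_genotypes(X, 0.01); Wf <- standardize_genotypes(Xf, 0.01)
  expect_equal(compute_grm(W)$matrix, compute_grm(Wf)$matrix, tolerance = 1e-10)
  expect_equal(ld_scores(X, 100)$ld, ld_scores(Xf, 100)$ld, tolerance = 1e-10)
  y <- rnorm(300)
  expect_equal(run_gwas(y, X)$chisq, run_gwas(y, Xf)$chisq, tolerance = 1e-10)
})

test_that("cross-trait LDSC is exact for a duplicated trait and null for
           independent ones", {
  m <- 4000
  set.seed(97)
  ld <- tibble::tibble(snp = paste0("s", 1:m), ld = 1 + rexp(m, 1 / 3))
  n <- 5000; h2 <- 0.3; M <- m
  z1 <- rnorm(m, 0, sqrt(1 + n * h2 * ld$ld / M))
  ss1 <- tibble::tibble(snp = ld$snp, n = n, z = z1, chisq = z1^2)
  expect_equal(ldsc_rg(ss1, ss1, ld)$r_g, 1, tolerance = 1e-8)
  z2 <- rnorm(m, 0, sqrt(1 + n * h2 * ld$ld / M))
  ss2 <- tibble::tibble(snp = ld$snp, n = n, z = z2, chisq = z2^2)
  rg <- ldsc_rg(ss1, ss2, ld)
  expect_lt(abs(rg$r_g), 3 * rg$se_rg + 0.05)
  # h2 <= 0 refused: chi2 declining in ld forces a negative slope
  ss_null <- tibble::tibble(snp = ld$snp, n = n, z = rnorm(m, 0, 0.1),
                            chisq = pmax(0, 1 - 0.2 * ld$ld))
  expect_error(ldsc_rg(ss_null, ss2, ld), "not positive")
})
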