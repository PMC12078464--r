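test_that("twin-design ACE fit matches the Falconer closed form", {
  set.seed(101)
  pairs <- dplyr::bind_rows(
    make_corr_pairs(15000, 0.6, "MZ", r_g = 1),
    make_corr_pairs(15000, 0.4, "DZ", r_g = 0.5))
  fit <- fit_pair_ace(pairs, rc_cousin = 0, sex_effect = FALSE)
  est <- tidy(fit)
  # Falconer: a2 = 2 (rMZ - rDZ) = 0.4, c2 = 2 rDZ - rMZ = 0.2, from the
  # empirical class correlations
  r_mz <- cor(pairs$y1[pairs$relationship == "MZ"],
              pairs$y2[pairs$relationship == "MZ"])
  r_dz <- cor(pairs$y1[pairs$relationship == "DZ"],
              pairs$y2[pairs$relationship == "DZ"])
  expect_lt(abs(est$estimate[est$component == "a2"] - 2 * (r_mz - r_dz)), 0.02)
  expect_lt(abs(est$estimate[est$component == "c2"] - (2 * r_dz - r_mz)), 0.02)
  expect_true(fit$converged)
})

test_that("ML equals the method-of-moments closed form on a balanced
           two-class design", {
  set.seed(102)
  pairs <- dplyr::bind_rows(
    make_corr_pairs(12000, 0.45, "fullsib", r_g = 0.5, r_c_label = "sib"),
    make_corr_pairs(12000, 0.05, "first_cousin", r_g = 0.125,
                    r_c_label = "cousin"))
  fit <- fit_pair_ace(pairs, rc_cousin = 0, sex_effect = FALSE)
  r_s <- cor(pairs$y1[pairs$r_c_label == "sib"], pairs$y2[pairs$r_c_label == "sib"])
  r_k <- cor(pairs$y1[pairs$r_c_label == "cousin"],
             pairs$y2[pairs$r_c_label == "cousin"])
  mom <- mom_ace_two_class(r_s, r_k, rc_cousin = 0)
  est <- tidy(fit)
  for (cmp in c("a2", "c2", "e2")) {
    expect_lt(abs(est$estimate[est$component == cmp] - mom[[cmp]]), 0.015)
  }
})

test_that("uncorrelated pairs yield a2 ~ 0, c2 ~ 0, e2 ~ 1", {
  set.seed(103)
  pairs <- dplyr::bind_rows(
    make_corr_pairs(4000, 0, "fullsib", r_g = 0.5, r_c_label = "sib"),
    make_corr_pairs(4000, 0, "first_cousin", r_g = 0.125, r_c_label = "cousin"))
  fit <- fit_pair_ace(pairs, rc_cousin = 0, sex_effect = FALSE)
  est <- tidy(fit)
  expect_lt(est$estimate[est$component == "a2"], 0.05)
  expect_lt(est$estimate[est$component == "c2"], 0.05)
  expect_gt(est$estimate[est$component == "e2"], 0.9)
  expect_true(fit$boundary)
})

test_that("identifiability violations are refused", {
  set.seed(104)
  sibs_only <- make_corr_pairs(500, 0.4, "fullsib", r_g = 0.5)
  expect_error(fit_pair_ace(sibs_only, rc_cousin = 0, sex_effect = FALSE),
               "not identifiable")
  two_class <- dplyr::bind_rows(
    sibs_only, make_corr_pairs(500, 0.1, "first_cousin", r_g = 0.125,
                               r_c_label = "cousin"))
  expect_error(fit_pair_ace(two_class, rc_cousin = "free", sex_effect = FALSE),
               "not identifiable")
})

test_that("free cousin correlation is recovered and nests the fixed fits", {
  cfg <- family_config(n_families = 2500, offspring_per_sibship = 2,
                       cousin_links = TRUE, twin_rate_mz = 0.1)
  ped <- sim_pedigree(cfg, seed = 111)
  ph <- sim_phenotypes(ped, trait_model(), seed = 112)  # a2 .30 c2 .25 rho .59
  pr <- classify_pairs(ped, ids = cohort_ids(ped))
  pt <- pair_trait(pr, ph, "education")
  fam <- stats::setNames(ped$family, ped$id)
  free <- fit_pair_ace(pt, rc_cousin = "free", cluster = fam[pt$id1])
  est <- tidy(free)
  pull <- function(cmp, col = "estimate") est[[col]][est$component == cmp]
  # 3 SE: recovery property check with headroom for the mild SE
  # understatement of the pseudo-likelihood at this design size
  expect_lt(abs(pull("a2") - 0.30), 3 * pull("a2", "se"))
  expect_lt(abs(pull("c2") - 0.25), 3 * pull("c2", "se"))
  expect_lt(abs(pull("rho_c") - 0.59), 3 * pull("rho_c", "se"))
  # nesting: the free optimum dominates any fixed value
  for (rc in c(0, 0.3, 0.59, 1)) {
    fixed <- fit_pair_ace(pt, rc_cousin = rc)
    expect_gte(free$loglik, fixed$loglik - 1e-4)
  }
  # standardized components sum to one and CIs stay in [0, 1]
  expect_equal(sum(est$estimate[est$component %in% c("a2", "c2", "e2")]), 1,
               tolerance = 1e-6)
  frac <- est[est$component %in% c("a2", "c2", "e2", "rho_c"), ]
  expect_true(all(frac$lo95 >= 0 & frac$hi95 <= 1))
})

test_that("misspecifying the cousin correlation downward inflates a2, and an
           AE fit exceeds the ACE fit when C > 0", {
  cfg <- family_config(n_families = 2000, offspring_per_sibship = 2,
                       cousin_links = TRUE)
  ped <- sim_pedigree(cfg, seed = 121)
  ph <- sim_phenotypes(ped, trait_model(rho_c_cousin = 0.6), seed = 122)
  pt <- pair_trait(pr <- classify_pairs(ped, ids = cohort_ids(ped)), ph,
                   "education")
  at0 <- fit_pair_ace(pt, rc_cousin = 0)
  at6 <- fit_pair_ace(pt, rc_cousin = 0.6)
  a2_of <- function(f) f$estimates$estimate[f$estimates$component == "a2"]
  expect_gt(a2_of(at0), a2_of(at6))
  ae <- fit_pair_ace(pt, components = "AE")
  expect_gt(a2_of(ae), a2_of(at6))
})

test_that("sensitivity sweep emits one constrained fit per grid point", {
  set.seed(131)
  pairs <- dplyr::bind_rows(
    make_corr_pairs(3000, 0.42, "fullsib", r_g = 0.5, r_c_label = "sib"),
    make_corr_pairs(3000, 0.12, "first_cousin", r_g = 0.125,
                    r_c_label = "cousin"))
  sw <- sensitivity_sweep(pairs, rc_grid = seq(0, 1, by = 0.05),
                          sex_effect = FALSE)
  expect_equal(length(unique(sw$rho_c_assumed)), 21L)
  expect_equal(nrow(sw), 21L * 3L)
  a2 <- sw$estimate[sw$component == "a2"]
  expect_gt(a2[1], a2[13])  # assumed 0 vs assumed 0.6: attenuation direction
  expect_error(sensitivity_sweep(pairs, rc_grid = numeric(0)), "empty")
  expect_error(sensitivity_sweep(pairs, rc_grid = c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("IBD-AE refuses degenerate sharing and ignores phenotypes without
           genetic signal", {
  set.seed(141)
  pairs <- make_corr_pairs(3000, 0.2, "fullsib", r_g = 0.5)
  pairs$r_g_hat <- 0.5
  expect_error(fit_ibd_ae(pairs, sex_effect = FALSE), "IBD variance zero")
  # phenotype independent of genotype: a2 ~ 0 despite varying sharing
  pairs$r_g_hat <- pmin(1, pmax(0, rnorm(3000, 0.5, 0.04)))
  pairs$y1 <- rnorm(3000); pairs$y2 <- rnorm(3000)
  fit <- fit_ibd_ae(pairs, sex_effect = FALSE)
  a2 <- fit$estimates$estimate[fit$estimates$component == "a2"]
  se <- fit$estimates$se[fit$estimates$component == "a2"]
  expect_lt(a2, max(0.1, 2 * se))
})

test_that("bivariate fit is exact for duplicated traits and null for
           independent ones", {
  set.seed(151)
  base <- dplyr::bind_rows(
    make_corr_pairs(4000, 0.45, "fullsib", r_g = 0.5, r_c_label = "sib"),
    make_corr_pairs(4000, 0.10, "first_cousin", r_g = 0.125,
                    r_c_label = "cousin"))
  dup <- dplyr::mutate(base, x1 = y1, x2 = y2)
  fd <- fit_pair_biv(dup, rc_cousin = 0)
  ed <- tidy(fd)
  for (cmp in c("r_A", "r_C", "r_E", "r_P")) {
    v <- ed$estimate[ed$component == cmp]
    if (!is.na(v)) expect_gt(v, 0.98)
  }
  # independent traits: phenotypic and component correlations near zero
  ind <- dplyr::bind_rows(
    make_corr_pairs(4000, 0.45, "fullsib", r_g = 0.5, r_c_label = "sib"),
    make_corr_pairs(4000, 0.10, "first_cousin", r_g = 0.125,
                    r_c_label = "cousin"))
  ind <- dplyr::mutate(base, x1 = ind$y1, x2 = ind$y2)
  fi <- fit_pair_biv(ind, rc_cousin = 0)
  ei <- tidy(fi)
  expect_lt(abs(ei$estimate[ei$component == "r_P"]), 0.05)
  # component-level correlations split the same phenotypic near-zero signal,
  # so they carry more sampling noise than r_P
  expect_lt(abs(ei$estimate[ei$component == "r_E"]),
            3 * ei$se[ei$component == "r_E"] + 0.05)
})

test_that("bivariate fit recovers generating component correlations", {
  cfg <- family_config(n_families = 3000, offspring_per_sibship = 2,
                       cousin_links = TRUE)
  ped <- sim_pedigree(cfg, seed = 161)
  mod <- trait_model(var_a = 0.3, var_c = 0.25, var_e = 0.45,
                     R_A = 0.9, R_C = 1, R_E = 0.3, rho_c_cousin = 0.59,
                     beta_sex = 0, traits = c("x", "y"))
  ph <- sim_phenotypes(ped, mod, seed = 162)
  pr <- classify_pairs(ped, ids = cohort_ids(ped))
  px <- pair_trait(pr, ph, "x", sex = FALSE)
  py <- pair_trait(pr, ph, "y", sex = FALSE)
  pp <- dplyr::mutate(px, x1 = y1, x2 = y2, y1 = py$y1, y2 = py$y2)
  fam <- stats::setNames(ped$family, ped$id)
  fit <- fit_pair_biv(pp, rc_cousin = 0.59, cluster = fam[pp$id1])
  est <- tidy(fit)
  pull <- function(cmp, col = "estimate") est[[col]][est$component == cmp]
  expect_lt(abs(pull("r_A") - 0.9), 2 * pull("r_A", "se"))
  expect_lt(abs(pull("r_C") - 1.0), 2 * pull("r_C", "se") + 0.01)
  expect_lt(abs(pull("r_E") - 0.3), 2 * pull("r_E", "se"))
})
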