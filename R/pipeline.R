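# Measure preprocessing and configuration-driven orchestration of the
# estimators, producing a tidy report bundle.

#' Log-transform monetary registry values
#'
#' Replaces non-positive values by 1, then applies the natural logarithm
#' (so zeros and negatives map to 0). Used for income and wealth, whose
#' registry distributions have extreme right tails and occasional zero or
#' negative entries.
#'
#' @param values Numeric vector.
#' @return `log` of the cleaned values.
#' @export
log_transform_monetary <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric")
  values[values <= 0] <- 1
  log(values)
}

#' Collapse a yearly registry panel to one value per person
#'
#' Income, wealth and occupational prestige are averaged over the available
#' years of the window (monetary indicators are log-transformed first);
#' educational attainment takes the highest value recorded in the window.
#' Person-indicator cells with no observed year are dropped with a message.
#'
#' @param panel Long tibble `id`, `age`, `indicator`, `value` (e.g. from
#'   [sim_registry_panel()]).
#' @param kinds Named character vector mapping indicator to one of
#'   `"monetary"`, `"max"`, `"mean"`.
#' @return A wide tibble, one row per `id`, one column per indicator.
#' @export
collapse_window <- function(panel,
                            kinds = c(income = "monetary", wealth = "monetary",
                                      education = "max", occupation = "mean")) {
  stopifnot(all(c("id", "indicator", "value") %in% names(panel)))
  unknown <- setdiff(unique(panel$indicator), names(kinds))
  if (length(unknown) > 0) stop("no collapse rule for: ", paste(unknown, collapse = ", "))
  n_missing <- panel |>
    dplyr::group_by(.data$id, .data$indicator) |>
    dplyr::summarise(all_na = all(is.na(.data$value)), .groups = "drop") |>
    dplyr::filter(.data$all_na)
  if (nrow(n_missing) > 0) {
    message(nrow(n_missing), " person-indicator cells with no observed year dropped")
  }
  out <- panel |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$id, .data$indicator) |>
    dplyr::summarise(value = {
      k <- kinds[[.data$indicator[1]]]
      switch(k,
             monetary = mean(log_transform_monetary(.data$value)),
             max = max(.data$value),
             mean = mean(.data$value))
    }, .groups = "drop") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "value")
  out
}

#' Residualize a trait on covariates and z-score the residuals
#'
#' OLS residuals of the trait on the covariates (with intercept), scaled to
#' unit variance. Used before the variance-component fits so that estimates
#' are fractions of the covariate-adjusted variance.
#'
#' @param trait Numeric vector.
#' @param covariates Data frame / matrix of covariates, or `NULL` to simply
#'   centre and scale.
#' @return Numeric vector of z-scored residuals.
#' @export
residualize_standardize <- function(trait, covariates = NULL) {
  ok <- !is.na(trait)
  if (stats::sd(trait[ok]) == 0) stop("constant trait")
  r <- rep(NA_real_, length(trait))
  if (is.null(covariates)) {
    r[ok] <- trait[ok] - mean(trait[ok])
  } else {
    X <- build_design(covariates, length(trait))
    if (anyNA(X[ok, ])) stop("covariates incomplete for included samples")
    r[ok] <- stats::lm.fit(X[ok, , drop = FALSE], trait[ok])$residuals
  }
  s <- stats::sd(r[ok])
  if (s < 1e-10) stop("constant residual: trait is fully explained by covariates")
  r / s
}

#' Analysis configuration for the full pipeline
#'
#' @param methods Character vector of estimators to run, any of
#'   `"FP-AE"`, `"FP-ACE-fixed"`, `"FP-ACE-free"`, `"IBD"`, `"GREML"`,
#'   `"LDSC"`. At least one must be enabled.
#' @param rc_grid Sensitivity grid of assumed cousin shared-environment
#'   correlations (used when `sweep_trait` is set).
#' @param sweep_trait Trait to run the sensitivity sweep on (`NULL` to skip).
#' @param maf_min MAF cutoff for SNP-based methods.
#' @param grm_cutoff Relatedness cutoff for GREML pruning.
#' @param ld_window LD-score half-window in SNP positions.
#' @param ibd_min_snps Minimum informative SNP count for a pair-level IBD
#'   sharing estimate to be used.
#' @param n_pcs Number of GRM eigenvector PCs used as GWAS covariates.
#' @param n_boot,n_perm Replicates for PCA bootstrap / permutation test.
#' @param seed Master seed for the run.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(methods = c("FP-ACE-fixed", "FP-ACE-free", "IBD",
                                        "GREML", "LDSC"),
                            rc_grid = seq(0, 1, by = 0.05),
                            sweep_trait = "education",
                            maf_min = 0.01, grm_cutoff = 0.025,
                            ld_window = 200, ibd_min_snps = 1000, n_pcs = 10,
                            n_boot = 1000, n_perm = 1000, seed = 1) {
  all_m <- c("FP-AE", "FP-ACE-fixed", "FP-ACE-free", "IBD", "GREML", "LDSC")
  if (is.null(methods) || length(methods) == 0) {
    stop("at least one method must be enabled")
  }
  methods <- match.arg(methods, all_m, several.ok = TRUE)
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  if (grm_cutoff <= 0) stop("grm_cutoff must be positive")
  structure(list(methods = methods, rc_grid = rc_grid,
                 sweep_trait = sweep_trait, maf_min = maf_min,
                 grm_cutoff = grm_cutoff, ld_window = ld_window,
                 ibd_min_snps = ibd_min_snps, n_pcs = n_pcs,
                 n_boot = n_boot, n_perm = n_perm, seed = seed),
            class = "analysis_config")
}

#' Run the full comparison pipeline on simulated or supplied data
#'
#' Orchestrates preprocessing, pair building and every enabled estimator on a
#' pedigree + phenotype (+ genotype) data set, then assembles the report
#' tables: heritability by method and indicator, shared-environment
#' estimates, the cousin-correlation sensitivity sweep, phenotypic and
#' component correlation matrices, and their PCA with parallel analysis and
#' bootstrap CIs. All randomness derives from `config$seed`, so a rerun with
#' the same inputs is reproducible.
#'
#' @param ped Pedigree tibble.
#' @param pheno Phenotype tibble (`id`, `sex`, trait columns); traits are
#'   residualized on sex and z-scored internally.
#' @param genos Genotypes (required for IBD, GREML, LDSC).
#' @param config An [analysis_config()].
#' @param traits Trait columns to analyse.
#' @return Object of class `ses_report`: list of tidy tables plus `meta`
#'   (seeds, methods, deviations from the reference software stack).
#' @export
run_full_analysis <- function(ped, pheno, genos = NULL, config = analysis_config(),
                              traits = c("education", "occupation", "income", "wealth")) {
  stopifnot(inherits(config, "analysis_config"))
  needs_geno <- intersect(config$methods, c("IBD", "GREML", "LDSC"))
  if (length(needs_geno) > 0 && is.null(genos)) {
    stop("methods ", paste(needs_geno, collapse = ", "), " require genotypes")
  }
  traits <- intersect(traits, names(pheno))
  if (length(traits) < 1) stop("no trait columns found")
  # preprocessing: residualize on sex, z-score
  std <- pheno
  for (tr in traits) {
    std[[tr]] <- residualize_standardize(pheno[[tr]], data.frame(sex = pheno$sex))
  }
  pairs <- classify_pairs(ped, ids = intersect(cohort_ids(ped), std$id))
  fam_of <- if ("family" %in% names(ped)) {
    stats::setNames(ped$family, ped$id)
  } else stats::setNames(ped$id, ped$id)
  herit <- list(); shared <- list(); fits <- list()
  run_fp <- function(trait, components, rc_cousin, label) {
    pt <- pair_trait(pairs, std, trait, sex = FALSE)
    fit <- fit_pair_ace(pt, components = components, rc_cousin = rc_cousin,
                        cluster = fam_of[pt$id1])
    est <- fit$estimates
    herit[[paste(label, trait)]] <<- tibble::tibble(
      method = label, indicator = trait,
      estimate = est$estimate[est$component == "a2"],
      se = est$se[est$component == "a2"],
      lo95 = est$lo95[est$component == "a2"],
      hi95 = est$hi95[est$component == "a2"])
    if ("c2" %in% est$component) {
      shared[[paste(label, trait)]] <<- tibble::tibble(
        method = label, indicator = trait,
        estimate = est$estimate[est$component == "c2"],
        se = est$se[est$component == "c2"],
        lo95 = est$lo95[est$component == "c2"],
        hi95 = est$hi95[est$component == "c2"],
        rho_c = if ("rho_c" %in% est$component)
          est$estimate[est$component == "rho_c"] else rc_cousin)
    }
    fits[[paste(label, trait)]] <<- fit
  }
  sib_pairs <- NULL
  if ("IBD" %in% config$methods) {
    sib <- dplyr::filter(pairs, .data$relationship %in% c("fullsib", "DZ"))
    sib_pairs <- estimate_ibd_sharing(genos, sib,
                                      min_snps = config$ibd_min_snps)
  }
  W <- NULL; grm <- NULL; kept <- NULL; pcs <- NULL; ld <- NULL
  if (any(c("GREML", "LDSC") %in% config$methods)) {
    W <- standardize_genotypes(genos, maf_min = config$maf_min)
    grm <- compute_grm(W)
    kept <- prune_relatives(grm, cutoff = config$grm_cutoff)
    kept <- intersect(kept, std$id)
    if ("LDSC" %in% config$methods) {
      pcs <- eigen(grm$matrix, symmetric = TRUE)$vectors[, seq_len(config$n_pcs)]
      ld <- ld_scores(dosage_matrix(genos)[, colnames(W), drop = FALSE],
                      window = config$ld_window)
    }
  }
  for (tr in traits) {
    if ("FP-AE" %in% config$methods) run_fp(tr, "AE", 0, "FP-AE")
    if ("FP-ACE-fixed" %in% config$methods) run_fp(tr, "ACE", 0, "FP-ACE-fixed")
    if ("FP-ACE-free" %in% config$methods) run_fp(tr, "ACE", "free", "FP-ACE-free")
    if ("IBD" %in% config$methods) {
      pt <- pair_trait(sib_pairs, std, tr, sex = FALSE)
      fit <- fit_ibd_ae(pt, sex_effect = FALSE, cluster = fam_of[pt$id1])
      est <- fit$estimates
      herit[[paste("IBD", tr)]] <- tibble::tibble(
        method = "IBD", indicator = tr,
        estimate = est$estimate[est$component == "a2"],
        se = est$se[est$component == "a2"],
        lo95 = est$lo95[est$component == "a2"],
        hi95 = est$hi95[est$component == "a2"])
      fits[[paste("IBD", tr)]] <- fit
    }
    if ("GREML" %in% config$methods) {
      ix <- match(kept, std$id)
      fit <- fit_greml(std[[tr]][ix], NULL,
                       structure(list(matrix = grm$matrix[kept, kept],
                                      n_snps = grm$n_snps), class = "ses_grm"))
      herit[[paste("GREML", tr)]] <- tibble::tibble(
        method = "GREML", indicator = tr, estimate = fit$h2, se = fit$se_h2,
        lo95 = max(0, fit$h2 - 1.96 * fit$se_h2),
        hi95 = min(1, fit$h2 + 1.96 * fit$se_h2))
      fits[[paste("GREML", tr)]] <- fit
    }
    if ("LDSC" %in% config$methods) {
      ids_g <- intersect(rownames(W), std$id)
      Gd <- dosage_matrix(genos)[ids_g, colnames(W), drop = FALSE]
      yv <- std[[tr]][match(ids_g, std$id)]
      ss <- run_gwas(yv, Gd, X = pcs[match(ids_g, rownames(W)), , drop = FALSE])
      fit <- ldsc_h2(ss, ld)
      herit[[paste("LDSC", tr)]] <- tibble::tibble(
        method = "LDSC", indicator = tr, estimate = fit$h2, se = fit$se_h2,
        lo95 = fit$h2_ci[1], hi95 = fit$h2_ci[2])
      fits[[paste("LDSC", tr)]] <- fit
    }
  }
  # sensitivity sweep
  sweep_tbl <- NULL
  if (!is.null(config$sweep_trait) && config$sweep_trait %in% traits &&
      any(grepl("^FP-ACE", config$methods))) {
    pt <- pair_trait(pairs, std, config$sweep_trait, sex = FALSE)
    sweep_tbl <- sensitivity_sweep(pt, rc_grid = config$rc_grid,
                                   sex_effect = FALSE,
                                   cluster = fam_of[pt$id1])
  }
  # component correlation matrices from bivariate family fits + phenotypic
  corr_mats <- list()
  pca_res <- list()
  if (length(traits) >= 3) {
    combos <- utils::combn(traits, 2)
    rows_phen <- purrr::map(seq_len(ncol(combos)), function(i) {
      tibble::tibble(trait1 = combos[1, i], trait2 = combos[2, i],
                     estimate = stats::cor(std[[combos[1, i]]], std[[combos[2, i]]],
                                           use = "complete.obs"))
    })
    corr_mats$phenotypic <- assemble_corr_matrix(dplyr::bind_rows(rows_phen),
                                                 traits = traits,
                                                 source = "phenotypic",
                                                 n_effective = nrow(std))
    if (any(grepl("^FP-ACE", config$methods))) {
      rows <- purrr::map(seq_len(ncol(combos)), function(i) {
        t1 <- combos[1, i]; t2 <- combos[2, i]
        pt <- pair_trait(pairs, std, t1, sex = FALSE)
        pt <- dplyr::rename(pt, x1 = "y1", x2 = "y2")
        p2 <- pair_trait(pairs, std, t2, sex = FALSE)
        pt$y1 <- p2$y1; pt$y2 <- p2$y2
        bf <- fit_pair_biv(pt, components = "ACE", rc_cousin = 0.59,
                           cluster = fam_of[pt$id1])
        e <- bf$estimates
        tibble::tibble(trait1 = t1, trait2 = t2,
                       r_A = e$estimate[e$component == "r_A"],
                       se_A = e$se[e$component == "r_A"],
                       r_C = e$estimate[e$component == "r_C"],
                       se_C = e$se[e$component == "r_C"],
                       r_E = e$estimate[e$component == "r_E"],
                       se_E = e$se[e$component == "r_E"])
      })
      biv <- dplyr::bind_rows(rows)
      n_eff <- nrow(pairs)
      for (src in c("A", "C", "E")) {
        est_col <- paste0("r_", src); se_col <- paste0("se_", src)
        if (anyNA(biv[[est_col]])) next
        corr_mats[[paste0("FP_", src)]] <- assemble_corr_matrix(
          dplyr::transmute(biv, trait1 = .data$trait1, trait2 = .data$trait2,
                           estimate = .data[[est_col]], se = .data[[se_col]]),
          traits = traits, source = src, n_effective = n_eff)
      }
    }
    for (nmm in names(corr_mats)) {
      m <- corr_mats[[nmm]]
      pa <- parallel_analysis(corr = m, n = attr(m, "n_effective", exact = TRUE),
                              n_sims = max(100, config$n_perm),
                              seed = config$seed + 11)
      bs <- bootstrap_pca(m, n_boot = config$n_boot, seed = config$seed + 13)
      pca_res[[nmm]] <- list(pca = pca_corr(m), parallel = pa, bootstrap = bs)
    }
  }
  meta <- list(
    seed = config$seed, methods = config$methods,
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    deviations = c(
      "GWAS uses OLS with PC covariates in place of a sparse-GRM mixed model",
      "pair likelihoods treat pairs as independent (pseudo-likelihood)"))
  structure(list(heritability = dplyr::bind_rows(herit),
                 shared_environment = dplyr::bind_rows(shared),
                 sensitivity = sweep_tbl,
                 corr_matrices = corr_mats,
                 pca = pca_res,
                 fits = fits,
                 meta = meta),
            class = "ses_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a report bundle to disk
#'
#' Writes the heritability, shared-environment and sensitivity tables as TSV,
#' each correlation matrix as TSV, and a JSON manifest with run metadata.
#'
#' @param report A `ses_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ses_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$heritability, file.path(dir, "heritability.tsv"))
  if (!is.null(report$shared_environment) && nrow(report$shared_environment) > 0) {
    readr::write_tsv(report$shared_environment, file.path(dir, "shared_environment.tsv"))
  }
  if (!is.null(report$sensitivity)) {
    readr::write_tsv(report$sensitivity, file.path(dir, "sensitivity.tsv"))
  }
  for (nm in names(report$corr_matrices)) {
    m <- report$corr_matrices[[nm]]
    df <- tibble::as_tibble(corr_matrix_of(m), rownames = "indicator")
    readr::write_tsv(df, file.path(dir, paste0("corr_", nm, ".tsv")))
  }
  jsonlite::write_json(report$meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.ses_report <- function(x, ...) {
  cat("SES heritability report (", paste(x$meta$methods, collapse = ", "), ")\n", sep = "")
  cat("Heritability by method and indicator:\n")
  print(x$heritability)
  invisible(x)
}
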