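# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Family structure configuration for the pedigree simulator
#'
#' @param n_families Number of extended families (>= 1).
#' @param offspring_per_sibship Children per sibship: a single count, or a
#'   vector sampled from uniformly per sibship.
#' @param twin_rate_mz,twin_rate_dz Probability that a sibship's first two
#'   children form an MZ (resp. DZ) twin pair; requires >= 2 offspring.
#' @param cousin_links If `TRUE` each family holds two sibships whose parents
#'   are full siblings (children of a shared founder grandparent couple), so
#'   the two sibships' offspring are first cousins. If `FALSE`, families are
#'   independent nuclear families.
#' @param n_subpops Number of subpopulations for the optional stratification
#'   scenario; families are assigned to subpopulations in equal proportions.
#' @return A validated list of class `family_config`.
#' @export
family_config <- function(n_families,
                          offspring_per_sibship = 2,
                          twin_rate_mz = 0,
                          twin_rate_dz = 0,
                          cousin_links = TRUE,
                          n_subpops = 1) {
  if (length(n_families) != 1 || is.na(n_families) || n_families < 1) {
    stop("n_families must be a single count >= 1")
  }
  if (any(offspring_per_sibship < 0)) stop("offspring_per_sibship must be >= 0")
  rates <- c(twin_rate_mz, twin_rate_dz)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("twin rates must lie in [0, 1] and sum to at most 1")
  }
  structure(list(n_families = as.integer(n_families),
                 offspring_per_sibship = as.integer(offspring_per_sibship),
                 twin_rate_mz = twin_rate_mz, twin_rate_dz = twin_rate_dz,
                 cousin_links = isTRUE(cousin_links),
                 n_subpops = as.integer(n_subpops)),
            class = "family_config")
}

#' Simulate a multi-generation pedigree
#'
#' With `cousin_links = TRUE`, each extended family consists of a founder
#' grandparent couple, their two adult children (a brother and a sister) each
#' mated to an unrelated founder, and the two resulting sibships, whose
#' members are first cousins of each other. Twin pairs (MZ/DZ) are inserted
#' at the configured per-sibship rates. The offspring generation carries
#' `cohort = TRUE` — it plays the role of the phenotyped registry cohort; the
#' parental and grandparental generations exist to define relationships and
#' to transmit genotypes.
#'
#' @param config A [family_config()].
#' @param seed Integer seed; the same seed reproduces the pedigree exactly.
#' @param id_prefix Prefix for individual ids, so pedigrees simulated in
#'   batches can be combined with `dplyr::bind_rows()`.
#' @return A pedigree tibble with columns `id`, `father`, `mother`, `sex`,
#'   `zygosity`, `family`, `generation`, `subpop`, `cohort`.
#' @export
sim_pedigree <- function(config, seed = NULL, id_prefix = "F") {
  stopifnot(inherits(config, "family_config"))
  with_seed(seed, {
    fams <- purrr::map(seq_len(config$n_families), function(f) {
      pre <- paste0(id_prefix, f, "_")
      n_sib <- if (config$cousin_links) 2L else 1L
      rows <- list()
      if (config$cousin_links) {
        gf <- paste0(pre, "gf"); gm <- paste0(pre, "gm")
        rows[[1]] <- tibble::tibble(
          id = c(gf, gm), father = NA_character_, mother = NA_character_,
          sex = c(1L, 2L), zygosity = NA_character_, generation = 0L)
        par_link <- c(paste0(pre, "p1"), paste0(pre, "p2"))
        rows[[2]] <- tibble::tibble(
          id = par_link, father = gf, mother = gm, sex = c(1L, 2L),
          zygosity = NA_character_, generation = 1L)
        spouses <- c(paste0(pre, "s1"), paste0(pre, "s2"))
        rows[[3]] <- tibble::tibble(
          id = spouses, father = NA_character_, mother = NA_character_,
          sex = c(2L, 1L), zygosity = NA_character_, generation = 1L)
        fathers <- c(par_link[1], spouses[2])
        mothers <- c(spouses[1], par_link[2])
      } else {
        fathers <- paste0(pre, "p1"); mothers <- paste0(pre, "p2")
        rows[[1]] <- tibble::tibble(
          id = c(fathers, mothers), father = NA_character_,
          mother = NA_character_, sex = c(1L, 2L),
          zygosity = NA_character_, generation = 1L)
      }
      kids <- purrr::map(seq_len(n_sib), function(s) {
        k <- if (length(config$offspring_per_sibship) == 1) {
          config$offspring_per_sibship
        } else {
          sample(config$offspring_per_sibship, 1)
        }
        if (k == 0) return(NULL)
        zyg <- rep(NA_character_, k)
        if (k >= 2) {
          u <- stats::runif(1)
          if (u < config$twin_rate_mz) zyg[1:2] <- "MZ"
          else if (u < config$twin_rate_mz + config$twin_rate_dz) zyg[1:2] <- "DZ"
        }
        sx <- sample(1:2, k, replace = TRUE)
        if (!is.na(zyg[1])) sx[2] <- sx[1]  # twins same sex
        tibble::tibble(id = paste0(pre, "c", s, "_", seq_len(k)),
                       father = fathers[s], mother = mothers[s],
                       sex = sx, zygosity = zyg, generation = 2L)
      })
      fam <- dplyr::bind_rows(c(rows, kids))
      fam$family <- paste0(id_prefix, f)
      fam
    })
    ped <- dplyr::bind_rows(fams)
    ped$subpop <- ((match(ped$family, unique(ped$family)) - 1L) %%
                     config$n_subpops) + 1L
    ped$cohort <- ped$generation == 2L
    as_pedigree(ped)
  })
}

#' Study-cohort ids of a simulated pedigree
#' @param ped A pedigree from [sim_pedigree()].
#' @return Character vector of ids in the phenotyped (offspring) generation.
#' @export
cohort_ids <- function(ped) {
  if (!"cohort" %in% names(ped)) return(ped$id)
  ped$id[ped$cohort]
}

# Extract the dosage matrix from a genotype object or plain matrix.
dosage_matrix <- function(genos) {
  if (is.matrix(genos)) return(genos)
  if (is.list(genos) && !is.null(genos$dosage)) return(genos$dosage)
  stop("cannot interpret `genos` as a dosage matrix")
}

#' Simulate genotypes by gene dropping through a pedigree
#'
#' Founder haplotypes are drawn from population allele frequencies
#' (uniform on `maf_range`), optionally with linkage disequilibrium within
#' recombination blocks via a Gaussian AR(1) copula. Non-founders inherit one
#' allele from each parent with block-wise recombination: within each block of
#' `block_len` consecutive SNPs a single grandparental origin is transmitted,
#' so realised genome sharing between siblings varies around 0.5 with
#' standard deviation approximately `sqrt(block_len / (8 * m_snps))`.
#' MZ twins receive identical genotypes.
#'
#' @param ped A pedigree tibble.
#' @param m_snps Number of SNPs (>= 1).
#' @param maf_range Range of population minor-allele frequencies.
#' @param block_len SNPs per recombination block (<= m_snps).
#' @param ld_rho Within-block AR(1) correlation of the latent Gaussian used to
#'   draw founder haplotypes: 0 for independent SNPs, or a length-2 range from
#'   which each block's value is drawn (gives LD-score variation across SNPs).
#' @param strat_shift Maximum absolute allele-frequency shift between
#'   subpopulations (uniform per SNP); 0 disables stratification.
#' @param ids Ids to return genotypes for (default: all pedigree members).
#' @param seed Integer seed.
#' @return An object of class `ses_genotypes`: list with `dosage` (integer
#'   matrix individuals x SNPs), `snp_id`, `freq` (base population frequency),
#'   `block` (block index per SNP).
#' @export
sim_genotypes <- function(ped, m_snps, maf_range = c(0.05, 0.5),
                          block_len = 100, ld_rho = 0, strat_shift = 0,
                          ids = NULL, seed = NULL) {
  ped <- as_pedigree(ped)
  if (m_snps < 1) stop("m_snps must be >= 1")
  if (block_len > m_snps) stop("block_len must not exceed m_snps")
  if (is.null(ids)) ids <- ped$id
  with_seed(seed, {
    m <- as.integer(m_snps)
    p <- stats::runif(m, maf_range[1], maf_range[2])
    block <- rep(seq_len(ceiling(m / block_len)), each = block_len)[seq_len(m)]
    n_block <- max(block)
    rho_blk <- if (length(ld_rho) == 2) stats::runif(n_block, ld_rho[1], ld_rho[2])
               else rep(ld_rho, n_block)
    subpop <- if ("subpop" %in% names(ped)) ped$subpop else rep(1L, nrow(ped))
    n_sub <- max(subpop)
    # per-subpopulation allele frequencies
    pmat <- matrix(rep(p, n_sub), ncol = n_sub)
    if (strat_shift > 0 && n_sub > 1) {
      delta <- stats::runif(m, 0, strat_shift)
      sgn <- matrix(sample(c(-1, 1), m * n_sub, replace = TRUE), ncol = n_sub)
      pmat <- pmin(pmax(pmat + delta * sgn, 0.01), 0.99)
    }
    depth <- ped_depth(ped)
    fa <- match(ped$father, ped$id)
    mo <- match(ped$mother, ped$id)
    founder <- is.na(fa)
    n <- nrow(ped)
    # MZ co-twin: point each later MZ twin at its earlier co-twin
    mz_src <- rep(NA_integer_, n)
    if (any(!is.na(ped$zygosity) & ped$zygosity == "MZ")) {
      key <- paste(ped$father, ped$mother)
      for (k in unique(key[!is.na(ped$zygosity) & ped$zygosity == "MZ"])) {
        tw <- which(key == k & !is.na(ped$zygosity) & ped$zygosity == "MZ")
        if (length(tw) >= 2) mz_src[tw[-1]] <- tw[1]
      }
    }
    keep_idx <- match(as.character(ids), ped$id)
    if (anyNA(keep_idx)) stop("ids not in pedigree")
    dosage <- matrix(0L, length(keep_idx), m,
                     dimnames = list(ped$id[keep_idx], paste0("snp", seq_len(m))))
    # chunk over whole blocks to bound memory
    blocks_per_chunk <- max(1L, ceiling(2000 / block_len))
    chunk_starts <- seq(1, n_block, by = blocks_per_chunk)
    seeds <- sample.int(.Machine$integer.max, length(chunk_starts))
    for (ci in seq_along(chunk_starts)) {
      b0 <- chunk_starts[ci]
      b1 <- min(n_block, b0 + blocks_per_chunk - 1L)
      cols <- which(block >= b0 & block <= b1)
      set.seed(seeds[ci])
      Lc <- length(cols)
      blk_c <- block[cols] - b0 + 1L           # local block index
      nb_c <- max(blk_c)
      H1 <- matrix(0L, n, Lc)
      H2 <- matrix(0L, n, Lc)
      # founder haplotypes
      fo <- which(founder)
      for (h in 1:2) {
        G <- matrix(stats::rnorm(length(fo) * Lc), length(fo), Lc)
        for (b in seq_len(nb_c)) {
          jj <- which(blk_c == b)
          r <- rho_blk[b0 + b - 1L]
          if (r > 0 && length(jj) > 1) {
            for (t in 2L:length(jj)) {
              G[, jj[t]] <- r * G[, jj[t - 1L]] + sqrt(1 - r^2) * G[, jj[t]]
            }
          }
        }
        thr <- stats::qnorm(t(pmat)[, cols, drop = FALSE])  # n_sub x Lc
        A <- (G < thr[subpop[fo], , drop = FALSE]) * 1L
        if (h == 1) H1[fo, ] <- A else H2[fo, ] <- A
      }
      # drop through generations, one generation at a time (vectorized)
      for (g in sort(unique(depth[!founder]))) {
        gi <- which(depth == g & !founder & is.na(mz_src))
        if (length(gi) > 0) {
          Of <- matrix(stats::rbinom(length(gi) * nb_c, 1, 0.5),
                       length(gi), nb_c)[, blk_c, drop = FALSE]
          Om <- matrix(stats::rbinom(length(gi) * nb_c, 1, 0.5),
                       length(gi), nb_c)[, blk_c, drop = FALSE]
          Hf <- H1[fa[gi], , drop = FALSE]
          alt <- H2[fa[gi], , drop = FALSE]
          Hf[Of == 1L] <- alt[Of == 1L]
          Hm <- H1[mo[gi], , drop = FALSE]
          alt <- H2[mo[gi], , drop = FALSE]
          Hm[Om == 1L] <- alt[Om == 1L]
          H1[gi, ] <- Hf
          H2[gi, ] <- Hm
        }
        tw <- which(depth == g & !is.na(mz_src))
        if (length(tw) > 0) {
          H1[tw, ] <- H1[mz_src[tw], , drop = FALSE]
          H2[tw, ] <- H2[mz_src[tw], , drop = FALSE]
        }
      }
      dosage[, cols] <- H1[keep_idx, , drop = FALSE] + H2[keep_idx, , drop = FALSE]
    }
    structure(list(dosage = dosage, snp_id = colnames(dosage),
                   freq = p, block = block),
              class = "ses_genotypes")
  })
}

#' Trait model for the phenotype simulator
#'
#' Defines the generating A/C/E structure for a set of correlated traits: the
#' per-trait standardized variance fractions, cross-trait correlation matrices
#' for each variance source, the cousin shared-environment correlation, and a
#' sex effect on the mean.
#'
#' @param var_a,var_c,var_e Per-trait variance fractions (recycled to the
#'   number of traits); each trait must satisfy var_a + var_c + var_e = 1.
#' @param R_A,R_C,R_E Cross-trait correlation matrices (symmetric, unit
#'   diagonal, positive semi-definite). Scalars are expanded to an
#'   exchangeable matrix with that off-diagonal value.
#' @param rho_c_cousin Shared-environment correlation between first cousins,
#'   in `[0, 1]`; siblings (incl. DZ and MZ twins) share at 1.
#' @param beta_sex Additive mean shift for males, per trait (recycled).
#' @param snp_mode If `TRUE` the additive genetic part is built from supplied
#'   genotypes (`m_causal` causal SNPs with normal effects), instead of the
#'   pedigree-expected relatedness; required for SNP-based estimators to have
#'   a recoverable signal.
#' @param m_causal Number of causal SNPs in `snp_mode` (default: all).
#' @param strat_effect Phenotypic mean offset per unit of (centred)
#'   subpopulation label; creates confounding for the stratification scenario.
#' @param traits Trait names; defaults to the four socioeconomic indicators.
#' @return A validated list of class `trait_model`.
#' @export
trait_model <- function(var_a = 0.30, var_c = 0.25, var_e = 0.45,
                        R_A = 0.6, R_C = 1, R_E = 0.1,
                        rho_c_cousin = 0.59, beta_sex = 0.1,
                        snp_mode = FALSE, m_causal = NULL, strat_effect = 0,
                        traits = c("education", "occupation", "income", "wealth")) {
  t_n <- length(traits)
  expand_R <- function(R) {
    if (length(R) == 1) {
      R <- matrix(R, t_n, t_n); diag(R) <- 1
    }
    R <- as.matrix(R)
    if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-10)) {
      stop("component correlation matrices must be symmetric with unit diagonal")
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("component correlation matrix is not positive semi-definite")
    }
    R
  }
  va <- rep_len(var_a, t_n); vc <- rep_len(var_c, t_n); ve <- rep_len(var_e, t_n)
  if (any(abs(va + vc + ve - 1) > 1e-8)) {
    stop("var_a + var_c + var_e must equal 1 for every trait")
  }
  if (any(c(va, vc, ve) < 0)) stop("variance fractions must be non-negative")
  if (rho_c_cousin < 0 || rho_c_cousin > 1) stop("rho_c_cousin must lie in [0, 1]")
  structure(list(var_a = va, var_c = vc, var_e = ve,
                 R_A = expand_R(R_A), R_C = expand_R(R_C), R_E = expand_R(R_E),
                 rho_c_cousin = rho_c_cousin,
                 beta_sex = rep_len(beta_sex, t_n),
                 snp_mode = isTRUE(snp_mode), m_causal = m_causal,
                 strat_effect = strat_effect, traits = traits),
            class = "trait_model")
}

# symmetric matrix square root with eigenvalue clipping at 0
mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Shared-environment correlation matrix among family members: 1 for members
# of the same sibship (incl. twins), rho_c between first cousins, 0 otherwise.
shared_env_matrix <- function(K, fa, mo, sibkey, rho_c) {
  k <- length(sibkey)
  Q <- diag(k)
  if (k > 1) {
    same_sib <- outer(sibkey, sibkey, "==")
    cousins <- abs(2 * K - 0.125) < 1e-12 & !same_sib
    Q[same_sib] <- 1
    Q[cousins] <- rho_c
    diag(Q) <- 1
  }
  Q
}

#' Simulate multi-trait phenotypes with known A/C/E structure
#'
#' For each extended family, cohort members' trait vectors are drawn jointly
#' from a zero-mean multivariate normal whose covariance is the Kronecker sum
#' `K (x) S_A + Q (x) S_C + I (x) S_E`, where `K` is the expected-relatedness
#' matrix (MZ pairs set to 1), `Q` the shared-environment matrix (1 within
#' sibships, `rho_c_cousin` between cousins), and `S_X = D_x^(1/2) R_X
#' D_x^(1/2)` scales the cross-trait correlation matrices by per-trait
#' variance fractions. Pairwise this reproduces
#' `Cov(P1, P2) = a^2 r_g + c^2 r_c` per trait. In `snp_mode` the additive
#' part is instead `W beta` from standardized genotypes with effect sizes
#' drawn to total `var_a` and correlated across traits by `R_A`.
#'
#' @param ped A pedigree tibble.
#' @param model A [trait_model()].
#' @param genos Genotypes from [sim_genotypes()] (required in `snp_mode`).
#' @param ids Ids to phenotype (default: the study cohort).
#' @param seed Integer seed.
#' @return A tibble with `id`, `family`, `sex`, `subpop`, and one column per
#'   trait on the standardized (latent) scale.
#' @export
sim_phenotypes <- function(ped, model, genos = NULL, ids = NULL, seed = NULL) {
  stopifnot(inherits(model, "trait_model"))
  ped <- as_pedigree(ped)
  if (is.null(ids)) ids <- cohort_ids(ped)
  ids <- as.character(ids)
  if (model$snp_mode && is.null(genos)) stop("snp_mode requires genotypes")
  t_n <- length(model$traits)
  Da <- sqrt(model$var_a); Dc <- sqrt(model$var_c); De <- sqrt(model$var_e)
  S_A <- outer(Da, Da) * model$R_A
  S_C <- outer(Dc, Dc) * model$R_C
  S_E <- outer(De, De) * model$R_E
  with_seed(seed, {
    comp <- ped_components(ped)
    keep <- ped$id %in% ids
    fam_rows <- split(which(keep), comp[keep])
    chol_cache <- new.env(parent = emptyenv())
    Y <- matrix(NA_real_, length(ids), t_n,
                dimnames = list(ids, model$traits))
    # genetic values from SNPs, if requested
    if (model$snp_mode) {
      X <- dosage_matrix(genos)
      X <- X[ids, , drop = FALSE]
      m <- ncol(X)
      mc <- if (is.null(model$m_causal)) m else min(model$m_causal, m)
      causal <- sort(sample.int(m, mc))
      p_all <- if (is.list(genos) && !is.null(genos$freq)) genos$freq
               else colMeans(X) / 2
      # per-trait effects correlated by R_A, scaled to total var_a per trait
      B <- matrix(stats::rnorm(mc * t_n), mc, t_n) %*% mat_sqrt(model$R_A)
      B <- sweep(B, 2, sqrt(model$var_a / mc), "*")
      # accumulate W %*% B chunk-wise to avoid materializing the full
      # standardized matrix
      G_snp <- matrix(0, length(ids), t_n)
      chunk <- max(1L, floor(5e7 / max(1L, length(ids))))
      for (s in seq(1, mc, by = chunk)) {
        e <- min(mc, s + chunk - 1L)
        jj <- causal[s:e]
        pj <- p_all[jj]
        Wc <- sweep(sweep(X[, jj, drop = FALSE], 2, 2 * pj, "-"),
                    2, sqrt(2 * pj * (1 - pj)), "/")
        G_snp <- G_snp + Wc %*% B[s:e, , drop = FALSE]
      }
      rownames(G_snp) <- ids
    }
    comp_rows <- split(seq_len(nrow(ped)), comp)
    all_id <- ped$id
    for (ix in fam_rows) {
      cix <- comp_rows[[as.character(comp[ix[1]])]]
      members <- all_id[ix]
      Kfull <- kinship_core(all_id[cix], match(ped$father[cix], all_id[cix]),
                            match(ped$mother[cix], all_id[cix]))
      K <- Kfull[members, members, drop = FALSE] * 2
      zyg <- ped$zygosity[ix]
      sibkey <- paste(ped$father[ix], ped$mother[ix])
      sibkey[is.na(ped$father[ix])] <- paste0("founder_", members[is.na(ped$father[ix])])
      if (any(!is.na(zyg) & zyg == "MZ")) {
        mz <- !is.na(zyg) & zyg == "MZ"
        same_par <- outer(sibkey, sibkey, "==")
        K[outer(mz, mz, "&") & same_par] <- 1
        diag(K) <- 1
      }
      Q <- shared_env_matrix(K / 2, NULL, NULL, sibkey, model$rho_c_cousin)
      k <- length(members)
      key <- paste(c(round(K, 6), round(Q, 6)), collapse = ",")
      U <- chol_cache[[key]]
      if (is.null(U)) {
        Sigma <- if (model$snp_mode) {
          kronecker(Q, S_C) + kronecker(diag(k), S_E)
        } else {
          kronecker(K, S_A) + kronecker(Q, S_C) + kronecker(diag(k), S_E)
        }
        U <- mat_sqrt(Sigma)
        chol_cache[[key]] <- U
      }
      z <- U %*% stats::rnorm(k * t_n)
      Y[members, ] <- matrix(z, k, t_n, byrow = TRUE)
    }
    if (model$snp_mode) Y <- Y + G_snp[rownames(Y), , drop = FALSE]
    info <- ped[match(ids, ped$id), ]
    mu <- outer(as.numeric(info$sex == 1L), model$beta_sex)
    if (model$strat_effect != 0 && "subpop" %in% names(info)) {
      sp <- info$subpop - mean(info$subpop)
      mu <- mu + model$strat_effect * sp
    }
    out <- tibble::tibble(id = ids,
                          family = if ("family" %in% names(info)) info$family else NA_character_,
                          sex = info$sex,
                          subpop = if ("subpop" %in% names(info)) info$subpop else 1L)
    dplyr::bind_cols(out, tibble::as_tibble(Y + mu))
  })
}

#' Simulate a yearly registry panel from latent traits
#'
#' Emulates the structure of administrative yearly measures over an age
#' window: monetary indicators (income, wealth) are emitted on a positive
#' kroner-like scale as `exp(mu_log + sd_log * z + noise)`, with a fraction
#' `zero_rate` of person-years replaced by zero or (half of them) small
#' negative amounts; educational attainment is a nondecreasing yearly series
#' of years-of-schooling whose maximum equals the final value; occupational
#' prestige is a bounded yearly score around the SIOPS scale midrange.
#'
#' @param pheno Phenotype tibble from [sim_phenotypes()] with trait columns
#'   `education`, `occupation`, `income`, `wealth` on the latent scale.
#' @param window_years Number of yearly observations (>= 1); ages run from
#'   `age_start` upward.
#' @param age_start First age of the window.
#' @param noise_sd Year-to-year log-scale (monetary) / point-scale
#'   (occupation) noise standard deviation.
#' @param zero_rate Probability a monetary person-year is nonpositive.
#' @param seed Integer seed.
#' @return A long tibble with columns `id`, `age`, `indicator`, `value`.
#' @export
sim_registry_panel <- function(pheno, window_years = 11, age_start = 35,
                               noise_sd = 0.1, zero_rate = 0.01, seed = NULL) {
  if (window_years < 1) stop("window_years must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  ages <- age_start + seq_len(window_years) - 1L
  n <- nrow(pheno)
  with_seed(seed, {
    panel <- list()
    for (tr in c("income", "wealth")) {
      if (!tr %in% names(pheno)) next
      mu_log <- if (tr == "income") 12.8 else 14.0   # ~ kroner scales
      sd_log <- 0.5
      z <- rep(pheno[[tr]], each = window_years)
      v <- exp(mu_log + sd_log * z +
                 stats::rnorm(n * window_years, 0, noise_sd))
      nonpos <- stats::runif(n * window_years) < zero_rate
      neg <- nonpos & (stats::runif(n * window_years) < 0.5)
      v[nonpos] <- 0
      v[neg] <- -stats::runif(sum(neg), 0, 1e4)
      panel[[tr]] <- tibble::tibble(id = rep(pheno$id, each = window_years),
                                    age = rep(ages, n), indicator = tr, value = v)
    }
    if ("education" %in% names(pheno)) {
      final <- pmin(21, pmax(9, round(14 + 2.2 * pheno$education)))
      start <- if (noise_sd > 0) {
        pmax(9, final - sample(0:2, n, replace = TRUE))
      } else final
      jump <- sample(seq_len(window_years), n, replace = TRUE)
      v <- ifelse(rep(seq_len(window_years), n) < rep(jump, each = window_years),
                  rep(start, each = window_years), rep(final, each = window_years))
      panel[["education"]] <- tibble::tibble(id = rep(pheno$id, each = window_years),
                                             age = rep(ages, n),
                                             indicator = "education", value = v)
    }
    if ("occupation" %in% names(pheno)) {
      v <- pmin(78, pmax(13, 45 + 12 * rep(pheno$occupation, each = window_years) +
                           stats::rnorm(n * window_years, 0, 10 * noise_sd)))
      panel[["occupation"]] <- tibble::tibble(id = rep(pheno$id, each = window_years),
                                              age = rep(ages, n),
                                              indicator = "occupation", value = v)
    }
    dplyr::arrange(dplyr::bind_rows(panel), .data$id, .data$indicator, .data$age)
  })
}
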