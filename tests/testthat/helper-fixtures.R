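# Hand-built pedigrees and small oracles shared across tests.

# 8-person, three-generation pedigree: founder couple, their two offspring
# each mated to an unrelated founder, one grandchild each (first cousins).
ped_cousins <- function() {
  tibble::tibble(
    id = c("gf", "gm", "a", "b", "sa", "sb", "k1", "k2"),
    father = c(NA, NA, "gf", "gf", NA, NA, "a", "sb"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "sa", "b"),
    sex = c(1L, 2L, 1L, 2L, 2L, 1L, 1L, 2L),
    zygosity = NA_character_)
}

# nuclear family: two founders, two offspring
ped_nuclear <- function(zyg = NA_character_) {
  tibble::tibble(
    id = c("f", "m", "c1", "c2"),
    father = c(NA, NA, "f", "f"),
    mother = c(NA, NA, "m", "m"),
    sex = c(1L, 2L, 1L, 1L),
    zygosity = c(NA, NA, zyg, zyg))
}

# paternal half siblings
ped_halfsibs <- function() {
  tibble::tibble(
    id = c("f", "m1", "m2", "c1", "c2"),
    father = c(NA, NA, NA, "f", "f"),
    mother = c(NA, NA, NA, "m1", "m2"),
    sex = c(1L, 2L, 2L, 1L, 1L),
    zygosity = NA_character_)
}

# Independent gene-dropping oracle for expected relatedness: label founder
# alleles uniquely, drop n_loci independent loci through the pedigree, and
# return the mean proportion of alleles shared identical by descent between
# id1 and id2 (which estimates 2 * kinship for non-inbred pairs).
gene_drop_relatedness <- function(ped, id1, id2, n_loci = 1e5, seed = 1) {
  ped <- sesherit::as_pedigree(ped)
  set.seed(seed)
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  depth <- rep(0L, n)
  repeat {
    new <- ifelse(is.na(fa), 0L, pmax(depth[fa], depth[mo], na.rm = TRUE) + 1L)
    new[is.na(new)] <- 0L
    if (identical(new, depth)) break
    depth <- new
  }
  A1 <- matrix(0L, n, n_loci)
  A2 <- matrix(0L, n, n_loci)
  lab <- 1L
  for (i in order(depth)) {
    if (is.na(fa[i])) {
      A1[i, ] <- lab; A2[i, ] <- lab + 1L; lab <- lab + 2L
    } else {
      pick <- stats::runif(n_loci) < 0.5
      A1[i, ] <- ifelse(pick, A1[fa[i], ], A2[fa[i], ])
      pick <- stats::runif(n_loci) < 0.5
      A2[i, ] <- ifelse(pick, A1[mo[i], ], A2[mo[i], ])
    }
  }
  i <- match(id1, ped$id); j <- match(id2, ped$id)
  shared <- (A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
    (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])
  mean(shared) / 2
}

# Bivariate-normal pair generator for the pair-likelihood fits (independent
# of the package's family simulator): n pairs with member correlation r.
make_corr_pairs <- function(n, r, relationship, r_g, r_c_label = "sib",
                            prefix = relationship) {
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  tibble::tibble(id1 = paste0(prefix, seq_len(n), "a"),
                 id2 = paste0(prefix, seq_len(n), "b"),
                 relationship = relationship, r_g = r_g,
                 r_c_label = r_c_label, y1 = z1, y2 = z2)
}

# exact method-of-moments ACE solution for a two-class (sib + cousin) design
# with rc_sib = 1, rc_cousin fixed: solves r_s = 0.5 a2 + c2,
# r_k = 0.125 a2 + rc * c2 on the standardized scale.
mom_ace_two_class <- function(r_s, r_k, rc_cousin = 0) {
  a2 <- (r_s - r_k / rc_cousin) / (0.5 - 0.125 / rc_cousin)
  if (rc_cousin == 0) a2 <- r_k / 0.125
  c2 <- r_s - 0.5 * a2
  c(a2 = a2, c2 = c2, e2 = 1 - a2 - c2)
}
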